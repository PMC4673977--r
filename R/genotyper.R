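# Emission model ---------------------------------------------------------
#
# Observations fall into 8 classes (Watson A/C/G/T, Crick A/C/G/T, reference
# orientation). An unambiguous observation of base b under genotype {a1,a2}
# has emission 1/2 p(b|a1) + 1/2 p(b|a2) with p(b|a) = 1-err if b == a else
# err/3. The two bisulfite-ambiguous classes (Watson T, Crick A) are split
# equally over their two compatible bases ({C,T} and {A,G}), i.e.
# q(a) = 1/2 [p(b1|a) + p(b2|a)]. Every emission is linear in err, so the
# 8 x 10 emission matrix is A0 + err * B with constant A0, B.

# compatible-base sets per class, in OBS_CLASSES order
CLASS_SPLIT <- list(
  "A", "C", "G", c("C", "T"),   # Watson A,C,G,T
  c("A", "G"), "C", "G", "T"    # Crick A,C,G,T
)

emission_coefs <- local({
  A0 <- matrix(0, 8, 10, dimnames = list(OBS_CLASSES, GENOTYPES))
  B <- A0
  for (i in 1:8) {
    S <- CLASS_SPLIT[[i]]
    for (g in 1:10) {
      a <- GT_ALLELES[g, ]
      nm <- c(a[1] %in% S, a[2] %in% S)
      # q(a) = (nm*(1-err) + (|S|-nm)*err/3) / |S|; emission = mean over alleles
      A0[i, g] <- mean(nm / length(S))
      B[i, g] <- mean((-nm + (length(S) - nm) / 3) / length(S))
    }
  }
  list(A0 = A0, B = B)
})

#' Average sequencing error rate at a site
#'
#' A single per-site error probability replaces per-read error modelling: each
#' retained observation class contributes `10^(-Qbar/10)` where `Qbar` is its
#' mean Phred quality (`qual_sum / count`), and the contributions are averaged
#' over all retained observations. Clamped to `[1e-4, 0.5]`.
#'
#' @param profile A [strand_profile()].
#' @return Error probability in `[1e-4, 0.5]`.
#' @export
#' @examples
#' average_error_rate(strand_profile(watson_count = c(A = 10),
#'                                   watson_qual_sum = c(A = 200)))
average_error_rate <- function(profile) {
  counts <- c(profile$watson_count, profile$crick_count)
  quals <- c(profile$watson_qual_sum, profile$crick_qual_sum)
  tot <- sum(counts)
  if (tot <= 0) bs_abort("zero depth: error rate undefined", "bsvar_data_error")
  nz <- counts > 0
  per_class <- 10^(-(quals[nz] / counts[nz]) / 10)
  clamp_err(sum(counts[nz] * per_class) / tot)
}

clamp_err <- function(e) pmin(pmax(e, 1e-4), 0.5)

# Vectorised core: counts (n x 8), err (length n) -> n x 10 log-likelihoods.
genotype_log_likelihoods <- function(counts, err) {
  counts <- matrix(counts, ncol = 8L)
  n <- nrow(counts)
  ll <- matrix(0, n, 10L, dimnames = list(NULL, GENOTYPES))
  A0 <- emission_coefs$A0
  B <- emission_coefs$B
  for (g in 1:10) {
    e <- matrix(A0[, g], n, 8L, byrow = TRUE) + outer(err, B[, g])
    ll[, g] <- rowSums(counts * log(e))
  }
  ll
}

#' Likelihood of a genotype given site observations
#'
#' `P(D|G)` as the product over independent observations of the per-read
#' emission probability, with bisulfite-ambiguous classes split equally over
#' their compatible bases. Computed in log space; an empty site returns 1 for
#' every genotype.
#'
#' @param profile A [strand_profile()].
#' @param genotype Two-letter genotype, e.g. `"AC"`.
#' @param err Per-site error probability in `(0, 0.5]`.
#' @return Likelihood in `(0, 1]`.
#' @export
#' @examples
#' likelihood(strand_profile(watson_count = c(A = 10)), "AA", 0.01)
likelihood <- function(profile, genotype, err) {
  g <- match(norm_gt(genotype), GENOTYPES)
  if (is.na(g)) bs_abort("unknown genotype", "bsvar_usage_error")
  counts <- c(profile$watson_count, profile$crick_count)
  unname(exp(genotype_log_likelihoods(counts, err)[1, g]))
}

norm_gt <- function(genotype) {
  a <- sort(strsplit(toupper(genotype), "")[[1]])
  paste(a, collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Prior vector over the ten genotypes for a reference base
#'
#' @param ref_base Reference base A/C/G/T.
#' @param prior A [genotype_prior()].
#' @return Named numeric vector of 10 probabilities summing to 1.
#' @export
prior_vector <- function(ref_base, prior = genotype_prior()) {
  ref_base <- toupper(ref_base)
  if (!ref_base %in% BASES) bs_abort("reference base must be A/C/G/T", "bsvar_usage_error")
  w <- numeric(10)
  for (g in 1:10) {
    a <- GT_ALLELES[g, ]
    n_ref <- sum(a == ref_base)
    w[g] <- if (n_ref == 2) prior$ref_hom
      else if (n_ref == 1) prior$het_with_ref
      else if (a[1] == a[2]) prior$non_ref_hom
      else prior$het_with_ref * prior$non_ref_hom
    if (TRANSITION[ref_base] %in% a) w[g] <- w[g] * prior$ts_tv_weight
  }
  setNames(w / sum(w), GENOTYPES)
}

#' Posterior over the ten diploid genotypes at a site
#'
#' Bayes' rule over the ten genotypes: `P(G|D) = P(G) P(D|G) / sum_G' P(G')
#' P(D|G')`, with the product likelihood evaluated in log space and the
#' SOAPsnp-style prior of [prior_vector()]. With no observations the posterior
#' equals the normalised prior.
#'
#' @param profile A [strand_profile()].
#' @param ref_base Reference base at the site.
#' @param prior A [genotype_prior()].
#' @param err Per-site error probability; by default computed with
#'   [average_error_rate()] (an empty profile uses 0.01).
#' @return Named numeric vector of 10 posterior probabilities summing to 1.
#' @export
#' @examples
#' posterior(strand_profile(watson_count = c(A = 30), crick_count = c(A = 10)), "A")
posterior <- function(profile, ref_base, prior = genotype_prior(), err = NULL) {
  if (is.null(err)) {
    err <- if (profile_depth(profile) > 0) average_error_rate(profile) else 0.01
  }
  counts <- c(profile$watson_count, profile$crick_count)
  lp <- genotype_log_likelihoods(counts, clamp_err(err))[1, ] +
    log(prior_vector(ref_base, prior))
  lp <- lp - max(lp)
  p <- exp(lp)
  setNames(p / sum(p), GENOTYPES)
}

# Vectorised posterior over many sites. counts: n x 8; err, ref: length n.
# Returns list(post = n x 10 matrix, gt = argmax genotype with ties broken
# toward the genotype containing the reference then lexicographically).
posterior_matrix <- function(counts, ref, prior = genotype_prior(), err) {
  counts <- matrix(counts, ncol = 8L)
  n <- nrow(counts)
  lp <- genotype_log_likelihoods(counts, clamp_err(err))
  pv <- vapply(BASES, prior_vector, numeric(10), prior = prior)  # 10 x 4
  lp <- lp + t(log(pv[, match(ref, BASES), drop = FALSE]))
  mx <- do.call(pmax, as.data.frame(lp))
  p <- exp(lp - mx)
  post <- p / rowSums(p)
  gt <- GENOTYPES[apply_argmax(post, ref)]
  list(post = post, gt = gt)
}

# Argmax with tie-breaking: highest posterior; among exact ties prefer a
# genotype containing the reference allele, then lexicographic order.
apply_argmax <- function(post, ref) {
  vapply(seq_len(nrow(post)), function(i) {
    p <- post[i, ]
    best <- which(p == max(p))
    if (length(best) > 1L) {
      with_ref <- best[GT_ALLELES[best, 1] == ref[i] | GT_ALLELES[best, 2] == ref[i]]
      if (length(with_ref)) best <- with_ref
    }
    best[1L]
  }, integer(1))
}

#' Call the genotype at a candidate site
#'
#' Runs the approximate Bayesian genotyper at one site and returns the
#' maximum-posterior genotype with its quality and filter status. Sites whose
#' retained depth falls outside `[min_cover, max_cover]` are rejected.
#'
#' @param profile A [strand_profile()].
#' @param ref_base Reference base at the site.
#' @param prior A [genotype_prior()].
#' @param params A [filter_params()].
#' @param pos Optional 1-based position carried into the result.
#' @return One-row tibble: `pos`, `ref`, `genotype`, `posterior`,
#'   `phred_quality` (`round(-10 log10(1 - posterior))`, capped at 1000),
#'   `depth`, `err`, `filter` (`PASS`, `LowQual` when quality < 10, `LowFreq`
#'   for a homozygous-alternate call whose alternate frequency is below
#'   `min_hom_freq`) and `is_variant`.
#' @export
#' @examples
#' call_site(strand_profile(watson_count = c(A = 8, G = 7),
#'                          crick_count = c(A = 0, G = 5)), "A")
call_site <- function(profile, ref_base, prior = genotype_prior(),
                      params = filter_params(), pos = NA_integer_) {
  depth <- profile_depth(profile)
  if (depth < params$min_cover || depth > params$max_cover) {
    bs_abort(
      paste0("site depth ", depth, " outside [", params$min_cover, ", ",
             params$max_cover, "]"),
      "bsvar_depth_error"
    )
  }
  err <- average_error_rate(profile)
  res <- posterior_matrix(
    rbind(c(profile$watson_count, profile$crick_count)),
    ref_base, prior, err
  )
  finalize_calls(
    tibble(pos = as.integer(pos), ref = ref_base, depth = as.integer(depth), err = err),
    res, params
  )
}

# Shared between call_site and the pipeline: derive quality, filter flags and
# variant status from a posterior_matrix() result.
finalize_calls <- function(sites, res, params) {
  post <- res$post[cbind(seq_len(nrow(res$post)), match(res$gt, GENOTYPES))]
  pq <- round(-10 * log10(pmax(1 - post, 1e-100)))
  pq <- as.integer(pmin(pq, 1000L))
  gt <- res$gt
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 2, 2)
  is_variant <- !(a1 == sites$ref & a2 == sites$ref)
  hom_alt <- a1 == a2 & a1 != sites$ref

  # alt frequency from effective counts where the profile columns are present
  alt_freq <- rep(NA_real_, nrow(sites))
  if (all(paste0("eff_", BASES) %in% names(sites))) {
    effm <- as.matrix(sites[paste0("eff_", BASES)])
    tot <- rowSums(effm)
    af <- effm[cbind(seq_len(nrow(sites)), match(a1, BASES))]
    alt_freq <- ifelse(tot > 0, af / tot, NA_real_)
  }
  filter <- rep("PASS", nrow(sites))
  filter[hom_alt & !is.na(alt_freq) & alt_freq < params$min_hom_freq] <- "LowFreq"
  filter[pq < 10L] <- "LowQual"

  dplyr::bind_cols(
    sites,
    tibble(genotype = gt, posterior = post, phred_quality = pq,
           filter = filter, is_variant = is_variant)
  )
}
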