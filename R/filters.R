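#' Admit or reject an alignment
#'
#' Read-level admission: a mapped read enters the pileup when it is primary,
#' not a duplicate, not QC-failed, has mapping quality at or above
#' `min_map_quality`, and its bisulfite-adjusted mismatch rate (mismatches per
#' aligned base, excluding Watson-strand C→T and Crick-strand G→A differences,
#' which are expected conversions rather than errors) does not exceed
#' `max_mismatch_rate`.
#'
#' @param read List or one-row data frame with `flag`, `mapq`, `pos`, `cigar`,
#'   `seq`, `qual` and `bs_strand` ("W"/"C").
#' @param params A [filter_params()].
#' @param reference Reference sequence of the read's chromosome (string, base
#'   vector or `DNAString`). When `NULL`, the mismatch-rate test is skipped.
#' @return List: `admitted` (logical) and `reason` (`NA` or the first failed
#'   test: `"secondary"`, `"duplicate"`, `"qc_fail"`, `"map_quality"`,
#'   `"mismatch_rate"`).
#' @export
#' @examples
#' admit_read(list(flag = 0L, mapq = 5L, pos = 1L, cigar = "4M",
#'                 seq = "ACGT", qual = "IIII", bs_strand = "W"),
#'            filter_params())
admit_read <- function(read, params = filter_params(), reference = NULL) {
  flag <- read$flag %||% 0L
  if (bitwAnd(flag, 4L) > 0L) {
    bs_abort("admit_read requires a mapped read", "bsvar_usage_error")
  }
  if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) {
    return(list(admitted = FALSE, reason = "secondary"))
  }
  if (bitwAnd(flag, 1024L) > 0L) {
    return(list(admitted = FALSE, reason = "duplicate"))
  }
  if (bitwAnd(flag, 512L) > 0L) {
    return(list(admitted = FALSE, reason = "qc_fail"))
  }
  if ((read$mapq %||% 0L) < params$min_map_quality) {
    return(list(admitted = FALSE, reason = "map_quality"))
  }
  if (!is.null(reference)) {
    mr <- mismatch_rate(read, reference)
    if (!is.na(mr) && mr > params$max_mismatch_rate) {
      return(list(admitted = FALSE, reason = "mismatch_rate"))
    }
  }
  list(admitted = TRUE, reason = NA_character_)
}

#' Bisulfite-adjusted mismatch rate of one read
#'
#' Fraction of aligned (CIGAR M/=/X) bases differing from the reference, after
#' excluding the expected conversions: C→T on Watson-strand reads and G→A on
#' Crick-strand reads (reference orientation). Ambiguous (N) bases on either
#' side are dropped from numerator and denominator.
#'
#' @inheritParams admit_read
#' @return Mismatch fraction in `[0, 1]`, or `NA` for a read with no aligned
#'   bases.
#' @export
mismatch_rate <- function(read, reference) {
  refv <- as_base_vector(reference)
  al <- cigar_aligned(read$cigar, as.integer(read$pos))
  if (length(al$rpos) == 0L) return(NA_real_)
  if (max(al$rpos) > length(refv)) {
    bs_abort("read extends beyond reference", "bsvar_coordinate_error")
  }
  rb <- refv[al$rpos]
  qb <- toupper(substring(read$seq, al$qpos, al$qpos))
  ok <- rb %in% BASES & qb %in% BASES
  rb <- rb[ok]; qb <- qb[ok]
  if (length(rb) == 0L) return(NA_real_)
  mm <- qb != rb
  if (identical(read$bs_strand, "C")) {
    mm <- mm & !(rb == "G" & qb == "A")
  } else {
    mm <- mm & !(rb == "C" & qb == "T")
  }
  sum(mm) / length(rb)
}

# Vectorised admission over a reads tibble; returns the tibble with `admitted`
# and `reason` columns. Mismatch rates are computed against the chromosome
# reference in one expansion pass.
admit_reads <- function(reads, reference, params = filter_params()) {
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  flag <- reads$flag
  reason[is.na(reason) & (bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L)] <- "secondary"
  reason[is.na(reason) & bitwAnd(flag, 1024L) > 0L] <- "duplicate"
  reason[is.na(reason) & bitwAnd(flag, 512L) > 0L] <- "qc_fail"
  reason[is.na(reason) & reads$mapq < params$min_map_quality] <- "map_quality"

  todo <- which(is.na(reason))
  if (length(todo) > 0 && !is.null(reference)) {
    refv <- as_base_vector(reference)
    mr <- vapply(todo, function(i) {
      mismatch_rate(reads[i, ], refv)
    }, numeric(1))
    reason[todo[!is.na(mr) & mr > params$max_mismatch_rate]] <- "mismatch_rate"
  }
  reads$admitted <- is.na(reason)
  reads$reason <- reason
  reads
}

#' Effective allele frequency at a site
#'
#' `freq(X) = effCount(X) / sum_b effCount(b)`, where effective counts exclude
#' the bisulfite-ambiguous observation classes (Watson T, Crick A; see
#' [effective_counts()]). Frequencies over the four alleles sum to 1.
#'
#' @param profile A [strand_profile()].
#' @param allele Base whose frequency is wanted.
#' @param ref_base Reference base at the site (part of the call signature for
#'   symmetry with the candidate screen; the frequency itself does not depend
#'   on it).
#' @return Frequency in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(strand_profile(watson_count = c(A = 9, G = 1)), "G", "A")
allele_frequency <- function(profile, allele, ref_base = NULL) {
  allele <- toupper(allele)
  if (!allele %in% BASES) bs_abort("allele must be A/C/G/T", "bsvar_usage_error")
  ec <- effective_counts(profile)
  tot <- sum(ec$eff_count)
  if (tot <= 0) {
    bs_abort("zero effective depth: frequency undefined", "bsvar_data_error")
  }
  unname(ec$eff_count[allele] / tot)
}

#' Screen a site's allele frequencies for candidate alleles
#'
#' Keeps every non-reference allele whose effective frequency is at least
#' `min_het_freq` **and** whose effective count is at least `min_alt_reads`;
#' the site is dropped when no allele survives.
#'
#' @param freqs Named (A/C/G/T) frequencies summing to 1.
#' @param ref_base Reference base.
#' @param eff_counts Named effective counts (used for the `min_alt_reads`
#'   gate; when `NULL` the count gate is skipped).
#' @param params A [filter_params()].
#' @return List: `keep` (logical) and `candidate_alleles` (character vector,
#'   possibly empty).
#' @export
#' @examples
#' classify_candidate(c(A = 0.95, C = 0, G = 0.05, T = 0), "A")
classify_candidate <- function(freqs, ref_base, eff_counts = NULL,
                               params = filter_params()) {
  f <- setNames(numeric(4), BASES)
  f[names(freqs)] <- freqs
  cand <- names(f)[f >= params$min_het_freq & names(f) != ref_base]
  if (!is.null(eff_counts)) {
    cand <- cand[eff_counts[cand] >= params$min_alt_reads]
  }
  list(keep = length(cand) > 0, candidate_alleles = cand)
}
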