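# Shared fixtures and the independent brute-force genotyping oracle.

qstr <- function(q, n) strrep(intToUtf8(q + 33L), n)

make_read <- function(pos, seq, cigar = paste0(nchar(seq), "M"), q = 30L,
                      flag = 0L, mapq = 60L, strand = "W", qname = "r1",
                      chrom = "chr1") {
  tibble::tibble(
    qname = qname, flag = as.integer(flag), chrom = chrom,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    seq = seq, qual = qstr(q, nchar(seq)), bs_strand = strand
  )
}

# Write a SAM file from a reads tibble (adds XG strand tags).
write_test_sam <- function(reads, seqinfo, path = tempfile(fileext = ".sam")) {
  reads$xg <- ifelse(reads$bs_strand == "W", "CT", "GA")
  reads$zs <- ifelse(reads$bs_strand == "W", "++", "-+")
  bsvar::write_sam(reads, seqinfo, path)
  path
}

write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  path
}

# Independent brute-force oracle: expands a strand profile into individual
# observations and evaluates prior x product-likelihood over an explicit
# enumeration of the ten diploid genotypes, in plain (non-log) arithmetic.
oracle_posterior <- function(profile, ref, prior = bsvar::genotype_prior()) {
  bases <- c("A", "C", "G", "T")
  obs_strand <- character(0)
  obs_base <- character(0)
  obs_err <- numeric(0)
  for (s in c("W", "C")) {
    cnt <- if (s == "W") profile$watson_count else profile$crick_count
    qs <- if (s == "W") profile$watson_qual_sum else profile$crick_qual_sum
    for (b in bases) {
      n <- cnt[[b]]
      if (n > 0) {
        obs_strand <- c(obs_strand, rep(s, n))
        obs_base <- c(obs_base, rep(b, n))
        obs_err <- c(obs_err, rep(10^(-(qs[[b]] / n) / 10), n))
      }
    }
  }
  err <- if (length(obs_err)) min(max(mean(obs_err), 1e-4), 0.5) else 0.01

  # emission of one observation given a single allele
  p_single <- function(b, a) if (b == a) 1 - err else err / 3
  emit_allele <- function(strand, b, a) {
    if (strand == "W" && b == "T") {
      0.5 * (p_single("C", a) + p_single("T", a))
    } else if (strand == "C" && b == "A") {
      0.5 * (p_single("A", a) + p_single("G", a))
    } else {
      p_single(b, a)
    }
  }

  gts <- unique(t(apply(expand.grid(bases, bases, stringsAsFactors = FALSE),
                        1, sort)))
  gt_names <- apply(gts, 1, paste, collapse = "")

  lik <- vapply(seq_len(nrow(gts)), function(g) {
    a1 <- gts[g, 1]; a2 <- gts[g, 2]
    pr <- 1
    for (i in seq_along(obs_base)) {
      pr <- pr * 0.5 * (emit_allele(obs_strand[i], obs_base[i], a1) +
                        emit_allele(obs_strand[i], obs_base[i], a2))
    }
    pr
  }, numeric(1))

  transition <- c(A = "G", G = "A", C = "T", T = "C")
  pw <- vapply(seq_len(nrow(gts)), function(g) {
    a <- gts[g, ]
    nref <- sum(a == ref)
    w <- if (nref == 2) prior$ref_hom
      else if (nref == 1) prior$het_with_ref
      else if (a[1] == a[2]) prior$non_ref_hom
      else prior$het_with_ref * prior$non_ref_hom
    if (transition[[ref]] %in% a) w <- w * prior$ts_tv_weight
    w
  }, numeric(1))
  pw <- pw / sum(pw)

  post <- pw * lik
  post <- post / sum(post)
  names(post) <- gt_names

  best <- which(post == max(post))
  if (length(best) > 1) {
    with_ref <- best[gts[best, 1] == ref | gts[best, 2] == ref]
    if (length(with_ref)) best <- with_ref
  }
  list(posterior = post, genotype = gt_names[best[1]], err = err)
}

# Random strand profile with integer per-class mean qualities.
random_profile <- function(max_depth = 50) {
  depth <- sample.int(max_depth, 1)
  probs <- runif(8)
  counts <- as.vector(rmultinom(1, depth, probs / sum(probs)))
  meanq <- sample(10:40, 8, replace = TRUE)
  bsvar::strand_profile(
    watson_count = counts[1:4], crick_count = counts[5:8],
    watson_qual_sum = counts[1:4] * meanq[1:4],
    crick_qual_sum = counts[5:8] * meanq[5:8]
  )
}
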