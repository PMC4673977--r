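#' Bisulfite-effective base counts at a site
#'
#' Bisulfite conversion turns unmethylated cytosines into observed thymines, so
#' a Watson-strand T observation cannot be attributed to a genomic T or an
#' unmethylated genomic C, and a Crick-strand A observation (reference
#' orientation: the converted base of the opposite strand) is likewise
#' ambiguous between genomic A and unmethylated genomic G. Both classes are
#' excluded from the effective counts and reported as ambiguity tallies;
#' every other observation passes through. Consequently C-versus-T
#' discrimination rests on Crick reads and G-versus-A discrimination on
#' Watson reads.
#'
#' @param profile A [strand_profile()].
#' @return List with `eff_count` (named A/C/G/T support), `ambiguous_watson_T`
#'   and `ambiguous_crick_A`.
#' @export
#' @examples
#' effective_counts(strand_profile(watson_count = c(T = 10), crick_count = c(G = 10)))
effective_counts <- function(profile) {
  w <- profile$watson_count
  k <- profile$crick_count
  eff <- c(
    A = unname(w["A"]),
    C = unname(w["C"] + k["C"]),
    G = unname(w["G"] + k["G"]),
    T = unname(k["T"])
  )
  list(
    eff_count = eff,
    ambiguous_watson_T = unname(w["T"]),
    ambiguous_crick_A = unname(k["A"])
  )
}

# Vectorised effective counts over a full pileup count matrix (n x 8,
# OBS_CLASSES order). Returns effective count matrix (n x 4) and ambiguity
# vectors.
effective_count_matrix <- function(counts) {
  eff <- cbind(
    A = counts[, "W_A"],
    C = counts[, "W_C"] + counts[, "C_C"],
    G = counts[, "W_G"] + counts[, "C_G"],
    T = counts[, "C_T"]
  )
  list(eff = eff, amb_wT = counts[, "W_T"], amb_cA = counts[, "C_A"])
}

#' Methylation context of a cytosine
#'
#' Standard two-base downstream classification on the strand carrying the
#' cytosine: CpG when the next base is G; CHG when the pattern is C-H-G
#' (H in A/C/T); CHH otherwise. For a Crick-strand cytosine (reference base G)
#' the context is read on the reverse complement, i.e. upstream on the
#' reference. Positions within two bases of the sequence end are
#' undetermined (`NA`).
#'
#' @param pos 1-based position(s) of the cytosine on the reference.
#' @param sequence Genotype-corrected chromosome sequence (string, base vector
#'   or `DNAString`).
#' @param strand `"+"` for Watson-strand cytosines (sequence base C), `"-"`
#'   for Crick-strand cytosines (sequence base G). Recycled against `pos`.
#' @return Character vector: `"CpG"`, `"CHG"`, `"CHH"` or `NA`.
#' @export
#' @examples
#' context_of(1, "CGT")
#' context_of(3, "ACG", strand = "-")
context_of <- function(pos, sequence, strand = "+") {
  s <- as_base_vector(sequence)
  n <- length(s)
  strand <- rep_len(strand, length(pos))
  b1 <- b2 <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  ok_p <- plus & pos + 2L <= n
  b1[ok_p] <- s[pos[ok_p] + 1L]
  b2[ok_p] <- s[pos[ok_p] + 2L]
  minus <- !plus
  ok_m <- minus & pos - 2L >= 1L
  b1[ok_m] <- COMPLEMENT[s[pos[ok_m] - 1L]]
  b2[ok_m] <- COMPLEMENT[s[pos[ok_m] - 2L]]
  out <- rep(NA_character_, length(pos))
  det <- !is.na(b1) & !is.na(b2) & b1 %in% BASES & b2 %in% BASES
  out[det & b1 == "G"] <- "CpG"
  out[det & b1 != "G" & b2 == "G"] <- "CHG"
  out[det & b1 != "G" & b2 != "G"] <- "CHH"
  out
}

#' Methylation level at a genotyped cytosine
#'
#' After genotyping, methylation is read from the conversion-informative
#' strand only: a site whose called genotype contains C on the Watson strand
#' is scored as `watson C / (watson C + watson T)`; a site whose genotype
#' contains G (a Crick-strand cytosine) as `crick G / (crick G + crick A)`.
#' A genotype that removes the cytosine (e.g. a TT homozygote at a reference
#' C) yields no methylation record.
#'
#' @param profile A [strand_profile()].
#' @param genotype Two-letter genotype string, e.g. `"CC"`, `"CT"`.
#' @param context `"CpG"`, `"CHG"` or `"CHH"` (carried through to the record).
#' @param strand `"+"` to score the Watson-strand cytosine, `"-"` for the
#'   Crick-strand cytosine.
#' @param ref Optional reference base; when given, the record's
#'   `genotype_corrected` flag marks genotypes other than the reference
#'   homozygote (otherwise heterozygotes are flagged).
#' @return One-row tibble (`strand`, `context`, `meth_count`, `total_count`,
#'   `level`, `genotype_corrected`), or a zero-row tibble when the genotype
#'   has no cytosine on that strand. Zero informative depth gives `level = NA`.
#' @export
#' @examples
#' methylation_call(strand_profile(watson_count = c(C = 7, T = 3)), "CC", "CpG")
methylation_call <- function(profile, genotype, context, strand = "+", ref = NULL) {
  alleles <- strsplit(genotype, "")[[1]]
  want <- if (strand == "+") "C" else "G"
  if (!want %in% alleles) {
    return(tibble(strand = character(), context = character(),
                  meth_count = numeric(), total_count = numeric(),
                  level = numeric(), genotype_corrected = logical()))
  }
  if (strand == "+") {
    m <- unname(profile$watson_count["C"])
    tot <- m + unname(profile$watson_count["T"])
  } else {
    m <- unname(profile$crick_count["G"])
    tot <- m + unname(profile$crick_count["A"])
  }
  tibble(
    strand = strand, context = context,
    meth_count = m, total_count = tot,
    level = if (tot > 0) m / tot else NA_real_,
    genotype_corrected = if (is.null(ref)) alleles[1] != alleles[2]
                         else genotype != paste0(ref, ref)
  )
}

# Genome-wide methylation extraction from a filled chrom_matrix.
#
# corrected: chromosome sequence with homozygous-alternate calls substituted.
# calls: tibble of genotyped candidate sites (pos, genotype) used to decide,
# at variant sites, whether a cytosine remains in the genotype. Non-candidate
# positions are treated as reference homozygotes.
extract_methylation <- function(matrix, corrected, calls = NULL, chrom = matrix$chrom_name) {
  s <- as_base_vector(corrected)[seq_len(matrix$length)]
  has_c <- s == "C"
  has_g <- s == "G"
  corrected_site <- rep(FALSE, matrix$length)
  if (!is.null(calls) && nrow(calls) > 0) {
    a1 <- substr(calls$genotype, 1, 1)
    a2 <- substr(calls$genotype, 2, 2)
    has_c[calls$pos] <- a1 == "C" | a2 == "C"
    has_g[calls$pos] <- a1 == "G" | a2 == "G"
    corrected_site[calls$pos] <- calls$genotype != paste0(calls$ref, calls$ref)
  }

  counts <- matrix$counts
  rows <- list()

  wpos <- which(has_c)
  if (length(wpos)) {
    m <- counts[wpos, "W_C"]
    tot <- m + counts[wpos, "W_T"]
    keep <- tot > 0
    rows$watson <- tibble(
      chrom = chrom, pos = wpos[keep], strand = "+",
      context = context_of(wpos[keep], s, "+"),
      meth_count = as.numeric(m[keep]), total_count = as.numeric(tot[keep]),
      level = m[keep] / tot[keep],
      genotype_corrected = corrected_site[wpos[keep]]
    )
  }
  cpos <- which(has_g)
  if (length(cpos)) {
    m <- counts[cpos, "C_G"]
    tot <- m + counts[cpos, "C_A"]
    keep <- tot > 0
    rows$crick <- tibble(
      chrom = chrom, pos = cpos[keep], strand = "-",
      context = context_of(cpos[keep], s, "-"),
      meth_count = as.numeric(m[keep]), total_count = as.numeric(tot[keep]),
      level = m[keep] / tot[keep],
      genotype_corrected = corrected_site[cpos[keep]]
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), meth_count = numeric(),
                  total_count = numeric(), level = numeric(),
                  genotype_corrected = logical()))
  }
  arrange(out, .data$pos, .data$strand)
}
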