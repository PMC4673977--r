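#' Compare called SNPs against a simulated truth set
#'
#' Confusion summary of a call set against planted truth: a call at a position
#' absent from the truth is a false positive, a truth SNP with no call is a
#' false negative, and genotype concordance is computed over the matched
#' positions. `FPR = FP / (TP + FP)` (fraction of calls not confirmed) and
#' `FNR = FN / n_truth`, mirroring exome-validation bookkeeping.
#'
#' @param called A `bs_calls` object, a tibble with `chrom`, `pos`,
#'   `genotype` (variant rows), or a VCF path (parsed with the vcfR package).
#' @param truth A `bs_simulation`, `bs_genome`, or tibble with `chrom`, `pos`,
#'   `ref`, `genotype`.
#' @param pass_only Count only `PASS`-filter variants as called (the final SNP
#'   set); set `FALSE` to include filtered (`LowQual`/`LowFreq`) calls.
#' @return A `bs_eval` list: `summary` (one-row tibble with `n_called`,
#'   `n_truth`, `tp`, `fp`, `fn`, `fpr`, `fnr`, `concordance`) and `matched`
#'   (per-position join of calls and truth).
#' @export
#' @examples
#' sim <- bs_simulate(sim_params(genome_length = 3000), seed = 11,
#'                    out_prefix = tempfile())
#' res <- bs_call(sim$paths[["sam"]], sim$paths[["ref"]], quiet = TRUE)
#' evaluate_calls(res, sim)$summary
evaluate_calls <- function(called, truth, pass_only = TRUE) {
  calls <- extract_variant_table(called, pass_only = pass_only)
  truth_snps <- extract_truth_table(truth)
  if (nrow(calls) > 0 && nrow(truth_snps) > 0) {
    common <- intersect(unique(calls$chrom), unique(truth_snps$chrom))
    if (length(common) == 0) {
      bs_abort("call set and truth share no chromosome names", "bsvar_data_error")
    }
  }
  matched <- dplyr::full_join(
    calls %>% rename(called_genotype = "genotype"),
    truth_snps %>% rename(truth_genotype = "genotype"),
    by = c("chrom", "pos")
  )
  tp <- sum(!is.na(matched$called_genotype) & !is.na(matched$truth_genotype))
  fp <- sum(!is.na(matched$called_genotype) & is.na(matched$truth_genotype))
  fn <- sum(is.na(matched$called_genotype) & !is.na(matched$truth_genotype))
  both <- !is.na(matched$called_genotype) & !is.na(matched$truth_genotype)
  concordance <- if (any(both)) {
    mean(matched$called_genotype[both] == matched$truth_genotype[both])
  } else {
    NA_real_
  }
  summary <- tibble(
    n_called = tp + fp, n_truth = tp + fn,
    tp = tp, fp = fp, fn = fn,
    fpr = if (tp + fp > 0) fp / (tp + fp) else 0,
    fnr = if (tp + fn > 0) fn / (tp + fn) else 0,
    concordance = concordance
  )
  structure(list(summary = summary, matched = as_tibble(matched)),
            class = "bs_eval")
}

extract_variant_table <- function(called, pass_only = TRUE) {
  if (inherits(called, "bs_calls")) {
    v <- called$calls[called$calls$is_variant, , drop = FALSE]
    if (pass_only) v <- v[v$filter == "PASS", , drop = FALSE]
    return(tibble(chrom = v$chrom, pos = v$pos, genotype = v$genotype))
  }
  if (is.character(called) && length(called) == 1L) {
    return(read_vcf_genotypes(called, pass_only = pass_only))
  }
  if (is.data.frame(called)) {
    need <- c("chrom", "pos", "genotype")
    if (!all(need %in% names(called))) {
      bs_abort("call table needs chrom, pos, genotype columns", "bsvar_usage_error")
    }
    if ("is_variant" %in% names(called)) called <- called[called$is_variant, ]
    if (pass_only && "filter" %in% names(called)) {
      called <- called[called$filter == "PASS", ]
    }
    return(as_tibble(called[c("chrom", "pos", "genotype")]))
  }
  bs_abort("unsupported call-set input", "bsvar_usage_error")
}

extract_truth_table <- function(truth) {
  if (inherits(truth, "bs_simulation")) truth <- truth$genome
  if (inherits(truth, "bs_genome")) truth <- truth$truth_snps
  if (is.character(truth) && length(truth) == 1L) return(read_vcf_genotypes(truth))
  if (!is.data.frame(truth) || !all(c("chrom", "pos", "genotype") %in% names(truth))) {
    bs_abort("truth needs chrom, pos, genotype columns", "bsvar_usage_error")
  }
  as_tibble(truth[intersect(c("chrom", "pos", "ref", "genotype"), names(truth))])
}

# Read CHROM/POS/REF/ALT/GT from a VCF into a genotype table via vcfR.
read_vcf_genotypes <- function(path, pass_only = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    bs_abort("reading VCF call sets requires the vcfR package", "bsvar_usage_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- if (nrow(fix) > 0) vcfR::extract.gt(v, element = "GT")[, 1] else character(0)
  if (pass_only && nrow(fix) > 0) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
    gt_raw <- gt_raw[keep]
  }
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), genotype = character()))
  }
  genotype <- vapply(seq_len(nrow(fix)), function(i) {
    alleles <- c(fix$REF[i], strsplit(fix$ALT[i], ",")[[1]])
    idx <- as.integer(strsplit(gt_raw[i], "[/|]")[[1]]) + 1L
    paste(sort(alleles[idx]), collapse = "")
  }, character(1))
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), genotype = genotype)
}

#' @export
print.bs_eval <- function(x, ...) {
  cat("<bs_eval>\n")
  print(x$summary)
  invisible(x)
}
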