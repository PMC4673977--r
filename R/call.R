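#' Call SNPs and methylation from bisulfite alignments
#'
#' End-to-end two-step caller. Step 1 builds, one chromosome at a time, the
#' strand-separated pileup of base counts and quality sums from admitted reads
#' and screens positions for candidate alleles by bisulfite-effective
#' frequency. Step 2 genotypes every candidate with the approximate Bayesian
#' model (SOAPsnp-style prior, product likelihood with a per-site average
#' error rate) and keeps the maximum-posterior genotype. Methylation levels
#' are then extracted genome-wide from the genotype-corrected sequence.
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file, or the list
#'   returned by [stream_alignments()].
#' @param reference Path to the reference FASTA, or a [load_reference()]
#'   object.
#' @param params A [filter_params()].
#' @param prior A [genotype_prior()].
#' @param quiet Suppress per-chromosome progress messages.
#' @return A `bs_calls` object: `calls` (tibble of genotyped candidate sites
#'   with posteriors, qualities, filters and `is_variant`), `meth` (per-
#'   cytosine methylation tibble), `counters`, `seqinfo`, `params`, `prior`.
#' @export
#' @examples
#' sim <- bs_simulate(sim_params(genome_length = 2000, depth = 15), seed = 7,
#'                    out_prefix = tempfile())
#' res <- bs_call(sim$paths[["sam"]], sim$paths[["ref"]], quiet = TRUE)
#' dplyr::filter(res$calls, is_variant)
bs_call <- function(alignments, reference,
                    params = filter_params(), prior = genotype_prior(),
                    quiet = FALSE) {
  aln <- if (is.character(alignments)) stream_alignments(alignments) else alignments
  ref <- if (is.character(reference)) load_reference(reference) else reference

  missing_ref <- setdiff(aln$seqinfo$chrom, names(ref))
  if (length(missing_ref) > 0) {
    bs_abort(
      paste0("alignment chromosomes missing from reference: ",
             paste(missing_ref, collapse = ", "),
             " (reference has: ", paste(names(ref), collapse = ", "), ")"),
      "bsvar_data_error"
    )
  }

  counters <- list(
    reads_total = nrow(aln$reads),
    reads_admitted = 0L,
    rejected = integer(0),
    strand_fallback = aln$n_strand_fallback,
    candidates = 0L,
    variants = 0L
  )
  all_calls <- list()
  all_meth <- list()

  chroms <- intersect(aln$seqinfo$chrom, unique(aln$reads$chrom))
  for (chrom in chroms) {
    refseq <- as_base_vector(reference_chrom(ref, chrom))
    clen <- aln$seqinfo$length[aln$seqinfo$chrom == chrom]
    reads_c <- aln$reads[aln$reads$chrom == chrom, , drop = FALSE]

    reads_c <- admit_reads(reads_c, refseq, params)
    rej <- table(reads_c$reason[!reads_c$admitted])
    for (r in names(rej)) {
      prev <- if (r %in% names(counters$rejected)) counters$rejected[[r]] else 0L
      counters$rejected[r] <- prev + rej[[r]]
    }
    admitted <- reads_c[reads_c$admitted, , drop = FALSE]
    counters$reads_admitted <- counters$reads_admitted + nrow(admitted)

    # dynamic matrix: allocate -> fill -> call -> release
    mat <- allocate_matrix(chrom, clen)
    mat <- accumulate_reads(mat, admitted, min_base_quality = params$min_base_quality)

    cand <- emit_candidates(mat, refseq, params)
    counters$candidates <- counters$candidates + nrow(cand)

    calls_c <- genotype_candidates(cand, mat, prior, params)
    if (nrow(calls_c) > 0) calls_c <- dplyr::bind_cols(tibble(chrom = chrom), calls_c)

    corrected <- refseq
    if (nrow(calls_c) > 0) {
      hom_alt <- substr(calls_c$genotype, 1, 1) == substr(calls_c$genotype, 2, 2) &
        calls_c$is_variant
      corrected[calls_c$pos[hom_alt]] <- substr(calls_c$genotype[hom_alt], 1, 1)
    }
    meth_c <- extract_methylation(mat, corrected, calls = calls_c, chrom = chrom)

    counters$variants <- counters$variants + sum(calls_c$is_variant)
    all_calls[[chrom]] <- calls_c
    all_meth[[chrom]] <- meth_c
    if (!quiet) {
      message(sprintf(
        "%s: %d reads (%d admitted), %d candidates, %d variants, %d methylation records",
        chrom, nrow(reads_c), nrow(admitted), nrow(cand),
        sum(calls_c$is_variant), nrow(meth_c)
      ))
    }
    rm(mat)  # release before the next chromosome
  }

  structure(
    list(
      calls = bind_rows(all_calls),
      meth = bind_rows(all_meth),
      counters = counters,
      seqinfo = aln$seqinfo,
      params = params,
      prior = prior
    ),
    class = "bs_calls"
  )
}

# Genotype a candidate tibble against a filled chrom_matrix (vectorised).
genotype_candidates <- function(cand, mat, prior, params) {
  if (nrow(cand) == 0L) {
    return(dplyr::bind_cols(
      empty_candidates(),
      tibble(err = numeric(), genotype = character(), posterior = numeric(),
             phred_quality = integer(), filter = character(), is_variant = logical())
    ))
  }
  counts <- as.matrix(cand[OBS_CLASSES])
  qs <- mat$qual_sums[cand$pos, , drop = FALSE]
  per_class_err <- ifelse(counts > 0, 10^(-(qs / pmax(counts, 1)) / 10), 0)
  err <- clamp_err(rowSums(counts * per_class_err) / rowSums(counts))
  res <- posterior_matrix(counts, cand$ref, prior, err)
  finalize_calls(dplyr::bind_cols(cand, tibble(err = err)), res, params)
}

#' @export
print.bs_calls <- function(x, ...) {
  cat("<bs_calls>\n")
  cat(sprintf("  reads: %d total, %d admitted\n",
              x$counters$reads_total, x$counters$reads_admitted))
  if (length(x$counters$rejected)) {
    cat("  rejected:", paste(names(x$counters$rejected),
                             x$counters$rejected, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  candidate sites: %d; variant calls: %d\n",
              x$counters$candidates, x$counters$variants))
  cat(sprintf("  methylation records: %d\n", nrow(x$meth)))
  invisible(x)
}

#' Write all outputs of a calling run
#'
#' @param x A `bs_calls` object.
#' @param vcf Output VCF path.
#' @param methcg,methchg,methchh Optional per-context methylation TSV paths.
#' @return Named vector of written paths, invisibly.
#' @export
write_outputs <- function(x, vcf, methcg = NULL, methchg = NULL, methchh = NULL) {
  stopifnot(inherits(x, "bs_calls"))
  write_vcf(x$calls, vcf, seqinfo = x$seqinfo)
  meth_paths <- write_methylation(x$meth, cg = methcg, chg = methchg, chh = methchh)
  invisible(c(vcf = vcf, meth_paths))
}
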