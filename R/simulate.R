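#' Simulate a diploid genome with known SNPs and methylation levels
#'
#' Draws a uniform-random ACGT reference, plants SNPs at `snp_rate` with a
#' transition:transversion ratio of 2, makes a fraction `het_fraction` of them
#' heterozygous (alternate allele on one haplotype), and assigns every
#' cytosine of the sample (both strands) its context-specific methylation
#' level. Uses the current RNG state; call `set.seed()` first (or use
#' [bs_simulate()]) for reproducible output.
#'
#' @param params A [sim_params()].
#' @return List of class `bs_genome`: `reference`, `hap1`, `hap2` (character
#'   strings), `truth_snps` tibble (`chrom`, `pos`, `ref`, `genotype`),
#'   `truth_meth` tibble (`chrom`, `pos`, `strand`, `context`, `level`), and
#'   per-strand level vectors used by the read simulator.
#' @export
simulate_genome <- function(params = sim_params()) {
  L <- params$genome_length
  refv <- sample(BASES, L, replace = TRUE)
  hap1 <- refv
  hap2 <- refv

  snp_pos <- which(runif(L) < params$snp_rate)
  alt <- character(length(snp_pos))
  genotype <- character(length(snp_pos))
  if (length(snp_pos) > 0) {
    for (i in seq_along(snp_pos)) {
      r <- refv[snp_pos[i]]
      # ts:tv ratio 2 -> P(transition) = 2/3, each transversion 1/6
      alt[i] <- if (runif(1) < 2 / 3) TRANSITION[[r]]
                else sample(setdiff(BASES, c(r, TRANSITION[[r]])), 1)
      if (runif(1) < params$het_fraction) {
        hap2[snp_pos[i]] <- alt[i]
        genotype[i] <- paste(sort(c(r, alt[i])), collapse = "")
      } else {
        hap1[snp_pos[i]] <- alt[i]
        hap2[snp_pos[i]] <- alt[i]
        genotype[i] <- paste0(alt[i], alt[i])
      }
    }
  }
  truth_snps <- tibble(chrom = params$chrom, pos = snp_pos,
                       ref = refv[snp_pos], genotype = genotype)

  # Per-position methylation level on each strand: defined wherever either
  # haplotype carries a cytosine (Watson: base C; Crick: base G in reference
  # orientation); the level follows the context on the haplotype carrying it.
  # Cytosines too close to the ends (undetermined context) stay NA and are
  # simulated as unmethylated.
  level_for <- function(strand) {
    lev <- rep(NA_real_, L)
    ctx <- rep(NA_character_, L)
    want <- if (strand == "+") "C" else "G"
    for (hap in list(hap1, hap2)) {
      pos <- which(hap == want & is.na(lev))
      if (length(pos) == 0) next
      cx <- context_of(pos, hap, strand)
      ok <- !is.na(cx)
      lev[pos[ok]] <- params$methylation_by_context[cx[ok]]
      ctx[pos[ok]] <- cx[ok]
    }
    list(level = lev, context = ctx)
  }
  w <- level_for("+")
  k <- level_for("-")
  truth_meth <- bind_rows(
    tibble(chrom = params$chrom, pos = which(!is.na(w$level)), strand = "+",
           context = w$context[!is.na(w$level)], level = w$level[!is.na(w$level)]),
    tibble(chrom = params$chrom, pos = which(!is.na(k$level)), strand = "-",
           context = k$context[!is.na(k$level)], level = k$level[!is.na(k$level)])
  ) %>% arrange(.data$pos, .data$strand)

  structure(
    list(
      reference = paste(refv, collapse = ""),
      hap1 = paste(hap1, collapse = ""),
      hap2 = paste(hap2, collapse = ""),
      truth_snps = truth_snps,
      truth_meth = truth_meth,
      level_watson = w$level,
      level_crick = k$level,
      params = params
    ),
    class = "bs_genome"
  )
}

#' Simulate bisulfite reads from a diploid sample
#'
#' Single-end reads are drawn uniformly from both haplotypes and both original
#' strands. On a Watson-strand read each haplotype C is kept as C with
#' probability equal to its methylation level; otherwise it reads as T with
#' probability `conversion_rate`. Crick-strand reads are generated in
#' reference orientation (as a bisulfite aligner reports them): each haplotype
#' G is kept as G with its Crick-strand methylation level, else converted to A
#' with probability `conversion_rate`. Uniform sequencing errors are applied
#' after conversion, and every base carries the constant Phred quality
#' `round(-10 log10(error_rate))`. Reads are returned coordinate-sorted with
#' Bismark-style `XG` and BSMAP-style `ZS` strand tags.
#'
#' @param genome A `bs_genome` from [simulate_genome()].
#' @param params A [sim_params()] (defaults to the genome's own).
#' @return Tibble of reads (`qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`,
#'   `seq`, `qual`, `bs_strand`, `xg`, `zs`).
#' @export
simulate_reads <- function(genome, params = genome$params) {
  L <- params$genome_length
  rl <- params$read_length
  n <- max(1L, round(params$depth * L / rl))
  hap <- sample(1:2, n, replace = TRUE)
  strand <- sample(c("W", "C"), n, replace = TRUE)
  start <- sample.int(L - rl + 1L, n, replace = TRUE)

  h1 <- strsplit(genome$hap1, "")[[1]]
  h2 <- strsplit(genome$hap2, "")[[1]]
  idx <- outer(start, 0:(rl - 1L), "+")          # n x rl positions
  base <- matrix(ifelse(rep(hap == 1L, rl), h1[idx], h2[idx]), n, rl)

  lw <- genome$level_watson
  lc <- genome$level_crick
  u_meth <- matrix(runif(n * rl), n, rl)
  u_conv <- matrix(runif(n * rl), n, rl)
  is_w <- matrix(rep(strand == "W", rl), n, rl)

  lev_w <- matrix(lw[idx], n, rl)
  convert_w <- is_w & base == "C" &
    !(u_meth < ifelse(is.na(lev_w), 0, lev_w)) & u_conv < params$conversion_rate
  base[convert_w] <- "T"

  lev_c <- matrix(lc[idx], n, rl)
  convert_c <- !is_w & base == "G" &
    !(u_meth < ifelse(is.na(lev_c), 0, lev_c)) & u_conv < params$conversion_rate
  base[convert_c] <- "A"

  err <- matrix(runif(n * rl) < params$error_rate, n, rl)
  if (any(err)) {
    shift <- sample.int(3L, sum(err), replace = TRUE)
    base[err] <- BASES[(match(base[err], BASES) - 1L + shift) %% 4L + 1L]
  }

  q <- as.integer(max(2, min(60, round(-10 * log10(max(params$error_rate, 1e-6))))))
  qual <- strrep(intToUtf8(q + 33L), rl)

  o <- order(start)
  seqs <- do.call(paste0, as.data.frame(base, stringsAsFactors = FALSE))
  tibble(
    qname = sprintf("sim_%06d", seq_len(n)),
    flag = ifelse(strand[o] == "W", 0L, 16L),
    chrom = params$chrom,
    pos = start[o],
    mapq = 60L,
    cigar = paste0(rl, "M"),
    seq = seqs[o],
    qual = qual,
    bs_strand = strand[o],
    xg = ifelse(strand[o] == "W", "CT", "GA"),
    zs = ifelse(strand[o] == "W", "++", "-+")
  )
}

#' Write simulated reads as a SAM file
#'
#' @param reads Tibble from [simulate_reads()].
#' @param seqinfo Tibble (`chrom`, `length`).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqinfo, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", seqinfo$chrom, seqinfo$length),
    "@PG\tID:bsvar\tPN:bsvar"
  )
  recs <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXG:Z:%s\tZS:Z:%s",
    reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
    reads$cigar, reads$seq, reads$qual, reads$xg, reads$zs
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Run the full simulator and write its outputs
#'
#' Generates a diploid genome and bisulfite reads under `params` and writes
#' `<prefix>_ref.fa` (with `.fai` index), `<prefix>_reads.sam`
#' (coordinate-sorted), `<prefix>_truth.vcf` and `<prefix>_truth_meth.tsv`.
#' With a fixed seed the outputs are byte-identical across runs.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed for all randomness.
#' @param out_prefix Path prefix for output files; `NULL` writes nothing.
#' @return List of class `bs_simulation`: the `bs_genome`, the reads tibble
#'   and (when written) the output `paths`.
#' @export
#' @examples
#' sim <- bs_simulate(sim_params(genome_length = 1000, depth = 5), seed = 1)
#' sim$genome$truth_snps
bs_simulate <- function(params = sim_params(), seed = 1L, out_prefix = NULL) {
  set.seed(seed)
  genome <- simulate_genome(params)
  reads <- simulate_reads(genome, params)
  paths <- NULL
  if (!is.null(out_prefix)) {
    paths <- c(
      ref = paste0(out_prefix, "_ref.fa"),
      sam = paste0(out_prefix, "_reads.sam"),
      truth_vcf = paste0(out_prefix, "_truth.vcf"),
      truth_meth = paste0(out_prefix, "_truth_meth.tsv")
    )
    ref <- Biostrings::DNAStringSet(setNames(genome$reference, params$chrom))
    Biostrings::writeXStringSet(ref, paths["ref"])
    Rsamtools::indexFa(paths["ref"])
    write_sam(reads, tibble(chrom = params$chrom, length = params$genome_length),
              paths["sam"])
    write_truth_vcf(genome$truth_snps, params, paths["truth_vcf"])
    readr::write_tsv(genome$truth_meth, paths["truth_meth"])
  }
  structure(list(genome = genome, reads = reads, params = params,
                 seed = seed, paths = paths),
            class = "bs_simulation")
}

# Minimal VCF for the planted truth genotypes.
write_truth_vcf <- function(truth_snps, params, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsvar-simulator",
    sprintf("##contig=<ID=%s,length=%d>", params$chrom, params$genome_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTRUTH"
  )
  recs <- character(0)
  if (nrow(truth_snps) > 0) {
    a1 <- substr(truth_snps$genotype, 1, 1)
    a2 <- substr(truth_snps$genotype, 2, 2)
    alts <- vapply(seq_len(nrow(truth_snps)), function(i) {
      paste(unique(setdiff(c(a1[i], a2[i]), truth_snps$ref[i])), collapse = ",")
    }, character(1))
    gt <- vapply(seq_len(nrow(truth_snps)), function(i) {
      alleles <- c(truth_snps$ref[i], strsplit(alts[i], ",")[[1]])
      paste(match(c(a1[i], a2[i]), alleles) - 1L, collapse = "/")
    }, character(1))
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    truth_snps$chrom, truth_snps$pos, truth_snps$ref, alts, gt)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
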