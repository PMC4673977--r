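#' Load a reference FASTA
#'
#' @param path FASTA file; soft-masked (lowercase) bases are uppercased on
#'   access.
#' @return Named list of per-chromosome character strings, class
#'   `bs_reference`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) bs_abort(paste0("reference not found: ", path), "bsvar_usage_error")
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(as.list(seqs), class = "bs_reference")
}

reference_chrom <- function(reference, chrom) {
  if (!chrom %in% names(reference)) {
    bs_abort(
      paste0("chromosome '", chrom, "' absent from reference (has: ",
             paste(names(reference), collapse = ", "), ")"),
      "bsvar_data_error"
    )
  }
  reference[[chrom]]
}

# Determine bisulfite strand of origin per read. Precedence: BSMAP ZS tag
# (leading "+" Watson, "-" Crick), Bismark XG tag ("CT" Watson, "GA" Crick),
# then FLAG bit 0x10 (with the orientation inverted for second-of-pair mates).
# Returns list(strand = "W"/"C" vector, n_fallback = reads resolved by FLAG).
assign_bs_strand <- function(flag, zs = NULL, xg = NULL) {
  n <- length(flag)
  strand <- rep(NA_character_, n)
  if (!is.null(zs)) {
    has <- !is.na(zs)
    strand[has] <- ifelse(startsWith(zs[has], "-"), "C", "W")
  }
  if (!is.null(xg)) {
    has <- is.na(strand) & !is.na(xg)
    strand[has] <- ifelse(toupper(xg[has]) == "GA", "C", "W")
  }
  miss <- is.na(strand)
  n_fallback <- sum(miss)
  if (n_fallback > 0) {
    rev <- bitwAnd(flag[miss], 16L) > 0L
    second <- bitwAnd(flag[miss], 128L) > 0L
    crick <- xor(rev, second)
    strand[miss] <- ifelse(crick, "C", "W")
  }
  list(strand = strand, n_fallback = n_fallback)
}

# Light sort-order scan of a SAM text file (RNAME/POS columns only; parsing
# proper is done by Rsamtools after conversion to BAM, which re-sorts and
# would otherwise mask unsorted input).
check_sam_sorted <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  last_chrom <- NULL
  last_pos <- 0L
  seen <- character(0)
  repeat {
    lines <- readLines(con, n = 10000L)
    if (length(lines) == 0L) break
    lines <- lines[!startsWith(lines, "@")]
    if (length(lines) == 0L) next
    f <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(f, `[[`, "", 3L)
    pos <- as.integer(vapply(f, `[[`, "", 4L))
    keep <- chrom != "*"
    chrom <- chrom[keep]; pos <- pos[keep]
    for (i in seq_along(chrom)) {
      if (is.null(last_chrom) || chrom[i] != last_chrom) {
        if (chrom[i] %in% seen) {
          bs_abort(
            paste0("alignments not coordinate-sorted: ", chrom[i], ":", pos[i],
                   " appears after a later chromosome block"),
            "bsvar_sort_error"
          )
        }
        seen <- c(seen, chrom[i])
        last_chrom <- chrom[i]
        last_pos <- 0L
      }
      if (pos[i] < last_pos) {
        bs_abort(
          paste0("alignments not coordinate-sorted at ", chrom[i], ":", pos[i],
                 " (previous ", last_pos, ")"),
          "bsvar_sort_error"
        )
      }
      last_pos <- pos[i]
    }
  }
  invisible(TRUE)
}

#' Read bisulfite alignments grouped by chromosome
#'
#' Loads a coordinate-sorted SAM or BAM file and returns the mapped reads as a
#' tibble together with the header sequence dictionary, so the pileup can
#' allocate and release one chromosome matrix at a time. SAM input is
#' validated for coordinate order and converted via [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @return List: `reads` tibble (`qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `bs_strand`, `strand_fallback` count attribute),
#'   `seqinfo` tibble (`chrom`, `length`), `n_strand_fallback`.
#' @export
stream_alignments <- function(path) {
  if (!file.exists(path)) bs_abort(paste0("alignments not found: ", path), "bsvar_usage_error")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    check_sam_sorted(path)
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("ZS", "XG")
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !is.na(b$pos) & !bitwAnd(b$flag, 4L)
  reads <- tibble(
    qname = b$qname[mapped],
    flag = b$flag[mapped],
    chrom = as.character(b$rname[mapped]),
    pos = b$pos[mapped],
    mapq = b$mapq[mapped],
    cigar = b$cigar[mapped],
    seq = as.character(b$seq)[mapped],
    qual = as.character(b$qual)[mapped]
  )
  # BAM input: verify coordinate order as stored
  if (!grepl("\\.sam$", path, ignore.case = TRUE) && nrow(reads) > 1) {
    blocks <- rle(reads$chrom)$values
    bad_block <- anyDuplicated(blocks)
    bad_pos <- which(diff(reads$pos) < 0 & reads$chrom[-1] == reads$chrom[-nrow(reads)])
    if (bad_block || length(bad_pos)) {
      where <- if (length(bad_pos)) paste0(reads$chrom[bad_pos[1] + 1], ":", reads$pos[bad_pos[1] + 1])
               else blocks[bad_block]
      bs_abort(paste0("alignments not coordinate-sorted at ", where), "bsvar_sort_error")
    }
  }
  st <- assign_bs_strand(reads$flag,
                         zs = as.character(b$tag$ZS[mapped]),
                         xg = as.character(b$tag$XG[mapped]))
  reads$bs_strand <- st$strand
  list(
    reads = reads,
    seqinfo = tibble(chrom = names(hdr), length = unname(hdr)),
    n_strand_fallback = st$n_fallback
  )
}

#' Write genotype calls as VCF 4.2
#'
#' Emits only variant genotypes, sorted by (chromosome, position), with
#' per-allele forward/reverse (Watson/Crick) depths in `ADF`/`ADR`, total
#' retained depth `DP` and effective alternate frequency `AF` in INFO, and
#' `GT:DP:GQ` sample fields. Multiallelic genotypes produce a single record
#' with comma-joined ALT.
#'
#' @param calls Tibble of genotyped sites as produced by [bs_call()] (needs
#'   `chrom`, `pos`, `ref`, `genotype`, `phred_quality`, `filter`, `depth`,
#'   the 8 class counts and `eff_*` columns).
#' @param path Output file.
#' @param seqinfo Tibble (`chrom`, `length`) for header contig lines.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, seqinfo = NULL, sample_name = "SAMPLE") {
  v <- calls[calls$is_variant, , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsvar",
    if (!is.null(seqinfo)) sprintf("##contig=<ID=%s,length=%d>", seqinfo$chrom, seqinfo$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Retained read depth\">",
    "##INFO=<ID=ADF,Number=R,Type=Integer,Description=\"Watson-strand allelic depths\">",
    "##INFO=<ID=ADR,Number=R,Type=Integer,Description=\"Crick-strand allelic depths\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Effective alternate allele frequency\">",
    "##FILTER=<ID=LowQual,Description=\"Genotype quality below 10\">",
    "##FILTER=<ID=LowFreq,Description=\"Homozygous-alternate call with alternate frequency below min_hom_freq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Retained read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  lines <- header
  if (nrow(v) > 0) {
    recs <- vapply(seq_len(nrow(v)), function(i) {
      r <- v[i, ]
      a <- c(substr(r$genotype, 1, 1), substr(r$genotype, 2, 2))
      alts <- unique(a[a != r$ref])
      alleles <- c(r$ref, alts)
      gt_idx <- match(a, alleles) - 1L
      wcols <- paste0("W_", alleles)
      ccols <- paste0("C_", alleles)
      adf <- as.integer(unlist(r[wcols]))
      adr <- as.integer(unlist(r[ccols]))
      eff <- unlist(r[paste0("eff_", BASES)])
      af <- round(eff[match(alts, BASES)] / max(sum(eff), 1), 4)
      paste(
        r$chrom, r$pos, ".", r$ref, paste(alts, collapse = ","),
        r$phred_quality, r$filter,
        sprintf("DP=%d;ADF=%s;ADR=%s;AF=%s", r$depth,
                paste(adf, collapse = ","), paste(adr, collapse = ","),
                paste(af, collapse = ",")),
        "GT:DP:GQ",
        sprintf("%d/%d:%d:%d", gt_idx[1], gt_idx[2], r$depth, r$phred_quality),
        sep = "\t"
      )
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-context methylation tables
#'
#' Tab-delimited records (`chrom`, 1-based `pos`, `strand`, `context`,
#' `meth_count`, `total_count`, `level`, `genotype_corrected`), one file per
#' requested context.
#'
#' @param meth Methylation tibble from [bs_call()].
#' @param cg,chg,chh Output paths (`NULL` to skip a context).
#' @return Named character vector of written paths, invisibly.
#' @export
write_methylation <- function(meth, cg = NULL, chg = NULL, chh = NULL) {
  paths <- c(CpG = cg %||% NA, CHG = chg %||% NA, CHH = chh %||% NA)
  written <- character(0)
  for (ctx in names(paths)) {
    if (is.na(paths[[ctx]])) next
    readr::write_tsv(meth[!is.na(meth$context) & meth$context == ctx, , drop = FALSE],
                     paths[[ctx]])
    written[ctx] <- paths[[ctx]]
  }
  invisible(written)
}
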