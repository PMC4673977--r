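#' Allocate the per-chromosome pileup matrix
#'
#' The caller processes one chromosome at a time: a matrix of per-position,
#' strand-separated base counts and Phred quality sums is allocated for the
#' chromosome, filled from its reads, genotyped, and released before the next
#' chromosome is touched, so peak memory is bounded by the largest chromosome.
#' Counts are recorded in reference orientation, i.e. as the bases appear in
#' the SAM SEQ field, for Watson- and Crick-origin reads separately.
#'
#' @param chrom_name Chromosome name.
#' @param length Chromosome length in bp (> 0).
#'
#' @return A `chrom_matrix`: zero-initialised `length` x 8 count and
#'   quality-sum matrices with columns Watson A/C/G/T then Crick A/C/G/T.
#' @export
#' @examples
#' m <- allocate_matrix("chr1", 10)
#' sum(m$counts)
allocate_matrix <- function(chrom_name, length) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0) {
    bs_abort("chromosome length must be a positive integer", "bsvar_usage_error")
  }
  structure(
    list(
      chrom_name = chrom_name,
      length = length,
      counts = matrix(0L, nrow = length, ncol = 8L,
                      dimnames = list(NULL, OBS_CLASSES)),
      qual_sums = matrix(0, nrow = length, ncol = 8L,
                         dimnames = list(NULL, OBS_CLASSES))
    ),
    class = "chrom_matrix"
  )
}

# Walk a CIGAR string; return 1-based reference and query positions of aligned
# (M/=/X) bases. Insertions and clips consume query only, deletions and N
# consume reference only. Unknown ops are a format error.
cigar_aligned <- function(cigar, pos) {
  if (grepl("^[0-9]+M$", cigar)) {
    n <- as.integer(sub("M", "", cigar, fixed = TRUE))
    return(list(rpos = pos + seq_len(n) - 1L, qpos = seq_len(n)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L) {
    bs_abort(paste0("malformed CIGAR: ", cigar), "bsvar_format_error")
  }
  rpos <- integer(0)
  qpos <- integer(0)
  r <- pos
  q <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]
    n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      rpos <- c(rpos, r + seq_len(n) - 1L)
      qpos <- c(qpos, q + seq_len(n) - 1L)
      r <- r + n
      q <- q + n
    } else if (op %in% c("I", "S")) {
      q <- q + n
    } else if (op %in% c("D", "N")) {
      r <- r + n
    } else if (op %in% c("H", "P")) {
      # consumes neither
    } else {
      bs_abort(paste0("unsupported CIGAR op '", op, "' in ", cigar),
               "bsvar_format_error")
    }
  }
  list(rpos = rpos, qpos = qpos)
}

# Expand a tibble of reads (pos, cigar, seq, qual, bs_strand, qname, flag)
# into one row per aligned base: ref_pos (1-based), base, qual (Phred int),
# strand ("W"/"C"), read id. N bases are dropped.
expand_aligned_bases <- function(reads) {
  n <- nrow(reads)
  if (n == 0L) {
    return(tibble(read_id = integer(), ref_pos = integer(), base = character(),
                  qual = integer(), strand = character()))
  }
  per_read <- vector("list", n)
  for (i in seq_len(n)) {
    al <- cigar_aligned(reads$cigar[i], reads$pos[i])
    if (length(al$rpos) == 0L) next
    bases <- substring(reads$seq[i], al$qpos, al$qpos)
    quals <- utf8ToInt(reads$qual[i])[al$qpos] - 33L
    per_read[[i]] <- tibble(
      read_id = i,
      ref_pos = al$rpos,
      base = bases,
      qual = quals,
      strand = reads$bs_strand[i]
    )
  }
  out <- bind_rows(per_read)
  out[out$base %in% BASES, , drop = FALSE]
}

#' Accumulate one aligned read into a pileup matrix
#'
#' Adds each aligned (CIGAR M/=/X) base with quality at or above
#' `min_base_quality` to the strand-matching count and quality-sum columns.
#' Insertions, soft/hard clips and skipped regions contribute nothing;
#' deletions advance the reference coordinate. Used mostly for illustration
#' and testing; the pipeline accumulates whole chromosomes at once with
#' [accumulate_reads()].
#'
#' @param matrix A `chrom_matrix` from [allocate_matrix()].
#' @param read A list or one-row data frame with `pos` (1-based), `cigar`,
#'   `seq`, `qual` (Phred+33 string), and optionally `qname`, `flag`.
#' @param strand `"W"` (Watson) or `"C"` (Crick) bisulfite strand of origin.
#' @param min_base_quality Minimum Phred quality to count an observation.
#'
#' @return The updated `chrom_matrix`.
#' @export
accumulate_read <- function(matrix, read, strand = c("W", "C"),
                            min_base_quality = 15L) {
  strand <- match.arg(strand)
  reads <- tibble(
    pos = as.integer(read$pos), cigar = read$cigar, seq = read$seq,
    qual = read$qual, bs_strand = strand,
    qname = read$qname %||% "r", flag = read$flag %||% 0L
  )
  accumulate_reads(matrix, reads, min_base_quality = min_base_quality)
}

#' Accumulate a set of admitted reads into a pileup matrix
#'
#' Vectorised accumulation of all aligned bases from `reads` into `matrix`.
#' When any read is flagged paired (FLAG 0x1), bases where mates of a pair
#' overlap are counted once, keeping the mate with the higher base quality, so
#' a single sequenced molecule never contributes twice at a position.
#'
#' @param matrix A `chrom_matrix`.
#' @param reads Tibble with columns `pos`, `cigar`, `seq`, `qual`,
#'   `bs_strand` ("W"/"C"), `qname`, `flag`.
#' @param min_base_quality Minimum Phred quality to count an observation.
#'
#' @return The updated `chrom_matrix`.
#' @export
accumulate_reads <- function(matrix, reads, min_base_quality = 15L) {
  stopifnot(inherits(matrix, "chrom_matrix"))
  ab <- expand_aligned_bases(reads)
  if (nrow(ab) == 0L) return(matrix)
  if (any(ab$ref_pos < 1L) || any(ab$ref_pos > matrix$length)) {
    bs_abort(
      paste0("read bases fall outside ", matrix$chrom_name,
             " [1, ", matrix$length, "]"),
      "bsvar_coordinate_error"
    )
  }
  ab <- ab[ab$qual >= min_base_quality, , drop = FALSE]
  if (nrow(ab) == 0L) return(matrix)

  if (any(bitwAnd(reads$flag, 1L) > 0L)) {
    ab$qname <- reads$qname[ab$read_id]
    ab <- ab %>%
      group_by(.data$qname, .data$ref_pos) %>%
      slice_max(.data$qual, n = 1, with_ties = FALSE) %>%
      ungroup()
  }

  col <- match(ab$base, BASES) + ifelse(ab$strand == "C", 4L, 0L)
  idx <- (col - 1L) * matrix$length + ab$ref_pos
  agg <- rowsum(cbind(count = rep(1L, nrow(ab)), qual = ab$qual), group = idx)
  at <- as.integer(rownames(agg))
  matrix$counts[at] <- matrix$counts[at] + as.integer(agg[, "count"])
  matrix$qual_sums[at] <- matrix$qual_sums[at] + agg[, "qual"]
  matrix
}

#' Extract the strand profile at one position
#'
#' @param matrix A `chrom_matrix`.
#' @param pos 1-based position.
#' @return A `strand_profile` list with per-base Watson/Crick counts and
#'   quality sums.
#' @export
profile_at <- function(matrix, pos) {
  if (pos < 1L || pos > matrix$length) {
    bs_abort("position outside chromosome", "bsvar_coordinate_error")
  }
  strand_profile(
    watson_count = matrix$counts[pos, 1:4],
    crick_count = matrix$counts[pos, 5:8],
    watson_qual_sum = matrix$qual_sums[pos, 1:4],
    crick_qual_sum = matrix$qual_sums[pos, 5:8]
  )
}

#' Build a strand profile by hand
#'
#' Convenience constructor for a per-position record of strand-separated base
#' counts and Phred quality sums, as accumulated by the pileup. Quality sums
#' default to 20 per counted observation.
#'
#' @param watson_count,crick_count Named (A,C,G,T) non-negative counts;
#'   unnamed vectors are taken in A,C,G,T order.
#' @param watson_qual_sum,crick_qual_sum Summed Phred qualities per base.
#' @return A `strand_profile` list.
#' @export
#' @examples
#' strand_profile(watson_count = c(C = 7, T = 3))
strand_profile <- function(watson_count = NULL, crick_count = NULL,
                           watson_qual_sum = NULL, crick_qual_sum = NULL) {
  fix <- function(x) {
    v <- setNames(numeric(4), BASES)
    if (is.null(x)) return(v)
    if (is.null(names(x))) {
      v[seq_along(x)] <- x
    } else {
      v[names(x)] <- x
    }
    v
  }
  wc <- fix(watson_count)
  cc <- fix(crick_count)
  wq <- if (is.null(watson_qual_sum)) wc * 20 else fix(watson_qual_sum)
  cq <- if (is.null(crick_qual_sum)) cc * 20 else fix(crick_qual_sum)
  if (any(c(wc, cc) < 0)) bs_abort("counts must be >= 0", "bsvar_usage_error")
  structure(
    list(watson_count = wc, crick_count = cc,
         watson_qual_sum = wq, crick_qual_sum = cq),
    class = "strand_profile"
  )
}

# Total retained observations at a site.
profile_depth <- function(profile) {
  sum(profile$watson_count) + sum(profile$crick_count)
}

#' Candidate variant sites from an accumulated pileup matrix
#'
#' Screens every position of a filled `chrom_matrix`: a site becomes a
#' candidate when its retained depth lies in `[min_cover, max_cover]` and at
#' least one non-reference allele passes the effective-frequency threshold
#' (`min_het_freq`, default 0.1) with at least `min_alt_reads` effective
#' observations. Frequencies use bisulfite-effective counts, so Watson-strand
#' T and Crick-strand A observations never seed a C/T or G/A candidate on
#' their own.
#'
#' @param matrix A filled `chrom_matrix`.
#' @param reference Reference sequence for the chromosome: a character string,
#'   a character vector of single bases, or a `DNAString`.
#' @param params A [filter_params()] object.
#'
#' @return Tibble, ascending by position: `pos` (1-based), `ref`, the 8 class
#'   counts, effective counts `eff_A..eff_T`, ambiguity counts, `depth`, and
#'   comma-joined `candidate_alleles`.
#' @export
emit_candidates <- function(matrix, reference, params = filter_params()) {
  refv <- as_base_vector(reference)
  if (length(refv) < matrix$length) {
    bs_abort("reference shorter than pileup matrix", "bsvar_coordinate_error")
  }
  counts <- matrix$counts
  depth <- rowSums(counts)
  eff <- effective_count_matrix(counts)
  eff_depth <- rowSums(eff$eff)
  refv <- refv[seq_len(matrix$length)]

  ok_depth <- depth >= params$min_cover & depth <= params$max_cover &
    eff_depth > 0 & refv %in% BASES
  if (!any(ok_depth)) return(empty_candidates())

  idx <- which(ok_depth)
  effi <- eff$eff[idx, , drop = FALSE]
  freqs <- effi / rowSums(effi)
  ref_col <- match(refv[idx], BASES)
  keep_allele <- freqs >= params$min_het_freq & effi >= params$min_alt_reads
  keep_allele[cbind(seq_along(idx), ref_col)] <- FALSE
  has_cand <- rowSums(keep_allele) > 0
  if (!any(has_cand)) return(empty_candidates())

  idx2 <- idx[has_cand]
  ka <- keep_allele[has_cand, , drop = FALSE]
  alleles <- apply(ka, 1L, function(k) paste(BASES[k], collapse = ","))

  out <- as_tibble(counts[idx2, , drop = FALSE])
  names(out) <- OBS_CLASSES
  dplyr::bind_cols(
    tibble(pos = idx2, ref = refv[idx2]),
    out,
    as_tibble(eff$eff[idx2, , drop = FALSE]) %>%
      rlang::set_names(paste0("eff_", BASES)),
    tibble(
      ambiguous_watson_T = eff$amb_wT[idx2],
      ambiguous_crick_A = eff$amb_cA[idx2],
      depth = as.integer(depth[idx2]),
      candidate_alleles = alleles
    )
  ) %>% arrange(.data$pos)
}

empty_candidates <- function() {
  tibble(
    pos = integer(), ref = character(),
    W_A = integer(), W_C = integer(), W_G = integer(), W_T = integer(),
    C_A = integer(), C_C = integer(), C_G = integer(), C_T = integer(),
    eff_A = numeric(), eff_C = numeric(), eff_G = numeric(), eff_T = numeric(),
    ambiguous_watson_T = numeric(), ambiguous_crick_A = numeric(),
    depth = integer(), candidate_alleles = character()
  )
}

# Accept a reference as string / base vector / DNAString and return an
# uppercase character vector of single bases.
as_base_vector <- function(reference) {
  if (inherits(reference, "DNAString") || inherits(reference, "DNAStringSet")) {
    reference <- as.character(reference)[1]
  }
  if (is.character(reference) && length(reference) == 1L && nchar(reference) > 1L) {
    reference <- strsplit(reference, "")[[1]]
  }
  toupper(reference)
}
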