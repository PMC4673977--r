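test_that("allocation is zero-initialised and rejects degenerate lengths", {
  m <- allocate_matrix("chr1", 10)
  expect_equal(m$length, 10L)
  expect_true(all(m$counts == 0L))
  expect_true(all(m$qual_sums == 0))
  expect_error(allocate_matrix("chrM", 0), class = "bsvar_usage_error")
  expect_error(allocate_matrix("chrM", -5), class = "bsvar_usage_error")
})

test_that("a fully aligned read maps bases and quality sums directly", {
  m <- allocate_matrix("chr1", 10)
  m <- accumulate_read(m, list(pos = 1, cigar = "4M", seq = "ACGT",
                               qual = qstr(30, 4)), strand = "W")
  expect_equal(unname(m$counts[1, "W_A"]), 1L)
  expect_equal(unname(m$counts[2, "W_C"]), 1L)
  expect_equal(unname(m$counts[3, "W_G"]), 1L)
  expect_equal(unname(m$counts[4, "W_T"]), 1L)
  expect_equal(unname(m$qual_sums[1, "W_A"]), 30)
  expect_equal(sum(m$counts), 4L)
  # Crick strand lands in the Crick columns
  m <- accumulate_read(m, list(pos = 1, cigar = "2M", seq = "AC",
                               qual = qstr(30, 2)), strand = "C")
  expect_equal(unname(m$counts[1, "C_A"]), 1L)
  expect_equal(unname(m$counts[2, "C_C"]), 1L)
})

test_that("CIGAR insertions and deletions walk the reference correctly", {
  # insertion: only the three M bases reach reference positions 1..3
  m <- allocate_matrix("chr1", 10)
  m <- accumulate_read(m, list(pos = 1, cigar = "2M1I1M", seq = "AACC",
                               qual = qstr(30, 4)), strand = "W")
  expect_equal(unname(m$counts[1:3, "W_A"]), c(1L, 1L, 0L))
  expect_equal(unname(m$counts[3, "W_C"]), 1L)
  expect_equal(sum(m$counts), 3L)

  # deletion: bases land at 1,2,5,6; 3,4 untouched; soft clips contribute nothing
  m2 <- allocate_matrix("chr1", 10)
  m2 <- accumulate_read(m2, list(pos = 1, cigar = "2M2D2M", seq = "ACGT",
                                 qual = qstr(30, 4)), strand = "W")
  expect_equal(sum(m2$counts[3:4, ]), 0L)
  expect_equal(unname(m2$counts[5, "W_G"]), 1L)
  expect_equal(unname(m2$counts[6, "W_T"]), 1L)

  m3 <- allocate_matrix("chr1", 10)
  m3 <- accumulate_read(m3, list(pos = 2, cigar = "2S2M", seq = "ACGT",
                                 qual = qstr(30, 4)), strand = "W")
  expect_equal(sum(m3$counts), 2L)
  expect_equal(unname(m3$counts[2, "W_G"]), 1L)

  expect_error(
    accumulate_read(allocate_matrix("chr1", 3),
                    list(pos = 1, cigar = "4M", seq = "ACGT", qual = qstr(30, 4)),
                    strand = "W"),
    class = "bsvar_coordinate_error"
  )
  expect_error(
    accumulate_read(allocate_matrix("chr1", 10),
                    list(pos = 1, cigar = "2M1Z", seq = "ACG", qual = qstr(30, 3)),
                    strand = "W"),
    class = "bsvar_format_error"
  )
})

test_that("low-quality and N bases are excluded from counts", {
  m <- allocate_matrix("chr1", 10)
  reads <- make_read(1, "ACNT", q = 30)
  reads$qual <- paste0(qstr(30, 2), qstr(5, 2))  # last two bases below floor
  m <- accumulate_reads(m, reads, min_base_quality = 15)
  expect_equal(sum(m$counts), 2L)  # N dropped anyway; T dropped by quality
  # quality sums never fall below count * floor for retained bases
  expect_true(all(m$qual_sums >= m$counts * 15))
  expect_true(all(m$qual_sums[m$counts == 0] == 0))
})

test_that("accumulation is order-independent and conserves base counts", {
  set.seed(11)
  ref_len <- 60L
  reads <- dplyr::bind_rows(lapply(1:30, function(i) {
    len <- sample(5:15, 1)
    pos <- sample.int(ref_len - len, 1)
    make_read(pos, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
              q = sample(c(5L, 20L, 35L), 1), strand = sample(c("W", "C"), 1),
              qname = paste0("r", i))
  }))
  m1 <- accumulate_reads(allocate_matrix("chr1", ref_len), reads)
  m2 <- accumulate_reads(allocate_matrix("chr1", ref_len),
                         reads[sample(nrow(reads)), ])
  expect_identical(m1$counts, m2$counts)
  expect_equal(m1$qual_sums, m2$qual_sums)

  # conservation: total counted bases == quality-passing aligned bases
  expected <- sum(vapply(seq_len(nrow(reads)), function(i) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    sum(q >= 15L)
  }, numeric(1)))
  expect_identical(sum(m1$counts), as.integer(expected))
})

test_that("pileup counts agree with Rsamtools pileup on simulated reads", {
  sim <- bs_simulate(sim_params(genome_length = 1500, depth = 8), seed = 5,
                     out_prefix = tempfile())
  aln <- stream_alignments(sim$paths[["sam"]])
  mat <- accumulate_reads(allocate_matrix("chr1", 1500), aln$reads,
                          min_base_quality = 0)
  bam <- Rsamtools::sortBam(Rsamtools::asBam(sim$paths[["sam"]], tempfile()),
                            tempfile())
  Rsamtools::indexBam(bam)
  pp <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10000, min_base_quality = 0, min_mapq = 0,
      distinguish_strands = TRUE, include_deletions = FALSE
    )
  )
  # simulator reads: Watson mapped forward, Crick reverse, so SAM strand
  # matches bisulfite strand here
  for (strand in c("+", "-")) {
    cols <- if (strand == "+") 1:4 else 5:8
    sub <- pp[pp$strand == strand & pp$nucleotide %in% c("A", "C", "G", "T"), ]
    ours <- mat$counts[, cols]
    theirs <- matrix(0L, 1500, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    theirs[cbind(sub$pos, match(as.character(sub$nucleotide), c("A", "C", "G", "T")))] <- sub$count
    expect_equal(unname(ours), unname(theirs))
  }
})

test_that("candidate emission applies the frequency and depth gates", {
  params <- filter_params()
  ref <- paste(rep("A", 30), collapse = "")

  build <- function(nA, nG) {
    m <- allocate_matrix("chr1", 30)
    reads <- dplyr::bind_rows(
      lapply(seq_len(nA), function(i) make_read(5, "A", q = 30, qname = paste0("a", i))),
      lapply(seq_len(nG), function(i) make_read(5, "G", q = 30, qname = paste0("g", i)))
    )
    accumulate_reads(m, reads)
  }
  # pure reference: no candidate
  expect_equal(nrow(emit_candidates(build(10, 0), ref, params)), 0L)
  # G at frequency 0.2 >= 0.1 default: yielded
  cand <- emit_candidates(build(8, 2), ref, params)
  expect_equal(cand$pos, 5L)
  expect_equal(cand$candidate_alleles, "G")
  # frequency 0.05 < 0.1: suppressed
  expect_equal(nrow(emit_candidates(build(19, 1), ref, params)), 0L)
  # below min_cover: suppressed
  expect_equal(nrow(emit_candidates(build(4, 3), ref, params)), 0L)
  # reference shorter than matrix: coordinate error
  expect_error(emit_candidates(build(8, 2), "ACGT", params),
               class = "bsvar_coordinate_error")
})

test_that("overlapping mates contribute a position once, keeping the better base", {
  m <- allocate_matrix("chr1", 10)
  r1 <- make_read(1, "AAAA", q = 20, flag = 1L + 64L, qname = "p1")
  r2 <- make_read(3, "CCCC", q = 35, flag = 1L + 128L + 16L, qname = "p1", strand = "W")
  m <- accumulate_reads(m, dplyr::bind_rows(r1, r2))
  # positions 3,4 covered by both mates: only the higher-quality C counted
  expect_equal(unname(m$counts[3, "W_A"]), 0L)
  expect_equal(unname(m$counts[3, "W_C"]), 1L)
  expect_equal(sum(m$counts), 6L)  # 2 A-only + 2 overlap + 2 C-only
})
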