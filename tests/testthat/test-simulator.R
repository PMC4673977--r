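test_that("degenerate rates behave as documented", {
  set.seed(61)
  g0 <- simulate_genome(sim_params(genome_length = 2000, snp_rate = 0))
  expect_identical(g0$hap1, g0$reference)
  expect_identical(g0$hap2, g0$reference)
  expect_equal(nrow(g0$truth_snps), 0L)

  set.seed(62)
  g1 <- simulate_genome(sim_params(genome_length = 5000, snp_rate = 0.01,
                                   het_fraction = 1))
  expect_gt(nrow(g1$truth_snps), 0L)
  expect_true(all(substr(g1$truth_snps$genotype, 1, 1) !=
                  substr(g1$truth_snps$genotype, 2, 2)))
  expect_true(all(substr(g1$truth_snps$genotype, 1, 1) == g1$truth_snps$ref |
                  substr(g1$truth_snps$genotype, 2, 2) == g1$truth_snps$ref))

  set.seed(63)
  g2 <- simulate_genome(sim_params(genome_length = 5000, snp_rate = 0.01,
                                   het_fraction = 0))
  expect_true(all(substr(g2$truth_snps$genotype, 1, 1) ==
                  substr(g2$truth_snps$genotype, 2, 2)))
})

test_that("planted SNP counts are Poisson-plausible and seed-reproducible", {
  set.seed(64)
  n1 <- nrow(simulate_genome(sim_params(genome_length = 10000, snp_rate = 0.001))$truth_snps)
  # 99% Poisson(10) interval
  expect_gte(n1, qpois(0.005, 10))
  expect_lte(n1, qpois(0.995, 10))
  set.seed(64)
  n2 <- nrow(simulate_genome(sim_params(genome_length = 10000, snp_rate = 0.001))$truth_snps)
  expect_identical(n1, n2)
})

test_that("conversion logic is exact in the deterministic limits", {
  # full conversion, no methylation, no error: Watson reads carry no C,
  # Crick reads (reference orientation) no G
  p <- sim_params(genome_length = 2000, depth = 5, snp_rate = 0,
                  methylation_by_context = c(CpG = 0, CHG = 0, CHH = 0),
                  conversion_rate = 1, error_rate = 0)
  set.seed(65)
  g <- simulate_genome(p)
  reads <- simulate_reads(g, p)
  expect_false(any(grepl("C", reads$seq[reads$bs_strand == "W"], fixed = TRUE)))
  expect_false(any(grepl("G", reads$seq[reads$bs_strand == "C"], fixed = TRUE)))

  # full methylation, no error: reads match the haplotype exactly
  p2 <- sim_params(genome_length = 2000, depth = 5, snp_rate = 0,
                   methylation_by_context = c(CpG = 1, CHG = 1, CHH = 1),
                   conversion_rate = 0.99, error_rate = 0)
  set.seed(66)
  g2 <- simulate_genome(p2)
  reads2 <- simulate_reads(g2, p2)
  for (i in seq_len(min(nrow(reads2), 50))) {
    expect_identical(reads2$seq[i],
                     substr(g2$reference, reads2$pos[i], reads2$pos[i] + 99))
  }
})

test_that("coverage matches the requested depth and output is deterministic", {
  dir <- withr::local_tempdir()
  s1 <- bs_simulate(sim_params(genome_length = 5000, depth = 20), seed = 9,
                    out_prefix = file.path(dir, "a"))
  mean_cov <- sum(nchar(s1$reads$seq)) / 5000
  expect_lt(abs(mean_cov - 20) / 20, 0.05)

  s2 <- bs_simulate(sim_params(genome_length = 5000, depth = 20), seed = 9,
                    out_prefix = file.path(dir, "b"))
  for (f in c("ref.fa", "reads.sam", "truth.vcf", "truth_meth.tsv")) {
    expect_identical(readLines(file.path(dir, paste0("a_", f))),
                     readLines(file.path(dir, paste0("b_", f))))
  }
  # truth files parse cleanly
  tv <- evaluate_calls(s1$paths[["truth_vcf"]], s1)
  expect_equal(tv$summary$fpr, 0)
  expect_equal(tv$summary$fnr, 0)
  expect_equal(tv$summary$concordance, 1)
})

test_that("methylation truth covers sample cytosines with context levels", {
  set.seed(67)
  p <- sim_params(genome_length = 3000, snp_rate = 0)
  g <- simulate_genome(p)
  refv <- strsplit(g$reference, "")[[1]]
  w <- g$truth_meth[g$truth_meth$strand == "+", ]
  expect_true(all(refv[w$pos] == "C"))
  expect_true(all(w$level == p$methylation_by_context[w$context]))
  k <- g$truth_meth[g$truth_meth$strand == "-", ]
  expect_true(all(refv[k$pos] == "G"))
})

test_that("call-set evaluation computes the confusion summary", {
  truth <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = c("A", "C"),
                          genotype = c("AG", "TT"))
  calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                          genotype = c("AG", "TT"))
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$summary$fpr, 0)
  expect_equal(ev$summary$fnr, 0)
  expect_equal(ev$summary$concordance, 1)

  empty <- evaluate_calls(tibble::tibble(chrom = character(), pos = integer(),
                                         genotype = character()), truth)
  expect_equal(empty$summary$fnr, 1)
  expect_equal(empty$summary$fn, 2L)

  spurious <- evaluate_calls(
    tibble::tibble(chrom = "chr1", pos = 5L, genotype = "AC"),
    tibble::tibble(chrom = "chr1", pos = integer(), ref = character(),
                   genotype = character())
  )
  expect_equal(spurious$summary$fp, 1L)
  expect_equal(spurious$summary$fpr, 1)

  expect_error(
    evaluate_calls(tibble::tibble(chrom = "chrX", pos = 1L, genotype = "AC"), truth),
    class = "bsvar_data_error"
  )
})
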