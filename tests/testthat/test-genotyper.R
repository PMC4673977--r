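test_that("the average error rate is the mean Phred-implied error", {
  # 10 observations at Q20
  p <- strand_profile(watson_count = c(A = 10), watson_qual_sum = c(A = 200))
  expect_equal(average_error_rate(p), 0.01)

  # 5 at Q10 and 5 at Q30 in different classes: arithmetic mean of errors
  p2 <- strand_profile(watson_count = c(A = 5), watson_qual_sum = c(A = 50),
                       crick_count = c(C = 5), crick_qual_sum = c(C = 150))
  expect_equal(average_error_rate(p2), (5 * 0.1 + 5 * 0.001) / 10)

  # clamping at the floor
  p3 <- strand_profile(watson_count = c(A = 10), watson_qual_sum = c(A = 600))
  expect_equal(average_error_rate(p3), 1e-4)

  expect_error(average_error_rate(strand_profile()), class = "bsvar_data_error")
})

test_that("product likelihoods match their closed forms", {
  p <- strand_profile(watson_count = c(A = 10))
  expect_equal(likelihood(p, "AA", 0.01), 0.99^10, tolerance = 1e-12)

  p2 <- strand_profile(watson_count = c(A = 5, C = 5))
  expect_equal(likelihood(p2, "AC", 0.01), ((0.99 + 0.01 / 3) / 2)^10,
               tolerance = 1e-12)

  # empty product: 1 for every genotype
  empty <- strand_profile()
  for (g in c("AA", "AC", "TT")) expect_equal(likelihood(empty, g, 0.01), 1)
})

test_that("genotype priors renormalise with transition weighting", {
  pv <- prior_vector("A", genotype_prior())
  expect_equal(sum(pv), 1, tolerance = 1e-12)
  expect_equal(names(which.max(pv)), "AA")
  # transition genotypes outweigh transversions at equal base prior
  expect_gt(pv[["AG"]], pv[["AC"]])
  expect_gt(pv[["GG"]], pv[["CC"]])
  # robust across reference bases
  for (b in c("A", "C", "G", "T")) {
    expect_equal(sum(prior_vector(b, genotype_prior())), 1, tolerance = 1e-12)
  }
})

test_that("posteriors normalise, follow the prior at zero depth, and favour strong evidence", {
  p <- strand_profile(watson_count = c(A = 20), crick_count = c(A = 10))
  post <- posterior(p, "A")
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_gt(post[["AA"]], 0.999)

  # uninformative data: posterior equals the normalised prior
  flat <- posterior(strand_profile(), "C")
  expect_equal(unname(flat), unname(prior_vector("C", genotype_prior())),
               tolerance = 1e-12)
})

test_that("a fully converted unmethylated cytosine is called CC, not TT", {
  # Watson reads all converted (ambiguous); Crick reads support C decisively
  p <- strand_profile(watson_count = c(T = 10), crick_count = c(C = 10))
  post <- posterior(p, "C")
  expect_equal(names(which.max(post)), "CC")
  expect_gt(post[["CC"]], 0.99)

  # whereas a true homozygous C->T SNP shows T on the Crick strand
  p2 <- strand_profile(watson_count = c(T = 12), crick_count = c(T = 11))
  call <- call_site(p2, "C", params = filter_params())
  expect_equal(call$genotype, "TT")
  expect_true(call$is_variant)
})

test_that("a both-strands-ambiguous site is flagged, never a confident C/T call", {
  p <- strand_profile(watson_count = c(T = 10), crick_count = c(A = 10))
  post <- posterior(p, "C")
  # CC and TT have identical likelihood here; their order is purely the prior
  expect_equal(post[["CC"]] / post[["TT"]],
               prior_vector("C")[["CC"]] / prior_vector("C")[["TT"]],
               tolerance = 1e-9)
  # no single genotype is resolvable: the call carries low confidence and the
  # LowQual filter, and it is never a homozygous C->T miscall
  call <- call_site(p, "C")
  expect_equal(call$filter, "LowQual")
  expect_lt(call$posterior, 0.6)
  expect_false(call$genotype %in% c("TT", "CC") && call$filter == "PASS")
})

test_that("site calls match the brute-force enumeration oracle", {
  p <- strand_profile(watson_count = c(A = 8, G = 7), crick_count = c(G = 5))
  call <- call_site(p, "A", params = filter_params())
  orc <- oracle_posterior(p, "A")
  expect_equal(call$genotype, orc$genotype)
  expect_equal(call$genotype, "AG")
  expect_equal(call$posterior, unname(orc$posterior[orc$genotype]),
               tolerance = 1e-9)

  set.seed(51)
  for (i in 1:200) {
    pr <- random_profile(40)
    if (profile_depth(pr) < 1) next
    got <- call_site(pr, sample(c("A", "C", "G", "T"), 1),
                     params = filter_params(min_cover = 1))
    orc <- oracle_posterior(pr, got$ref)
    # argmax must agree except at exact numerical ties between genotypes
    agree <- got$genotype == orc$genotype ||
      abs(orc$posterior[[got$genotype]] - orc$posterior[[orc$genotype]]) < 1e-9
    expect_true(agree)
    expect_equal(got$posterior, unname(orc$posterior[got$genotype]),
                 tolerance = 1e-9)
  }
})

test_that("reference calls are non-variant and depth gates are enforced", {
  p <- strand_profile(watson_count = c(A = 10), crick_count = c(A = 5))
  call <- call_site(p, "A")
  expect_equal(call$genotype, "AA")
  expect_false(call$is_variant)
  expect_equal(call$filter, "PASS")

  expect_error(call_site(strand_profile(watson_count = c(A = 3)), "A"),
               class = "bsvar_depth_error")
  expect_error(call_site(strand_profile(watson_count = c(A = 3000)), "A"),
               class = "bsvar_depth_error")
})

test_that("quality is the Phred-scaled posterior complement, capped at 1000", {
  p <- strand_profile(watson_count = c(A = 8, G = 7), crick_count = c(G = 5))
  call <- call_site(p, "A")
  expect_equal(call$phred_quality,
               as.integer(round(-10 * log10(1 - call$posterior))))
  # overwhelming evidence saturates the cap
  big <- strand_profile(watson_count = c(G = 500), crick_count = c(G = 400),
                        watson_qual_sum = c(G = 500 * 40),
                        crick_qual_sum = c(G = 400 * 40))
  expect_equal(call_site(big, "A")$phred_quality, 1000L)
  # weak evidence is flagged LowQual
  weak <- call_site(strand_profile(watson_count = c(A = 6, G = 4),
                                   crick_count = c(A = 1)),
                    "A", params = filter_params(min_cover = 5))
  if (weak$phred_quality < 10) expect_equal(weak$filter, "LowQual")
})
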