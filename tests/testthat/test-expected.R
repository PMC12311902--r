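fx <- hla_fixtures()
pools <- gene_pools(fx$ims, fx$registry)

test_that("gene pools partition the scores by gene", {
  expect_equal(lengths(pools),
               c(A = 20L, B = 36L, C = 13L, DPB1 = 15L, DQB1 = 14L,
                 DRB1 = 29L))
  expect_equal(sum(lengths(pools)), 127L)
  # dropping every C allele leaves an empty pool -> error
  no_c <- fx$ims[fx$ims$gene != "C", ]
  expect_error(gene_pools(no_c, fx$registry), "empty score pool.*C")
  expect_error(gene_pools(setNames(0.1, "Z*09:09"), fx$registry),
               "not in registry")
})

toy_pools <- function(c_val = 0.3) {
  ims <- setNames(rep(c_val, 8),
                  c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "C*01:02",
                    "DPB1*01:01", "DQB1*02:01", "DRB1*01:01"))
  gene_pools(ims, toy_registry())
}

test_that("constant pools give the constant back exactly", {
  p <- toy_pools(0.3)
  expect_equal(closed_form_expectation("B*07:02", p), 0.3)
  est <- sample_expected_score("B*07:02", p, n_replicates = 200, seed = 4)
  expect_equal(est$r_prime_expected, 0.3)
  expect_equal(est$mc_se, 0)
})

test_that("closed form matches hand-derived values on the bundled scores", {
  expect_equal(round(closed_form_expectation("B*38:01", pools), 4), -0.1737)
  expect_equal(round(closed_form_expectation("A*31:01", pools), 4), -0.0005)
  # direct evaluation of the formula as an independent check
  gm <- vapply(pools, mean, numeric(1))
  a <- "DQB1*03:01"
  manual <- (pools$DQB1[[a]] + gm[["DQB1"]] +
               2 * sum(gm[c("A", "B", "C", "DPB1", "DRB1")])) / 12
  expect_equal(closed_form_expectation(a, pools), unname(manual))
})

test_that("expected score rises with the allele's own score at slope 1/12", {
  base <- closed_form_expectation("B*38:01", pools)
  bumped <- setNames(fx$ims$r_prime, fx$ims$allele)
  bumped[["B*38:01"]] <- bumped[["B*38:01"]] + 0.6
  pools2 <- gene_pools(bumped, fx$registry)
  shifted <- closed_form_expectation("B*38:01", pools2)
  # own score enters twice: directly and through the own-gene pool mean
  expect_equal(shifted - base, 0.6 / 12 + 0.6 / (12 * length(pools$B)))
})

test_that("Monte Carlo estimates are seeded, reproducible and unbiased", {
  e1 <- sample_expected_score("B*38:01", pools, 1000, seed = 9)
  e2 <- sample_expected_score("B*38:01", pools, 1000, seed = 9)
  expect_identical(e1, e2)
  e3 <- sample_expected_score("B*38:01", pools, 1000, seed = 10)
  expect_false(identical(e1$r_prime_expected, e3$r_prime_expected))
  for (e in list(e1, e3)) {
    expect_lt(abs(e$r_prime_expected - e$closed_form), 4 * e$mc_se)
  }
  expect_error(sample_expected_score("B*38:01", pools, 1000), "seed")
  expect_error(sample_expected_score("B*38:01", pools, 0, seed = 1),
               "n_replicates")
})

test_that("excluding the allele from its own pool shifts the mean slightly", {
  cf_in <- closed_form_expectation("B*38:01", pools, include_self = TRUE)
  cf_ex <- closed_form_expectation("B*38:01", pools, include_self = FALSE)
  expect_false(cf_in == cf_ex)
  expect_lt(abs(cf_in - cf_ex), 0.01)
  est <- sample_expected_score("B*38:01", pools, 2000, seed = 2,
                               include_self = FALSE)
  expect_equal(est$closed_form, cf_ex)
  # exclusion impossible when the allele is alone in its gene pool
  p1 <- toy_pools()
  expect_error(sample_expected_score("C*01:02", p1, 10, seed = 1,
                                     include_self = FALSE), "empty")
})

test_that("compute_all_expected covers every allele deterministically", {
  r1 <- compute_all_expected(fx$ims, fx$registry, n_replicates = 50,
                             seed = 3)
  r2 <- compute_all_expected(fx$ims, fx$registry, n_replicates = 50,
                             seed = 3)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 127L)
  expect_equal(r1$allele, fx$registry$allele)
  one_rep <- compute_all_expected(fx$ims, fx$registry, n_replicates = 1,
                                  seed = 3)
  expect_true(all(is.na(one_rep$mc_se)))
})

test_that("CBI outcome directions agree with the published expected scores", {
  rep <- check_cbi_congruence(fx$expected)
  expect_equal(rep$n_congruent, 6L)
  expect_equal(rep$fraction, 1)
  expect_setequal(rep$table$allele,
                  c("B*18:01", "B*44:02", "B*44:03", "B*44:05", "B*50:01",
                    "B*15:01"))
  # zero scores carry no sign and are incongruent by convention
  zeros <- data.frame(allele = rep$table$allele, r_prime_expected = 0)
  expect_equal(check_cbi_congruence(zeros)$n_congruent, 0L)
  expect_error(check_cbi_congruence(
    data.frame(allele = "B*18:01", r_prime_expected = -1)), "missing")
})

test_that("B*44:02 flips sign between its own score and its context score", {
  # own IMS is positive, yet the expected genotype-context score is negative
  expect_gt(fx$ims$r_prime[fx$ims$allele == "B*44:02"], 0)
  expect_lt(fx$expected$r_prime_expected[
    fx$expected$allele == "B*44:02"], 0)
  expect_lt(closed_form_expectation("B*44:02", pools), 0)
})
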