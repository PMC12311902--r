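pe_small <- data.frame(allele = c("A*61:01", "A*62:01", "A*63:01"),
                       target_rho = c(-0.9, 0, 0.9))

test_that("simulation configs are validated", {
  expect_error(simulation_config(seed = 1, n_countries = 2), "3 countries")
  expect_error(simulation_config(
    seed = 1, planted_effects = data.frame(allele = "A*61:01",
                                           target_rho = 1)), "target_rho")
  expect_error(simulation_config(seed = 1, planted_effects = pe_small,
                                 prevalence_range = c(0.5, 0.1)),
               "increasing pair")
  expect_error(simulation_config(seed = 1, planted_effects = pe_small,
                                 noise_sd = 0), "noise_sd")
  expect_error(simulation_config(seed = 1, planted_effects = pe_small,
                                 coverage = 2), "coverage")
  expect_error(simulation_config(planted_effects = pe_small), "seed")
})

test_that("panels respect bounds, coverage and the seed", {
  cfg <- simulation_config(planted_effects = pe_small,
                           coverage = c(9, 12, 14), seed = 41)
  p <- generate_panel(cfg)
  expect_s3_class(p$ft, "freq_table")
  expect_equal(dim(p$ft), c(14L, 3L))
  f <- unclass(p$ft)
  expect_true(all(f[!is.na(f)] >= 0 & f[!is.na(f)] <= 1))
  expect_equal(unname(colSums(!is.na(f))), c(9L, 12L, 14L))
  expect_true(all(p$pt$prevalence >= 0.001 & p$pt$prevalence <= 0.006))
  expect_equal(p$truth, c("A*61:01" = -0.9, "A*62:01" = 0, "A*63:01" = 0.9))
  expect_identical(generate_panel(cfg), p)
  cfg2 <- simulation_config(planted_effects = pe_small,
                            coverage = c(9, 12, 14), seed = 42)
  expect_false(identical(generate_panel(cfg2)$ft, p$ft))
})

test_that("default panel mirrors the reference footprint", {
  cfg <- simulation_config(seed = 7)
  p <- generate_panel(cfg)
  expect_equal(dim(p$ft), c(14L, 127L))
  cov <- colSums(!is.na(unclass(p$ft)))
  expect_true(all(cov >= 9 & cov <= 14))
  # planted signs follow the bundled protective/susceptibility labels
  fx <- hla_fixtures()
  expect_equal(unname(sign(p$truth[fx$ims$allele])),
               ifelse(fx$ims$label == "protective", -1, 1))
})

test_that("planted correlations shape the sampled correlation", {
  strong_neg <- 0L
  null_small <- 0L
  n_rep <- 200L
  seeds <- withr::with_seed(13, sample.int(1e6, n_rep))
  for (s in seeds) {
    cfg <- simulation_config(planted_effects = pe_small, coverage = 14,
                             seed = s)
    p <- generate_panel(cfg)
    r_neg <- pearson_r(unclass(p$ft)[, "A*61:01"], p$pt$prevalence)
    r_null <- pearson_r(unclass(p$ft)[, "A*62:01"], p$pt$prevalence)
    strong_neg <- strong_neg + (r_neg < 0)
    null_small <- null_small + (abs(r_null) < 0.6)
  }
  # atanh(0.9) * sqrt(11) is ~5 null SDs: essentially always negative
  expect_gt(strong_neg / n_rep, 0.99)
  expect_gte(null_small / n_rep, 0.95)
})

test_that("sign recovery improves with planted signal and coverage", {
  rec <- sign_recovery_experiment(rho = c(-0.7, 0, 0.7), coverage = c(9, 14),
                                  n_panels = 60, n_alleles = 4, seed = 17)
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$n_alleles, rep(240L, 6))
  strong <- rec[abs(rec$target_rho) == 0.7 & rec$coverage == 14, ]
  expect_true(all(strong$recovery >= 0.9))
  null_row <- rec[rec$target_rho == 0 & rec$coverage == 14, ]
  expect_gt(null_row$recovery, 0.3)
  expect_lt(null_row$recovery, 0.7)
  for (r in c(-0.7, 0.7)) {
    expect_gte(rec$recovery[rec$target_rho == r & rec$coverage == 14],
               rec$recovery[rec$target_rho == r & rec$coverage == 9] - 0.05)
  }
})

test_that("the full pipeline recovers a planted 79/48 split", {
  cfg <- simulation_config(seed = 97, coverage = 14)
  p <- generate_panel(cfg)
  ims <- compute_ims(p$ft, p$pt, min_countries = 9)
  expect_equal(nrow(ims), 127L)
  agree <- sign(ims$r_prime) == sign(p$truth[ims$allele])
  expect_gt(mean(agree), 0.95)
  # and the downstream proportion machinery runs on simulated output
  tab <- class_gene_table(ims, hla_fixtures()$registry)
  expect_equal(tab$n_total[tab$stratum == "Total"], 127)
})
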