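make_ft <- function(m) freq_table(m)

test_that("coverage filter keeps alleles reported in enough countries", {
  m <- matrix(runif(28, 0.01, 0.2), 14, 2,
              dimnames = list(paste0("c", 1:14), c("A*01:01", "A*02:01")))
  m[1:6, 2] <- NA  # second allele reported in 8 of 14 countries
  ft <- make_ft(m)
  kept <- filter_alleles(ft, 9)
  expect_equal(colnames(kept), "A*01:01")
  expect_equal(rownames(kept), rownames(m))
  expect_equal(colnames(filter_alleles(ft, 8)), c("A*01:01", "A*02:01"))
  expect_error(filter_alleles(ft, 2), "min_countries")
  expect_warning(filter_alleles(make_ft(m * NA + NA), 9), "no allele")
})

test_that("pearson_r matches a brute-force oracle on random draws", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      n <- sample(5:20, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
    }
  })
})

test_that("pearson_r handles perfect, missing and degenerate inputs", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:3, c(3, 2, 1)), -1)
  # pairwise-complete: NA pairs dropped before correlating
  x <- c(1, 2, 3, NA, 5)
  y <- c(2, 4, 6, 1, NA)
  expect_equal(pearson_r(x, y), 1)
  expect_error(pearson_r(c(1, 1, 1), 1:3, allele = "A*01:01"),
               "zero variance for allele A\\*01:01")
  expect_error(pearson_r(c(1, 2, NA), c(1, 2, 3)), "fewer than 3")
})

test_that("a planted correlation is recovered within its sampling interval", {
  rho <- 0.8
  withr::with_seed(23, {
    z <- rnorm(14)
    x <- rho * z + sqrt(1 - rho^2) * rnorm(14)
  })
  r <- pearson_r(x, z)
  expect_equal(r, brute_pearson(x, z), tolerance = 1e-12)
  # 95% sampling interval of r at n = 14 via Fisher z
  band <- tanh(atanh(rho) + c(-1, 1) * 1.959964 / sqrt(11))
  expect_gt(r, band[1])
  expect_lt(r, band[2])
})

test_that("fisher_z is the odd, increasing inverse of tanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.851), 1.2598, tolerance = 1e-4)
  expect_equal(fisher_z(0.777), 1.0378, tolerance = 1e-4)
  grid <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-grid), -fisher_z(grid))
  expect_true(all(diff(fisher_z(grid)) > 0))
  xs <- seq(-5, 5, length.out = 101)
  expect_equal(fisher_z(tanh(xs)), xs, tolerance = 1e-9)
  expect_error(fisher_z(1), ">= 1")
  expect_error(fisher_z(-1.2), ">= 1")
})

test_that("classification is by sign with zero refused", {
  expect_equal(classify_ims(-1.095), "protective")
  expect_equal(classify_ims(1.037), "susceptibility")
  expect_error(classify_ims(0), "unclassifiable")
})

make_panel <- function(n_alleles = 6, n = 14, seed = 5) {
  withr::with_seed(seed, {
    prev <- runif(n, 0.001, 0.006)
    z <- as.numeric(scale(prev))
    rho <- rep(c(-0.7, 0.7), length.out = n_alleles)
    m <- sapply(seq_len(n_alleles), function(i) {
      0.1 + 0.02 * (rho[i] * z + sqrt(1 - rho[i]^2) * rnorm(n))
    })
    dimnames(m) <- list(sprintf("c%02d", 1:n),
                        sprintf("A*%02d:01", seq_len(n_alleles) + 10))
    list(ft = freq_table(m),
         pt = data.frame(country = rownames(m), prevalence = prev))
  })
}

test_that("compute_ims is invariant to country and allele ordering", {
  p <- make_panel()
  res <- compute_ims(p$ft, p$pt, min_countries = 9)
  perm <- freq_table(unclass(p$ft)[sample(14), sample(6)])
  res2 <- compute_ims(perm, p$pt[sample(14), ], min_countries = 9)
  expect_equal(res2, res, ignore_attr = TRUE)
  expect_false(is.unsorted(res$r_prime))
})

test_that("compute_ims uses pairwise-complete countries and keeps n", {
  p <- make_panel()
  m <- unclass(p$ft)
  m[1:5, 1] <- NA  # first allele: exactly 9 reporting countries
  res <- compute_ims(freq_table(m), p$pt, min_countries = 9)
  row <- res[res$allele == colnames(m)[1], ]
  expect_equal(row$n_countries, 9L)
  expect_equal(row$r, brute_pearson(m[, 1], p$pt$prevalence),
               tolerance = 1e-12)
})

test_that("degenerate correlations are flagged, not fatal", {
  p <- make_panel(n_alleles = 2)
  m <- unclass(p$ft)
  m[, 1] <- p$pt$prevalence  # frequency identical to prevalence: r = 1
  res <- compute_ims(freq_table(m), p$pt, min_countries = 9)
  row <- res[res$allele == colnames(m)[1], ]
  expect_true(row$degenerate)
  expect_true(is.na(row$r_prime))
  expect_match(row$note, "perfect correlation")
  expect_false(any(res$degenerate[res$allele != colnames(m)[1]]))
})

test_that("countries missing from the prevalence table are an error", {
  p <- make_panel()
  expect_error(compute_ims(p$ft, p$pt[-c(1, 2), ], min_countries = 9),
               "absent from prevalence table: c01, c02")
})
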