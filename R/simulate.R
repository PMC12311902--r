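#' Configuration for a synthetic country panel
#'
#' Describes a simulated country-level panel mirroring the footprint of the
#' reference data: `n_countries` countries (default 14), one planted
#' frequency-prevalence correlation per allele, and per-allele country
#' coverage between 9 and `n_countries`. Frequencies follow a
#' linear-Gaussian model, `f_c = mu_a + beta_a * z(prev_c) + eps_c`, with
#' `z` the standardized prevalence and `beta_a`, `sd(eps)` chosen so the
#' model correlation equals `target_rho`; the linear-Gaussian form is used
#' because the object of interest is the planted correlation, not marginal
#' realism of the frequency distribution.
#'
#' @param n_countries number of countries, default 14.
#' @param planted_effects data.frame with columns `allele` and `target_rho`
#'   (|rho| < 1). Default: the bundled 127-allele panel with rho = -0.8 for
#'   the 79 protective and +0.8 for the 48 susceptibility alleles.
#' @param prevalence_range uniform range for country prevalence, as
#'   proportions; default `c(0.001, 0.006)`, the order of magnitude of
#'   melanoma prevalence in Western Europe.
#' @param freq_mean_range uniform range for per-allele mean frequency;
#'   default `c(0.01, 0.15)`, typical 4-digit HLA allele frequencies.
#' @param noise_sd frequency-scale total standard deviation of the signal +
#'   noise around the allele mean, default 0.02; shrunk automatically per
#'   allele when needed to keep frequencies inside \[0, 1\].
#' @param coverage per-allele number of reporting countries: `NULL`
#'   (default) draws each allele's coverage uniformly from 9 to
#'   `n_countries`; otherwise a scalar or per-allele vector in
#'   \[3, n_countries\].
#' @param seed integer seed; required.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_countries = 14, planted_effects = NULL,
                              prevalence_range = c(0.001, 0.006),
                              freq_mean_range = c(0.01, 0.15),
                              noise_sd = 0.02, coverage = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_countries < 3) stop("need at least 3 countries", call. = FALSE)
  if (is.null(planted_effects)) {
    fx <- hla_fixtures()
    planted_effects <- data.frame(
      allele = fx$ims$allele,
      target_rho = ifelse(fx$ims$label == "protective", -0.8, 0.8),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(planted_effects),
            all(c("allele", "target_rho") %in% names(planted_effects)))
  if (anyDuplicated(planted_effects$allele)) {
    stop("duplicate alleles in planted_effects", call. = FALSE)
  }
  if (any(abs(planted_effects$target_rho) >= 1)) {
    stop("|target_rho| must be < 1", call. = FALSE)
  }
  check_range <- function(r, what) {
    if (length(r) != 2 || any(r <= 0) || any(r >= 1) || r[1] > r[2]) {
      stop(what, " must be an increasing pair inside (0, 1)", call. = FALSE)
    }
  }
  check_range(prevalence_range, "prevalence_range")
  check_range(freq_mean_range, "freq_mean_range")
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (!is.null(coverage)) {
    coverage <- rep_len(as.integer(coverage), nrow(planted_effects))
    if (any(coverage < 3) || any(coverage > n_countries)) {
      stop("coverage must lie in [3, n_countries]", call. = FALSE)
    }
  }
  structure(
    list(n_countries = as.integer(n_countries),
         planted_effects = planted_effects,
         prevalence_range = prevalence_range,
         freq_mean_range = freq_mean_range,
         noise_sd = noise_sd,
         coverage = coverage,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Draw one allele's frequency column with model correlation rho against the
# standardized prevalence zs. Total sd is shrunk (never the values clipped)
# until all frequencies fall inside [0, 1].
draw_frequency_column <- function(mu, rho, s, zs, max_tries = 20L) {
  margin <- min(mu, 1 - mu)
  need <- abs(rho) * max(abs(zs)) + 4 * sqrt(1 - rho^2)
  if (margin <= 0) {
    stop("infeasible config: mean frequency ", signif(mu, 3),
         " leaves no room inside [0,1]; narrow freq_mean_range",
         call. = FALSE)
  }
  if (s * need > margin) s <- 0.95 * margin / need
  for (i in seq_len(max_tries)) {
    f <- mu + s * rho * zs + rnorm(length(zs), 0, s * sqrt(1 - rho^2))
    if (all(f >= 0 & f <= 1)) return(f)
    s <- 0.7 * s
  }
  stop("infeasible config: could not keep frequencies in [0,1]; ",
       "reduce noise_sd or narrow freq_mean_range", call. = FALSE)
}

#' Generate a synthetic country panel
#'
#' Draws country prevalences uniformly from the configured range and one
#' frequency column per planted allele under the linear-Gaussian model of
#' [simulation_config()], then masks each allele down to its configured
#' country coverage. Fully deterministic given the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return a `sim_panel` list: `ft` ([freq_table()]), `pt`
#'   (prevalence table), `truth` (named vector allele -> target rho), and
#'   `config`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_countries
    countries <- sprintf("country%02d", seq_len(n))
    prev <- runif(n, cfg$prevalence_range[1], cfg$prevalence_range[2])
    zs <- as.numeric(scale(prev))
    pe <- cfg$planted_effects
    coverage <- if (is.null(cfg$coverage)) {
      sample(9:n, nrow(pe), replace = TRUE)
    } else cfg$coverage
    freq <- matrix(NA_real_, n, nrow(pe),
                   dimnames = list(countries, pe$allele))
    for (i in seq_len(nrow(pe))) {
      mu <- runif(1, cfg$freq_mean_range[1], cfg$freq_mean_range[2])
      col <- draw_frequency_column(mu, pe$target_rho[i], cfg$noise_sd, zs)
      drop <- sample.int(n, n - coverage[i])
      col[drop] <- NA_real_
      freq[, i] <- col
    }
    pt <- as_prevalence_table(
      data.frame(country = countries, prevalence = prev,
                 stringsAsFactors = FALSE)
    )
    structure(
      list(ft = freq_table(freq), pt = pt,
           truth = setNames(pe$target_rho, pe$allele), config = cfg),
      class = "sim_panel"
    )
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Synthetic panel: ", nrow(x$ft), " countries x ", ncol(x$ft),
      " alleles (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Sign-recovery experiment for planted correlations
#'
#' Measures how reliably the IMS pipeline recovers the direction of a
#' planted frequency-prevalence correlation: for each (target rho, country
#' coverage) cell it simulates `n_panels` independent panels carrying
#' `n_alleles` alleles per rho, scores them with [compute_ims()], and
#' reports the fraction of planted alleles whose label matches the sign of
#' rho, with an Agresti-Coull interval. For rho = 0 (no signal) the
#' reported fraction is the proportion labelled protective, which should
#' sit near 0.5 by symmetry.
#'
#' @param rho numeric vector of planted correlations, |rho| < 1.
#' @param coverage integer vector of per-allele country coverages to test.
#' @param n_panels panels per coverage level, default 500.
#' @param n_alleles alleles per rho value per panel, default 4.
#' @param n_countries countries per panel, default 14.
#' @param seed integer master seed; per-panel seeds are derived from it.
#' @param ... further arguments passed to [simulation_config()]
#'   (`prevalence_range`, `freq_mean_range`, `noise_sd`).
#' @return data.frame with one row per (rho, coverage) cell: `target_rho`,
#'   `coverage`, `n_alleles`, `n_matched`, `recovery`, `ci_low`, `ci_high`.
#' @export
sign_recovery_experiment <- function(rho = c(-0.8, -0.7, 0, 0.7, 0.8),
                                     coverage = c(9, 14), n_panels = 500,
                                     n_alleles = 4, n_countries = 14,
                                     seed, ...) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(all(abs(rho) < 1), all(coverage >= 3),
            all(coverage <= n_countries), n_panels >= 1, n_alleles >= 1)
  pe <- data.frame(
    allele = sprintf("A*%02d:%02d",
                     rep(seq_along(rho), each = n_alleles) + 60,
                     rep(seq_len(n_alleles), times = length(rho))),
    target_rho = rep(rho, each = n_alleles),
    stringsAsFactors = FALSE
  )
  n_cells <- length(coverage) * n_panels
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_cells))
  hits <- array(0L, dim = c(length(rho), length(coverage)))
  totals <- array(0L, dim = c(length(rho), length(coverage)))
  s <- 0L
  for (ci in seq_along(coverage)) {
    for (p in seq_len(n_panels)) {
      s <- s + 1L
      cfg <- simulation_config(n_countries = n_countries,
                               planted_effects = pe,
                               coverage = coverage[ci],
                               seed = sub_seeds[s], ...)
      panel <- generate_panel(cfg)
      ims <- compute_ims(panel$ft, panel$pt, min_countries = 3)
      ims <- ims[!ims$degenerate, , drop = FALSE]
      tr <- panel$truth[ims$allele]
      prot <- ims$label == "protective"
      for (ri in seq_along(rho)) {
        in_cell <- tr == rho[ri]
        if (rho[ri] == 0) {
          # no true sign: track the protective fraction (expected ~0.5)
          hits[ri, ci] <- hits[ri, ci] + sum(prot[in_cell])
        } else {
          match_sign <- if (rho[ri] < 0) prot[in_cell] else !prot[in_cell]
          hits[ri, ci] <- hits[ri, ci] + sum(match_sign)
        }
        totals[ri, ci] <- totals[ri, ci] + sum(in_cell)
      }
    }
  }
  grid <- expand.grid(ri = seq_along(rho), ci = seq_along(coverage))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ri <- grid$ri[i]; ci <- grid$ci[i]
    k <- hits[ri, ci]; n <- totals[ri, ci]
    ci_ac <- agresti_coull_ci(k, n)
    data.frame(target_rho = rho[ri], coverage = coverage[ci],
               n_alleles = n, n_matched = k, recovery = k / n,
               ci_low = ci_ac$low, ci_high = ci_ac$high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
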