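#' Filter alleles by country coverage
#'
#' Keeps the alleles reported (non-missing frequency) in at least
#' `min_countries` countries. The country list is unchanged. With the
#' reference panel of 14 countries the default of 9 reproduces the inclusion
#' rule that selects the 127-allele set.
#'
#' @param ft a [freq_table()].
#' @param min_countries minimum number of non-missing countries per allele;
#'   must be at least 3, since a correlation needs three points.
#' @return the filtered `freq_table` (possibly with zero columns, with a
#'   warning).
#' @export
filter_alleles <- function(ft, min_countries = 9) {
  stopifnot(inherits(ft, "freq_table"))
  if (min_countries < 3) {
    stop("min_countries must be >= 3 (a correlation needs 3 points)",
         call. = FALSE)
  }
  keep <- colSums(!is.na(ft)) >= min_countries
  if (!any(keep)) {
    warning("no allele reported in at least ", min_countries, " countries",
            call. = FALSE)
  }
  freq_table(unclass(ft)[, keep, drop = FALSE])
}

#' Pearson correlation between allele frequency and prevalence
#'
#' Pairwise-complete product-moment correlation: pairs where either value is
#' missing are dropped first. Errors (rather than returning `NA` or `NaN`)
#' on fewer than three complete pairs or zero variance, so callers can flag
#' degenerate alleles explicitly.
#'
#' @param x numeric vector (e.g. allele frequencies by country).
#' @param y numeric vector, same length (e.g. prevalence by country).
#' @param allele optional allele name used in error messages.
#' @return the correlation, a scalar in \[-1, 1\].
#' @export
pearson_r <- function(x, y, allele = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  who <- if (is.null(allele)) "" else paste0(" for allele ", allele)
  keep <- complete.cases(x, y)
  if (sum(keep) < 3L) {
    stop("fewer than 3 complete (frequency, prevalence) pairs", who,
         call. = FALSE)
  }
  x <- x[keep]; y <- y[keep]
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance", who, "; correlation undefined", call. = FALSE)
  }
  cor(x, y, method = "pearson")
}

#' Fisher z-transform (the immunogenetic score transform)
#'
#' Maps a correlation r to r' = atanh(r) = 0.5 * log((1 + r) / (1 - r)),
#' the variance-stabilising transform under which the score is analysed.
#' Strictly increasing and odd; requires |r| < 1 (a perfect correlation has
#' no finite score and is refused rather than clamped).
#'
#' @param r numeric vector of correlations with |r| < 1.
#' @return atanh(r).
#' @examples
#' fisher_z(0.851)  # 1.2598
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(is.na(r))) stop("NA correlation", call. = FALSE)
  if (any(abs(r) >= 1)) {
    stop("|r| >= 1: Fisher z-transform undefined (degenerate correlation)",
         call. = FALSE)
  }
  atanh(r)
}

#' Classify an immunogenetic score
#'
#' Negative scores mark protective alleles (frequency falls as prevalence
#' rises), positive scores susceptibility alleles. A score of exactly zero
#' carries no direction and is refused.
#'
#' @param r_prime numeric vector of Fisher-z scores.
#' @return character vector, `"protective"` or `"susceptibility"`.
#' @export
classify_ims <- function(r_prime) {
  stopifnot(is.numeric(r_prime))
  if (any(is.na(r_prime)) || any(r_prime == 0)) {
    stop("score of exactly 0 (or NA) is unclassifiable", call. = FALSE)
  }
  ifelse(r_prime < 0, "protective", "susceptibility")
}

#' Compute immunogenetic melanoma scores for a panel
#'
#' For each allele passing the coverage filter, correlates its frequency
#' with country prevalence over exactly the countries where the frequency is
#' reported (pairwise-complete), Fisher z-transforms the correlation into
#' the IMS r', and labels the allele protective (r' < 0) or susceptibility
#' (r' > 0). Alleles whose correlation is degenerate (zero variance, |r| =
#' 1, or an exactly zero score) are retained as flagged rows with `NA`
#' score/label and a reason, never dropped silently.
#'
#' @param ft a [freq_table()]; every country must appear in `pt`.
#' @param pt a `prevalence_table` (see [compute_prevalence()]), or a
#'   data.frame with columns `country` and `prevalence`.
#' @param min_countries coverage threshold passed to [filter_alleles()].
#' @return an `ims_result` data.frame sorted by `r_prime` ascending (most
#'   protective first; degenerate rows last) with columns `allele`,
#'   `n_countries`, `r`, `r_prime`, `label`, `degenerate`, `note`.
#'   Attribute `min_countries` records the filter; attribute `assumptions`
#'   records the pairwise-complete country rule.
#' @export
compute_ims <- function(ft, pt, min_countries = 9) {
  stopifnot(inherits(ft, "freq_table"))
  pt <- as_prevalence_table(pt)
  missing_countries <- setdiff(rownames(ft), pt$country)
  if (length(missing_countries)) {
    stop("countries absent from prevalence table: ",
         paste(missing_countries, collapse = ", "), call. = FALSE)
  }
  ft <- filter_alleles(ft, min_countries)
  prev <- setNames(pt$prevalence, pt$country)[rownames(ft)]
  rows <- lapply(colnames(ft), function(a) {
    f <- unclass(ft)[, a]
    n <- sum(!is.na(f) & !is.na(prev))
    r <- tryCatch(pearson_r(f, prev, allele = a), error = function(e) e)
    if (inherits(r, "error")) {
      return(data.frame(allele = a, n_countries = n, r = NA_real_,
                        r_prime = NA_real_, label = NA_character_,
                        degenerate = TRUE, note = conditionMessage(r),
                        stringsAsFactors = FALSE))
    }
    if (abs(r) >= 1 - 1e-12 || r == 0) {
      note <- if (r == 0) "exactly zero correlation: no direction" else
        "perfect correlation: Fisher z undefined"
      return(data.frame(allele = a, n_countries = n, r = r,
                        r_prime = NA_real_, label = NA_character_,
                        degenerate = TRUE, note = note,
                        stringsAsFactors = FALSE))
    }
    rp <- fisher_z(r)
    data.frame(allele = a, n_countries = n, r = r, r_prime = rp,
               label = classify_ims(rp), degenerate = FALSE,
               note = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(allele = character(), n_countries = integer(),
                      r = numeric(), r_prime = numeric(),
                      label = character(), degenerate = logical(),
                      note = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$degenerate, res$r_prime), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "min_countries") <- min_countries
  attr(res, "assumptions") <-
    "pairwise-complete countries per allele (missing cells dropped, not imputed as zero)"
  class(res) <- c("ims_result", "data.frame")
  res
}

#' @export
print.ims_result <- function(x, digits = 3, ...) {
  ok <- !x$degenerate
  cat("IMS results: ", nrow(x), " allele(s); ",
      sum(x$label[ok] == "protective"), " protective, ",
      sum(x$label[ok] == "susceptibility"), " susceptibility, ",
      sum(!ok), " degenerate\n", sep = "")
  y <- as.data.frame(x)
  y$r <- round(y$r, digits)
  y$r_prime <- round(y$r_prime, digits)
  print(utils::head(y, 10))
  if (nrow(y) > 10) cat("... (", nrow(y) - 10, " more rows)\n", sep = "")
  invisible(x)
}
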