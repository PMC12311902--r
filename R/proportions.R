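#' Wald test for a single proportion
#'
#' Two-sided z-test of H0: p = `p0` using the Wald standard error, i.e. the
#' standard error evaluated at the sample proportion k/n (this is the form
#' that reproduces the published stratum statistics; the score test, with SE
#' at p0, does not). z is signed: negative when k/n < p0.
#'
#' @param k number of successes (here, protective alleles in a stratum).
#' @param n number of trials (alleles in the stratum); requires 0 < k < n so
#'   the Wald standard error is positive.
#' @param p0 null proportion, default 0.5 (no protective/susceptibility
#'   preponderance).
#' @return list with components `z` and `p_value` (two-sided normal tail).
#'   Vectorised over `k` and `n`.
#' @examples
#' wald_single_proportion(79, 127)  # z = 2.837, p = 0.005
#' @export
wald_single_proportion <- function(k, n, p0 = 0.5) {
  stopifnot(is.numeric(k), is.numeric(n), length(p0) == 1, p0 > 0, p0 < 1)
  if (any(k <= 0 | k >= n)) {
    stop("k must satisfy 0 < k < n: the Wald SE degenerates at the ",
         "boundary; use the Agresti-Coull interval (agresti_coull_ci) ",
         "for inference there", call. = FALSE)
  }
  p_hat <- k / n
  z <- (p_hat - p0) / sqrt(p_hat * (1 - p_hat) / n)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Agresti-Coull confidence interval for a proportion
#'
#' Adds z*^2 pseudo-observations (z* the two-sided normal quantile,
#' 1.959964 at 95%) before the normal approximation: with n~ = n + z*^2 and
#' p~ = (k + z*^2/2)/n~, the interval is p~ +/- z* sqrt(p~(1-p~)/n~),
#' clamped to \[0, 1\]. Well-behaved at k = 0 and k = n, unlike the Wald
#' interval.
#'
#' @param k successes, 0 <= k <= n.
#' @param n trials, n >= 1.
#' @param conf confidence level in (0, 1), default 0.95.
#' @return data.frame with columns `low` and `high`; one row per element of
#'   `k`/`n`.
#' @examples
#' agresti_coull_ci(79, 127)  # (0.535, 0.702)
#' @export
agresti_coull_ci <- function(k, n, conf = 0.95) {
  stopifnot(is.numeric(k), is.numeric(n))
  if (length(conf) != 1 || !is.finite(conf) || conf <= 0 || conf >= 1) {
    stop("conf must be in (0, 1)", call. = FALSE)
  }
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    stop("need n >= 1 and 0 <= k <= n", call. = FALSE)
  }
  zs <- qnorm(1 - (1 - conf) / 2)
  n_t <- n + zs^2
  p_t <- (k + zs^2 / 2) / n_t
  hw <- zs * sqrt(p_t * (1 - p_t) / n_t)
  data.frame(low = pmax(0, p_t - hw), high = pmin(1, p_t + hw))
}

#' Confidence limit ratio
#'
#' Upper confidence bound divided by the lower: a width diagnostic for
#' ratio-scale estimates (e.g. hazard ratios). Large values indicate that a
#' pooled stratum mixes members with very different effects.
#'
#' @param low,high confidence bounds with 0 < low <= high.
#' @return high / low.
#' @examples
#' confidence_limit_ratio(0.43, 2.94)  # 6.84
#' @export
confidence_limit_ratio <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high))
  if (any(low <= 0)) {
    stop("confidence limit ratio undefined for lower bound <= 0",
         call. = FALSE)
  }
  if (any(high < low)) stop("need low <= high", call. = FALSE)
  high / low
}

#' Stratified protective-allele proportions
#'
#' Counts protective vs susceptibility alleles overall or within strata
#' (HLA class, gene, or class I supertype) and tests each stratum's
#' protective proportion against 0.5 with [wald_single_proportion()] and
#' [agresti_coull_ci()]. For the supertype scheme, dual-assigned alleles
#' form their own combined stratum (label such as `"A01 A24"`) and
#' unassigned alleles are excluded. Strata smaller than `min_stratum_size`
#' are still computed but flagged `below_threshold` (the published analysis
#' reports supertypes with more than 5 alleles only). Strata with all
#' alleles on one side get `NA` Wald statistics (degenerate SE); the
#' Agresti-Coull interval is still reported.
#'
#' @param ims an `ims_result` (see [compute_ims()]) or any data.frame with
#'   columns `allele` and `label`; degenerate rows are ignored.
#' @param registry an `hla_registry` covering every allele in `ims`.
#' @param scheme `"total"`, `"by_class"`, `"by_gene"`, or `"by_supertype"`.
#' @param min_stratum_size strata with fewer alleles are flagged, default 6.
#' @param conf confidence level for the intervals.
#' @return a `proportion_table` data.frame with columns `stratum`,
#'   `n_total`, `n_protective`, `n_susceptibility`, `proportion`, `ci_low`,
#'   `ci_high`, `z`, `p_two_sided`, `below_threshold`.
#' @export
group_proportions <- function(ims, registry,
                              scheme = c("total", "by_class", "by_gene",
                                         "by_supertype"),
                              min_stratum_size = 6, conf = 0.95) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(ims), all(c("allele", "label") %in% names(ims)))
  if ("degenerate" %in% names(ims)) ims <- ims[!ims$degenerate, , drop = FALSE]
  unknown <- setdiff(ims$allele, registry$allele)
  if (length(unknown)) {
    stop("allele(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(ims$allele, registry$allele)
  strat <- switch(
    scheme,
    total = rep("Total", nrow(ims)),
    by_class = paste("Class", registry$hla_class[idx]),
    by_gene = registry$gene[idx],
    by_supertype = supertype_stratum(registry)[idx]
  )
  keep <- !is.na(strat)
  ims <- ims[keep, , drop = FALSE]
  strat <- strat[keep]
  levels <- switch(
    scheme,
    total = "Total",
    by_class = c("Class I", "Class II"),
    by_gene = HLA_GENES,
    by_supertype = sort(unique(strat))
  )
  levels <- intersect(levels, strat)
  rows <- lapply(levels, function(s) {
    lab <- ims$label[strat == s]
    n <- length(lab)
    k <- sum(lab == "protective")
    ci <- agresti_coull_ci(k, n, conf)
    if (k > 0 && k < n) {
      w <- wald_single_proportion(k, n)
      z <- w$z; p <- w$p_value
    } else {
      z <- NA_real_; p <- NA_real_
    }
    data.frame(stratum = s, n_total = n, n_protective = k,
               n_susceptibility = n - k, proportion = k / n,
               ci_low = ci$low, ci_high = ci$high, z = z, p_two_sided = p,
               below_threshold = n < min_stratum_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(stratum = character(), n_total = integer(),
                      n_protective = integer(), n_susceptibility = integer(),
                      proportion = numeric(), ci_low = numeric(),
                      ci_high = numeric(), z = numeric(),
                      p_two_sided = numeric(), below_threshold = logical(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "scheme") <- scheme
  attr(out, "conf") <- conf
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' Class/gene summary table in publication layout
#'
#' Stacks the per-gene, per-class and overall protective-proportion rows in
#' the conventional order: class I genes (A, B, C), class I total, class II
#' genes (DPB1, DQB1, DRB1), class II total, grand total — nine rows for
#' the full six-gene panel.
#'
#' @inheritParams group_proportions
#' @return a `proportion_table` (see [group_proportions()]).
#' @export
class_gene_table <- function(ims, registry, conf = 0.95) {
  by_gene <- group_proportions(ims, registry, "by_gene", conf = conf)
  by_class <- group_proportions(ims, registry, "by_class", conf = conf)
  total <- group_proportions(ims, registry, "total", conf = conf)
  pick <- function(tab, strata) tab[match(strata, tab$stratum), , drop = FALSE]
  out <- rbind(pick(by_gene, intersect(CLASS_I_GENES, by_gene$stratum)),
               pick(by_class, intersect("Class I", by_class$stratum)),
               pick(by_gene, intersect(setdiff(HLA_GENES, CLASS_I_GENES),
                                       by_gene$stratum)),
               pick(by_class, intersect("Class II", by_class$stratum)),
               total)
  rownames(out) <- NULL
  attr(out, "scheme") <- "class_gene"
  attr(out, "conf") <- conf
  class(out) <- c("proportion_table", "data.frame")
  out
}

#' @export
print.proportion_table <- function(x, digits = 3, ...) {
  cat("Protective-allele proportions (", attr(x, "scheme"), ", ",
      100 * attr(x, "conf"), "% Agresti-Coull CI)\n", sep = "")
  y <- as.data.frame(x)
  for (cl in c("proportion", "ci_low", "ci_high", "z", "p_two_sided")) {
    y[[cl]] <- round(y[[cl]], digits)
  }
  print(y)
  invisible(x)
}
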