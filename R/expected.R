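# Alleles with a published effect of the allele on melanoma checkpoint
# blockade immunotherapy (CBI) outcome, and the direction of that effect.
CBI_REFERENCE <- data.frame(
  allele = c("B*18:01", "B*44:02", "B*44:03", "B*44:05", "B*50:01",
             "B*15:01"),
  cbi_outcome = c(rep("favorable", 5), "poor"),
  stringsAsFactors = FALSE
)

#' Per-gene pools of immunogenetic scores
#'
#' Partitions a set of allele scores into the six classical-gene pools
#' (A, B, C, DPB1, DQB1, DRB1) from which random genotype contexts are
#' drawn. All six pools must be non-empty.
#'
#' @param ims named numeric vector of scores (names = alleles), or a
#'   data.frame with columns `allele` and `r_prime`.
#' @param registry an `hla_registry` covering every scored allele.
#' @return named list of six named numeric vectors, in canonical gene order.
#' @export
gene_pools <- function(ims, registry) {
  v <- as_ims_vector(ims)
  unknown <- setdiff(names(v), registry$allele)
  if (length(unknown)) {
    stop("allele(s) not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  gene <- registry$gene[match(names(v), registry$allele)]
  pools <- lapply(HLA_GENES, function(g) v[gene == g])
  names(pools) <- HLA_GENES
  empty <- HLA_GENES[lengths(pools) == 0L]
  if (length(empty)) {
    stop("empty score pool for gene(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  pools
}

find_pool <- function(allele, pools) {
  g <- HLA_GENES[vapply(pools, function(p) allele %in% names(p), logical(1))]
  if (length(g) != 1L) {
    stop("allele ", allele, " must appear in exactly one gene pool",
         call. = FALSE)
  }
  g
}

#' Closed-form expectation of the genotype-context score
#'
#' Analytic mean of the Monte Carlo procedure in [sample_expected_score()]:
#' the 12-allele replicate keeps the allele's own score, adds one draw from
#' its own gene pool and two draws from each of the other five pools, all
#' uniform with replacement, so the expectation is
#' `(r'_a + mean(own pool) + 2 * sum(other pool means)) / 12`.
#'
#' @param allele allele name; must belong to exactly one pool.
#' @param pools output of [gene_pools()].
#' @param include_self if `FALSE`, the own-gene pool mean excludes the
#'   allele itself (see [sample_expected_score()]).
#' @return the expectation, a scalar.
#' @export
closed_form_expectation <- function(allele, pools, include_self = TRUE) {
  g <- find_pool(allele, pools)
  own <- pools[[g]]
  r_a <- own[[allele]]
  if (!include_self) {
    own <- own[names(own) != allele]
    if (length(own) == 0L) {
      stop("own-gene pool empty after excluding ", allele, call. = FALSE)
    }
  }
  others <- pools[setdiff(HLA_GENES, g)]
  (r_a + mean(own) + 2 * sum(vapply(others, mean, numeric(1)))) / 12
}

sample_one_expected <- function(allele, pools, n_replicates, include_self) {
  g <- find_pool(allele, pools)
  own <- pools[[g]]
  r_a <- own[[allele]]
  if (!include_self) {
    own <- own[names(own) != allele]
    if (length(own) == 0L) {
      stop("own-gene pool empty after excluding ", allele, call. = FALSE)
    }
  }
  draw <- function(pool, times) {
    pool[sample.int(length(pool), times * n_replicates, replace = TRUE)]
  }
  # replicate total = own score + 1 own-gene draw + 2 draws per other gene
  total <- r_a + draw(own, 1)
  for (og in setdiff(HLA_GENES, g)) {
    total <- total + draw(pools[[og]], 1) + draw(pools[[og]], 1)
  }
  rep_scores <- total / 12
  list(
    r_prime_expected = mean(rep_scores),
    mc_se = if (n_replicates > 1) {
      sd(rep_scores) / sqrt(n_replicates)
    } else NA_real_
  )
}

#' Monte Carlo expected genotype-context score for one allele
#'
#' Estimates R', the expected protection/susceptibility score of an allele
#' in the population: each replicate assembles a 12-allele diploid genotype
#' around the allele (its own score retained; the remaining eleven scores
#' drawn uniformly with replacement from the per-gene pools: one more from
#' its own gene, two from each of the other five genes) and averages the 12
#' scores; R' is the mean over replicates.
#'
#' @param allele allele name.
#' @param pools output of [gene_pools()].
#' @param n_replicates number of genotype replicates, default 1000.
#' @param seed integer seed; required, so results are reproducible and no
#'   implicit global RNG state is consumed.
#' @param include_self if `TRUE` (default) the extra own-gene draw comes
#'   from the full gene pool including the allele itself; `FALSE` excludes
#'   it (the two readings differ by under ~0.01 on the bundled scores).
#' @return an `expected_score` list: `allele`, `r_prime_expected`, `mc_se`
#'   (standard error of the replicate mean; `NA` when `n_replicates` is 1),
#'   `closed_form`, `n_replicates`.
#' @export
sample_expected_score <- function(allele, pools, n_replicates = 1000, seed,
                                  include_self = TRUE) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  est <- withr::with_seed(seed, {
    sample_one_expected(allele, pools, n_replicates, include_self)
  })
  structure(
    list(allele = allele,
         r_prime_expected = est$r_prime_expected,
         mc_se = est$mc_se,
         closed_form = closed_form_expectation(allele, pools, include_self),
         n_replicates = as.integer(n_replicates)),
    class = "expected_score"
  )
}

#' @export
print.expected_score <- function(x, ...) {
  cat(sprintf("Expected score R' for %s: %.5f (MC SE %.2g, closed form %.5f, %d replicates)\n",
              x$allele, x$r_prime_expected, x$mc_se, x$closed_form,
              x$n_replicates))
  invisible(x)
}

#' Expected genotype-context scores for all alleles
#'
#' Runs [sample_expected_score()] for every scored allele, in registry
#' order, from a single seeded RNG stream; given the same seed, registry
#' order and replicate count the full table is bit-reproducible.
#'
#' @inheritParams gene_pools
#' @inheritParams sample_expected_score
#' @return data.frame with one row per allele: `allele`, `r_prime_expected`,
#'   `mc_se`, `closed_form`, `n_replicates`.
#' @export
compute_all_expected <- function(ims, registry, n_replicates = 1000, seed,
                                 include_self = TRUE) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  pools <- gene_pools(ims, registry)
  alleles <- intersect(registry$allele, names(as_ims_vector(ims)))
  res <- withr::with_seed(seed, {
    lapply(alleles, function(a) {
      est <- sample_one_expected(a, pools, n_replicates, include_self)
      data.frame(allele = a,
                 r_prime_expected = est$r_prime_expected,
                 mc_se = est$mc_se,
                 closed_form = closed_form_expectation(a, pools,
                                                       include_self),
                 n_replicates = as.integer(n_replicates),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "seed") <- seed
  out
}

#' Sign congruence with published immunotherapy outcomes
#'
#' Checks, for the six alleles with a published effect on melanoma
#' checkpoint blockade immunotherapy (CBI) outcome, whether the sign of the
#' expected score R' matches the published direction: favorable outcome
#' should pair with a protective (negative) score, poor outcome with a
#' susceptibility (positive) score. A zero score matches neither direction.
#'
#' @param expected output of [compute_all_expected()], the bundled expected
#'   fixture, or any data.frame with columns `allele` and
#'   `r_prime_expected`.
#' @return list with `table` (per-allele data.frame: `allele`,
#'   `r_prime_expected`, `cbi_outcome`, `congruent`), `n_congruent`, and
#'   `fraction`.
#' @export
check_cbi_congruence <- function(expected) {
  stopifnot(is.data.frame(expected),
            all(c("allele", "r_prime_expected") %in% names(expected)))
  missing <- setdiff(CBI_REFERENCE$allele, expected$allele)
  if (length(missing)) {
    stop("expected scores missing for CBI reference allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(CBI_REFERENCE$allele, expected$allele)
  r <- expected$r_prime_expected[idx]
  congruent <- ifelse(CBI_REFERENCE$cbi_outcome == "favorable", r < 0, r > 0)
  tab <- data.frame(allele = CBI_REFERENCE$allele,
                    r_prime_expected = r,
                    cbi_outcome = CBI_REFERENCE$cbi_outcome,
                    congruent = congruent,
                    stringsAsFactors = FALSE)
  list(table = tab, n_congruent = sum(congruent),
       fraction = mean(congruent))
}
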