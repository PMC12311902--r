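#' Construct an individual 12-allele HLA genotype
#'
#' An individual carries two alleles at each of the six classical genes
#' (A, B, C, DPB1, DQB1, DRB1), twelve in all. Homozygous pairs are allowed;
#' the order of the two alleles within a gene carries no meaning.
#'
#' @param x data.frame with columns `gene`, `allele_1`, `allele_2` and one
#'   row per gene (exactly six genes, each once).
#' @return an `hla_genotype` data.frame, rows in canonical gene order.
#' @examples
#' g <- hla_genotype(data.frame(
#'   gene = c("A", "B", "C", "DPB1", "DQB1", "DRB1"),
#'   allele_1 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
#'                "DQB1*03:01", "DRB1*04:01"),
#'   allele_2 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
#'                "DQB1*03:01", "DRB1*04:01")))
#' @export
hla_genotype <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("gene", "allele_1", "allele_2")
  if (!all(need %in% names(x))) {
    stop("genotype needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) != 6L || !setequal(x$gene, HLA_GENES) ||
      anyDuplicated(x$gene)) {
    stop("genotype must have exactly one row for each of the six genes (",
         paste(HLA_GENES, collapse = ", "), "); got ", nrow(x), " row(s)",
         call. = FALSE)
  }
  x <- x[match(HLA_GENES, x$gene), need]
  for (col in c("allele_1", "allele_2")) {
    pa <- parse_hla_allele(x[[col]])
    bad <- pa$gene != x$gene
    if (any(bad)) {
      stop("allele(s) placed under the wrong gene: ",
           paste(x[[col]][bad], "in slot", x$gene[bad], collapse = "; "),
           call. = FALSE)
    }
  }
  rownames(x) <- NULL
  class(x) <- c("hla_genotype", "data.frame")
  x
}

genotype_alleles <- function(g) c(rbind(g$allele_1, g$allele_2))

#' Read a genotype file
#'
#' Accepts either a CSV with header `gene,allele_1,allele_2` and six rows,
#' or a single-line 12-field format listing the two alleles per gene in
#' canonical gene order (A, A, B, B, C, C, DPB1, DPB1, DQB1, DQB1, DRB1,
#' DRB1).
#'
#' @param path input file path.
#' @return an `hla_genotype`.
#' @export
read_genotype <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("\\bgene\\b", first)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    return(hla_genotype(df))
  }
  fields <- trimws(strsplit(first, ",")[[1]])
  if (length(fields) != 12L) {
    stop("single-line genotype must have 12 comma-separated alleles, got ",
         length(fields), call. = FALSE)
  }
  hla_genotype(data.frame(
    gene = HLA_GENES,
    allele_1 = fields[seq(1, 11, by = 2)],
    allele_2 = fields[seq(2, 12, by = 2)],
    stringsAsFactors = FALSE
  ))
}

#' Validate a genotype against an allele registry
#'
#' In strict mode any allele unknown to the registry is an error, with
#' nearest-name suggestions (edit distance) to catch typos. In lenient mode
#' unknown alleles are flagged in the attribute `unknown_alleles` and left
#' in place, for downstream scoring with the `available_mean` policy.
#'
#' @param g an [hla_genotype()].
#' @param registry an `hla_registry`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return the genotype, invisibly annotated in lenient mode.
#' @export
validate_genotype <- function(g, registry, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "hla_genotype"))
  alleles <- genotype_alleles(g)
  unknown <- setdiff(alleles, registry$allele)
  if (length(unknown) == 0L) return(g)
  if (mode == "strict") {
    sugg <- vapply(unknown, function(a) {
      d <- adist(a, registry$allele)
      registry$allele[which.min(d)]
    }, character(1))
    stop("allele(s) not in registry: ",
         paste0(unknown, " (nearest: ", sugg, ")", collapse = ", "),
         call. = FALSE)
  }
  attr(g, "unknown_alleles") <- unknown
  g
}

#' Overall melanoma protection/susceptibility risk score for an individual
#'
#' The individual's score is the mean of the IMS values of the twelve
#' alleles carried (two per gene; homozygous alleles count twice). Negative
#' means net protective, positive net susceptible. With policy
#' `"available_mean"` the mean runs over the alleles that have a known IMS
#' (real genotypes can carry alleles outside the scored panel) and the
#' count used is reported; `"strict"` requires all twelve.
#'
#' @param g an [hla_genotype()] (validate first with [validate_genotype()]).
#' @param ims named numeric score vector or data.frame with `allele`,
#'   `r_prime` (e.g. `hla_fixtures()$ims`).
#' @param policy `"strict"` (default) or `"available_mean"`.
#' @param statistic `"mean"` (default; the score) or `"sum"` (12 x mean,
#'   for comparability with a summed formulation).
#' @return an `hla_risk_score` list: `score`, `n_alleles_used`, `policy`,
#'   `statistic`, and `per_allele` breakdown (gene, allele, r_prime, used).
#' @examples
#' fx <- hla_fixtures()
#' g <- hla_genotype(data.frame(
#'   gene = c("A", "B", "C", "DPB1", "DQB1", "DRB1"),
#'   allele_1 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
#'                "DQB1*03:01", "DRB1*04:01"),
#'   allele_2 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
#'                "DQB1*03:01", "DRB1*04:01")))
#' overall_risk_score(g, fx$ims)$score  # -0.0887
#' @export
overall_risk_score <- function(g, ims,
                               policy = c("strict", "available_mean"),
                               statistic = c("mean", "sum")) {
  policy <- match.arg(policy)
  statistic <- match.arg(statistic)
  stopifnot(inherits(g, "hla_genotype"))
  v <- as_ims_vector(ims)
  alleles <- genotype_alleles(g)
  score_vals <- unname(v[alleles])
  used <- !is.na(score_vals)
  if (policy == "strict" && !all(used)) {
    stop("no IMS value for allele(s): ",
         paste(unique(alleles[!used]), collapse = ", "),
         "; use policy = 'available_mean' to score the known alleles",
         call. = FALSE)
  }
  if (!any(used)) {
    stop("none of the genotype's alleles has an IMS value", call. = FALSE)
  }
  m <- mean(score_vals[used])
  structure(
    list(score = if (statistic == "mean") m else m * sum(used),
         n_alleles_used = sum(used),
         policy = policy,
         statistic = statistic,
         per_allele = data.frame(
           gene = rep(g$gene, each = 2),
           allele = alleles,
           r_prime = score_vals,
           used = used,
           stringsAsFactors = FALSE)),
    class = "hla_risk_score"
  )
}

#' @export
print.hla_risk_score <- function(x, ...) {
  direction <- if (x$score < 0) "net protective" else if (x$score > 0) {
    "net susceptible"
  } else "neutral"
  cat(sprintf("Overall melanoma P/S risk score: %.4f (%s; %s of %d allele(s), policy %s)\n",
              x$score, direction, x$statistic, x$n_alleles_used, x$policy))
  invisible(x)
}
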