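fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "hlaims", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p)) {
    stop("bundled fixture not found: ", file, call. = FALSE)
  }
  p
}

check_fixture_manifest <- function() {
  man <- read.csv(fixture_path("fixture_manifest.csv"),
                  stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    got <- unname(tools::md5sum(fixture_path(man$file[i])))
    if (!identical(got, man$md5[i])) {
      stop("fixture ", man$file[i], " fails its checksum (expected ",
           man$md5[i], ", got ", got, ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Bundled allele registry and score tables
#'
#' Returns the package's reference data: the registry of the 127 four-digit
#' HLA alleles reported in nine or more of the 14 Continental Western
#' European countries, with class, gene and class I supertype assignments;
#' their published immunogenetic melanoma scores (IMS, the Fisher
#' z-transformed frequency-prevalence correlation; 79 protective, 48
#' susceptibility); and the published Monte Carlo expected genotype-context
#' scores R'. Two typographical gene-cell errors in the source score tables
#' (a blank gene for DQB1*05:02 and DRB1*04:08 listed under DQB1) are
#' corrected from the allele name, which is authoritative for the gene.
#'
#' File checksums and row counts are verified at load.
#'
#' @return a list with components:
#'   \describe{
#'     \item{registry}{an `hla_registry` (127 rows), see
#'       [read_allele_registry()].}
#'     \item{ims}{data.frame `allele`, `hla_class`, `gene`, `r_prime`,
#'       `label` (127 rows).}
#'     \item{expected}{data.frame `allele`, `r_prime_expected` (127 rows).}
#'   }
#' @examples
#' fx <- hla_fixtures()
#' subset(fx$ims, allele == "B*38:01")
#' @export
hla_fixtures <- function() {
  check_fixture_manifest()
  registry <- read_allele_registry(fixture_path("allele_registry.csv"))
  ims <- read.csv(fixture_path("ims_scores.csv"), stringsAsFactors = FALSE)
  names(ims)[names(ims) == "class"] <- "hla_class"
  ims$label <- ifelse(ims$r_prime < 0, "protective", "susceptibility")
  expected <- read.csv(fixture_path("expected_scores.csv"),
                       stringsAsFactors = FALSE)
  if (nrow(registry) != 127L) {
    stop("registry fixture must have 127 alleles, found ", nrow(registry),
         call. = FALSE)
  }
  if (nrow(ims) != 127L || sum(ims$r_prime < 0) != 79L ||
      sum(ims$r_prime > 0) != 48L) {
    stop("IMS fixture must have 79 protective and 48 susceptibility alleles",
         call. = FALSE)
  }
  if (nrow(expected) != 127L) {
    stop("expected-score fixture must have 127 alleles", call. = FALSE)
  }
  if (!setequal(registry$allele, ims$allele) ||
      !setequal(registry$allele, expected$allele)) {
    stop("fixture allele sets disagree between registry and score tables",
         call. = FALSE)
  }
  list(registry = registry, ims = ims, expected = expected)
}

# Named numeric vector allele -> r_prime from a fixture-style data.frame,
# a named vector, or an ims_result.
as_ims_vector <- function(ims) {
  if (is.numeric(ims) && !is.null(names(ims))) return(ims)
  if (is.data.frame(ims)) {
    col <- intersect(c("r_prime", "ims"), names(ims))[1]
    if (!is.na(col) && "allele" %in% names(ims)) {
      keep <- !is.na(ims[[col]])
      return(setNames(ims[[col]][keep], ims$allele[keep]))
    }
  }
  stop("cannot interpret IMS input; need a named numeric vector or a ",
       "data.frame with columns allele and r_prime", call. = FALSE)
}
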