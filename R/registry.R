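#' Parse 4-digit HLA allele names
#'
#' Splits allele names in two-field (4-digit) HLA nomenclature, e.g.
#' `"B*38:01"` or `"DRB1*04:01"`, into the gene token (before `"*"`) and the
#' allele-group/protein fields (separated by `":"`).
#'
#' @param allele character vector of allele names.
#' @return data.frame with columns `allele`, `gene`, `field1`, `field2`.
#' @examples
#' parse_hla_allele(c("B*38:01", "DQB1*03:01"))
#' @export
parse_hla_allele <- function(allele) {
  stopifnot(is.character(allele), length(allele) >= 1L)
  ok <- grepl("^[A-Z][A-Z0-9]*\\*[0-9]+:[0-9]+$", allele)
  if (any(!ok)) {
    stop("malformed HLA allele name(s) (expected '<gene>*<dd>:<dd>'): ",
         paste(allele[!ok], collapse = ", "), call. = FALSE)
  }
  gene <- sub("\\*.*$", "", allele)
  rest <- sub("^[^*]*\\*", "", allele)
  data.frame(
    allele = allele,
    gene = gene,
    field1 = sub(":.*$", "", rest),
    field2 = sub("^.*:", "", rest),
    stringsAsFactors = FALSE
  )
}

#' Gene of an HLA allele name
#' @param allele character vector of allele names.
#' @return character vector: the token before `"*"`.
#' @export
hla_gene <- function(allele) parse_hla_allele(allele)$gene

new_hla_registry <- function(df) {
  class(df) <- c("hla_registry", "data.frame")
  df
}

validate_registry <- function(df) {
  pa <- parse_hla_allele(df$allele)
  bad_gene <- df$gene != pa$gene
  if (any(bad_gene)) {
    stop("registry gene column inconsistent with allele name in row(s) ",
         paste(which(bad_gene), collapse = ", "), ": ",
         paste(df$allele[bad_gene], collapse = ", "), call. = FALSE)
  }
  expect_class <- ifelse(df$gene %in% CLASS_I_GENES, "I", "II")
  bad_class <- df$hla_class != expect_class
  if (any(bad_class)) {
    stop("registry class column inconsistent with gene in row(s) ",
         paste(which(bad_class), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$allele)) {
    stop("duplicate allele(s) in registry: ",
         paste(unique(df$allele[duplicated(df$allele)]), collapse = ", "),
         call. = FALSE)
  }
  st_outside_ab <- lengths(df$supertypes) > 0L & !(df$gene %in% c("A", "B"))
  if (any(st_outside_ab)) {
    stop("supertype assigned to gene without described supertypes: ",
         paste(df$allele[st_outside_ab], collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an HLA allele registry
#'
#' Reads a CSV with columns `allele,class,gene,supertype` mapping each
#' 4-digit allele to its HLA class (I/II), gene (A, B, C, DPB1, DQB1, DRB1)
#' and class I supertype assignment. The supertype cell may be blank,
#' `"Unassigned"`, a single label, or several space-separated labels (dual
#' assignments such as `"A01 A24"`); blank and `"Unassigned"` both become an
#' empty set. Gene/class consistency with the allele name is enforced.
#'
#' @param path path to a registry CSV.
#' @return an `hla_registry` data.frame with columns `allele`, `hla_class`,
#'   `gene`, and list-column `supertypes` (character vector per allele,
#'   possibly empty).
#' @seealso [hla_fixtures()] for the bundled 127-allele registry.
#' @export
read_allele_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("allele", "class", "gene", "supertype")
  if (!all(need %in% names(raw))) {
    stop("registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  st <- trimws(raw$supertype)
  st[is.na(st) | tolower(st) %in% c("", "unassigned", "na")] <- ""
  supertypes <- lapply(strsplit(st, "[[:space:]]+"),
                       function(x) x[nzchar(x)])
  df <- new_hla_registry(data.frame(
    allele = trimws(raw$allele),
    hla_class = trimws(raw$class),
    gene = trimws(raw$gene),
    stringsAsFactors = FALSE
  ))
  df$supertypes <- supertypes
  validate_registry(df)
  df
}

#' @export
print.hla_registry <- function(x, ...) {
  cat("HLA allele registry: ", nrow(x), " alleles (",
      sum(x$hla_class == "I"), " class I, ",
      sum(x$hla_class == "II"), " class II)\n", sep = "")
  tab <- table(factor(x$gene, levels = HLA_GENES))
  cat("  per gene: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Single supertype stratum label per allele: the label itself for
# single-assigned alleles, the space-joined combination for dual-assigned
# ones (its own stratum), NA for unassigned.
supertype_stratum <- function(registry) {
  vapply(registry$supertypes, function(s) {
    if (length(s) == 0L) NA_character_ else paste(sort(s), collapse = " ")
  }, character(1))
}
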