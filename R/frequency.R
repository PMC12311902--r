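#' Construct a country-by-allele frequency table
#'
#' A `freq_table` is a numeric matrix of population allele frequencies
#' (proportions in \[0, 1\]) with countries as rows and alleles as columns;
#' `NA` marks a missing (unreported) country/allele cell.
#'
#' @param freq numeric matrix with row names (countries) and column names
#'   (alleles).
#' @return a `freq_table` object.
#' @export
freq_table <- function(freq) {
  stopifnot(is.matrix(freq), is.numeric(freq))
  if ((nrow(freq) > 0 && is.null(rownames(freq))) ||
      (ncol(freq) > 0 && is.null(colnames(freq)))) {
    stop("frequency matrix needs country row names and allele column names",
         call. = FALSE)
  }
  if (is.null(dimnames(freq))) {
    dimnames(freq) <- list(character(0), character(0))
  }
  if (anyDuplicated(rownames(freq))) {
    stop("duplicate country identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(freq))) {
    stop("duplicate allele identifiers", call. = FALSE)
  }
  bad <- which(!is.na(freq) & (freq < 0 | freq > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("frequency outside [0,1] at (",
         paste(rownames(freq)[bad[1, 1]], colnames(freq)[bad[1, 2]],
               sep = ", "),
         ") and possibly elsewhere (", nrow(bad), " cell(s))", call. = FALSE)
  }
  structure(freq, class = c("freq_table", "matrix", "array"))
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table: ", nrow(x), " countries x ", ncol(x), " alleles; ",
      sum(is.na(x)), " missing cell(s)\n", sep = "")
  invisible(x)
}

#' Read a country-by-allele frequency table
#'
#' Two CSV layouts are supported. Wide: one row per country, first column
#' `country`, one column per allele. Long: columns `country,allele,frequency`,
#' one row per reported cell. Both yield the same `freq_table`; cells absent
#' from a long file (or blank/`NA`/`NaN` in a wide file) are missing.
#'
#' @param path CSV path.
#' @param layout `"wide"` or `"long"`.
#' @param percent if `TRUE`, input values are percentages and are divided by
#'   100 on load (allele frequency databases publish both conventions).
#' @return a [freq_table()].
#' @export
read_frequency_table <- function(path, layout = c("wide", "long"),
                                 percent = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("frequency file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("", "NA", "NaN"))
  if (layout == "wide") {
    if (names(raw)[1] != "country") {
      stop("wide layout requires first column 'country'", call. = FALSE)
    }
    mat <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- as.character(raw$country)
  } else {
    need <- c("country", "allele", "frequency")
    if (!all(need %in% names(raw))) {
      stop("long layout requires columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    key <- paste(raw$country, raw$allele, sep = "\r")
    if (anyDuplicated(key)) {
      d <- raw[duplicated(key), c("country", "allele")]
      stop("duplicate (country, allele) pair(s) in long table: ",
           paste(d$country[1], d$allele[1]), call. = FALSE)
    }
    countries <- unique(raw$country)
    alleles <- unique(raw$allele)
    mat <- matrix(NA_real_, length(countries), length(alleles),
                  dimnames = list(countries, alleles))
    mat[cbind(match(raw$country, countries), match(raw$allele, alleles))] <-
      raw$frequency
  }
  if (percent) mat <- mat / 100
  freq_table(mat)
}

#' Write a frequency table
#'
#' Inverse of [read_frequency_table()]: missing cells become blank cells
#' (wide) or omitted rows (long), so a write/read round trip reproduces the
#' table and its missingness mask exactly.
#'
#' @param ft a [freq_table()].
#' @param path output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(ft, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(ft, "freq_table"))
  # %.17g keeps every double exactly, so a round trip is bit-identical
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  if (layout == "wide") {
    chr <- matrix(fmt(unclass(ft)), nrow(ft), ncol(ft),
                  dimnames = dimnames(ft))
    df <- data.frame(country = rownames(ft), chr,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    idx <- which(!is.na(ft), arr.ind = TRUE)
    df <- data.frame(
      country = rownames(ft)[idx[, 1]],
      allele = colnames(ft)[idx[, 2]],
      frequency = fmt(ft[idx]),
      stringsAsFactors = FALSE
    )
    df <- df[order(match(df$country, rownames(ft)),
                   match(df$allele, colnames(ft))), ]
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Country-level disease prevalence from case counts
#'
#' Prevalence per country is the case count divided by the total population
#' for the same year (here, proportions in \[0, 1\]).
#'
#' @param cases named numeric vector of case counts (names = countries).
#' @param population named numeric vector of total populations, same key set.
#' @return a `prevalence_table` data.frame with columns `country`, `cases`,
#'   `population`, `prevalence`.
#' @examples
#' compute_prevalence(c(X = 1000), c(X = 1e6))
#' @export
compute_prevalence <- function(cases, population) {
  if (is.null(names(cases)) || is.null(names(population))) {
    stop("'cases' and 'population' must be named by country", call. = FALSE)
  }
  only_cases <- setdiff(names(cases), names(population))
  only_pop <- setdiff(names(population), names(cases))
  if (length(only_cases) || length(only_pop)) {
    stop("country key sets differ; in cases only: {",
         paste(only_cases, collapse = ", "), "}; in population only: {",
         paste(only_pop, collapse = ", "), "}", call. = FALSE)
  }
  population <- population[names(cases)]
  if (any(population <= 0)) {
    stop("population must be positive for every country", call. = FALSE)
  }
  if (any(cases < 0)) stop("case counts must be non-negative", call. = FALSE)
  if (any(cases > population)) {
    stop("case count exceeds population for: ",
         paste(names(cases)[cases > population], collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    country = names(cases),
    cases = as.numeric(cases),
    population = as.numeric(population),
    prevalence = as.numeric(cases) / as.numeric(population),
    stringsAsFactors = FALSE
  )
  class(df) <- c("prevalence_table", "data.frame")
  df
}

#' Coerce to a prevalence table
#'
#' Accepts a `prevalence_table`, or any data.frame with columns `country`
#' and `prevalence` (e.g. when only precomputed prevalence values are
#' available, without the underlying counts).
#'
#' @param x object to coerce.
#' @return a `prevalence_table`.
#' @export
as_prevalence_table <- function(x) {
  if (inherits(x, "prevalence_table")) return(x)
  if (is.data.frame(x) && all(c("country", "prevalence") %in% names(x))) {
    if (any(x$prevalence < 0 | x$prevalence > 1, na.rm = TRUE)) {
      stop("prevalence must be a proportion in [0,1]", call. = FALSE)
    }
    if (anyDuplicated(x$country)) {
      stop("duplicate countries in prevalence table", call. = FALSE)
    }
    df <- data.frame(country = as.character(x$country),
                     cases = if ("cases" %in% names(x)) x$cases else NA_real_,
                     population = if ("population" %in% names(x)) {
                       x$population
                     } else NA_real_,
                     prevalence = x$prevalence,
                     stringsAsFactors = FALSE)
    class(df) <- c("prevalence_table", "data.frame")
    return(df)
  }
  stop("cannot interpret as a prevalence table", call. = FALSE)
}
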