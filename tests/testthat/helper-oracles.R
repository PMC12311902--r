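# Independent brute-force Pearson correlation: two-pass sum-of-products
# formula, kept free of stats::cor so it can serve as an oracle.
brute_pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Tiny two-gene registry for toy tests.
toy_registry <- function() {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "allele,class,gene,supertype",
    "A*01:01,I,A,A01",
    "A*02:01,I,A,A02",
    "B*07:02,I,B,B07",
    "B*08:01,I,B,B08",
    "C*01:02,I,C,",
    "DPB1*01:01,II,DPB1,",
    "DQB1*02:01,II,DQB1,",
    "DRB1*01:01,II,DRB1,"
  ), tmp)
  read_allele_registry(tmp)
}

# Full homozygous genotype used in the worked example.
example_genotype <- function() {
  hla_genotype(data.frame(
    gene = c("A", "B", "C", "DPB1", "DQB1", "DRB1"),
    allele_1 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
                 "DQB1*03:01", "DRB1*04:01"),
    allele_2 = c("A*01:01", "B*38:01", "C*07:02", "DPB1*10:01",
                 "DQB1*03:01", "DRB1*04:01"),
    stringsAsFactors = FALSE
  ))
}

# Random full genotype drawn from the bundled registry.
random_genotype <- function(registry) {
  rows <- lapply(c("A", "B", "C", "DPB1", "DQB1", "DRB1"), function(g) {
    pool <- registry$allele[registry$gene == g]
    data.frame(gene = g,
               allele_1 = sample(pool, 1),
               allele_2 = sample(pool, 1),
               stringsAsFactors = FALSE)
  })
  hla_genotype(do.call(rbind, rows))
}
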