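# Independent straight-line oracles used by the property tests. These
# re-apply the definitions cell-by-cell / predicate-by-predicate and stay
# independent of the package's implementation paths.

# three-predicate reference filter: returns logical keep-vector
oracle_filter <- function(affected, unaffected, min_alt = 4,
                          lo = 0.3, hi = 0.8) {
  ukey <- if (!is.null(unaffected) && nrow(unaffected)) {
    paste(unaffected$chrom, unaffected$start, unaffected$ref,
          unaffected$alt, sep = ":")
  } else character()
  vapply(seq_len(nrow(affected)), function(i) {
    v <- affected[i, ]
    a <- v$alt_reads > min_alt
    b <- v$fraction > lo && v$fraction < hi
    absent <- !(paste(v$chrom, v$start, v$ref, v$alt, sep = ":") %in% ukey)
    fun <- v$location_class == "splicing" ||
      (v$location_class == "exonic" &&
         v$effect_class %in% c("nonsynonymous", "stopgain", "stoploss"))
    a && b && absent && fun
  }, logical(1))
}

# definitional co-segregation scan: one verdict per panel row
oracle_coseg <- function(panel) {
  vapply(seq_along(panel$variants), function(i) {
    ok <- TRUE
    for (j in seq_len(nrow(panel$mice))) {
      g <- panel$calls[i, j]
      if (g == "?") next
      exp <- if (panel$mice$phenotype[j] == "affected") "+" else "-"
      if (g != exp) ok <- FALSE
    }
    ok
  }, logical(1))
}

# random variant table for property tests
random_variant_table <- function(n) {
  loc <- sample(c("exonic", "intronic", "UTR5", "UTR3", "splicing",
                  "intergenic"), n, replace = TRUE)
  depth <- sample(5:60, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample.int(d, 1), 0L)
  as_variant_table(data.frame(
    chrom = sample(as.character(1:5), n, replace = TRUE),
    start = sample.int(1e6, n, replace = TRUE), end = NA,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt_reads = alt, depth = depth,
    location_class = loc,
    effect_class = ifelse(loc == "exonic",
                          sample(c("nonsynonymous", "synonymous",
                                   "stopgain"), n, replace = TRUE),
                          "unknown"),
    gene = "", stringsAsFactors = FALSE) |>
      transform(end = start))
}

# random genotype panel
random_panel <- function(n_var, n_aff = 4, n_un = 3) {
  mice <- data.frame(
    mouse_id = c(paste0("A", seq_len(n_aff)), paste0("U", seq_len(n_un))),
    phenotype = rep(c("affected", "unaffected"), c(n_aff, n_un)))
  calls <- matrix(sample(c("+", "-", "?"), n_var * (n_aff + n_un),
                         replace = TRUE),
                  nrow = n_var)
  segregation_panel(mice, paste0("v", seq_len(n_var)), calls)
}
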