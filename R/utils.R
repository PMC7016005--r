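# shared helpers

#' Round half-up to a fixed number of decimals
#'
#' Report percentages use commercial (half-up) rounding, not the IEEE
#' round-half-even used by [base::round()], so 0.05 at the last kept digit
#' always rounds away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 54.545 stored just below
  # the decimal midpoint still round up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype alphabet used throughout: "+" carrier, "-" non-carrier, "?" missing
.GT_LEVELS <- c("+", "-", "?")

#' Normalize genotype symbols
#'
#' Maps Unicode minus (U+2212) and hyphen-minus to "-" and validates that
#' every symbol is one of "+", "-", "?".
#'
#' @param x character vector of raw genotype symbols.
#' @return character vector over the closed alphabet \code{c("+", "-", "?")}.
#' @export
normalize_genotype <- function(x) {
  x <- gsub("−", "-", x)
  bad <- !(x %in% .GT_LEVELS)
  if (any(bad)) {
    stop("illegal genotype symbol(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected one of +, -, ?)", call. = FALSE)
  }
  x
}

.location_classes <- c("exonic", "intronic", "UTR5", "UTR3", "splicing",
                       "intergenic")
.effect_classes <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                     "unknown")
.genic_classes <- c("exonic", "intronic", "UTR5", "UTR3", "splicing")
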