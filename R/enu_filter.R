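# Candidate-variant filtering: the three screen criteria that reduce raw
# affected-exome calls to functional candidates absent from the unaffected
# exome.

#' Filter configuration
#'
#' All threshold comparisons are strict: a variant passes read support when
#' \code{alt_reads > min_alt_reads_exclusive} and passes the heterozygous
#' allelic-fraction band when \code{fraction_low < fraction < fraction_high}.
#'
#' @param min_alt_reads_exclusive exclusive lower bound on alternate-
#'   supporting reads (default 4).
#' @param fraction_low,fraction_high exclusive bounds of the allelic-fraction
#'   band (defaults 0.3 and 0.8).
#' @param functional_classes effect/location classes counted as functional.
#' @param unaffected_noise_floor an unaffected call only counts as "present"
#'   when its fraction exceeds this (default 0: any call counts).
#' @param unaffected_mode with multiple unaffected samples, \code{"any"}
#'   excludes on presence in any sample, \code{"all"} only on presence in all.
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_alt_reads_exclusive = 4L,
                          fraction_low = 0.3, fraction_high = 0.8,
                          functional_classes = c("nonsynonymous", "stopgain",
                                                 "stoploss", "splicing"),
                          unaffected_noise_floor = 0,
                          unaffected_mode = c("any", "all")) {
  stopifnot(min_alt_reads_exclusive >= 0,
            fraction_low >= 0, fraction_low < fraction_high,
            fraction_high <= 1)
  structure(list(min_alt_reads_exclusive = min_alt_reads_exclusive,
                 fraction_low = fraction_low, fraction_high = fraction_high,
                 functional_classes = functional_classes,
                 unaffected_noise_floor = unaffected_noise_floor,
                 unaffected_mode = match.arg(unaffected_mode)),
            class = "filter_config")
}

#' Criterion (a): alternate-read support
#'
#' @param v a \code{variant_table} (vectorized over rows).
#' @param cfg a [filter_config()].
#' @return logical vector: \code{alt_reads > min_alt_reads_exclusive}.
#' @export
passes_support <- function(v, cfg = filter_config()) {
  v$alt_reads > cfg$min_alt_reads_exclusive
}

#' Criterion (b), band part: heterozygous allelic fraction
#'
#' @inheritParams passes_support
#' @return logical vector: \code{fraction} strictly inside the open band.
#' @export
passes_fraction_band <- function(v, cfg = filter_config()) {
  v$fraction > cfg$fraction_low & v$fraction < cfg$fraction_high
}

#' Criterion (b), absence part: not called in the unaffected sample
#'
#' Matching is on the exact allele key (chrom, start, ref, alt); a matching
#' unaffected call only counts when its fraction exceeds the configured
#' noise floor.
#'
#' @inheritParams passes_support
#' @param unaffected_calls \code{variant_table} of the unaffected sample
#'   (may have zero rows).
#' @return logical vector, TRUE where the variant is absent from the
#'   unaffected call set.
#' @export
absent_in_unaffected <- function(v, unaffected_calls,
                                 cfg = filter_config()) {
  if (is.null(unaffected_calls) || nrow(unaffected_calls) == 0) {
    return(rep(TRUE, nrow(v)))
  }
  u <- unaffected_calls[!is.na(unaffected_calls$fraction) &
                          unaffected_calls$fraction >
                          cfg$unaffected_noise_floor |
                          is.na(unaffected_calls$fraction), , drop = FALSE]
  key <- function(x) paste(x$chrom, x$start, x$ref, x$alt, sep = ":")
  !(key(v) %in% key(u))
}

#' Criterion (c): functional annotation class
#'
#' @inheritParams passes_support
#' @return logical vector: TRUE for splicing-site variants and for exonic
#'   variants whose effect class is in \code{cfg$functional_classes}.
#' @export
is_functional <- function(v, cfg = filter_config()) {
  (v$location_class == "splicing" &
     "splicing" %in% cfg$functional_classes) |
    (v$location_class == "exonic" &
       v$effect_class %in% setdiff(cfg$functional_classes, "splicing"))
}

#' Apply the three candidate criteria
#'
#' Partitions the affected sample's calls into candidates (pass all of read
#' support, fraction band, absence from the unaffected sample, and
#' functional class) and rejected calls labelled with every criterion they
#' fail. Order-preserving and deterministic.
#'
#' @param affected_calls \code{variant_table} from the affected exome.
#' @param unaffected_calls \code{variant_table} from the unaffected exome.
#' @param cfg a [filter_config()].
#' @return list of class \code{candidate_set} with elements
#'   \code{candidates} (variant_table), \code{rejected} (variant_table with
#'   an extra \code{failed} column, criteria joined by ","), and \code{cfg}.
#' @export
apply_criteria <- function(affected_calls, unaffected_calls = NULL,
                           cfg = filter_config()) {
  v <- as_variant_table(affected_calls)
  if (nrow(v) == 0) {
    rej <- v
    rej$failed <- character(0)
    return(structure(list(candidates = v, rejected = rej, cfg = cfg),
                     class = "candidate_set"))
  }
  fails <- cbind(
    support = !passes_support(v, cfg),
    fraction_band = !passes_fraction_band(v, cfg),
    present_in_unaffected = !absent_in_unaffected(v, unaffected_calls, cfg),
    not_functional = !is_functional(v, cfg))
  any_fail <- rowSums(fails) > 0
  cand <- v[!any_fail, , drop = FALSE]
  rej <- v[any_fail, , drop = FALSE]
  rej$failed <- apply(fails[any_fail, , drop = FALSE], 1, function(r)
    paste(colnames(fails)[r], collapse = ","))
  rownames(cand) <- rownames(rej) <- NULL
  structure(list(candidates = cand, rejected = rej, cfg = cfg),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x$candidates), "candidates,",
      nrow(x$rejected), "rejected\n")
  invisible(x)
}

#' Summarize a call set by annotation class
#'
#' @param calls a \code{variant_table}.
#' @return list with \code{n}, \code{by_location} (named counts over
#'   location classes), \code{by_effect} (counts over effect classes for
#'   exonic calls), and \code{genic_fraction} = (exonic + intronic + UTR +
#'   splicing) / total (NA for an empty input).
#' @export
summarize_calls <- function(calls) {
  calls <- as_variant_table(calls)
  by_loc <- table(factor(calls$location_class, levels = .location_classes))
  exonic <- calls[calls$location_class == "exonic", , drop = FALSE]
  by_eff <- table(factor(exonic$effect_class, levels = .effect_classes))
  n <- nrow(calls)
  list(n = n,
       by_location = as.integer(by_loc) |> stats::setNames(names(by_loc)),
       by_effect = as.integer(by_eff) |> stats::setNames(names(by_eff)),
       genic_fraction = if (n == 0) NA_real_ else
         sum(calls$location_class %in% .genic_classes) / n)
}
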