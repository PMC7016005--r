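# Pedigree co-segregation exclusion mapping under a fully penetrant
# dominant model: affected mice must carry the candidate allele, unaffected
# mice must not; ungenotyped cells are skipped.

#' Evaluate one variant's co-segregation with the phenotype
#'
#' Under the dominant fully penetrant model the expected genotype is
#' \code{"+"} for affected and \code{"-"} for unaffected mice. \code{"?"}
#' cells are vacuously consistent and excluded from the informative counts.
#' With \code{incomplete_penetrance = TRUE}, unaffected carriers are
#' tolerated and only affected non-carriers contradict.
#'
#' @param calls character vector of genotypes over \code{c("+","-","?")},
#'   aligned with \code{mice}.
#' @param mice data.frame with \code{mouse_id} and \code{phenotype}.
#' @param min_informative verdicts based on fewer informative genotypes than
#'   this are flagged \code{vacuous} (default 2).
#' @param incomplete_penetrance logical, see above (default FALSE).
#' @param variant_id label carried into the result.
#' @return list of class \code{segregation_result}: \code{variant_id},
#'   \code{consistent}, \code{contradictions} (data.frame mouse_id /
#'   observed / expected), \code{informative_affected},
#'   \code{informative_unaffected}, \code{vacuous}.
#' @export
evaluate_variant <- function(calls, mice, min_informative = 2L,
                             incomplete_penetrance = FALSE,
                             variant_id = NA_character_) {
  if (length(calls) != nrow(mice)) {
    stop("calls/mice length mismatch", call. = FALSE)
  }
  calls <- normalize_genotype(calls)
  affected <- mice$phenotype == "affected"
  informative <- calls != "?"
  expected <- ifelse(affected, "+", "-")
  contradicts <- informative & calls != expected
  if (incomplete_penetrance) contradicts <- contradicts & affected
  contradictions <- data.frame(
    mouse_id = mice$mouse_id[contradicts],
    observed = calls[contradicts],
    expected = expected[contradicts],
    stringsAsFactors = FALSE)
  ia <- sum(informative & affected)
  iu <- sum(informative & !affected)
  structure(list(variant_id = variant_id,
                 consistent = nrow(contradictions) == 0,
                 contradictions = contradictions,
                 informative_affected = ia,
                 informative_unaffected = iu,
                 vacuous = (ia + iu) < min_informative),
            class = "segregation_result")
}

#' Evaluate a whole genotype panel
#'
#' Applies [evaluate_variant()] to every row of the panel and partitions the
#' variants into \code{surviving} (consistent and non-vacuous) and
#' \code{excluded} (contradicted). Vacuously consistent variants appear in
#' neither list but are flagged in \code{results}.
#'
#' @param panel a \code{segregation_panel}.
#' @inheritParams evaluate_variant
#' @return list of class \code{cosegregation_report}: \code{results}
#'   (data.frame in panel order with columns variant_id, consistent,
#'   vacuous, n_contradictions, informative_affected,
#'   informative_unaffected), \code{details} (list of
#'   \code{segregation_result}), \code{surviving}, \code{excluded}.
#' @export
evaluate_panel <- function(panel, min_informative = 2L,
                           incomplete_penetrance = FALSE) {
  if (!inherits(panel, "segregation_panel")) {
    stop("expected a segregation_panel", call. = FALSE)
  }
  if (length(panel$variants) == 0) stop("empty panel", call. = FALSE)
  details <- lapply(seq_along(panel$variants), function(i)
    evaluate_variant(panel$calls[i, ], panel$mice, min_informative,
                     incomplete_penetrance,
                     variant_id = panel$variants[i]))
  results <- do.call(rbind, lapply(details, function(r) data.frame(
    variant_id = r$variant_id, consistent = r$consistent,
    vacuous = r$vacuous, n_contradictions = nrow(r$contradictions),
    informative_affected = r$informative_affected,
    informative_unaffected = r$informative_unaffected,
    stringsAsFactors = FALSE)))
  structure(list(
    results = results, details = details,
    surviving = results$variant_id[results$consistent & !results$vacuous],
    excluded = results$variant_id[!results$consistent]),
    class = "cosegregation_report")
}

#' @export
print.cosegregation_report <- function(x, ...) {
  cat("cosegregation_report:", nrow(x$results), "variants;",
      length(x$excluded), "excluded;",
      length(x$surviving), "surviving",
      if (length(x$surviving)) paste0("(", paste(x$surviving,
                                                 collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Backcross disassociation check
#'
#' A candidate variant is disassociated from the phenotype when a
#' phenotype-selected late-backcross affected animal does not carry it.
#'
#' @param v single-row \code{variant_table} (or any variant label; used only
#'   for error messages).
#' @param backcross_affected_genotype genotype of the backcross affected
#'   animal at the variant: \code{"+"}, \code{"-"} or \code{"?"}.
#' @return TRUE (disassociated) iff the genotype is \code{"-"}; a
#'   \code{"?"} genotype is an indeterminate observation and raises an
#'   error rather than returning a verdict.
#' @export
disassociation_check <- function(v, backcross_affected_genotype) {
  g <- normalize_genotype(backcross_affected_genotype)
  if (length(g) != 1) stop("one genotype expected", call. = FALSE)
  if (g == "?") {
    stop("indeterminate: backcross animal not genotyped", call. = FALSE)
  }
  g == "-"
}
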