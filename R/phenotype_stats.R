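# Penetrance and expressivity arithmetic for carrier cohorts.

#' Penetrance of a variant in a genotyped cohort
#'
#' Penetrance is 100 x (affected genotyped carriers) / (all genotyped
#' carriers); mice with a missing genotype at the variant contribute to
#' neither numerator nor denominator. Obligate carriers inferred from the
#' pedigree are not imputed.
#'
#' @param panel a \code{segregation_panel}.
#' @param variant_id variant identifier present in the panel.
#' @param conf_level if non-NULL, a Wilson score interval at this confidence
#'   level is attached as \code{ci} (percent scale).
#' @return list of class \code{penetrance_report}: \code{variant_id},
#'   \code{n_carriers}, \code{n_affected_carriers}, \code{penetrance_pct}
#'   (full precision; print method rounds), optional \code{ci}, and
#'   \code{laterality} (see [laterality_expressivity()]) computed over the
#'   affected carriers when any laterality is known.
#' @export
penetrance <- function(panel, variant_id, conf_level = NULL) {
  i <- match(variant_id, panel$variants)
  if (is.na(i)) stop("variant not in panel: ", variant_id, call. = FALSE)
  calls <- panel$calls[i, ]
  carriers <- calls == "+"
  n <- sum(carriers)
  if (n == 0) stop("penetrance undefined: no genotyped carriers",
                   call. = FALSE)
  k <- sum(carriers & panel$mice$phenotype == "affected")
  rep <- list(variant_id = variant_id, n_carriers = n,
              n_affected_carriers = k, penetrance_pct = 100 * k / n)
  if (!is.null(conf_level)) {
    rep$ci <- 100 * wilson_interval(k, n, conf_level)
  }
  aff_car <- panel$mice[carriers & panel$mice$phenotype == "affected", ,
                        drop = FALSE]
  if (any(aff_car$laterality %in% c("bilateral", "unilateral", "none"))) {
    rep$laterality <- laterality_expressivity(aff_car)
  }
  structure(rep, class = "penetrance_report")
}

#' @export
print.penetrance_report <- function(x, ...) {
  cat(sprintf("penetrance of %s: %s%% (%d/%d genotyped carriers affected)\n",
              x$variant_id, round_half_up(x$penetrance_pct, 1),
              x$n_affected_carriers, x$n_carriers))
  if (!is.null(x$laterality)) {
    cat(sprintf("  laterality: %.1f%% bilateral / %.1f%% unilateral\n",
                x$laterality$pct_bilateral, x$laterality$pct_unilateral))
  }
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, @param n trials, @param conf_level confidence level.
#' @return length-2 numeric (lower, upper) on the proportion scale.
#' @export
wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Laterality expressivity of an affected cohort
#'
#' Splits an affected cohort into bilateral and unilateral presentations;
#' percentages are over the mice with known laterality and rounded half-up
#' to one decimal.
#'
#' @param cohort data.frame of affected mice with a \code{laterality} column
#'   over \code{c("bilateral","unilateral","none","unknown")}.
#' @return list: \code{n_bilateral}, \code{n_unilateral},
#'   \code{pct_bilateral}, \code{pct_unilateral}.
#' @export
laterality_expressivity <- function(cohort) {
  lat <- cohort$laterality
  known <- lat %in% c("bilateral", "unilateral")
  if (!any(known)) stop("no mouse with known laterality", call. = FALSE)
  nb <- sum(lat == "bilateral")
  nu <- sum(lat == "unilateral")
  list(n_bilateral = nb, n_unilateral = nu,
       pct_bilateral = round_half_up(100 * nb / (nb + nu), 1),
       pct_unilateral = round_half_up(100 * nu / (nb + nu), 1))
}

#' Per-trait penetrance
#'
#' @param cohort data.frame of mice with a \code{mouse_id} column.
#' @param trait_scores named logical vector, names being mouse ids scored
#'   for the trait (must all be in the cohort).
#' @return list: \code{n_scored}, \code{n_positive}, \code{pct} (half-up,
#'   one decimal).
#' @export
trait_penetrance <- function(cohort, trait_scores) {
  if (length(trait_scores) == 0) stop("empty trait_scores", call. = FALSE)
  extra <- setdiff(names(trait_scores), cohort$mouse_id)
  if (length(extra)) stop("trait scores for unknown mice: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  n <- length(trait_scores)
  k <- sum(trait_scores)
  list(n_scored = n, n_positive = k, pct = round_half_up(100 * k / n, 1))
}
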