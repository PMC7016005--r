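# Chou-Fasman alpha-helix propensity profiling and missense-impact ranking.
#
# A per-residue propensity scale (Palpha) is averaged over a sliding window
# of odd width with uniform weights; profiles are reported only at centers
# where the full window fits, ProtScale-style. The impact of a missense
# mutation is the mutant-minus-wildtype profile difference, which for a
# uniform window is exactly (Palpha(alt) - Palpha(ref)) / window at every
# covered center and 0 elsewhere.

.scale_registry <- new.env(parent = emptyenv())

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Retrieve a residue propensity scale
#'
#' The bundled scale \code{"chou_fasman_helix"} holds the Chou-Fasman
#' alpha-helix formation propensities Palpha (e.g. Glu 1.51, Ala 1.42,
#' Pro 0.57). Additional scales can be added with [register_scale()].
#'
#' @param name scale name.
#' @return list of class \code{propensity_scale}: \code{name} and
#'   \code{values}, a named numeric over the 20 one-letter amino acids.
#' @export
propensity_scale <- function(name = "chou_fasman_helix") {
  if (!exists(name, envir = .scale_registry, inherits = FALSE)) {
    f <- system.file("extdata", paste0(name, ".tsv"), package = "enuscan")
    if (!nzchar(f)) stop("unknown propensity scale: ", name, call. = FALSE)
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    register_scale(name, stats::setNames(tab$palpha, tab$aa))
  }
  get(name, envir = .scale_registry, inherits = FALSE)
}

#' Register a propensity scale by name
#'
#' @param name scale name.
#' @param values named numeric vector over exactly the 20 one-letter amino
#'   acids; all values must be positive.
#' @return the registered \code{propensity_scale}, invisibly.
#' @export
register_scale <- function(name, values) {
  if (!setequal(names(values), unname(.aa3to1)) || length(values) != 20) {
    stop("scale must cover exactly the 20 amino acids", call. = FALSE)
  }
  if (any(values <= 0)) stop("propensities must be positive", call. = FALSE)
  sc <- structure(list(name = name, values = values[unname(.aa3to1)]),
                  class = "propensity_scale")
  assign(name, sc, envir = .scale_registry)
  invisible(sc)
}

#' Parse a protein-level mutation specification
#'
#' Accepts one-letter ("p.F191S") or three-letter ("p.Ser192Pro") HGVS-style
#' substitutions and normalizes to one-letter codes.
#'
#' @param text mutation string.
#' @return list of class \code{mutation_spec}: \code{ref_aa},
#'   \code{position}, \code{alt_aa}, \code{notation} (canonical one-letter
#'   form).
#' @export
parse_mutation <- function(text) {
  m1 <- regmatches(text, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", text))[[1]]
  m3 <- regmatches(text,
                   regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                           text))[[1]]
  if (length(m1) == 4) {
    ref <- m1[2]; pos <- as.integer(m1[3]); alt <- m1[4]
    if (!(ref %in% .aa3to1) || !(alt %in% .aa3to1)) {
      stop("unknown amino-acid code in ", text, call. = FALSE)
    }
  } else if (length(m3) == 4) {
    if (!(m3[2] %in% names(.aa3to1)) || !(m3[4] %in% names(.aa3to1))) {
      stop("unknown amino-acid code in ", text, call. = FALSE)
    }
    ref <- .aa3to1[[m3[2]]]; pos <- as.integer(m3[3]); alt <- .aa3to1[[m3[4]]]
  } else {
    stop("malformed mutation spec: ", text,
         " (expected p.<ref><pos><alt>)", call. = FALSE)
  }
  if (ref == alt) stop("ref and alt residues identical in ", text,
                       call. = FALSE)
  structure(list(ref_aa = ref, position = pos, alt_aa = alt,
                 notation = paste0("p.", ref, pos, alt)),
            class = "mutation_spec")
}

.check_residues <- function(seq) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seq)) {
    stop("non-canonical residue in sequence", call. = FALSE)
  }
}

#' Sliding-window helix-propensity profile
#'
#' Uniform-weight mean of the scale over every full window; centers are in
#' protein coordinates (\code{offset} = coordinate of the first residue).
#'
#' @param seq amino-acid sequence string.
#' @param offset protein coordinate of the first residue (default 1).
#' @param scale a [propensity_scale()].
#' @param window odd window width, \code{1 <= window <= nchar(seq)}
#'   (default 9, the ProtScale default with 100\%/100\% edge weights).
#' @param sequence_id label carried into the profile.
#' @return list of class \code{helix_profile}: \code{sequence_id},
#'   \code{offset}, \code{window}, and \code{scores}, a data.frame with
#'   columns \code{center} (protein coordinate) and \code{score}.
#' @export
window_profile <- function(seq, offset = 1L,
                           scale = propensity_scale(), window = 9L,
                           sequence_id = NA_character_) {
  .check_residues(seq)
  L <- nchar(seq)
  if (window %% 2 == 0 || window < 1) stop("window must be odd and >= 1",
                                           call. = FALSE)
  if (window > L) stop("window (", window, ") exceeds sequence length (",
                       L, ")", call. = FALSE)
  p <- scale$values[strsplit(seq, "")[[1]]]
  half <- (window - 1L) %/% 2L
  n_out <- L - window + 1L
  scores <- vapply(seq_len(n_out), function(s)
    mean(p[s:(s + window - 1L)]), 0)
  list(sequence_id = sequence_id, offset = offset, window = window,
       scores = data.frame(center = offset + half + seq_len(n_out) - 1L,
                           score = unname(scores))) |>
    structure(class = "helix_profile")
}

#' Apply a missense mutation to a sequence
#'
#' @param seq amino-acid sequence string.
#' @param offset protein coordinate of the first residue.
#' @param m a \code{mutation_spec} (or string parsed by [parse_mutation()]).
#' @return the mutated sequence; errors if the position falls outside the
#'   sequence or the reference residue does not match (guards coordinate
#'   bugs).
#' @export
apply_mutation <- function(seq, offset, m) {
  if (is.character(m)) m <- parse_mutation(m)
  .check_residues(seq)
  idx <- m$position - offset + 1L
  if (idx < 1 || idx > nchar(seq)) {
    stop("position ", m$position, " outside sequence [", offset, ", ",
         offset + nchar(seq) - 1L, "]", call. = FALSE)
  }
  obs <- substr(seq, idx, idx)
  if (obs != m$ref_aa) {
    stop("reference mismatch at ", m$position, ": spec says ", m$ref_aa,
         ", sequence has ", obs, call. = FALSE)
  }
  paste0(substr(seq, 1, idx - 1L), m$alt_aa,
         substr(seq, idx + 1L, nchar(seq)))
}

#' Helix-score impact of a missense mutation
#'
#' Computes the mutant-minus-wildtype profile difference. With uniform
#' window weights every center whose window covers the mutated site shifts
#' by exactly \code{(Palpha(alt) - Palpha(ref)) / window}; all other centers
#' are unchanged.
#'
#' @inheritParams window_profile
#' @param m a \code{mutation_spec} or string.
#' @return list of class \code{mutation_impact}: \code{mutation},
#'   \code{delta_palpha} (Palpha(alt) - Palpha(ref)),
#'   \code{max_abs_window_delta}, \code{sum_window_delta}, and
#'   \code{profile}, a data.frame (center, wt_score, mut_score, delta).
#' @export
mutation_impact <- function(seq, offset, m, scale = propensity_scale(),
                            window = 9L) {
  if (is.character(m)) m <- parse_mutation(m)
  wt <- window_profile(seq, offset, scale, window)
  mut <- window_profile(apply_mutation(seq, offset, m), offset, scale,
                        window)
  delta <- mut$scores$score - wt$scores$score
  structure(list(
    mutation = m,
    delta_palpha = unname(scale$values[m$alt_aa] - scale$values[m$ref_aa]),
    max_abs_window_delta = max(abs(delta)),
    sum_window_delta = sum(delta),
    profile = data.frame(center = wt$scores$center,
                         wt_score = wt$scores$score,
                         mut_score = mut$scores$score, delta = delta)),
    class = "mutation_impact")
}

#' Rank missense mutations by helix disruption
#'
#' Orders mutations from most to least helix-disrupting by
#' \code{max_abs_window_delta}; ties are broken by smaller position, then
#' by notation.
#'
#' @inheritParams mutation_impact
#' @param mutations list of \code{mutation_spec} objects or strings.
#' @return data.frame in rank order with columns \code{notation},
#'   \code{position}, \code{delta_palpha}, \code{max_abs_window_delta},
#'   \code{sum_window_delta}.
#' @export
rank_mutations <- function(seq, offset, mutations,
                           scale = propensity_scale(), window = 9L) {
  specs <- lapply(mutations, function(m)
    if (is.character(m)) parse_mutation(m) else m)
  imp <- lapply(specs, function(m)
    mutation_impact(seq, offset, m, scale, window))
  df <- data.frame(
    notation = vapply(specs, `[[`, "", "notation"),
    position = vapply(specs, `[[`, 0L, "position"),
    delta_palpha = vapply(imp, `[[`, 0, "delta_palpha"),
    max_abs_window_delta = vapply(imp, `[[`, 0, "max_abs_window_delta"),
    sum_window_delta = vapply(imp, `[[`, 0, "sum_window_delta"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$max_abs_window_delta, df$position, df$notation), ]
  rownames(df) <- NULL
  df
}
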