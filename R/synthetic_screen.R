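# Synthetic dominant ENU-screen generator.
#
# Emulates the screen end to end: a Poisson mutation load on the mutagenized
# founder genome with a transition-biased substitution spectrum, one planted
# dominant causal allele, Mendelian transmission to a genotype panel and
# through repeated backcrosses, binomial sampling of alternate-supporting
# reads at log-uniform depth, and missing-at-random genotyping. All
# randomness flows from cfg$seed: simulate_variants() seeds with cfg$seed,
# simulate_panel() with cfg$seed + 1 and simulate_backcross() with
# cfg$seed + 2, so each stage is independently reproducible.

.default_enu_spectrum <- c(
  "A>G" = 0.19, "T>C" = 0.19, "A>T" = 0.22, "T>A" = 0.22,
  "A>C" = 0.04, "T>G" = 0.04, "G>A" = 0.04, "C>T" = 0.04,
  "G>C" = 0.005, "C>G" = 0.005, "G>T" = 0.005, "C>A" = 0.005)

#' Screen simulation configuration
#'
#' Defaults mirror the mapped screen: an expected load of 160 exome-captured
#' mutations of which 97\% fall in gene regions, a genotype panel of 7
#' affected and 5 unaffected mice with the bundled panel's missing-call
#' density (110/192), full penetrance of the dominant causal allele, per-
#' variant sequencing depth log-uniform over the observed 7-244 range, and a
#' ten-generation backcross.
#'
#' @param seed integer random seed (mandatory).
#' @param n_variants Poisson mean of the mutation load (default 160).
#' @param genic_fraction probability a variant is genic (default 0.97).
#' @param class_weights named weights over genic location classes.
#' @param effect_weights named weights over exonic effect classes
#'   (transition-heavy ENU yields mostly missense changes).
#' @param n_affected,n_unaffected panel sizes (defaults 7 and 5).
#' @param missing_prob per-cell genotyping missingness (default 110/192).
#' @param depth_range depth sampled log-uniformly over this range.
#' @param het_fraction_mean expected allelic fraction of a heterozygote.
#' @param penetrance probability a carrier of the causal allele is affected.
#' @param phenocopy_rate probability a non-carrier is affected.
#' @param backcross_generations number of backcross generations (default 10).
#' @param recomb_fraction if non-NULL, recombination fraction assigned to
#'   non-causal variants on the causal chromosome (models linked passenger
#'   mutations); all other variants are unlinked (r = 0.5).
#' @param enu_spectrum named substitution weights ("ref>alt").
#' @return list of class \code{screen_config}.
#' @export
screen_config <- function(seed,
                          n_variants = 160,
                          genic_fraction = 0.97,
                          class_weights = c(exonic = 0.15, intronic = 0.70,
                                            UTR5 = 0.05, UTR3 = 0.10,
                                            splicing = 0.00),
                          effect_weights = c(nonsynonymous = 0.70,
                                             synonymous = 0.25,
                                             stopgain = 0.04,
                                             stoploss = 0.01),
                          n_affected = 7L, n_unaffected = 5L,
                          missing_prob = 110 / 192,
                          depth_range = c(7L, 244L),
                          het_fraction_mean = 0.5,
                          penetrance = 1.0, phenocopy_rate = 0.0,
                          backcross_generations = 10L,
                          recomb_fraction = NULL,
                          enu_spectrum = .default_enu_spectrum) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_variants > 0,
            genic_fraction >= 0, genic_fraction <= 1,
            missing_prob >= 0, missing_prob <= 1,
            penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            het_fraction_mean > 0, het_fraction_mean < 1,
            backcross_generations >= 1)
  structure(list(seed = as.integer(seed), n_variants = n_variants,
                 genic_fraction = genic_fraction,
                 class_weights = class_weights,
                 effect_weights = effect_weights,
                 n_affected = as.integer(n_affected),
                 n_unaffected = as.integer(n_unaffected),
                 missing_prob = missing_prob,
                 depth_range = depth_range,
                 het_fraction_mean = het_fraction_mean,
                 penetrance = penetrance, phenocopy_rate = phenocopy_rate,
                 backcross_generations = as.integer(backcross_generations),
                 recomb_fraction = recomb_fraction,
                 enu_spectrum = enu_spectrum),
            class = "screen_config")
}

.sample_depth <- function(n, range) {
  as.integer(round(exp(stats::runif(n, log(range[1]), log(range[2])))))
}

#' Simulate the founder mutation load and the two sequenced exomes
#'
#' Draws the mutation count from Poisson(\code{n_variants}), assigns
#' location/effect classes and a transition-biased substitution per variant,
#' plants exactly one causal exonic nonsynonymous allele, and generates the
#' call sets of one sequenced affected and one sequenced unaffected sibling
#' (each non-causal variant transmitted independently with probability 1/2;
#' the causal allele is carried by the affected and absent from the
#' unaffected animal). Alternate-supporting reads are
#' Binomial(depth, \code{het_fraction_mean}); because the screen is
#' ascertained on having discovered its causal variant, the causal allele's
#' read draw is conditioned on clearing the screen's support and fraction
#' thresholds.
#'
#' @param cfg a [screen_config()].
#' @return list with \code{affected_calls} and \code{unaffected_calls}
#'   (variant tables) and \code{truth}, a \code{screen_truth} list:
#'   \code{causal_variant_id}, \code{variant_id}, \code{variants} (full
#'   founder variant table), \code{affected_carrier},
#'   \code{unaffected_carrier} (named logicals), \code{recomb_fraction}
#'   (named, r vs the causal locus; 0.5 = unlinked), \code{causal_chrom}.
#' @export
simulate_variants <- function(cfg) {
  set.seed(cfg$seed)
  n <- max(1L, stats::rpois(1, cfg$n_variants))
  genic <- stats::runif(n) < cfg$genic_fraction
  loc <- ifelse(genic,
                sample(names(cfg$class_weights), n, replace = TRUE,
                       prob = cfg$class_weights),
                "intergenic")
  eff <- ifelse(loc == "exonic",
                sample(names(cfg$effect_weights), n, replace = TRUE,
                       prob = cfg$effect_weights),
                "unknown")
  sub <- sample(names(cfg$enu_spectrum), n, replace = TRUE,
                prob = cfg$enu_spectrum)
  ref <- substr(sub, 1, 1)
  alt <- substr(sub, 3, 3)
  chrom <- sample(c(as.character(1:19), "X"), n, replace = TRUE)
  pos <- sample.int(120e6, n)
  # plant the causal allele: genic, exonic, nonsynonymous
  causal <- sample.int(n, 1)
  loc[causal] <- "exonic"
  eff[causal] <- "nonsynonymous"
  gene <- ifelse(loc == "intergenic", "",
                 sprintf("Gene%04d", seq_len(n)))
  id <- ifelse(nzchar(gene), gene, paste0(chrom, ":", pos))
  variants <- as_variant_table(data.frame(
    chrom = chrom, start = pos, end = pos, ref = ref, alt = alt,
    alt_reads = 0L, depth = 1L, location_class = loc, effect_class = eff,
    gene = gene, stringsAsFactors = FALSE))
  aff_carrier <- stats::runif(n) < 0.5
  unaff_carrier <- stats::runif(n) < 0.5
  aff_carrier[causal] <- TRUE
  unaff_carrier[causal] <- FALSE
  names(aff_carrier) <- names(unaff_carrier) <- id

  make_calls <- function(carried, causal_idx = NA) {
    idx <- which(carried)
    depth <- .sample_depth(length(idx), cfg$depth_range)
    altr <- stats::rbinom(length(idx), depth, cfg$het_fraction_mean)
    if (!is.na(causal_idx)) {
      j <- match(causal_idx, idx)
      # ascertainment: the discovered causal call clears criteria (a), (b)
      while (altr[j] <= 4 || altr[j] / depth[j] <= 0.3 ||
             altr[j] / depth[j] >= 0.8) {
        depth[j] <- .sample_depth(1, cfg$depth_range)
        altr[j] <- stats::rbinom(1, depth[j], cfg$het_fraction_mean)
      }
    }
    v <- variants[idx, , drop = FALSE]
    v$depth <- depth
    v$alt_reads <- altr
    v$fraction <- altr / depth
    as_variant_table(v)
  }
  affected_calls <- make_calls(aff_carrier, causal)
  unaffected_calls <- make_calls(unaff_carrier)

  r <- rep(0.5, n)
  if (!is.null(cfg$recomb_fraction)) {
    r[chrom == chrom[causal]] <- cfg$recomb_fraction
  }
  r[causal] <- 0
  names(r) <- id
  truth <- structure(list(causal_variant_id = id[causal],
                          variant_id = id, variants = variants,
                          affected_carrier = aff_carrier,
                          unaffected_carrier = unaff_carrier,
                          recomb_fraction = r,
                          causal_chrom = chrom[causal]),
                     class = "screen_truth")
  list(affected_calls = affected_calls,
       unaffected_calls = unaffected_calls, truth = truth)
}

#' Simulate a genotype/phenotype panel from the screen truth
#'
#' Draws mice until the affected/unaffected quotas are filled: each mouse
#' inherits the causal allele with probability 1/2 and is affected with
#' probability \code{penetrance} if a carrier (\code{phenocopy_rate}
#' otherwise). Every other variant co-segregates with the causal allele
#' according to its recombination fraction (r = 0.5 means independent
#' transmission). Cells are then masked to \code{"?"} with
#' \code{missing_prob}.
#'
#' @param truth a \code{screen_truth} from [simulate_variants()].
#' @param cfg the same [screen_config()].
#' @param variants optional character vector restricting the panel to these
#'   variant ids (default: all variants in the truth).
#' @return a \code{segregation_panel}.
#' @export
simulate_panel <- function(truth, cfg, variants = NULL) {
  set.seed(cfg$seed + 1L)
  ids <- variants %||% truth$variant_id
  stopifnot(all(ids %in% truth$variant_id))
  r <- truth$recomb_fraction[ids]
  causal_in <- truth$causal_variant_id %in% ids

  n_aff <- 0L; n_un <- 0L
  cols <- list(); phen <- character()
  while (n_aff < cfg$n_affected || n_un < cfg$n_unaffected) {
    cc <- stats::runif(1) < 0.5
    affected <- stats::runif(1) <
      (if (cc) cfg$penetrance else cfg$phenocopy_rate)
    if (affected && n_aff >= cfg$n_affected) next
    if (!affected && n_un >= cfg$n_unaffected) next
    carrier <- ifelse(stats::runif(length(ids)) < 1 - r, cc, !cc)
    if (causal_in) carrier[ids == truth$causal_variant_id] <- cc
    cols[[length(cols) + 1L]] <- ifelse(carrier, "+", "-")
    phen <- c(phen, if (affected) "affected" else "unaffected")
    if (affected) n_aff <- n_aff + 1L else n_un <- n_un + 1L
  }
  calls <- do.call(cbind, cols)
  miss <- matrix(stats::runif(length(calls)) < cfg$missing_prob,
                 nrow = nrow(calls))
  calls[miss] <- "?"
  ord <- order(phen != "affected")
  calls <- calls[, ord, drop = FALSE]
  phen <- phen[ord]
  mid <- character(length(phen))
  mid[phen == "affected"] <- paste0("A", seq_len(sum(phen == "affected")))
  mid[phen == "unaffected"] <- paste0("U", seq_len(sum(phen == "unaffected")))
  segregation_panel(
    data.frame(mouse_id = mid, phenotype = phen, stringsAsFactors = FALSE),
    ids, calls)
}

#' Simulate variant persistence through a backcross
#'
#' In each backcross generation a phenotype-selected affected animal is
#' crossed to wildtype, so the causal allele is retained by construction; a
#' passenger variant survives a generation only while co-inherited with the
#' causal allele, i.e. with probability \code{(1 - r)} per generation
#' (\code{2^-1} per generation when unlinked), giving persistence
#' \code{(1 - r)^n} after \code{n} generations.
#'
#' @param truth a \code{screen_truth}.
#' @param cfg the same [screen_config()].
#' @return named logical vector: is the variant present in the generation-n
#'   affected animal?
#' @export
simulate_backcross <- function(truth, cfg) {
  set.seed(cfg$seed + 2L)
  n <- cfg$backcross_generations
  r <- truth$recomb_fraction
  present <- stats::runif(length(r)) < (1 - r)^n
  present[truth$variant_id == truth$causal_variant_id] <- TRUE
  names(present) <- truth$variant_id
  present
}

#' Run the full synthetic screen
#'
#' Convenience wrapper chaining [simulate_variants()], [simulate_panel()]
#' and [simulate_backcross()].
#'
#' @param cfg a [screen_config()].
#' @return list: \code{affected_calls}, \code{unaffected_calls},
#'   \code{truth}, \code{panel}, \code{backcross}.
#' @export
simulate_screen <- function(cfg) {
  sim <- simulate_variants(cfg)
  sim$panel <- simulate_panel(sim$truth, cfg)
  sim$backcross <- simulate_backcross(sim$truth, cfg)
  sim
}
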