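---
title: "Mapping dominant ENU-induced mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dominant ENU-induced mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enuscan)
```

## The mapping problem

A dominant forward-genetics screen injects male mice (G0) with the point
mutagen ENU, breeds G1 offspring, and selects families in which a visible
phenotype — here hindlimb polydactyly — is inherited dominantly. Exome
sequencing of one affected animal yields on the order of a few hundred
induced point mutations, of which exactly one is causal. `enuscan`
implements the down-stream mapping arithmetic: candidate filtering from the
affected/unaffected exome pair, co-segregation exclusion over a genotyped
pedigree panel, backcross disassociation, penetrance/expressivity
statistics, and Chou–Fasman helix-propensity scoring of candidate missense
changes.

## Candidate filtering

A call in the affected exome is a candidate only if it clears three
criteria, all with strict inequalities:

1. **Read support**: alternate-supporting reads $> 4$;
2. **Heterozygous band**: allelic fraction (alt reads / depth) strictly
   inside $(0.3, 0.8)$, and no call with the same (chrom, pos, ref, alt)
   key in the unaffected exome;
3. **Functional class**: splicing-site, or exonic with a nonsynonymous /
   stop-gain / stop-loss effect.

The band targets germline heterozygotes, whose expected fraction is 0.5;
at depth 16 the exact binomial probability of a heterozygote falling inside
the open band is `sum(dbinom(5:12, 16, 0.5))` ≈ 0.92. The unaffected-sample
exclusion uses the full allele key, so a different alternate allele at the
same locus does not exclude. A `unaffected_noise_floor` (default 0) lets
callers that emit low-fraction noise be tolerated; with several unaffected
exomes, presence in *any* of them excludes by default. `stoploss` is
included among functional classes by analogy with stop-gain.

## Co-segregation exclusion

Genotypes over a panel of affected and unaffected relatives are coded
`+` (carrier), `-` (non-carrier), `?` (not genotyped). Under the fully
penetrant dominant model every genotyped affected mouse must be `+` and
every genotyped unaffected mouse `-`; one contradiction excludes the
variant, `?` cells are skipped but counted out of the informative totals.
A verdict supported by fewer than `min_informative` genotypes (default 2)
is flagged *vacuous*: an all-`?` row is formally consistent but evidentially
empty. When several variants survive, all are reported — the package never
auto-picks a winner. An incomplete-penetrance mode (tolerate unaffected
carriers, contradict only on affected non-carriers) is available behind a
flag and off by default, matching the screen's fully penetrant design.

The bundled 16-variant × 12-mouse panel fixture is transcribed verbatim
from the screen this package models, including its mixed typography for the
minus sign (both U+2212 and the ASCII hyphen are accepted and normalized)
and its original row order, which lists one chromosome-6 variant out of
sorted order; the fixture preserves that order rather than re-sorting.
Evaluating it excludes 15 of the 16 candidates and leaves a single
survivor, *Twist1* p.F191S, with all 12 mice informative.

Backcross disassociation is the complementary exclusion: after $n$
generations of crossing phenotype-selected affected animals to wildtype, a
passenger variant survives only while co-inherited with the causal allele —
probability $(1-r)^n$ for recombination fraction $r$, i.e. $2^{-n}$ when
unlinked. A variant absent from a late-generation affected animal is
disassociated; an ungenotyped animal yields an error, never a verdict.

## Penetrance and expressivity

Penetrance is $100 \times$ affected genotyped carriers / all genotyped
carriers; mice missing the genotype contribute to neither side, and
obligate carriers are never imputed from the pedigree. Expressivity splits
affected animals by laterality (bilateral vs unilateral), as percentages
over animals with known laterality. All reported percentages use half-up
rounding to one decimal (so 16/19 → 84.2, 3/19 → 15.8, 6/11 → 54.5); full
precision is kept internally. A Wilson score interval is available via
`conf_level`. The published record for this screen contains two different
unilateral percentages (15.8 and 16.8); the package follows the value
internally consistent with the bilateral 84.2.

## Helix-propensity scoring

The Chou–Fasman α-helix propensity $P_\alpha$ is a per-residue empirical
scale (bundled: Glu 1.51, Ala 1.42, …, Pro 0.57, Gly 0.57). A profile is
the uniform-weight sliding mean over an odd window, reported only at
centers where the full window fits — the ProtScale convention, which also
keeps mutation deltas exact. The screen's source did not state its window,
so the default is ProtScale's (window 9, 100%/100% edge weights) and the
window is a parameter.

For a missense mutation the mutant-minus-wildtype profile difference is
zero at every center whose window misses the site and exactly
$\Delta P_\alpha / w$ at every center that covers it — a closed form the
tests assert. Ranking by `max_abs_window_delta` is therefore
window-independent in order, and on the 13-residue transactivation-domain
peptide (positions 185–197, reconstructed by translating the wildtype
codons embedded in the published mutagenesis primers) it gives
A190T ($|\Delta P_\alpha| = 0.59$) ≻ F191S (0.36) ≻ S192P (0.20) for every
odd window 5–11: strongest, intermediate, mildest. Ties break by position,
then notation. Full Chou–Fasman secondary-structure *assignment*
(nucleation/extension) is out of scope; only the propensity profile is
computed.

## The synthetic screen generator

`screen_config()` fixes the study conditions; its defaults are the screen's
own scale and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_variants` | 160 | Poisson mean mutation load of the sequenced exome |
| `genic_fraction` | 0.97 | probability a variant falls in a gene region |
| `class_weights` | exonic .15, intronic .70, UTR5 .05, UTR3 .10 | location mix within genic |
| `effect_weights` | nonsyn .70, syn .25, stopgain .04, stoploss .01 | exonic effect mix |
| `n_affected`, `n_unaffected` | 7, 5 | genotype panel sizes |
| `missing_prob` | 110/192 | per-cell `?` probability, the bundled panel's observed sparsity |
| `depth_range` | 7–244 | per-call depth, log-uniform (the observed depth extremes) |
| `het_fraction_mean` | 0.5 | binomial success probability for alt reads |
| `penetrance` | 1.0 | P(carrier is affected) |
| `backcross_generations` | 10 | generations for the disassociation cross |

The location/effect weights are a declared convention chosen so that the
expected nonsynonymous load matches the 16 the screen reported
(160 × 0.97 × 0.15 × 0.70 ≈ 16); the depth model likewise, since only four
per-site depths are on record. The ENU substitution spectrum defaults to
the transition-biased table (A:T→G:C and A:T→T:A enriched) typical of
spermatogonial ENU and is overridable.

Two modelling choices deserve note. First, all induced mutations arise on
the mutagenized founder haplotype, so a passenger variant co-segregates
with the causal allele according to its recombination fraction; unlinked
variants are modelled as $r = 0.5$, and `recomb_fraction` can plant linked
passengers on the causal chromosome (the linked-intronic scenario that the
backcross resolves). Second, the causal variant's simulated read draw is
conditioned (by rejection) on clearing the support and fraction criteria:
the screen is *ascertained* on having discovered its causal allele, and
without that conditioning a low-depth draw could hide the very allele the
study is defined by. No other call is conditioned, so allelic-fraction
statistics on passengers remain exactly binomial.

Determinism: `simulate_variants()`, `simulate_panel()` and
`simulate_backcross()` seed the RNG with `seed`, `seed + 1` and `seed + 2`
respectively, so each stage is independently reproducible and a full
`simulate_screen()` is bit-identical across runs.

What the generator does *not* emulate: read-level errors and mapping
artefacts, a real genetic map (positions are labels), homozygous-lethality
selection, and phenocopies (off by default via `phenocopy_rate`). Passing
recovery tests on synthetic screens therefore demonstrates the logic of the
pipeline, not robustness to caller-specific noise.

## Problem sizes used in the checks

The bundled worked examples are desk-scale (16 × 12 panel, 4-row variant
table) and run in milliseconds. The stochastic properties use 200 seeds for
the load/genic expectations, 100 seeds for end-to-end causal recovery
(expected false-survivor rate ≈ candidates × $2^{-12}$, hence the mean
survivor count bound of 1.2), and $10^4$ replicates for the backcross
persistence probability $2^{-10}$, each compared at three standard errors.

## Limitations

* Exclusion mapping is purely deterministic; no LOD scores, recombination
  mapping or genotype imputation.
* Variant annotation (location/effect classes) is consumed, not computed.
* Minimal VCF dialect only: single-allelic records, INFO keys
  `DP`/`AO`/`LOC`/`EFF`/`GENE`; no FORMAT/genotype columns.
* The helix module scores propensity profiles; it does not predict
  secondary-structure segments or 3-D structure.
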