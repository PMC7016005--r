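# enuscan

Forward-genetics mapping toolkit for dominant ENU mutagenesis screens in
the mouse, written for screen analysts who have an affected/unaffected
exome pair, a Sanger-genotyped pedigree panel, and a shortlist of candidate
missense mutations to rank.

An ENU screen induces a Poisson load of point mutations on the founder
genome; exactly one is causal for the selected phenotype. `enuscan` covers
the mapping arithmetic end to end:

* **Candidate filtering** — a call is a candidate iff alt-supporting reads
  > 4, allelic fraction strictly in (0.3, 0.8), no identical allele in the
  unaffected exome, and a functional annotation class (nonsynonymous,
  stop-gain/loss, splicing).
* **Co-segregation exclusion** — under a fully penetrant dominant model,
  genotyped affected mice must be carriers (`+`) and unaffected mice
  non-carriers (`-`); one contradiction excludes a variant, `?` cells are
  skipped.
* **Backcross disassociation** — a passenger variant survives n
  phenotype-selected backcross generations with probability (1−r)^n
  (2^−n when unlinked); absence from a late-generation affected animal
  disassociates it.
* **Penetrance / expressivity** — penetrance = 100 × affected genotyped
  carriers / genotyped carriers; laterality composition and per-trait
  penetrance with half-up one-decimal rounding.
* **Helix-impact ranking** — Chou–Fasman α-helix propensity profiles
  (uniform sliding window, full windows only); a missense change shifts
  every covering window by exactly ΔPα/w, so mutations are ranked by
  |ΔPα|/w.
* **Synthetic screen simulator** — generates exomes, panels and backcross
  genotypes with a planted causal allele for end-to-end validation.

## Worked example

The package bundles the screen's printed genotype panel (16 candidate
variants × 7 affected + 5 unaffected mice) and chromosome-12 variant table:

```r
library(enuscan)

panel <- table1_panel()
report <- evaluate_panel(panel)
report
#> cosegregation_report: 16 variants; 15 excluded; 1 surviving (Twist1)

penetrance(panel, report$surviving)
#> penetrance of Twist1: 100% (7/7 genotyped carriers affected)

apply_criteria(table2_variants())$candidates[, c("gene", "fraction", "depth")]
#>     gene fraction depth
#> 1 Twist1   0.4375    16

pep <- ta_domain_peptide()   # ERLSYAFSVWRME, protein positions 185-197
rank_mutations(pep$sequence, pep$offset, c("p.A190T", "p.F191S", "p.S192P"))
#>   notation position delta_palpha max_abs_window_delta sum_window_delta
#> 1  p.A190T      190        -0.59           0.06555556       -0.3277778
#> 2  p.F191S      191        -0.36           0.04000000       -0.2000000
#> 3  p.S192P      192        -0.20           0.02222222       -0.1111111
```

Fifteen of the sixteen candidates are contradicted by at least one
genotyped mouse; the surviving *Twist1* variant is fully penetrant in the
panel, is the only record clearing the three filter criteria (allelic
fraction 0.4375 at depth 16), and its p.F191S substitution has an
intermediate helix-disrupting effect — stronger than S192P, weaker than
A190T — for every odd window width.

A thin command-line front end wraps the same functions:

```sh
inst/exec/enuscan coseg  --panel inst/extdata/table1_panel.tsv --out report.tsv
inst/exec/enuscan helix  --fasta inst/extdata/ta_domain.fa --offset 185 \
    --mutations p.A190T,p.F191S,p.S192P --window 9 --out impact.tsv
inst/exec/enuscan simulate --seed 17 --outdir sim/
```

## Layout

* `R/` — implementation (variant/panel/peptide I/O, filter,
  co-segregation, phenotype statistics, helix scoring, simulator, CLI)
* `inst/extdata/` — transcribed panel and variant-table fixtures, the
  TA-domain peptide, the Chou–Fasman Pα scale
* `vignettes/enu-screen-mapping.Rmd` — models, assumptions, parameter
  defaults and design choices
* `tests/testthat/` — unit, property and end-to-end tests with independent
  straight-line oracles
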