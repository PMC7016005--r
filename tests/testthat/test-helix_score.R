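setup_pep <- function() ta_domain_peptide()

test_that("mutation notation parses and normalizes", {
  m <- parse_mutation("p.F191S")
  expect_equal(m$ref_aa, "F")
  expect_equal(m$position, 191L)
  expect_equal(m$alt_aa, "S")
  expect_equal(m$notation, "p.F191S")
  m3 <- parse_mutation("p.Ser192Pro")
  expect_equal(m3$notation, "p.S192P")
  expect_error(parse_mutation("p.F191F"), "identical")
  expect_error(parse_mutation("F191S"), "malformed")
  expect_error(parse_mutation("p.B191S"), "unknown amino-acid")
})

test_that("the bundled propensity scale is complete and positive", {
  sc <- propensity_scale()
  expect_equal(length(sc$values), 20)
  expect_true(all(sc$values > 0))
  # the three substitutions of interest under this scale
  expect_equal(unname(sc$values["T"] - sc$values["A"]), -0.59)
  expect_equal(unname(sc$values["S"] - sc$values["F"]), -0.36)
  expect_equal(unname(sc$values["P"] - sc$values["S"]), -0.20)
  expect_error(register_scale("bad", c(A = 1)), "20 amino acids")
})

test_that("window profiles are uniform sliding means over full windows", {
  sc <- propensity_scale()
  # constant sequence: single full window equals the residue propensity
  pa <- window_profile(strrep("A", 9), 1, sc, 9)
  expect_equal(nrow(pa$scores), 1)
  expect_equal(pa$scores$score, unname(sc$values["A"]))
  # degenerate window 1 equals per-residue propensities
  p <- setup_pep()
  w1 <- window_profile(p$sequence, p$offset, sc, 1)
  expect_equal(w1$scores$score,
               unname(sc$values[strsplit(p$sequence, "")[[1]]]))
  expect_equal(w1$scores$center, 185:197)
  # 13-mer at window 9: 5 centers, 189-193, hand-checked means
  w9 <- window_profile(p$sequence, p$offset, sc, 9)
  expect_equal(nrow(w9$scores), 13 - 9 + 1)
  expect_equal(w9$scores$center, 189:193)
  hand <- vapply(1:5, function(s)
    mean(sc$values[strsplit(p$sequence, "")[[1]]][s:(s + 8)]), 0)
  expect_equal(w9$scores$score, hand)
  expect_error(window_profile(p$sequence, p$offset, sc, 15), "exceeds")
  expect_error(window_profile(p$sequence, p$offset, sc, 4), "odd")
  expect_error(window_profile("ABZ", 1, sc, 1), "non-canonical")
})

test_that("in-silico mutagenesis substitutes the right residue", {
  p <- setup_pep()
  expect_equal(apply_mutation(p$sequence, p$offset, "p.F191S"),
               "ERLSYASSVWRME")
  expect_equal(apply_mutation(p$sequence, p$offset, "p.A190T"),
               "ERLSYTFSVWRME")
  expect_error(apply_mutation(p$sequence, p$offset, "p.F190S"),
               "mismatch")
  expect_error(apply_mutation(p$sequence, p$offset, "p.F300S"),
               "outside")
})

test_that("window deltas have the closed form delta_palpha / window", {
  p <- setup_pep()
  sc <- propensity_scale()
  for (w in c(5L, 7L, 9L, 11L, 13L)) {
    imp <- mutation_impact(p$sequence, p$offset, "p.S192P", sc, w)
    expect_equal(imp$delta_palpha,
                 unname(sc$values["P"] - sc$values["S"]))
    expect_lt(imp$delta_palpha, 0)
    nz <- imp$profile$delta[imp$profile$delta != 0]
    expect_true(all(abs(nz - imp$delta_palpha / w) < 1e-12))
    expect_equal(imp$max_abs_window_delta, abs(imp$delta_palpha) / w)
    # locality: only centers whose window covers 192 change
    half <- (w - 1) / 2
    covered <- abs(imp$profile$center - 192) <= half
    expect_equal(imp$profile$delta != 0, covered)
  }
  # neutral substitution: Trp and Ile share Palpha 1.08 under this scale
  neutral <- mutation_impact("AWA", 1, "p.W2I", sc, 1)
  expect_equal(neutral$max_abs_window_delta, 0)
  # site at the edge with window = length: the single window shifts
  edge <- mutation_impact("EAAAA", 1, "p.E1G", sc, 5)
  expect_equal(nrow(edge$profile), 1)
  expect_equal(edge$profile$delta,
               unname(sc$values["G"] - sc$values["E"]) / 5)
})

test_that("mutation ranking reproduces strongest/intermediate/mildest", {
  p <- setup_pep()
  for (w in c(5L, 7L, 9L, 11L)) {
    ranked <- rank_mutations(p$sequence, p$offset,
                             c("p.A190T", "p.F191S", "p.S192P"),
                             window = w)
    expect_equal(ranked$notation, c("p.A190T", "p.F191S", "p.S192P"))
  }
  single <- rank_mutations(p$sequence, p$offset, "p.F191S")
  expect_equal(nrow(single), 1)
  # equal |delta| ties break by smaller position: L1087/I have equal Palpha?
  # use two substitutions with identical propensity change instead
  sc <- propensity_scale()
  tie <- rank_mutations("AFAFA", 1, c("p.F4S", "p.F2S"), sc, 1)
  expect_equal(tie$notation, c("p.F2S", "p.F4S"))
})
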