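test_that("per-variant evaluation follows the dominant model", {
  p <- table1_panel()
  tw <- evaluate_variant(p$calls["Twist1", ], p$mice,
                         variant_id = "Twist1")
  expect_true(tw$consistent)
  expect_equal(nrow(tw$contradictions), 0)
  expect_equal(tw$informative_affected, 7)
  expect_equal(tw$informative_unaffected, 5)
  expect_false(tw$vacuous)

  # a single genotyped affected non-carrier contradicts
  tm <- evaluate_variant(p$calls["Tmprss15", ], p$mice,
                         variant_id = "Tmprss15")
  expect_false(tm$consistent)
  expect_equal(nrow(tm$contradictions), 1)
  expect_equal(tm$contradictions$observed, "-")
  expect_equal(tm$contradictions$expected, "+")

  allq <- evaluate_variant(rep("?", 12), p$mice)
  expect_true(allq$consistent)
  expect_true(allq$vacuous)
  expect_equal(allq$informative_affected + allq$informative_unaffected, 0)

  expect_error(evaluate_variant(c("+", "-"), p$mice), "mismatch")
})

test_that("the bundled panel leaves a single survivor", {
  rep <- evaluate_panel(table1_panel())
  expect_equal(length(rep$excluded), 15)
  expect_equal(rep$surviving, "Twist1")
  expect_equal(intersect(rep$surviving, rep$excluded), character(0))
  expect_error(evaluate_panel(segregation_panel(
    data.frame(mouse_id = "m", phenotype = "affected"),
    character(0), matrix(character(0), 0, 1))), "empty")
})

test_that("unaffected mice alone exclude every unaffected-carrier row", {
  p <- table1_panel()
  keep <- p$mice$phenotype == "unaffected"
  sub <- segregation_panel(p$mice[keep, ], p$variants,
                           p$calls[, keep, drop = FALSE])
  rep <- evaluate_panel(sub, min_informative = 1)
  expect_true("Twist1" %in% rep$surviving)
  # rows printed with at least one "+" in an unaffected column
  expect_true(all(c("Lcorl", "Oas3", "Xirp1", "Slc18b1", "Herc2", "Hemk1",
                    "Hebp1") %in% rep$excluded))
  by_hand <- p$variants[apply(p$calls[, keep, drop = FALSE] == "+", 1, any)]
  expect_setequal(rep$excluded, by_hand)
})

test_that("panel verdicts equal the brute-force scan on random panels", {
  set.seed(31)
  for (i in 1:4) {
    p <- random_panel(50)
    rep <- evaluate_panel(p, min_informative = 0)
    expect_equal(rep$results$consistent, oracle_coseg(p))
  }
})

test_that("missing cells are neutral and informative flips break consistency", {
  set.seed(41)
  p <- random_panel(20)
  rep0 <- evaluate_panel(p, min_informative = 0)
  # adding a mouse with all-MISSING calls never changes any verdict
  p2 <- segregation_panel(
    rbind(p$mice, data.frame(mouse_id = "extra", phenotype = "affected",
                             generation = NA_character_,
                             laterality = "unknown")),
    p$variants, cbind(p$calls, "?"))
  rep2 <- evaluate_panel(p2, min_informative = 0)
  expect_equal(rep2$results$consistent, rep0$results$consistent)
  # flipping an informative affected call to "-" always breaks a
  # consistent variant
  cons <- which(rep0$results$consistent)
  aff_cols <- which(p$mice$phenotype == "affected")
  for (i in cons) {
    inf <- aff_cols[p$calls[i, aff_cols] == "+"]
    if (!length(inf)) next
    p3 <- p
    p3$calls[i, inf[1]] <- "-"
    expect_false(evaluate_panel(p3, min_informative = 0)$results$consistent[i])
  }
  # permutation invariance over mouse columns
  perm <- sample(ncol(p$calls))
  pp <- segregation_panel(p$mice[perm, ], p$variants,
                          p$calls[, perm, drop = FALSE])
  expect_equal(evaluate_panel(pp, min_informative = 0)$results$consistent,
               rep0$results$consistent)
})

test_that("incomplete-penetrance mode tolerates unaffected carriers", {
  mice <- data.frame(mouse_id = c("a1", "u1"),
                     phenotype = c("affected", "unaffected"))
  r <- evaluate_variant(c("+", "+"), mice, incomplete_penetrance = TRUE)
  expect_true(r$consistent)
  r2 <- evaluate_variant(c("-", "+"), mice, incomplete_penetrance = TRUE)
  expect_false(r2$consistent)
})

test_that("disassociation verdicts come only from observed genotypes", {
  v <- table2_variants()
  geno <- ifelse(v$present_in_backcross_affected, "+", "-")
  verdict <- vapply(seq_len(nrow(v)), function(i)
    disassociation_check(v[i, ], geno[i]), logical(1))
  expect_equal(verdict, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(v$gene[verdict], c("Srp54a", "Ppm1a", "Fut8"))
  expect_true(all(v$location_class[verdict] == "intronic"))
  expect_error(disassociation_check(v[1, ], "?"), "indeterminate")
})
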