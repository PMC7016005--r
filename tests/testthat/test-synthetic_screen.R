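test_that("generator defaults reproduce the screen scale in expectation", {
  counts <- genic <- numeric(200)
  for (i in seq_len(200)) {
    sim <- simulate_variants(screen_config(seed = 1000L + i))
    counts[i] <- nrow(sim$truth$variants)
    genic[i] <- summarize_calls(sim$truth$variants)$genic_fraction
  }
  # Poisson(160) mean over 200 seeds
  expect_lt(abs(mean(counts) - 160), 3 * sqrt(160 / 200))
  se_genic <- sqrt(0.97 * 0.03 / (160 * 200))
  expect_lt(abs(mean(genic) - 0.97), 3 * se_genic + 0.002)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- screen_config(seed = 5L)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$affected_calls, b$affected_calls)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$backcross, b$backcross)
})

test_that("noiseless limit: the causal variant is always recovered", {
  for (s in 1:20) {
    cfg <- screen_config(seed = s, missing_prob = 0)
    sim <- simulate_variants(cfg)
    cs <- apply_criteria(sim$affected_calls, sim$unaffected_calls)
    cid <- sim$truth$causal_variant_id
    expect_true(cid %in% cs$candidates$gene)
    panel <- simulate_panel(sim$truth, cfg,
                            variants = cs$candidates$gene)
    rep <- evaluate_panel(panel)
    expect_true(cid %in% rep$surviving)
  }
})

test_that("panel transmission honours penetrance, linkage and missingness", {
  cfg <- screen_config(seed = 7L)
  sim <- simulate_variants(cfg)
  # default missingness matches the bundled panel's density in expectation
  miss <- vapply(1:30, function(s) {
    p <- simulate_panel(sim$truth, screen_config(seed = s))
    mean(p$calls == "?")
  }, 0)
  expect_lt(abs(mean(miss) - 110 / 192), 0.03)

  # penetrance 1, missingness 0: causal row is all-+/all--
  p0 <- simulate_panel(sim$truth, screen_config(seed = 7L,
                                                missing_prob = 0))
  crow <- p0$calls[sim$truth$causal_variant_id, ]
  expect_equal(unname(crow[p0$mice$phenotype == "affected"]), rep("+", 7))
  expect_equal(unname(crow[p0$mice$phenotype == "unaffected"]), rep("-", 5))

  # a perfectly linked variant always matches the causal row
  truth <- sim$truth
  other <- setdiff(truth$variant_id, truth$causal_variant_id)[1]
  truth$recomb_fraction[other] <- 0
  p1 <- simulate_panel(truth, screen_config(seed = 8L, missing_prob = 0))
  expect_equal(unname(p1$calls[other, ]),
               unname(p1$calls[truth$causal_variant_id, ]))
})

test_that("backcross persistence follows (1 - r)^n", {
  # analytic oracle: unlinked persistence after 10 generations is 2^-10
  mk_truth <- function(n_var) {
    structure(list(causal_variant_id = "causal",
                   variant_id = c("causal", paste0("v", seq_len(n_var))),
                   recomb_fraction = c(0, rep(0.5, n_var))),
              class = "screen_truth")
  }
  truth <- mk_truth(10000)
  pres <- simulate_backcross(truth, screen_config(seed = 3L))
  expect_true(pres[["causal"]])
  p_hat <- mean(pres[-1])
  p0 <- 2^-10
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
  # r = 0 is never disassociated
  truth$recomb_fraction[] <- 0
  expect_true(all(simulate_backcross(truth, screen_config(seed = 4L))))
})

test_that("simulated heterozygous fractions match the binomial band mass", {
  cfg <- screen_config(seed = 2L, depth_range = c(16L, 16L),
                       n_variants = 400)
  sims <- lapply(1:25, function(s)
    simulate_variants(screen_config(seed = s, depth_range = c(16L, 16L),
                                    n_variants = 400)))
  fr <- unlist(lapply(sims, function(s) {
    f <- s$affected_calls$fraction
    # drop the ascertained causal call, which is conditioned on the band
    f[s$affected_calls$gene != s$truth$causal_variant_id]
  }))
  inside <- mean(fr > 0.3 & fr < 0.8)
  expected <- sum(stats::dbinom(5:12, 16, 0.5))
  expect_lt(abs(inside - expected),
            3 * sqrt(expected * (1 - expected) / length(fr)))
})

test_that("end-to-end recovery: the planted allele survives the pipeline", {
  hits <- 0L
  sizes <- integer(100)
  for (s in seq_len(100)) {
    cfg <- screen_config(seed = 20000L + s, missing_prob = 0)
    sim <- simulate_variants(cfg)
    cs <- apply_criteria(sim$affected_calls, sim$unaffected_calls)
    panel <- simulate_panel(sim$truth, cfg, variants = cs$candidates$gene)
    rep <- evaluate_panel(panel)
    if (sim$truth$causal_variant_id %in% rep$surviving) hits <- hits + 1L
    sizes[s] <- length(rep$surviving)
  }
  expect_equal(hits, 100L)
  expect_lte(mean(sizes), 1.2)
})
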