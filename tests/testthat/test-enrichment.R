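test_that("the 2x2 enrichment table and odds ratio follow the cross-product", {
  # universe 1000 (200 in set), selected 100 (40 in set)
  universe <- paste0("p", 1:1000)
  target <- locus_set("SET", universe[1:200])
  selected <- c(universe[1:40], universe[201:260])
  e <- fisher_enrichment(selected, target, universe)
  expect_equal(unname(e$table), c(40, 60, 160, 740))
  expect_equal(e$odds_ratio, 40 * 740 / (60 * 160))
  expect_equal(e$p_value, oracle_fisher_p(40, 60, 160, 740), tolerance = 1e-10)
  expect_lt(e$ci_low, e$odds_ratio)
  expect_gt(e$ci_high, e$odds_ratio)
  expect_error(fisher_enrichment(c("zzz"), target, universe), "subset")
})

test_that("odds ratio is invariant under simultaneous row/column swap", {
  set.seed(6)
  for (i in 1:25) {
    tab <- rpois(4, 20) + 1
    e1 <- fisher_counts(tab[1], tab[2], tab[3], tab[4])
    e2 <- fisher_counts(tab[4], tab[3], tab[2], tab[1])
    expect_equal(e1$odds_ratio, e2$odds_ratio)
    expect_equal(e1$p_value, e2$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate tables are flagged and carry no p-value", {
  # selected = all of target = universe: b = c = d = 0
  u <- paste0("p", 1:5)
  e <- fisher_enrichment(u, locus_set("S", u), u)
  expect_true(e$degenerate)
  expect_true(is.na(e$p_value))
  expect_true(e$haldane_corrected)
})

test_that("random selections show no enrichment on average", {
  set.seed(7)
  universe <- paste0("p", 1:1000)
  target <- locus_set("SET", universe[1:200])
  lors <- ps <- numeric(200)
  for (i in seq_len(200)) {
    sel <- sample(universe, 100)
    e <- fisher_enrichment(sel, target, universe)
    lors[i] <- log(e$odds_ratio)
    ps[i] <- e$p_value
  }
  lors <- lors[is.finite(lors)]
  expect_lt(abs(mean(lors)), 0.08)
  expect_gt(mean(ps < 0.05), 0.0)  # sanity: p computed
  expect_lt(mean(ps < 0.05), 0.12) # near-nominal false positive rate
})

test_that("baseline filtering defines the enrichment universe", {
  nm <- c(a = 0.1, b = 0.1, c = 0.1, d = 0.5, e = 0.6, f = 0.9)
  cm <- c(a = 0.3, b = 0.05, c = 0.4, d = 0.5, e = 0.6, f = 0.9)
  tgt <- locus_set("T", c("a", "c"))
  e <- baseline_matched_enrichment(nm, cm, tgt, "hyper", 0.2)
  expect_setequal(e$universe, c("a", "b", "c"))
  expect_setequal(e$selected, c("a", "c"))

  nm_high <- c(x = 0.9, y = 0.95)
  expect_warning(
    e2 <- baseline_matched_enrichment(nm_high, nm_high, tgt, "hyper", 0.2),
    "baseline")
  expect_true(e2$degenerate)
})

test_that("planted hypermethylation at target probes is detected", {
  set.seed(8)
  n <- 2000
  probes <- paste0("p", seq_len(n))
  is_t <- seq_len(n) <= 300
  nm <- setNames(runif(n, 0.02, 0.18), probes)      # all pass baseline < 0.2
  cm <- nm + ifelse(is_t, rbinom(n, 1, 0.5) * 0.4, 0) +
    rnorm(n, 0, 0.005)
  tgt <- locus_set("T", probes[is_t])
  e <- baseline_matched_enrichment(nm, cm, tgt, "hyper", 0.2)
  expect_gt(e$odds_ratio, 1)
  expect_lt(e$p_value, 0.01)
})

test_that("control-matched enrichment isolates the baseline effect", {
  set.seed(9)
  n <- 1500
  probes <- paste0("p", seq_len(n))
  is_t <- seq_len(n) <= 250
  nm <- setNames(numeric(n), probes)
  nm[is_t] <- runif(250, 0.82, 0.88)
  nm[!is_t] <- runif(n - 250, 0.3, 0.95)
  tgt <- locus_set("T", probes[is_t])

  # equal demethylation of targets and matched controls: no enrichment
  cm0 <- nm - rbinom(n, 1, 0.3) * 0.5
  e0 <- control_matched_enrichment(nm, cm0, tgt, "hypo",
                                   baseline_band = c(0.8, 0.9))
  expect_lt(abs(log(e0$odds_ratio)), log(2))

  # only targets demethylated: strong enrichment
  cm1 <- nm - ifelse(is_t, rbinom(n, 1, 0.4) * 0.5, 0)
  e1 <- control_matched_enrichment(nm, cm1, tgt, "hypo",
                                   baseline_band = c(0.8, 0.9))
  expect_gt(e1$odds_ratio, 1)
  expect_lt(e1$p_value, 0.01)
  # controls restricted to the band
  expect_true(all(nm[setdiff(e1$universe, tgt$members)] > 0.8))

  expect_error(control_matched_enrichment(nm[is_t], cm1[is_t], tgt, "hypo",
                                          baseline_band = c(0.8, 0.9)),
               "band")
})
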