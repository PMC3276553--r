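test_that("tertile grouping is balanced and deterministic under ties", {
  g <- tertile_groups(1:9)
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  expect_equal(as.character(g[1:3]), rep("lower", 3))

  # heavy ties at the cut: assignment follows input order, reproducibly
  x <- c(1, 2, 2, 2, 2, 3)
  g1 <- suppressMessages(tertile_groups(x))
  g2 <- suppressMessages(tertile_groups(x))
  expect_identical(g1, g2)
  expect_equal(as.vector(table(g1)), c(2, 2, 2))

  expect_error(tertile_groups(c(1, 2)), "fewer than 3")
  expect_error(tertile_groups(rep(5, 10)), "constant")
})

test_that("Cox fits recover a planted hazard ratio and fail loudly", {
  set.seed(12)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(log(2) * x))
  cc <- rexp(n, 0.05)
  fit <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), x, standardize = FALSE)
  expect_gt(fit$hr, 1.6)
  expect_lt(fit$hr, 2.5)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  expect_error(cox_fit(tt, rep(0L, n), x), class = "cox_no_events")
  expect_error(cox_fit(tt, as.integer(tt <= cc), rep(1, n)),
               class = "cox_constant_index")
  # tertile-contrast mode labels its scale
  fit_t <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), x, tertile = TRUE)
  expect_match(fit_t$scale, "tertile")
  expect_gt(fit_t$hr, 1)
})

test_that("covariate screening keeps univariately prognostic factors", {
  set.seed(13)
  n <- 300
  x <- rnorm(n); junk <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.8 * x))
  keep <- suppressMessages(
    screen_covariates(tt, rep(1L, n), data.frame(x = x, junk = junk)))
  expect_true("x" %in% keep)
  expect_false("junk" %in% keep)
})

test_that("KM curves and the log-rank test behave at the boundaries", {
  tt <- c(1, 2, 3, 4, 5, 6)
  ev <- rep(1L, 6)
  # identical groups: p = 1
  km <- km_curves(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(km$logrank_p, 1, tolerance = 1e-9)
  # perfectly separated: p tiny
  km2 <- km_curves(c(1:10, 101:110), rep(1L, 20), rep(c("a", "b"), each = 10))
  expect_lt(km2$logrank_p, 1e-4)
  # all censored: curves stay at 1, no deaths
  km3 <- km_curves(tt, rep(0L, 6), rep(c("a", "b"), each = 3))
  expect_true(all(km3$fit$surv == 1))
  # single group: curves only
  km4 <- km_curves(tt, ev, rep("a", 6))
  expect_true(is.na(km4$logrank_p))
})

test_that("the one-tailed rank-sum test matches exact enumeration", {
  out <- stage_shift_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(out$exact)
  expect_equal(out$p_value, 1 / choose(6, 3))   # 0.05

  same <- stage_shift_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)

  tied <- stage_shift_test(rep(2, 4), rep(2, 5))
  expect_equal(tied$p_value, 1)
  expect_true(tied$all_tied)

  set.seed(14)
  b <- rnorm(30, 1); a <- rnorm(30)
  expect_lt(stage_shift_test(a, b)$p_value, 0.01)
})

test_that("AUC equals pair concordance and survives monotone transforms", {
  r <- roc_auc(c(0.1, 0.4, 0.2, 0.9), c("p", "p", "m", "m"), positive = "m")
  expect_equal(r$auc, 0.75)   # 3 of 4 concordant pairs
  expect_equal(r$n_pos, 2)

  perfect <- suppressWarnings(
    roc_auc(c(1, 2, 3, 10, 11, 12),
            rep(c("p", "m"), each = 3), positive = "m"))
  expect_equal(perfect$auc, 1)

  set.seed(15)
  idx <- rnorm(200)
  lab <- rep(c("p", "m"), each = 100)
  r1 <- roc_auc(idx, lab, positive = "m")
  r2 <- roc_auc(exp(3 * idx), lab, positive = "m")
  expect_equal(r1$auc, r2$auc)
  expect_lt(abs(r1$auc - 0.5), 0.12)
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)
  # oracle cross-check on random data with ties
  scores <- sample(1:5, 60, replace = TRUE)
  lab2 <- rep(c("p", "m"), each = 30)
  expect_equal(roc_auc(scores, lab2, positive = "m")$auc,
               oracle_auc(scores[31:60], scores[1:30]))
  expect_error(roc_auc(1:5, rep("m", 5), positive = "m"), "two classes")
})

test_that("TET anti-correlation enrichment finds planted MESC structure", {
  set.seed(16)
  n_s <- 60; n_p <- 500
  probes <- paste0("p", seq_len(n_p))
  is_mesc <- seq_len(n_p) <= 150
  tet <- rnorm(n_s)
  v <- matrix(0.6, n_p, n_s, dimnames = list(probes, NULL))
  # beta = a - b*TET + noise on MESC probes only
  v[is_mesc, ] <- 0.6 - 0.08 * matrix(tet, sum(is_mesc), n_s, byrow = TRUE)
  v <- pmin(pmax(v + rnorm(n_p * n_s, 0, 0.05), 0), 1)
  bm <- make_bm(v)
  mesc <- locus_set("MESC", probes[is_mesc])
  res <- tet_anticorrelation(bm, probes, setNames(tet, bm$samples$sample_id),
                             mesc)
  expect_gt(res$enrichment$odds_ratio, 1)
  expect_lt(res$enrichment$p_value, 0.01)
  # ranked from most anti-correlated; MESC probes concentrate at the top
  expect_gt(mean(res$correlations$is_mesc[1:100]), 0.8)

  # permuted expression: no enrichment
  res0 <- tet_anticorrelation(bm, probes, sample(tet), mesc)
  expect_true(is.na(res0$enrichment$p_value) ||
                res0$enrichment$p_value > 0.01)

  expect_error(tet_anticorrelation(bm, probes, rep(1, n_s), mesc), "constant")
  expect_error(tet_anticorrelation(bm[, 1:4], probes, tet[1:4], mesc),
               "at least 5")
})
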