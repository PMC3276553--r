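test_that("the simulator is fully deterministic given its config", {
  cfg <- sim_config(seed = 21, n_probes = 400)
  m1 <- simulate_manifest(cfg)
  m2 <- simulate_manifest(cfg)
  expect_identical(m1, m2)
  b1 <- quiet(simulate_cohort(cfg, "cancer", m1))
  b2 <- quiet(simulate_cohort(cfg, "cancer", m1))
  expect_identical(b1$values, b2$values)
  expect_identical(attr(b1, "truth"), attr(b2, "truth"))
  s1 <- simulate_survival(cfg, runif(30))
  expect_identical(s1, simulate_survival(cfg, runif(30)))
  expect_error(sim_config(n_probes = 10), "seed")
})

test_that("manifest class fractions and validation hold", {
  cfg <- sim_config(seed = 7, n_probes = 1000, frac_pcgt = 0.1,
                    frac_mesc = 0.2)
  sm <- simulate_manifest(cfg)
  expect_length(sm$pcgt$members, 100)
  expect_length(sm$mesc$members, 200)
  expect_equal(sum(sm$manifest$is_pcgt), 100)
  expect_length(intersect(sm$pcgt$members, sm$mesc$members), 0)
  # PMD flags are realised by the emitted intervals
  man2 <- quiet(annotate_manifest(sm$manifest[, 1:4], pmd = sm$pmd))
  expect_equal(man2$is_pmd, sm$manifest$is_pmd)
  expect_error(sim_config(seed = 1, frac_pcgt = 0.6, frac_mesc = 0.6))
  expect_error(sim_config(seed = 1,
                          mesc_loss_prob = c(0.4, 0.3, 0.2, 0.1)),
               "non-decreasing")
})

test_that("all simulated betas are in range and flips cross boundaries", {
  cfg <- sim_config(seed = 23, n_probes = 500, concentration = Inf,
                    chip_shift = 0)
  sm <- simulate_manifest(cfg)
  bm <- quiet(simulate_cohort(cfg, "cancer", sm))
  expect_true(all(bm$values >= 0 & bm$values <= 1))
  # noise-free: the truth table is exactly recoverable by the instability
  # module
  normals <- bm[, bm$samples$group == "normal"]
  cases <- bm[, bm$samples$group != "normal"]
  stable <- find_stable(normals)
  truth <- attr(bm, "truth")
  for (sid in unique(truth$sample_id)[1:5]) {
    v <- cases$values[, sid]
    names(v) <- rownames(cases$values)
    lab <- transitions(v, stable)
    called <- stable$probe_id[!is.na(lab) & lab != "none"]
    expect_setequal(called, truth$probe_id[truth$sample_id == sid])
    tt <- truth[truth$sample_id == sid, ]
    expect_equal(lab[match(tt$probe_id, stable$probe_id)],
                 tt$transition, ignore_attr = TRUE)
  }
})

test_that("zero effect probabilities leave cases at the noise floor", {
  cfg <- sim_config(seed = 24, n_probes = 800,
                    pcgt_gain_prob = c(bdy = 0, dysplasia = 0, cancer = 0,
                                       metastasis = 0),
                    mesc_loss_prob = c(bdy = 0, dysplasia = 0, cancer = 0,
                                       metastasis = 0))
  sm <- simulate_manifest(cfg)
  bm <- quiet(simulate_cohort(cfg, "cancer", sm))
  expect_equal(nrow(attr(bm, "truth")), 0)
  normals <- bm[, bm$samples$group == "normal"]
  cases <- bm[, bm$samples$group != "normal"]
  idx <- epi_indices(cases, find_stable(normals),
                     locus_sets = list(mesc = sm$mesc))
  expect_lt(mean(idx$mesc_demi, na.rm = TRUE), 0.01)
})

test_that("WGBS count simulation supports the derivation's operating range", {
  cfg <- sim_config(seed = 25, n_sites = 400, high_frac = 1)
  # true level ~0.9 at coverage 30: essentially always classified MESC
  wg <- simulate_wgbs_counts(cfg, coverage = 30)
  hi <- wg$truth$site_id[wg$truth$true_level > 0.93]
  ms <- derive_mesc(wg$counts)
  expect_gt(mean(hi %in% ms$members), 0.99)

  # intermediate levels almost never pass the 80% rule
  cfg2 <- sim_config(seed = 26, n_sites = 400, high_frac = 0)
  wg2 <- simulate_wgbs_counts(cfg2, coverage = 30)
  mid <- wg2$truth$site_id[abs(wg2$truth$true_level - 0.5) < 0.1]
  ms2 <- suppressWarnings(derive_mesc(wg2$counts))
  expect_lt(mean(mid %in% ms2$members), 0.01)

  # coverage 2 everywhere: the coverage rule excludes everything
  wg3 <- simulate_wgbs_counts(cfg, coverage = 2)
  expect_length(suppressWarnings(derive_mesc(wg3$counts))$members, 0)
})

test_that("survival simulation respects censoring and the null", {
  cfg <- sim_config(seed = 27, censoring_rate = 1)
  demi <- runif(50)
  s <- simulate_survival(cfg, demi)
  expect_true(all(s$event == 0))
  expect_error(cox_fit(s$time, s$event, demi), class = "cox_no_events")

  # null hazard: p-values uniform over replicates
  ps <- vapply(1:100, function(r) {
    cfg_r <- sim_config(seed = 5000 + r, loghr_per_sd = 0)
    set.seed(6000 + r)
    d <- rbeta(200, 2, 8)
    s <- simulate_survival(cfg_r, d)
    cox_fit(s$time, s$event, d)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("TET simulation links expression to demethylation burden", {
  cfg <- sim_config(seed = 28, tet_noise_sd = 1e-6)
  burden <- runif(40)
  expr <- simulate_tet(cfg, burden)
  expect_gt(cor(expr, burden, method = "spearman"), 0.999)
  cfg0 <- sim_config(seed = 28, tet_slope = 0)
  expr0 <- simulate_tet(cfg0, burden)
  expect_lt(abs(cor(expr0, burden)), 0.5)
})
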