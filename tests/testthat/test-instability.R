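test_that("beta discretization uses inclusive hemimethylated boundaries", {
  expect_equal(discretize(c(0.10, 0.25, 0.70, 0.701, 0.249, 0, 1)),
               c(0L, 1L, 1L, 2L, 0L, 0L, 2L))
  expect_true(is.na(discretize(NA_real_)))
  expect_error(discretize(1.2), "\\[0, 1\\]")
})

test_that("stable CpGs require an identical state in all normals", {
  v <- rbind(cg1 = c(0.80, 0.90, 0.75),   # states 2,2,2 -> stable
             cg2 = c(0.80, 0.69, 0.90),   # states 2,1,2 -> not stable
             cg3 = c(0.10, 0.20, 0.24),   # states 0,0,0 -> stable
             cg4 = c(NA, 0.80, 0.90))     # 2 usable normals -> stable
  st <- find_stable(make_bm(v))
  expect_setequal(st$probe_id, c("cg1", "cg3", "cg4"))
  expect_equal(st$stable_state[st$probe_id == "cg1"], 2L)
  expect_equal(st$normal_mean_beta[st$probe_id == "cg1"], mean(c(.8, .9, .75)))
  expect_equal(st$stable_state[st$probe_id == "cg3"], 0L)
  expect_equal(st$n_normals[st$probe_id == "cg4"], 2L)
  expect_error(find_stable(make_bm(v[, 1, drop = FALSE])), "2 normal")
})

test_that("transition calls need both a state change and the beta buffer", {
  st <- data.frame(probe_id = c("a", "b", "c"),
                   stable_state = c(2L, 2L, 2L),
                   normal_mean_beta = c(0.80, 0.75, 0.80),
                   n_normals = 3L)
  class(st) <- c("stable_set", "data.frame")
  tumour <- c(a = 0.68, b = 0.69, c = 0.73)
  lab <- transitions(tumour, st)
  expect_equal(unname(lab), c("2->0/1",  # state 1, delta 0.12 >= 0.10
                              "none",    # state 1 but delta 0.06 < 0.10
                              "none"))   # still state 2
  # missing tumour beta propagates as NA (dropped from denominators)
  expect_true(is.na(transitions(c(a = NA, b = 0.69, c = 0.73), st)[1]))
})

test_that("transition calling agrees with a brute-force oracle on a beta grid", {
  grid <- seq(0, 1, by = 0.01)
  for (s0 in 0:2) {
    for (nmb in c(0.10, 0.24, 0.5, 0.69, 0.80, 0.95)) {
      st0 <- if (nmb < 0.25) 0L else if (nmb <= 0.7) 1L else 2L
      if (st0 != s0) next
      st <- data.frame(probe_id = paste0("g", seq_along(grid)),
                       stable_state = s0, normal_mean_beta = nmb,
                       n_normals = 3L)
      class(st) <- c("stable_set", "data.frame")
      got <- transitions(setNames(grid, st$probe_id), st)
      want <- vapply(grid, oracle_transition, character(1),
                     stable_state = s0, normal_mean = nmb)
      expect_equal(unname(got), want)
    }
  }
})

test_that("indices are monotone non-increasing in the buffer", {
  set.seed(10)
  st <- data.frame(probe_id = paste0("g", 1:200),
                   stable_state = sample(0:2, 200, replace = TRUE),
                   normal_mean_beta = runif(200), n_normals = 3L)
  st$normal_mean_beta <- c(0.1, 0.5, 0.85)[st$stable_state + 1] +
    runif(200, -0.05, 0.05)
  class(st) <- c("stable_set", "data.frame")
  tumour <- setNames(runif(200), st$probe_id)
  buffers <- c(0, 0.05, 0.10, 0.2, 0.4)
  counts <- vapply(buffers, function(b)
    sum(transitions(tumour, st, buffer = b) != "none", na.rm = TRUE),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the four indices match the hand-worked examples", {
  # 4 stable state-2 MESC probes; transitions qualify at probes 1 and 3
  st <- data.frame(probe_id = paste0("m", 1:4), stable_state = 2L,
                   normal_mean_beta = c(0.80, 0.85, 0.90, 0.75),
                   n_normals = 3L)
  class(st) <- c("stable_set", "data.frame")
  tumour <- setNames(c(0.68, 0.73, 0.20, 0.69), st$probe_id)
  mesc <- locus_set("MESC", st$probe_id)
  idx <- epi_indices(tumour, st, locus_sets = list(mesc = mesc))
  expect_equal(idx$demi, 0.5)
  expect_equal(idx$mesc_demi, 0.5)
  expect_equal(idx$n2, 4)
  # no state-0/1 stable probes: those indices are undefined, not zero
  expect_true(is.na(idx$f_0_gain))
  expect_true(is.na(idx$f_1_gain))

  # tumour identical to the normal means: all indices zero
  idx0 <- epi_indices(setNames(st$normal_mean_beta, st$probe_id), st)
  expect_equal(idx0$demi, 0)
})

test_that("combined DeMI pools transitions over the pooled denominator", {
  st <- data.frame(probe_id = paste0("m", 1:6),
                   stable_state = c(1L, 1L, 2L, 2L, 2L, 2L),
                   normal_mean_beta = c(0.5, 0.5, 0.85, 0.85, 0.85, 0.85),
                   n_normals = 3L)
  class(st) <- c("stable_set", "data.frame")
  mesc <- locus_set("MESC", st$probe_id)
  # one 1->0 transition and two 2->0/1 transitions: 3 / 6
  tumour <- setNames(c(0.10, 0.5, 0.10, 0.15, 0.85, 0.85), st$probe_id)
  expect_equal(combined_demi(tumour, st, mesc), 0.5)
  # no transitions -> 0; all transition -> 1
  expect_equal(combined_demi(setNames(st$normal_mean_beta, st$probe_id),
                             st, mesc), 0)
  expect_equal(combined_demi(setNames(rep(0.05, 6), st$probe_id), st, mesc), 1)
  expect_warning(
    expect_true(is.na(combined_demi(tumour, st, locus_set("M", "zz")))),
    "no stable MESC")
})

test_that("hypomethylation frequency counts qualifying tumours per probe", {
  st <- data.frame(probe_id = c("m1", "m2", "m3"), stable_state = 2L,
                   normal_mean_beta = 0.85, n_normals = 3L)
  class(st) <- c("stable_set", "data.frame")
  mesc <- locus_set("MESC", st$probe_id)
  v <- rbind(m1 = c(0.1, 0.1, 0.1, 0.85, 0.85, 0.85, 0.85, 0.85, 0.85, 0.85),
             m2 = rep(0.85, 10),
             m3 = c(rep(0.1, 5), rep(0.85, 5)))
  hf <- hypo_frequency(make_bm(v), st, mesc)
  expect_equal(hf$probe_id, c("m3", "m1", "m2"))  # sorted by frequency
  expect_equal(hf$frequency, c(0.5, 0.3, 0))
  expect_equal(hf$probe_id[3], "m2")              # never demethylated: last
})

test_that("indices are invariant to probe and normal-sample ordering", {
  set.seed(11)
  v <- matrix(c(runif(30, 0.75, 0.95)), 10, 3,
              dimnames = list(paste0("cg", 1:10), NULL))
  tumour <- setNames(runif(10), paste0("cg", 1:10))
  st1 <- find_stable(make_bm(v))
  st2 <- find_stable(make_bm(v[sample(10), c(3, 1, 2)]))
  i1 <- epi_indices(tumour, st1)
  i2 <- epi_indices(tumour, st2)
  expect_equal(i1$demi, i2$demi)
  expect_equal(i1$n2, i2$n2)
})
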