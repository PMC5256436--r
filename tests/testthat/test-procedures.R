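test_that("showup rates match the closed-form normal operating point", {
  m <- eq_model(1.5)
  pool <- sample_trials(m, 10000, 10000, lineup_size = 1, seed = 101)
  r <- run_showup(pool, criteria = 1.00)
  # (F, H) = (pnorm(-1), pnorm(0.5)) = (0.1587, 0.6915)
  expect_lt(abs(r$H - pnorm(0.5)), rate_tol(pnorm(0.5), 10000))
  expect_lt(abs(r$F - pnorm(-1)), rate_tol(pnorm(-1), 10000))
  # full sweep matches H = pnorm(d' - c), F = pnorm(-c) pointwise
  sweep <- seq(-2, 3, by = 0.25)
  rs <- run_showup(pool, criteria = sweep)
  expect_true(all(abs(rs$H - pnorm(1.5 - sweep)) <=
                    rate_tol(pnorm(1.5 - sweep), 10000) + 1e-12))
  expect_true(all(abs(rs$F - pnorm(-sweep)) <=
                    rate_tol(pnorm(-sweep), 10000) + 1e-12))
})

test_that("degenerate criteria behave: d'=0 gives H=F, +inf criterion gives (0,0)", {
  pool0 <- sample_trials(evidence_model(0), 5000, 5000, lineup_size = 1, seed = 102)
  r0 <- run_showup(pool0, criteria = c(-0.5, 0.5))
  expect_true(all(abs(r0$H - r0$F) < rate_tol(0.5, 5000) * sqrt(2)))
  pool <- sample_trials(eq_model(), 1000, 1000, lineup_size = 6, seed = 103)
  hi <- run_simultaneous(pool, criteria = 50)
  expect_identical(c(hi$H, hi$F), c(0, 0))
  fi <- run_sequential(pool, criteria = 50, variant = "first_id")
  expect_identical(c(fi$H, fi$F), c(0, 0))
})

test_that("TA chance rate is capped at 1/N under the divide-by-N convention", {
  pool <- sample_trials(eq_model(), 200, 5000, lineup_size = 6, seed = 104)
  r <- run_simultaneous(pool, criteria = -50)
  expect_equal(r$F, 1 / 6)  # every TA lineup yields an ID; rate / 6 exactly
  expect_equal(r$filler_id_rate_ta, 5 / 6)
})

test_that("rates are proper and category rates sum to one within trial type", {
  pool <- sample_trials(eq_model(), 2000, 2000, lineup_size = 6, seed = 105)
  for (r in list(run_simultaneous(pool),
                 run_simultaneous(pool, rule = "relative_guess"),
                 run_sequential(pool, variant = "first_id"))) {
    expect_true(all(r$H >= 0 & r$H <= 1 & r$F >= 0 & r$F <= 1))
    expect_equal(r$H + r$filler_id_rate_tp + r$rejection_rate_tp,
                 rep(1, nrow(r)))
    expect_equal(r$F + r$filler_id_rate_ta + r$rejection_rate_ta,
                 rep(1, nrow(r)))
  }
})

test_that("H and F are exactly non-increasing in the criterion on a shared pool", {
  pool <- sample_trials(eq_model(), 3000, 3000, lineup_size = 6, seed = 106)
  for (r in list(run_simultaneous(pool),
                 run_simultaneous(pool, rule = "relative_reject"),
                 run_simultaneous(pool, rule = "relative_guess"),
                 run_sequential(pool, variant = "any_id"))) {
    expect_true(all(diff(r$H) <= 0))
    expect_true(all(diff(r$F) <= 0))
  }
})

test_that("a zero margin makes the relative rule identical to the absolute rule", {
  pool <- sample_trials(eq_model(), 2000, 2000, lineup_size = 6, seed = 107)
  sweep <- criterion_sweep(eq_model())
  abs_r <- run_simultaneous(pool, sweep, rule = "absolute")
  rel0 <- run_simultaneous(pool, sweep, rule = "relative_reject", delta = 0)
  expect_equal(dplyr::select(as.data.frame(rel0), -rule),
               dplyr::select(as.data.frame(abs_r), -rule))
})

test_that("guessing on small margins only adds identifications", {
  pool <- sample_trials(eq_model(), 4000, 4000, lineup_size = 6, seed = 108)
  sweep <- criterion_sweep(eq_model())
  reject <- run_simultaneous(pool, sweep, rule = "relative_reject")
  guess <- run_simultaneous(pool, sweep, rule = "relative_guess")
  expect_true(all(guess$H >= reject$H))
  expect_true(all(guess$F >= reject$F))
  # and relative rules are (weakly) more conservative than the absolute rule
  abs_r <- run_simultaneous(pool, sweep, rule = "absolute")
  expect_true(all(reject$H <= abs_r$H))
  expect_true(all(reject$F <= abs_r$F))
})

test_that("any-ID sequential reproduces the absolute simultaneous rule trial by trial", {
  pool <- sample_trials(eq_model(), 3000, 3000, lineup_size = 6, seed = 109)
  sweep <- criterion_sweep(eq_model())
  sim <- run_simultaneous(pool, sweep, rule = "absolute")
  seq_any <- run_sequential(pool, sweep, variant = "any_id")
  # identical response-category rates at every criterion (same trials)
  expect_equal(seq_any$H, sim$H)
  expect_equal(seq_any$F, sim$F)
  expect_equal(seq_any$filler_id_rate_tp, sim$filler_id_rate_tp)
  expect_equal(seq_any$rejection_rate_ta, sim$rejection_rate_ta)
})

test_that("first-ID sequential hits 1/6 at a floor criterion and is nonmonotone", {
  pool <- sample_trials(eq_model(), 10000, 10000, lineup_size = 6, seed = 110)
  sweep <- c(-10, criterion_sweep(eq_model()))
  r <- run_sequential(pool, sweep, variant = "first_id")
  h_floor <- r$H[r$criterion == -10]
  expect_lt(abs(h_floor - 1 / 6), rate_tol(1 / 6, 10000))
  # interior maximum exceeds the liberal limit: the ROC folds back
  expect_gt(max(r$H), h_floor + 4 * rate_tol(1 / 6, 10000))
  # F itself stays monotone in the criterion
  expect_true(all(diff(r$F) <= 0))
})

test_that("growing the lineup weakly depresses both H and F at a fixed criterion", {
  m <- eq_model(1.5)
  crit <- 1.0
  rates <- purrr::map_dfr(c(1, 2, 3, 6), function(N) {
    pool <- sample_trials(m, 8000, 8000, lineup_size = N, seed = 111 + N)
    if (N == 1) run_showup(pool, crit) else run_simultaneous(pool, crit)
  })
  tol <- rate_tol(0.5, 8000) * 2
  expect_true(all(diff(rates$H) <= tol))
  expect_true(all(diff(rates$F) <= tol))
})

test_that("divide-by-N and designated-innocent TA conventions agree in expectation", {
  pool <- sample_trials(eq_model(), 200, 10000, lineup_size = 6, seed = 113)
  crit <- c(0.18, 0.67, 1.53)
  div <- run_simultaneous(pool, crit, ta_convention = "divide_by_n")
  des <- run_simultaneous(pool, crit, ta_convention = "designated_innocent")
  # designated innocent is one exchangeable filler; same mean rate, more noise
  expect_true(all(abs(div$F - des$F) <= rate_tol(div$F, 10000) + 1e-12))
})

test_that("2AFC simulation matches its analytic difference-distribution ROC", {
  m <- eq_model(1.5)
  pairs <- sample_trials(m, 10000, 0, lineup_size = 2, seed = 114)
  grid <- seq(-4, 4, length.out = 21)
  r <- run_2afc(pairs, criteria = grid)
  a <- roc_2afc_analytic(m, criteria = grid)
  expect_true(all(abs(r$H - a$H) <= rate_tol(a$H, 10000) + 1e-12))
  expect_true(all(abs(r$F - a$F) <= rate_tol(a$F, 10000) + 1e-12))
  # proportion correct = H at criterion 0 = pnorm(d'/sqrt(2))
  r0 <- run_2afc(pairs, criteria = 0)
  expect_lt(abs(r0$H - pnorm(1.5 / sqrt(2))), rate_tol(pnorm(1.5 / sqrt(2)), 10000))
  # full area under the analytic rating ROC is pnorm(d') for s = 1
  dense <- roc_2afc_analytic(m, criteria = seq(-9, 9, length.out = 2001))
  expect_equal(pauc(dense, 1), pnorm(1.5), tolerance = 2e-3)
  # chance: d' = 0 pairs give AUC 1/2
  pairs0 <- sample_trials(evidence_model(0), 5000, 0, lineup_size = 2, seed = 115)
  r0afc <- run_2afc(pairs0)
  expect_equal(pauc(roc_points(r0afc), 1), 0.5, tolerance = 0.02)
})

test_that("procedure input validation rejects malformed pools", {
  pool6 <- sample_trials(eq_model(), 10, 10, lineup_size = 6, seed = 116)
  expect_error(run_showup(pool6), "lineup_size = 1")
  expect_error(run_2afc(pool6), "lineup_size = 2")
  expect_error(run_simultaneous(pool6, rule = "absolute", delta = -1), "delta")
  bad <- pool6
  bad$is_guilty <- FALSE
  expect_error(run_simultaneous(bad), "exactly one guilty")
})
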