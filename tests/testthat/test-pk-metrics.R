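test_that("LLOQ censoring removes (not zeroes) unquantifiable samples", {
  p <- make_profile(c(1, 24, 500), c(0.2, 0.3, 0.1), lloq = 0.667)
  cp <- censor_below_lloq(p)
  expect_length(cp$times, 0)
  expect_true(cp$all_censored)
  expect_equal(cp$n_censored_removed, 3L)

  p2 <- make_profile(c(1, 24, 500), c(10, 5, 0.5), lloq = 0.667)
  cp2 <- censor_below_lloq(p2)
  expect_equal(cp2$times, c(1, 24))
  expect_equal(cp2$concentrations, c(10, 5))

  p3 <- make_profile(c(1, 24), c(10, 5), lloq = 0)
  expect_identical(censor_below_lloq(p3), p3)
})

test_that("NCA handles simple closed-form profiles", {
  p <- make_profile(c(0, 10), c(10, 10))
  pk <- nca(p)
  expect_equal(pk$auc_last, 100)
  expect_equal(pk$cmax, 10)

  # mono-exponential decay: half-life recovered within 0.1%
  t <- seq(0, 1008, by = 24)
  p2 <- make_profile(t, 100 * exp(-log(2) * t / 360))
  expect_equal(nca(p2)$half_life, 360, tolerance = 1e-3)

  expect_error(nca(make_profile(5, 1)), class = "insufficient_data_error")
})

test_that("trapezoid AUC matches a fine-grid oracle on random profiles", {
  set.seed(7)
  for (k in 1:10) {
    t <- sort(runif(20, 0, 500))
    c <- exp(rnorm(20, 2, 1))
    p <- make_profile(t, c)
    auc <- nca(p)$auc_last
    # oracle: integrate the linear-up/log-down interpolant segment by
    # segment with adaptive quadrature
    oracle <- sum(vapply(1:19, function(i) {
      f <- if (c[i + 1] >= c[i] || c[i] <= 0 || c[i + 1] <= 0) {
        function(x) c[i] + (c[i + 1] - c[i]) * (x - t[i]) / (t[i + 1] - t[i])
      } else {
        function(x) c[i] * (c[i + 1] / c[i])^((x - t[i]) / (t[i + 1] - t[i]))
      }
      integrate(f, t[i], t[i + 1], rel.tol = 1e-13)$value
    }, 0))
    expect_equal(auc, oracle, tolerance = 1e-9)
  }
})

test_that("AUC is additive over contiguous partitions", {
  set.seed(8)
  t <- sort(runif(30, 0, 300))
  c <- exp(rnorm(30, 1, 0.8))
  full <- nca(make_profile(t, c))$auc_last
  split <- nca(make_profile(t[1:15], c[1:15]))$auc_last +
    nca(make_profile(t[15:30], c[15:30]))$auc_last
  expect_equal(full, split, tolerance = 1e-12)
})

test_that("half-life is invariant to uniform concentration scaling", {
  t <- c(seq(0, 96, 12), seq(168, 1008, 96))
  c <- 80 * exp(-log(2) * t / 300) + 20 * exp(-t / 20)
  h1 <- nca(make_profile(t, c))$half_life
  h2 <- nca(make_profile(t, 1000 * c))$half_life
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("half-life is omitted when the terminal fit is inadequate", {
  set.seed(9)
  t <- seq(0, 100, by = 10)
  pk <- nca(make_profile(t, exp(runif(11, 0, 4)))) # noise, no trend
  expect_true(is.na(pk$half_life))
  expect_gt(pk$n_points_terminal, 0)
})

test_that("GMFE and fold statistics behave as exact arithmetic", {
  expect_equal(gmfe(pk_comparison(100, 50)), 2)
  expect_equal(gmfe(pk_comparison(c(3, 7, 11), c(3, 7, 11))), 1)
  fs <- fold_stats(pk_comparison(10, 30), k = 2)
  expect_equal(fs$n_within, 0L)
  expect_equal(fs$max_fold, 3)
  expect_error(pk_comparison(numeric(0), numeric(0)),
               class = "insufficient_data_error")
  expect_error(pk_comparison(c(1, -2), c(1, 1)), class = "validation_error")
})

test_that("GMFE is symmetric and at least 1, with equality iff identical", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(3:20, 1)
    a <- exp(rnorm(n, 3, 1)); b <- exp(rnorm(n, 3, 1))
    g1 <- gmfe(pk_comparison(a, b))
    g2 <- gmfe(pk_comparison(b, a))
    expect_equal(g1, g2, tolerance = 1e-12)
    expect_gte(g1, 1)
  }
  expect_equal(gmfe(pk_comparison(c(2, 5), c(2, 5))), 1)
  expect_gt(gmfe(pk_comparison(c(2, 5), c(2, 5.0001))), 1)
})

test_that("steady-state exposure stabilizes and scales with dose", {
  adult <- reference_adult()
  m <- build_model(adult, batch = batch_properties("b", 0.64))
  times <- sort(unique(c(seq(13 * 168, 15 * 168, by = 2),
                         13 * 168 + c(0.25, 0.5, 1),
                         14 * 168 + c(0.25, 0.5, 1))))
  s <- simulate_pbpk(m, weekly_schedule(400), times)
  e14 <- steady_state_exposure(s, 14)
  e15 <- steady_state_exposure(s, 15)
  expect_gt(e15$auc_tau / e14$auc_tau, 0.99)
  expect_lt(e15$auc_tau / e14$auc_tau, 1.01)

  s2 <- simulate_pbpk(m, weekly_schedule(800), times)
  e15b <- steady_state_exposure(s2, 15)
  expect_equal(e15b$auc_tau / e15$auc_tau, 2, tolerance = 0.05)

  single <- simulate_pbpk(m, dose_event(0, 0.5, 400), seq(0, 336, 4))
  expect_error(steady_state_exposure(single, 15), class = "span_error")
})

test_that("parameters without a pathway have zero or tiny sensitivity", {
  adult <- reference_adult()
  m <- build_model(adult, batch = batch_properties("b", 0.64))
  # multiplicative perturbation of an exactly-zero parameter stays zero
  expect_identical(local_sensitivity(m, parameter_name = "gfr_fraction",
                                     output_times = seq(1, 672, 24)), 0)
  s_asgr <- local_sensitivity(m, parameter_name = "asgr_cl_spec",
                              output_times = seq(1, 1344, 24))
  expect_lt(abs(s_asgr), 0.05)
  expect_error(local_sensitivity(m, parameter_name = "no_such_parameter"),
               class = "lookup_error")
})
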