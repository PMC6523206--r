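drug <- asunercept_parameters()
adult <- reference_adult()

test_that("ASGR clearance follows the sialylation Hill function", {
  a <- asgr_model()
  # at the half-maximum ratio the clearance is exactly half the maximum
  expect_equal(asgr_clearance_rate(a, 0.378), a$cl_spec / 2,
               tolerance = 1e-14)
  expect_equal(asgr_clearance_rate(a, 0), a$cl_spec, tolerance = 1e-14)
  # highly sialylated batches retain <2% of the maximal clearance
  cl64 <- asgr_clearance_rate(a, 0.64)
  expect_lt(cl64 / a$cl_spec, 0.02)
  # independent evaluation of the Hill expression
  h <- 8.03; k <- 0.378
  expect_equal(cl64, a$cl_spec * k^h / (0.64^h + k^h), tolerance = 1e-12)
  # strictly decreasing in the ratio
  grid <- asgr_clearance_rate(a, seq(0, 1, by = 0.05))
  expect_true(all(diff(grid) < 0))
  expect_error(asgr_clearance_rate(a, -0.1), class = "validation_error")
})

test_that("derived drug parameters are consistent", {
  expect_equal(drug$cd95l_kon, drug$cd95l_koff / drug$cd95l_kd)
  expect_equal(drug$fcrn_koff_lysosomal,
               drug$fcrn_kass * drug$fcrn_kd_lysosomal)
  expect_error(asunercept_parameters(gfr_fraction = 1.5),
               class = "validation_error")
  expect_error(asunercept_parameters(cd95l_kd = -1),
               class = "validation_error")
})

test_that("compiled right-hand side matches an independent rate oracle", {
  model <- build_model(adult, drug, batch = batch_properties("b", 0.34))
  nstates <- length(model$state_names)
  set.seed(42)
  for (k in 1:100) {
    y <- runif(nstates, 0, 1000)
    # keep receptor/target-bound pools below their capacities
    y[grep("endo_fcrn", model$state_names)] <-
      runif(15) * model$parms[asunpbpk:::parm_index("r_tot", NULL)][1:15]
    y[grep("inter_target", model$state_names)] <-
      runif(15) * model$parms[asunpbpk:::parm_index("t_tot", NULL)][1:15]
    inf <- if (k %% 2) 0 else 500
    p <- model$parms
    p[asunpbpk:::parm_index("inf_rate")] <- inf
    expect_equal(compiled_rhs(model, y, inf_rate = inf),
                 oracle_rhs(y, p), tolerance = 1e-10)
  }
})

test_that("mass balance closes for every simulation", {
  for (cfg in list(list(r = 0.64, dose = 400, dur = 1, weeks = 8),
                   list(r = 0.30, dose = 15, dur = 0.5, weeks = 6),
                   list(r = 0.45, dose = 1500, dur = 2, weeks = 10))) {
    m <- build_model(adult, drug, batch = batch_properties("b", cfg$r))
    s <- simulate_pbpk(m, dose_event(0, cfg$dur, cfg$dose),
                       seq(1, cfg$weeks * 168, by = 12))
    expect_lt(s$mass_balance_rel_error, 1e-6)
    expect_true(all(s$states >= 0))
  }
  # multiple-dose schedule
  m <- build_model(adult, drug, batch = batch_properties("b", 0.5))
  s <- simulate_pbpk(m, weekly_schedule(400, n_doses = 4),
                     seq(1, 5 * 168, by = 12))
  expect_lt(s$mass_balance_rel_error, 1e-6)
})

test_that("zero dose gives identically zero concentrations", {
  m <- build_model(adult, drug)
  s <- simulate_pbpk(m, dose_event(0, 1, 0), c(1, 24, 168))
  expect_true(all(s$profile$concentrations == 0))
})

test_that("PK is dose-linear across 0.2-20 mg/kg", {
  times <- c(1, 1.5, 2, 4, 8, seq(24, 1008, by = 24))
  doses <- c(0.2, 1, 5, 15, 20)
  pk <- lapply(doses, function(d) {
    m <- build_model(adult, drug, batch = batch_properties("b", 0.34))
    nca(simulate_pbpk(m, dose_event(0, 1, d * adult$body_weight),
                      times)$profile)
  })
  auc_norm <- vapply(pk, `[[`, 0, "auc_last") / doses
  cmax_norm <- vapply(pk, `[[`, 0, "cmax") / doses
  expect_lt(max(auc_norm) / min(auc_norm) - 1, 0.05)
  expect_lt(max(cmax_norm) / min(cmax_norm) - 1, 0.05)
  # Cmax ratio between 20 and 5 mg/kg is 4.0 within 5%
  expect_equal(pk[[5]]$cmax / pk[[3]]$cmax, 4, tolerance = 0.05)
})

test_that("exposure increases with batch sialylation", {
  times <- seq(1, 1008, by = 24)
  auc <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(r) {
    m <- build_model(adult, drug, batch = batch_properties("b", r))
    nca(simulate_pbpk(m, dose_event(0, 1, 400), times)$profile)$auc_last
  }, 0)
  expect_true(all(diff(auc) > 0))
})

test_that("deleting the ASGR pathway barely changes a high-sialylation batch", {
  times <- seq(1, 1344, by = 24)
  m1 <- build_model(adult, drug, batch = batch_properties("b", 0.64))
  m0 <- build_model(adult, asunercept_parameters(asgr_cl_spec = 0),
                    batch = batch_properties("b", 0.64))
  a1 <- nca(simulate_pbpk(m1, dose_event(0, 1, 400), times)$profile)$auc_last
  a0 <- nca(simulate_pbpk(m0, dose_event(0, 1, 400), times)$profile)$auc_last
  expect_lt(abs(a1 - a0) / a0, 0.02)
})

test_that("renal elimination is absent when the GFR fraction is zero", {
  m <- build_model(adult, drug, batch = batch_properties("b", 0.4))
  s <- simulate_pbpk(m, dose_event(0, 1, 400), seq(1, 336, by = 6))
  expect_true(all(s$states[, "cum_renal"] == 0))
  # and present when it is not
  m2 <- build_model(adult, asunercept_parameters(gfr_fraction = 0.01),
                    batch = batch_properties("b", 0.4))
  s2 <- simulate_pbpk(m2, dose_event(0, 1, 400), seq(1, 336, by = 6))
  expect_gt(s2$states[nrow(s2$states), "cum_renal"], 0)
})

test_that("FcRn rescue prolongs the terminal half-life", {
  hl_ref <- serum_halflife(adult, sim_weeks = 10)
  hl_stronger <- serum_halflife(adult,
                                asunercept_parameters(fcrn_kd_lysosomal =
                                                        0.63),
                                sim_weeks = 10)
  hl_none <- serum_halflife(adult,
                            asunercept_parameters(fcrn_kass = 1e-9),
                            sim_weeks = 10)
  expect_gt(hl_stronger, hl_ref)
  expect_lt(hl_none, hl_ref)
})

test_that("two-pore transport parameters are physically sensible", {
  tp <- asunpbpk:::two_pore_parameters(1, 4.01, platform_constants())
  expect_gt(tp$sig_s, tp$sig_l) # small pores reflect the solute more
  expect_true(tp$sig_s > 0.9 && tp$sig_s < 1)
  expect_true(tp$sig_l > 0 && tp$sig_l < 0.5)
  expect_true(tp$ps_s > 0 && tp$ps_l > 0)
  expect_equal(tp$js + tp$jl, 1, tolerance = 1e-12) # fluxes sum to lymph
})

test_that("misconfigured expression organs are rejected", {
  expect_error(target_expression(cd95l_organs = c("brain", "thymus")),
               class = "configuration_error")
})
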