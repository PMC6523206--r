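# Fitting tests use compact training sets so the whole file stays within a
# few minutes; the full recovery experiment lives in the acceptance suite.

small_entries <- function(cv = 0, seed = 21) {
  design <- asunpbpk:::recovery_design(n_weekly_doses = 4)[c(3, 5, 9, 16)]
  asunpbpk:::with_seed(seed, lapply(design, asunpbpk:::make_training_entry,
                                    drug = asunercept_parameters(),
                                    cv = cv,
                                    platform = platform_constants()))
}

test_that("noise-free data identify all four parameters exactly", {
  entries <- small_entries(cv = 0)
  init <- list(cd95l_kd = 1.91 * 3, cd95l_koff = 9.7e-5 / 3,
               asgr_cl_spec = 2.43e-4 * 3, fcrn_kd_lysosomal = 1.73 / 3)
  fit <- fit_parameters(training_set(entries), initial = init)
  expect_true(fit$converged)
  truth <- c(cd95l_kd = 1.91, cd95l_koff = 9.7e-5, asgr_cl_spec = 2.43e-4,
             fcrn_kd_lysosomal = 1.73)
  expect_equal(fit$estimates, truth, tolerance = 0.01)
  expect_lt(fit$objective_value, 1e-6)
  # CIs bracket the estimates
  expect_true(all(fit$ci95[, "low"] <= fit$estimates &
                    fit$estimates <= fit$ci95[, "high"]))
})

test_that("fits are invariant to the subject ordering", {
  entries <- small_entries(cv = 0)
  init <- list(asgr_cl_spec = 5e-4, fcrn_kd_lysosomal = 1.0)
  f1 <- fit_parameters(training_set(entries),
                       free_parameters = c("asgr_cl_spec",
                                           "fcrn_kd_lysosomal"),
                       initial = init)
  f2 <- fit_parameters(training_set(rev(entries)),
                       free_parameters = c("asgr_cl_spec",
                                           "fcrn_kd_lysosomal"),
                       initial = init)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-8)
})

test_that("the ASGR pathway is non-identifiable on high-sialylation batches", {
  # with every batch above ratio 0.6 the pathway carries <2% of its
  # maximal clearance, so its parameter cannot be resolved from the data
  design <- asunpbpk:::recovery_design(n_weekly_doses = 4)[c(9, 12)]
  design <- lapply(design, function(d) {
    d$r <- 0.62 + 0.02 * (d$age > 50)
    d
  })
  entries <- asunpbpk:::with_seed(31, lapply(
    design, asunpbpk:::make_training_entry,
    drug = asunercept_parameters(), cv = 0.1,
    platform = platform_constants()))
  fit <- fit_parameters(training_set(entries),
                        free_parameters = c("asgr_cl_spec",
                                            "fcrn_kd_lysosomal"))
  expect_true("asgr_cl_spec" %in% fit$wide_ci)
  expect_false("fcrn_kd_lysosomal" %in% fit$wide_ci)
})

test_that("fit inputs are validated", {
  entries <- small_entries(cv = 0)
  expect_error(fit_parameters(training_set(entries),
                              free_parameters = "molecular_weight"),
               class = "validation_error")
  expect_error(fit_parameters(training_set(entries),
                              initial = list(cd95l_kd = 1),
                              bounds = list(cd95l_kd = c(2, 10))),
               class = "validation_error")
  expect_error(training_set(list()), class = "validation_error")
  # profiles must be LLOQ-censored before fitting
  bad <- entries
  bad[[1]]$profile$lloq <- 1e3
  expect_error(training_set(bad), class = "validation_error")
})

test_that("the recovery report is reproducible and unbiased without noise", {
  r1 <- recovery_report(n_replicates = 1, seed = 5, cv = 0,
                        free_parameters = c("asgr_cl_spec",
                                            "fcrn_kd_lysosomal"),
                        initial_spread = 2)
  r2 <- recovery_report(n_replicates = 1, seed = 5, cv = 0,
                        free_parameters = c("asgr_cl_spec",
                                            "fcrn_kd_lysosomal"),
                        initial_spread = 2)
  expect_identical(r1$summary, r2$summary)
  expect_true(all(abs(r1$summary$median_rel_bias) < 0.01))
  expect_equal(r1$n_failed, 0)
})
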