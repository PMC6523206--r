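# a minimal hand-built subject record for boundary tests of the rules
stub_record <- function(id = "X", uric = c(200, 250), rs = c(0.4, 0.4, 0.4),
                        conc = c(50, 40, 30, 20, 10), lloq = 0.1) {
  times <- seq_along(conc) * 100
  doses <- lapply(seq_along(rs), function(k) dose_event((k - 1) * 168,
                                                        0.5, 400))
  structure(list(
    individual = build_individual(40, "male", id = id),
    batch_sequence = lapply(rs, function(r) batch_properties("b", r)),
    uric_acid_series = uric,
    dose_events = doses,
    profile = concentration_profile(id, times, conc, lloq = lloq,
                                    dose_schedule = doses),
    true_concentrations = conc,
    exclusion_flags = character(0)), class = "asun_subject_record")
}

test_that("the Phase I generator reproduces the study design", {
  p1 <- generate_phase1(seed = 2)
  expect_length(p1, 16)
  doses <- vapply(p1, function(r) r$dose_events[[1]]$amount /
                    r$individual$body_weight, 0)
  expect_equal(unname(table(round(doses, 1))[as.character(c(0.2, 1, 5, 15,
                                                            20))]),
               c(2L, 2L, 4L, 4L, 4L), ignore_attr = TRUE)
  ages <- vapply(p1, function(r) r$individual$age, 0)
  wts <- vapply(p1, function(r) r$individual$body_weight, 0)
  expect_true(all(ages >= 21 & ages <= 44))
  expect_true(all(wts >= 63 & wts <= 94))
  expect_true(all(vapply(p1, function(r) r$individual$sex, "") == "male"))
  rs <- vapply(p1, function(r) r$batch_sequence[[1]]$sa_glycan_ratio, 0)
  expect_true(all(rs %in% c(0.27, 0.34)))
  # follow-up spans at least 6 weeks
  expect_true(all(vapply(p1, function(r) max(r$profile$times), 0) >= 1008))
  expect_identical(generate_phase1(seed = 2), p1)
})

test_that("the generator reuses the simulator (no second PK code path)", {
  p1 <- generate_phase1(seed = 4)
  r <- p1[[5]]
  m <- build_model(r$individual, asunercept_parameters(),
                   batch = r$batch_sequence[[1]])
  s <- simulate_pbpk(m, r$dose_events, r$profile$times)
  expect_identical(r$true_concentrations, s$profile$concentrations)
})

test_that("back-calculated residual error reproduces the configured CV", {
  p1 <- generate_phase1(seed = 6)
  res <- unlist(lapply(p1, function(r) {
    hi <- r$true_concentrations > 10 * r$profile$lloq # additive negligible
    log(r$profile$concentrations[hi] / r$true_concentrations[hi])
  }))
  expect_gt(length(res), 100)
  cv_hat <- sqrt(exp(sd(res)^2) - 1)
  expect_lt(abs(cv_hat / 0.20 - 1), 0.10)
})

test_that("the Phase II generator carries the designed exclusion features", {
  p2 <- generate_phase2(seed = 7)
  expect_length(p2, 58)
  expect_true(all(vapply(p2, function(r)
    all(vapply(r$dose_events, function(d) d$amount, 0) == 400), TRUE)))
  expect_true(all(vapply(p2, function(r)
    length(r$batch_sequence) == length(r$dose_events), TRUE)))
  expect_identical(generate_phase2(seed = 7), p2)
  ex <- apply_exclusions(p2)
  expect_length(ex$included, 35)
  counts <- table(ex$reasons$reason)
  expect_equal(counts[["uric_acid"]], 11L)
  expect_equal(counts[["batch_change"]], 7L)
  expect_equal(counts[["sparse_sampling"]], 5L)
})

test_that("exclusion boundaries follow the rules exactly", {
  # uric acid exactly at the threshold is excluded (rule is "below 343")
  at_343 <- stub_record(uric = c(200, 343))
  below <- stub_record(uric = c(200, 342.9))
  ex <- apply_exclusions(list(at_343, below))
  expect_length(ex$included, 1)
  expect_equal(ex$reasons$reason, "uric_acid")

  # exactly 5 quantifiable samples is enough
  five <- stub_record(conc = c(50, 40, 30, 20, 10))
  four <- stub_record(conc = c(50, 40, 30, 20, 0.05)) # one below LLOQ
  ex2 <- apply_exclusions(list(five, four))
  expect_length(ex2$included, 1)
  expect_equal(ex2$reasons$reason, "sparse_sampling")

  # batch change after dose 2 excludes; after dose 3 does not
  early <- stub_record(rs = c(0.4, 0.5, 0.5, 0.5))
  late <- stub_record(rs = c(0.4, 0.4, 0.4, 0.5))
  ex3 <- apply_exclusions(list(early, late))
  expect_length(ex3$included, 1)
  expect_equal(ex3$reasons$reason, "batch_change")
})

test_that("exclusions are idempotent and order-independent", {
  p2 <- generate_phase2(seed = 9, n = 20, n_flag_uric = 4, n_flag_batch = 3,
                        n_flag_sparse = 2, n_doses = 6)
  ids <- function(recs) sort(vapply(recs, function(r)
    r$profile$subject_id, ""))
  e1 <- apply_exclusions(p2)
  e2 <- apply_exclusions(e1$included)
  expect_identical(ids(e2$included), ids(e1$included))
  expect_length(e2$excluded, 0)
  e3 <- apply_exclusions(rev(p2))
  expect_identical(ids(e3$included), ids(e1$included))
})

test_that("the train/test split is sized, stratified and seeded", {
  p2 <- generate_phase2(seed = 7)
  inc <- apply_exclusions(p2)$included
  sp <- split_train_test(inc, seed = 3)
  expect_length(sp$training, 19)
  expect_length(sp$test, 16)
  first_r <- function(recs) vapply(recs, function(r)
    r$batch_sequence[[1]]$sa_glycan_ratio, 0)
  shared <- as.numeric(names(which(table(first_r(inc)) >= 2)))
  expect_true(all(shared %in% first_r(sp$training)))
  expect_true(all(shared %in% first_r(sp$test)))
  sp2 <- split_train_test(inc, seed = 3)
  expect_identical(vapply(sp$training, function(r) r$profile$subject_id, ""),
                   vapply(sp2$training, function(r) r$profile$subject_id,
                          ""))
  expect_error(split_train_test(inc[1:10], seed = 1), class = "split_error")
})

test_that("datasets export to the documented CSV/JSON layout", {
  p1 <- generate_phase1(seed = 2)[1:3]
  prefix <- file.path(tempdir(), "ds")
  paths <- dataset_to_csv(p1, prefix, manifest = list(design = "phase1",
                                                      seed = 2))
  expect_true(all(file.exists(paths)))
  prof <- read.csv(paths[1])
  expect_named(prof, c("subject_id", "time_h", "conc_ug_per_mL",
                       "censored_flag"))
  subj <- read.csv(paths[2])
  expect_equal(nrow(subj), 3)
  unlink(paths)
})
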