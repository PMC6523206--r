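# Synthetic Phase I / Phase II study generation and cohort inclusion rules.
#
# The generator reuses the whole-body simulator for every concentration (no
# second PK implementation); measurement error is proportional-lognormal
# plus additive at the quantification limit. Uric-acid series are generated
# as levels only; no PK interaction is modeled (elevated uric acid leads to
# exclusion, mirroring the cohort rules, not to a mechanism).

#' Cohort exclusion rules
#'
#' @param uric_acid_max subjects with any on-treatment uric acid at or
#'   above this level (umol/L) are excluded (the rule is "below 343").
#' @param min_samples minimum number of quantifiable samples (subjects with
#'   fewer are excluded; default 5, i.e. "<= 4 samples" excludes).
#' @param min_same_batch_doses minimum number of leading same-batch doses;
#'   a batch change after fewer doses excludes the subject.
#' @return an object of class `asun_rules`.
#' @export
exclusion_rules <- function(uric_acid_max = 343, min_samples = 5,
                            min_same_batch_doses = 3) {
  check_positive(uric_acid_max, "uric_acid_max")
  check_positive(min_samples, "min_samples")
  check_positive(min_same_batch_doses, "min_same_batch_doses")
  structure(list(uric_acid_max = uric_acid_max, min_samples = min_samples,
                 min_same_batch_doses = min_same_batch_doses),
            class = "asun_rules")
}

PHASE1_LLOQ <- 0.667 # ug/mL
PHASE2_LLOQ <- 0.100 # ug/mL

# Phase I dose groups: dose (mg/kg), group size, batch sialylation and
# demographic ranges (age y, weight kg, height cm) per group
phase1_groups <- function() {
  data.frame(
    dose_mg_kg = c(0.2, 1.0, 5.0, 15.0, 20.0),
    n = c(2L, 2L, 4L, 4L, 4L),
    sa_ratio = c(0.27, 0.34, 0.34, 0.34, 0.34),
    age_lo = c(30, 33, 28, 21, 25), age_hi = c(41, 44, 33, 40, 44),
    wt_lo = c(66, 87, 65, 64, 63), wt_hi = c(86, 89, 94, 84, 82),
    ht_lo = c(183, 178, 177, 175, 178), ht_hi = c(187, 184, 185, 183, 188))
}

# measurement error: proportional lognormal (CV) plus additive gaussian
# scaled to the LLOQ, truncated at zero
add_measurement_error <- function(conc, cv, lloq, additive_frac = 0.3) {
  out <- conc * rlnorm_cv(length(conc), cv) +
    stats::rnorm(length(conc), 0, additive_frac * lloq)
  pmax(out, 0)
}

make_record <- function(individual, batch_sequence, dose_events,
                        uric_acid_series, times, lloq, cv, platform,
                        drug, expression) {
  model <- build_model(individual, drug, expression = expression,
                       batch = batch_sequence[[1]], platform = platform)
  sim <- simulate_pbpk(model, dose_events, times)
  true_conc <- sim$profile$concentrations
  obs <- add_measurement_error(true_conc, cv, lloq)
  profile <- concentration_profile(individual$id, times, obs, lloq = lloq,
                                   dose_schedule = dose_events,
                                   censored = obs < lloq)
  structure(list(individual = individual, batch_sequence = batch_sequence,
                 uric_acid_series = uric_acid_series,
                 dose_events = dose_events, profile = profile,
                 true_concentrations = true_conc,
                 exclusion_flags = character(0)),
            class = "asun_subject_record")
}

#' Generate the synthetic Phase I dataset
#'
#' 16 male healthy volunteers in single-dose groups of 2/2/4/4/4 subjects
#' at 0.2/1/5/15/20 mg/kg (1-h infusion), demographics sampled within the
#' published group ranges, rich sampling over 6 weeks, batch sialic
#' acid:glycan ratio 0.27 (lowest dose group) or 0.34, proportional error
#' CV 20% plus additive error of 0.3 x LLOQ, LLOQ 0.667 ug/mL.
#'
#' @param seed RNG seed.
#' @param cv proportional error CV.
#' @param drug,expression,platform model configuration.
#' @return list of subject records.
#' @export
generate_phase1 <- function(seed = 1, cv = 0.20,
                            drug = asunercept_parameters(),
                            expression = target_expression(),
                            platform = platform_constants()) {
  groups <- phase1_groups()
  times <- c(0.5, 1, 1.5, 2, 4, 8, 24, 48, 96, 168, 336, 504, 672, 840,
             1008)
  with_seed(seed, {
    records <- list()
    sid <- 0L
    for (g in seq_len(nrow(groups))) {
      for (k in seq_len(groups$n[g])) {
        sid <- sid + 1L
        ind <- build_individual(
          stats::runif(1, groups$age_lo[g], groups$age_hi[g]), "male",
          body_weight = stats::runif(1, groups$wt_lo[g], groups$wt_hi[g]),
          height = stats::runif(1, groups$ht_lo[g], groups$ht_hi[g]),
          id = sprintf("P1_%02d", sid))
        batch <- batch_properties(sprintf("b%02.0f", groups$sa_ratio[g] *
                                            100), groups$sa_ratio[g])
        dose <- dose_event(0, 1, groups$dose_mg_kg[g] * ind$body_weight)
        uric <- stats::runif(6, 150, 320)
        records[[sid]] <- make_record(ind, list(batch), list(dose), uric,
                                      times, PHASE1_LLOQ, cv, platform,
                                      drug, expression)
      }
    }
    records
  })
}

#' Generate the synthetic Phase II dataset
#'
#' 58 glioblastoma patients following the full Phase II demographics (67%
#' male, 20-73 years, 50-127 kg, 151-190 cm, BMI 18-50), on weekly 400 mg
#' infusions with jittered administration times (+/- 1 day) and variable
#' durations (0.4-1 h), per-subject batch sequences with sialic
#' acid:glycan ratios in 0.30-0.57, sparse trough sampling, LLOQ
#' 0.1 ug/mL. Deterministically sized subsets of subjects carry the cohort
#' exclusion features: elevated uric acid, a batch change after the first
#' or second dose, and sparse sampling (4 samples); a further
#' `n_late_switch` subjects switch batches late (after at least
#' `min_same_batch_doses` doses), which does not exclude them.
#'
#' @param seed RNG seed.
#' @param n number of subjects.
#' @param n_flag_uric subjects with uric acid >= 343 umol/L.
#' @param n_flag_batch subjects with an early batch change.
#' @param n_flag_sparse subjects with only 4 samples.
#' @param n_late_switch subjects with a late (allowed) batch change.
#' @param n_doses weekly doses simulated.
#' @param cv proportional error CV.
#' @param drug,expression,platform model configuration.
#' @return list of subject records.
#' @export
generate_phase2 <- function(seed = 1, n = 58, n_flag_uric = 11,
                            n_flag_batch = 7, n_flag_sparse = 5,
                            n_late_switch = 4, n_doses = 15, cv = 0.20,
                            drug = asunercept_parameters(),
                            expression = target_expression(),
                            platform = platform_constants()) {
  if (n_flag_uric + n_flag_batch + n_flag_sparse > n)
    asun_stop("validation_error", "flag counts exceed the cohort size")
  with_seed(seed, {
    pop <- generate_population(
      population_spec(n, 0.67, c(20, 73), weight_range = c(50, 127),
                      height_range = c(151, 190), bmi_range = c(18, 50),
                      bmi_mean = 25.5, seed = stats::runif(1, 1, 1e6)))
    # deterministic, disjoint flag assignment over a shuffled order
    ord <- sample(n)
    flag_uric <- ord[seq_len(n_flag_uric)]
    flag_batch <- ord[n_flag_uric + seq_len(n_flag_batch)]
    flag_sparse <- ord[n_flag_uric + n_flag_batch + seq_len(n_flag_sparse)]
    late_switch <- ord[n_flag_uric + n_flag_batch + n_flag_sparse +
                         seq_len(min(n_late_switch, n - n_flag_uric -
                                       n_flag_batch - n_flag_sparse))]
    lapply(seq_len(n), function(i) {
      ind <- pop[[i]]
      ind$id <- sprintf("P2_%02d", i)
      # jittered weekly infusions, variable duration
      starts <- c(0, (seq_len(n_doses - 1)) * 168 +
                    stats::runif(n_doses - 1, -24, 24))
      durations <- stats::runif(n_doses, 0.4, 1)
      doses <- lapply(seq_len(n_doses), function(k)
        dose_event(starts[k], durations[k], 400))
      # batch sequence
      r1 <- round(stats::runif(1, 0.30, 0.57), 2)
      batches <- rep(list(batch_properties(sprintf("b%02.0f", r1 * 100),
                                           r1)), n_doses)
      switch_at <- NA_integer_
      if (i %in% flag_batch) switch_at <- sample(1:2, 1)
      if (i %in% late_switch) switch_at <- sample(3:(n_doses - 1), 1)
      if (!is.na(switch_at)) {
        r2 <- round(stats::runif(1, 0.30, 0.57), 2)
        if (abs(r2 - r1) < 0.05) r2 <- round(min(0.57, r1 + 0.08), 2)
        for (k in (switch_at + 1):n_doses)
          batches[[k]] <- batch_properties(sprintf("b%02.0f", r2 * 100), r2)
      }
      uric <- stats::runif(n_doses, 150, 320)
      if (i %in% flag_uric)
        uric[sample(n_doses, 1)] <- stats::runif(1, 343, 520)
      # sparse trough sampling 1 h before selected later doses
      sample_after <- if (i %in% flag_sparse) c(2, 4, 8, 12)
      else c(2, 3, 4, 6, 8, 10, 12, 15)
      sample_after <- sample_after[sample_after <= n_doses]
      times <- sort(starts[sample_after] - 1)
      make_record(ind, batches, doses, uric, times, PHASE2_LLOQ, cv,
                  platform, drug, expression)
    })
  })
}

exclusion_reasons <- function(record, rules) {
  reasons <- character(0)
  if (any(record$uric_acid_series >= rules$uric_acid_max))
    reasons <- c(reasons, "uric_acid")
  rs <- vapply(record$batch_sequence, function(b) b$sa_glycan_ratio, 0)
  change_at <- which(diff(rs) != 0)
  if (length(change_at) && min(change_at) < rules$min_same_batch_doses)
    reasons <- c(reasons, "batch_change")
  n_quant <- sum(record$profile$concentrations >= record$profile$lloq)
  if (n_quant < rules$min_samples)
    reasons <- c(reasons, "sparse_sampling")
  reasons
}

#' Apply the cohort inclusion rules
#'
#' Excludes subjects with any on-treatment uric acid at or above the
#' threshold, subjects whose batch changed after the first or second dose,
#' and subjects with fewer quantifiable samples than required. Deterministic
#' and idempotent; every exclusion carries its rule tag.
#'
#' @param records list of subject records.
#' @param rules an [exclusion_rules()] object.
#' @return list with `included` (records), `excluded` (records) and
#'   `reasons` (data.frame subject_id/reason, one row per triggered rule).
#' @export
apply_exclusions <- function(records, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "asun_rules"))
  for (r in records)
    if (!inherits(r, "asun_subject_record"))
      asun_stop("validation_error", "records must be subject records")
  tags <- lapply(records, exclusion_reasons, rules = rules)
  keep <- lengths(tags) == 0
  records <- lapply(seq_along(records), function(i) {
    records[[i]]$exclusion_flags <- tags[[i]]
    records[[i]]
  })
  reasons <- do.call(rbind, lapply(records[!keep], function(r)
    data.frame(subject_id = r$profile$subject_id,
               reason = r$exclusion_flags)))
  list(included = records[keep], excluded = records[!keep],
       reasons = reasons %||% data.frame(subject_id = character(0),
                                         reason = character(0)))
}

#' Stratified training/test split
#'
#' Splits the included records into training and test sets of the given
#' sizes, stratified by the (first) batch sialylation level so that every
#' batch represented by at least two subjects appears in both sets.
#'
#' @param records included subject records.
#' @param seed RNG seed.
#' @param n_train,n_test split sizes (default 19/16).
#' @return list with `training` and `test` record lists.
#' @export
split_train_test <- function(records, seed = 1, n_train = 19, n_test = 16) {
  if (length(records) < n_train + n_test)
    asun_stop("split_error", "need %d records for a %d/%d split, have %d",
              n_train + n_test, n_train, n_test, length(records))
  rs <- vapply(records, function(r) r$batch_sequence[[1]]$sa_glycan_ratio, 0)
  with_seed(seed, {
    use <- if (length(records) > n_train + n_test)
      sort(sample(length(records), n_train + n_test))
    else seq_along(records)
    rs <- rs[use]
    idx_by_r <- split(seq_along(use), rs)
    idx_by_r <- lapply(idx_by_r, function(v) v[sample.int(length(v))])
    cap <- c(train = n_train, test = n_test)
    assign <- character(length(use))
    # guarantee both sets see every stratum of size >= 2
    for (grp in idx_by_r[order(-lengths(idx_by_r))]) {
      if (length(grp) >= 2 && all(cap > 0)) {
        assign[grp[1]] <- "train"; cap["train"] <- cap["train"] - 1
        assign[grp[2]] <- "test"; cap["test"] <- cap["test"] - 1
      }
    }
    rest <- which(assign == "")
    rest <- rest[sample.int(length(rest))]
    for (i in rest) {
      pick <- if (cap["train"] >= cap["test"]) "train" else "test"
      if (cap[pick] == 0) pick <- setdiff(c("train", "test"), pick)
      assign[i] <- pick
      cap[pick] <- cap[pick] - 1
    }
    list(training = records[use[assign == "train"]],
         test = records[use[assign == "test"]])
  })
}

#' Export a synthetic dataset
#'
#' Writes one profiles CSV (subject_id, time_h, conc_ug_per_mL,
#' censored_flag), one subjects CSV (demographics, batch per dose,
#' uric-acid maximum, exclusion flags) and a JSON design manifest.
#'
#' @param records subject records.
#' @param prefix output path prefix; files are written as
#'   `<prefix>_profiles.csv`, `<prefix>_subjects.csv`,
#'   `<prefix>_manifest.json`.
#' @param manifest list of design metadata to store.
#' @return invisibly, the file paths.
#' @export
dataset_to_csv <- function(records, prefix, manifest = list()) {
  prof <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$profile$subject_id,
               time_h = r$profile$times,
               conc_ug_per_mL = r$profile$concentrations,
               censored_flag = r$profile$censored)))
  subj <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$profile$subject_id,
               age = r$individual$age, sex = r$individual$sex,
               body_weight = r$individual$body_weight,
               height = r$individual$height,
               n_doses = length(r$dose_events),
               batches = paste(vapply(r$batch_sequence,
                                      function(b) b$batch_id, ""),
                               collapse = ";"),
               uric_acid_max = max(r$uric_acid_series),
               flags = paste(r$exclusion_flags, collapse = ";"))))
  paths <- paste0(prefix, c("_profiles.csv", "_subjects.csv",
                            "_manifest.json"))
  utils::write.csv(prof, paths[1], row.names = FALSE)
  utils::write.csv(subj, paths[2], row.names = FALSE)
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE)
  invisible(paths)
}
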