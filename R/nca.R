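# Non-compartmental analysis and model-qualification statistics.

#' Remove samples below the lower limit of quantification
#'
#' Samples with concentration strictly below the LLOQ are removed (not set
#' to zero); the number removed is recorded on the returned profile.
#'
#' @param profile an [concentration_profile()].
#' @return the censored profile.
#' @export
censor_below_lloq <- function(profile) {
  stopifnot(inherits(profile, "asun_profile"))
  if (is.null(profile$lloq) || profile$lloq <= 0) return(profile)
  keep <- profile$concentrations >= profile$lloq
  out <- profile
  out$times <- profile$times[keep]
  out$concentrations <- profile$concentrations[keep]
  out$censored <- rep(FALSE, sum(keep))
  out$n_censored_removed <- profile$n_censored_removed + sum(!keep)
  out$all_censored <- !any(keep)
  out
}

# linear-up/log-down trapezoid over paired vectors
auc_lin_log <- function(t, c) {
  if (length(t) < 2) return(0)
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1]
  seg <- ifelse(c2 >= c1 | c1 <= 0 | c2 <= 0,
                (c1 + c2) / 2 * dt,
                (c1 - c2) / log(c1 / c2) * dt)
  sum(seg)
}

# terminal log-linear fit: among candidate windows (the last m samples after
# the last dose), pick the one maximizing adjusted R^2
terminal_fit <- function(times, conc, after = -Inf, min_points = 3,
                         max_points = 8, r2_min = 0.85) {
  sel <- times > after & conc > 0
  tt <- times[sel]; cc <- conc[sel]
  n <- length(tt)
  if (n < min_points) return(list(half_life = NA_real_, n_points = n,
                                  r2 = NA_real_))
  best <- NULL
  for (m in min_points:min(n, max_points)) {
    ti <- tt[(n - m + 1):n]; ci <- cc[(n - m + 1):n]
    # noiseless profiles fit exactly; lm's perfect-fit warning is expected
    fit <- stats::lm(log(ci) ~ ti)
    sl <- unname(stats::coef(fit)[2])
    r2a <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.finite(sl) && sl < 0 &&
        (is.null(best) || r2a > best$r2)) {
      best <- list(half_life = log(2) / (-sl), n_points = m, r2 = r2a)
    }
  }
  if (is.null(best) || !is.finite(best$r2) || best$r2 < r2_min)
    return(list(half_life = NA_real_,
                n_points = if (is.null(best)) n else best$n_points,
                r2 = if (is.null(best)) NA_real_ else best$r2))
  best
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes `auc_last` (linear-up/log-down trapezoid from the first dose
#' start to the last quantifiable sample), `cmax`, and the terminal
#' half-life from a log-linear regression over the terminal window. The
#' window is the last 3-8 samples after the final dose, chosen to maximize
#' the adjusted R^2 of the fit; the half-life is reported as `NA` (with the
#' window size in `n_points_terminal`) when no window reaches R^2 >= 0.85.
#'
#' @param profile an [concentration_profile()].
#' @return an object of class `asun_pk` with fields `subject_id`,
#'   `auc_last` (h*ug/mL), `cmax` (ug/mL), `half_life` (h or `NA`),
#'   `n_points_terminal`.
#' @export
nca <- function(profile) {
  stopifnot(inherits(profile, "asun_profile"))
  t <- profile$times
  c <- profile$concentrations
  if (length(t) > 1 && any(diff(t) <= 0))
    asun_stop("validation_error", "profile times must be strictly increasing")
  if (length(t) < 2)
    asun_stop("insufficient_data_error",
              "at least 2 quantifiable samples required for NCA")
  dose_start <- if (!is.null(profile$dose_schedule))
    min(vapply(profile$dose_schedule, function(d) d$start_time, 0))
  else t[1]
  last_dose_end <- if (!is.null(profile$dose_schedule))
    max(vapply(profile$dose_schedule,
               function(d) d$start_time + d$duration, 0))
  else -Inf
  if (dose_start < t[1]) {
    t <- c(dose_start, t)
    c <- c(0, c)
  }
  term <- terminal_fit(profile$times, profile$concentrations,
                       after = last_dose_end)
  structure(list(subject_id = profile$subject_id,
                 auc_last = auc_lin_log(t, c),
                 cmax = max(c),
                 half_life = term$half_life,
                 n_points_terminal = term$n_points),
            class = "asun_pk")
}

#' Paired predicted/observed PK parameters
#'
#' @param predicted,observed strictly positive paired values.
#' @param parameter_name label (e.g. `"auc_last"`).
#' @return an object of class `asun_pkcomp`.
#' @export
pk_comparison <- function(predicted, observed, parameter_name = "pk") {
  if (length(predicted) != length(observed))
    asun_stop("validation_error", "predicted/observed lengths differ")
  if (length(predicted) == 0)
    asun_stop("insufficient_data_error", "no pairs supplied")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    asun_stop("validation_error", "pairs must be strictly positive")
  structure(list(predicted = as.numeric(predicted),
                 observed = as.numeric(observed),
                 parameter_name = parameter_name),
            class = "asun_pkcomp")
}

#' Geometric mean fold error
#'
#' `GMFE = 10 ^ (mean |log10(predicted / observed)|)`. Always >= 1 and
#' symmetric under swapping predictions and observations; values <= 2 are
#' conventionally considered adequate.
#'
#' @param comparison a [pk_comparison()].
#' @return the GMFE (dimensionless).
#' @export
gmfe <- function(comparison) {
  stopifnot(inherits(comparison, "asun_pkcomp"))
  10^mean(abs(log10(comparison$predicted / comparison$observed)))
}

#' Fold-error statistics
#'
#' The fold error of a pair is `max(pred/obs, obs/pred)`.
#'
#' @param comparison a [pk_comparison()].
#' @param k fold threshold (default 2).
#' @return list with `n_within` (pairs with fold <= k), `n`, `min_fold`,
#'   `max_fold`.
#' @export
fold_stats <- function(comparison, k = 2) {
  stopifnot(inherits(comparison, "asun_pkcomp"))
  fold <- pmax(comparison$predicted / comparison$observed,
               comparison$observed / comparison$predicted)
  list(n_within = sum(fold <= k), n = length(fold),
       min_fold = min(fold), max_fold = max(fold))
}

#' Steady-state exposure over one dosing interval
#'
#' AUC and Cmax over the `interval_index`-th dosing interval (by default
#' the 15th weekly interval, hours 2352-2520 after the first dose), from
#' dense simulation output. Interval boundaries are interpolated when not
#' sampled exactly.
#'
#' @param sim an [simulate_pbpk()] result.
#' @param interval_index which interval (1-based).
#' @param interval interval length, h.
#' @return list with `auc_tau` (h*ug/mL) and `cmax_tau` (ug/mL).
#' @export
steady_state_exposure <- function(sim, interval_index = 15, interval = 168) {
  stopifnot(inherits(sim, "asun_sim"))
  t0 <- (interval_index - 1) * interval
  t1 <- interval_index * interval
  t <- sim$profile$times
  c <- sim$profile$concentrations
  if (max(t) < t1 - 1e-9)
    asun_stop("span_error",
              "simulation ends at %.4g h but interval %d needs %.4g h",
              max(t), interval_index, t1)
  inside <- t >= t0 & t <= t1
  tt <- t[inside]; cc <- c[inside]
  if (!any(abs(tt - t0) < 1e-9)) {
    tt <- c(t0, tt); cc <- c(stats::approx(t, c, t0)$y, cc)
  }
  if (!any(abs(tt - t1) < 1e-9)) {
    tt <- c(tt, t1); cc <- c(cc, stats::approx(t, c, t1)$y)
  }
  if (length(tt) < 3)
    asun_stop("span_error", "too few samples inside the dosing interval")
  list(auc_tau = auc_lin_log(tt, cc), cmax_tau = max(cc))
}

#' Sensitivity analysis settings
#'
#' @param relative_perturbation forward relative perturbation (default 10%).
#' @param cutoff sensitivity cutoff used for reporting (default 0.5).
#' @param output_metric `"auc"`, `"cmax"` or `"half_life"`.
#' @return an `asun_sens_settings` object.
#' @export
sensitivity_settings <- function(relative_perturbation = 0.10, cutoff = 0.5,
                                 output_metric = c("auc", "cmax",
                                                   "half_life")) {
  check_positive(relative_perturbation, "relative_perturbation")
  structure(list(relative_perturbation = relative_perturbation,
                 cutoff = cutoff, output_metric = match.arg(output_metric)),
            class = "asun_sens_settings")
}

sens_metric <- function(model, schedule, output_times, metric) {
  sim <- simulate_pbpk(model, schedule, output_times)
  pk <- nca(sim$profile)
  switch(metric, auc = pk$auc_last, cmax = pk$cmax,
         half_life = pk$half_life)
}

#' Local sensitivity coefficient of a drug parameter
#'
#' `S = (dM/M) / (dp/p)` with a one-sided forward perturbation of the named
#' drug parameter and M the chosen output metric of a single-dose
#' simulation (default: AUC to the last output time).
#'
#' @param model an [build_model()] object.
#' @param schedule dosing schedule for the sensitivity run (default one
#'   400 mg dose over 0.5 h).
#' @param parameter_name one of the primary drug parameters, e.g.
#'   `"fcrn_kd_lysosomal"`, `"cd95l_kd"`, `"cd95l_koff"`, `"asgr_cl_spec"`,
#'   `"gfr_fraction"`.
#' @param settings [sensitivity_settings()].
#' @param output_times simulation output grid, h.
#' @return the signed sensitivity coefficient.
#' @export
local_sensitivity <- function(model, schedule = dose_event(0, 0.5, 400),
                              parameter_name,
                              settings = sensitivity_settings(),
                              output_times = seq(1, 8 * 7 * 24, by = 24)) {
  stopifnot(inherits(model, "asun_model"))
  prim <- setdiff(names(formals(asunercept_parameters)), "...")
  if (!parameter_name %in% prim)
    asun_stop("lookup_error", "unknown drug parameter '%s'", parameter_name)
  base_args <- lapply(prim, function(nm) model$drug[[nm]])
  names(base_args) <- prim
  m0 <- sens_metric(model, schedule, output_times,
                    settings$output_metric)
  pert <- base_args
  pert[[parameter_name]] <- pert[[parameter_name]] *
    (1 + settings$relative_perturbation)
  drug2 <- do.call(asunercept_parameters, pert)
  model2 <- build_model(model$individual, drug2,
                        expression = model$expression, batch = model$batch,
                        platform = model$platform)
  m1 <- sens_metric(model2, schedule, output_times,
                    settings$output_metric)
  ((m1 - m0) / m0) / settings$relative_perturbation
}
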