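# Numerical integration of the assembled system and serum observables.

#' Serum concentration-time profile
#'
#' Container for timestamped serum concentrations with quantification-limit
#' metadata; the common currency between the simulator, the
#' non-compartmental analysis and the fitting machinery.
#'
#' @param subject_id subject identifier.
#' @param times sampling times, h (strictly increasing).
#' @param concentrations serum concentrations, ug/mL.
#' @param lloq lower limit of quantification, ug/mL (0 = none).
#' @param dose_schedule optional list of [dose_event()]s.
#' @param censored optional logical flags for below-LLOQ samples.
#' @return an object of class `asun_profile`.
#' @export
concentration_profile <- function(subject_id, times, concentrations,
                                  lloq = 0, dose_schedule = NULL,
                                  censored = NULL) {
  if (length(times) != length(concentrations))
    asun_stop("validation_error", "times and concentrations differ in length")
  if (length(times) > 1 && any(diff(times) <= 0))
    asun_stop("validation_error", "times must be strictly increasing")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    asun_stop("validation_error", "concentrations must be finite and >= 0")
  structure(list(subject_id = subject_id, times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 lloq = lloq, dose_schedule = dose_schedule,
                 censored = censored %||% rep(FALSE, length(times)),
                 n_censored_removed = 0L),
            class = "asun_profile")
}

#' @export
print.asun_profile <- function(x, ...) {
  cat(sprintf("<asun_profile> %s: %d samples over %.3g h (LLOQ %.3g ug/mL)\n",
              x$subject_id, length(x$times),
              if (length(x$times)) max(x$times) else 0, x$lloq))
  invisible(x)
}

normalize_schedule <- function(schedule) {
  if (inherits(schedule, "asun_dose")) schedule <- list(schedule)
  if (!length(schedule) || !all(vapply(schedule, inherits, TRUE, "asun_dose")))
    asun_stop("validation_error", "schedule must be a list of dose events")
  schedule
}

#' Simulate the PBPK system under a dosing schedule
#'
#' Integrates the whole-body system with a stiff solver (lsoda), treating
#' infusion starts and stops as exact segment boundaries (the system is
#' re-initialized at each boundary, so the right-hand side is smooth within
#' every integration segment). The serum concentration is the venous plasma
#' concentration converted to ug/mL.
#'
#' @param model an [build_model()] object.
#' @param schedule a [dose_event()] or list thereof.
#' @param output_times requested output times, h.
#' @param rtol,atol solver tolerances; `atol` defaults to `1e-10` times the
#'   total administered amount (nmol).
#' @return an object of class `asun_sim` with elements `times`, `states`
#'   (matrix, one row per output time), `profile` (serum
#'   [concentration_profile()]), `mass_balance_rel_error`,
#'   `administered_nmol` and the generating `model`/`schedule`.
#' @export
simulate_pbpk <- function(model, schedule, output_times,
                          rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(model, "asun_model"))
  schedule <- normalize_schedule(schedule)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0))
    asun_stop("validation_error", "output times must be >= 0")

  starts <- vapply(schedule, function(d) d$start_time, 0)
  ends <- vapply(schedule, function(d) d$start_time + d$duration, 0)
  rates <- vapply(schedule, function(d) d$amount * model$nmol_per_mg /
                    d$duration, 0)
  total_nmol <- sum(vapply(schedule, function(d) d$amount, 0)) *
    model$nmol_per_mg
  atol <- atol %||% max(total_nmol, 1) * 1e-10

  t_end <- max(output_times, ends)
  bounds <- sort(unique(c(0, starts[starts < t_end], ends[ends < t_end],
                          t_end)))
  nms <- model$state_names
  y <- stats::setNames(numeric(length(nms)), nms)
  p <- model$parms

  keep_t <- numeric(0)
  keep_y <- list()
  if (bounds[1] %in% output_times) {
    keep_t <- 0
    keep_y[[1]] <- y
  }
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    active <- starts <= t0 & ends > t0
    p[parm_index("inf_rate")] <- sum(rates[active])
    seg_times <- sort(unique(c(t0, output_times[output_times > t0 &
                                                  output_times <= t1], t1)))
    out <- tryCatch(
      deSolve::lsoda(y = y, times = seg_times, func = "asun_derivs",
                     parms = p, dllname = "asunpbpk",
                     initfunc = "asun_initmod", rtol = rtol, atol = atol,
                     maxsteps = 50000),
      warning = function(w) asun_stop(
        "integration_error",
        "integration failed in segment [%.4g, %.4g] h: %s", t0, t1,
        conditionMessage(w)))
    y <- out[nrow(out), -1]
    want <- out[, 1] %in% output_times & out[, 1] > t0
    if (any(want)) {
      idx <- which(want)
      keep_t <- c(keep_t, out[idx, 1])
      keep_y <- c(keep_y, lapply(idx, function(i) out[i, -1]))
    }
  }
  states <- do.call(rbind, keep_y)
  colnames(states) <- nms

  neg <- min(states)
  floor_tol <- max(total_nmol, 1) * 1e-9
  if (neg < -floor_tol)
    asun_stop("integrity_error",
              "state %s fell to %.3g nmol (beyond the negativity floor)",
              nms[which(states == neg, arr.ind = TRUE)[1, 2]], neg)
  states[states < 0] <- 0

  administered <- vapply(keep_t, function(tt)
    sum(pmin(pmax(tt - starts, 0), ends - starts) * rates), 0)
  total_in_system <- rowSums(states)
  mb <- if (total_nmol > 0)
    max(abs(total_in_system - administered)) / total_nmol else 0

  conc <- states[, "venous"] / model$individual$venous_plasma_volume *
    model$ug_ml_per_nmol_l
  profile <- concentration_profile(model$individual$id, keep_t, pmax(conc, 0),
                                   dose_schedule = schedule)

  structure(list(times = keep_t, states = states, profile = profile,
                 schedule = schedule, model = model,
                 administered_nmol = total_nmol,
                 mass_balance_rel_error = mb),
            class = "asun_sim")
}

#' @export
print.asun_sim <- function(x, ...) {
  cat(sprintf(
    "<asun_sim> %s: %d output times to %.4g h, mass balance error %.2e\n",
    x$model$individual$id, length(x$times), max(x$times),
    x$mass_balance_rel_error))
  invisible(x)
}

#' Reference adult individual
#'
#' The 30-year-old reference male used for model qualification and
#' sensitivity analysis.
#'
#' @return an [build_individual()] object.
#' @export
reference_adult <- function() build_individual(30, "male", id = "ref_adult")

#' Terminal serum half-life from a single-dose simulation
#'
#' Runs a single intravenous infusion in the given individual and estimates
#' the terminal half-life of the serum concentration-time curve by
#' log-linear regression (see [nca()]).
#'
#' @param individual an [build_individual()] object.
#' @param drug drug parameters.
#' @param batch batch properties (defaults to a highly sialylated batch,
#'   sialic acid:glycan ratio 0.64).
#' @param dose_mg infusion amount, mg.
#' @param infusion_h infusion duration, h.
#' @param sim_weeks simulated washout length, weeks (>= 8).
#' @param platform [platform_constants()].
#' @return terminal half-life in days.
#' @export
serum_halflife <- function(individual, drug = asunercept_parameters(),
                           batch = batch_properties("hi_sial", 0.64),
                           dose_mg = 400, infusion_h = 1,
                           sim_weeks = 12, platform = platform_constants()) {
  if (sim_weeks < 8)
    asun_stop("validation_error",
              "washout must span at least 8 weeks for a terminal estimate")
  model <- build_model(individual, drug, batch = batch, platform = platform)
  times <- c(infusion_h, seq(24, sim_weeks * 7 * 24, by = 24))
  sim <- simulate_pbpk(model, dose_event(0, infusion_h, dose_mg), times)
  pk <- nca(sim$profile)
  if (is.na(pk$half_life))
    asun_stop("insufficient_data_error",
              "terminal phase not identifiable from the washout simulation")
  pk$half_life / 24
}
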