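# Virtual individuals and populations.
#
# Anatomy and physiology come from an embedded age-by-sex lookup table
# (ICRP-style reference values for ages 1-100 years, see
# inst/extdata/physiology_*.csv). Organ parameters are linearly interpolated
# in age; organ volumes scale proportionally with body weight relative to
# the age/sex reference, and blood flows scale with cardiac output
# (allometric body-weight exponent 0.75).

ORGANS <- c("lung", "brain", "heart", "kidney", "liver", "spleen",
            "stomach", "small_intestine", "large_intestine", "pancreas",
            "gonads", "bone", "muscle", "fat", "skin")

# organs that drain into the liver via the portal vein
PORTAL_ORGANS <- c("spleen", "stomach", "small_intestine",
                   "large_intestine", "pancreas")

#' Embedded physiology lookup tables
#'
#' Returns the age- and sex-resolved physiology tables shipped with the
#' package: per-organ volumes, compartment fractions, plasma flows and
#' lymph-flow fractions (`organs`), and whole-body scalars (`scalars`).
#'
#' @return a list with data.frames `organs` and `scalars`.
#' @export
physiology_table <- function() {
  if (is.null(.asun$phys)) {
    od <- utils::read.csv(system.file("extdata", "physiology_organs.csv",
                                      package = "asunpbpk"))
    sd <- utils::read.csv(system.file("extdata", "physiology_reference.csv",
                                      package = "asunpbpk"))
    .asun$phys <- list(organs = od, scalars = sd)
  }
  .asun$phys
}

#' Body surface area (DuBois-DuBois)
#'
#' @param body_weight body weight in kg.
#' @param height height in cm.
#' @return body surface area in m^2.
#' @examples
#' body_surface_area(77, 176)
#' @export
body_surface_area <- function(body_weight, height) {
  if (!is.numeric(body_weight) || !is.numeric(height) ||
      any(!is.finite(body_weight)) || any(!is.finite(height)) ||
      any(body_weight <= 0) || any(height <= 0))
    asun_stop("validation_error",
              "body_weight and height must be positive numbers")
  0.007184 * body_weight^0.425 * height^0.725
}

ref_scalars <- function(age, sex) {
  sc <- physiology_table()$scalars
  sc <- sc[sc$sex == sex, ]
  sc <- sc[order(sc$age_y), ]
  out <- lapply(sc[setdiff(names(sc), c("age_y", "sex"))],
                function(v) interp_age(sc$age_y, v, age))
  out
}

ref_organs <- function(age, sex) {
  od <- physiology_table()$organs
  od <- od[od$sex == sex, ]
  out <- do.call(rbind, lapply(ORGANS, function(org) {
    o <- od[od$organ == org, ]
    o <- o[order(o$age_y), ]
    data.frame(
      name = org,
      total_volume = interp_age(o$age_y, o$total_volume_L, age),
      vascular_frac = interp_age(o$age_y, o$vascular_frac, age),
      interstitial_frac = interp_age(o$age_y, o$interstitial_frac, age),
      endosomal_frac = interp_age(o$age_y, o$endosomal_frac, age),
      plasma_flow = interp_age(o$age_y, o$plasma_flow_L_min, age),
      lymph_frac = interp_age(o$age_y, o$lymph_frac, age),
      capillary_type = o$capillary_type[1],
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$name
  out
}

#' Construct a virtual individual
#'
#' Builds a fully parameterized individual (organ volumes, compartment
#' volumes, plasma and lymph flows, hematocrit, cardiac output) for a given
#' age and sex. When body weight and height are omitted, the age- and
#' sex-specific reference values of the embedded physiology table are used.
#' Organ volumes are scaled proportionally to `body_weight` relative to the
#' reference weight; blood flows scale with cardiac output, which follows
#' allometric body-weight scaling (exponent 0.75).
#'
#' Ages below 1 year are rejected: the maturation assumptions of the model
#' (fully expressed CD95L, ASGR and FcRn) only cover children above 1 year.
#'
#' @param age age in years, between 1 and 100.
#' @param sex `"male"` or `"female"`.
#' @param body_weight optional body weight in kg.
#' @param height optional height in cm.
#' @param id optional subject identifier.
#' @param organ_cv optional named list with elements `volume` and `flow`
#'   giving lognormal coefficients of variation applied per organ (used by
#'   [generate_population()]; default none).
#' @return an object of class `asun_individual`.
#' @examples
#' adult <- build_individual(30, "male")
#' adult$body_weight
#' @export
build_individual <- function(age, sex = c("male", "female"),
                             body_weight = NULL, height = NULL, id = NULL,
                             organ_cv = NULL) {
  if (!is_scalar_num(age))
    asun_stop("validation_error", "age must be a single number")
  if (age < 1 || age > 100)
    asun_stop("unsupported_age_error",
              "age %.3g y is outside the supported range [1, 100]", age)
  sex <- match.arg(sex)
  sc <- ref_scalars(age, sex)
  height <- height %||% sc$height_cm
  body_weight <- body_weight %||%
    (sc$body_weight_kg * (height / sc$height_cm)^2)
  check_positive(body_weight, "body_weight")
  check_positive(height, "height")
  bmi <- body_weight / (height / 100)^2
  if (bmi < 10 || bmi > 60)
    asun_stop("validation_error",
              "BMI %.1f kg/m^2 outside plausible range [10, 60]", bmi)

  wscale <- body_weight / sc$body_weight_kg
  co <- sc$cardiac_output_L_min * wscale^0.75
  fscale <- co / sc$cardiac_output_L_min
  hct <- sc$hematocrit

  org <- ref_organs(age, sex)
  org$total_volume <- org$total_volume * wscale
  org$plasma_flow <- org$plasma_flow * fscale
  if (!is.null(organ_cv)) {
    n <- nrow(org)
    org$total_volume <- org$total_volume * rlnorm_cv(n, organ_cv$volume)
    org$plasma_flow <- org$plasma_flow * rlnorm_cv(n, organ_cv$flow)
  }
  # the lung is perfused in series and must carry the total venous return
  # (systemic organ outflows plus lymph), keeping the circulation coherent
  # whether or not organ flows were perturbed
  not_lung <- org$name != "lung"
  lf_lung <- org$lymph_frac[!not_lung]
  org$plasma_flow[!not_lung] <- sum(org$plasma_flow[not_lung]) /
    (1 - lf_lung)
  org$vascular_volume <- org$total_volume * org$vascular_frac
  org$interstitial_volume <- org$total_volume * org$interstitial_frac
  org$endosomal_volume <- org$total_volume * org$endosomal_frac
  # liver lymph is driven by its total (arterial + portal) through-flow
  through <- stats::setNames(org$plasma_flow, org$name)
  through["liver"] <- through["liver"] + sum(through[PORTAL_ORGANS])
  org$lymph_flow <- org$lymph_frac * through

  blood <- sc$blood_volume_L * wscale
  vasc_sum <- sum(org$vascular_volume)
  large_vessel <- max(blood - vasc_sum, 0.2 * blood)
  v_ven_pl <- large_vessel * (2 / 3) * (1 - hct)
  v_art_pl <- large_vessel * (1 / 3) * (1 - hct)

  structure(list(
    id = id %||% sprintf("%s_%03.0f", substr(sex, 1, 1), age),
    age = age, sex = sex, body_weight = body_weight, height = height,
    bsa = body_surface_area(body_weight, height), hematocrit = hct,
    cardiac_output = co,
    total_lymph_flow = sum(org$lymph_flow),
    gfr = sc$gfr_L_h * wscale^0.75,
    blood_volume = blood,
    venous_plasma_volume = v_ven_pl,
    arterial_plasma_volume = v_art_pl,
    organs = org[, c("name", "total_volume", "vascular_volume",
                     "interstitial_volume", "endosomal_volume",
                     "plasma_flow", "lymph_flow", "capillary_type")]
  ), class = "asun_individual")
}

#' @export
print.asun_individual <- function(x, ...) {
  cat(sprintf("<asun_individual> %s: %s, %.3g y, %.1f kg, %.0f cm, BSA %.2f m^2\n",
              x$id, x$sex, x$age, x$body_weight, x$height, x$bsa))
  invisible(x)
}

#' Specify a virtual population
#'
#' @param n number of individuals.
#' @param male_fraction fraction of males.
#' @param age_range two-element range in years.
#' @param weight_range optional body-weight range in kg.
#' @param height_range optional height range in cm.
#' @param bmi_range optional BMI range in kg/m^2.
#' @param bmi_mean,bmi_sd optional: when given, body weight is sampled via
#'   BMI from a normal distribution (truncated to `bmi_range`) instead of
#'   around the age/sex reference weight. Used for adult patient cohorts,
#'   whose weight distribution is not that of healthy reference adults.
#' @param seed integer seed for reproducible sampling.
#' @return an object of class `asun_popspec`.
#' @export
population_spec <- function(n, male_fraction = 0.5, age_range = c(20, 50),
                            weight_range = NULL, height_range = NULL,
                            bmi_range = NULL, bmi_mean = NULL,
                            bmi_sd = 4.5, seed = 1L) {
  if (!is_scalar_num(n) || n < 0 || n != round(n))
    asun_stop("validation_error", "n must be a non-negative integer")
  if (!is_scalar_num(male_fraction) || male_fraction < 0 || male_fraction > 1)
    asun_stop("validation_error", "male_fraction must lie in [0, 1]")
  chk_range <- function(r, nm) {
    if (!is.null(r) && (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]))
      asun_stop("validation_error", "%s must be an ordered range", nm)
  }
  chk_range(age_range, "age_range")
  chk_range(weight_range, "weight_range")
  chk_range(height_range, "height_range")
  chk_range(bmi_range, "bmi_range")
  structure(list(n = as.integer(n), male_fraction = male_fraction,
                 age_range = age_range, weight_range = weight_range,
                 height_range = height_range, bmi_range = bmi_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 seed = as.integer(seed)),
            class = "asun_popspec")
}

# anthropometric variability: height lognormal (CV 3.5%) around the age/sex
# reference, weight from reference weight scaled by (height/ref_height)^2
# with an additional lognormal relative-weight factor (CV 15%)
HEIGHT_CV <- 0.035
WEIGHT_CV <- 0.15
ORGAN_VOLUME_CV <- 0.10
ORGAN_FLOW_CV <- 0.15

#' Generate a virtual population
#'
#' Samples `spec$n` individuals with reproducible anthropometric and
#' organ-level variability. Height is drawn lognormally around the age- and
#' sex-specific reference (CV 3.5%); weight follows the reference weight
#' scaled to the sampled height with an additional lognormal relative-weight
#' factor (CV 15%); organ volumes and flows receive lognormal perturbations
#' (CV 10% and 15%). Draws violating the requested weight/height/BMI ranges
#' are rejected and resampled; persistent infeasibility raises an error.
#'
#' @param spec an [population_spec()] object.
#' @param max_attempts rejection-sampling attempts per individual.
#' @return list of [build_individual()] objects.
#' @export
generate_population <- function(spec, max_attempts = 1000L) {
  stopifnot(inherits(spec, "asun_popspec"))
  if (spec$n == 0L) return(list())
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      sex <- if (stats::runif(1) < spec$male_fraction) "male" else "female"
      for (att in seq_len(max_attempts)) {
        age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
        sc <- ref_scalars(age, sex)
        ht <- sc$height_cm * rlnorm_cv(1, HEIGHT_CV)
        bw <- if (is.null(spec$bmi_mean)) {
          sc$body_weight_kg * (ht / sc$height_cm)^2 * rlnorm_cv(1, WEIGHT_CV)
        } else {
          stats::rnorm(1, spec$bmi_mean, spec$bmi_sd) * (ht / 100)^2
        }
        bmi <- bw / (ht / 100)^2
        ok <- (is.null(spec$weight_range) ||
                 (bw >= spec$weight_range[1] && bw <= spec$weight_range[2])) &&
          (is.null(spec$height_range) ||
             (ht >= spec$height_range[1] && ht <= spec$height_range[2])) &&
          (is.null(spec$bmi_range) ||
             (bmi >= spec$bmi_range[1] && bmi <= spec$bmi_range[2])) &&
          bmi >= 10 && bmi <= 60
        if (ok) {
          return(build_individual(age, sex, body_weight = bw, height = ht,
                                  id = sprintf("S%03d", i),
                                  organ_cv = list(volume = ORGAN_VOLUME_CV,
                                                  flow = ORGAN_FLOW_CV)))
        }
      }
      asun_stop("infeasibility_error",
                "could not satisfy population constraints in %d attempts",
                max_attempts)
    })
  })
}

#' Export a population to CSV (one row per individual) with a JSON sidecar
#' recording the generating specification.
#'
#' @param pop list of individuals.
#' @param spec the generating [population_spec()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return invisibly, the data.frame written.
#' @export
population_to_csv <- function(pop, spec, path) {
  df <- do.call(rbind, lapply(pop, function(p)
    data.frame(id = p$id, age = p$age, sex = p$sex,
               body_weight = p$body_weight, height = p$height, bsa = p$bsa,
               hematocrit = p$hematocrit, cardiac_output = p$cardiac_output)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(df)
}
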