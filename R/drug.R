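# Drug-dependent parameters, batch properties, target expression and dosing.

#' Drug-dependent parameters of the asunercept protein model
#'
#' Returns the final drug-dependent parameter set of the adult asunercept
#' model. Units follow the conventional reporting: dissociation constants in
#' umol/L, rate constants in 1/min, the FcRn association rate constant in
#' L/(umol*min). Derived quantities (CD95L on-rate, FcRn off-rates per
#' compartment) are computed from the primary parameters.
#'
#' The serum-side FcRn dissociation constant is so large (999999 umol/L)
#' that binding in plasma is negligible; the model therefore implements FcRn
#' binding in the endosomal/lysosomal space only.
#'
#' @param molecular_weight g/mol.
#' @param fraction_unbound fraction unbound in serum.
#' @param solute_radius hydrodynamic radius, nm.
#' @param cd95l_kd CD95L dissociation constant, umol/L.
#' @param cd95l_koff CD95L dissociation rate constant, 1/min.
#' @param asgr_cl_spec maximal (zero-sialylation) specific ASGR clearance,
#'   1/min.
#' @param fcrn_kd_lysosomal FcRn dissociation constant at endosomal pH,
#'   umol/L.
#' @param fcrn_kd_serum FcRn dissociation constant at serum pH, umol/L.
#' @param fcrn_kass FcRn association rate constant, L/(umol*min).
#' @param gfr_fraction fraction of glomerularly filtered drug reaching
#'   urine.
#' @return an object of class `asun_drug`.
#' @examples
#' drug <- asunercept_parameters()
#' drug$cd95l_kon  # derived, L/(umol*min)
#' @export
asunercept_parameters <- function(molecular_weight = 84082.0,
                                  fraction_unbound = 1.0,
                                  solute_radius = 4.01,
                                  cd95l_kd = 1.91,
                                  cd95l_koff = 9.70e-5,
                                  asgr_cl_spec = 2.43e-4,
                                  fcrn_kd_lysosomal = 1.73,
                                  fcrn_kd_serum = 999999.0,
                                  fcrn_kass = 0.87,
                                  gfr_fraction = 0.0) {
  for (nm in c("molecular_weight", "solute_radius", "cd95l_kd", "cd95l_koff",
               "fcrn_kd_lysosomal", "fcrn_kd_serum"))
    check_positive(get(nm), nm)
  for (nm in c("asgr_cl_spec", "fcrn_kass")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v < 0)
      asun_stop("validation_error", "%s must be non-negative", nm)
  }
  if (!is_scalar_num(gfr_fraction) || gfr_fraction < 0 || gfr_fraction > 1)
    asun_stop("validation_error", "gfr_fraction must lie in [0, 1]")
  if (!is_scalar_num(fraction_unbound) || fraction_unbound <= 0 ||
      fraction_unbound > 1)
    asun_stop("validation_error", "fraction_unbound must lie in (0, 1]")
  structure(list(
    molecular_weight = molecular_weight,
    fraction_unbound = fraction_unbound,
    solute_radius = solute_radius,
    cd95l_kd = cd95l_kd,
    cd95l_koff = cd95l_koff,
    cd95l_kon = cd95l_koff / cd95l_kd,
    asgr_cl_spec = asgr_cl_spec,
    fcrn_kd_lysosomal = fcrn_kd_lysosomal,
    fcrn_kd_serum = fcrn_kd_serum,
    fcrn_kass = fcrn_kass,
    fcrn_koff_lysosomal = fcrn_kass * fcrn_kd_lysosomal,
    fcrn_koff_serum = fcrn_kass * fcrn_kd_serum,
    gfr_fraction = gfr_fraction
  ), class = "asun_drug")
}

#' Sialylation-dependent ASGR clearance model
#'
#' The asialoglycoprotein receptor removes glycoproteins with exposed
#' galactose residues (missing terminal sialic acids) from the circulation.
#' The specific clearance falls as a Hill function of the batch sialic
#' acid:glycan ratio:
#' `CL(r) = cl_spec * (1 - r^h / (r^h + k^h))`
#' with Hill exponent `h` and half-maximum ratio `k`.
#'
#' @param cl_spec maximal specific clearance at zero sialylation, 1/min.
#' @param hill_exponent Hill exponent (default 8.03).
#' @param sa_ratio_50 sialic acid:glycan ratio at half-maximal clearance
#'   (default 0.378).
#' @return an object of class `asun_asgr`.
#' @export
asgr_model <- function(cl_spec = 2.43e-4, hill_exponent = 8.03,
                       sa_ratio_50 = 0.378) {
  check_positive(hill_exponent, "hill_exponent")
  check_positive(sa_ratio_50, "sa_ratio_50")
  if (!is_scalar_num(cl_spec) || cl_spec < 0)
    asun_stop("validation_error", "cl_spec must be non-negative")
  structure(list(cl_spec = cl_spec, hill_exponent = hill_exponent,
                 sa_ratio_50 = sa_ratio_50), class = "asun_asgr")
}

#' ASGR clearance for a given batch sialylation
#'
#' @param asgr an [asgr_model()] object.
#' @param sa_glycan_ratio sialic acid:glycan ratio of the batch (>= 0).
#' @return specific ASGR clearance in 1/min; lies in `[0, cl_spec]` and is
#'   strictly decreasing in the ratio.
#' @examples
#' asgr_clearance_rate(asgr_model(), 0.378)  # exactly cl_spec / 2
#' @export
asgr_clearance_rate <- function(asgr, sa_glycan_ratio) {
  stopifnot(inherits(asgr, "asun_asgr"))
  if (!is.numeric(sa_glycan_ratio) || any(!is.finite(sa_glycan_ratio)) ||
      any(sa_glycan_ratio < 0))
    asun_stop("validation_error", "sa_glycan_ratio must be >= 0")
  h <- asgr$hill_exponent
  rh <- sa_glycan_ratio^h
  asgr$cl_spec * (1 - rh / (rh + asgr$sa_ratio_50^h))
}

#' Manufacturing batch properties
#'
#' @param batch_id batch label.
#' @param sa_glycan_ratio average number of terminal sialic acid residues
#'   per N-glycan for the batch.
#' @return an object of class `asun_batch`.
#' @export
batch_properties <- function(batch_id = "batch", sa_glycan_ratio = 0.64) {
  if (!is_scalar_num(sa_glycan_ratio) || sa_glycan_ratio < 0)
    asun_stop("validation_error", "sa_glycan_ratio must be >= 0")
  structure(list(batch_id = as.character(batch_id),
                 sa_glycan_ratio = sa_glycan_ratio), class = "asun_batch")
}

#' Target and receptor expression placement
#'
#' CD95L is placed as a reversible binding species in the interstitial space
#' of the listed organs and, for the "blood cells" site, in the venous and
#' arterial plasma spaces. ASGR elimination acts on liver
#' interstitial-accessible drug.
#'
#' @param cd95l_organs organs carrying interstitial CD95L.
#' @param cd95l_relative_expression relative expression (dimensionless).
#' @param cd95l_reference_concentration reference concentration, umol/L.
#' @param asgr_organ organ carrying ASGR (liver).
#' @param asgr_reference_concentration reference concentration, umol/L.
#' @return an object of class `asun_expression`.
#' @export
target_expression <- function(cd95l_organs = c("bone", "brain", "gonads",
                                               "kidney", "lung"),
                              cd95l_relative_expression = 1.0,
                              cd95l_reference_concentration = 1.0,
                              asgr_organ = "liver",
                              asgr_reference_concentration = 1.0) {
  if (!all(cd95l_organs %in% ORGANS))
    asun_stop("configuration_error", "unknown organ in cd95l_organs: %s",
              paste(setdiff(cd95l_organs, ORGANS), collapse = ", "))
  if (!identical(asgr_organ, "liver"))
    asun_stop("configuration_error", "ASGR is implemented in liver only")
  if (cd95l_relative_expression < 0 || cd95l_reference_concentration < 0 ||
      asgr_reference_concentration < 0)
    asun_stop("validation_error", "expression values must be >= 0")
  structure(list(cd95l_organs = cd95l_organs,
                 cd95l_relative_expression = cd95l_relative_expression,
                 cd95l_reference_concentration = cd95l_reference_concentration,
                 asgr_organ = asgr_organ,
                 asgr_reference_concentration = asgr_reference_concentration),
            class = "asun_expression")
}

#' Intravenous infusion dose event
#'
#' @param start_time infusion start, h after time zero.
#' @param duration infusion duration, h.
#' @param amount dose amount, mg.
#' @return an object of class `asun_dose`.
#' @export
dose_event <- function(start_time = 0, duration = 1, amount = 400) {
  if (!is_scalar_num(start_time) || start_time < 0)
    asun_stop("validation_error", "start_time must be >= 0")
  check_positive(duration, "duration")
  if (!is_scalar_num(amount) || amount < 0)
    asun_stop("validation_error", "dose amount must be >= 0")
  structure(list(start_time = start_time, duration = duration,
                 amount = amount, route = "iv_infusion"),
            class = "asun_dose")
}

#' Weekly infusion schedule
#'
#' @param dose_mg dose per administration, mg.
#' @param n_doses number of weekly doses (default 15).
#' @param interval dosing interval, h (default 168).
#' @param duration infusion duration, h (default 0.5).
#' @param start first infusion start, h.
#' @return list of [dose_event()] objects.
#' @export
weekly_schedule <- function(dose_mg, n_doses = 15, interval = 168,
                            duration = 0.5, start = 0) {
  lapply(seq_len(n_doses) - 1L, function(k)
    dose_event(start + k * interval, duration, dose_mg))
}
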