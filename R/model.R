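# Assembly of the whole-body ODE system for one individual, one drug
# parameterization and one batch sialylation level.

#' Large-molecule platform constants
#'
#' Constants of the generic large-molecule disposition platform that are not
#' drug-dependent: the two-pore geometry (small/large pore radii, fractional
#' hydraulic conductances, isogravimetric circular flow), the anchoring of
#' the diffusive permeability-surface products, and the endothelial
#' endosomal machinery (pinocytosis rate, FcRn concentration, recycling and
#' lysosomal degradation rates). See the methods vignette for the sources
#' and the derivation of each default.
#'
#' @param r_small_nm small pore radius, nm.
#' @param r_large_nm large pore radius, nm.
#' @param alpha_large fractional hydraulic conductance of large pores.
#' @param j_iso_per_lymph isogravimetric circular flow as a fraction of the
#'   organ lymph flow.
#' @param ndp_pa net driving pressure anchoring the pore hydraulic
#'   conductance to the organ lymph flow, Pa.
#' @param visc_pore_pa_s effective plasma viscosity in the pores, Pa*s.
#' @param visc_water_pa_s water viscosity at 37C (Stokes-Einstein), Pa*s.
#' @param temperature_k absolute temperature, K.
#' @param kup_per_h pinocytosis (endosomal uptake) rate constant per unit
#'   endosomal volume, 1/h.
#' @param fcrn_umol FcRn concentration in the endosomal space, umol/L.
#' @param krec_per_h endosomal recycling rate constant, 1/h.
#' @param kdeg_per_h lysosomal degradation rate constant for unbound
#'   endosomal drug, 1/h.
#' @param fr_plasma fraction of recycled drug returned to the vascular side.
#' @return list of platform constants.
#' @export
platform_constants <- function(r_small_nm = 4.44,
                               r_large_nm = 22.85,
                               alpha_large = 0.042,
                               j_iso_per_lymph = 0.042,
                               ndp_pa = 133.3,
                               visc_pore_pa_s = 1.2e-3,
                               visc_water_pa_s = 6.9e-4,
                               temperature_k = 310.15,
                               kup_per_h = 0.887,
                               fcrn_umol = 49.8,
                               krec_per_h = 10.0,
                               kdeg_per_h = 32.2,
                               fr_plasma = 0.715) {
  list(r_small_nm = r_small_nm, r_large_nm = r_large_nm,
       alpha_large = alpha_large, j_iso_per_lymph = j_iso_per_lymph,
       ndp_pa = ndp_pa, visc_pore_pa_s = visc_pore_pa_s,
       visc_water_pa_s = visc_water_pa_s, temperature_k = temperature_k,
       kup_per_h = kup_per_h, fcrn_umol = fcrn_umol,
       krec_per_h = krec_per_h, kdeg_per_h = kdeg_per_h,
       fr_plasma = fr_plasma)
}

# Renkin diffusive hindrance factor for a solute/pore radius ratio lambda
renkin_hindrance <- function(lambda) {
  ifelse(lambda >= 1, 0,
         (1 - lambda)^2 *
           (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5))
}

# osmotic reflection coefficient for a cylindrical pore
pore_reflection <- function(lambda) {
  if (lambda >= 1) return(1)
  phi <- (1 - lambda)^2
  1 - phi * (2 - phi) * (1 - lambda / 3)
}

# free diffusion coefficient (Stokes-Einstein), m^2/s
stokes_einstein <- function(radius_nm, visc_pa_s, temp_k) {
  kb <- 1.380649e-23
  kb * temp_k / (6 * pi * visc_pa_s * radius_nm * 1e-9)
}

# two-pore transport parameters for a vector of organ lymph flows (L/h)
two_pore_parameters <- function(lymph_flow, solute_radius_nm, platform) {
  lam_s <- solute_radius_nm / platform$r_small_nm
  lam_l <- solute_radius_nm / platform$r_large_nm
  a_l <- platform$alpha_large
  a_s <- 1 - a_l
  j_iso <- platform$j_iso_per_lymph * lymph_flow
  # pore volume fluxes (sum to total lymph flow)
  js <- a_s * lymph_flow - j_iso
  jl <- a_l * lymph_flow + j_iso
  # diffusive PS from Poiseuille pore area anchored at the net driving
  # pressure: A/dx = 8 * eta * (L/NDP) * alpha / r^2
  d_free <- stokes_einstein(solute_radius_nm, platform$visc_water_pa_s,
                            platform$temperature_k)
  lps_si <- (lymph_flow * 1e-3 / 3600) / platform$ndp_pa  # m^3/(s Pa)
  area_ratio <- function(alpha, r_nm) {
    8 * platform$visc_pore_pa_s * lps_si * alpha / (r_nm * 1e-9)^2
  }
  ps_s <- d_free * renkin_hindrance(lam_s) * area_ratio(a_s, platform$r_small_nm)
  ps_l <- d_free * renkin_hindrance(lam_l) * area_ratio(a_l, platform$r_large_nm)
  list(js = js, jl = jl,
       sig_s = pore_reflection(lam_s), sig_l = pore_reflection(lam_l),
       ps_s = ps_s * 3.6e6, ps_l = ps_l * 3.6e6)  # m^3/s -> L/h
}

# parameter-vector layout shared with src/pbpk_model.c
NORG <- 15L
PARM_SCALARS <- c("inf_rate", "v_ven", "v_art", "kdeg", "krec", "fr",
                  "kass", "koff_fcrn", "kon_t", "koff_t", "k_asgr",
                  "t_ven", "t_art", "gfr_cl")
PARM_ARRAYS <- c("q", "lf", "v_pl", "v_is", "v_e", "j_s", "j_l",
                 "sig_s", "sig_l", "ps_s", "ps_l", "cl_up", "t_tot",
                 "r_tot")

parm_index <- function(name, organ = NULL) {
  if (name %in% PARM_SCALARS) return(match(name, PARM_SCALARS))
  k <- match(name, PARM_ARRAYS)
  stopifnot(!is.na(k))
  base <- length(PARM_SCALARS) + (k - 1L) * NORG
  if (is.null(organ)) base + seq_len(NORG) else base + match(organ, ORGANS)
}

state_names <- function() {
  c("venous", "arterial",
    paste0(ORGANS, "_plasma"), paste0(ORGANS, "_endo_free"),
    paste0(ORGANS, "_endo_fcrn"), paste0(ORGANS, "_inter_free"),
    paste0(ORGANS, "_inter_target"),
    "venous_target", "arterial_target",
    "cum_lysosomal", "cum_asgr", "cum_renal")
}

#' Assemble the whole-body PBPK system
#'
#' Combines an individual's physiology with the drug parameters, the target
#' expression placement and the batch sialylation level into an ODE system
#' ready for [simulate_pbpk()]. Rate constants are converted to per-hour;
#' amounts are carried in nmol.
#'
#' @param individual an [build_individual()] object.
#' @param drug an [asunercept_parameters()] object.
#' @param expression a [target_expression()] object.
#' @param batch a [batch_properties()] object.
#' @param asgr an [asgr_model()]; defaults to the drug's `asgr_cl_spec` with
#'   the standard Hill constants.
#' @param platform [platform_constants()].
#' @return an object of class `asun_model`.
#' @export
build_model <- function(individual, drug = asunercept_parameters(),
                        expression = target_expression(),
                        batch = batch_properties(),
                        asgr = NULL, platform = platform_constants()) {
  stopifnot(inherits(individual, "asun_individual"),
            inherits(drug, "asun_drug"),
            inherits(expression, "asun_expression"),
            inherits(batch, "asun_batch"))
  asgr <- asgr %||% asgr_model(cl_spec = drug$asgr_cl_spec)
  org <- individual$organs
  if (!all(expression$cd95l_organs %in% org$name))
    asun_stop("configuration_error",
              "expression organ missing from individual physiology")

  q <- org$plasma_flow * 60          # L/min -> L/h
  lf <- org$lymph_flow * 60
  tp <- two_pore_parameters(lf, drug$solute_radius, platform)

  # target amounts: reference concentration (umol/L -> nmol/L) times
  # relative expression times interstitial volume
  t_conc <- expression$cd95l_reference_concentration * 1000 *
    expression$cd95l_relative_expression
  t_tot <- ifelse(org$name %in% expression$cd95l_organs,
                  t_conc * org$interstitial_volume, 0)

  kass_h <- drug$fcrn_kass * 60 / 1000        # L/(umol min) -> L/(nmol h)
  koff_fcrn_h <- kass_h * drug$fcrn_kd_lysosomal * 1000
  kon_t_h <- drug$cd95l_kon * 60 / 1000       # L/(umol min) -> L/(nmol h)
  koff_t_h <- drug$cd95l_koff * 60
  k_asgr_h <- asgr_clearance_rate(asgr, batch$sa_glycan_ratio) * 60

  p <- numeric(length(PARM_SCALARS) + length(PARM_ARRAYS) * NORG)
  set <- function(name, value, organ = NULL) {
    p[parm_index(name, organ)] <<- value
  }
  set("inf_rate", 0)
  set("v_ven", individual$venous_plasma_volume)
  set("v_art", individual$arterial_plasma_volume)
  set("kdeg", platform$kdeg_per_h)
  set("krec", platform$krec_per_h)
  set("fr", platform$fr_plasma)
  set("kass", kass_h)
  set("koff_fcrn", koff_fcrn_h)
  set("kon_t", kon_t_h)
  set("koff_t", koff_t_h)
  set("k_asgr", k_asgr_h)
  set("t_ven", t_conc * individual$venous_plasma_volume)
  set("t_art", t_conc * individual$arterial_plasma_volume)
  set("gfr_cl", drug$gfr_fraction * individual$gfr)
  set("q", q)
  set("lf", lf)
  set("v_pl", org$vascular_volume * (1 - individual$hematocrit))
  set("v_is", org$interstitial_volume)
  set("v_e", org$endosomal_volume)
  set("j_s", tp$js)
  set("j_l", tp$jl)
  set("sig_s", rep(tp$sig_s, NORG))
  set("sig_l", rep(tp$sig_l, NORG))
  set("ps_s", tp$ps_s)
  set("ps_l", tp$ps_l)
  set("cl_up", platform$kup_per_h * org$endosomal_volume)
  set("t_tot", t_tot)
  set("r_tot", platform$fcrn_umol * 1000 * org$endosomal_volume)

  structure(list(
    individual = individual, drug = drug, expression = expression,
    batch = batch, asgr = asgr, platform = platform,
    parms = p, state_names = state_names(),
    nmol_per_mg = 1e6 / drug$molecular_weight,
    ug_ml_per_nmol_l = drug$molecular_weight / 1e6
  ), class = "asun_model")
}

#' @export
print.asun_model <- function(x, ...) {
  cat(sprintf(
    "<asun_model> %s (%.3g y %s, %.1f kg), batch %s (SA ratio %.2f), %d states\n",
    x$individual$id, x$individual$age, x$individual$sex,
    x$individual$body_weight, x$batch$batch_id, x$batch$sa_glycan_ratio,
    length(x$state_names)))
  invisible(x)
}
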