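# Builds the embedded physiology lookup tables shipped in inst/extdata.
#
# Scalar anthropometry (body weight, height, hematocrit, cardiac output,
# blood volume) and organ masses follow ICRP Publication 89 reference
# individuals. Organ-level vascular / interstitial / endosomal fractions and
# lymph-flow fractions follow the generic large-molecule PBPK literature
# (two-pore formalism with lysosomal degradation in the vascular
# endothelium). Ages above 30 are held at the adult reference. Tissue
# density is taken as 1 kg/L.
#
# Run from the package root:  Rscript data-raw/build_physiology.R

ages <- c(1, 5, 10, 15, 18, 30, 50, 70, 100)
# index into the 6 tabulated age columns (30+ constant)
acol <- c(1, 2, 3, 4, 5, 6, 6, 6, 6)

organs <- c("lung", "brain", "heart", "kidney", "liver", "spleen",
            "stomach", "small_intestine", "large_intestine", "pancreas",
            "gonads", "bone", "muscle", "fat", "skin")

# organ masses [kg] at ages 1, 5, 10, 15, 18, 30 (male)
mass_m <- rbind(
  lung            = c(0.080, 0.125, 0.210, 0.330, 0.480, 0.500),
  brain           = c(0.950, 1.245, 1.310, 1.420, 1.440, 1.450),
  heart           = c(0.050, 0.085, 0.140, 0.230, 0.310, 0.330),
  kidney          = c(0.070, 0.110, 0.180, 0.250, 0.300, 0.310),
  liver           = c(0.330, 0.570, 0.830, 1.300, 1.700, 1.800),
  spleen          = c(0.029, 0.050, 0.080, 0.130, 0.145, 0.150),
  stomach         = c(0.020, 0.050, 0.085, 0.120, 0.140, 0.150),
  small_intestine = c(0.085, 0.220, 0.370, 0.520, 0.620, 0.650),
  large_intestine = c(0.070, 0.120, 0.210, 0.300, 0.350, 0.370),
  pancreas        = c(0.020, 0.035, 0.060, 0.110, 0.130, 0.140),
  gonads          = c(0.0015, 0.002, 0.004, 0.025, 0.033, 0.035),
  bone            = c(1.180, 2.430, 4.500, 7.950, 10.000, 10.500),
  muscle          = c(1.900, 5.600, 11.000, 24.000, 27.500, 29.000),
  fat             = c(3.800, 5.500, 8.600, 12.000, 17.000, 18.200),
  skin            = c(0.350, 0.570, 0.820, 2.000, 3.100, 3.300)
)

# female organ masses: shared with male through age 10, diverging at puberty
mass_f <- mass_m
mass_f[, 4:6] <- rbind(
  lung            = c(0.300, 0.400, 0.420),
  brain           = c(1.300, 1.300, 1.300),
  heart           = c(0.220, 0.240, 0.250),
  kidney          = c(0.240, 0.270, 0.275),
  liver           = c(1.300, 1.380, 1.400),
  spleen          = c(0.130, 0.130, 0.130),
  stomach         = c(0.120, 0.140, 0.140),
  small_intestine = c(0.520, 0.580, 0.600),
  large_intestine = c(0.290, 0.350, 0.360),
  pancreas        = c(0.100, 0.120, 0.120),
  gonads          = c(0.011, 0.011, 0.011),
  bone            = c(6.300, 7.600, 7.800),
  muscle          = c(17.000, 17.500, 17.500),
  fat             = c(18.000, 21.500, 22.500),
  skin            = c(1.700, 2.200, 2.300)
)

scalar <- list(
  m = list(bw = c(10, 19, 32, 56, 70, 73),
           ht = c(76, 109, 138, 167, 176, 176),
           hct = c(0.35, 0.37, 0.39, 0.42, 0.43, 0.43),
           co = c(1.2, 3.4, 5.0, 6.1, 6.5, 6.5),
           blood = c(0.78, 1.4, 2.4, 4.5, 5.2, 5.3),
           gfr = c(1.7, 3.0, 4.3, 5.8, 6.4, 6.5)),
  f = list(bw = c(10, 19, 32, 53, 59, 60),
           ht = c(76, 109, 138, 161, 163, 163),
           hct = c(0.35, 0.37, 0.39, 0.39, 0.39, 0.39),
           co = c(1.2, 3.4, 5.0, 5.5, 5.9, 5.9),
           blood = c(0.78, 1.4, 2.4, 3.6, 3.9, 3.9),
           gfr = c(1.7, 3.0, 4.3, 5.2, 5.6, 5.6))
)

vascular_frac <- c(lung = 0.36, brain = 0.035, heart = 0.14, kidney = 0.16,
                   liver = 0.21, spleen = 0.28, stomach = 0.08,
                   small_intestine = 0.08, large_intestine = 0.08,
                   pancreas = 0.10, gonads = 0.05, bone = 0.045,
                   muscle = 0.035, fat = 0.02, skin = 0.05)

interstitial_base <- c(lung = 0.19, brain = 0.17, heart = 0.14,
                       kidney = 0.20, liver = 0.16, spleen = 0.15,
                       stomach = 0.10, small_intestine = 0.13,
                       large_intestine = 0.12, pancreas = 0.12,
                       gonads = 0.07, bone = 0.10, muscle = 0.13,
                       fat = 0.135, skin = 0.30)
# extracellular (interstitial) water is relatively larger in young children
# (~26% of body weight at 1 year vs ~18% in adults)
interstitial_age_mult <- c(1.35, 1.25, 1.15, 1.0, 1.0, 1.0)

# fraction of organ volume occupied by vascular-endothelial endosomes
# (the lysosomal degradation / FcRn rescue space); tracks capillary density
endosomal_frac <- c(lung = 0.010, brain = 0.006, heart = 0.006,
                    kidney = 0.007, liver = 0.005, spleen = 0.005,
                    stomach = 0.004, small_intestine = 0.004,
                    large_intestine = 0.004, pancreas = 0.004,
                    gonads = 0.004, bone = 0.001, muscle = 0.0015,
                    fat = 0.001, skin = 0.003)

lymph_frac <- c(lung = 0.0002, brain = 0.0001, heart = 0.0005,
                kidney = 0.0010, liver = 0.0008, spleen = 0.0020,
                stomach = 0.0010, small_intestine = 0.0010,
                large_intestine = 0.0010, pancreas = 0.0010,
                gonads = 0.0010, bone = 0.0012, muscle = 0.0005,
                fat = 0.0005, skin = 0.0007)

capillary_type <- c(lung = "continuous", brain = "continuous",
                    heart = "continuous", kidney = "fenestrated",
                    liver = "sinusoidal", spleen = "sinusoidal",
                    stomach = "fenestrated", small_intestine = "fenestrated",
                    large_intestine = "fenestrated", pancreas = "fenestrated",
                    gonads = "fenestrated", bone = "sinusoidal",
                    muscle = "continuous", fat = "continuous",
                    skin = "continuous")

# organ plasma-flow shares of cardiac plasma output at ages 1,5,10,15,18,30.
# Lung is in series (receives total cardiac plasma flow); liver share is the
# hepatic-arterial component only (portal organs drain through the liver).
share_const <- c(heart = 0.04, liver = 0.065, spleen = 0.03, stomach = 0.01,
                 small_intestine = 0.10, large_intestine = 0.04,
                 pancreas = 0.01, gonads = 0.0005, bone = 0.05)
share_age <- list(
  brain  = c(0.30, 0.25, 0.18, 0.13, 0.12, 0.12),
  muscle = c(0.08, 0.10, 0.13, 0.16, 0.17, 0.17),
  kidney = c(0.16, 0.17, 0.18, 0.19, 0.19, 0.19),
  fat    = c(0.03, 0.035, 0.04, 0.05, 0.05, 0.05),
  skin   = c(0.06, 0.055, 0.05, 0.05, 0.05, 0.05)
)

rows <- list()
srows <- list()
for (sex in c("male", "female")) {
  sx <- substr(sex, 1, 1)
  mass <- if (sx == "m") mass_m else mass_f
  sc <- scalar[[sx]]
  for (k in seq_along(ages)) {
    j <- acol[k]
    co_plasma <- sc$co[j] * (1 - sc$hct[j]) # L/min
    srows[[length(srows) + 1]] <- data.frame(
      age_y = ages[k], sex = sex, body_weight_kg = sc$bw[j],
      height_cm = sc$ht[j], hematocrit = sc$hct[j],
      cardiac_output_L_min = sc$co[j], blood_volume_L = sc$blood[j],
      gfr_L_h = sc$gfr[j])
    for (org in organs) {
      share <- if (org == "lung") 1.0
      else if (org %in% names(share_age)) share_age[[org]][j]
      else share_const[[org]]
      q <- share * co_plasma
      isf <- min(interstitial_base[[org]] * interstitial_age_mult[j], 0.45)
      rows[[length(rows) + 1]] <- data.frame(
        age_y = ages[k], sex = sex, organ = org,
        total_volume_L = mass[org, j],
        vascular_frac = vascular_frac[[org]],
        interstitial_frac = isf,
        endosomal_frac = endosomal_frac[[org]],
        plasma_flow_L_min = round(q, 6),
        lymph_frac = lymph_frac[[org]],
        capillary_type = capillary_type[[org]])
    }
  }
}

org_tab <- do.call(rbind, rows)
sc_tab <- do.call(rbind, srows)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(org_tab, "inst/extdata/physiology_organs.csv", row.names = FALSE,
          quote = FALSE)
write.csv(sc_tab, "inst/extdata/physiology_reference.csv", row.names = FALSE,
          quote = FALSE)
cat("wrote", nrow(org_tab), "organ rows and", nrow(sc_tab), "scalar rows\n")
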