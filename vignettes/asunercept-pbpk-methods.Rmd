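---
title: "Methods: whole-body PBPK modeling of asunercept and pediatric dose translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modeling of asunercept and pediatric dose translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`asunpbpk` implements a mechanistic whole-body pharmacokinetic model of the
CD95L-neutralizing Fc-fusion protein asunercept (APG101) in adults and
children, together with the translational workflow built on it: adult model
qualification by geometric mean fold errors (GMFE), extrapolation of the
adult model to pediatric physiology, and optimization of weekly body-weight
doses so that children reach the steady-state exposure of the adult
reference population. This vignette documents the model equations, the
platform constants and their provenance, the numerical choices, and the
design decisions taken where the underlying analysis leaves them open.

# Model structure

Fifteen organ compartments (lung, brain, heart, kidney, liver, spleen,
stomach, small and large intestine, pancreas, gonads, bone, muscle, fat,
skin) are each divided into a vascular plasma space, an endothelial
endosomal space, and an interstitial space; the cellular space is not
accessible to a 84-kDa protein without receptor-mediated uptake and carries
no drug. Venous and arterial plasma pools close the circulation: the lung
is perfused in series (venous to arterial) and carries the total venous
return; all other organs are perfused in parallel from the arterial pool.
The splanchnic organs (spleen, stomach, intestines, pancreas) drain through
the liver via the portal vein. Amounts are carried in nmol, time in hours,
volumes in liters; serum concentrations are reported in ug/mL via the
molecular weight (84082 g/mol).

## Two-pore extravasation

Transcapillary solute transport follows the two-pore formalism: convection
through small (radius 4.44 nm) and large (22.85 nm) cylindrical pores with
fractional hydraulic conductances 0.958/0.042, plus diffusion. For a solute
of hydrodynamic radius $a$ (4.01 nm for asunercept) and pore radius $r$,
with $\lambda = a/r$ and partition coefficient $\Phi = (1-\lambda)^2$:

* reflection coefficient: $\sigma = 1 - \Phi(2-\Phi)(1-\lambda/3)$,
  giving $\sigma_S = 0.987$ and $\sigma_L = 0.155$;
* Renkin diffusive hindrance:
  $A/A_0 = \Phi\,(1 - 2.104\lambda + 2.09\lambda^3 - 0.95\lambda^5)$.

Each organ's total pore volume flux equals its lymph flow $L$; the
isogravimetric circular flow $J_{iso} = \alpha_L L$ recirculates outward
through large pores and inward through small pores, so
$J_S = \alpha_S L - J_{iso}$ and $J_L = \alpha_L L + J_{iso}$. Solute flux
per pore class uses the Patlak (convection-diffusion) expression

$$J_{solute} = J(1-\sigma)\,\frac{C_{pl} - C_{is} e^{-Pe}}{1 - e^{-Pe}},
\qquad Pe = \frac{J(1-\sigma)}{PS}.$$

The permeability-surface products are derived once from pore theory rather
than fitted: anchoring each organ's hydraulic conductance to its lymph flow
at a net driving pressure of 1 mmHg, the Poiseuille pore area per unit path
length is $A/\Delta x = 8\eta\,(L/NDP)\,\alpha_p/r_p^2$, and
$PS_p = D \cdot (A/A_0)_p \cdot A/\Delta x$ with the free diffusion
coefficient $D$ from Stokes-Einstein at 310 K. For asunercept this yields
$PS \approx 0.1$-$0.2$ L/h per L/h of lymph flow for both pore classes.
Interstitial drug returns to the venous pool with lymph (no reflection).

## Endosomal uptake, lysosomal degradation and FcRn rescue

Vascular endothelial cells take up drug by pinocytosis from both the
vascular and the interstitial side at clearance
$CL_{up,i} = k_{up} V_{endo,i}$. In the endosomal space, unbound drug is
degraded (lysosomal pathway, first order $k_{deg}$) or binds FcRn by mass
action ($k_{ass}$ = 0.87 L/(umol min), endosomal $K_d$ = 1.73 umol/L for
asunercept); FcRn-bound drug is recycled (rate $k_{rec}$), a fraction
$FR$ = 0.715 to plasma and the rest to the interstitium. The serum-side
FcRn $K_d$ of 999999 umol/L means plasma binding is negligible and is
implemented as its limit: no plasma FcRn reaction at all. Endogenous IgG
competition for FcRn is not modeled; FcRn occupancy by asunercept itself is
far below the 49.8 umol/L endosomal receptor concentration at therapeutic
doses, so rescue operates in its linear range.

Platform constants that the underlying analysis inherits from its modeling
platform without printing them ($k_{up}$, endosomal FcRn concentration,
$k_{rec}$, $k_{deg}$, $FR$) are shipped at magnitudes established in the
published large-molecule platform literature. The single pinocytosis rate
constant $k_{up}$ (0.887 per hour per unit endosomal volume) is anchored so
that the reference adult model with the final drug parameters and a highly
sialylated batch reproduces the program's reported adult terminal
half-life of 15 days; this is the one degree of freedom that ties the
endosomal machinery to the observed disposition, and the half-life check in
the test suite guards it.

## Target binding and clearance pathways

CD95L is a reversible, non-eliminating binding species: neutralization of
the ligand is the pharmacology, and target-mediated *clearance* is
deliberately absent (it did not improve the underlying model). CD95L sits
in the interstitial space of bone, brain, gonads, kidney and lung at a
reference concentration of 1 umol/L (relative expression 1.0), and - for
the "blood cells" site - as a binding species in the venous and arterial
plasma spaces. Binding kinetics use $k_{off}$ = 9.70e-5 /min and
$k_{on} = k_{off}/K_d$ with $K_d$ = 1.91 umol/L. Because the complex is
not eliminated, reversible binding redistributes exposure in time but
leaves total clearance unchanged; dose linearity of AUC and Cmax holds to
well within 5% across 0.2-20 mg/kg, which the test suite verifies.

The asialoglycoprotein receptor (ASGR) clearance is first order on the
liver's plasma-accessible pools - the sinusoidal endothelium is
fenestrated, so both the liver vascular plasma and the interstitial (space
of Disse) amounts are exposed - at the batch-specific rate

$$CL_{ASGR}(r) = CL_{spec}\left(1 - \frac{r^{8.03}}{r^{8.03} +
0.378^{8.03}}\right)$$

with $r$ the batch sialic acid:glycan ratio and $CL_{spec}$ = 2.43e-4 /min.
At $r = 0.378$ the clearance is exactly half-maximal; at $r \ge 0.6$ it
retains under 2% of its maximum and is pharmacokinetically irrelevant,
which is why highly sialylated batches show the full 15-day half-life
while early batches ($r \approx 0.3$) show about 12.5 days. Minor ASGR
expression outside the liver is not modeled (relative values unavailable).
Glomerular filtration is scaled by the filtered fraction, which is 0.0 for
asunercept; the renal pathway is therefore present but inactive.

# Physiology

The embedded physiology table (`inst/extdata/physiology_*.csv`) tabulates
organ masses, blood volumes, hematocrit and cardiac output at ages 1, 5,
10, 15, 18 and 30-100 years for both sexes, following ICRP reference
individuals, with organ-level vascular, interstitial and endosomal volume
fractions, lymph-flow fractions and capillary types (continuous,
fenestrated, sinusoidal) from the large-molecule PBPK literature. Ages are
linearly interpolated; ages below 1 year are rejected because the
maturation assumptions (fully expressed CD95L, ASGR and FcRn) are only
defensible above 1 year. Organ volumes scale proportionally with body
weight relative to the age/sex reference; cardiac output scales
allometrically ($BW^{0.75}$) and organ flows with it. Interstitial volume
fractions carry an age multiplier (1.35 at 1 year declining to 1.0 by
adolescence) reflecting the larger extracellular water fraction of young
children. The endosomal (endothelial) fractions are organ-specific
constants tracking capillary density; because young children have
proportionally larger capillary-dense organs (brain above all), the
weight-normalized endosomal volume - and with it clearance per kg - is
about 12% higher at age 1 than in adults and converges to the adult value
during adolescence. This emergent maturation of clearance, not any explicit
ontogeny factor, is what drives the pediatric dose adjustments.

Population variability: height is lognormal around the age/sex reference
(CV 3.5%); weight follows the reference scaled by height squared with a
lognormal relative-weight factor (CV 15%); organ volumes and flows receive
lognormal perturbations (CV 10% and 15%), after which the lung flow is
recomputed as the total venous return so the perturbed circulation stays
coherent. Adult *patient* cohorts are sampled differently: the Phase II
demographics print ranges plus a cohort mean weight of 77 kg and mean BSA
of 1.918 m^2, which reference-centered sampling of healthy adults cannot
reproduce; for specs with a BMI range, BMI is therefore drawn from a
truncated normal (mean 25.5, SD 4.5 kg/m^2) and weight derived from it,
which recovers the printed cohort means. Draws violating the requested
weight/height/BMI ranges are rejected and resampled.

# Non-compartmental analysis and qualification statistics

AUC to the last sample uses the linear-up/log-down trapezoid - the
pharmacokinetic convention - with the curve anchored at zero concentration
at the first infusion start. The terminal half-life comes from a log-linear
regression over the last 3-8 samples after the final dose, choosing the
window that maximizes adjusted R^2 and reporting no half-life when the best
window stays below R^2 = 0.85; this mirrors qualification practice where
inadequate terminal phases are omitted rather than forced (the adult
qualification dataset itself reports 14 of 16 half-lives). GMFE is
$10^{\mathrm{mean}|\log_{10}(pred/obs)|}$; fold errors are
$\max(pred/obs, obs/pred)$. Steady-state exposure is the AUC over the 15th
weekly dosing interval, hours 2352-2520 after the first dose - with a
15-day half-life, more than six half-lives of accumulation have elapsed and
the interval-to-interval AUC ratio is within 1%.

Local sensitivity uses a one-sided +10% perturbation of one drug parameter,
with the AUC of a single 400 mg dose in the reference adult as the output
metric: $S = (\Delta M/M)/(\Delta p/p)$, reported with sign and screened at
the conventional cutoff 0.5. For highly sialylated batches only the
lysosomal FcRn $K_d$ crosses that cutoff ($S \approx -0.6$): it governs the
principal (lysosomal) clearance pathway, while the CD95L parameters move
only the shape, not the area, and the ASGR pathway is inactive at high
sialylation.

# Parameter estimation

The four optimized parameters (CD95L $K_d$, CD95L $k_{off}$, ASGR
$CL_{spec}$, lysosomal FcRn $K_d$) are fitted simultaneously across all
training subjects by Levenberg-Marquardt on log-transformed concentrations,
with the parameters searched in log space and linearized 95% confidence
intervals from the Jacobian at the optimum. Residuals are unweighted
log-residuals by default (configurable to linear). The finite-difference
step of the numerical Jacobian is set to about 1% relative (`epsfcn`) -
far above the integrator noise floor at the fitting tolerance (rtol 1e-7) -
because machine-epsilon-scale steps would differentiate solver noise
instead of the model.

Identifiability, measured by seeded recovery experiments (simulate with
known parameters, add proportional lognormal error, refit from perturbed
starts): the lysosomal FcRn $K_d$ recovers within a few percent and ASGR
$CL_{spec}$ and CD95L $K_d$ within roughly 10-20% at error CV 20% on a
20-subject design. CD95L $k_{off}$ does not: its largest effect on any
serum sample is about 0.07% per 1% parameter change, so at CV 20% its
estimator spread remains of order 50-100% regardless of starting values.
This is a property of the data, not the optimizer - the published adult
analysis, with its full 35-subject training set, likewise reports a 95%
confidence interval of about +/-32% for this parameter, the widest of the
well-identified ones, and +/-123% for ASGR $CL_{spec}$. When every training
batch is highly sialylated ($r \ge 0.6$) the ASGR pathway becomes formally
non-identifiable and the fit flags its parameter (CI spanning more than two
orders of magnitude).

# Synthetic studies

The synthetic Phase I dataset reproduces the single-dose escalation design:
16 male volunteers in groups of 2/2/4/4/4 at 0.2/1/5/15/20 mg/kg (1-h
infusions), demographics inside the published group ranges, batch
sialylation 0.27 (lowest group) or 0.34, rich sampling over six weeks, and
LLOQ 0.667 ug/mL. The synthetic Phase II dataset has 58 patients on weekly
400 mg infusions (nominal 0.5 h; actual start times jittered +/-1 day and
durations 0.4-1 h), per-subject batches with sialylation 0.30-0.57, sparse
trough sampling, and LLOQ 0.1 ug/mL. Measurement error is proportional
lognormal (CV 20%) plus additive noise at 0.3 x LLOQ, truncated at zero;
back-calculated residuals reproduce the configured CV within 10%. Every
concentration is produced by the same simulator the analysis uses - the
generator contains no second PK implementation.

Cohort features that trigger the inclusion rules are assigned
deterministically (disjoint subject subsets in a seeded shuffle): 11
subjects with an on-treatment uric acid level at or above 343 umol/L, 7
with a batch change after the first or second dose, 5 with only four
samples; four further subjects switch batches late, which is permitted.
Applying the rules - any uric acid >= 343 umol/L (the criterion is "below
343"), batch change before three same-batch doses, fewer than five
quantifiable samples - excludes exactly 23 and retains 35, which are then
split 19/16 into training and test sets, stratified by batch sialylation so
every batch with at least two subjects appears in both sets. Uric acid is
generated as a level series only; its pharmacokinetic interaction is
deliberately not modeled (the underlying analysis offered no mechanism and
excluded the affected patients; the generator mimics the exclusion, not a
mechanism). Subjects with a mid-treatment batch switch are simulated under
their first batch; only early switchers are affected materially and they
are excluded by construction.

# Pediatric translation and dose optimization

Pediatric populations (50% male, 50 subjects per one-year-capable band by
default) are simulated on 15 weekly 0.5-h infusions; exposure is the
week-15 AUC. The adult reference is the 58-subject Phase II demographic
population on 400 mg fixed. The fixed dose corresponds to about 5.2 mg/kg
at the cohort mean weight and about 209 mg/m^2 at the cohort mean BSA, and
5.2 mg/kg is the floor of every recommendation. Dose optimization finds the
smallest dose on a 0.2 mg/kg grid (inferred from the recommendation
pattern; configurable) whose population median week-15 AUC matches the
adult median. "Matches" is judged with a 1% equality band: the optimization
criterion is that medians be "the same or slightly higher", and a strict
inequality on medians estimated from 50-subject samples would let ~1%
sampling noise force a full 4% grid step. Because per-subject steady-state
AUC is linear in dose to well under 1%, the search is seeded by linear
scaling from a base simulation at 5.2 mg/kg and verified by direct
simulation at each visited candidate dose.

With the shipped physiology the ladder reproduces the expected pattern:
about 6.0 mg/kg at 1-2 years declining to 5.2 mg/kg above 12 years,
non-increasing in age, with individual band edges occasionally one grid
step from their nominal values depending on the seed - the band medians
carry ~1% sampling noise while adjacent grid steps differ by ~4%.

# Numerical choices

* Stiff integration (lsoda) with rtol 1e-8 and atol 1e-10 x dose;
  infusion starts/stops are exact segment boundaries (the solver is
  restarted, never stepped across a discontinuity).
* Mass balance (administered = in-system + cumulative eliminated) is
  computed for every simulation and verified at 1e-6 relative in the test
  suite; state negativity beyond 1e-9 x dose aborts with an integrity
  error, and sub-tolerance negative excursions are clamped to zero.
* The right-hand side is compiled C (82 states); an independently written
  R implementation of the rate equations serves as a term-by-term oracle in
  the test suite (100 random states, 1e-10 relative agreement).
* Default problem sizes (50 subjects per pediatric band, 58 adults, 20
  recovery replicates on a 20-subject design) were chosen so the pipeline's
  median-based statistics are stable while a full run of the suite remains
  comfortable on a single CPU; all are arguments, not constants.

# Known limitations

* The platform constants of the endosomal machinery are stand-ins at
  literature magnitudes with one anchored degree of freedom; they are not
  the (unpublished) values of the original modeling platform.
* Proportional organ scaling means body composition does not change with
  BMI; an obese virtual patient is a uniformly enlarged lean one. This
  matters mainly for the spread (not the median) of adult exposure.
* Endogenous IgG competition for FcRn, soluble CD95L, Fc-gamma receptor
  binding, blood-brain-barrier penetration and any uric-acid mechanism are
  out of scope, matching the underlying analysis.
* Children below 1 year are rejected rather than extrapolated.
* Batch switches within a subject are simulated under the first batch;
  a time-varying ASGR rate would be needed for late-switch subjects'
  profiles to be exact.
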