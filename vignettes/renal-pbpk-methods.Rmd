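---
title: "Methods: a mechanistic-kidney PBPK simulator for renal drug disposition and crystalluria risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanistic-kidney PBPK simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model structure

`nephrosim` simulates the systemic and intra-tubular disposition of a
renally secreted, poorly permeable drug — shipped parameterisation:
ganciclovir, dosed IV or orally as its prodrug valganciclovir — across
virtual populations spanning healthy adults, old age and chronic kidney
disease (CKD), and evaluates crystalluria risk by comparing simulated
medullary collecting-duct (MCD) concentrations with the drug's aqueous
solubility window.

The systemic model is deliberately standard: a perfusion-rate-limited
whole-body compartment set (blood, liver, kidney, muscle, adipose,
rest-of-body) with linear kinetics throughout. The scientific core is the
permeability-limited mechanistic kidney:

* **Filtration.** Unbound drug enters the first proximal-tubule lumen (PT1)
  at fu·GFR·C_plasma.
* **Secretion.** A lumped basolateral uptake transporter ("OAT1" — the OAT2/
  OAT3 contributions are not separated, since plasma data cannot identify
  them) moves drug into a proximal-tubule cell pool; whole-kidney uptake
  clearance scales as CLint,OAT1 × PTCPGK × kidney weight, where PTCPGK is
  proximal tubule cells per gram kidney. Fast apical MATE efflux then
  delivers the drug into the PT lumens. Because efflux is fast, uptake is the
  rate-determining step and the model's renal clearance is, at quasi-steady
  state, CL_R = fu·(GFR + CLu_uptake) — which makes the calibration
  (below) well-posed and the MATE parameters insensitive.
* **Flow-driven concentration.** Filtrate flows through seven luminal
  compartments (PT1, PT2, PT3, loop of Henle, distal tubule, cortical and
  medullary collecting duct). Water reabsorption shrinks the flow from GFR to
  the urine flow; with negligible passive permeability (ganciclovir) the drug
  cannot follow the water, so its concentration rises roughly as
  GFR/urine-flow along the nephron. The MCD outflow accumulates into urine.

At steady state under a constant input the luminal chain has the closed form
C_i = (q_in,i·C_{i−1} + entry_i)/q_out,i, implemented independently as
`steady_state_luminal_oracle()` and used in the tests as an analytic oracle
for the integrated ODE system (agreement required to 0.1%).

# Parameters, units, defaults

Internal units are mg, L, h; filtrate and urine flows are user-facing in
mL/min (1 mL/min = 0.06 L/h). The shipped drug config
(`inst/extdata/ganciclovir.yaml`) declares a unit per parameter.

| parameter | default | unit | rationale |
|---|---|---|---|
| fu_plasma | 0.98 | – | 1–2% plasma protein binding; rescaled per subject by albumin |
| ka | 0.895 | 1/h | first-order oral absorption of valganciclovir |
| F_abs | 0.60 | – | systemic availability of ganciclovir from the prodrug |
| fe_target | 0.88 | – | fraction excreted unchanged in urine (refined from unity) |
| target_total_cl | 15.0 | L/h | reference IV plasma clearance (literature IV CL ≈ 3.0–3.6 mL/min/kg) |
| CLint,OAT1 | calibrated (≈5.9) | µL/min/10⁶ cells | set by reverse translation |
| CLint,met | calibrated (≈1.9) | L/h | minor hepatic route, not enzyme-specific |
| CLint,MATE | 60 | µL/min/10⁶ cells | fast efflux; insensitive by design |
| passive permeability | 0 | L/h/segment | hydrophilic drug, negligible reabsorption |
| solubility window | 2600–6000 | mg/L | aqueous solubility range; urine pH has little effect for pKa 2.2/9.4 |
| Kp set | liver 0.9, kidney 1.5, muscle 0.8, adipose 0.15, rest 0.88 | – | hydrophilic distribution, Vss ≈ 0.71 L/kg |

The Kp set was chosen once so that steady-state volume of distribution and
the resulting terminal half-lives sit inside their literature ranges
(healthy ≈ 2.6 h; severe renal impairment ≈ 10 h). Exact tissue partitioning
is not the scientific core and only shapes the distribution phase.

**Calibration ("reverse translation").** `calibrate_elimination()` adjusts
CLint,OAT1 and CLint,met so that a simulated IV dose in the reference
subject (healthy male, 30 y, 81 kg, GFR 114 mL/min) achieves
Ae(0–∞)/Dose = fe_target ± 0.005 and total plasma clearance within 2% of
target. Because the model is linear and CL_R = fu·(GFR + CLu_uptake) holds
exactly at quasi-steady state, an analytic initial guess followed by a
damped multiplicative fixed-point update converges in one or two iterations;
the filtration clearance fu·GFR is a hard floor, and targets below it raise
an explicit infeasibility error. Calibration is idempotent to < 0.1%.

# Nephron flows and luminal volumes

Per-segment exit flows default to a canonical water-reabsorption profile
(fractions of GFR: PT1 0.75, PT2 0.55, PT3 0.33, LoH 0.20, DT 0.10,
CCD 0.05), with the MCD outflow always equal to the urine flow; a config can
override the fractions with a transcribed flow table. Two structural choices
deserve comment:

* **Floor on late-segment flows.** In CKD, urine output is preserved while
  GFR falls, so fractional water reabsorption must shrink; scaling all flows
  proportionally to GFR would push the CCD outflow below the urine flow
  (negative water reabsorption). `build_flow_profile()` therefore walks
  upstream from the MCD enforcing each exit flow to be at least 1.2× the
  next one.
* **Luminal volumes.** Volumes are small (PT1–PT3 15/15/10 mL, LoH 15, DT
  10, CCD 3, MCD 1.5 mL) so that residence is flow-dominated. The collecting
  ducts must be small: at 0.1 mL/min urine flow a 5 mL MCD would have a
  50-minute residence time that clips concentration peaks and visibly breaks
  the structural 1/urine-flow scaling of MCD Cmax (the tests check 2× and
  10× at 0.5 and 0.1 mL/min to within 5%).
* **Efflux localisation.** Secreted drug is delivered into the PT lumens
  with weights 0.15/0.50/0.35 (PT1/PT2/PT3), reflecting the S2-predominant
  expression of the basolateral organic-anion transporters rather than a
  uniform split.

Two flow modes exist. By default each subject's upstream flows scale with
their own GFR while the terminal urine flow is sampled independently of GFR
(urine production is preserved in CKD until renal failure). The *fixed-flows*
mode applies one shared profile to all subjects and is required whenever the
urine flow is perturbed; it mirrors the constraint of the commercial platform
this workflow replicates, at the cost of suppressing inter-individual
variability in filtrate flows. In fixed-flows mode the shared GFR also drives
filtration, keeping filtrate flow and filtration consistent.

# Virtual populations

Positive physiological quantities (weight, GFR, PTCPGK, transporter
abundances, kidney-weight multiplier, urine flow) are log-normal; bounded
ones (height, albumin, haematocrit) truncated-normal; ages uniform within
the population's range. GFR is sampled on the BSA-normalised scale — CKD
severity classes are defined per 1.73 m² (moderate 30–60, severe 15–30) —
then de-normalised with the subject's Du Bois BSA. Serum creatinine is a
descriptive output derived from GFR; it drives no kinetics.

The platform's proprietary demographic covariate equations are replaced by
published allometric and age relations, calibrated once against reported
population medians and then frozen: healthy median absolute GFR 114 mL/min
(90% range ≈ 87–166), severe-CKD median 21 mL/min, albumin 46.4 vs
36.7 µmol/L, haematocrit lowered with severity. Checked properties rather
than bit-level reproduction are the contract here.

Three further covariate choices are the package's own:

* **Kidney atrophy in CKD.** Kidney weight scales as (GFR_bsa/100)^0.42
  (capped at 1) in the CKD populations only. The exponent was fixed by
  requiring the whole population model to reproduce the reported clearance
  shifts (≈86% lower median CL_R in severe CKD under the intact-nephron
  scenarios; a further ≈8%/16% under uremic OAT1 inhibition) while keeping
  the default-CKD scenario's exposure drop at or below ~60%. Ageing does
  *not* shrink the kidney in this model — the geriatric population keeps a
  healthy kidney weight, consistent with the reported comparison.
* **Volume overload.** The extracellular-water-rich rest-of-body volume is
  expanded ×1.08 (moderate) and ×1.15 (severe), reflecting the fluid
  retention of advancing CKD; this lengthens the terminal half-life in
  severe disease toward its reported ~10 h.
* **Age decline.** GFR and cardiac output decline linearly beyond age 40
  (−1.125%/y and −0.475%/y of the age-40 value), continuous across the
  healthy/geriatric boundary, calibrated so the geriatric (65–95 y)
  medians fall ≈45% and ≈19% below healthy while the healthy 18–65 median is
  essentially unaffected.

The five CKD secretion scenarios (`ckd_scenario()`) rescale the sampled
PTCPGK, OAT1/MATE abundance or OAT1 activity by severity-specific mean
ratios (e.g. PTCPGK 21/10.2 ×10⁶ cells/g for moderate/severe under the
intact-nephron hypothesis; OAT1 activity 0.73/0.41 under uremic inhibition)
with unchanged CVs (30% cellularity, 60% abundances). Scaling secretion
through cellularity or through abundance with equal products yields
identical whole-kidney intrinsic clearance, and the tests assert equal CL_R
at matched seeds.

The flow-limited CKD preset (`ckd_flow_limited_preset()`) encodes the one
renal-impairment scenario that can be combined with altered urine flow: GFR
fixed at 50 mL/min/1.73 m² (the platform's floor when urine flow is edited)
and tubular secretion reduced 60%, on otherwise healthy demographics —
deliberately nothing else, since the scenario is defined by exactly those
two changes.

# Trial engine and numerics

* **Integrator.** `deSolve::lsoda` (stiff-capable, adaptive) at rtol 1e-8 /
  atol 1e-10 mg; dose and infusion switch events restart integration at the
  event times exactly, and events coinciding with the start time are folded
  into the initial state so the first output point is post-dose. Mass
  balance (administered = body + urine + metabolised) must close to 1e-4 of
  the dose in every simulation; it typically closes to 1e-7.
* **Output grid.** 0.05 h spacing for 8 h after each dose, 0.5 h elsewhere;
  segment Cmax is read off this solver-dense grid to avoid aliasing sharp
  peaks. Negative states beyond 1e-6 of the dose abort with an error; smaller
  solver noise is clamped to zero.
* **Multi-dose fast path.** The system is linear and time-invariant, so the
  trial engine computes repeated-dose profiles by exact superposition of a
  single-dose solve (verified against event-based multi-dose integration to
  0.2%). This makes 21-day BID simulations of 200-subject populations a
  matter of seconds.
* **NCA.** Trapezoid AUC on the dense grid; terminal slope from a log-linear
  fit over the last points of a ~1 h down-sampled terminal series, accepted
  at r² ≥ 0.95 (window widened once, then flagged `NA` — never guessed).
  CL/F for the oral route uses the nominal prodrug dose; fe is referenced to
  the systemically available amount.
* **Determinism.** Every stochastic step derives its seed from the run seed
  (per-trial sub-seeds via a fixed linear-congruential map), so a seed fixes
  every downstream number; trial replicates are stable under reordering.
* **Percent-change summaries.** Accumulation and between-population shifts
  are ratios of medians (median last-dose MCD Cmax over median first-dose
  MCD Cmax, etc.); with these population sizes they agree closely with
  medians of per-subject ratios.

Problem sizes used in the shipped tests and the scenario script: 100–200
subjects per scenario for trial medians, 1000 for population-distribution
summaries, 24 subjects for parameter-recovery benchmarks. These match the
design sizes of the scenarios being reproduced (hypothetical scenarios use
≥200 virtual subjects; distribution analyses 1000).

# Synthetic observed data

`generate_observed()` emulates the *structure* of sparse clinical PK data —
per-subject plasma samples at nominal times with multiplicative log-normal
residual error (default 20%), LLOQ censoring (default 0.05 mg/L), optional
cumulative urine collections, and per-subject renal-function covariates — in
the conventional pharmacometric CSV layout (ID/TIME/DV/AMT/EVID/MDV/CENS).
It does not emulate real-data features such as dropout, dosing-history
errors, assay batch effects, between-occasion variability, or model
misspecification; parameter-recovery results on these datasets therefore
demonstrate identifiability under the generating model, not robustness to
real-world messiness.

`recover_parameters()` refits selected drug parameters (default CLint,OAT1
and CLint,met) by Nelder-Mead least squares on log concentrations and log
urine amounts, using the package's own simulation as the structural model.
The urine records carry the information that splits the large renal from the
small metabolic route: with plasma data alone the split is a ridge in the
objective and the metabolic component is weakly identified — a property the
tests assert directly. At 20% residual error the limiting quantity is
CLint,met, whose share of total clearance is only ~12%; the recovery
benchmark (median relative error ≤ 15% at 24 rich profiles) reflects that
information limit.

# Limitations

* Tissue partitioning is a minimal lumped Kp set; the model is not intended
  for tissue-exposure questions outside the kidney lumen.
* The secretion model is operational: one lumped uptake transporter, no
  OAT1/OAT2/OAT3 delineation, no transporter saturation (linear kinetics
  throughout, so superposition holds by construction).
* Crystalluria is assessed as concentration-vs-solubility-window only; no
  nucleation/precipitation kinetics, and aqueous solubility stands in for
  urine solubility.
* CKD populations are discretely specified severity classes; pooling them
  produces multimodal parameter distributions with empty bands (the
  diagnostics flag these gaps) rather than a continuous disease trajectory.
* The prodrug is reduced to a first-order absorption with fixed
  availability; absorption-phase nonlinearities (transporter-mediated
  uptake, food effects) are out of scope.
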