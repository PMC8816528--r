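## Shared fixtures, built once per test run.

## calibrated ganciclovir parameter set (reverse-translated against the
## reference healthy subject)
gcv <- ganciclovir_parameters()

## uncalibrated copy for tests that exercise the calibration itself
gcv_raw <- ganciclovir_parameters(calibrated = FALSE)

oral_900 <- dose_regimen("oral", 900)
oral_900_bid <- function(days = 21) {
  dose_regimen("oral", 900, interval = 12, n_doses = 2L * days)
}

## Degenerate one-compartment configuration: a subject whose only elimination
## route is glomerular filtration with fu = 1, V_central = 10 L and
## fu*GFR = 1 L/h, and negligible tissue exchange. The closed-form solution
## of a 100 mg IV bolus is C(t) = 10 * exp(-0.1 t).
one_compartment_subject <- function(v = 10, cl = 1) {
  s <- reference_subject()
  s$tissue_volumes <- list(blood = v, liver = 1e-6, muscle = 1e-6,
                           adipose = 1e-6, rest = 1e-6, kidney = 1e-6)
  s$tissue_flows <- list(liver = 1e-7, kidney = 1e-7, muscle = 1e-7,
                         adipose = 1e-7, rest = 1e-7)
  s$gfr <- cl / 0.06   # mL/min so that fu * GFR = cl L/h
  s$hsa <- 46.4
  s$urine_flow <- 0.5
  s
}

one_compartment_drug <- function() {
  drug_parameters(molecular_weight = 250, fu_plasma = 1,
                  ka = 1, f_abs = 1, clint_met = 0, clint_oat1 = 0,
                  clint_mate = 0, fe_target = 1,
                  solubility_low = 2600, solubility_high = 6000)
}

## spec with all inter-individual variability switched off: every subject is
## the same 45-year-old male
degenerate_spec <- function(base = "healthy") {
  population_spec(base, overrides = list(
    sex_ratio = 1,
    params = list(
      age = list(dist = "uniform", min = 45, max = 45),
      weight = list(dist = "lognormal", median = c(M = 81, F = 66), cv = 0,
                    trunc = c(40, 140)),
      height = list(dist = "normal", mean = c(M = 178, F = 164),
                    sd = c(M = 0, F = 0), trunc = c(140, 210)),
      gfr_bsa = list(dist = "lognormal", median = 100, cv = 0,
                     trunc = c(0, 200)),
      ptcpgk = list(dist = "lognormal", mean = 60, cv = 0),
      oat1_rel = list(dist = "lognormal", mean = 1, cv = 0),
      mate_rel = list(dist = "lognormal", mean = 1, cv = 0),
      hsa = list(dist = "normal", mean = 46.4, sd = 0, trunc = c(20, 60)),
      haematocrit = list(dist = "normal", mean = 0.44, sd = 0,
                         trunc = c(0.2, 0.6)),
      urine_flow = list(dist = "lognormal", median = 1, cv = 0,
                        trunc = c(0.1, 3)),
      kw_mult = list(dist = "lognormal", median = 1, cv = 0,
                     trunc = c(0.5, 2)))))
}

subject_field <- function(subjects, field) {
  vapply(subjects, `[[`, numeric(1L), field)
}
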