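## Superposition of a single-dose response onto a multi-dose schedule.
## The PBPK system is linear and time-invariant (no saturable terms), so the
## response to n identical doses spaced tau apart is the sum of shifted
## single-dose responses. `time`/`value` is the solver-dense single-dose
## response from t = 0; returns the profile over one interval starting at
## dose index `at_dose` (1-based) on a uniform grid.
superpose_interval <- function(time, value, tau, at_dose, n_doses,
                               dt = 0.05) {
  grid <- seq(0, tau, by = dt)
  total <- numeric(length(grid))
  f <- approxfun(time, value, yleft = 0, yright = 0, rule = 2)
  for (j in seq_len(at_dose)) {       # doses 1..at_dose contribute
    shift <- (at_dose - j) * tau
    total <- total + f(grid + shift)
  }
  list(time = grid + (at_dose - 1) * tau, value = total)
}

## Simulate one subject under a regimen and extract per-dose segment Cmax,
## plasma metrics. Uses exact superposition for multi-dose regimens.
simulate_for_trial <- function(subject, drug, regimen, flows = NULL,
                               dt = 0.05) {
  tau <- regimen$interval
  n <- regimen$n_doses
  if (n == 1L) {
    sim <- simulate_subject(subject, drug, regimen, flows = flows,
                            duration = max(6 * tau, 48))
    met <- nca(sim, regimen)
    cmax_first <- apply(sim$segment_conc, 2L, max)
    return(list(nca = met, plasma_cmax = c(first = met$cmax, last = met$cmax),
                seg_first = cmax_first, seg_last = cmax_first,
                mass_balance_residual = sim$mass_balance_residual,
                administered = sim$administered))
  }
  single <- regimen
  single$n_doses <- 1L
  horizon <- n * tau
  sim <- simulate_subject(subject, drug, single, flows = flows,
                          duration = horizon, grid_fine = dt)
  met <- nca(sim, single)
  first_idx <- sim$time <= tau
  seg_first <- apply(sim$segment_conc[first_idx, , drop = FALSE], 2L, max)
  seg_last <- vapply(NEPHRON_SEGMENTS, function(sg) {
    max(superpose_interval(sim$time, sim$segment_conc[, sg], tau, n, n,
                           dt)$value)
  }, numeric(1L))
  pl_first <- max(sim$plasma_conc[first_idx])
  pl_last <- max(superpose_interval(sim$time, sim$plasma_conc, tau, n, n,
                                    dt)$value)
  list(nca = met, plasma_cmax = c(first = pl_first, last = pl_last),
       seg_first = seg_first, seg_last = seg_last,
       mass_balance_residual = sim$mass_balance_residual,
       administered = sim$administered)
}

#' Run a virtual trial
#'
#' Samples virtual subjects, applies an optional CKD scenario, builds nephron
#' flow profiles, simulates every subject under the regimen, and collects
#' per-subject PK metrics and per-segment luminal Cmax for the first and last
#' dose, plus trial-level percentile summaries. Fully deterministic for a
#' given seed.
#'
#' Flow modes: by default every subject gets flows scaled to their own GFR and
#' urine flow. Supplying `urine_flow` switches to the fixed-flows mode, in
#' which a single filtrate-flow profile (GFR `fixed_gfr`, defaulting to the
#' median sampled GFR) is applied to all subjects — the mode required when the
#' urine flow is perturbed, at the cost of suppressing inter-individual
#' variability in filtrate flows.
#'
#' @param spec a `population_spec`.
#' @param drug a `drug_parameters`.
#' @param regimen a `dose_regimen`.
#' @param scenario optional `ckd_scenario`.
#' @param urine_flow optional fixed urine flow, mL/min (enables fixed-flows
#'   mode).
#' @param fixed_gfr absolute GFR (mL/min) of the shared flow profile in
#'   fixed-flows mode.
#' @param secretion_scale multiplier on transporter-mediated secretion applied
#'   to every subject (used by the flow-limited CKD preset, which reduces GFR
#'   and secretion by 60%).
#' @param n_subjects subjects per trial.
#' @param n_trials number of trial replicates (resampled subject sets with
#'   derived sub-seeds).
#' @param seed integer seed; fixes every downstream number.
#' @param dt output grid spacing, h.
#' @return object of class `trial_result`: `pk` (data.frame of per-subject NCA
#'   metrics), `segment_cmax` (data.frame subject x segment x dose), `subjects`
#'   (data.frame), `summary` (percentiles of key quantities, across subjects
#'   and across trial means), `failures`, plus the run descriptor.
#' @export
run_trial <- function(spec, drug, regimen, scenario = NULL, urine_flow = NULL,
                      fixed_gfr = NULL, secretion_scale = 1,
                      n_subjects = 200L, n_trials = 1L, seed = 1L,
                      dt = 0.05) {
  stopifnot(n_subjects >= 1L, n_trials >= 1L)
  pk_rows <- list(); seg_rows <- list(); subj_rows <- list(); fails <- list()
  for (trial in seq_len(n_trials)) {
    subjects <- sample_population(spec, n_subjects,
                                  derive_seed(seed, trial))
    subjects <- lapply(subjects, apply_ckd_scenario, scenario = scenario)
    if (secretion_scale != 1)
      subjects <- lapply(subjects, function(s) {
        s$oat1_activity_scale <- s$oat1_activity_scale * secretion_scale
        s
      })
    fixed_flows <- NULL
    if (!is.null(urine_flow)) {
      gfr_fix <- fixed_gfr %||%
        median(vapply(subjects, `[[`, numeric(1L), "gfr"))
      fixed_flows <- build_flow_profile(gfr_fix, urine_flow)
    }
    for (i in seq_along(subjects)) {
      s <- subjects[[i]]
      res <- tryCatch(
        simulate_for_trial(s, drug, regimen, flows = fixed_flows, dt = dt),
        error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(trial = trial, subject = i,
                                                  message = conditionMessage(res))
        next
      }
      m <- res$nca
      pk_rows[[length(pk_rows) + 1L]] <- data.frame(
        trial = trial, subject = i, cmax = m$cmax, tmax = m$tmax,
        auc_0_t = m$auc_0_t, auc_0_inf = m$auc_0_inf, cl = m$cl,
        cl_r = m$cl_r, vd = m$vd, t_half = m$t_half, ae_cum = m$ae_cum,
        fe = m$fe, plasma_cmax_first = res$plasma_cmax[["first"]],
        plasma_cmax_last = res$plasma_cmax[["last"]],
        mass_balance_residual = res$mass_balance_residual,
        administered = res$administered)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        trial = trial, subject = i,
        segment = rep(NEPHRON_SEGMENTS, 2L),
        dose = rep(c("first", "last"), each = 7L),
        cmax = c(res$seg_first, res$seg_last))
      subj_rows[[length(subj_rows) + 1L]] <-
        cbind(trial = trial, subject = i, subjects_to_dataframe(list(s)))
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(trial = integer(), subject = integer(), message = character())
  if (nrow(failures) > 0.1 * n_subjects * n_trials)
    stop("more than 10% of subject simulations failed", call. = FALSE)
  pk <- do.call(rbind, pk_rows)
  seg <- do.call(rbind, seg_rows)
  qs <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE, na.rm = TRUE)
  mcd_rows <- seg[seg$segment == "MCD" & seg$dose == "last", ]
  mcd_last <- mcd_rows$cmax
  by_trial <- vapply(split(mcd_rows$cmax, mcd_rows$trial), mean, numeric(1L))
  summary <- list(
    mcd_cmax_last = setNames(qs(mcd_last), c("p5", "median", "p95")),
    trial_means_mcd_cmax_last = setNames(qs(by_trial),
                                         c("p5", "median", "p95")),
    cl_r = setNames(qs(pk$cl_r), c("p5", "median", "p95")),
    cl = setNames(qs(pk$cl), c("p5", "median", "p95")))
  structure(
    list(scenario = list(population = spec$name,
                         scenario = if (is.null(scenario)) "none" else
                           scenario$name,
                         urine_flow = urine_flow, fixed_gfr = fixed_gfr,
                         secretion_scale = secretion_scale, seed = seed,
                         n_subjects = n_subjects, n_trials = n_trials),
         pk = pk, segment_cmax = seg,
         subjects = do.call(rbind, subj_rows), summary = summary,
         failures = failures, regimen = regimen),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$scenario$population, "/", x$scenario$scenario, "\n")
  cat(sprintf("  %d subjects x %d trials; median CL_R %.3g L/h; median MCD Cmax (last dose) %.4g mg/L\n",
              x$scenario$n_subjects, x$scenario$n_trials,
              x$summary$cl_r[["median"]],
              x$summary$mcd_cmax_last[["median"]]))
  invisible(x)
}

#' Median segment Cmax of a trial
#'
#' @param result a `trial_result`.
#' @param segment nephron segment label.
#' @param dose `"first"` or `"last"`.
#' @return median across subjects of the luminal Cmax, mg/L.
#' @export
median_segment_cmax <- function(result, segment = "MCD", dose = "last") {
  seg <- result$segment_cmax
  rows <- seg$segment == segment & seg$dose == dose
  if (!any(rows)) stop("segment not present in result", call. = FALSE)
  median(seg$cmax[rows])
}

#' Accumulation ratio of segment Cmax
#'
#' Per-subject ratio of last-dose to first-dose luminal Cmax in a segment.
#' A drug with a half-life much shorter than the dosing interval has a ratio
#' near 1; renal impairment prolongs the half-life and increases accumulation.
#'
#' @param result a `trial_result` from a multi-dose regimen.
#' @param segment nephron segment label (default `"MCD"`).
#' @return list with `ratios` (per subject) and `median`.
#' @export
accumulation_ratio <- function(result, segment = "MCD") {
  if (result$regimen$n_doses < 2L)
    stop("accumulation ratio requires a multi-dose regimen", call. = FALSE)
  seg <- result$segment_cmax
  first <- seg$cmax[seg$segment == segment & seg$dose == "first"]
  last <- seg$cmax[seg$segment == segment & seg$dose == "last"]
  ratios <- last / first
  list(ratios = ratios, median = median(ratios))
}

#' Percent change of a median metric between two trials
#'
#' `100 * (1 - median_test / median_reference)` for a named metric: any NCA
#' column of the trial PK table (`cl_r`, `cl`, `cmax`, ...) or
#' `"cmax_<segment>"` for a luminal segment Cmax (last dose).
#'
#' @param test_result,reference_result `trial_result` objects from the same
#'   drug/regimen.
#' @param metric metric label.
#' @return percent decrease of the test median relative to the reference
#'   median (negative = increase).
#' @export
clearance_shift <- function(test_result, reference_result, metric = "cl_r") {
  value_of <- function(res) {
    if (grepl("^cmax_", metric)) {
      median_segment_cmax(res, sub("^cmax_", "", metric), dose = "last")
    } else {
      if (!metric %in% names(res$pk))
        stop("metric '", metric, "' absent from trial result", call. = FALSE)
      median(res$pk[[metric]], na.rm = TRUE)
    }
  }
  100 * (1 - value_of(test_result) / value_of(reference_result))
}

#' Flow-limited CKD preset
#'
#' The named scenario combining renal impairment with perturbed urine flow:
#' GFR fixed at 50 mL/min/1.73 m2 (the lowest filtration compatible with an
#' altered urine flow in the platform whose constraint this mode mirrors) and
#' tubular secretion reduced by 60% versus healthy, on otherwise healthy
#' demographics. Returns the arguments to splice into [run_trial()].
#'
#' @param urine_flow urine flow, mL/min.
#' @return list of `run_trial()` arguments.
#' @export
ckd_flow_limited_preset <- function(urine_flow = 0.1) {
  list(spec = population_spec("healthy"), urine_flow = urine_flow,
       fixed_gfr = 50, secretion_scale = 0.4)
}
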