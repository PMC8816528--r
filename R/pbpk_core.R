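#' Dosing regimen
#'
#' @param route `"iv_infusion"` (zero-order input into plasma) or `"oral"`
#'   (first-order absorption of the prodrug dose; systemic availability and
#'   absorption rate come from the drug parameters).
#' @param dose_amount dose per administration, mg (for the oral route this is
#'   the prodrug dose).
#' @param infusion_duration h, IV route only; 0 means bolus.
#' @param interval dosing interval, h (required when `n_doses > 1`).
#' @param n_doses number of administrations.
#' @param start_time time of first dose, h.
#' @return object of class `dose_regimen`.
#' @examples
#' dose_regimen("oral", 900)                      # single 900 mg oral dose
#' dose_regimen("oral", 900, interval = 12, n_doses = 42)  # BID x 21 days
#' @export
dose_regimen <- function(route = c("iv_infusion", "oral"), dose_amount,
                         infusion_duration = 0, interval = 24, n_doses = 1,
                         start_time = 0) {
  route <- match.arg(route)
  check_positive(dose_amount, "dose_amount")
  check_positive(n_doses, "n_doses")
  if (n_doses > 1) check_positive(interval, "interval")
  if (infusion_duration < 0) stop_field("infusion_duration", "must be >= 0")
  structure(list(route = route, dose_amount = dose_amount,
                 infusion_duration = infusion_duration, interval = interval,
                 n_doses = as.integer(n_doses), start_time = start_time),
            class = "dose_regimen")
}

dose_times <- function(regimen) {
  regimen$start_time + regimen$interval * (seq_len(regimen$n_doses) - 1L)
}

## state layout of the whole-body + mechanistic kidney ODE system
.state_names <- c("depot", "central", "liver", "muscle", "adipose", "rest",
                  "kidney_tis", "ptcell", NEPHRON_SEGMENTS, "urine", "metab")

## Assemble solver parameters for one subject. All internal units mg, L, h.
build_ode_params <- function(subject, drug, flows) {
  cl <- kidney_secretion_clearances(subject, drug)
  tis <- c("liver", "muscle", "adipose", "rest", "kidney")
  kp <- unlist(drug$kp[tis])
  list(
    fu = subject_fu(subject, drug),
    ka = drug$ka,
    v_central = subject$tissue_volumes[["blood"]],
    v_tis = unlist(subject$tissue_volumes[tis]),
    q_tis = unlist(subject$tissue_flows[tis]),
    kp_tis = kp,
    clint_met = drug$clint_met,
    cl_up = cl$uptake, cl_eff = cl$efflux, v_cell = cl$v_cell,
    p_perm = drug$passive_perm_clearance,
    gfr_lh = flows$gfr * ML_MIN_TO_L_H,
    q_out_lh = flows$q_out * ML_MIN_TO_L_H,
    v_lum = flows$luminal_volume / 1000,
    inf_start = numeric(0), inf_end = numeric(0), inf_rate = 0)
}

## Shared kidney flux kernel (numeric-vector in/out; also wrapped by the
## exported kidney_fluxes()).
.kidney_rates <- function(cu_plasma, conc_lum, cell, p) {
  filt <- p$gfr_lh * cu_plasma
  upt <- p$cl_up * cu_plasma
  eff <- p$cl_eff * cell / p$v_cell
  pass <- p$p_perm * (cu_plasma - conc_lum)
  inflow <- c(0, p$q_out_lh[-7L] * conc_lum[-7L])
  entry <- c(filt + eff * PT_EFFLUX_WEIGHTS[[1L]],
             eff * PT_EFFLUX_WEIGHTS[[2L]], eff * PT_EFFLUX_WEIGHTS[[3L]],
             0, 0, 0, 0)
  dlum <- inflow - p$q_out_lh * conc_lum + entry + pass
  list(filt = filt, upt = upt, eff = eff, pass = pass, dlum = dlum,
       durine = p$q_out_lh[[7L]] * conc_lum[[7L]])
}

pbpk_rhs <- function(t, y, p) {
  cp <- y[[2L]] / p$v_central
  ct_eq <- y[3:7] / (p$v_tis * p$kp_tis)     # plasma-equivalent tissue conc
  exch <- p$q_tis * (cp - ct_eq)
  metab <- p$clint_met * p$fu * ct_eq[[1L]]  # well-stirred liver
  cu <- p$fu * cp
  conc_lum <- y[9:15] / p$v_lum
  kid <- .kidney_rates(cu, conc_lum, y[[8L]], p)
  infusion <- if (length(p$inf_start))
    p$inf_rate * sum(t >= p$inf_start & t < p$inf_end) else 0
  ddepot <- -p$ka * y[[1L]]
  dcentral <- p$ka * y[[1L]] + infusion - sum(exch) - kid$filt - kid$upt -
    sum(kid$pass)
  dtis <- exch
  dtis[[1L]] <- dtis[[1L]] - metab
  list(c(ddepot, dcentral, dtis, kid$upt - kid$eff, kid$dlum, kid$durine,
         metab))
}

## time grid: fine spacing after each dose, coarse elsewhere
build_time_grid <- function(regimen, duration, fine = 0.05, coarse = 0.5,
                            fine_window = 8) {
  td <- dose_times(regimen)
  pieces <- lapply(td, function(t0)
    seq(t0, min(t0 + fine_window, duration), by = fine))
  grid <- sort(unique(c(0, seq(0, duration, by = coarse), unlist(pieces),
                        td, duration)))
  grid[grid <= duration]
}

#' Simulate one subject
#'
#' Integrates the coupled whole-body and mechanistic-kidney ODE system for a
#' virtual subject under a dosing regimen. All tissues are perfusion-rate
#' limited except the kidney, which carries a permeability-limited proximal
#' tubule cell pool and seven luminal filtrate compartments (PT1-PT3, loop of
#' Henle, distal tubule, cortical and medullary collecting duct); the medullary
#' collecting duct outflow accumulates into urine. Dosing is implemented as
#' integration events (zero-order infusion or first-order absorption input),
#' so the solver is restarted exactly at dose and infusion switch times.
#'
#' @param subject a `virtual_subject`.
#' @param drug a `drug_parameters`.
#' @param regimen a `dose_regimen`.
#' @param flows optional `nephron_flow_profile`; defaults to the profile
#'   implied by the subject's GFR and urine flow (upstream flows scale with
#'   GFR, terminal urine flow is GFR-independent). Pass an explicit profile for
#'   the fixed-flows mode in which all subjects share one set of filtrate
#'   flows; the subject's filtration then also uses the profile's GFR, keeping
#'   filtration and filtrate flow consistent.
#' @param duration simulation end time, h; must cover the last dose.
#' @param grid_fine,grid_coarse output grid spacing (h) near doses / elsewhere.
#' @param rtol,atol solver tolerances (lsoda, stiff-capable, adaptive).
#' @return object of class `simulation_result`: `time` (h), `plasma_conc`
#'   (mg/L), `segment_conc` (time x 7 matrix, mg/L), `urine_cum`,
#'   `liver_metabolized_cum` (mg), `administered` (mg reaching the systemic
#'   model), `mass_balance_residual` (mg), plus the inputs.
#' @export
simulate_subject <- function(subject, drug, regimen, flows = NULL,
                             duration = NULL, grid_fine = 0.05,
                             grid_coarse = 0.5, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(drug, "drug_parameters"), inherits(regimen, "dose_regimen"))
  flows <- flows %||% build_flow_profile(subject$gfr, subject$urine_flow)
  td <- dose_times(regimen)
  duration <- duration %||% (max(td) + 4 * regimen$interval)
  if (duration < max(td))
    stop("duration must cover the last dose time", call. = FALSE)
  p <- build_ode_params(subject, drug, flows)

  if (regimen$route == "oral") {
    amt <- drug$f_abs * regimen$dose_amount
    ev <- data.frame(var = "depot", time = td, value = amt, method = "add")
  } else if (regimen$infusion_duration > 0) {
    p$inf_start <- td
    p$inf_end <- td + regimen$infusion_duration
    p$inf_rate <- regimen$dose_amount / regimen$infusion_duration
    ## zero-add events force solver restarts at the rate discontinuities
    ev <- data.frame(var = "central",
                     time = sort(unique(c(p$inf_start, p$inf_end))),
                     value = 0, method = "add")
  } else {
    ev <- data.frame(var = "central", time = td,
                     value = regimen$dose_amount, method = "add")
  }
  ev <- ev[ev$time <= duration, ]
  times <- sort(unique(c(build_time_grid(regimen, duration, grid_fine,
                                         grid_coarse), ev$time)))
  y0 <- setNames(numeric(length(.state_names)), .state_names)
  ## fold dose events at the very start into the initial state so that the
  ## first output point reflects the post-dose condition
  at_start <- ev$time == times[1L]
  if (any(at_start)) {
    for (i in which(at_start)) y0[[ev$var[i]]] <- y0[[ev$var[i]]] + ev$value[i]
    ev <- ev[!at_start, , drop = FALSE]
  }
  out <- deSolve::lsoda(y0, times, pbpk_rhs, p, events = list(data = ev),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1L] < 0)
    stop(sprintf("ODE solver failed at t = %.3f h", max(out[, "time"])),
         call. = FALSE)
  administered <- if (regimen$route == "oral")
    drug$f_abs * regimen$dose_amount * sum(td <= duration)
  else regimen$dose_amount * sum(td <= duration)
  states <- out[, .state_names, drop = FALSE]
  neg <- min(states)
  if (neg < -1e-6 * max(administered, 1))
    stop("negative state beyond tolerance in ODE solution", call. = FALSE)
  states[states < 0] <- 0
  nfin <- nrow(states)
  residual <- administered - sum(states[nfin, ])
  seg <- sweep(states[, NEPHRON_SEGMENTS, drop = FALSE], 2L,
               flows$luminal_volume / 1000, "/")
  structure(
    list(time = out[, "time"],
         plasma_conc = states[, "central"] / p$v_central,
         segment_conc = seg,
         urine_cum = states[, "urine"],
         liver_metabolized_cum = states[, "metab"],
         administered = administered,
         mass_balance_residual = residual,
         subject = subject, drug = drug, regimen = regimen, flows = flows),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  %d time points over %.1f h; Cmax plasma %.3g mg/L\n",
              length(x$time), max(x$time), max(x$plasma_conc)))
  cat(sprintf("  urine Ae %.4g mg of %.4g mg administered (residual %.2e mg)\n",
              max(x$urine_cum), x$administered, x$mass_balance_residual))
  invisible(x)
}
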