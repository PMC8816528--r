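cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

## Terminal log-linear regression. Uses the last `npt` points of a ~1 h
## down-sampled terminal series; accepted when r-squared >= 0.95, otherwise
## the window is widened once before the phase is flagged unavailable.
terminal_slope <- function(time, conc, t_start, npt = 5L) {
  keep <- time >= t_start & conc > 0
  t <- time[keep]; c0 <- conc[keep]
  if (length(t) < 3L) return(NULL)
  step <- max(1L, floor(length(t) / max(npt, (max(t) - min(t)))))
  idx <- unique(c(seq(1L, length(t), by = step), length(t)))
  t <- t[idx]; c0 <- c0[idx]
  for (n in c(npt, min(length(t), 3L * npt))) {
    if (length(t) < n) next
    ti <- tail(t, n); ci <- tail(c0, n)
    fit <- lm(log(ci) ~ ti)
    lz <- -coef(fit)[[2L]]
    r2 <- summary(fit)$r.squared
    if (lz > 0 && r2 >= 0.95)
      return(list(lambda_z = lz, r2 = r2, n = n))
  }
  NULL
}

#' Noncompartmental analysis of a simulated profile
#'
#' Computes standard NCA metrics from the solver-dense plasma profile of a
#' [simulate_subject()] result: Cmax, Tmax (relative to the preceding dose),
#' AUC0-t by trapezoid, AUC0-inf by log-linear tail extrapolation, CL (or CL/F
#' for the oral route) as nominal dose / AUC0-inf, renal clearance CL_R =
#' Ae(0-t)/AUC0-t, volume of distribution Vd (or Vd/F) = CL/lambda_z, and
#' terminal half-life from log-linear regression. When the tail does not decay
#' log-linearly (r-squared < 0.95), AUC0-inf, CL, Vd and t1/2 are returned as
#' `NA` rather than guessed.
#'
#' @param result a `simulation_result` covering at least one full dosing
#'   interval.
#' @param regimen the `dose_regimen` used (defaults to the one stored in
#'   `result`).
#' @return object of class `pk_metrics` (a named list): `cmax`, `tmax`,
#'   `auc_0_t`, `auc_0_inf`, `cl`, `cl_r`, `vd`, `t_half`, `ae_cum`, `ae_inf`,
#'   `fe` (Ae(0-inf)/nominal dose) and `lambda_z`.
#' @export
nca <- function(result, regimen = NULL) {
  regimen <- regimen %||% result$regimen
  time <- result$time
  conc <- result$plasma_conc
  td <- dose_times(regimen)
  if (max(time) < max(td) + 0.5 * regimen$interval && regimen$n_doses > 1)
    stop("profile does not cover a full dosing interval", call. = FALSE)
  imax <- which.max(conc)
  cmax <- conc[imax]
  prior_dose <- max(td[td <= time[imax]])
  tmax <- time[imax] - prior_dose
  auc_cum <- cumtrapz(time, conc)
  auc_t <- auc_cum[length(auc_cum)]
  ae_cum <- max(result$urine_cum)
  cl_r <- if (auc_t > 0) ae_cum / auc_t else NA_real_

  ts <- terminal_slope(time, conc, t_start = max(td) + tmax)
  nominal <- regimen$dose_amount * regimen$n_doses
  if (is.null(ts)) {
    auc_inf <- cl <- vd <- t_half <- lambda_z <- NA_real_
    ae_inf <- ae_cum
  } else {
    lambda_z <- ts$lambda_z
    c_last <- conc[length(conc)]
    auc_inf <- auc_t + c_last / lambda_z
    cl <- nominal / auc_inf
    vd <- cl / lambda_z
    t_half <- log(2) / lambda_z
    ae_inf <- ae_cum + cl_r * (auc_inf - auc_t)
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_t,
                 auc_0_inf = auc_inf, cl = cl, cl_r = cl_r, vd = vd,
                 t_half = t_half, ae_cum = ae_cum, ae_inf = ae_inf,
                 fe = ae_inf / result$administered, lambda_z = lambda_z,
                 route = regimen$route),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  suffix <- if (x$route == "oral") "/F" else ""
  cat("<pk_metrics>\n")
  cat(sprintf("  Cmax %.4g mg/L at Tmax %.2f h; AUC0-t %.4g, AUC0-inf %.4g mg*h/L\n",
              x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf))
  cat(sprintf("  CL%s %.4g L/h, CL_R %.4g L/h, Vd%s %.4g L, t1/2 %.3g h\n",
              suffix, x$cl, x$cl_r, suffix, x$vd, x$t_half))
  invisible(x)
}
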