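#' Build a nephron filtrate-flow profile
#'
#' Constructs the per-segment filtrate flows of the mechanistic kidney model.
#' Filtrate enters the first proximal segment (PT1) at the glomerular
#' filtration rate and is progressively concentrated by water reabsorption as
#' it moves through PT1-PT3, the loop of Henle (LoH), distal tubule (DT), and
#' the cortical and medullary collecting ducts (CCD, MCD). The flow leaving the
#' MCD is the urine flow. Drug (for a low-permeability compound) stays in the
#' lumen, so falling flow means rising luminal concentration.
#'
#' Intermediate exit flows are `gfr * fraction(segment)`; the MCD exit flow is
#' always the requested urine flow, independent of the upstream fractions.
#'
#' @param gfr glomerular filtration rate, mL/min; this is `q_in` of PT1.
#' @param urine_flow terminal urine flow, mL/min (0.1-1 mL/min covers the
#'   physiologically realistic range explored in the scenario simulations).
#' @param fractions named numeric vector of exit flows as fractions of GFR for
#'   segments PT1..CCD (MCD is set by `urine_flow`). The default is a canonical
#'   renal water-reabsorption profile; a transcribed platform flow table can be
#'   passed to override it.
#' @param volumes named numeric vector of luminal volumes per segment, mL.
#'   Defaults are small, so luminal residence is flow-dominated.
#' @return object of class `nephron_flow_profile` with elements `segments`,
#'   `q_in`, `q_out` (mL/min), `luminal_volume` (mL), `gfr`, `urine_flow`.
#' @examples
#' fp <- build_flow_profile(gfr = 120, urine_flow = 1)
#' fp$q_out[["MCD"]]  # 1 mL/min
#' @export
build_flow_profile <- function(gfr, urine_flow,
                               fractions = default_exit_fractions(),
                               volumes = default_luminal_volumes()) {
  check_positive(gfr, "gfr")
  check_positive(urine_flow, "urine_flow")
  if (urine_flow >= gfr)
    stop("urine_flow (", urine_flow, " mL/min) must be below GFR (", gfr,
         " mL/min)", call. = FALSE)
  upstream <- NEPHRON_SEGMENTS[-7L]
  if (!all(upstream %in% names(fractions)))
    stop("fractions must name segments ", paste(upstream, collapse = ", "),
         call. = FALSE)
  fractions <- fractions[upstream]
  if (any(diff(fractions) > 0))
    stop("segment exit fractions must be non-increasing along the nephron",
         call. = FALSE)
  q_out <- c(gfr * fractions, MCD = urine_flow)
  ## In renal impairment, urine output is preserved while GFR falls, so the
  ## fractional water reabsorption per segment must shrink: enforce a
  ## monotone floor above the urine flow, walking upstream from the MCD.
  for (i in 6:1)
    q_out[[i]] <- max(q_out[[i]], 1.2 * q_out[[i + 1L]])
  if (q_out[["PT1"]] > gfr || urine_flow >= q_out[["CCD"]])
    stop("urine_flow (", urine_flow, " mL/min) is too close to GFR (", gfr,
         " mL/min): water reabsorption cannot be negative", call. = FALSE)
  q_in <- c(PT1 = gfr, q_out[-7L])
  names(q_in) <- NEPHRON_SEGMENTS
  names(q_out) <- NEPHRON_SEGMENTS
  if (!all(NEPHRON_SEGMENTS %in% names(volumes)))
    stop("volumes must name all segments", call. = FALSE)
  volumes <- volumes[NEPHRON_SEGMENTS]
  if (any(volumes <= 0)) stop("luminal volumes must be > 0", call. = FALSE)
  structure(
    list(segments = NEPHRON_SEGMENTS, q_in = q_in, q_out = q_out,
         luminal_volume = volumes, gfr = gfr, urine_flow = urine_flow),
    class = "nephron_flow_profile")
}

#' @rdname build_flow_profile
#' @export
default_exit_fractions <- function() {
  c(PT1 = 0.75, PT2 = 0.55, PT3 = 0.33, LoH = 0.20, DT = 0.10, CCD = 0.05)
}

#' @rdname build_flow_profile
#' @export
default_luminal_volumes <- function() {
  c(PT1 = 15, PT2 = 15, PT3 = 10, LoH = 15, DT = 10, CCD = 3, MCD = 1.5)
}

## Whole-kidney secretion clearances (L/h, unbound-plasma referenced) from the
## per-cell intrinsic clearances. clint_* are uL/min per 1e6 proximal tubule
## cells; ptcpgk is 1e6 cells per g kidney.
kidney_secretion_clearances <- function(subject, drug) {
  scale <- subject$ptcpgk * subject$kidney_weight * 6e-5  # uL/min -> L/h
  list(
    uptake = drug$clint_oat1 * subject$oat1_rel * subject$oat1_activity_scale *
      scale,
    efflux = drug$clint_mate * subject$mate_rel * scale,
    ## PT cell water volume: ~5 pL per cell.
    v_cell = max(subject$ptcpgk * subject$kidney_weight * 5e-6, 1e-4)  # L
  )
}

#' Instantaneous kidney model fluxes
#'
#' Computes the rates (mg/h) of the mechanistic kidney model for a given state:
#' glomerular filtration of unbound drug into the PT1 lumen, transporter-
#' mediated basolateral uptake into the proximal tubule cell pool, apical
#' efflux from cells into the proximal segment lumens (weighted toward the
#' S2/S3 region where the uptake transporters sit), passive exchange, convective transport between segments, and
#' outflow from the MCD into urine. This is the flux kernel used by the ODE
#' right-hand side of [simulate_subject()], exposed so it can be interrogated
#' and tested directly.
#'
#' @param state list with `lumen` (named mg per segment), `cell` (mg in the
#'   proximal tubule cell pool) and `c_plasma` (total plasma concentration,
#'   mg/L).
#' @param subject a `virtual_subject`.
#' @param drug a `drug_parameters`.
#' @param flows a `nephron_flow_profile`.
#' @return list with `filtration`, `uptake`, `efflux` (mg/h), `dlumen` (named
#'   mg/h per segment), `dcell` (mg/h), `durine` (mg/h), and `dplasma_loss`
#'   (mg/h removed from plasma).
#' @export
kidney_fluxes <- function(state, subject, drug, flows) {
  if (any(c(unlist(state$lumen), state$cell) < -1e-9))
    stop("negative kidney state", call. = FALSE)
  p <- build_ode_params(subject, drug, flows)
  conc <- unname(state$lumen[NEPHRON_SEGMENTS]) / p$v_lum
  k <- .kidney_rates(p$fu * state$c_plasma, conc, state$cell, p)
  list(filtration = k$filt, uptake = k$upt, efflux = k$eff,
       dlumen = setNames(k$dlum, NEPHRON_SEGMENTS),
       dcell = k$upt - k$eff, durine = k$durine,
       dplasma_loss = k$filt + k$upt + sum(k$pass))
}

#' Analytic steady-state luminal concentrations
#'
#' Independent closed-form solution of the nephron chain at steady state under
#' constant segment entry rates: `C_i = (q_in_i * C_{i-1} + entry_i) / q_out_i`.
#' Used as an oracle to validate the ODE kidney model: for a constant-rate
#' input the integrated model must converge to these concentrations.
#'
#' @param flows a `nephron_flow_profile`.
#' @param entry_rates named numeric, constant drug entry rate per segment,
#'   mg/h. Missing segments default to zero.
#' @return named numeric of steady-state luminal concentrations, mg/L.
#' @examples
#' fp <- build_flow_profile(120, 1)
#' # all drug entering at PT1 leaves in urine: C_MCD = rate / urine flow
#' steady_state_luminal_oracle(fp, c(PT1 = 60))[["MCD"]]  # 60/0.06 = 1000 mg/L
#' @export
steady_state_luminal_oracle <- function(flows, entry_rates) {
  if (any(flows$q_out <= 0)) stop("zero segment outflow", call. = FALSE)
  entry <- setNames(numeric(7L), NEPHRON_SEGMENTS)
  entry[names(entry_rates)] <- entry_rates
  q_in <- flows$q_in * ML_MIN_TO_L_H
  q_out <- flows$q_out * ML_MIN_TO_L_H
  conc <- numeric(7L)
  prev <- 0
  for (i in seq_along(NEPHRON_SEGMENTS)) {
    inflow <- if (i == 1L) 0 else q_in[[i]] * prev
    conc[i] <- (inflow + entry[[i]]) / q_out[[i]]
    prev <- conc[i]
  }
  setNames(conc, NEPHRON_SEGMENTS)
}
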