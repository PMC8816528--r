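#' Drug parameter set
#'
#' Container for the drug-specific constants of the PBPK model. The shipped
#' parameterisation is ganciclovir dosed either intravenously or orally as its
#' prodrug valganciclovir; the prodrug is handled as complete presystemic
#' hydrolysis, i.e. the oral route delivers ganciclovir into the absorption
#' depot with first-order rate `ka` and systemic availability `f_abs`, with no
#' circulating prodrug species.
#'
#' @param molecular_weight g/mol.
#' @param fu_plasma fraction unbound in plasma (0, 1].
#' @param blood_plasma_ratio blood-to-plasma concentration ratio.
#' @param ka first-order absorption rate constant, 1/h.
#' @param f_abs fraction of an oral prodrug dose reaching the systemic
#'   circulation as parent drug.
#' @param clint_met whole-liver metabolic intrinsic clearance, L/h (not
#'   attributed to a specific enzyme).
#' @param clint_oat1 lumped basolateral uptake transporter intrinsic clearance
#'   ("OAT1"), uL/min per 1e6 proximal tubule cells.
#' @param clint_mate apical efflux (MATE) intrinsic clearance, uL/min per 1e6
#'   proximal tubule cells.
#' @param passive_perm_clearance passive transcellular clearance per nephron
#'   segment, L/h (approximately zero for a poorly permeable drug such as
#'   ganciclovir, hence negligible tubular reabsorption).
#' @param fe_target fraction of the absorbed dose excreted unchanged in urine.
#' @param solubility_low,solubility_high aqueous solubility window, mg/L.
#' @param target_total_cl reference total (IV) plasma clearance used by
#'   [calibrate_elimination()], L/h.
#' @param kp named list/vector of tissue-to-plasma partition coefficients for
#'   `liver`, `kidney`, `muscle`, `adipose`, `rest`.
#' @return object of class `drug_parameters`.
#' @seealso [load_drug_parameters()] to read a config file,
#'   [calibrate_elimination()] for the reverse-translation step.
#' @export
drug_parameters <- function(molecular_weight, fu_plasma, blood_plasma_ratio = 1,
                            ka, f_abs = 1, clint_met, clint_oat1, clint_mate,
                            passive_perm_clearance = 0, fe_target,
                            solubility_low, solubility_high,
                            target_total_cl = NULL,
                            kp = list(liver = 0.9, kidney = 1.5, muscle = 0.8,
                                      adipose = 0.15, rest = 0.88)) {
  check_positive(molecular_weight, "molecular_weight")
  check_positive(fu_plasma, "fu_plasma")
  if (fu_plasma > 1) stop_field("fu_plasma", "must be <= 1")
  check_positive(blood_plasma_ratio, "blood_plasma_ratio")
  check_positive(ka, "ka")
  check_positive(f_abs, "f_abs")
  if (f_abs > 1) stop_field("f_abs", "must be <= 1")
  check_positive(clint_met, "clint_met", strict = FALSE)
  check_positive(clint_oat1, "clint_oat1", strict = FALSE)
  check_positive(clint_mate, "clint_mate", strict = FALSE)
  check_positive(passive_perm_clearance, "passive_perm_clearance",
                 strict = FALSE)
  check_positive(fe_target, "fe_target", strict = FALSE)
  if (fe_target > 1) stop_field("fe_target", "must be <= 1")
  check_positive(solubility_low, "solubility_low")
  check_positive(solubility_high, "solubility_high")
  if (solubility_low >= solubility_high)
    stop_field("solubility_low", "solubility_low must be below solubility_high")
  if (!is.null(target_total_cl)) check_positive(target_total_cl,
                                                "target_total_cl")
  need <- c("liver", "kidney", "muscle", "adipose", "rest")
  if (!all(need %in% names(kp)))
    stop_field("kp", paste("must name", paste(need, collapse = ", ")))
  structure(
    list(molecular_weight = molecular_weight, fu_plasma = fu_plasma,
         blood_plasma_ratio = blood_plasma_ratio, ka = ka, f_abs = f_abs,
         clint_met = clint_met, clint_oat1 = clint_oat1,
         clint_mate = clint_mate,
         passive_perm_clearance = passive_perm_clearance,
         fe_target = fe_target, solubility_low = solubility_low,
         solubility_high = solubility_high,
         target_total_cl = target_total_cl, kp = as.list(kp)[need]),
    class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>\n")
  cat(sprintf("  fu %.3g, ka %.3g 1/h, F_abs %.3g, fe_target %.3g\n",
              x$fu_plasma, x$ka, x$f_abs, x$fe_target))
  cat(sprintf("  CLint,met %.3g L/h; CLint,OAT1 %.3g, CLint,MATE %.3g uL/min/1e6 cells\n",
              x$clint_met, x$clint_oat1, x$clint_mate))
  cat(sprintf("  solubility window %g-%g mg/L\n", x$solubility_low,
              x$solubility_high))
  invisible(x)
}

## unit string -> multiplier into internal units (h, L, mg, and the native
## per-cell clearance unit uL/min/1e6 cells)
.unit_factor <- function(unit, field) {
  factors <- c("1/h" = 1, "1/min" = 60,
               "L/h" = 1, "mL/min" = 0.06, "L/min" = 60,
               "mg/L" = 1, "g/L" = 1000, "ug/mL" = 1,
               "g/mol" = 1, "fraction" = 1, "unitless" = 1,
               "uL/min/10^6 cells" = 1, "uL/min/1e6 cells" = 1)
  if (is.null(unit)) return(1)
  if (!unit %in% names(factors))
    stop_field(field, paste("unknown unit", unit))
  factors[[unit]]
}

#' Load drug parameters from a YAML/JSON config
#'
#' Reads a drug configuration in which every scalar parameter is either a bare
#' number (assumed already in internal units: mg, L, h) or a `{value, unit}`
#' pair, converts to internal units and validates via [drug_parameters()].
#' The packaged ganciclovir file is at
#' `system.file("extdata", "ganciclovir.yaml", package = "nephrosim")`.
#'
#' @param config_path path to a `.yaml`/`.yml`/`.json` file.
#' @return a `drug_parameters` object.
#' @export
load_drug_parameters <- function(config_path) {
  if (!file.exists(config_path))
    stop("drug config not found: ", config_path, call. = FALSE)
  raw <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  required <- c("molecular_weight", "fu_plasma", "ka", "clint_met",
                "clint_oat1", "clint_mate", "fe_target", "solubility_low",
                "solubility_high")
  for (key in required)
    if (is.null(raw[[key]]))
      stop_field(key, "missing from drug config")
  take <- function(key, default = NULL) {
    x <- raw[[key]]
    if (is.null(x)) return(default)
    if (is.list(x)) {
      if (is.null(x$value)) stop_field(key, "entry must have a 'value'")
      as.numeric(x$value) * .unit_factor(x$unit, key)
    } else as.numeric(x)
  }
  drug_parameters(
    molecular_weight = take("molecular_weight"),
    fu_plasma = take("fu_plasma"),
    blood_plasma_ratio = take("blood_plasma_ratio", 1),
    ka = take("ka"),
    f_abs = take("f_abs", 1),
    clint_met = take("clint_met"),
    clint_oat1 = take("clint_oat1"),
    clint_mate = take("clint_mate"),
    passive_perm_clearance = take("passive_perm_clearance", 0),
    fe_target = take("fe_target"),
    solubility_low = take("solubility_low"),
    solubility_high = take("solubility_high"),
    target_total_cl = take("target_total_cl"),
    kp = if (!is.null(raw$kp)) raw$kp else
      list(liver = 0.9, kidney = 1.5, muscle = 0.8, adipose = 0.15,
           rest = 0.88))
}

#' Packaged ganciclovir parameter set
#'
#' Convenience loader for the shipped ganciclovir/valganciclovir config.
#'
#' @param calibrated if `TRUE` (default), run [calibrate_elimination()] against
#'   the reference healthy subject so that the simulated fraction excreted in
#'   urine and total clearance match `fe_target` and `target_total_cl`.
#' @return a `drug_parameters` object.
#' @export
ganciclovir_parameters <- function(calibrated = TRUE) {
  drug <- load_drug_parameters(
    system.file("extdata", "ganciclovir.yaml", package = "nephrosim"))
  if (calibrated)
    drug <- calibrate_elimination(drug, reference_subject(),
                                  target_total_cl = drug$target_total_cl)
  drug
}

#' Calibrate the elimination split by reverse translation
#'
#' Splits total plasma clearance into renal (filtration + transporter-mediated
#' secretion) and hepatic metabolic components so that a simulated IV dose in a
#' reference subject reproduces (i) the target fraction excreted unchanged in
#' urine, `Ae(0-Inf)/Dose = fe_target` within 0.005, and (ii) the target total
#' plasma clearance within 2%. The two scalars adjusted are `clint_oat1`
#' (secretion) and `clint_met` (metabolism); the filtration clearance
#' `fu * GFR` is fixed by physiology and acts as a floor on achievable renal
#' clearance.
#'
#' @param drug a `drug_parameters` object (starting values).
#' @param reference_subject subject in which the calibration is performed;
#'   defaults to the population-median healthy male (30 y, 81 kg, GFR 114
#'   mL/min).
#' @param iv_regimen IV regimen used for the calibration simulations; default
#'   400 mg infused over 1 h.
#' @param target_total_cl target total plasma clearance, L/h; defaults to
#'   `drug$target_total_cl`.
#' @param max_iter maximum fixed-point iterations.
#' @return a `drug_parameters` object with calibrated `clint_oat1`, `clint_met`
#'   and attributes `calibration` (achieved fe and CL).
#' @export
calibrate_elimination <- function(drug, reference_subject = NULL,
                                  iv_regimen = NULL, target_total_cl = NULL,
                                  max_iter = 8L) {
  subject <- reference_subject %||% nephrosim::reference_subject()
  regimen <- iv_regimen %||% dose_regimen(route = "iv_infusion",
                                          dose_amount = 400,
                                          infusion_duration = 1)
  target_cl <- target_total_cl %||% drug$target_total_cl
  check_positive(target_cl, "target_total_cl")
  fe <- drug$fe_target
  if (fe <= 0 || fe > 1)
    stop("fe_target must be in (0, 1] for calibration", call. = FALSE)
  fu <- subject_fu(subject, drug)
  cl_filt <- fu * subject$gfr * ML_MIN_TO_L_H
  cl_r_target <- fe * target_cl
  if (cl_filt > cl_r_target)
    stop(sprintf(paste0("infeasible calibration: filtration clearance floor ",
                        "fu*GFR = %.2f L/h exceeds the renal clearance target ",
                        "fe*CL = %.2f L/h"), cl_filt, cl_r_target),
         call. = FALSE)
  cl_nr_target <- (1 - fe) * target_cl
  q_h <- subject$tissue_flows[["liver"]]
  if (cl_nr_target >= q_h)
    stop("infeasible calibration: non-renal clearance target exceeds liver blood flow",
         call. = FALSE)

  scale <- subject$ptcpgk * subject$kidney_weight * 6e-5  # uL/min -> L/h
  ## analytic initial guess: CL_R = fu*(GFR + CLu_up); well-stirred liver
  clu_up <- (cl_r_target - cl_filt) / fu
  drug$clint_oat1 <- clu_up / (scale * subject$oat1_rel *
                                 subject$oat1_activity_scale)
  drug$clint_met <- if (cl_nr_target <= 0) 0 else
    q_h * cl_nr_target / (q_h - cl_nr_target) / fu

  achieved <- NULL
  for (iter in seq_len(max_iter)) {
    sim <- simulate_subject(subject, drug, regimen,
                            duration = 96, grid_fine = 0.05)
    met <- nca(sim, regimen)
    achieved <- list(fe = met$fe, cl = met$cl, cl_r = met$cl_r)
    ok_fe <- abs(achieved$fe - fe) <= 0.0025
    ok_cl <- abs(achieved$cl / target_cl - 1) <= 0.01
    if (ok_fe && ok_cl) break
    ## multiplicative update on the secretion component and on CLint,met
    if (cl_nr_target <= 0) {
      drug$clint_met <- 0
    } else {
      cl_nr_ach <- max(achieved$cl * (1 - achieved$fe), 1e-9)
      drug$clint_met <- drug$clint_met * cl_nr_target / cl_nr_ach *
        (q_h - cl_nr_ach) / (q_h - cl_nr_target)
    }
    sec_ach <- max(achieved$cl * achieved$fe - cl_filt, 1e-9)
    sec_tgt <- max(cl_r_target - cl_filt, 0)
    if (drug$clint_oat1 > 0 && sec_tgt > 0)
      drug$clint_oat1 <- drug$clint_oat1 * sec_tgt / sec_ach
  }
  attr(drug, "calibration") <- c(achieved, list(iterations = iter,
                                                target_cl = target_cl))
  drug
}
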