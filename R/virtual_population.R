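## Du Bois body surface area, m^2
du_bois_bsa <- function(weight, height) 0.007184 * weight^0.425 * height^0.725

## Age-decline multipliers shared by all populations (continuous across the
## young-adult / geriatric boundary). Calibrated so that the geriatric
## (65-95 y) population medians fall ~45% (GFR) and ~19% (cardiac output)
## below the healthy-adult medians while leaving the healthy 18-65 y median
## essentially unchanged.
age_gfr_factor <- function(age) pmax(0.25, 1 - 0.01125 * pmax(age - 40, 0))
age_co_factor <- function(age) pmax(0.5, 1 - 0.00475 * pmax(age - 40, 0))

## fraction unbound at the subject's albumin level; drug fu is defined at the
## healthy reference HSA of 46.4 umol/L
subject_fu <- function(subject, drug) {
  hsa <- subject$hsa %||% 46.4
  1 / (1 + (1 / drug$fu_plasma - 1) * hsa / 46.4)
}

.dist_draw <- function(d, sex) {
  pick <- function(x) if (length(x) == 2L && !is.null(names(x)))
    unname(x[[sex]]) else unname(x[[1L]])
  lo <- if (!is.null(d$trunc)) d$trunc[[1L]] else -Inf
  hi <- if (!is.null(d$trunc)) d$trunc[[2L]] else Inf
  for (i in seq_len(1000L)) {
    x <- switch(d$dist,
      uniform = runif(1L, d$min, d$max),
      normal = rnorm(1L, pick(d$mean), pick(d$sd)),
      lognormal = {
        cv <- d$cv
        if (!is.null(d$median)) {
          sdlog <- sqrt(log(1 + cv^2))
          rlnorm(1L, log(pick(d$median)), sdlog)
        } else {
          sdlog <- sqrt(log(1 + cv^2))
          rlnorm(1L, log(pick(d$mean)) - sdlog^2 / 2, sdlog)
        }
      },
      stop("unknown distribution family ", d$dist, call. = FALSE))
    if (x >= lo && x <= hi) return(x)
  }
  stop("unsatisfiable truncation bounds for a population parameter",
       call. = FALSE)
}

#' Virtual population specifications
#'
#' Returns the sampling specification for one of the built-in virtual
#' populations:
#' \describe{
#'   \item{`healthy`}{healthy volunteers, 18-65 y, GFR > 90 mL/min/1.73 m2.}
#'   \item{`neurcaucasian`}{North-European-Caucasian adults, 18-95 y (the base
#'     population from which the geriatric population is drawn).}
#'   \item{`geriatric`}{65-95 y; age-related decline in GFR and cardiac output,
#'     no change in proximal tubule cellularity, transporter abundance, kidney
#'     weight or urine flow.}
#'   \item{`ckd_moderate`}{moderate chronic kidney disease, GFR 30-60
#'     mL/min/1.73 m2; lowered albumin and haematocrit, kidney atrophy.}
#'   \item{`ckd_severe`}{severe CKD, GFR 15-30 mL/min/1.73 m2.}
#' }
#' Positive physiological quantities are sampled log-normally, bounded
#' quantities truncated-normally; GFR is sampled on the per-1.73 m2 scale
#' (severity classes are defined per BSA) and de-normalised with the subject's
#' Du Bois BSA. Distribution locations were calibrated once against reported
#' population medians and 90% ranges (healthy GFR 114 mL/min, severe CKD
#' 21 mL/min, HSA 46.4 vs 36.7 umol/L) and are fixed.
#'
#' @param name one of `"healthy"`, `"neurcaucasian"`, `"geriatric"`,
#'   `"ckd_moderate"`, `"ckd_severe"`.
#' @param overrides named list merged over the preset (advanced use).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name = c("healthy", "neurcaucasian", "geriatric",
                                     "ckd_moderate", "ckd_severe"),
                            overrides = NULL) {
  name <- match.arg(name)
  base <- list(
    name = name,
    sex_ratio = 0.5,
    age_gfr_decline = TRUE,
    kidney_atrophy = FALSE,
    ecw_expansion = 1,
    severity = NA_character_,
    params = list(
      age = list(dist = "uniform", min = 18, max = 65),
      weight = list(dist = "lognormal", median = c(M = 81, F = 66), cv = 0.15,
                    trunc = c(42, 135)),
      height = list(dist = "normal", mean = c(M = 178, F = 164),
                    sd = c(M = 7, F = 6.5), trunc = c(145, 205)),
      gfr_bsa = list(dist = "lognormal", median = 112, cv = 0.155,
                     trunc = c(90, 170)),
      ptcpgk = list(dist = "lognormal", mean = 60, cv = 0.30),
      oat1_rel = list(dist = "lognormal", mean = 1, cv = 0.60),
      mate_rel = list(dist = "lognormal", mean = 1, cv = 0.60),
      hsa = list(dist = "normal", mean = 46.4, sd = 4.8, trunc = c(25, 62)),
      haematocrit = list(dist = "normal", mean = c(M = 0.445, F = 0.405),
                         sd = 0.028, trunc = c(0.25, 0.56)),
      urine_flow = list(dist = "lognormal", median = 1, cv = 0.20,
                        trunc = c(0.4, 2.5)),
      kw_mult = list(dist = "lognormal", median = 1, cv = 0.12,
                     trunc = c(0.6, 1.6))))
  spec <- switch(name,
    healthy = base,
    neurcaucasian = modifyList(base, list(
      params = list(age = list(dist = "uniform", min = 18, max = 95)))),
    geriatric = modifyList(base, list(
      params = list(age = list(dist = "uniform", min = 65, max = 95)))),
    ckd_moderate = modifyList(base, list(
      severity = "moderate", age_gfr_decline = FALSE, kidney_atrophy = TRUE,
      ecw_expansion = 1.08,
      params = list(
        age = list(dist = "uniform", min = 35, max = 85),
        gfr_bsa = list(dist = "lognormal", median = 44, cv = 0.15,
                       trunc = c(30, 59.99)),
        hsa = list(dist = "normal", mean = 41.5, sd = 4.6, trunc = c(20, 60)),
        haematocrit = list(dist = "normal", mean = 0.375, sd = 0.035,
                           trunc = c(0.2, 0.52))))),
    ckd_severe = modifyList(base, list(
      severity = "severe", age_gfr_decline = FALSE, kidney_atrophy = TRUE,
      ecw_expansion = 1.15,
      params = list(
        age = list(dist = "uniform", min = 35, max = 85),
        gfr_bsa = list(dist = "lognormal", median = 19.7, cv = 0.14,
                       trunc = c(15, 29.99)),
        hsa = list(dist = "normal", mean = 36.7, sd = 4.6, trunc = c(18, 55)),
        haematocrit = list(dist = "normal", mean = 0.33, sd = 0.035,
                           trunc = c(0.18, 0.48))))))
  if (!is.null(overrides)) spec <- modifyList(spec, overrides)
  ## spec-level GFR band (per 1.73 m2) used for the severity partition
  spec$gfr_range_bsa <- spec$params$gfr_bsa$trunc %||% c(90, Inf)
  structure(spec, class = "population_spec")
}

## Deterministic construction of a subject from sampled primitives.
make_subject <- function(age, sex, weight, height, gfr_bsa, ptcpgk, oat1_rel,
                         mate_rel, hsa, haematocrit, urine_flow, kw_mult = 1,
                         kidney_atrophy = FALSE, oat1_activity_scale = 1,
                         scr_mult = 1, ecw_expansion = 1,
                         population = NA_character_) {
  bsa <- du_bois_bsa(weight, height)
  gfr <- gfr_bsa * bsa / 1.73
  atrophy <- if (kidney_atrophy) pmin(1, gfr_bsa / 100)^0.42 else 1
  kidney_weight <- 3.83 * weight * atrophy * kw_mult  # g, both kidneys
  co <- 12.43 * weight^0.75 * ifelse(sex == "F", 0.92, 1) * age_co_factor(age)
  frac_adipose <- if (sex == "F") 0.27 else 0.19
  frac_muscle <- if (sex == "F") 0.30 else 0.36
  tissue_volumes <- list(
    blood = 0.067 * weight, liver = 0.022 * weight,
    muscle = frac_muscle * weight, adipose = frac_adipose * weight,
    ## rest is the extracellular-water-rich lumped tissue; chronic kidney
    ## disease brings volume overload, so it expands with disease severity
    rest = 0.28 * weight * ecw_expansion, kidney = kidney_weight / 1000)
  tissue_flows <- list(liver = 0.24 * co, kidney = 0.19 * co,
                       muscle = 0.17 * co, adipose = 0.05 * co,
                       rest = 0.35 * co)
  scr <- 0.9 * (100 / gfr_bsa) * scr_mult  # mg/dL, descriptive only
  structure(
    list(age = age, sex = sex, body_weight = weight, height = height,
         body_surface_area = bsa, cardiac_output = co,
         tissue_volumes = tissue_volumes, tissue_flows = tissue_flows,
         kidney_weight = kidney_weight, gfr = gfr, gfr_bsa = gfr_bsa,
         ptcpgk = ptcpgk, oat1_rel = oat1_rel, mate_rel = mate_rel,
         oat1_activity_scale = oat1_activity_scale, hsa = hsa,
         haematocrit = haematocrit, serum_creatinine = scr,
         urine_flow = urine_flow, population = population),
    class = "virtual_subject")
}

#' Reference healthy subject
#'
#' The population-median healthy male used for model calibration: 30 y, 81 kg,
#' 178 cm, absolute GFR 114 mL/min, median proximal tubule cellularity and
#' transporter abundances, urine flow 1 mL/min.
#' @return a `virtual_subject`.
#' @export
reference_subject <- function() {
  bsa <- du_bois_bsa(81, 178)
  make_subject(age = 30, sex = "M", weight = 81, height = 178,
               gfr_bsa = 114 * 1.73 / bsa, ptcpgk = 60, oat1_rel = 1,
               mate_rel = 1, hsa = 46.4, haematocrit = 0.445, urine_flow = 1,
               population = "reference")
}

## draw the primitive quantities for one subject (assumes RNG state set)
.draw_subject <- function(spec) {
  p <- spec$params
  sex <- if (runif(1L) < spec$sex_ratio) "M" else "F"
  age <- .dist_draw(p$age, sex)
  weight <- .dist_draw(p$weight, sex)
  height <- .dist_draw(p$height, sex)
  gfr_bsa <- .dist_draw(p$gfr_bsa, sex)
  if (isTRUE(spec$age_gfr_decline)) gfr_bsa <- gfr_bsa * age_gfr_factor(age)
  make_subject(
    age = age, sex = sex, weight = weight, height = height, gfr_bsa = gfr_bsa,
    ptcpgk = .dist_draw(p$ptcpgk, sex),
    oat1_rel = .dist_draw(p$oat1_rel, sex),
    mate_rel = .dist_draw(p$mate_rel, sex),
    hsa = .dist_draw(p$hsa, sex),
    haematocrit = .dist_draw(p$haematocrit, sex),
    urine_flow = .dist_draw(p$urine_flow, sex),
    kw_mult = .dist_draw(p$kw_mult, sex),
    kidney_atrophy = isTRUE(spec$kidney_atrophy),
    scr_mult = rlnorm(1L, 0, 0.15),
    ecw_expansion = spec$ecw_expansion %||% 1,
    population = spec$name)
}

#' Sample virtual subjects
#'
#' `sample_subject()` draws a single subject deterministically from a seed;
#' `sample_population()` draws `n` subjects. Sampling is rejection-based
#' against the spec's truncation bounds, and all derived quantities (BSA,
#' absolute GFR, kidney weight, cardiac output, tissue volumes and flows)
#' follow the spec's covariate rules.
#'
#' @param spec a `population_spec`.
#' @param rng_seed,seed integer seed; the same spec and seed always reproduce
#'   the same subject(s).
#' @param n number of subjects.
#' @return a `virtual_subject`, or a list of them (class
#'   `virtual_population`).
#' @export
sample_subject <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(rng_seed)
  .draw_subject(spec)
}

#' @rdname sample_subject
#' @export
sample_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  set.seed(seed)
  structure(lapply(seq_len(n), function(i) .draw_subject(spec)),
            class = "virtual_population")
}

#' Chronic kidney disease scenario
#'
#' The five CKD hypotheses about the decline of tubular secretion, applied on
#' top of a CKD population's demographic/renal changes. Mean multipliers
#' relative to the healthy means (PTCPGK 60 x 1e6 cells/g; relative transporter
#' abundances 1):
#' \tabular{lccc}{
#'   scenario \tab PTCPGK (mod/sev) \tab OAT1 (mod/sev) \tab other \cr
#'   `default` \tab 60 / 60 \tab 1 / 1 \tab - \cr
#'   `inh_ptcpgk` \tab 21 / 10.2 \tab 1 / 1 \tab - \cr
#'   `inh_oat1` \tab 60 / 60 \tab 0.35 / 0.17 \tab - \cr
#'   `inh_oat1_mate` \tab 60 / 60 \tab 0.35 / 0.17 \tab MATE 0.35 / 0.17 \cr
#'   `inh_ptcpgk_uremic` \tab 21 / 10.2 \tab activity 0.73 / 0.41 \tab - \cr
#' }
#' Coefficients of variation are unchanged (30% cellularity, 60% abundances),
#' so applying a scenario to a sampled subject multiplies the sampled value by
#' the mean ratio.
#'
#' @param name scenario name (see table).
#' @param severity `"moderate"` or `"severe"`.
#' @return object of class `ckd_scenario` with the multipliers.
#' @export
ckd_scenario <- function(name = c("default", "inh_ptcpgk", "inh_oat1",
                                  "inh_oat1_mate", "inh_ptcpgk_uremic"),
                         severity = c("moderate", "severe")) {
  name <- match.arg(name)
  severity <- match.arg(severity)
  sev <- severity == "severe"
  ptc_inh <- (if (sev) 10.2 else 21) / 60
  oat_inh <- if (sev) 0.17 else 0.35
  f <- switch(name,
    default = list(ptcpgk = 1, oat1 = 1, mate = 1, activity = 1),
    inh_ptcpgk = list(ptcpgk = ptc_inh, oat1 = 1, mate = 1, activity = 1),
    inh_oat1 = list(ptcpgk = 1, oat1 = oat_inh, mate = 1, activity = 1),
    inh_oat1_mate = list(ptcpgk = 1, oat1 = oat_inh, mate = oat_inh,
                         activity = 1),
    inh_ptcpgk_uremic = list(ptcpgk = ptc_inh, oat1 = 1, mate = 1,
                             activity = if (sev) 0.41 else 0.73))
  structure(c(list(name = name, severity = severity), f),
            class = "ckd_scenario")
}

#' Apply a CKD scenario to a sampled subject
#'
#' Multiplies the subject's proximal tubule cellularity, transporter
#' abundances and OAT1 activity by the scenario's mean ratios.
#'
#' @param subject a `virtual_subject` drawn from the matching severity
#'   population.
#' @param scenario a `ckd_scenario` (or `NULL`, returned unchanged).
#' @return the modified `virtual_subject`.
#' @export
apply_ckd_scenario <- function(subject, scenario) {
  if (is.null(scenario)) return(subject)
  if (!inherits(scenario, "ckd_scenario"))
    stop("unknown scenario; use ckd_scenario()", call. = FALSE)
  subject$ptcpgk <- subject$ptcpgk * scenario$ptcpgk
  subject$oat1_rel <- subject$oat1_rel * scenario$oat1
  subject$mate_rel <- subject$mate_rel * scenario$mate
  subject$oat1_activity_scale <- subject$oat1_activity_scale *
    scenario$activity
  subject$scenario <- scenario$name
  subject
}

#' Age-decline covariates
#'
#' Re-derives the age-dependent quantities (GFR and cardiac output and the
#' flows that scale with them) of a subject at a new age, using the same
#' continuous decline functions applied during sampling. Proximal tubule
#' cellularity, transporter abundances, kidney weight and urine flow are
#' unchanged: ageing lowers filtration and perfusion, not the secretory
#' machinery per cell.
#'
#' @param age new age in years, within 65-95.
#' @param base the `virtual_subject` to re-age.
#' @return a `virtual_subject` at the new age.
#' @export
geriatric_covariates <- function(age, base) {
  if (age < 65 || age > 95)
    stop("age must be within 65-95 years", call. = FALSE)
  gfr_bsa <- base$gfr_bsa / age_gfr_factor(base$age) * age_gfr_factor(age)
  out <- make_subject(
    age = age, sex = base$sex, weight = base$body_weight,
    height = base$height, gfr_bsa = gfr_bsa, ptcpgk = base$ptcpgk,
    oat1_rel = base$oat1_rel, mate_rel = base$mate_rel, hsa = base$hsa,
    haematocrit = base$haematocrit, urine_flow = base$urine_flow,
    kidney_atrophy = FALSE,
    oat1_activity_scale = base$oat1_activity_scale,
    population = base$population)
  out$kidney_weight <- base$kidney_weight
  out$tissue_volumes$kidney <- base$kidney_weight / 1000
  out$serum_creatinine <- 0.9 * (100 / gfr_bsa)
  out
}

#' Flatten subjects to a data frame
#'
#' @param subjects a `virtual_population` or list of `virtual_subject`s.
#' @return data.frame with one row per subject.
#' @export
subjects_to_dataframe <- function(subjects) {
  rows <- lapply(subjects, function(s) data.frame(
    population = s$population, age = s$age, sex = s$sex,
    weight = s$body_weight, bsa = s$body_surface_area,
    kidney_weight = s$kidney_weight, gfr = s$gfr, gfr_bsa = s$gfr_bsa,
    ptcpgk = s$ptcpgk, oat1_rel = s$oat1_rel, mate_rel = s$mate_rel,
    oat1_activity_scale = s$oat1_activity_scale,
    oat1_whole_kidney = s$ptcpgk * s$oat1_rel * s$oat1_activity_scale *
      s$kidney_weight,
    haematocrit = s$haematocrit, hsa = s$hsa, scr = s$serum_creatinine,
    urine_flow = s$urine_flow, cardiac_output = s$cardiac_output))
  do.call(rbind, rows)
}

#' Population distribution diagnostics
#'
#' Univariate summaries (median, 5th/95th percentile), pairwise correlations,
#' and a gap report that flags empty bands in the parameter space. Pooling
#' discretely specified populations (e.g. healthy + moderate + severe CKD)
#' produces multimodal distributions with unpopulated bands, most visibly for
#' GFR; such bands are reported as gaps.
#'
#' @param subjects a list of `virtual_subject`s (possibly pooled across
#'   populations); at least 2.
#' @param gap_bins number of histogram bins used in gap detection.
#' @param gap_min_width minimum gap width as a fraction of the observed range
#'   before it is flagged.
#' @return list with `summary` (data.frame), `correlations` (matrix; `NA` for
#'   degenerate zero-variance parameters), `gaps` (data.frame of flagged empty
#'   bands), and `data` (per-subject data.frame).
#' @export
population_diagnostics <- function(subjects, gap_bins = 30L,
                                   gap_min_width = 0.1) {
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  df <- subjects_to_dataframe(subjects)
  vars <- c("age", "weight", "kidney_weight", "gfr", "gfr_bsa", "ptcpgk",
            "oat1_whole_kidney", "haematocrit", "hsa", "scr")
  summ <- do.call(rbind, lapply(vars, function(v) {
    x <- df[[v]]
    q <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    data.frame(parameter = v, median = q[2L], p5 = q[1L], p95 = q[3L],
               range90 = q[3L] - q[1L], sd = sd(x),
               degenerate = sd(x) == 0)
  }))
  num <- df[vars]
  keep <- vapply(num, function(x) sd(x) > 0, logical(1L))
  corr <- matrix(NA_real_, length(vars), length(vars),
                 dimnames = list(vars, vars))
  if (sum(keep) >= 2L)
    corr[keep, keep] <- cor(num[keep])
  gaps <- do.call(rbind, lapply(vars, function(v) {
    x <- df[[v]]
    if (sd(x) == 0) return(NULL)
    h <- hist(x, breaks = seq(min(x), max(x), length.out = gap_bins + 1L),
              plot = FALSE)
    empty <- h$counts == 0
    r <- rle(empty)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hits <- which(r$values & r$lengths >= max(2L,
                    ceiling(gap_min_width * gap_bins)))
    ## only interior runs (populated bins on both sides) count as gaps
    hits <- hits[starts[hits] > 1L & ends[hits] < gap_bins]
    if (!length(hits)) return(NULL)
    data.frame(parameter = v,
               gap_low = h$breaks[starts[hits]],
               gap_high = h$breaks[ends[hits] + 1L])
  }))
  list(summary = summ, correlations = corr,
       gaps = gaps %||% data.frame(parameter = character(),
                                   gap_low = numeric(), gap_high = numeric()),
       data = df)
}
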