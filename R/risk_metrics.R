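#' Crystalluria risk assessment
#'
#' Compares per-subject luminal Cmax in a nephron segment against the drug's
#' aqueous solubility window. Because solubility is reported as a range rather
#' than a point value, risk is assessed against both bounds: a median above
#' the lower bound flags possible precipitation ("risk"), a median above the
#' upper bound flags likely precipitation ("high risk").
#'
#' @param result a `trial_result`.
#' @param drug a `drug_parameters` (supplies the solubility window, mg/L).
#' @param segment nephron segment, default the medullary collecting duct
#'   (the most concentrated, hence highest-risk, segment).
#' @param dose `"first"` or `"last"` dose Cmax.
#' @return object of class `crystalluria_assessment`: per-subject `cmax`,
#'   `fraction_exceeding_low`, `fraction_exceeding_high`, `median_cmax`,
#'   `median_margin` (median Cmax / upper solubility bound), and the flags
#'   `risk` and `high_risk`.
#' @export
assess_crystalluria <- function(result, drug, segment = "MCD",
                                dose = "last") {
  seg <- result$segment_cmax
  rows <- seg$segment == segment & seg$dose == dose
  if (!any(rows)) stop("segment not present in result", call. = FALSE)
  cmax <- seg$cmax[rows]
  med <- median(cmax)
  structure(
    list(segment = segment, cmax = cmax,
         solubility_low = drug$solubility_low,
         solubility_high = drug$solubility_high,
         fraction_exceeding_low = mean(cmax > drug$solubility_low),
         fraction_exceeding_high = mean(cmax > drug$solubility_high),
         median_cmax = med,
         median_margin = med / drug$solubility_high,
         risk = med > drug$solubility_low,
         high_risk = med > drug$solubility_high),
    class = "crystalluria_assessment")
}

#' @export
print.crystalluria_assessment <- function(x, ...) {
  cat(sprintf("<crystalluria_assessment> %s: median Cmax %.4g mg/L vs %g-%g mg/L\n",
              x$segment, x$median_cmax, x$solubility_low, x$solubility_high))
  cat(sprintf("  exceeding low/high bound: %.0f%% / %.0f%% of subjects; %s\n",
              100 * x$fraction_exceeding_low, 100 * x$fraction_exceeding_high,
              if (x$high_risk) "HIGH RISK" else if (x$risk) "risk flagged"
              else "below solubility"))
  invisible(x)
}

.check_pairs <- function(predicted, observed, positive = TRUE) {
  if (length(predicted) != length(observed) || !length(predicted))
    stop("predicted and observed must be equal-length, non-empty",
         call. = FALSE)
  if (positive && (any(predicted <= 0) || any(observed <= 0)))
    stop("fold-error metrics require strictly positive values", call. = FALSE)
}

#' Prediction-performance metrics
#'
#' Standard fold-error and error metrics for predicted-vs-observed PK
#' quantities, in base-10 logarithms:
#' \itemize{
#'   \item AFE (average fold error): `10^mean(log10(pred/obs))` — bias;
#'     under- and over-predictions cancel.
#'   \item GMFE (geometric mean fold error, also called absolute average fold
#'     error): `10^mean(|log10(pred/obs)|)` — spread; always `>= max(AFE,
#'     1/AFE)`.
#'   \item RMSE: `sqrt(mean((pred - obs)^2))`, in the units of the inputs.
#' }
#'
#' @param predicted,observed numeric vectors of paired values (> 0 for the
#'   fold-error metrics).
#' @return a single numeric value.
#' @examples
#' afe(c(2, 0.5), c(1, 1))   # 1: symmetric log errors cancel
#' gmfe(c(2, 0.5), c(1, 1))  # 2
#' rmse(c(3, 1), c(1, 3))    # 2
#' @export
afe <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^mean(log10(predicted / observed))
}

#' @rdname afe
#' @export
gmfe <- function(predicted, observed) {
  .check_pairs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' @rdname afe
#' @export
rmse <- function(predicted, observed) {
  .check_pairs(predicted, observed, positive = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Model-validation gate
#'
#' Applies the acceptance rules used for PBPK model verification: AFE and GMFE
#' within the 1.25-fold bioequivalence limits and within the conventional
#' twofold limits (each reported as a separate flag), and, when per-study
#' observations are supplied, whether each study's observation falls within
#' the 99% confidence interval of the simulated geometric mean.
#'
#' @param predicted,observed paired values used for AFE/GMFE.
#' @param study_observed optional named vector of per-study observed values.
#' @param simulated optional vector of simulated per-subject values used to
#'   build the 99% CI of the simulated geometric mean.
#' @return list with `afe`, `gmfe`, flags `afe_within_1.25`,
#'   `gmfe_within_1.25`, `afe_within_2`, `gmfe_within_2`, and (when supplied)
#'   a per-study data.frame `studies` with `within_ci99`.
#' @export
validation_gate <- function(predicted, observed, study_observed = NULL,
                            simulated = NULL) {
  a <- afe(predicted, observed)
  g <- gmfe(predicted, observed)
  within <- function(x, fold) x <= fold & x >= 1 / fold
  out <- list(afe = a, gmfe = g,
              afe_within_1.25 = within(a, 1.25),
              gmfe_within_1.25 = within(g, 1.25),
              afe_within_2 = within(a, 2),
              gmfe_within_2 = within(g, 2))
  if (!is.null(study_observed) && !is.null(simulated)) {
    logs <- log(simulated[simulated > 0])
    se <- sd(logs) / sqrt(length(logs))
    ci <- exp(mean(logs) + qnorm(c(0.005, 0.995)) * se)
    out$studies <- data.frame(
      study = names(study_observed) %||% seq_along(study_observed),
      observed = as.numeric(study_observed),
      ci99_low = ci[1L], ci99_high = ci[2L],
      within_ci99 = study_observed >= ci[1L] & study_observed <= ci[2L])
  }
  out
}
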