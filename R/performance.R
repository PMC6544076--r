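#' Standard error from a symmetric-normal 95% confidence interval
#'
#' @param ci_low,ci_high 95% CI bounds.
#' @return `(ci_high - ci_low) / (2 * qnorm(0.975))`.
#' @examples
#' ci_to_se(0.005, 0.017)  # ~0.00306
#' @export
ci_to_se <- function(ci_low, ci_high) {
  if (any(ci_high < ci_low, na.rm = TRUE))
    stop("ci_high must be >= ci_low")
  (ci_high - ci_low) / (2 * stats::qnorm(0.975))
}

#' Proportion of patients above a health-status score cutoff
#'
#' Converts a mean and SD on the 0-100 Kansas City Cardiomyopathy
#' Questionnaire (KCCQ) scale into the proportion of patients achieving at
#' least a cutoff score, under a normal approximation of the score
#' distribution: `1 - pnorm((cutoff - mean) / sd)`. Used to express
#' 'independence' (symptom relief) as a probability.
#'
#' @param mean_score,sd_score mean and SD of the score; `sd_score > 0`.
#' @param cutoff threshold score, default 75.
#' @return proportion in `[0, 1]`.
#' @export
kccq_threshold_proportion <- function(mean_score, sd_score, cutoff = 75) {
  if (any(sd_score <= 0)) stop("sd_score must be positive")
  p <- 1 - stats::pnorm((cutoff - mean_score) / sd_score)
  pmin(pmax(p, 0), 1)
}

#' Adjust an all-stroke risk to non-fatal disabling stroke
#'
#' Removes fatal strokes from an all-stroke risk by multiplying by the
#' survival fraction of stroke events: `all_stroke_risk * (1 -
#' stroke_case_fatality)`. The case-fatality fraction is a configuration
#' parameter (trial-derived, not estimated here).
#'
#' @param all_stroke_risk,stroke_case_fatality proportions in `[0, 1]`.
#' @return non-fatal disabling stroke risk.
#' @export
nonfatal_stroke_adjust <- function(all_stroke_risk, stroke_case_fatality) {
  if (any(all_stroke_risk < 0 | all_stroke_risk > 1) ||
      any(stroke_case_fatality < 0 | stroke_case_fatality > 1))
    stop("risks and case-fatality must be proportions in [0, 1]")
  all_stroke_risk * (1 - stroke_case_fatality)
}

#' Apply configured performance transformations
#'
#' Applies the transformation parameters stored under a configuration's
#' `transforms` key to the alternatives' performance: a
#' `stroke_case_fatality` entry converts the `stroke` attribute's all-stroke
#' risks to non-fatal disabling risks via [nonfatal_stroke_adjust()] (CI
#' bounds scale with the mean). With an empty `transforms` list (the
#' default) the configuration passes through untouched.
#'
#' @param config a [bra_config()].
#' @return the configuration with transformed performance values.
#' @export
apply_transforms <- function(config) {
  tf <- config$transforms
  if (is.null(tf) || length(tf) == 0) return(config)
  if (!is.null(tf$stroke_case_fatality) && "stroke" %in% config$attributes$name) {
    surv <- 1 - tf$stroke_case_fatality
    if (surv < 0 || surv > 1) stop("stroke_case_fatality must lie in [0, 1]")
    for (alt in names(config$alternatives)) {
      i <- config$alternatives[[alt]]$attribute == "stroke"
      for (col in c("mean", "ci_low", "ci_high"))
        config$alternatives[[alt]][[col]][i] <-
          config$alternatives[[alt]][[col]][i] * surv
    }
  }
  validate_config(config)
  config
}

#' Signed performance differences between two alternatives
#'
#' @param config a [bra_config()].
#' @param alternatives character(2); differences are first minus second.
#' @return named numeric vector of mean differences in attribute units.
#' @examples
#' impact_table(tavr_savr_config())  # pacemaker +0.033, mortality -0.029, ...
#' @export
impact_table <- function(config, alternatives = names(config$alternatives)[1:2]) {
  a <- profile_levels(config, alternatives[1])
  b <- profile_levels(config, alternatives[2])
  a - b
}
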