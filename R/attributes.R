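#' Define a benefit-risk attribute set
#'
#' An attribute set is the backbone of the additive value model: each
#' attribute has a direction (whether higher levels are better or worse), a
#' model range whose endpoints anchor the linear partial value function at 0
#' and 1, and units. Risk attributes (lower is better) have `worst > best`
#' numerically; benefit attributes the reverse.
#'
#' @param name character vector of attribute identifiers.
#' @param direction `"benefit"` (higher better) or `"risk"` (lower better),
#'   recycled to `length(name)`.
#' @param worst,best numeric range endpoints in attribute units. `worst`
#'   anchors partial value 0, `best` anchors 1.
#' @param units one of `"proportion"`, `"years"`, `"binary"` per attribute.
#'   Proportions are stored on the 0-1 scale and rendered as percentages in
#'   reports.
#' @param label optional human-readable labels (defaults to `name`).
#' @return A data frame of class `bra_attributes` with one row per attribute.
#' @examples
#' attribute_set("mortality", "risk", worst = 0.053, best = 0.005, units = "proportion")
#' @export
attribute_set <- function(name, direction, worst, best, units, label = name) {
  direction <- match.arg(direction, c("benefit", "risk"), several.ok = TRUE)
  n <- length(name)
  out <- data.frame(
    name = as.character(name),
    label = rep_len(as.character(label), n),
    direction = rep_len(direction, n),
    worst = rep_len(as.numeric(worst), n),
    best = rep_len(as.numeric(best), n),
    units = rep_len(match.arg(units, c("proportion", "years", "binary"),
                              several.ok = TRUE), n),
    stringsAsFactors = FALSE
  )
  validate_attributes(out)
  class(out) <- c("bra_attributes", "data.frame")
  out
}

validate_attributes <- function(attrs) {
  if (anyDuplicated(attrs$name))
    stop("duplicate attribute names: ",
         paste(unique(attrs$name[duplicated(attrs$name)]), collapse = ", "))
  if (any(attrs$worst == attrs$best))
    stop("attribute range is degenerate (worst == best) for: ",
         paste(attrs$name[attrs$worst == attrs$best], collapse = ", "))
  bad_dir <- (attrs$direction == "risk" & attrs$worst <= attrs$best) |
             (attrs$direction == "benefit" & attrs$worst >= attrs$best)
  if (any(bad_dir))
    stop("range orientation inconsistent with direction for: ",
         paste(attrs$name[bad_dir], collapse = ", "))
  prop <- attrs$units == "proportion"
  rng <- c(attrs$worst[prop], attrs$best[prop])
  if (length(rng) && (any(rng < 0) || any(rng > 1)))
    stop("proportion attributes must have ranges within [0, 1]")
  invisible(attrs)
}

attr_row <- function(attributes, name) {
  i <- match(name, attributes$name)
  if (is.na(i)) stop("unknown attribute: ", name)
  attributes[i, , drop = FALSE]
}

#' Width of each attribute's model range
#'
#' @param attributes a [attribute_set()] data frame.
#' @return named numeric vector `|best - worst|` in attribute units.
#' @export
range_width <- function(attributes) {
  stats::setNames(abs(attributes$best - attributes$worst), attributes$name)
}

#' The TAVR vs SAVR attribute set
#'
#' The seven-attribute set used in the published aortic-stenosis
#' benefit-risk analysis: the binary procedure-invasiveness attribute (the
#' swing-weight anchor), four risks (one-month mortality, disabling non-fatal
#' stroke, one-year new permanent pacemaker, one-year dialysis) and two
#' benefits (probability of regaining independence at one month, years the
#' procedure has been proven to work). Ranges are the published model
#' performance ranges.
#'
#' @return a `bra_attributes` data frame with seven rows.
#' @export
tavr_savr_attributes <- function() {
  attribute_set(
    name = c("procedure", "mortality", "stroke", "independence",
             "pacemaker", "dialysis", "proven"),
    label = c("Type of procedure", "Mortality (1 month)",
              "Disabling non-fatal stroke", "Independence",
              "New permanent pacemaker", "Requirement for dialysis",
              "Proven to work"),
    direction = c("benefit", "risk", "risk", "benefit",
                  "risk", "risk", "benefit"),
    worst = c(0, 0.053, 0.044, 0.227, 0.142, 0.060, 5),
    best  = c(1, 0.005, 0.002, 0.500, 0.072, 0.021, 30),
    units = c("binary", "proportion", "proportion", "proportion",
              "proportion", "proportion", "years")
  )
}

#' Build a benefit-risk configuration
#'
#' Couples an attribute set with the performance profiles of the alternatives
#' under comparison. Each profile gives, per attribute, a mean level and an
#' optional 95% confidence interval used by the Monte Carlo simulation.
#'
#' @param attributes a [attribute_set()] data frame.
#' @param alternatives named list; each element a data frame with columns
#'   `attribute`, `mean` and optionally `ci_low`, `ci_high`.
#' @param transforms optional named list of performance-transformation
#'   parameters (`stroke_case_fatality`, `kccq_cutoff`); empty by default so
#'   configured performance values pass through untouched. See
#'   [apply_transforms()].
#' @return an object of class `bra_config`.
#' @export
bra_config <- function(attributes, alternatives, transforms = list()) {
  stopifnot(inherits(attributes, "bra_attributes"))
  unknown <- setdiff(names(transforms),
                     c("stroke_case_fatality", "kccq_cutoff"))
  if (length(unknown))
    stop("unknown transform parameter(s): ", paste(unknown, collapse = ", "))
  if (is.null(names(alternatives)) || any(!nzchar(names(alternatives))))
    stop("alternatives must be a named list")
  alternatives <- lapply(alternatives, function(p) {
    p <- as.data.frame(p)
    if (is.null(p$ci_low)) p$ci_low <- NA_real_
    if (is.null(p$ci_high)) p$ci_high <- NA_real_
    p[, c("attribute", "mean", "ci_low", "ci_high")]
  })
  cfg <- structure(list(attributes = attributes, alternatives = alternatives,
                        transforms = transforms),
                   class = "bra_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  attrs <- config$attributes
  for (alt in names(config$alternatives)) {
    p <- config$alternatives[[alt]]
    missing <- setdiff(attrs$name, p$attribute)
    if (length(missing))
      stop("alternative '", alt, "' is missing attributes: ",
           paste(missing, collapse = ", "))
    unknown <- setdiff(p$attribute, attrs$name)
    if (length(unknown))
      stop("alternative '", alt, "' has unknown attributes: ",
           paste(unknown, collapse = ", "))
    i <- match(p$attribute, attrs$name)
    prop <- attrs$units[i] == "proportion"
    if (any(p$mean[prop] < 0 | p$mean[prop] > 1))
      stop("alternative '", alt, "' has proportion means outside [0, 1]")
    has_ci <- !is.na(p$ci_low) & !is.na(p$ci_high)
    bad <- has_ci & (p$ci_low > p$mean | p$ci_high < p$mean)
    if (any(bad))
      stop("alternative '", alt, "' has CI bounds not bracketing the mean for: ",
           paste(p$attribute[bad], collapse = ", "))
  }
  invisible(config)
}

#' Levels of one alternative as a named vector
#'
#' @param config a [bra_config()].
#' @param alternative alternative name.
#' @return named numeric vector of mean levels in attribute order.
#' @export
profile_levels <- function(config, alternative) {
  p <- config$alternatives[[alternative]]
  if (is.null(p)) stop("unknown alternative: ", alternative)
  stats::setNames(p$mean[match(config$attributes$name, p$attribute)],
                  config$attributes$name)
}

#' The published TAVR vs SAVR configuration
#'
#' Performance of transcatheter (TAVR) and surgical (SAVR) aortic valve
#' replacement on the seven model attributes: means and 95% CIs for the five
#' probability attributes, point values for proven-to-work years and the
#' binary procedure attribute (TAVR minimally invasive = 1, SAVR invasive
#' = 0).
#'
#' @return a `bra_config` with alternatives `TAVR` and `SAVR`.
#' @examples
#' cfg <- tavr_savr_config()
#' profile_levels(cfg, "TAVR")
#' @export
tavr_savr_config <- function() {
  attrs <- tavr_savr_attributes()
  mk <- function(mean, lo, hi) {
    data.frame(attribute = attrs$name, mean = mean, ci_low = lo, ci_high = hi,
               stringsAsFactors = FALSE)
  }
  tavr <- mk(mean = c(1, 0.011, 0.008, 0.479, 0.123, 0.032, 10),
             lo = c(NA, 0.005, 0.002, 0.454, 0.103, 0.021, NA),
             hi = c(NA, 0.017, 0.013, 0.500, 0.142, 0.042, NA))
  savr <- mk(mean = c(0, 0.040, 0.033, 0.249, 0.090, 0.047, 20),
             lo = c(NA, 0.028, 0.021, 0.227, 0.072, 0.034, NA),
             hi = c(NA, 0.053, 0.044, 0.276, 0.108, 0.060, NA))
  bra_config(attrs, list(TAVR = tavr, SAVR = savr))
}

#' Published mean indifference points (MIR/MRB) by age group
#'
#' Survey summary of the maximum acceptable increase in risk (MIR) or maximum
#' acceptable reduction in benefit (MRB) per attribute: mean, SD and number of
#' respondents with the attribute observed, for the whole sample and the
#' under-60 / 60-and-over subgroups. Values are stored in internal units
#' (proportions for probability attributes, years for proven-to-work).
#'
#' @param group `"whole"`, `"under60"` or `"ge60"`; `NULL` returns the full
#'   long-format summary data frame.
#' @return if `group` is given, a named vector of mean MIR/MRB per
#'   non-procedure attribute; otherwise a data frame with columns
#'   `attribute`, `group`, `mean`, `sd`, `n`.
#' @examples
#' reference_mir("whole")
#' @export
reference_mir <- function(group = NULL) {
  attrs <- c("mortality", "stroke", "independence", "pacemaker",
             "dialysis", "proven")
  tab <- data.frame(
    attribute = rep(attrs, times = 3),
    group = rep(c("whole", "under60", "ge60"), each = length(attrs)),
    mean = c(0.0386, 0.0669, 0.1394, 0.0698, 0.0621, 17.42,
             0.034,  0.065,  0.135,  0.059,  0.054,  17.9,
             0.045,  0.070,  0.146,  0.084,  0.075,  16.6),
    sd   = c(0.0295, 0.0573, 0.1177, 0.0571, 0.0562, 16.86,
             0.027,  0.056,  0.115,  0.051,  0.051,  16.7,
             0.032,  0.060,  0.122,  0.062,  0.062,  17.2),
    n    = c(109, 110, 131, 132, 131, 131,
             65, 67, 80, 76, 81, 80,
             44, 43, 51, 56, 50, 51),
    stringsAsFactors = FALSE
  )
  if (is.null(group)) return(tab)
  group <- match.arg(group, c("whole", "under60", "ge60"))
  sub <- tab[tab$group == group, ]
  stats::setNames(sub$mean, sub$attribute)
}
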