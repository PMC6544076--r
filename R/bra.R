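#' Fit a patient-preference benefit-risk model
#'
#' The central fitting function: combines an attribute/alternative
#' configuration with preference weights -- supplied directly, or derived
#' from a respondent panel via group-mean indifference points -- and computes
#' the additive value model's outputs: overall values, the incremental value
#' decomposition between the first two alternatives, the per-attribute
#' threshold table (maximum acceptable risk / minimum acceptable benefit),
#' and the performance impact table.
#'
#' @param config a [bra_config()], e.g. [tavr_savr_config()].
#' @param panel optional long-format respondent panel; used to derive
#'   group-mean weights when `weights` is not given, and by [simulate.bra()].
#' @param weights optional [mir_weights()] / [group_weights()] object or
#'   named raw-weight vector; overrides panel-derived weights.
#' @param group subgroup used for panel-derived weights (`"all"`,
#'   `"under60"`, `"ge60"`).
#' @param exclude_straight_liners sensitivity switch for panel-derived
#'   weights.
#' @param alternatives character(2): the focal alternative and the
#'   comparator; defaults to the first two in the config.
#' @return an object of class `bra` with components `config`, `panel`,
#'   `weights`, `group`, `alternatives`, `values` (named overall values),
#'   `decomposition`, `thresholds`, `impacts`.
#' @examples
#' fit <- bra(tavr_savr_config(), weights = mir_weights(reference_mir("whole"),
#'                                                      tavr_savr_attributes()))
#' summary(fit)
#' @export
bra <- function(config, panel = NULL, weights = NULL,
                group = "all", exclude_straight_liners = FALSE,
                alternatives = names(config$alternatives)[1:2]) {
  validate_config(config)
  if (is.null(weights)) {
    if (is.null(panel))
      stop("supply either a respondent panel or a weight vector")
    weights <- group_weights(panel, config$attributes, group,
                             exclude_straight_liners)
  } else if (!inherits(weights, "bra_weights")) {
    weights <- new_weights(weights[config$attributes$name],
                           provenance = "supplied")
  }
  pa <- profile_levels(config, alternatives[1])
  pb <- profile_levels(config, alternatives[2])
  values <- vapply(names(config$alternatives), function(alt)
    overall_value(profile_levels(config, alt), weights, config$attributes),
    numeric(1))
  structure(list(
    config = config,
    panel = panel,
    weights = weights,
    group = group,
    alternatives = alternatives,
    values = values,
    decomposition = incremental_value(pa, pb, weights, config$attributes),
    thresholds = threshold_table(config, weights, alternatives),
    impacts = impact_table(config, alternatives)
  ), class = "bra")
}

#' @export
print.bra <- function(x, digits = 3, ...) {
  cat("Additive benefit-risk model:", x$alternatives[1], "vs",
      x$alternatives[2], "\n")
  cat("Weights:", x$weights$provenance,
      if (!is.null(x$panel)) paste0("(group: ", x$group, ")"), "\n")
  cat("Overall values (raw units):",
      paste(names(x$values), round(x$values, digits), collapse = ", "), "\n")
  cat("Incremental value", paste0("(", x$alternatives[1], " - ",
                                  x$alternatives[2], "):"),
      round(x$decomposition$overall_increment, digits), "\n")
  invisible(x)
}

#' Summarise a fitted benefit-risk model
#'
#' @param object a [bra()] fit.
#' @param percent render proportion attributes as percentages (default).
#' @param ... unused.
#' @return the fit, invisibly; prints weights, the value decomposition and
#'   the threshold table.
#' @export
summary.bra <- function(object, percent = TRUE, ...) {
  print(object)
  cat("\n")
  print(object$weights)
  cat("\nIncremental value by attribute (raw units):\n")
  print(round(object$decomposition$per_attribute, 4))
  cat("\nThreshold analysis (", object$alternatives[1],
      " performance at indifference):\n", sep = "")
  thr <- object$thresholds
  if (percent) {
    units <- object$config$attributes$units[
      match(thr$attribute, object$config$attributes$name)]
    shown <- ifelse(units == "proportion",
                    sprintf("%.1f%%", 100 * thr$threshold),
                    sprintf("%.1f %s", thr$threshold, units))
    thr <- data.frame(attribute = thr$attribute, kind = thr$kind,
                      threshold = shown, clamped = thr$clamped)
  }
  print(thr, row.names = FALSE)
  invisible(object)
}

#' Attribute weights of a fitted model
#'
#' @param object a [bra()] fit.
#' @param type `"normalized"` (sum-100 scale, default) or `"raw"`
#'   (procedure-anchored).
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.bra <- function(object, type = c("normalized", "raw"), ...) {
  type <- match.arg(type)
  object$weights[[type]]
}

#' Overall value of (new) performance profiles
#'
#' @param object a [bra()] fit.
#' @param newdata named list of level vectors (or a single named vector);
#'   `NULL` returns the fitted alternatives' values.
#' @param ... unused.
#' @return named numeric vector of overall values on the raw weight scale.
#' @export
predict.bra <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$values)
  if (is.numeric(newdata)) newdata <- list(profile = newdata)
  vapply(newdata, overall_value, numeric(1),
         weights = object$weights, attributes = object$config$attributes,
         strict = FALSE)
}

#' Monte Carlo simulation from a fitted model
#'
#' Delegates to [run_mcs()] with the fit's configuration and panel.
#'
#' @param object a [bra()] fit (needs a panel for weight uncertainty;
#'   otherwise weights stay fixed at the fitted vector).
#' @param nsim number of iterations.
#' @param seed integer seed.
#' @param ... further arguments to [run_mcs()].
#' @return a `bra_mcs` object.
#' @export
simulate.bra <- function(object, nsim = 10000, seed = NULL, ...) {
  run_mcs(object$config, panel = object$panel, n_iterations = nsim,
          seed = seed, group = object$group,
          weights = object$weights,
          weight_uncertainty = !is.null(object$panel), ...)
}

#' Plot the incremental value decomposition
#'
#' Horizontal bar chart of the per-attribute incremental values (positive
#' bars favour the focal alternative) with the overall increment annotated.
#'
#' @param x a [bra()] fit.
#' @param ... passed to [graphics::barplot()].
#' @return the fit, invisibly.
#' @export
plot.bra <- function(x, ...) {
  inc <- rev(x$decomposition$per_attribute)
  labels <- x$config$attributes$label[match(names(inc),
                                            x$config$attributes$name)]
  old <- graphics::par(mar = c(4, 10, 3, 1))
  on.exit(graphics::par(old))
  graphics::barplot(inc, names.arg = labels, horiz = TRUE, las = 1,
                    col = ifelse(inc >= 0, "steelblue", "firebrick"),
                    xlab = "Incremental value (raw weight units)",
                    main = paste("Incremental value of", x$alternatives[1],
                                 "vs", x$alternatives[2]), ...)
  graphics::abline(v = 0)
  graphics::mtext(sprintf("overall increment = %.3f",
                          x$decomposition$overall_increment), side = 3,
                  line = -1, adj = 1, cex = 0.8)
  invisible(x)
}
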