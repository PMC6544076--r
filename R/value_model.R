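#' Linear partial value of a performance level
#'
#' Maps a level on one attribute to the 0-1 value scale: 0 at the model
#' range's worst endpoint, 1 at the best, linear in between. For risk
#' attributes the worst endpoint is the numerically larger one, so value
#' decreases as the risk level rises.
#'
#' @param level numeric level(s) in attribute units.
#' @param attribute a one-row slice of a [attribute_set()] (or any list with
#'   `worst` and `best`).
#' @param strict if `TRUE` (default) levels outside the model range are an
#'   error; if `FALSE` the linear function is extrapolated.
#' @return numeric value(s); in `[0, 1]` when the level is in range.
#' @examples
#' m <- attr_row(tavr_savr_attributes(), "mortality")
#' partial_value(0.011, m)  # 0.875
#' @export
partial_value <- function(level, attribute, strict = TRUE) {
  worst <- attribute$worst[1]
  best <- attribute$best[1]
  if (strict) {
    lo <- min(worst, best); hi <- max(worst, best)
    out <- level < lo - 1e-12 | level > hi + 1e-12
    if (any(out))
      stop("level ", paste(level[out], collapse = ", "), " outside range [",
           lo, ", ", hi, "] of attribute '", attribute$name[1], "'")
  }
  (level - worst) / (best - worst)
}

# vectorised partial values for a full profile; returns values in attribute order
partial_values <- function(levels, attributes, strict = TRUE) {
  levels <- levels[attributes$name]
  v <- (levels - attributes$worst) / (attributes$best - attributes$worst)
  if (strict && any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
    bad <- attributes$name[which(v < -1e-9 | v > 1 + 1e-9)]
    stop("levels outside model range for: ", paste(bad, collapse = ", "))
  }
  stats::setNames(v, attributes$name)
}

#' Overall value of an alternative
#'
#' The additive model `U = sum_i w_i v_i(x_i)` evaluated on the raw
#' (procedure-anchored) weight scale.
#'
#' @param profile named numeric vector of levels, or an alternative name when
#'   `config` is supplied via `attributes`.
#' @param weights a [mir_weights()] / [group_weights()] object (or a named
#'   raw-weight vector).
#' @param attributes a [attribute_set()] data frame.
#' @param strict passed to the partial value computation.
#' @return scalar overall value `U` in raw weight units.
#' @export
overall_value <- function(profile, weights, attributes, strict = TRUE) {
  w <- raw_weights(weights)
  missing <- setdiff(attributes$name, names(w))
  if (length(missing))
    stop("no weight for attribute(s): ", paste(missing, collapse = ", "))
  v <- partial_values(profile, attributes, strict = strict)
  sum(w[attributes$name] * v)
}

#' Incremental value of one alternative over another
#'
#' Computes the overall value increment `U(a) - U(b)` and its exact
#' decomposition into per-attribute incremental partial values
#' `w_i (v_i(x_a) - v_i(x_b))`, which sum to the overall increment.
#'
#' @param profile_a,profile_b named level vectors (same attribute set).
#' @inheritParams overall_value
#' @return an object of class `bra_decomposition`: list with
#'   `overall_increment` and named vector `per_attribute`.
#' @export
incremental_value <- function(profile_a, profile_b, weights, attributes,
                              strict = TRUE) {
  w <- raw_weights(weights)[attributes$name]
  va <- partial_values(profile_a, attributes, strict = strict)
  vb <- partial_values(profile_b, attributes, strict = strict)
  per <- w * (va - vb)
  structure(list(overall_increment = sum(per), per_attribute = per),
            class = "bra_decomposition")
}

#' @export
print.bra_decomposition <- function(x, digits = 4, ...) {
  cat("Incremental value decomposition (raw weight units)\n")
  print(round(x$per_attribute, digits))
  cat("overall increment:", format(x$overall_increment, digits = digits), "\n")
  invisible(x)
}

#' Threshold analysis: maximum acceptable risk / minimum acceptable benefit
#'
#' Finds the performance level on one attribute at which the first
#' alternative's overall value would equal the second's, holding everything
#' else fixed. For a risk attribute this is the maximum acceptable risk
#' (MAR): the level to which the risk could rise before indifference. For a
#' benefit it is the minimum acceptable benefit (MAB): the level to which the
#' benefit could fall. With a linear partial value function the displacement
#' is the value increment divided by the weight per attribute unit,
#' `w_a / |range_a|`; the sign is direction-aware so the threshold always
#' moves toward worse performance of the first alternative. The result is
#' invariant to weight normalisation.
#'
#' @param attribute attribute name.
#' @param profile_a named level vector of the alternative whose threshold is
#'   sought (conventionally the less invasive one).
#' @param profile_b named level vector of the comparator.
#' @inheritParams overall_value
#' @param clamp if `TRUE` (default) the threshold is clamped to feasible
#'   bounds: `[0, 1]` for proportions, `>= 0` for years. The unclamped value
#'   is retained in `raw`.
#' @return one-row data frame of class `bra_threshold`: `attribute`, `kind`
#'   (`"MAR"` or `"MAB"`), `threshold`, `raw`, `clamped`, `clamp_bound`.
#' @examples
#' cfg <- tavr_savr_config()
#' w <- mir_weights(reference_mir("whole"), cfg$attributes)
#' threshold("mortality", profile_levels(cfg, "TAVR"),
#'           profile_levels(cfg, "SAVR"), w, cfg$attributes)
#' @export
threshold <- function(attribute, profile_a, profile_b, weights, attributes,
                      clamp = TRUE) {
  a <- attr_row(attributes, attribute)
  w <- raw_weights(weights)
  wa <- w[[attribute]]
  if (is.null(wa) || is.na(wa) || wa == 0)
    stop("threshold is undefined: attribute '", attribute,
         "' has zero or missing weight")
  du <- incremental_value(profile_a, profile_b, weights, attributes,
                          strict = FALSE)$overall_increment
  width <- abs(a$best - a$worst)
  displacement <- du * width / wa
  raw <- if (a$direction == "risk") profile_a[[attribute]] + displacement
         else profile_a[[attribute]] - displacement
  lo <- if (a$units == "proportion") 0 else if (a$units == "years") 0 else -Inf
  hi <- if (a$units == "proportion") 1 else Inf
  thr <- min(max(raw, lo), hi)
  clamped <- clamp && !isTRUE(all.equal(thr, raw, tolerance = 0))
  out <- data.frame(
    attribute = attribute,
    kind = if (a$direction == "risk") "MAR" else "MAB",
    threshold = if (clamp) thr else raw,
    raw = raw,
    clamped = clamped,
    clamp_bound = if (clamped) (if (raw < lo) lo else hi) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bra_threshold", "data.frame")
  out
}

#' Threshold table over all non-anchor attributes
#'
#' Runs [threshold()] for every attribute except the binary procedure anchor.
#'
#' @param config a [bra_config()].
#' @param weights a weight object covering all attributes.
#' @param alternatives character(2): the alternative whose thresholds are
#'   computed and the comparator; defaults to the first two in the config.
#' @param clamp passed to [threshold()].
#' @return a `bra_threshold` data frame, one row per attribute.
#' @export
threshold_table <- function(config, weights,
                            alternatives = names(config$alternatives)[1:2],
                            clamp = TRUE) {
  attrs <- config$attributes
  pa <- profile_levels(config, alternatives[1])
  pb <- profile_levels(config, alternatives[2])
  keep <- attrs$name[attrs$units != "binary"]
  rows <- lapply(keep, threshold, profile_a = pa, profile_b = pb,
                 weights = weights, attributes = attrs, clamp = clamp)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
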