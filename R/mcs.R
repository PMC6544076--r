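#' Sample performance levels from an estimate's confidence interval
#'
#' Draws from a normal centred at the mean with SE derived from the 95% CI
#' ([ci_to_se()]), truncated to the attribute's feasible bounds (`[0, 1]`
#' for proportions, `>= 0` for years) via the inverse-CDF transform.
#' Estimates without a CI (or with a zero-width one) are point masses at the
#' mean.
#'
#' @param n number of draws.
#' @param mean,ci_low,ci_high the performance estimate.
#' @param units attribute units (`"proportion"`, `"years"`, `"binary"`).
#' @return numeric vector of length `n`.
#' @export
sample_performance <- function(n, mean, ci_low = NA, ci_high = NA,
                               units = "proportion") {
  if (is.na(ci_low) || is.na(ci_high)) return(rep(mean, n))
  se <- ci_to_se(ci_low, ci_high)
  if (se == 0) return(rep(mean, n))
  lo <- if (units == "proportion") 0 else if (units == "years") 0 else -Inf
  hi <- if (units == "proportion") 1 else Inf
  rtrunc_norm(n, mean, se, lo, hi)
}

#' Sample weight vectors from a respondent panel
#'
#' Two schemes for propagating preference heterogeneity: the default
#' respondent bootstrap draws a respondent uniformly and uses their complete
#' individual weight vector (preserving within-person correlation across
#' attributes); the attribute-independent bootstrap resamples each
#' attribute's indifference point independently from the panel's empirical
#' marginal.
#'
#' @param n number of weight vectors.
#' @param panel long-format respondent panel.
#' @param attributes a [attribute_set()] data frame.
#' @param scheme `"respondent"` or `"attribute"`.
#' @param exclude_straight_liners drop flagged respondents first.
#' @return matrix `n` x attributes of raw weights.
#' @export
sample_weights <- function(n, panel, attributes,
                           scheme = c("respondent", "attribute"),
                           exclude_straight_liners = FALSE) {
  scheme <- match.arg(scheme)
  sub <- filter_panel(panel, "all", exclude_straight_liners)
  if (nrow(sub) == 0) stop("empty panel")
  if (scheme == "respondent") {
    iw <- individual_weights(sub, attributes)
    idx <- sample.int(nrow(iw$weights), n, replace = TRUE)
    return(iw$weights[idx, , drop = FALSE])
  }
  need <- attributes$name[attributes$units != "binary"]
  W <- matrix(1, n, nrow(attributes),
              dimnames = list(NULL, attributes$name))
  for (a in need) {
    pool <- sub$mir[sub$attribute == a & !is.na(sub$mir)]
    if (length(pool) == 0) stop("attribute '", a, "' has no observed MIR")
    draws <- pool[sample.int(length(pool), n, replace = TRUE)]
    W[, a] <- weight_from_mir(draws, attr_row(attributes, a))
  }
  W
}

#' Monte Carlo simulation of the benefit-risk ranking
#'
#' Runs the additive value model repeatedly, each iteration drawing
#' performance levels from the alternatives' confidence intervals and a
#' weight vector from the respondent panel, and records which alternative
#' ranks first on overall value. Exact ties split 0.5/0.5. The result is
#' reproducible given the seed.
#'
#' @param config a [bra_config()].
#' @param panel long-format respondent panel; `NULL` fixes weights at
#'   `weights` (performance uncertainty only).
#' @param n_iterations number of model evaluations (default 10000).
#' @param seed integer seed.
#' @param scheme weight-sampling scheme, see [sample_weights()].
#' @param group subgroup filter (`"all"`, `"under60"`, `"ge60"`).
#' @param exclude_straight_liners sensitivity switch.
#' @param performance_uncertainty set `FALSE` to hold performance at the
#'   means (preference uncertainty only).
#' @param weights fallback fixed weights when `panel` is `NULL`, or when
#'   `weight_uncertainty = FALSE`.
#' @param weight_uncertainty set `FALSE` to hold weights fixed.
#' @return object of class `bra_mcs`: `n_iterations`, `p_first` (named),
#'   `mc_se`, `seed`, `scheme`, `subgroup`, `exclusions`.
#' @export
run_mcs <- function(config, panel = NULL, n_iterations = 10000, seed = NULL,
                    scheme = c("respondent", "attribute"),
                    group = "all", exclude_straight_liners = FALSE,
                    performance_uncertainty = TRUE,
                    weights = NULL, weight_uncertainty = !is.null(panel)) {
  scheme <- match.arg(scheme)
  stopifnot(n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  attrs <- config$attributes
  alts <- names(config$alternatives)
  sub <- if (is.null(panel)) NULL else filter_panel(panel, group, FALSE)
  # weight draws
  if (weight_uncertainty) {
    if (is.null(sub)) stop("weight uncertainty requires a panel")
    W <- sample_weights(n_iterations, sub, attrs, scheme,
                        exclude_straight_liners)
  } else {
    w0 <- if (!is.null(weights)) raw_weights(weights)
          else group_weights(sub, attrs,
                             if (group == "all") "all" else group,
                             exclude_straight_liners)$raw
    W <- matrix(w0, n_iterations, nrow(attrs), byrow = TRUE,
                dimnames = list(NULL, attrs$name))
  }
  # performance draws: values matrix per alternative
  U <- matrix(0, n_iterations, length(alts), dimnames = list(NULL, alts))
  for (alt in alts) {
    p <- config$alternatives[[alt]]
    for (i in seq_len(nrow(attrs))) {
      a <- attrs[i, ]
      row <- p[p$attribute == a$name, ]
      x <- if (performance_uncertainty)
        sample_performance(n_iterations, row$mean, row$ci_low, row$ci_high,
                           a$units)
      else rep(row$mean, n_iterations)
      v <- (x - a$worst) / (a$best - a$worst)
      U[, alt] <- U[, alt] + W[, a$name] * v
    }
  }
  best <- U == apply(U, 1, max)
  first <- best / rowSums(best)  # ties split equally
  p_first <- colMeans(first)
  mc_se <- sqrt(p_first * (1 - p_first) / n_iterations)
  structure(list(
    n_iterations = n_iterations,
    p_first = p_first,
    mc_se = mc_se,
    seed = seed,
    scheme = if (weight_uncertainty) scheme else "fixed-weights",
    subgroup = group,
    exclusions = if (exclude_straight_liners) "straight-liners" else "none"
  ), class = "bra_mcs")
}

#' @export
print.bra_mcs <- function(x, digits = 3, ...) {
  cat("Monte Carlo benefit-risk simulation (", x$n_iterations,
      " iterations, subgroup: ", x$subgroup, ")\n", sep = "")
  tab <- rbind(`P(ranks first)` = x$p_first, `MC SE` = x$mc_se)
  print(round(tab, digits))
  if (!is.null(x$seed)) cat("seed:", x$seed, "  scheme:", x$scheme,
                            "  exclusions:", x$exclusions, "\n")
  invisible(x)
}
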