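#' Convert an indifference point into a raw swing weight
#'
#' A respondent who would accept at most a change `mir` on an attribute in
#' exchange for the full invasiveness swing values the attribute's model
#' range at `|range| / mir` times the procedure swing. The procedure
#' attribute itself is the anchor with weight 1 and bypasses this
#' conversion.
#'
#' @param mir maximum acceptable increase in risk (or reduction in benefit),
#'   in the attribute's units; must be positive. `NA` propagates.
#' @param attribute one-row slice of a [attribute_set()].
#' @return raw weight (procedure anchor = 1 scale).
#' @examples
#' m <- attr_row(tavr_savr_attributes(), "mortality")
#' weight_from_mir(0.02, m)  # 2.4
#' @export
weight_from_mir <- function(mir, attribute) {
  if (attribute$units[1] == "binary") return(rep(1, length(mir)))
  bad <- !is.na(mir) & mir <= 0
  if (any(bad))
    stop("mir must be positive on attribute '", attribute$name[1], "'")
  abs(attribute$best[1] - attribute$worst[1]) / mir
}

#' Build a weight vector from per-attribute indifference points
#'
#' Applies [weight_from_mir()] attribute-wise, anchors the binary procedure
#' attribute at 1, and normalises to sum to 100. Both scales are kept: the
#' raw (anchor = 1) scale on which the value model is evaluated, and the
#' normalised scale used for reporting.
#'
#' @param mir named numeric vector of MIR/MRB values covering every
#'   non-binary attribute, in attribute units.
#' @param attributes a [attribute_set()] data frame.
#' @param provenance `"individual"` or `"group-mean"`.
#' @return an object of class `bra_weights`: list with `raw`, `normalized`,
#'   `provenance`.
#' @export
mir_weights <- function(mir, attributes, provenance = "individual") {
  need <- attributes$name[attributes$units != "binary"]
  missing <- setdiff(need, names(mir)[!is.na(mir)])
  if (length(missing))
    stop("missing MIR for attribute(s): ", paste(missing, collapse = ", "))
  raw <- vapply(seq_len(nrow(attributes)), function(i) {
    a <- attributes[i, , drop = FALSE]
    if (a$units == "binary") 1 else weight_from_mir(mir[[a$name]], a)
  }, numeric(1))
  names(raw) <- attributes$name
  new_weights(raw, provenance)
}

new_weights <- function(raw, provenance) {
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw weights must be finite and positive")
  structure(list(raw = raw,
                 normalized = normalize_weights(raw),
                 provenance = provenance),
            class = "bra_weights")
}

#' Normalise raw weights to sum to 100
#'
#' @param raw named positive numeric vector of raw weights.
#' @return named vector summing to 100.
#' @export
normalize_weights <- function(raw) {
  if (inherits(raw, "bra_weights")) raw <- raw$raw
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw weights must be finite and positive")
  100 * raw / sum(raw)
}

raw_weights <- function(weights) {
  if (inherits(weights, "bra_weights")) weights$raw else weights
}

#' @export
print.bra_weights <- function(x, digits = 4, ...) {
  cat("Attribute weights (", x$provenance, ")\n", sep = "")
  print(round(rbind(raw = x$raw, normalized = x$normalized), digits))
  invisible(x)
}

#' Group-level weights from a respondent panel
#'
#' Derives one weight vector for a (sub)group of respondents: per attribute,
#' the mean of the observed MIR/MRB values in the group (per-attribute n may
#' differ because of missingness) is converted to a weight via
#' [weight_from_mir()]. This range-over-mean-MIR construction is the
#' group-level analogue of the individual conversion and is distinct from
#' averaging individual weights.
#'
#' @param panel long-format panel data frame with columns `respondent_id`,
#'   `age_group` (`"under60"` / `"ge60"`), `attribute`, `mir`, `censored`,
#'   `straight_liner` (see [read_panel()]).
#' @param attributes a [attribute_set()] data frame.
#' @param group `"all"`, `"under60"` or `"ge60"`.
#' @param exclude_straight_liners drop respondents flagged as straight-liners
#'   (sensitivity analysis); by default their censored indifference points
#'   are retained at the censoring bound.
#' @return a `bra_weights` object with provenance `"group-mean"`.
#' @export
group_weights <- function(panel, attributes, group = c("all", "under60", "ge60"),
                          exclude_straight_liners = FALSE) {
  group <- match.arg(group)
  sub <- filter_panel(panel, group, exclude_straight_liners)
  if (nrow(sub) == 0) stop("no respondents in group '", group, "'")
  need <- attributes$name[attributes$units != "binary"]
  means <- vapply(need, function(a) {
    x <- sub$mir[sub$attribute == a & !is.na(sub$mir)]
    if (length(x) == 0)
      stop("attribute '", a, "' has no observed MIR in group '", group, "'")
    mean(x)
  }, numeric(1))
  mir_weights(means, attributes, provenance = "group-mean")
}

filter_panel <- function(panel, group = "all", exclude_straight_liners = FALSE) {
  sub <- panel
  if (group != "all") sub <- sub[sub$age_group == group, , drop = FALSE]
  if (exclude_straight_liners)
    sub <- sub[!sub$straight_liner, , drop = FALSE]
  sub
}

#' Per-attribute panel summary of indifference points
#'
#' Summarises a respondent panel the way preference surveys report it: per
#' attribute and group, the mean, sample SD (n-1 denominator) and n of
#' observed MIR/MRB values, plus -- when a TAVR-vs-SAVR impact table is
#' supplied -- the proportion of respondents whose indifference point exceeds
#' the actual performance change. For attributes on which the first
#' alternative is better the proportion is 100% by construction (every
#' respondent prefers an improvement plus reduced invasiveness).
#'
#' @inheritParams group_weights
#' @param impacts optional [impact_table()] result (signed differences,
#'   first alternative minus second).
#' @param groups character vector of groups to tabulate.
#' @return data frame with columns `attribute`, `group`, `mean`, `sd`, `n`
#'   and, when `impacts` is given, `prop_mir_gt_impact` (percent).
#' @export
panel_summary <- function(panel, attributes, impacts = NULL,
                          groups = c("whole", "under60", "ge60"),
                          exclude_straight_liners = FALSE) {
  need <- attributes$name[attributes$units != "binary"]
  rows <- list()
  for (g in groups) {
    sub <- filter_panel(panel, if (g == "whole") "all" else g,
                        exclude_straight_liners)
    for (a in need) {
      x <- sub$mir[sub$attribute == a & !is.na(sub$mir)]
      n <- length(x)
      row <- data.frame(attribute = a, group = g,
                        mean = if (n) mean(x) else NA_real_,
                        sd = if (n > 1) stats::sd(x) else NA_real_,
                        n = n, stringsAsFactors = FALSE)
      if (!is.null(impacts)) {
        d <- impacts[[a]]
        ai <- attr_row(attributes, a)
        tavr_better <- (ai$direction == "risk" && d < 0) ||
                       (ai$direction == "benefit" && d > 0)
        row$prop_mir_gt_impact <-
          if (tavr_better) 100
          else if (n) 100 * mean(x > abs(d))
          else NA_real_
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual raw-weight table for a panel
#'
#' One raw weight vector per respondent (range / individual MIR), used for
#' respondent-bootstrap weight sampling in the Monte Carlo simulation.
#' Missing attributes are filled from the group-mean MIR of the respondent's
#' subgroup (falling back to the whole panel), so every row is a complete
#' weight vector.
#'
#' @inheritParams group_weights
#' @return list with `weights` (matrix, respondents x attributes, raw scale)
#'   and `respondents` (data frame: `respondent_id`, `age_group`,
#'   `straight_liner`).
#' @export
individual_weights <- function(panel, attributes,
                               exclude_straight_liners = FALSE) {
  sub <- filter_panel(panel, "all", exclude_straight_liners)
  ids <- unique(sub$respondent_id)
  if (length(ids) == 0) stop("empty panel")
  need <- attributes$name[attributes$units != "binary"]
  group_mean <- function(a, g) {
    x <- sub$mir[sub$attribute == a & sub$age_group == g & !is.na(sub$mir)]
    if (length(x)) mean(x)
    else mean(sub$mir[sub$attribute == a & !is.na(sub$mir)])
  }
  meta <- unique(sub[, c("respondent_id", "age_group", "straight_liner")])
  meta <- meta[match(ids, meta$respondent_id), ]
  W <- matrix(NA_real_, length(ids), nrow(attributes),
              dimnames = list(ids, attributes$name))
  for (k in seq_along(ids)) {
    ri <- sub[sub$respondent_id == ids[k], ]
    mir <- stats::setNames(ri$mir[match(need, ri$attribute)], need)
    fill <- is.na(mir)
    if (any(fill))
      mir[fill] <- vapply(need[fill], group_mean, numeric(1),
                          g = meta$age_group[k])
    W[k, ] <- mir_weights(mir, attributes)$raw
  }
  list(weights = W, respondents = meta)
}
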