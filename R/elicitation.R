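#' Define an adaptive swing-weighting choice ladder
#'
#' One ladder per attribute: three iterations of a pairwise choice between
#' reducing procedure invasiveness and improving the attribute by an offered
#' amount. Offers follow a dyadic bisection of `(0, max_change]`: the first
#' offer is `max_change / 2` and each response halves the step, so three
#' responses localise the respondent's indifference point to one of eight
#' adjacent intervals of width `max_change / 8`.
#'
#' @param attribute attribute name the ladder elicits.
#' @param max_change largest offerable change, in attribute units.
#' @param base_level the 'current' level from which changes are offered
#'   (bookkeeping only; offers are expressed as changes).
#' @return an object of class `asw_ladder`.
#' @export
asw_ladder <- function(attribute, max_change, base_level = 0) {
  stopifnot(is.numeric(max_change), max_change > 0)
  structure(list(attribute = attribute, max_change = max_change,
                 base_level = base_level),
            class = "asw_ladder")
}

# bisection state after a response history: interval (lo, hi] containing the
# indifference point; chose_procedure means the offer was too small.
bisect_interval <- function(max_change, history) {
  lo <- 0; hi <- max_change
  for (chose_procedure in history) {
    mid <- (lo + hi) / 2
    if (chose_procedure) lo <- mid else hi <- mid
  }
  c(lo, hi)
}

#' Next offered change in an ASW ladder
#'
#' @param ladder an [asw_ladder()].
#' @param history logical vector of previous responses (`TRUE` = chose the
#'   procedure improvement, i.e. the offered attribute change was worth less
#'   than de-invasiveness); length 0 to 2.
#' @return the next offered change in attribute units (midpoint of the
#'   current bracketing interval).
#' @export
next_offer <- function(ladder, history = logical(0)) {
  if (length(history) >= 3)
    stop("ladder has three iterations; history of length ",
         length(history), " is complete")
  iv <- bisect_interval(ladder$max_change, history)
  (iv[1] + iv[2]) / 2
}

#' Estimate the indifference point from a completed ladder
#'
#' The eight response patterns partition `(0, max_change]` into eight
#' adjacent intervals of width `max_change / 8`; the estimate is the interval
#' midpoint. The two boundary patterns are censored: a respondent who always
#' chose the procedure improvement has an indifference point at or beyond the
#' ladder maximum (`censored = "at_max"`, point set to `max_change`); one who
#' always chose the attribute improvement sits in the lowest interval
#' (`censored = "at_min"`) and is a straight-liner candidate.
#'
#' @param ladder an [asw_ladder()].
#' @param responses logical vector of exactly three responses
#'   (`TRUE` = chose procedure).
#' @return list of class `asw_estimate`: `attribute`, `point`, `interval`
#'   (length-2 numeric), `censored` (`"none"`, `"at_max"`, `"at_min"`).
#' @export
estimate_indifference <- function(ladder, responses) {
  if (length(responses) != 3 || anyNA(responses))
    stop("a completed ladder has exactly three responses")
  responses <- as.logical(responses)
  iv <- bisect_interval(ladder$max_change, responses)
  censored <- if (all(responses)) "at_max"
              else if (!any(responses)) "at_min"
              else "none"
  point <- if (censored == "at_max") ladder$max_change else mean(iv)
  structure(list(attribute = ladder$attribute, point = point,
                 interval = iv, censored = censored),
            class = "asw_estimate")
}

#' Simulate one choice response
#'
#' A respondent with latent indifference point `latent_mir` chooses the
#' attribute improvement when the offered change is worth more to them than
#' the invasiveness reduction, i.e. when `offer > latent_mir`. The logistic
#' error model passes that comparison through a logistic choice probability
#' with the given scale (attribute units); as the scale shrinks it converges
#' to the deterministic rule.
#'
#' @param latent_mir positive latent indifference point.
#' @param offer offered change in attribute units.
#' @param error_model `"deterministic"` or `"logistic"`.
#' @param scale logistic scale (> 0), required for the logistic model.
#' @return logical: `TRUE` if the respondent chose the procedure improvement.
#' @export
simulate_response <- function(latent_mir, offer,
                              error_model = c("deterministic", "logistic"),
                              scale = NULL) {
  error_model <- match.arg(error_model)
  if (error_model == "deterministic")
    return(!(offer > latent_mir))
  if (is.null(scale) || scale <= 0)
    stop("logistic error model needs a positive scale")
  p_attr <- stats::plogis((offer - latent_mir) / scale)
  stats::runif(1) >= p_attr
}

#' Run a full three-iteration ladder against a chooser
#'
#' @param ladder an [asw_ladder()].
#' @param chooser function(offer) returning `TRUE` when the procedure
#'   improvement is chosen; typically a closure over [simulate_response()].
#' @return data frame: `iteration`, `offered_change`, `chose_procedure`.
#' @export
run_ladder <- function(ladder, chooser) {
  history <- logical(0)
  offers <- numeric(3)
  for (i in 1:3) {
    offers[i] <- next_offer(ladder, history)
    history <- c(history, isTRUE(chooser(offers[i])))
  }
  data.frame(iteration = 1:3, offered_change = offers,
             chose_procedure = history)
}

#' Classify a respondent as a straight-liner
#'
#' A respondent straight-lines when every completed exercise is an
#' all-same-side pattern: all three choices for the procedure improvement, or
#' all three for the comparison attribute.
#'
#' @param exercises list of logical length-3 vectors, one per completed
#'   exercise (`TRUE` = chose procedure).
#' @return logical flag.
#' @export
classify_straight_liner <- function(exercises) {
  if (length(exercises) == 0)
    stop("respondent has no completed exercises")
  all(vapply(exercises, function(r) all(r) || !any(r), logical(1)))
}

#' Recover a respondent panel from raw choice logs
#'
#' Replays each respondent-by-attribute block of a choice log through
#' [estimate_indifference()] and classifies straight-liners, producing the
#' long-format panel used by the weighting functions.
#'
#' @param logs choice-log data frame with columns `respondent_id`,
#'   `attribute`, `iteration`, `offered_change`, `chose_procedure` (see
#'   [read_choice_logs()]).
#' @param ladders named list of [asw_ladder()] objects covering every
#'   attribute present in the logs.
#' @param age_groups optional named vector mapping respondent ids to
#'   `"under60"` / `"ge60"`; defaults to `NA`.
#' @return long panel data frame (`respondent_id`, `age_group`, `attribute`,
#'   `mir`, `censored`, `straight_liner`).
#' @export
elicit_panel <- function(logs, ladders, age_groups = NULL) {
  need <- setdiff(unique(logs$attribute), names(ladders))
  if (length(need))
    stop("no ladder for attribute(s): ", paste(need, collapse = ", "))
  by_resp <- split(logs, logs$respondent_id)
  rows <- lapply(by_resp, function(li) {
    patterns <- lapply(split(li, li$attribute), function(e)
      e$chose_procedure[order(e$iteration)])
    sl <- classify_straight_liner(patterns)
    ests <- lapply(names(patterns), function(a)
      estimate_indifference(ladders[[a]], patterns[[a]]))
    data.frame(
      respondent_id = li$respondent_id[1],
      age_group = if (is.null(age_groups)) NA_character_
                  else unname(age_groups[as.character(li$respondent_id[1])]),
      attribute = names(patterns),
      mir = vapply(ests, `[[`, numeric(1), "point"),
      censored = vapply(ests, function(e) e$censored != "none", logical(1)),
      straight_liner = sl,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
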