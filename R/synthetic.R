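#' Default ladder maxima for the TAVR vs SAVR attributes
#'
#' The largest offerable change per attribute, in attribute units. Chosen so
#' the published mean indifference points sit well inside the offer grid
#' (roughly mean + 2 SD, rounded to display-friendly levels).
#'
#' @return named numeric vector.
#' @export
default_max_change <- function() {
  c(mortality = 0.12, stroke = 0.20, independence = 0.40,
    pacemaker = 0.24, dialysis = 0.20, proven = 60)
}

#' Default per-attribute missingness rates
#'
#' One minus the published per-attribute response counts over the panel size
#' (each respondent completed only a subset of the exercises).
#'
#' @return named numeric vector of missingness probabilities.
#' @export
default_missingness <- function() {
  n <- stats::setNames(reference_mir()$n[reference_mir()$group == "whole"],
                       reference_mir()$attribute[reference_mir()$group == "whole"])
  1 - n / 219
}

#' Specify a synthetic respondent panel
#'
#' Defaults reproduce the published study conditions: 219 respondents, 132 of
#' them under 60; latent per-attribute indifference points drawn from a
#' truncated normal on `(0, max_change]` with the published age-group means
#' and SDs; 8.68% straight-liners; per-attribute missingness matching the
#' published response counts.
#'
#' @param n_respondents panel size.
#' @param age_mix proportion under 60.
#' @param mir_mean,mir_sd matrices (attributes x `c("under60","ge60")`) of
#'   latent means and SDs in attribute units; defaults from the published
#'   age-group summaries.
#' @param max_change named vector of ladder maxima ([default_max_change()]).
#' @param missingness named vector of per-attribute missingness
#'   probabilities, or `NULL` for none.
#' @param missingness_mode `"independent"` (per-attribute Bernoulli) or
#'   `"assignment"` (each respondent is assigned 3 or 4 of the exercises at
#'   random, mimicking the study design).
#' @param straight_liner_fraction proportion of respondents who answer every
#'   exercise on the same side.
#' @param latent_family `"truncnorm"` or `"lognormal"` (moment-matched, then
#'   truncated to the ladder).
#' @param error_model,logistic_scale response error model used when choice
#'   logs are generated; `logistic_scale` is a fraction of each attribute's
#'   `max_change`.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(n_respondents = 219, age_mix = 132 / 219,
                       mir_mean = NULL, mir_sd = NULL,
                       max_change = default_max_change(),
                       missingness = default_missingness(),
                       missingness_mode = c("independent", "assignment"),
                       straight_liner_fraction = 0.0868,
                       latent_family = c("truncnorm", "lognormal"),
                       error_model = c("deterministic", "logistic"),
                       logistic_scale = 0.05) {
  ref <- reference_mir()
  attrs <- names(max_change)
  pick <- function(col, g) {
    s <- ref[ref$group == g, ]
    stats::setNames(s[[col]], s$attribute)[attrs]
  }
  if (is.null(mir_mean))
    mir_mean <- cbind(under60 = pick("mean", "under60"),
                      ge60 = pick("mean", "ge60"))
  if (is.null(mir_sd))
    mir_sd <- cbind(under60 = pick("sd", "under60"),
                    ge60 = pick("sd", "ge60"))
  spec <- structure(list(
    n_respondents = n_respondents, age_mix = age_mix,
    mir_mean = mir_mean, mir_sd = mir_sd, max_change = max_change,
    missingness = missingness,
    missingness_mode = match.arg(missingness_mode),
    straight_liner_fraction = straight_liner_fraction,
    latent_family = match.arg(latent_family),
    error_model = match.arg(error_model),
    logistic_scale = logistic_scale
  ), class = "panel_spec")
  validate_panel_spec(spec)
  spec
}

validate_panel_spec <- function(spec) {
  stopifnot(spec$n_respondents >= 1,
            spec$age_mix >= 0, spec$age_mix <= 1,
            spec$straight_liner_fraction >= 0,
            spec$straight_liner_fraction <= 1,
            all(spec$mir_sd >= 0))
  attrs <- names(spec$max_change)
  bad <- character(0)
  for (g in colnames(spec$mir_mean)) {
    m <- spec$mir_mean[attrs, g]
    out <- m <= 0 | m > spec$max_change[attrs]
    if (any(out)) bad <- c(bad, paste0(attrs[out], "/", g))
  }
  if (length(bad))
    stop("latent means outside (0, max_change] for: ",
         paste(bad, collapse = ", "))
  if (!is.null(spec$missingness) &&
      (any(spec$missingness < 0) || any(spec$missingness > 1)))
    stop("missingness rates must lie in [0, 1]")
  invisible(spec)
}

# inverse-CDF truncated normal on (lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# mean of a normal(mu, sd) truncated to (lo, hi)
trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# parent location such that the (lo, hi)-truncated normal has the target mean;
# keeps sd at the target scale. Without this, truncation at zero would inflate
# the realised panel means above the specified ones.
calibrate_trunc_mean <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  stats::uniroot(function(mu) trunc_norm_mean(mu, sd, lo, hi) - target,
                 interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

# moment-matched lognormal, truncated to (lo, hi] by inverse CDF
rtrunc_lnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  plo <- stats::plnorm(lo, mu, sqrt(sigma2))
  phi <- stats::plnorm(hi, mu, sqrt(sigma2))
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), mu, sqrt(sigma2))
}

#' Read and write panel specifications as JSON
#'
#' All [panel_spec()] fields round-trip; the mean/SD matrices are stored as
#' per-group named objects.
#'
#' @param path file path.
#' @return [read_panel_spec()] returns a `panel_spec`;
#'   [write_panel_spec()] returns `path` invisibly.
#' @export
read_panel_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    m <- cbind(under60 = unlist(x$under60), ge60 = unlist(x$ge60))
    m[names(doc$max_change), , drop = FALSE]
  }
  panel_spec(
    n_respondents = doc$n_respondents, age_mix = doc$age_mix,
    mir_mean = as_mat(doc$mir_mean), mir_sd = as_mat(doc$mir_sd),
    max_change = unlist(doc$max_change),
    missingness = if (is.null(doc$missingness)) NULL
                  else unlist(doc$missingness),
    missingness_mode = doc$missingness_mode,
    straight_liner_fraction = doc$straight_liner_fraction,
    latent_family = doc$latent_family,
    error_model = doc$error_model,
    logistic_scale = doc$logistic_scale
  )
}

#' @rdname read_panel_spec
#' @param spec a [panel_spec()].
#' @export
write_panel_spec <- function(spec, path) {
  as_obj <- function(m) list(under60 = as.list(m[, "under60"]),
                             ge60 = as.list(m[, "ge60"]))
  doc <- list(
    n_respondents = spec$n_respondents, age_mix = spec$age_mix,
    mir_mean = as_obj(spec$mir_mean), mir_sd = as_obj(spec$mir_sd),
    max_change = as.list(spec$max_change),
    missingness = if (is.null(spec$missingness)) NULL
                  else as.list(spec$missingness),
    missingness_mode = spec$missingness_mode,
    straight_liner_fraction = spec$straight_liner_fraction,
    latent_family = spec$latent_family,
    error_model = spec$error_model,
    logistic_scale = spec$logistic_scale
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic respondent panel
#'
#' Draws a panel per the spec: age group, latent indifference point per
#' attribute, straight-liner status (latents pushed beyond the ladder
#' bounds, side split 50/50), and per-attribute missingness. For the
#' truncated-normal family the parent location is calibrated so the
#' truncated distribution's mean equals the specified mean (truncation at
#' zero would otherwise inflate it). Returns both the
#' observable records -- straight-liners censored at the ladder bounds, as
#' the elicitation engine would report them -- and the latent truth for
#' recovery tests. Respondents left with no observed attribute are excluded,
#' mirroring the study's completed-at-least-one-exercise rule.
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed; panels are reproducible given `spec` and `seed`.
#' @return list with `panel` (long data frame: `respondent_id`, `age_group`,
#'   `attribute`, `mir`, `censored`, `straight_liner`) and `truth` (long data
#'   frame of latent values, incl. unobserved cells, plus `sl_side`).
#' @export
generate_panel <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  attrs <- names(spec$max_change)
  n <- spec$n_respondents
  age <- ifelse(stats::runif(n) < spec$age_mix, "under60", "ge60")
  sl <- stats::runif(n) < spec$straight_liner_fraction
  sl_side <- ifelse(sl, ifelse(stats::runif(n) < 0.5, "procedure", "attribute"),
                    NA_character_)
  rdraw <- if (spec$latent_family == "truncnorm") rtrunc_norm else rtrunc_lnorm
  # latent matrix, respondent-major fill per attribute
  latent <- matrix(NA_real_, n, length(attrs), dimnames = list(NULL, attrs))
  for (a in attrs) {
    for (g in c("under60", "ge60")) {
      idx <- which(age == g)
      if (length(idx)) {
        m <- spec$mir_mean[a, g]
        # the specified means describe the observed panel (which, like the
        # study's, retains straight-liners at their censoring bounds); back
        # out the non-straight-liner target before calibrating the parent
        f <- spec$straight_liner_fraction / 2
        mx <- spec$max_change[[a]]
        m <- (m - f * mx - f * mx / 16) / (1 - 2 * f)
        if (m <= 0)
          stop("straight-liner censoring leaves no room for a positive ",
               "latent mean on attribute '", a, "'")
        if (spec$latent_family == "truncnorm")
          m <- calibrate_trunc_mean(m, spec$mir_sd[a, g], 0, spec$max_change[a])
        latent[idx, a] <- rdraw(length(idx), m, spec$mir_sd[a, g],
                                0, spec$max_change[a])
      }
    }
  }
  latent[sl_side %in% "procedure", ] <- rep(2 * spec$max_change,
                                            each = sum(sl_side %in% "procedure"))
  latent[sl_side %in% "attribute", ] <- 0
  observed <- matrix(TRUE, n, length(attrs), dimnames = list(NULL, attrs))
  if (spec$missingness_mode == "assignment") {
    k <- ifelse(stats::runif(n) < 0.5, 3L, 4L)
    observed[] <- FALSE
    for (i in seq_len(n))
      observed[i, sample(attrs, k[i])] <- TRUE
  } else if (!is.null(spec$missingness)) {
    for (a in attrs)
      observed[, a] <- stats::runif(n) >= spec$missingness[a]
  }
  keep <- rowSums(observed) > 0
  ids <- sprintf("R%04d", seq_len(n))
  truth <- data.frame(
    respondent_id = rep(ids, times = length(attrs)),
    age_group = rep(age, times = length(attrs)),
    attribute = rep(attrs, each = n),
    latent = as.vector(latent),
    observed = as.vector(observed) & rep(keep, times = length(attrs)),
    straight_liner = rep(sl, times = length(attrs)),
    sl_side = rep(sl_side, times = length(attrs)),
    stringsAsFactors = FALSE
  )
  rec <- truth[truth$observed, ]
  mir <- rec$latent
  maxes <- spec$max_change[rec$attribute]
  proc_sl <- rec$sl_side %in% "procedure"
  attr_sl <- rec$sl_side %in% "attribute"
  mir[proc_sl] <- maxes[proc_sl]
  mir[attr_sl] <- maxes[attr_sl] / 16
  panel <- data.frame(
    respondent_id = rec$respondent_id,
    age_group = rec$age_group,
    attribute = rec$attribute,
    mir = mir,
    censored = proc_sl | attr_sl,
    straight_liner = rec$straight_liner,
    stringsAsFactors = FALSE
  )
  ord <- order(panel$respondent_id, match(panel$attribute, attrs))
  panel <- panel[ord, ]
  rownames(panel) <- NULL
  list(panel = panel, truth = truth)
}

#' Generate raw choice logs from latent truths
#'
#' Plays every observed respondent-by-attribute latent through the
#' three-iteration bisection ladder under the spec's response error model, in
#' fixed respondent-major order, producing a choice log that can be fed back
#' through [elicit_panel()] for round-trip tests.
#'
#' @param truth the `truth` component of [generate_panel()].
#' @param spec the [panel_spec()] used to generate it.
#' @param seed integer seed (only consumed by the logistic error model).
#' @return choice-log data frame: `respondent_id`, `attribute`, `iteration`,
#'   `offered_change`, `chose_procedure`.
#' @export
generate_choice_logs <- function(truth, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  attrs <- names(spec$max_change)
  obs <- truth[truth$observed, ]
  obs <- obs[order(obs$respondent_id, match(obs$attribute, attrs)), ]
  m <- nrow(obs)
  offers <- matrix(0, m, 3)
  chose <- matrix(FALSE, m, 3)
  for (i in seq_len(m)) {
    mx <- spec$max_change[[obs$attribute[i]]]
    lo <- 0; hi <- mx
    for (k in 1:3) {
      offers[i, k] <- (lo + hi) / 2
      chose[i, k] <- simulate_response(obs$latent[i], offers[i, k],
                                       spec$error_model,
                                       scale = spec$logistic_scale * mx)
      if (chose[i, k]) lo <- offers[i, k] else hi <- offers[i, k]
    }
  }
  data.frame(
    respondent_id = rep(obs$respondent_id, each = 3),
    attribute = rep(obs$attribute, each = 3),
    iteration = rep(1:3, times = m),
    offered_change = as.vector(t(offers)),
    chose_procedure = as.vector(t(chose)),
    stringsAsFactors = FALSE
  )
}
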