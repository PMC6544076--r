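# shared fixtures built in code

# minimal three-attribute model: binary anchor, one risk, one benefit
toy_attributes <- function() {
  attribute_set(
    name = c("procedure", "riskA", "benB"),
    direction = c("benefit", "risk", "benefit"),
    worst = c(0, 0.50, 0.10),
    best = c(1, 0.10, 0.90),
    units = c("binary", "proportion", "proportion")
  )
}

toy_config <- function() {
  attrs <- toy_attributes()
  mk <- function(mean) data.frame(attribute = attrs$name, mean = mean,
                                  ci_low = NA_real_, ci_high = NA_real_)
  bra_config(attrs, list(NEW = mk(c(1, 0.20, 0.60)),
                         OLD = mk(c(0, 0.30, 0.40))))
}

# random configuration for property tests: binary anchor + k continuous
# attributes with random ranges, profiles interior to the ranges
random_config <- function(k = 4) {
  dirs <- sample(c("risk", "benefit"), k, replace = TRUE)
  lo <- runif(k, 0, 0.4)
  hi <- lo + runif(k, 0.1, 0.5)
  attrs <- attribute_set(
    name = c("procedure", paste0("a", seq_len(k))),
    direction = c("benefit", dirs),
    worst = c(0, ifelse(dirs == "risk", hi, lo)),
    best = c(1, ifelse(dirs == "risk", lo, hi)),
    units = c("binary", rep("proportion", k))
  )
  lev <- function() c(1, lo + runif(k) * (hi - lo))
  mk <- function(mean) data.frame(attribute = attrs$name, mean = mean,
                                  ci_low = NA_real_, ci_high = NA_real_)
  cfg <- bra_config(attrs, list(NEW = mk(lev()), OLD = mk(lev())))
  cfg$alternatives$OLD$mean[1] <- 0
  cfg
}

random_weights <- function(attributes) {
  raw <- c(1, runif(nrow(attributes) - 1, 0.2, 3))
  names(raw) <- attributes$name
  mir_like <- abs(attributes$best - attributes$worst) / raw
  w <- mir_weights(stats::setNames(mir_like[-1], attributes$name[-1]),
                   attributes)
  w
}

# homogeneous panel: every respondent has the same MIR vector
homogeneous_panel <- function(mir, n = 5, age_group = "under60") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(respondent_id = sprintf("H%02d", i), age_group = age_group,
               attribute = names(mir), mir = unname(mir),
               censored = FALSE, straight_liner = FALSE,
               stringsAsFactors = FALSE)
  }))
}

tavr_whole_fit <- function() {
  cfg <- tavr_savr_config()
  bra(cfg, weights = mir_weights(reference_mir("whole"), cfg$attributes,
                                 provenance = "group-mean"))
}

# thresholds on the reporting scale (percent for proportions, years as-is)
threshold_percent <- function(fit) {
  thr <- fit$thresholds
  units <- fit$config$attributes$units[match(thr$attribute,
                                             fit$config$attributes$name)]
  stats::setNames(ifelse(units == "proportion", 100 * thr$threshold,
                         thr$threshold), thr$attribute)
}
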