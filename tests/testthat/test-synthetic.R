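test_that("degenerate specs produce identical respondents at the means", {
  spec <- panel_spec(n_respondents = 8,
                     mir_sd = matrix(0, 6, 2,
                                     dimnames = list(names(default_max_change()),
                                                     c("under60", "ge60"))),
                     missingness = NULL, straight_liner_fraction = 0)
  gp <- generate_panel(spec, seed = 1)
  expect_equal(nrow(gp$panel), 8 * 6)
  for (a in names(default_max_change())) {
    for (g in c("under60", "ge60")) {
      sub <- gp$panel[gp$panel$attribute == a & gp$panel$age_group == g, ]
      if (nrow(sub)) expect_true(all(sub$mir == spec$mir_mean[a, g]))
    }
  }
  expect_true(all(!gp$panel$censored))
  expect_true(all(!gp$panel$straight_liner))
})

test_that("infeasible latent means are rejected with the offending cells", {
  mm <- panel_spec()$mir_mean
  mm["mortality", "under60"] <- 0.5  # beyond max_change of 0.12
  expect_error(panel_spec(mir_mean = mm), "mortality/under60")
  expect_error(panel_spec(straight_liner_fraction = 2), "straight_liner")
})

test_that("large panels recover the specified group means within 3 SE", {
  spec <- panel_spec(n_respondents = 2000)
  gp <- generate_panel(spec, seed = 42)
  s <- panel_summary(gp$panel, tavr_savr_attributes(),
                     groups = c("under60", "ge60"))
  z <- vapply(seq_len(nrow(s)), function(i)
    (s$mean[i] - spec$mir_mean[s$attribute[i], s$group[i]]) /
      (s$sd[i] / sqrt(s$n[i])), numeric(1))
  # 12 attribute-by-group cells: allow the single ~3-sigma excursion a
  # correctly calibrated generator produces at this multiplicity
  expect_true(all(abs(z) < 4))
  expect_lte(sum(abs(z) >= 3), 1)
  expect_lt(abs(mean(z)), 1)
})

test_that("planted straight-liners are all recovered from deterministic choice logs", {
  spec <- panel_spec(n_respondents = 2000)
  gp <- generate_panel(spec, seed = 77)
  planted <- tapply(gp$panel$straight_liner, gp$panel$respondent_id, any)
  frac <- mean(planted)
  expect_lt(abs(frac - 0.0868), 3 * sqrt(0.0868 * (1 - 0.0868) / 2000))
  logs <- generate_choice_logs(gp$truth, spec, seed = 78)
  lads <- lapply(names(spec$max_change),
                 function(a) asw_ladder(a, spec$max_change[[a]]))
  names(lads) <- names(spec$max_change)
  pan <- elicit_panel(logs, lads)
  recovered <- tapply(pan$straight_liner, pan$respondent_id, any)
  ids <- names(planted)[planted]
  expect_true(all(recovered[ids]))         # no false negatives by design
  # false positives (genuine latents in the outer grid intervals) are few
  expect_lt(mean(recovered) - frac, 0.06)
})

test_that("interior zero-spread latents never straight-line", {
  spec <- panel_spec(n_respondents = 30, straight_liner_fraction = 0,
                     mir_sd = matrix(0, 6, 2,
                                     dimnames = list(names(default_max_change()),
                                                     c("under60", "ge60"))),
                     missingness = NULL)
  gp <- generate_panel(spec, seed = 5)
  logs <- generate_choice_logs(gp$truth, spec, seed = 6)
  lads <- lapply(names(spec$max_change),
                 function(a) asw_ladder(a, spec$max_change[[a]]))
  names(lads) <- names(spec$max_change)
  pan <- elicit_panel(logs, lads)
  expect_true(all(!pan$straight_liner))
})

test_that("choice logs are reproducible and round-trip within one grid interval", {
  spec <- panel_spec(n_respondents = 50, straight_liner_fraction = 0,
                     missingness = NULL)
  gp <- generate_panel(spec, seed = 9)
  logs1 <- generate_choice_logs(gp$truth, spec, seed = 9)
  logs2 <- generate_choice_logs(gp$truth, spec, seed = 9)
  expect_identical(logs1, logs2)
  lads <- lapply(names(spec$max_change),
                 function(a) asw_ladder(a, spec$max_change[[a]]))
  names(lads) <- names(spec$max_change)
  pan <- elicit_panel(logs1, lads)
  merged <- merge(pan, gp$truth, by = c("respondent_id", "attribute"))
  err <- abs(merged$mir - merged$latent)
  expect_true(all(err <= spec$max_change[merged$attribute] / 8 + 1e-12))
  uncens <- !merged$censored
  expect_true(all(err[uncens] <=
                    spec$max_change[merged$attribute][uncens] / 16 + 1e-12))
  # logistic error with a large scale still stays on the ladder grid
  spec2 <- panel_spec(n_respondents = 20, straight_liner_fraction = 0,
                      missingness = NULL, error_model = "logistic",
                      logistic_scale = 0.5)
  gp2 <- generate_panel(spec2, seed = 12)
  pan2 <- elicit_panel(generate_choice_logs(gp2$truth, spec2, seed = 13), lads)
  expect_true(all(pan2$mir > 0 & pan2$mir <= spec2$max_change[pan2$attribute]))
})

test_that("elicited thresholds match latent-mean thresholds within the propagated grid resolution", {
  cfg <- tavr_savr_config()
  spec <- panel_spec(n_respondents = 600, straight_liner_fraction = 0,
                     missingness = NULL)
  gp <- generate_panel(spec, seed = 21)
  logs <- generate_choice_logs(gp$truth, spec, seed = 22)
  lads <- lapply(names(spec$max_change),
                 function(a) asw_ladder(a, spec$max_change[[a]]))
  names(lads) <- names(spec$max_change)
  pan <- elicit_panel(logs, lads)
  latent_means <- tapply(gp$truth$latent[gp$truth$observed],
                         gp$truth$attribute[gp$truth$observed], mean)
  elicited_means <- tapply(pan$mir, pan$attribute, mean)
  thr_of <- function(means)
    threshold_table(cfg, mir_weights(means[names(spec$max_change)],
                                     cfg$attributes))$threshold
  base <- thr_of(latent_means)
  elic <- thr_of(elicited_means)
  # first-order propagation of a one-grid-interval (max/8) shift per mean
  bound <- rep(0, length(base))
  for (a in names(spec$max_change)) {
    pert <- latent_means
    pert[a] <- pert[a] + spec$max_change[[a]] / 8
    bound <- bound + abs(thr_of(pert) - base)
  }
  expect_true(all(abs(elic - base) <= bound + 1e-9))
})

test_that("default-condition panels reproduce the published whole-sample thresholds within 1pp", {
  cfg <- tavr_savr_config()
  gp <- generate_panel(panel_spec(n_respondents = 2000), seed = 42)
  fit <- bra(cfg, panel = gp$panel, group = "all")
  got <- threshold_percent(fit)
  published <- c(mortality = 12.6, stroke = 20.7, independence = 6.5,
                 pacemaker = 33.0, dialysis = 21.6, proven = 0)
  expect_true(all(abs(got[names(published)] - published) < 1))
})
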