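test_that("offers follow the dyadic bisection ladder", {
  lad <- asw_ladder("riskA", max_change = 8)
  expect_equal(next_offer(lad), 4)                        # midpoint opener
  expect_equal(next_offer(lad, TRUE), 6)                  # chose procedure
  expect_equal(next_offer(lad, FALSE), 2)                 # chose attribute
  expect_equal(next_offer(lad, c(TRUE, FALSE)), 5)
  expect_error(next_offer(lad, c(TRUE, TRUE, TRUE)), "three iterations")
  # exhaustive: all 8 paths only visit levels on the k * max/8 grid
  for (p in 0:7) {
    resp <- as.logical(bitwAnd(p, c(4, 2, 1)) > 0)
    offers <- c(next_offer(lad), next_offer(lad, resp[1]),
                next_offer(lad, resp[1:2]))
    expect_true(all(offers %% 1 == 0))
    expect_true(all(offers > 0 & offers <= 8))
  }
})

test_that("the 8 response patterns partition (0, max] into width-max/8 intervals", {
  lad <- asw_ladder("riskA", max_change = 8)
  ivs <- t(sapply(0:7, function(p) {
    resp <- as.logical(bitwAnd(p, c(4, 2, 1)) > 0)
    estimate_indifference(lad, resp)$interval
  }))
  ord <- order(ivs[, 1])
  expect_equal(ivs[ord, 1], seq(0, 7))          # adjacent lows 0..7
  expect_equal(ivs[ord, 2] - ivs[ord, 1], rep(1, 8))  # width max/8
  # censoring at the boundary patterns
  at_min <- estimate_indifference(lad, c(FALSE, FALSE, FALSE))
  expect_identical(at_min$censored, "at_min")
  expect_equal(at_min$point, 0.5)               # smallest interval midpoint
  at_max <- estimate_indifference(lad, c(TRUE, TRUE, TRUE))
  expect_identical(at_max$censored, "at_max")
  expect_equal(at_max$point, 8)
  mid <- estimate_indifference(lad, c(TRUE, FALSE, TRUE))
  expect_identical(mid$censored, "none")
  expect_equal(mid$point, mean(mid$interval))
  expect_error(estimate_indifference(lad, c(TRUE, FALSE)), "three responses")
})

test_that("deterministic respondents are localised to the interval holding their latent", {
  lad <- asw_ladder("riskA", max_change = 8)
  for (latent in seq(0.05, 7.95, by = 0.1)) {
    resp <- run_ladder(lad, function(offer)
      simulate_response(latent, offer))$chose_procedure
    est <- estimate_indifference(lad, resp)
    if (est$censored == "none") {
      expect_true(latent > est$interval[1] && latent <= est$interval[2])
      expect_lte(abs(est$point - latent), 8 / 16)
    } else {
      # boundary patterns only fire for latents in the outer intervals
      expect_lte(abs(est$point - latent), 8 / 8)
    }
  }
  # the worked case: latent 3.1 lands in an interval containing it
  est <- estimate_indifference(lad, run_ladder(lad, function(o)
    simulate_response(3.1, o))$chose_procedure)
  expect_true(est$interval[1] < 3.1 && 3.1 <= est$interval[2])
  expect_lte(abs(est$point - 3.1), 0.5)
})

test_that("indifference estimation is invariant to attribute units", {
  for (scale in c(0.01, 1, 250)) {
    lad1 <- asw_ladder("a", max_change = 8)
    lad2 <- asw_ladder("a", max_change = 8 * scale)
    for (latent in c(0.7, 3.1, 6.9)) {
      r1 <- run_ladder(lad1, function(o) simulate_response(latent, o))
      r2 <- run_ladder(lad2, function(o) simulate_response(latent * scale, o))
      expect_equal(r1$chose_procedure, r2$chose_procedure)
      e1 <- estimate_indifference(lad1, r1$chose_procedure)
      e2 <- estimate_indifference(lad2, r2$chose_procedure)
      expect_equal(e2$point, e1$point * scale, tolerance = 1e-12)
    }
  }
})

test_that("simulated choices compare offer against the latent indifference point", {
  expect_false(simulate_response(5, 6))  # offer worth more: chose attribute
  expect_true(simulate_response(5, 4))   # offer too small: chose procedure
  # logistic model converges to the deterministic rule as scale -> 0
  set.seed(1)
  draws <- replicate(200, simulate_response(5, 5.01, "logistic", scale = 1e-6))
  expect_true(all(!draws))
  draws2 <- replicate(200, simulate_response(5, 4.99, "logistic", scale = 1e-6))
  expect_true(all(draws2))
  # at huge scale choices are near-coin-flips
  set.seed(2)
  p <- mean(replicate(500, simulate_response(5, 1, "logistic", scale = 1e6)))
  expect_gt(p, 0.4); expect_lt(p, 0.6)
  expect_error(simulate_response(5, 4, "logistic", scale = 0), "positive scale")
})

test_that("straight-liners are respondents whose every exercise is one-sided", {
  allp <- c(TRUE, TRUE, TRUE)
  alla <- c(FALSE, FALSE, FALSE)
  mixed <- c(TRUE, FALSE, TRUE)
  expect_true(classify_straight_liner(list(allp, allp)))
  expect_true(classify_straight_liner(list(allp, alla)))  # side may differ
  expect_false(classify_straight_liner(list(allp, mixed)))
  expect_false(classify_straight_liner(list(mixed)))
  expect_error(classify_straight_liner(list()), "no completed exercises")
})

test_that("choice logs replay into a panel with straight-liner flags", {
  lads <- list(riskA = asw_ladder("riskA", 8), benB = asw_ladder("benB", 4))
  logs <- rbind(
    data.frame(respondent_id = "r1", attribute = "riskA", iteration = 1:3,
               offered_change = c(4, 2, 3), chose_procedure = c(FALSE, TRUE, FALSE)),
    data.frame(respondent_id = "r1", attribute = "benB", iteration = 1:3,
               offered_change = c(2, 3, 3.5), chose_procedure = c(TRUE, TRUE, TRUE)),
    data.frame(respondent_id = "r2", attribute = "riskA", iteration = 1:3,
               offered_change = c(4, 6, 7), chose_procedure = c(TRUE, TRUE, TRUE))
  )
  pan <- elicit_panel(logs, lads, age_groups = c(r1 = "under60", r2 = "ge60"))
  expect_equal(nrow(pan), 3)
  r1a <- pan[pan$respondent_id == "r1" & pan$attribute == "riskA", ]
  expect_equal(r1a$mir, 2.5)        # pattern FTF -> interval (2,3]
  expect_false(r1a$straight_liner)
  expect_true(pan$censored[pan$respondent_id == "r1" & pan$attribute == "benB"])
  expect_true(all(pan$straight_liner[pan$respondent_id == "r2"]))
  expect_equal(pan$age_group[pan$respondent_id == "r2"], "ge60")
  expect_error(elicit_panel(logs, lads["riskA"]), "no ladder")
})
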