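test_that("partial value anchors at 0/1 and is linear between them", {
  attrs <- tavr_savr_attributes()
  for (a in attrs$name) {
    row <- attr_row(attrs, a)
    expect_identical(partial_value(row$worst, row), 0)
    expect_identical(partial_value(row$best, row), 1)
    # affine at interior points: v(worst + t*(best-worst)) == t
    for (t in c(0.2, 0.5, 0.9)) {
      lev <- row$worst + t * (row$best - row$worst)
      expect_equal(partial_value(lev, row), t, tolerance = 1e-12)
    }
  }
  m <- attr_row(attrs, "mortality")
  expect_equal(partial_value(0.011, m), (0.053 - 0.011) / 0.048)
  expect_equal(partial_value(0.011, m), 0.875)
  expect_error(partial_value(0.08, m), "outside range")
  expect_silent(partial_value(0.08, m, strict = FALSE))
})

test_that("overall value reduces to a single weight at that attribute's best", {
  attrs <- toy_attributes()
  w <- c(procedure = 0, riskA = 3.5, benB = 0)
  prof <- c(procedure = 0, riskA = 0.10, benB = 0.10)  # riskA at best
  expect_equal(overall_value(prof, w, attrs), 3.5)
  # symmetry: identical profiles give identical U under any weights
  set.seed(11)
  for (i in 1:5) {
    w2 <- random_weights(attrs)
    p <- c(procedure = 1, riskA = runif(1, 0.1, 0.5), benB = runif(1, 0.1, 0.9))
    expect_identical(overall_value(p, w2, attrs), overall_value(p, w2, attrs))
  }
  expect_error(overall_value(prof, c(riskA = 1), attrs), "no weight")
})

test_that("published performance and mean preferences give dU ~ 2.970", {
  # independent spreadsheet-style evaluation of the seven weighted partial
  # values, kept free of the package's model functions
  mir <- c(mortality = 0.0386, stroke = 0.0669, independence = 0.1394,
           pacemaker = 0.0698, dialysis = 0.0621, proven = 17.42)
  width <- c(mortality = 0.048, stroke = 0.042, independence = 0.273,
             pacemaker = 0.070, dialysis = 0.039, proven = 25)
  w <- width / mir
  dv <- c(mortality = (0.040 - 0.011) / 0.048,
          stroke = (0.033 - 0.008) / 0.042,
          independence = (0.479 - 0.249) / 0.273,
          pacemaker = (0.090 - 0.123) / 0.070,
          dialysis = (0.047 - 0.032) / 0.039,
          proven = (10 - 20) / 25)
  expected <- sum(w * dv) + 1  # + procedure anchor swing
  fit <- tavr_whole_fit()
  expect_equal(fit$decomposition$overall_increment, expected, tolerance = 1e-12)
  expect_equal(expected, 2.970, tolerance = 3e-4)
  # the procedure increment is the anchor weight times the full swing
  expect_equal(fit$decomposition$per_attribute[["procedure"]], 1)
})

test_that("value decomposition sums to the overall increment", {
  set.seed(42)
  for (i in 1:20) {
    cfg <- random_config(k = sample(2:6, 1))
    w <- random_weights(cfg$attributes)
    dec <- incremental_value(profile_levels(cfg, "NEW"),
                             profile_levels(cfg, "OLD"), w, cfg$attributes)
    expect_equal(sum(dec$per_attribute), dec$overall_increment,
                 tolerance = 1e-9)
  }
  # equal profiles decompose to zeros
  cfg <- toy_config()
  dec0 <- incremental_value(profile_levels(cfg, "NEW"),
                            profile_levels(cfg, "NEW"),
                            random_weights(cfg$attributes), cfg$attributes)
  expect_equal(unname(dec0$per_attribute), rep(0, 3))
  expect_equal(dec0$overall_increment, 0)
})

test_that("unclamped thresholds restore exact indifference", {
  set.seed(99)
  for (i in 1:20) {
    cfg <- random_config(k = sample(2:5, 1))
    w <- random_weights(cfg$attributes)
    pa <- profile_levels(cfg, "NEW")
    pb <- profile_levels(cfg, "OLD")
    for (a in cfg$attributes$name[-1]) {
      thr <- threshold(a, pa, pb, w, cfg$attributes, clamp = FALSE)
      pa2 <- pa
      pa2[a] <- thr$raw
      u_new <- overall_value(pa2, w, cfg$attributes, strict = FALSE)
      u_old <- overall_value(pb, w, cfg$attributes, strict = FALSE)
      expect_equal(u_new, u_old, tolerance = 1e-9)
    }
  }
})

test_that("thresholds are invariant to weight normalisation", {
  cfg <- tavr_savr_config()
  w <- mir_weights(reference_mir("whole"), cfg$attributes)
  raw <- threshold_table(cfg, w)
  scaled <- threshold_table(cfg, w$normalized)          # sum-100 scale
  arbitrary <- threshold_table(cfg, w$raw * 17.3)        # any positive scale
  expect_equal(raw$threshold, scaled$threshold, tolerance = 1e-9)
  expect_equal(raw$threshold, arbitrary$threshold, tolerance = 1e-9)
})

test_that("growing the value increment moves every threshold toward worse levels", {
  set.seed(7)
  for (i in 1:10) {
    cfg <- random_config(k = 4)
    w <- random_weights(cfg$attributes)
    pa <- profile_levels(cfg, "NEW")
    pb <- profile_levels(cfg, "OLD")
    # degrade the comparator on the anchor swing => larger increment
    pb2 <- pb
    pb2["procedure"] <- -0.5
    for (a in cfg$attributes$name[-1]) {
      t1 <- threshold(a, pa, pb, w, cfg$attributes, clamp = FALSE)
      t2 <- threshold(a, pa, pb2, w, cfg$attributes, clamp = FALSE)
      if (t1$kind == "MAR") expect_gte(t2$raw, t1$raw)
      else expect_lte(t2$raw, t1$raw)
    }
  }
})

test_that("threshold edge cases: equal values, clamping, zero weight", {
  cfg <- tavr_savr_config()
  attrs <- cfg$attributes
  w <- mir_weights(reference_mir("whole"), attrs)
  pa <- profile_levels(cfg, "TAVR")
  # equal overall values => threshold at current performance exactly
  t0 <- threshold("mortality", pa, pa, w, attrs)
  expect_equal(t0$threshold, pa[["mortality"]])
  expect_false(t0$clamped)
  # proven-to-work floors at zero years with the raw value retained
  tp <- threshold("proven", pa, profile_levels(cfg, "SAVR"), w, attrs)
  expect_equal(tp$threshold, 0)
  expect_true(tp$clamped)
  expect_lt(tp$raw, 0)
  expect_equal(tp$clamp_bound, 0)
  expect_identical(tp$kind, "MAB")
  # zero weight is undefined
  w0 <- w$raw
  w0["mortality"] <- 0
  expect_error(threshold("mortality", pa, pa, w0, attrs), "zero or missing")
})
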