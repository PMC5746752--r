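test_that("specific clearance and USL back-calculation follow their algebra", {
  expect_equal(specific_clearance(2, 1), 2)
  expect_equal(specific_clearance(3.7, 3.7), 1)
  expect_error(specific_clearance(3, 0), "> 0")
  expect_error(specific_clearance(-1, 2), ">= 0")

  expect_equal(threshold_from_usl(1, c(2, 0.5)), 1)
  expect_equal(threshold_from_usl(0.1, c(3, 3)), 0.9)
  # invariant under permutation of the clearance chain
  sc <- c(1.7, 0.4, 2.9, 1.1)
  expect_equal(threshold_from_usl(0.2, sc), threshold_from_usl(0.2, rev(sc)))
  expect_error(threshold_from_usl(1, numeric(0)), "at least one clearance")
  expect_error(cqa_spec("q", usl_ds = 1, threshold_direct = 2),
               "exactly one")
})

test_that("set-point critical gap is directional and errors past threshold", {
  expect_equal(critical_gap_setpoint(1, 0.4, "upper")$value, 0.6)
  expect_equal(critical_gap_setpoint(0.4, 1, "lower")$value, 0.6)
  expect_error(critical_gap_setpoint(0.4, 1, "upper"), "beyond")
  cg <- critical_gap_setpoint(cqa_spec("q", threshold_direct = 1), 0.4)
  expect_s3_class(cg, "critical_gap")
  expect_equal(cg$basis, "set_point")
})

test_that("critical effect implements the weighted-gap-over-NOR formula", {
  expect_equal(critical_effect(1, 2, factor_specs("x")), 2)
  expect_equal(critical_effect(0.5, 2, factor_specs("x", nor_low = -0.5,
                                                    nor_high = 1.1)),
               0.5 * 2 / 1.1)
  expect_equal(critical_effect(0, 2, factor_specs("x")), 0)
  expect_error(critical_effect(1.5, 2, factor_specs("x")), "\\[0, 1\\]")
  # linear in w and in CG; halving a centered NOR doubles the effect
  f <- factor_specs("x", nor_low = -0.8, nor_high = 0.8)
  for (w in c(0.1, 0.4, 0.9)) {
    expect_equal(critical_effect(w, 3, f), w * critical_effect(1, 3, f))
    expect_equal(critical_effect(w, 6, f), 2 * critical_effect(w, 3, f))
  }
  expect_equal(critical_effect(0.3, 1, shrink_nor(f, "x", 0.5)),
               2 * critical_effect(0.3, 1, f))
})

test_that("worst-case prediction matches a dense grid oracle", {
  f2 <- factor_specs(c("A", "B"), nor_low = c(-1.1, -0.5),
                     nor_high = c(0.6, 1.1))
  d <- generate_dsd(4)[, 1:2]
  colnames(d) <- c("A", "B")
  d <- design_matrix(d, f2)

  # additive linear: attained at the sign-matched vertex
  set.seed(1)
  y <- drop(as.matrix(d) %*% c(0.8, -0.5)) + rnorm(nrow(d), 0, 0.01)
  fit <- fit_terms(d, y, build_candidates(f2, include_quadratic = FALSE))
  wc <- worst_case_prediction(fit, f2, "upper")
  expect_equal(unname(wc$location), c(0.6, -0.5), tolerance = 1e-9)
  oracle <- grid_worst_case(fit, f2, "upper")
  expect_equal(wc$value, oracle$value, tolerance = 1e-6)

  # quadratic term: interior per-coordinate optimum
  y2 <- 0.2 + 0.3 * d[, "A"] - 0.9 * d[, "A"]^2 + 0.4 * d[, "B"]
  fit2 <- fit_terms(d, y2, terms_for(c("A", "A^2", "B")))
  wc2 <- worst_case_prediction(fit2, f2, "upper")
  or2 <- grid_worst_case(fit2, f2, "upper", step = 0.001)
  expect_equal(wc2$value, or2$value, tolerance = 1e-4)
  expect_equal(wc2$location[["A"]], 0.3 / (2 * 0.9), tolerance = 1e-6)

  # interaction model against the grid oracle, both directions
  y3 <- 0.1 - 0.2 * d[, "A"] + 0.5 * d[, "B"] - 0.7 * d[, "A"] * d[, "B"]
  fit3 <- fit_terms(d, y3, terms_for(c("A", "B", "A:B")))
  for (dir in c("upper", "lower")) {
    wc3 <- worst_case_prediction(fit3, f2, dir)
    or3 <- grid_worst_case(fit3, f2, dir)
    expect_equal(wc3$value, or3$value, tolerance = 1e-6)
  }
})

test_that("3-factor mixed model still agrees with the grid oracle", {
  f3 <- factor_specs(c("A", "B", "C"), nor_low = c(-1, -0.6, -0.9),
                     nor_high = c(0.8, 1, 0.9))
  m <- as.matrix(generate_dsd(4))[, 1:3]
  colnames(m) <- c("A", "B", "C")
  d <- design_matrix(m, f3)
  y <- 0.3 * d[, "A"] - 0.6 * d[, "A"]^2 + 0.5 * d[, "B"] * d[, "C"] -
    0.2 * d[, "C"]
  fit <- fit_terms(d, y, terms_for(c("A", "A^2", "B:C", "C")))
  for (dir in c("upper", "lower")) {
    wc <- worst_case_prediction(fit, f3, dir)
    or <- grid_worst_case(fit, f3, dir, step = 0.02)
    expect_true(if (dir == "upper") wc$value >= or$value - 1e-9
                else wc$value <= or$value + 1e-9)
    expect_equal(wc$value, or$value, tolerance = 1e-3)
  }
})

test_that("worst-case critical gap behaves like the set-point gap", {
  d <- generate_dsd(4)
  f <- design_factors(d)
  fit0 <- stepwise_select(d, rep(0.4, nrow(d)), build_candidates(f))
  # intercept-only model: gap is threshold - intercept
  cg <- critical_gap_worstcase(1, fit0, f)
  expect_equal(cg$value, 1 - fit0$intercept, tolerance = 1e-6)
  expect_equal(cg$basis, "worst_case")
  expect_error(critical_gap_worstcase(0.39, fit0, f), "beyond")

  # shrinking a modelled factor's NOR strictly increases the gap
  y2 <- 0.2 + 0.6 * d[, "X1"] + rnorm(nrow(d), 0, 1e-6)
  set.seed(2)
  fit1 <- stepwise_select(d, y2, build_candidates(f))
  expect_true("X1" %in% names(fit1$coefficients))
  cg_full <- critical_gap_worstcase(1.5, fit1, f)
  cg_tight <- critical_gap_worstcase(1.5, fit1, shrink_nor(f, "X1", 0.5))
  expect_gt(cg_tight$value, cg_full$value)
})
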