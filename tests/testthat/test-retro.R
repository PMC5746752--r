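test_that("residual permutation conserves the multiset and is uniform", {
  res <- c(0.3, -0.1, 0.5, -0.7, 0.05)
  set.seed(1)
  for (i in 1:20) expect_equal(sort(permute_residuals(res)), sort(res))
  set.seed(10)
  a <- permute_residuals(res)
  set.seed(10)
  expect_identical(permute_residuals(res), a)
  # frequency audit: each value lands on each position ~ 1/n of the time
  set.seed(2)
  n <- 4
  vals <- c(1, 2, 3, 4)
  counts <- matrix(0, n, n)
  for (i in seq_len(10000)) {
    p <- permute_residuals(vals)
    counts[cbind(seq_len(n), p)] <- counts[cbind(seq_len(n), p)] + 1
  }
  expect_true(all(abs(counts / 10000 - 1 / n) < 0.02))
})

test_that("synthesized alternative responses evaluate the model identity", {
  X_s <- matrix(c(1, -1, 1, -1), 4, 1, dimnames = list(NULL, "A"))
  Z <- matrix(c(1, 1, -1, -1, 0, 1, 0, -1), 4, 2,
              dimnames = list(NULL, c("B", "C")))
  r <- c(0.1, -0.2, 0.05, 0.05)
  # hand evaluation on a 4-run toy design
  got <- synthesize_alternative(2, 0.5, X_s, c(0.3, -0.4), Z, r)
  expect_equal(got, c(2 + 0.5 + 0.3 + 0.1,
                      2 - 0.5 + 0.3 - 0.4 - 0.2,
                      2 + 0.5 - 0.3 + 0.05,
                      2 - 0.5 - 0.3 + 0.4 + 0.05))
  # zero critical effects: permuted-residual version of the fitted values
  expect_equal(synthesize_alternative(2, 0.5, X_s, c(0, 0), Z, r),
               2 + 0.5 * drop(X_s) + r)
  # zero residuals: exact injected-effect prediction
  expect_equal(synthesize_alternative(0, numeric(0),
                                      matrix(nrow = 4, ncol = 0),
                                      c(1, 0), Z, rep(0, 4)),
               drop(Z %*% c(1, 0)))
  expect_error(synthesize_alternative(0, 1, X_s, c(1, 2, 3), Z, r),
               "beta_crit")
})

test_that("assess_significance matches a closed-form OLS oracle", {
  d <- as.matrix(generate_dsd(4))[1:8, ]  # 8-run toy design
  X_s <- d[, 1, drop = FALSE]
  Z <- d[, 2:4]
  set.seed(5)
  y <- 0.3 + 0.8 * X_s[, 1] + 1.2 * Z[, 1] + rnorm(8, 0, 0.2)
  got <- assess_significance(y, X_s, Z, alpha = 0.05)
  cf <- summary(lm(y ~ ., data = data.frame(y = y, X_s, Z)))$coefficients
  pz <- cf[3:5, "Pr(>|t|)"]
  expect_equal(unname(attr(got, "p_values")), unname(pz), tolerance = 1e-10)
  expect_equal(as.logical(got), unname(pz < 0.05))
  # an injected effect far above the residual scale is always detected
  y2 <- drop(Z %*% c(50, 0, 0)) + rnorm(8, 0, 0.1)
  expect_true(assess_significance(y2, matrix(nrow = 8, ncol = 0), Z)[["X2"]])
  # rank deficiency is reported with the offending column
  Zbad <- cbind(Z, X2_copy = Z[, 1])
  expect_error(assess_significance(y, X_s, Zbad, 0.05), "X2_copy")
})

test_that("retrospective power is seeded-deterministic and sensible", {
  sc <- scenario_cc1_like(seed = 3)
  st <- simulate_study(sc)
  f <- attr(sc$design, "factors")
  fit <- stepwise_select(sc$design, st$response, build_candidates(f))
  cfg <- retro_config(n_iterations = 150, step_count = 8, rng_seed = 11)
  r1 <- retrospective_power(sc$design, st$response, f, sc$threshold, fit,
                            cfg)
  r2 <- retrospective_power(sc$design, st$response, f, sc$threshold, fit,
                            cfg)
  expect_identical(r1$per_parameter_power, r2$per_parameter_power)
  expect_identical(r1$per_combination, r2$per_combination)
  expect_true(all(r1$per_parameter_power >= 0 &
                    r1$per_parameter_power <= 1))
  expect_equal(r1$cg_used$basis, "worst_case")
  # a different seed moves estimates only within Monte-Carlo error
  r3 <- retrospective_power(sc$design, st$response, f, sc$threshold, fit,
                            retro_config(n_iterations = 150, step_count = 8,
                                         rng_seed = 12))
  expect_true(all(abs(r3$per_parameter_power - r1$per_parameter_power)
                  < 0.15))
  # sampled strategy: same estimand, coarser accounting
  r4 <- retrospective_power(sc$design, st$response, f, sc$threshold, fit,
                            retro_config(n_iterations = 2000,
                                         step_count = 8, rng_seed = 11,
                                         combination_strategy = "sampled"))
  expect_true(all(abs(r4$per_parameter_power - r1$per_parameter_power)
                  < 0.2))
})

test_that("power grows with the critical gap", {
  st <- fixture_study(seed = 21, beta = c(X1 = 0, X2 = 0, X3 = 0, X4 = 0,
                                          X5 = 0), sigma = 0.3)
  f <- design_factors(st$design)
  fit <- stepwise_select(st$design, st$y, build_candidates(f))
  cfg <- retro_config(n_iterations = 200, step_count = 6, rng_seed = 5)
  thresholds <- c(0.8, 1.6, 3.2)  # larger threshold => larger CG
  powers <- sapply(thresholds, function(th)
    mean(retrospective_power(st$design, st$y, f, th, fit,
                             cfg)$per_parameter_power))
  expect_true(all(diff(powers) > 0))
})

test_that("a model involving every factor leaves nothing to assess", {
  d <- generate_dsd(4)
  f <- design_factors(d)
  y <- drop(as.matrix(d) %*% c(4, 2, 1, 0.5))
  fit <- stepwise_select(d, y, build_candidates(f))
  expect_message(
    r <- retrospective_power(d, y, f, 100, fit, retro_config()),
    "nothing to assess")
  expect_length(r$per_parameter_power, 0)
})

test_that("NOR scans reproduce the tightening phenomenology", {
  sc <- scenario_cc1_like(seed = 3)
  st <- simulate_study(sc)
  f <- attr(sc$design, "factors")
  fit <- stepwise_select(sc$design, st$response, build_candidates(f))
  nonsig <- setdiff(f$name, unique(unlist(lapply(fit$terms, `[[`,
                                                 "factors"))))
  target <- nonsig[1]
  cfg <- retro_config(n_iterations = 150, step_count = 8, rng_seed = 7)
  scan <- nor_scan(sc$design, st$response, f, sc$threshold, fit, cfg,
                   target_factor = target, shrink_fractions = c(0, 0.5))
  base <- retrospective_power(sc$design, st$response, f, sc$threshold,
                              fit, cfg)
  # shrink 0 is bit-identical to the baseline
  expect_identical(scan$results[[1]]$per_parameter_power,
                   base$per_parameter_power)
  # shrinking a NON-significant target raises only that parameter's power
  expect_gt(scan$summary[2, target], scan$summary[1, target])
  others <- setdiff(nonsig, target)
  expect_equal(unlist(scan$summary[2, others]),
               unlist(scan$summary[1, others]), tolerance = 1e-12)
  expect_error(nor_scan(sc$design, st$response, f, sc$threshold, fit, cfg,
                        target_factor = target, shrink_fractions = 1),
               "\\[0, 1\\)")
})
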