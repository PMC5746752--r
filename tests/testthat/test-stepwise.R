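test_that("candidate term lists are deterministic and typed", {
  f5 <- default_factors(5)
  expect_length(build_candidates(f5), 10)  # 5 main + 5 quadratic
  f4 <- factor_specs(c("a", "b", "c", "mix"),
                     kind = c("numeric", "numeric", "numeric",
                              "categorical2"))
  expect_message(cands <- build_candidates(f4), "categorical2")
  expect_length(cands, 7)  # 4 main + 3 quadratic
  cands3 <- build_candidates(default_factors(3)[1:3, ],
                             include_interactions = TRUE)
  expect_length(cands3, 9)  # 3 main + 3 quadratic + 3 interactions
  labels <- vapply(cands3, `[[`, character(1), "label")
  expect_equal(labels, c("X1", "X2", "X3", "X1^2", "X2^2", "X3^2",
                         "X1:X2", "X1:X3", "X2:X3"))
})

test_that("noiseless single signal is recovered exactly", {
  d <- generate_dsd(5)
  y <- 3 * d[, "X1"]
  fit <- stepwise_select(d, y, build_candidates(design_factors(d)))
  expect_equal(names(fit$coefficients), "X1")
  expect_equal(unname(fit$coefficients), 3, tolerance = 1e-10)
  expect_lt(fit$p_values[["X1"]], 1e-12)
  expect_equal(fit$sigma_residues, 0, tolerance = 1e-10)
})

test_that("constant response yields the intercept-only model", {
  d <- generate_dsd(4)
  fit <- stepwise_select(d, rep(2.5, nrow(d)),
                         build_candidates(design_factors(d)))
  expect_length(fit$terms, 0)
  expect_equal(fit$intercept, 2.5)
  expect_equal(fit$fitted, rep(2.5, nrow(d)))
})

test_that("selection path matches a hand-traced lm() oracle", {
  st <- fixture_study(seed = 42)
  cands <- build_candidates(design_factors(st$design))
  fit <- stepwise_select(st$design, st$y, cands)
  cols <- dsdpower:::term_columns(cands, as.matrix(st$design))
  oracle <- trace_stepwise_lm(as.matrix(st$design), st$y, cols)
  got_log <- paste0(fit$trace$action, ":", fit$trace$term)
  expect_equal(got_log, oracle$log)
  expect_setequal(names(fit$coefficients), oracle$selected)

  # a second fixture with correlated noise exercises enter-then-exit paths
  st2 <- fixture_study(seed = 7, beta = c(X1 = 0.4, X2 = 0.35, X3 = 0.1,
                                          X4 = 0, X5 = 0), sigma = 0.15)
  fit2 <- stepwise_select(st2$design, st2$y, cands)
  oracle2 <- trace_stepwise_lm(as.matrix(st2$design), st2$y, cols)
  expect_equal(paste0(fit2$trace$action, ":", fit2$trace$term), oracle2$log)
})

test_that("selected models obey the enter/exit p-value contract", {
  for (seed in 1:5) {
    st <- fixture_study(seed = seed, beta = c(X1 = 0.4, X2 = 0.2, X3 = 0.1,
                                              X4 = 0, X5 = 0), sigma = 0.12)
    fit <- stepwise_select(st$design, st$y,
                           build_candidates(design_factors(st$design)))
    if (length(fit$p_values))
      expect_true(all(fit$p_values <= 0.10 + 1e-12))
    entered <- fit$trace[fit$trace$action == "enter", ]
    expect_true(all(entered$p_value < 0.05))
    # residuals of a least-squares fit with intercept sum to zero
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  }
})

test_that("refitting the final term set reproduces the coefficients", {
  st <- fixture_study(seed = 11, beta = c(X1 = 0.5, X2 = 0.3, X3 = 0,
                                          X4 = 0, X5 = 0), sigma = 0.1)
  fit <- stepwise_select(st$design, st$y,
                         build_candidates(design_factors(st$design)))
  refit <- fit_terms(st$design, st$y, fit$terms)
  expect_equal(refit$coefficients[names(fit$coefficients)],
               fit$coefficients, tolerance = 1e-10)
  expect_equal(refit$intercept, fit$intercept, tolerance = 1e-10)
})

test_that("residual sd uses raw residuals over n - 1, and ratios follow", {
  st <- fixture_study(seed = 3)
  fit <- stepwise_select(st$design, st$y,
                         build_candidates(design_factors(st$design)))
  expect_equal(fit$sigma_residues,
               sqrt(sum(fit$residuals^2) / (length(st$y) - 1)))
  sp <- set_point_sample(c(-0.1, 0.05, 0.02, -0.03, 0.06))
  expect_equal(residual_sd_ratio(fit, sp), fit$sigma_residues / sp$sd)
  q <- length(fit$terms)
  expect_equal(residual_sd_ratio(fit, sp, method = "ols"),
               sqrt(sum(fit$residuals^2) / (fit$n - q - 1)) / sp$sd)
  # zero residuals give ratio 0
  fitz <- stepwise_select(st$design, 2 * st$design[, "X2"],
                          build_candidates(design_factors(st$design)))
  expect_equal(residual_sd_ratio(fitz, sp), 0, tolerance = 1e-9)
})

test_that("perfectly collinear candidates are skipped with a notice", {
  d <- generate_dsd(4)
  f <- design_factors(d)
  dup <- c(build_candidates(f, include_quadratic = FALSE),
           list(dsdpower:::model_term("main", "X1")))
  y <- 1.2 * d[, "X1"] + rnorm(nrow(d), 0, 0.05)
  expect_message(fit <- stepwise_select(d, y, dup), "collinear")
  expect_equal(names(fit$coefficients), "X1")
})

test_that("predict() evaluates selected terms on new settings", {
  d <- generate_dsd(4)
  y <- 0.5 + 1.5 * d[, "X2"] - 0.8 * d[, "X3"]^2
  fit <- fit_terms(d, y, terms_for(c("X2", "X3^2")))
  new <- matrix(c(0.5, -0.5), 1, 2, dimnames = list(NULL, c("X2", "X3")))
  expect_equal(unname(predict(fit, new)), 0.5 + 1.5 * 0.5 - 0.8 * 0.25,
               tolerance = 1e-9)
  expect_error(predict(fit, matrix(1, 1, 1, dimnames = list(NULL, "X2"))),
               "missing factor")
})
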