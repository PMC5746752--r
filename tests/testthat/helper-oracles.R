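# Independent oracles used across the test suite. These re-derive expected
# values by brute force (grid search, plain loops over lm(), Monte-Carlo
# simulation) and deliberately share no code with the implementation paths
# they check.

# dense grid search for the extreme prediction of a doe_fit over the NOR box
grid_worst_case <- function(model, factors, direction = "upper",
                            step = 0.01) {
  grids <- lapply(seq_len(nrow(factors)), function(i)
    seq(factors$nor_low[i], factors$nor_high[i], by = step))
  pts <- as.matrix(expand.grid(grids))
  colnames(pts) <- factors$name
  preds <- predict(model, pts)
  i <- if (direction == "upper") which.max(preds) else which.min(preds)
  list(value = preds[i], location = pts[i, ])
}

# plain-loop forward/backward stepwise tracer built directly on lm();
# returns the ordered action log and the final term labels
trace_stepwise_lm <- function(X, y, cols, p_enter = 0.05, p_exit = 0.10) {
  selected <- character(0)
  log <- character(0)
  repeat {
    changed <- FALSE
    avail <- setdiff(colnames(cols), selected)
    if (length(avail) && length(y) - length(selected) - 3 >= 2) {
      ps <- sapply(avail, function(lbl) {
        d <- data.frame(y = y, cols[, c(selected, lbl), drop = FALSE],
                        check.names = FALSE)
        fit <- stats::lm(y ~ ., data = d)
        cf <- summary(fit)$coefficients
        if (nrow(cf) < length(selected) + 2) NA_real_
        else cf[nrow(cf), "Pr(>|t|)"]
      })
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < p_enter) {
        lbl <- avail[which.min(ps)]
        selected <- c(selected, lbl)
        log <- c(log, paste0("enter:", lbl))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      d <- data.frame(y = y, cols[, selected, drop = FALSE],
                      check.names = FALSE)
      cf <- summary(stats::lm(y ~ ., data = d))$coefficients
      ps <- cf[-1, "Pr(>|t|)"]
      if (max(ps) > p_exit) {
        k <- which.max(ps)
        log <- c(log, paste0("exit:", selected[k]))
        selected <- selected[-k]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(log = log, selected = selected)
}

# fully parametric Monte-Carlo power oracle: true model y = mu + Z beta + eps
# with Gaussian noise, refit by lm(), fraction of two-sided coefficient
# p-values below alpha, per Z column
parametric_power_oracle <- function(mu, Xs, Z, beta_z, sigma, alpha = 0.05,
                                    reps = 2000) {
  n <- length(mu)
  M <- cbind(Xs, Z)
  hits <- numeric(ncol(Z))
  for (r in seq_len(reps)) {
    y <- mu + drop(Z %*% beta_z) + rnorm(n, 0, sigma)
    d <- data.frame(y = y, M, check.names = FALSE)
    cf <- summary(stats::lm(y ~ ., data = d))$coefficients
    pz <- cf[(nrow(cf) - ncol(Z) + 1):nrow(cf), "Pr(>|t|)"]
    hits <- hits + (pz < alpha)
  }
  hits / reps
}

# build a model_terms list from term labels ("A", "A^2", "A:B")
terms_for <- function(labels) dsdpower:::terms_from_labels(labels, NULL)

# a small fixed 5-factor study used by several files: 13-run DSD plus a
# deterministic seeded response with one strong and one null block
fixture_study <- function(seed = 42, beta = c(X1 = 0.5, X2 = 0.2, X3 = 0,
                                              X4 = 0, X5 = 0),
                          sigma = 0.1) {
  design <- generate_dsd(5)
  set.seed(seed)
  y <- drop(as.matrix(design) %*% beta) + rnorm(nrow(design), 0, sigma)
  list(design = design, y = y, beta = beta, sigma = sigma)
}
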