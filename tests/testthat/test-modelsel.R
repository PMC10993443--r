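test_that("noise-free responses are fit exactly", {
  set.seed(1)
  X <- cbind(a = rnorm(50), b = rnorm(50), c = rbinom(50, 1, 0.5))
  y <- 2 - 1.5 * X[, "a"] + 0.7 * X[, "b"] + 0 * X[, "c"]
  f <- fit_linear(y, X)
  expect_equal(f$intercept, 2, tolerance = 1e-10)
  expect_equal(f$coefficients$estimate,
               c(-1.5, 0.7, 0), tolerance = 1e-10)
  expect_lte(f$adj_r_square, f$r_square)
})

test_that("estimates agree with the normal-equation oracle", {
  set.seed(2)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(20)
  f <- fit_linear(y, X)
  want <- oracle_ols(y, X)
  expect_equal(c(f$intercept, f$coefficients$estimate), unname(want),
               tolerance = 1e-10)
})

test_that("collinear and all-zero effects are excluded by name, rest unchanged", {
  set.seed(3)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- 1 + X[, "a"] - 2 * X[, "b"] + rnorm(40, 0, 0.1)
  f0 <- fit_linear(y, X)
  Xz <- cbind(X, zero = 0)
  expect_warning(fz <- fit_linear(y, Xz), "zero")
  expect_false("zero" %in% fz$coefficients$effect)
  expect_equal(
    fz$coefficients$estimate[match(c("a", "b"), fz$coefficients$effect)],
    f0$coefficients$estimate[match(c("a", "b"), f0$coefficients$effect)],
    tolerance = 1e-12)
  Xc <- cbind(X, dup = X[, "a"])
  expect_warning(fit_linear(y, Xc), "dup|a")
})

test_that("backwards selection keeps significant effects and is a fixed point", {
  set.seed(4)
  n <- 2000
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("true", paste0("noise", 1:5))))
  y <- 0.4 * X[, "true"] + rnorm(n)
  bs <- backward_select(y, X)
  expect_true("true" %in% bs$selected)
  # already-significant models pass through unchanged
  X2 <- X[, "true", drop = FALSE]
  f2 <- fit_linear(y, X2)
  b2 <- backward_select(y, X2)
  expect_equal(b2$coefficients$estimate, f2$coefficients$estimate)
  expect_equal(b2$removed, character(0))
})

test_that("noise effects survive backwards selection at roughly the alpha rate", {
  set.seed(44)
  hits <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 400
    X <- cbind(true = rnorm(n), noise1 = rnorm(n))
    y <- 0.5 * X[, "true"] + rnorm(n)
    bs <- backward_select(y, X)
    hits <- hits + ("noise1" %in% bs$selected)
  }
  rate <- hits / reps
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("categorical levels leave the model independently (split semantics)", {
  set.seed(5)
  n <- 3000
  g <- factor(sample(c("A", "B", "C"), n, TRUE))
  df <- data.frame(g = g)
  X <- build_design(df, "g")  # dummies g=B, g=C against reference A
  y <- 0.8 * (g == "B") + rnorm(n)  # only level B is predictive
  bs <- backward_select(y, X)
  expect_true("g=B" %in% bs$selected)
  expect_false("g=C" %in% bs$selected)
  expect_true("g=C" %in% bs$removed)
})

test_that("the per-effect observation floor is enforced", {
  set.seed(6)
  X <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rnorm(50)
  expect_error(backward_select(y, X), "floor")
  expect_silent(suppressWarnings(
    backward_select(y, X, min_obs_per_effect = 8)))
})

test_that("intercept-only fallback warns when everything leaves", {
  set.seed(7)
  X <- cbind(n1 = rnorm(500), n2 = rnorm(500))
  y <- rnorm(500)
  res <- tryCatch(backward_select(y, X), warning = function(w) w)
  # either some noise survived by chance or the fallback warned
  if (inherits(res, "warning")) {
    expect_match(conditionMessage(res), "intercept-only")
  } else {
    expect_lte(length(res$selected), 2L)
  }
})

test_that("stability selection is reproducible and retains by frequency", {
  set.seed(8)
  n <- 1500
  X <- cbind(strong = rnorm(n), weak = rnorm(n), noise = rnorm(n))
  y <- 0.5 * X[, "strong"] + 0.05 * X[, "weak"] + rnorm(n)
  s1 <- stability_select(y, X, n_resamples = 40, seed = 99)
  s2 <- stability_select(y, X, n_resamples = 40, seed = 99)
  expect_identical(s1$effects, s2$effects)
  eff <- s1$effects
  expect_identical(eff$retained, eff$selection_frequency >= 0.20)
  expect_equal(eff$selection_frequency[eff$effect == "strong"], 1)
  expect_error(stability_select(y, X, n_resamples = 10), "seed")
})

test_that("zero-noise data give frequency one and the generating value", {
  set.seed(9)
  n <- 600
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- 1 + 0.9 * X[, "a"] - 0.6 * X[, "b"]
  s <- stability_select(y, X, n_resamples = 25, seed = 5)
  expect_equal(s$effects$selection_frequency, c(1, 1))
  expect_equal(s$effects$avg_estimate, c(0.9, -0.6), tolerance = 1e-9)
  main <- fit_linear(y, X)
  cmp <- compare_models(main, s)
  expect_equal(cmp$verdict, "robust")
  expect_true(all(abs(cmp$table$difference) < 1e-9))
})

test_that("model comparison flags injected instability", {
  main <- fit_linear(
    c(1, 2, 3, 4, 5) + 0.01 * rnorm(5),
    cbind(x = c(0.1, 0.2, 0.3, 0.4, 0.48)))
  # a hand-built stability result whose average is far from the main fit
  stab <- structure(list(
    effects = data.frame(effect = "x", selection_frequency = 0.25,
                         avg_estimate = -main$coefficients$estimate,
                         sd_estimate = 0.01, n_selected = 25,
                         retained = TRUE),
    n_resamples = 100, n_failed = 0, fraction = 0.75, retain = 0.2,
    seed = 1, membership = list()), class = "stability_model")
  cmp <- compare_models(main, stab)
  expect_equal(cmp$verdict, "unstable")
  expect_true(cmp$table$flagged)
  bad <- stab
  bad$effects$effect <- "unrelated"
  expect_error(compare_models(main, bad), "no effects")
})
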