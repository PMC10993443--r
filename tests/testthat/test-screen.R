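test_that("the K^2 normality statistic matches an external reference", {
  # frozen reference computed independently (omnibus skewness+kurtosis
  # test on this fixed 25-point sample): K2 = 0.2977675569, p = 0.8616692536
  x <- c(0.2, -1.1, 0.7, 1.5, -0.3, 0.9, -2.2, 0.05, 1.3, -0.6, 0.33,
         -0.41, 1.9, -1.7, 0.12, 0.55, -0.95, 2.1, -0.08, 0.61, -1.25,
         0.4, 0.77, -0.52, 1.05)
  r <- malnut:::dagostino_k2(x)
  expect_equal(r$statistic, 0.2977675569, tolerance = 1e-9)
  expect_equal(r$p, 0.8616692536, tolerance = 1e-9)
  # platykurtic sample (negative base in the kurtosis transform):
  # reference K2 = 5.4191881472, p = 0.0665638212
  r2 <- malnut:::dagostino_k2(seq(0, 1, length.out = 30))
  expect_equal(r2$statistic, 5.4191881472, tolerance = 1e-9)
  expect_equal(r2$p, 0.0665638212, tolerance = 1e-9)
  expect_error(malnut:::dagostino_k2(rep(1, 30)), "constant")
})

test_that("method choice is pearson for normal pairs, spearman for skewed", {
  set.seed(2)
  xn <- rnorm(500); yn <- rnorm(500)
  xs <- exp(rnorm(500, 0, 1))
  expect_equal(choose_method(xn, yn), "pearson")
  expect_equal(choose_method(xn, xs), "spearman")
  expect_equal(choose_method(xs, yn), "spearman")
  # invariant under affine rescaling of either variable
  expect_equal(choose_method(3 * xn - 7, yn / 10), "pearson")
  expect_equal(choose_method(xn, -2 * xs + 1), "spearman")
})

test_that("correlation screen reports r, CI, p and the reportability rule", {
  set.seed(3)
  x <- rnorm(200)
  r1 <- correlate(x, x, method = "pearson", variable = "self")
  expect_equal(r1$r, 1)
  # |r| >= 0.10 with p < 0.05 is reportable (e.g. a drought-index
  # correlation of -0.236 at n = 6575 clears both bars)
  n <- 6575
  set.seed(9)
  z <- rnorm(n)
  y <- -0.236 * z + rnorm(n, 0, sqrt(1 - 0.236^2))
  r2 <- correlate(z, y, method = "pearson", variable = "mvhi1")
  expect_true(abs(r2$r) >= 0.10 && r2$p < 0.05)
  expect_true(r2$reportable)
  expect_true(r2$ci95[1] <= r2$r && r2$r <= r2$ci95[2])
  # weak or non-significant correlations are not reportable
  set.seed(10)
  w <- rnorm(200)
  r3 <- correlate(w, 0.05 * w + rnorm(200), method = "pearson")
  if (abs(r3$r) < 0.10 || r3$p >= 0.05) expect_false(r3$reportable)
  expect_error(correlate(w, rep(1, 200), method = "pearson"),
               "zero-variance")
})

test_that("spearman equals pearson on brute-force ranks for small n", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(8:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    # exhaustive rank computation by pairwise counting
    rk <- function(v) vapply(v, function(vi) sum(v <= vi), 0)
    want <- sum((rk(x) - mean(rk(x))) * (rk(y) - mean(rk(y)))) /
      sqrt(sum((rk(x) - mean(rk(x)))^2) * sum((rk(y) - mean(rk(y)))^2))
    got <- correlate(x, y, method = "spearman")
    expect_equal(got$r, want, tolerance = 1e-12)
  }
})

test_that("t-test matches a closed-form hand computation and branches", {
  z0 <- c(1, 2, 3); z1 <- c(2, 4, 6)
  tt <- ttest_dichotomous(c(z0, z1), rep(c("a", "b"), each = 3))
  # hand computation: pooled variance (2*1 + 2*4)/4 = 2.5,
  # t = (2-4)/sqrt(2.5*(2/3)), folded F = 4/1 with p = 2*(1 - F(4;2,2))
  expect_equal(tt$folded_f, 4)
  expect_equal(tt$folded_f_p, 2 * pf(4, 2, 2, lower.tail = FALSE))
  expect_equal(tt$branch, "pooled")
  t_hand <- (2 - 4) / sqrt(2.5 * (2 / 3))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(tt$diff_means, -2)
  # identical groups: zero difference, p near 1
  set.seed(21)
  z <- rnorm(40)
  ti <- ttest_dichotomous(c(z, z), rep(c("a", "b"), each = 40))
  expect_equal(ti$diff_means, 0)
  expect_gt(ti$p, 0.999)
})

test_that("folded F keeps the pooled branch under equal variances", {
  set.seed(6)
  pooled <- replicate(1000, {
    ttest_dichotomous(rnorm(60), rep(c("a", "b"), each = 30))$branch
  })
  expect_gte(mean(pooled == "pooled"), 0.90)
})

test_that("one-way screen: F = t^2 for two levels, invariances hold", {
  set.seed(7)
  z <- rnorm(80)
  g <- rep(c("a", "b"), each = 40)
  z[g == "b"] <- z[g == "b"] + 0.6
  an <- anova_categorical(z, g, variable = "g")
  tt <- ttest_dichotomous(z, g)
  expect_equal(an$F, tt$t^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p, tolerance = 1e-10)
  # translation invariance of the variance-explained share
  an2 <- anova_categorical(z + 100, g)
  expect_equal(an2$r_square, an$r_square, tolerance = 1e-12)
  expect_equal(an$lowest_level, "a")
  # identical level means: nothing explained, F = 0, p = 1
  an3 <- anova_categorical(c(1, 2, 3, 1, 2, 3),
                           rep(c("a", "b"), each = 3))
  expect_equal(an3$r_square, 0)
  expect_equal(an3$F, 0)
  expect_equal(an3$p, 1)
  expect_error(anova_categorical(z, rep("a", 80)), ">= 2")
})

test_that("interaction screen is symmetric and detects built-in modification", {
  set.seed(8)
  n <- 400
  v1 <- sample(c("x", "y"), n, TRUE)
  v2 <- sample(c("p", "q", "r"), n, TRUE)
  z_add <- 0.5 * (v1 == "y") + 0.4 * (v2 == "q") + rnorm(n)
  i1 <- interaction_screen(z_add, v1, v2)
  i2 <- interaction_screen(z_add, v2, v1)
  expect_equal(i1$interaction_p, i2$interaction_p, tolerance = 1e-10)
  # multiplicative effect large enough for near-certain detection
  z_mult <- z_add + 1.5 * (v1 == "y") * (v2 == "q")
  im <- interaction_screen(z_mult, v1, v2)
  expect_true(im$modifies)
})

test_that("categorization schemes follow the published class bounds", {
  expect_equal(as.character(categorize(7, "household_size")), "6-10")
  expect_equal(as.character(categorize(c(3, 11), "household_size")),
               c("0-5", ">10"))
  expect_equal(as.character(categorize(900, "altitude")), "800-1000")
  expect_equal(as.character(categorize(c(800, 1500), "altitude")),
               c("<=800", ">1200"))
  expect_equal(as.character(categorize(c(10, 300, 501), "pop_density")),
               c("<=50", "50-500", ">500"))
  expect_equal(as.character(categorize(c(0, 1.5, 3), "agri_land")),
               c("no land", "<3 ha", ">=3 ha"))
  expect_equal(as.character(categorize(c(5, 8, 20, 31), "slope")),
               c("<8", "8-16", "16-30", ">30"))
  set.seed(30)
  q <- categorize(rnorm(4000), "quartiles")
  expect_true(all(abs(table(q) / 4000 - 0.25) < 0.03))
  expect_error(categorize(1:10, c(3, 3, 5)), "strictly increasing")
  expect_error(categorize(1:10, "no_such_scheme"), "unknown")
})

test_that("screen results are invariant to record order", {
  set.seed(33)
  n <- 300
  z <- rnorm(n)
  g <- sample(c("a", "b"), n, TRUE)
  f <- sample(c("p", "q", "r"), n, TRUE)
  perm <- sample(n)
  t1 <- ttest_dichotomous(z, g); t2 <- ttest_dichotomous(z[perm], g[perm])
  expect_equal(t1$t, t2$t)
  a1 <- anova_categorical(z, f); a2 <- anova_categorical(z[perm], f[perm])
  expect_equal(a1$F, a2$F)
})
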