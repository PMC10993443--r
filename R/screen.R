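# Bivariate screening of candidate determinants of the three Z-score
# outcomes. The screen mirrors a conventional epidemiological workflow:
# Pearson or Spearman correlation for continuous determinants (with a
# deterministic normality-based choice standing in for visual scatterplot
# inspection), independent-samples t-tests for dichotomous determinants
# (folded F-test deciding pooled vs Satterthwaite), one-way GLM F-tests
# for categorical determinants, and a pairwise interaction screen for
# effect modification. No multiplicity adjustment is applied at this
# stage -- screening is deliberately liberal; model selection downstream
# does the pruning.

# D'Agostino K^2 omnibus normality test: skewness Z (D'Agostino 1970)
# plus kurtosis Z (Anscombe & Glynn 1983), K2 = Z1^2 + Z2^2 ~ chi^2(2).
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L) stop("K^2 normality test needs n >= 20")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant sample: normality test undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  # signed cube root: the base goes negative for heavy-tailed samples
  cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) -
           cbrt((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Choose Pearson or Spearman for a pair of continuous variables
#'
#' Deterministic surrogate for visual distribution assessment: Pearson is
#' chosen iff both variables pass the D'Agostino K^2 normality test at
#' alpha = 0.05, otherwise Spearman. Invariant under affine rescaling of
#' either variable.
#'
#' @param x,y numeric samples (n >= 20).
#' @param alpha normality test level, default 0.05.
#' @return "pearson" or "spearman".
#' @export
choose_method <- function(x, y, alpha = 0.05) {
  px <- dagostino_k2(x)$p
  py <- dagostino_k2(y)$p
  if (px >= alpha && py >= alpha) "pearson" else "spearman"
}

#' Correlation screen for one continuous determinant
#'
#' Reports the coefficient, a Fisher-z 95% confidence interval, the
#' two-sided p-value, and the reportability flag |r| >= 0.10 & p < 0.05.
#'
#' @param x outcome sample; @param y determinant sample (equal length).
#' @param method "auto" (see [choose_method()]), "pearson" or "spearman".
#' @param variable label carried into the result.
#' @return list with `variable`, `method`, `r`, `ci95`, `p`, `reportable`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      variable = deparse(substitute(y))) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop("need n >= 8 for the correlation screen")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance sample: correlation undefined")
  if (method == "auto") method <- choose_method(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  # Fisher z interval; wider variance factor for the rank coefficient
  zse <- if (method == "pearson") sqrt(1 / (n - 3)) else sqrt(1.06 / (n - 3))
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * zse)
  p <- ct$p.value
  list(variable = variable, method = method, r = r, ci95 = ci, p = p,
       reportable = abs(r) >= 0.10 && p < 0.05)
}

#' Two-group t-test with folded F variance screen
#'
#' The folded F statistic (larger sample variance over smaller) decides
#' at alpha = 0.05 between the pooled t-test (variances compatible) and
#' the Welch--Satterthwaite t-test. `diff_means` is mean(group0) -
#' mean(group1), where group0 is the first factor level.
#'
#' @param z numeric outcome; @param g two-level grouping vector.
#' @param alpha folded-F level, default 0.05.
#' @return list with group labels/means/ns, `diff_means`, `folded_f`,
#'   `folded_f_p`, `variance_equal`, `branch`, `t`, `df`, `p`, `ci95`.
#' @export
ttest_dichotomous <- function(z, g, alpha = 0.05) {
  ok <- !is.na(z) & !is.na(g)
  z <- z[ok]
  g <- droplevels(as.factor(g[ok]))
  if (nlevels(g) != 2L) stop("grouping variable must have exactly two levels")
  z0 <- z[g == levels(g)[1L]]
  z1 <- z[g == levels(g)[2L]]
  if (length(z0) < 2L || length(z1) < 2L) stop("both groups need n >= 2")
  v0 <- stats::var(z0); v1 <- stats::var(z1)
  if ((v0 == 0 && length(z0) < 3L) || (v1 == 0 && length(z1) < 3L)) {
    stop("zero-variance group too small for a variance test")
  }
  if (v0 >= v1) {
    f <- if (v1 > 0) v0 / v1 else Inf
    df1 <- length(z0) - 1L; df2 <- length(z1) - 1L
  } else {
    f <- v1 / v0
    df1 <- length(z1) - 1L; df2 <- length(z0) - 1L
  }
  fp <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  equal <- fp >= alpha
  tt <- stats::t.test(z0, z1, var.equal = equal)
  list(
    groups = levels(g),
    n = c(length(z0), length(z1)),
    means = c(mean(z0), mean(z1)),
    diff_means = mean(z0) - mean(z1),
    folded_f = f, folded_f_p = fp, variance_equal = equal,
    branch = if (equal) "pooled" else "satterthwaite",
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, ci95 = unname(tt$conf.int)
  )
}

#' One-way GLM F-test for a categorical determinant
#'
#' Fixed-effects one-way analysis of variance on (possibly) unbalanced
#' data, reporting F, p, the share of variance explained
#' (R^2 = SS_between / SS_total) and the level with the lowest mean.
#'
#' @param z numeric outcome; @param f categorical determinant.
#' @param variable label carried into the result.
#' @return list `variable`, `levels`, `n_per_level`, `F`, `p`,
#'   `r_square`, `lowest_level`, `means`.
#' @export
anova_categorical <- function(z, f, variable = deparse(substitute(f))) {
  ok <- !is.na(z) & !is.na(f)
  z <- z[ok]
  f <- droplevels(as.factor(f[ok]))
  if (nlevels(f) < 2L) stop("categorical screen needs >= 2 non-empty levels")
  fit <- stats::lm(z ~ f)
  an <- stats::anova(fit)
  means <- tapply(z, f, mean)
  list(
    variable = variable,
    levels = levels(f),
    n_per_level = as.vector(table(f)),
    F = an$`F value`[1L], p = an$`Pr(>F)`[1L],
    r_square = summary(fit)$r.squared,
    lowest_level = names(means)[which.min(means)],
    means = means
  )
}

#' Interaction (effect-modification) screen for a variable pair
#'
#' Fits outcome ~ v1 + v2 + v1:v2 on categorical v1, v2 and tests the
#' interaction term with an F-test (the interaction F is order-invariant
#' in v1, v2). Empty level combinations are dropped from the interaction
#' and flagged.
#'
#' @param z numeric outcome; @param v1,v2 categorical variables.
#' @param alpha modification level, default 0.05.
#' @return list `pair`, `interaction_F`, `interaction_p`, `modifies`,
#'   `empty_cells`.
#' @export
interaction_screen <- function(z, v1, v2, alpha = 0.05) {
  ok <- !is.na(z) & !is.na(v1) & !is.na(v2)
  z <- z[ok]
  v1 <- droplevels(as.factor(v1[ok]))
  v2 <- droplevels(as.factor(v2[ok]))
  lab <- c(deparse(substitute(v1)), deparse(substitute(v2)))
  empty <- sum(table(v1, v2) == 0L)
  fit <- stats::lm(z ~ v1 * v2)
  an <- stats::anova(fit)
  irow <- grep(":", rownames(an))
  if (length(irow) == 0L || an$Df[irow] == 0L) {
    stop("interaction not estimable (all interaction cells aliased)")
  }
  list(pair = lab,
       interaction_F = an$`F value`[irow],
       interaction_p = an$`Pr(>F)`[irow],
       modifies = an$`Pr(>F)`[irow] < alpha,
       empty_cells = empty)
}

# Built-in categorization schemes for continuous determinants. Bounds
# follow the conventions used for Timor-Leste biophysical covariates:
# household size counts, altitude in metres, population density in
# persons/km^2, agricultural land in hectares, slope in percent.
builtin_schemes <- list(
  household_size = list(breaks = c(-Inf, 5, 10, Inf),
                        labels = c("0-5", "6-10", ">10"), right = TRUE),
  altitude = list(breaks = c(-Inf, 800, 1000, 1200, Inf),
                  labels = c("<=800", "800-1000", "1000-1200", ">1200"),
                  right = TRUE),
  pop_density = list(breaks = c(-Inf, 50, 500, Inf),
                     labels = c("<=50", "50-500", ">500"), right = TRUE),
  slope = list(breaks = c(-Inf, 8, 16, 30, Inf),
               labels = c("<8", "8-16", "16-30", ">30"), right = FALSE)
)

#' Categorize a continuous variable
#'
#' Built-in schemes: `"household_size"` (0-5, 6-10, >10),
#' `"altitude"` (<=800, 800-1000, 1000-1200, >1200 m),
#' `"pop_density"` (<=50, 50-500, >500 per km^2),
#' `"agri_land"` (no land, <3 ha, >=3 ha),
#' `"slope"` (<8, 8-16, 16-30, >30 %),
#' `"quartiles"` (sample quartiles, used e.g. for the drought index),
#' or a numeric vector of strictly increasing interior cut-points.
#'
#' @param x numeric vector.
#' @param scheme scheme name or numeric cut-points.
#' @return ordered factor.
#' @export
categorize <- function(x, scheme) {
  if (is.numeric(scheme)) {
    if (any(diff(scheme) <= 0)) stop("cut-points must be strictly increasing")
    return(cut(x, breaks = c(-Inf, scheme, Inf), ordered_result = TRUE))
  }
  if (scheme == "quartiles") {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    return(cut(x, breaks = unique(c(-Inf, q, Inf)),
               labels = paste0("Q", seq_len(length(unique(q)) + 1L)),
               ordered_result = TRUE))
  }
  if (scheme == "agri_land") {
    lab <- ifelse(x <= 0, "no land", ifelse(x < 3, "<3 ha", ">=3 ha"))
    return(factor(lab, levels = c("no land", "<3 ha", ">=3 ha"),
                  ordered = TRUE))
  }
  sc <- builtin_schemes[[scheme]]
  if (is.null(sc)) stop("unknown categorization scheme '", scheme, "'")
  cut(x, breaks = sc$breaks, labels = sc$labels, right = sc$right,
      ordered_result = TRUE)
}
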