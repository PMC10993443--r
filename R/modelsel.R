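# Linear outcome models: design construction with reference-level
# encoding, least-squares fitting, backwards p-value selection with
# "split" categorical semantics (individual levels leave the model
# independently of their parent variable), and subsampling stability
# selection with model averaging.

#' Build a reference-coded design matrix
#'
#' Numeric variables contribute one column; factors contribute one dummy
#' column per non-reference level, named `variable=level`. The reference
#' level is the first factor level unless overridden.
#'
#' @param data data.frame of covariates.
#' @param variables character vector of column names to include.
#' @param references optional named character vector, variable -> level.
#' @return numeric matrix (no intercept column) with attribute
#'   `variable_of` mapping each column to its source variable.
#' @export
build_design <- function(data, variables, references = NULL) {
  cols <- list()
  varof <- character()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop("variable '", v, "' not found in data")
    if (is.numeric(x)) {
      cols[[v]] <- x
      varof[v] <- v
    } else {
      f <- as.factor(x)
      ref <- references[[v]] %||% levels(f)[1L]
      if (!ref %in% levels(f)) stop("reference level '", ref,
                                    "' absent in '", v, "'")
      for (lv in setdiff(levels(f), ref)) {
        nm <- paste0(v, "=", lv)
        cols[[nm]] <- as.numeric(f == lv)
        varof[nm] <- v
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "variable_of") <- varof
  X
}

#' Least-squares linear fit with t-based p-values
#'
#' Ordinary least squares of `y` on an intercept plus the columns of `X`,
#' via the QR decomposition. Collinear columns (those beyond the design's
#' numerical rank) are excluded with a warning naming them.
#'
#' @param y numeric response.
#' @param X numeric design matrix (no intercept; may have zero columns).
#' @return object of class `malnut_fit`: data.frame `coefficients`
#'   (effect, estimate, se, t, p), plus `intercept`, `r_square`,
#'   `adj_r_square`, `sigma`, `n`, `df_residual`, `dropped_effects`.
#' @export
fit_linear <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  Xi <- cbind(`(Intercept)` = 1, X)
  if (n <= ncol(Xi)) stop("need n > number of effects + 1")
  qx <- qr(Xi)
  dropped <- character(0)
  if (qx$rank < ncol(Xi)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(Xi)[setdiff(seq_len(ncol(Xi)), keep)]
    warning("rank-deficient design; excluding collinear effect(s): ",
            paste(dropped, collapse = ", "))
    Xi <- Xi[, sort(keep), drop = FALSE]
    qx <- qr(Xi)
  }
  beta <- qr.coef(qx, y)
  res <- y - as.vector(Xi %*% beta)
  dfres <- n - ncol(Xi)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / dfres
  # unscaled covariance; undo any column pivoting done by the QR
  piv <- qx$pivot
  xtx_inv <- matrix(NA_real_, ncol(Xi), ncol(Xi))
  xtx_inv[piv, piv] <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  p_eff <- ncol(Xi) - 1L
  adj <- 1 - (1 - r2) * (n - 1) / dfres
  eff <- colnames(Xi) != "(Intercept)"
  structure(list(
    coefficients = data.frame(
      effect = colnames(Xi)[eff], estimate = unname(beta[eff]),
      se = unname(se[eff]), t = unname(tval[eff]), p = unname(pval[eff]),
      stringsAsFactors = FALSE),
    intercept = unname(beta["(Intercept)"]),
    r_square = r2, adj_r_square = adj, sigma = sqrt(sigma2),
    n = n, df_residual = dfres, n_effects = p_eff,
    dropped_effects = dropped
  ), class = "malnut_fit")
}

#' @export
print.malnut_fit <- function(x, ...) {
  cat(sprintf("Linear model: %d effects, n = %d, adj R^2 = %.4f\n",
              x$n_effects, x$n, x$adj_r_square))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Backwards p-value selection
#'
#' Iteratively removes the single effect with the worst p-value at or
#' above `alpha_stay` and refits, until every remaining effect has
#' p < `alpha_stay`. Individual dummy columns of a categorical variable
#' leave independently of their parent ("split classification variable"
#' semantics). Tie-break is deterministic: larger p first, then
#' lexicographic effect name. A hard sample-size floor of
#' `min_obs_per_effect` observations per candidate effect is enforced up
#' front.
#'
#' @param y numeric response; @param X design matrix from [build_design()].
#' @param alpha_stay retention threshold, default 0.05.
#' @param min_obs_per_effect observations required per candidate effect
#'   (default 10, configurable up to 15).
#' @return `malnut_fit` with extra fields `removed` (effects in removal
#'   order) and `selected` (surviving effect names). Removing everything
#'   returns the intercept-only model with a warning.
#' @export
backward_select <- function(y, X, alpha_stay = 0.05, min_obs_per_effect = 10) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("no candidate effects")
  if (length(y) < min_obs_per_effect * ncol(X)) {
    stop(sprintf(
      "n = %d violates the floor of %d observations per effect (%d effects)",
      length(y), min_obs_per_effect, ncol(X)))
  }
  removed <- character(0)
  repeat {
    fit <- fit_linear(y, X)
    if (length(fit$dropped_effects) > 0L) {
      # collinear columns leave immediately, like any other removal
      removed <- c(removed, fit$dropped_effects)
      X <- X[, setdiff(colnames(X), fit$dropped_effects), drop = FALSE]
      if (ncol(X) == 0L) break
      next
    }
    co <- fit$coefficients
    bad <- co[co$p >= alpha_stay, , drop = FALSE]
    if (nrow(bad) == 0L) {
      fit$removed <- removed
      fit$selected <- co$effect
      return(fit)
    }
    bad <- bad[order(-bad$p, bad$effect), , drop = FALSE]
    worst <- bad$effect[1L]
    removed <- c(removed, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
    if (ncol(X) == 0L) break
  }
  warning("all effects removed; returning intercept-only model")
  fit <- fit_linear(y, matrix(numeric(0), length(y), 0))
  fit$removed <- removed
  fit$selected <- character(0)
  fit
}

#' Stability selection by subsampling
#'
#' Repeats [backward_select()] on `n_resamples` subsets, each a random
#' `fraction` of the rows drawn without replacement, independently across
#' resamples. Reports per-effect selection frequencies, coefficients
#' averaged over the subsample models in which the effect appeared, and a
#' retention flag at frequency >= `retain` (so 20 of 100 is retained, 19
#' is dropped). Averaged p-values are deliberately not produced.
#'
#' @param y,X response and design as in [backward_select()].
#' @param n_resamples number of subsamples, default 100.
#' @param fraction subsample fraction, default 0.75.
#' @param retain retention frequency threshold, default 0.20.
#' @param seed integer seed; the procedure is fully reproducible.
#' @param alpha_stay,min_obs_per_effect passed to [backward_select()].
#' @return object of class `stability_model`: data.frame `effects`
#'   (effect, selection_frequency, avg_estimate, sd_estimate, n_selected,
#'   retained), `n_resamples`, `n_failed`, `membership` (list of row
#'   index vectors, for audit).
#' @export
stability_select <- function(y, X, n_resamples = 100, fraction = 0.75,
                             retain = 0.20, seed,
                             alpha_stay = 0.05, min_obs_per_effect = 10) {
  if (missing(seed)) stop("a seed is required for reproducible resampling")
  X <- as.matrix(X)
  n <- length(y)
  m <- floor(n * fraction)
  est <- matrix(NA_real_, n_resamples, ncol(X),
                dimnames = list(NULL, colnames(X)))
  membership <- vector("list", n_resamples)
  failed <- logical(n_resamples)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, m, replace = FALSE)
    membership[[b]] <- idx
    fit <- tryCatch(
      suppressWarnings(backward_select(
        y[idx], X[idx, , drop = FALSE],
        alpha_stay = alpha_stay, min_obs_per_effect = min_obs_per_effect)),
      error = function(e) NULL)
    if (is.null(fit)) {
      failed[b] <- TRUE
      next
    }
    if (length(fit$selected) > 0L) {
      est[b, fit$selected] <-
        fit$coefficients$estimate[match(fit$selected, fit$coefficients$effect)]
    }
  }
  n_failed <- sum(failed)
  if (n_failed > 0.10 * n_resamples) {
    stop(n_failed, " of ", n_resamples, " resample fits failed (> 10%)")
  }
  ok <- !failed
  freq <- colMeans(!is.na(est[ok, , drop = FALSE]))
  avg <- suppressWarnings(colMeans(est[ok, , drop = FALSE], na.rm = TRUE))
  sdv <- apply(est[ok, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  structure(list(
    effects = data.frame(
      effect = colnames(X),
      selection_frequency = unname(freq),
      avg_estimate = unname(ifelse(is.nan(avg), NA_real_, avg)),
      sd_estimate = unname(sdv),
      n_selected = unname(colSums(!is.na(est[ok, , drop = FALSE]))),
      retained = unname(freq >= retain),
      stringsAsFactors = FALSE),
    n_resamples = n_resamples, n_failed = n_failed,
    fraction = fraction, retain = retain, seed = seed,
    membership = membership
  ), class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf(
    "Stability selection: %d resamples (%.0f%% subsamples), %d failed\n",
    x$n_resamples, 100 * x$fraction, x$n_failed))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Compare a main model against its stability-selection average
#'
#' Per-effect difference (main estimate minus subsample average), flagged
#' when its magnitude exceeds twice the resample SD of the estimates. The
#' verdict is "robust" when nothing is flagged.
#'
#' @param main `malnut_fit` for the full-data model.
#' @param stability matching `stability_model`.
#' @return list `table` (effect, main_estimate, avg_estimate,
#'   difference, sd_estimate, flagged), `verdict`.
#' @export
compare_models <- function(main, stability) {
  co <- main$coefficients
  se <- stability$effects
  common <- intersect(co$effect, se$effect)
  if (length(common) == 0L) stop("models share no effects; cannot compare")
  i <- match(common, co$effect)
  j <- match(common, se$effect)
  diff <- co$estimate[i] - se$avg_estimate[j]
  sdv <- se$sd_estimate[j]
  tol <- 1e-10  # numerical floor: exact fits give zero spread
  flagged <- !is.na(diff) & !is.na(sdv) & sdv > tol & abs(diff) > 2 * sdv
  # zero-spread resamples with a real difference are also unstable
  flagged[!is.na(diff) & !is.na(sdv) & sdv <= tol & abs(diff) > 1e-8] <- TRUE
  list(table = data.frame(
    effect = common,
    main_estimate = co$estimate[i],
    avg_estimate = se$avg_estimate[j],
    difference = diff,
    sd_estimate = sdv,
    flagged = flagged,
    stringsAsFactors = FALSE),
    verdict = if (any(flagged)) "unstable" else "robust")
}

# Save/restore the global RNG state so seeded procedures do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
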