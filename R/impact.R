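# Quasi-experimental impact analysis: changes in mean Z-scores between a
# baseline and an endline wave are compared between intervention ("JP")
# districts and non-intervention districts, overall and within strata.
# Impact is the difference of changes, JP minus non-JP (positive = the
# intervention group improved more). Exposure is intent-to-treat at the
# district level: every child in an intervention district counts as
# exposed. Relative change uses |baseline mean| as denominator. Strata
# with fewer than 50 children at either wave are flagged as too small to
# report reliably.

SMALL_STRATUM_FLOOR <- 50L

#' Baseline/endline change for one exposure group
#'
#' @param records data.frame with the outcome column, `wave` and an
#'   `exposure` column ("JP"/"non-JP").
#' @param outcome outcome column name ("haz", "waz" or "whz").
#' @param exposure exposure label to subset on.
#' @param baseline,endline wave labels; defaults are the two sorted
#'   unique waves.
#' @param stratum label carried into the result ("overall" by default).
#' @return list of class `group_change`: `exposure`, `stratum`,
#'   `n_baseline`, `n_endline`, `mean_baseline`, `mean_endline`,
#'   `abs_change`, `rel_change_pct`, `small_stratum`.
#' @export
group_change <- function(records, outcome, exposure,
                         baseline = NULL, endline = NULL,
                         stratum = "overall") {
  waves <- sort(unique(records$wave))
  baseline <- baseline %||% waves[1L]
  endline <- endline %||% waves[2L]
  g <- records[records$exposure == exposure & !is.na(records[[outcome]]), ,
               drop = FALSE]
  zb <- g[[outcome]][g$wave == baseline]
  ze <- g[[outcome]][g$wave == endline]
  mb <- if (length(zb)) mean(zb) else NA_real_
  me <- if (length(ze)) mean(ze) else NA_real_
  group_change_from_means(
    exposure = exposure, stratum = stratum,
    mean_baseline = mb, mean_endline = me,
    n_baseline = length(zb), n_endline = length(ze),
    sd_baseline = if (length(zb) > 1) sd(zb) else NA_real_,
    sd_endline = if (length(ze) > 1) sd(ze) else NA_real_)
}

#' Assemble a group change from summary statistics
#'
#' Useful when only published group means are available.
#'
#' @param exposure,stratum labels.
#' @param mean_baseline,mean_endline group means (Z-score units).
#' @param n_baseline,n_endline group sizes.
#' @param sd_baseline,sd_endline optional SDs (for standard errors).
#' @return `group_change` object; `rel_change_pct` is NA (flagged) when
#'   the baseline mean is exactly zero.
#' @export
group_change_from_means <- function(exposure, stratum = "overall",
                                    mean_baseline, mean_endline,
                                    n_baseline, n_endline,
                                    sd_baseline = NA_real_,
                                    sd_endline = NA_real_) {
  abs_change <- mean_endline - mean_baseline
  rel <- if (!is.na(mean_baseline) && mean_baseline == 0) {
    NA_real_
  } else {
    100 * abs_change / abs(mean_baseline)
  }
  structure(list(
    exposure = exposure, stratum = stratum,
    n_baseline = n_baseline, n_endline = n_endline,
    mean_baseline = mean_baseline, mean_endline = mean_endline,
    sd_baseline = sd_baseline, sd_endline = sd_endline,
    abs_change = abs_change, rel_change_pct = rel,
    rel_change_undefined = !is.na(mean_baseline) && mean_baseline == 0,
    small_stratum = (min(n_baseline, n_endline) < SMALL_STRATUM_FLOOR)
  ), class = "group_change")
}

#' Impact of the intervention: difference of changes
#'
#' @param jp,nonjp `group_change` objects for the exposed and unexposed
#'   group in the same stratum.
#' @param outcome outcome label.
#' @return list of class `impact_row`: `outcome`, `stratum`, `jp`,
#'   `nonjp`, `impact_abs` (jp change minus non-JP change), `reliable`
#'   (neither side small).
#' @export
impact_row <- function(jp, nonjp, outcome = NA_character_) {
  stopifnot(inherits(jp, "group_change"), inherits(nonjp, "group_change"))
  structure(list(
    outcome = outcome, stratum = jp$stratum, jp = jp, nonjp = nonjp,
    impact_abs = jp$abs_change - nonjp$abs_change,
    reliable = !jp$small_stratum && !nonjp$small_stratum
  ), class = "impact_row")
}

#' Baseline (or endline) group comparison of means
#'
#' Difference of means JP minus non-JP within one wave, with the
#' pooled/Satterthwaite branch chosen by the folded F-test.
#'
#' @param records data.frame with outcome, `wave`, `exposure`.
#' @param outcome outcome column name.
#' @param wave wave label.
#' @return list `outcome`, `wave`, `diff_means` (JP - non-JP), `ci95`,
#'   `p`, `branch`.
#' @export
baseline_endline_tests <- function(records, outcome, wave) {
  w <- records[records$wave == wave & !is.na(records[[outcome]]), ,
               drop = FALSE]
  if (!all(c("JP", "non-JP") %in% w$exposure)) {
    stop("both exposure groups must be non-empty in wave '", wave, "'")
  }
  g <- factor(w$exposure, levels = c("JP", "non-JP"))
  tt <- ttest_dichotomous(w[[outcome]], g)
  list(outcome = outcome, wave = wave, diff_means = tt$diff_means,
       ci95 = tt$ci95, p = tt$p, branch = tt$branch,
       n = tt$n, means = tt$means)
}

#' Overall and stratified impact table
#'
#' One overall row plus one row per level of every requested stratifying
#' covariate. The same stratum definition is applied in both exposure
#' groups and both waves. Rows where either exposure side is small
#' (min n < 50) are marked unreliable.
#'
#' @param records data.frame with the outcome, `wave`, `exposure`, and
#'   the stratifying covariates.
#' @param outcome outcome column name.
#' @param strata character vector of covariate names (may be empty).
#' @return data.frame, one row per stratum, with group ns, means,
#'   absolute and relative changes, `impact_abs` and `reliable`.
#' @export
impact_table <- function(records, outcome, strata = character(0)) {
  for (s in strata) {
    if (!s %in% names(records)) stop("stratifying covariate '", s,
                                     "' not found")
  }
  rows <- list(impact_row(
    group_change(records, outcome, "JP"),
    group_change(records, outcome, "non-JP"),
    outcome = outcome))
  for (s in strata) {
    for (lv in levels(as.factor(records[[s]]))) {
      sub <- records[!is.na(records[[s]]) & records[[s]] == lv, ,
                     drop = FALSE]
      lab <- paste0(s, "=", lv)
      rows[[length(rows) + 1L]] <- impact_row(
        group_change(sub, outcome, "JP", stratum = lab),
        group_change(sub, outcome, "non-JP", stratum = lab),
        outcome = outcome)
    }
  }
  do.call(rbind, lapply(rows, as.data.frame.impact_row))
}

as.data.frame.impact_row <- function(x, ...) {
  data.frame(
    outcome = x$outcome, stratum = x$stratum,
    jp_n_baseline = x$jp$n_baseline, jp_n_endline = x$jp$n_endline,
    jp_mean_baseline = x$jp$mean_baseline,
    jp_mean_endline = x$jp$mean_endline,
    jp_abs_change = x$jp$abs_change,
    jp_rel_change_pct = x$jp$rel_change_pct,
    nonjp_n_baseline = x$nonjp$n_baseline,
    nonjp_n_endline = x$nonjp$n_endline,
    nonjp_mean_baseline = x$nonjp$mean_baseline,
    nonjp_mean_endline = x$nonjp$mean_endline,
    nonjp_abs_change = x$nonjp$abs_change,
    nonjp_rel_change_pct = x$nonjp$rel_change_pct,
    impact_abs = x$impact_abs,
    reliable = x$reliable,
    stringsAsFactors = FALSE)
}

#' Render a Z-score change with implied decimal places
#'
#' Table convention in which +0.37 prints as "37" (two implied
#' decimals); rounding is half away from zero, so -0.773 prints "-77".
#'
#' @param x numeric change(s) in Z-score units.
#' @param implied_decimals number of implied decimals, default 2.
#' @return character vector.
#' @export
format_zchange <- function(x, implied_decimals = 2) {
  out <- sprintf("%d", as.integer(round_half_up(x * 10^implied_decimals)))
  out[is.na(x)] <- NA_character_
  out
}

#' Render an impact table in publication style
#'
#' Changes at two implied decimals, impact differences at one decimal on
#' the implied scale, relative changes as whole percents; unreliable
#' rows (small strata) carried with a `*` marker. The machine-precision
#' values live in the [impact_table()] data.frame; this is presentation
#' only.
#'
#' @param tab data.frame from [impact_table()].
#' @return data.frame of character columns.
#' @export
format_impact_table <- function(tab) {
  fmt_rel <- function(x) ifelse(is.na(x), NA_character_,
                                sprintf("%d%%", as.integer(round_half_up(x))))
  data.frame(
    outcome = tab$outcome,
    stratum = ifelse(tab$reliable, tab$stratum, paste0(tab$stratum, " *")),
    nonjp_change = format_zchange(tab$nonjp_abs_change),
    nonjp_rel = fmt_rel(tab$nonjp_rel_change_pct),
    jp_change = format_zchange(tab$jp_abs_change),
    jp_rel = fmt_rel(tab$jp_rel_change_pct),
    impact = sprintf("%.1f", round_half_up(tab$impact_abs * 100, 1)),
    stringsAsFactors = FALSE)
}
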