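# Undernutrition classification and prevalence accounting.
#
# A child is classified against the WHO growth-reference scale from three
# Z-scores: height-for-age (HAZ, stunting), weight-for-age (WAZ,
# underweight) and weight-for-height (WHZ, wasting). A Z-score strictly
# below -2.0 flags the condition; the composite index of anthropometric
# failure (CIAF) is used here as the binary "fails at least one" flag.
# Excess prevalence subtracts the 2.3% of children expected below -2 SD
# in a well-nourished reference population from natural variation.

Z_CUTOFF <- -2.0
NATURAL_PREVALENCE_PCT <- 2.3

#' Classify undernutrition from Z-scores
#'
#' Strict inequality at the cutoff: a Z-score of exactly -2.0 does not
#' flag the condition.
#'
#' @param haz,waz,whz numeric Z-score vectors (no missing values; filter
#'   incomplete records upstream, e.g. with [harmonize()]).
#' @param cutoff Z-score threshold, default -2.0.
#' @return data.frame of logicals: `stunted`, `underweight`, `wasted`,
#'   `ciaf` (any of the three).
#' @export
classify_undernutrition <- function(haz, waz, whz, cutoff = Z_CUTOFF) {
  if (anyNA(haz) || anyNA(waz) || anyNA(whz)) {
    stop("classify_undernutrition requires complete Z-scores; ",
         "drop incomplete records first")
  }
  stunted <- haz < cutoff
  underweight <- waz < cutoff
  wasted <- whz < cutoff
  data.frame(stunted = stunted, underweight = underweight, wasted = wasted,
             ciaf = stunted | underweight | wasted)
}

#' Summarize anthropometry for one survey wave
#'
#' Means, SDs and prevalences over complete cases (all three Z-scores
#' present).
#'
#' @param records data.frame with columns `haz`, `waz`, `whz` and `wave`.
#' @param wave wave label to summarize.
#' @param excess also attach excess prevalences (default TRUE).
#' @return list with `n` (complete cases), per-outcome `mean` and `sd`,
#'   `prevalence_pct` and `excess_prevalence_pct` named vectors over
#'   conditions stunted/underweight/wasted/any.
#' @export
summarize_prevalence <- function(records, wave, excess = TRUE) {
  w <- records[records$wave == wave, , drop = FALSE]
  complete <- !is.na(w$haz) & !is.na(w$waz) & !is.na(w$whz)
  w <- w[complete, , drop = FALSE]
  if (nrow(w) == 0L) stop("no complete records in wave '", wave, "'")
  fl <- classify_undernutrition(w$haz, w$waz, w$whz)
  prev <- 100 * c(stunted = mean(fl$stunted),
                  underweight = mean(fl$underweight),
                  wasted = mean(fl$wasted),
                  any = mean(fl$ciaf))
  out <- list(
    wave = wave,
    n = nrow(w),
    mean = c(haz = mean(w$haz), waz = mean(w$waz), whz = mean(w$whz)),
    sd = c(haz = sd(w$haz), waz = sd(w$waz), whz = sd(w$whz)),
    prevalence_pct = prev
  )
  if (excess) out$excess_prevalence_pct <- excess_prevalence(prev)
  out
}

#' Excess prevalence over the natural background
#'
#' Subtracts the prevalence expected from natural variation in a
#' well-nourished population (2.3% below -2 SD), floored at zero. Values
#' are kept at full precision; round half-up only at report time
#' (61.05% excess 58.75 prints as 59%).
#'
#' @param prevalence_pct numeric prevalence(s) in percent, 0..100.
#' @param natural_pct background percentage to subtract, default 2.3.
#' @return excess prevalence(s) in percent.
#' @export
excess_prevalence <- function(prevalence_pct, natural_pct = NATURAL_PREVALENCE_PCT) {
  stopifnot(all(prevalence_pct >= 0 & prevalence_pct <= 100))
  pmax(prevalence_pct - natural_pct, 0)
}

#' Missing-anthropometry accounting for one wave
#'
#' @param records data.frame with `haz`, `waz`, `whz`, `wave`.
#' @param wave wave label; NULL for all records.
#' @return list `total`, `complete`, `missing_pct` (full precision;
#'   conventionally reported at one decimal).
#' @export
missingness_report <- function(records, wave = NULL) {
  w <- if (is.null(wave)) records else records[records$wave == wave, , drop = FALSE]
  total <- nrow(w)
  if (total == 0L) stop("no records in wave '", wave, "'")
  complete <- sum(!is.na(w$haz) & !is.na(w$waz) & !is.na(w$whz))
  list(total = total, complete = complete,
       missing_pct = 100 * (total - complete) / total)
}
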