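# Shared numeric helpers.

#' Round half away from zero
#'
#' Commercial rounding used everywhere a value is rendered for a report:
#' 58.75 rounds to 59, -77.5 rounds to -78. Underlying values are always
#' carried at full precision; this is applied only at format time.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a substream seed from a global seed. Streams keep the landscape,
# record and missingness RNGs independent so each can be regenerated alone.
# Result stays below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 16807) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Great-circle distance in km on the WGS84 sphere (radius 6371.0088 km),
# vectorized over the second point set. Precomputed trig may be supplied
# when many queries share one target set.
haversine_km <- function(lat1, lon1, lat2, lon2,
                         sin_lat2 = NULL, cos_lat2 = NULL) {
  r <- 6371.0088
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  s_lat2 <- sin_lat2 %||% sin(p2)
  c_lat2 <- cos_lat2 %||% cos(p2)
  # haversine via the half-angle form, numerically safe for small distances
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * c_lat2 * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
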