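# Shared fixtures and independent oracles for the test suite.

# Small, fast generator configuration used across tests.
small_cfg <- function(seed = 11, ...) {
  gen_config(n_children_per_wave = 400, n_districts = 4,
             jp_district_ids = c(0, 1), resolution_arcsec = 600,
             seed = seed, ...)
}

# Independent haversine oracle (not the package's implementation):
# spherical law of haversines written out directly, radius 6371.0088 km.
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * atan2(sqrt(a), sqrt(1 - a))
}

# Exhaustive O(n*m) nearest-neighbour scan, ties to the lowest ordinal.
oracle_nn_scan <- function(points, vectors) {
  idx <- integer(nrow(points))
  dk <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    d <- oracle_haversine_km(points$lat[k], points$lon[k],
                             vectors$lat, vectors$lon)
    j <- which.min(d)  # first minimum = smallest ordinal
    idx[k] <- j
    dk[k] <- d[j]
  }
  list(ordinal = vectors$ordinal[idx], dist_km = dk,
       value = vectors$value[idx])
}

# Normal-equations least-squares oracle: beta = (X'X)^-1 X'y with an
# intercept prepended.
oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  solve(crossprod(Xi), crossprod(Xi, y))[, 1]
}
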