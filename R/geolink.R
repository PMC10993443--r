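# Geographic link between survey points and gridded attribute maps.
#
# The link proceeds in three steps: (1) bring every attribute grid onto a
# common geo-reference by nearest-neighbour resampling; (2) export each
# grid into three aligned vectors (cell-centre latitude, longitude,
# attribute value), dropping nodata cells; (3) assign to every survey
# point the attribute of the nearest cell centre by great-circle distance.
# Because a grid cell is ~1 km, several survey points may legitimately
# share one cell (many-to-one links are allowed).

#' Resample a grid onto the geo-reference of another
#'
#' Nearest-neighbour resampling: each output cell takes the value of the
#' input cell containing the output cell's centre. Output cells whose
#' centre falls outside the input extent become nodata.
#'
#' @param grid input `raster_grid`.
#' @param reference `raster_grid` supplying origin, resolution and shape.
#' @return a `raster_grid` on the reference geometry carrying `grid`'s
#'   attribute.
#' @export
resample_to_reference <- function(grid, reference) {
  stopifnot(inherits(grid, "raster_grid"), inherits(reference, "raster_grid"))
  eg <- raster_extent_of(grid)
  er <- raster_extent_of(reference)
  if (eg$lat_min >= er$lat_max || er$lat_min >= eg$lat_max ||
      eg$lon_min >= er$lon_max || er$lon_min >= eg$lon_max) {
    stop("grids have disjoint extents; nothing to resample")
  }
  cc <- cell_centers(reference)
  # source cell indices containing each reference-cell centre
  si <- floor((grid$origin_lat - cc$lat) / grid$resolution) + 1
  sj <- floor((cc$lon - grid$origin_lon) / grid$resolution) + 1
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  out <- matrix(reference$nodata, length(cc$lat), length(cc$lon))
  ok_i <- si >= 1 & si <= nr
  ok_j <- sj >= 1 & sj <= nc
  if (any(ok_i) && any(ok_j)) {
    out[ok_i, ok_j] <- grid$values[si[ok_i], sj[ok_j], drop = FALSE]
  }
  # propagate the source's own nodata under the reference sentinel
  out[out == grid$nodata & !is.na(out)] <- reference$nodata
  raster_grid(out, reference$origin_lat, reference$origin_lon,
              reference$resolution, nodata = reference$nodata,
              attribute_name = grid$attribute_name)
}

#' Export a grid into aligned latitude/longitude/attribute vectors
#'
#' One triplet per non-nodata cell, in row-major order (cell ordinal
#' `(i-1)*ncols + j` ascending).
#'
#' @param grid a `raster_grid`.
#' @return data.frame with columns `lat`, `lon`, `value`, `ordinal`.
#' @export
grid_to_vectors <- function(grid) {
  cc <- cell_centers(grid)
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  # row-major enumeration
  lat <- rep(cc$lat, each = nc)
  lon <- rep(cc$lon, times = nr)
  val <- as.vector(t(grid$values))
  keep <- !is.na(val) & val != grid$nodata
  if (!any(keep)) {
    warning("grid '", grid$attribute_name, "' is entirely nodata")
  }
  data.frame(lat = lat[keep], lon = lon[keep], value = val[keep],
             ordinal = which(keep))
}

#' Link points to the nearest grid cell centres
#'
#' For each point, the vector entry minimizing the great-circle
#' (haversine) distance on a sphere of radius 6371.0088 km; ties are
#' broken by the smallest cell ordinal. Equivalent to the exhaustive
#' scan over all cells, evaluated in vectorized chunks.
#'
#' @param points data.frame (or matrix) with columns `lat`, `lon`.
#' @param vectors output of [grid_to_vectors()].
#' @return data.frame with one row per point: `value`, `dist_km`,
#'   `ordinal`.
#' @export
nearest_neighbor_link <- function(points, vectors) {
  points <- as.data.frame(points)
  if (nrow(vectors) == 0L) stop("attribute vectors are empty; cannot link")
  stopifnot(all(c("lat", "lon") %in% names(points)))
  # target trig precomputed once; vectors rows are in ascending ordinal
  # order so which.min's first-match rule implements the tie-break
  p2 <- vectors$lat * pi / 180
  s2 <- sin(p2)
  c2 <- cos(p2)
  n <- nrow(points)
  idx <- integer(n)
  dk <- numeric(n)
  for (k in seq_len(n)) {
    d <- haversine_km(points$lat[k], points$lon[k],
                      vectors$lat, vectors$lon,
                      sin_lat2 = s2, cos_lat2 = c2)
    j <- which.min(d)
    idx[k] <- j
    dk[k] <- d[j]
  }
  data.frame(value = vectors$value[idx], dist_km = dk,
             ordinal = vectors$ordinal[idx])
}

#' Link a point table to several attribute grids at once
#'
#' Grids are first resampled onto the first grid's geo-reference; when the
#' resampled grids share one nodata footprint the nearest-neighbour search
#' runs once and attribute values are picked by cell ordinal, which is
#' behaviorally identical to (and much cheaper than) one search per grid.
#'
#' @param records data.frame with `lat`, `lon` columns.
#' @param grids named list of `raster_grid`s.
#' @return `records` with one extra column per attribute plus
#'   `link_dist_km` and `link_ordinal` (from the reference grid search).
#' @export
link_points_to_grids <- function(records, grids) {
  stopifnot(length(grids) >= 1L)
  if (is.null(names(grids)) || any(!nzchar(names(grids)))) {
    names(grids) <- vapply(grids, function(g) g$attribute_name, "")
  }
  ref <- grids[[1L]]
  grids <- lapply(grids, resample_to_reference, reference = ref)
  vecs <- lapply(grids, grid_to_vectors)
  same_footprint <- all(vapply(
    vecs, function(v) identical(v$ordinal, vecs[[1L]]$ordinal), TRUE))
  if (same_footprint) {
    link <- nearest_neighbor_link(records[, c("lat", "lon")], vecs[[1L]])
    pos <- match(link$ordinal, vecs[[1L]]$ordinal)
    for (a in names(vecs)) records[[a]] <- vecs[[a]]$value[pos]
  } else {
    for (a in names(vecs)) {
      la <- nearest_neighbor_link(records[, c("lat", "lon")], vecs[[a]])
      records[[a]] <- la$value
      link <- la
    }
    link <- nearest_neighbor_link(records[, c("lat", "lon")], vecs[[1L]])
  }
  records$link_dist_km <- link$dist_km
  records$link_ordinal <- link$ordinal
  records
}

#' Drop rows with missing analysis values (harmonized full matrix)
#'
#' @param records data.frame.
#' @param columns columns that must be complete; default all columns.
#' @return data.frame of surviving rows with attribute `dropped_count`;
#'   errors with a per-column missingness diagnostic if no row survives.
#' @export
harmonize <- function(records, columns = names(records)) {
  stopifnot(all(columns %in% names(records)))
  miss <- vapply(records[columns], function(x) is.na(x), logical(nrow(records)))
  if (nrow(records) == 1L) miss <- matrix(miss, nrow = 1L)
  keep <- rowSums(miss) == 0L
  if (!any(keep)) {
    per_col <- colSums(miss)
    stop("no complete rows remain; missing per column: ",
         paste(sprintf("%s=%d", names(per_col), per_col), collapse = ", "))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_count") <- sum(!keep)
  out
}
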