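# Minimal single-band geographic raster container and plain-text I/O.
#
# Grids are registered to the upper-left corner: `origin_lat` is the north
# edge, `origin_lon` the west edge, and the centre of cell (i, j) (1-based,
# row-major, latitude decreasing with row index) is
#   lat = origin_lat - (i - 0.5) * resolution
#   lon = origin_lon + (j - 0.5) * resolution
# Serialization uses the ESRI ASCII grid format, a standard plain-text
# raster interchange format readable by every GIS.

#' Construct a raster grid
#'
#' @param values numeric matrix, rows ordered north to south.
#' @param origin_lat,origin_lon decimal degrees of the upper-left corner.
#' @param resolution cell size in decimal degrees (default 1/120, i.e. 30
#'   arcseconds, roughly 1 km at the equator).
#' @param nodata sentinel marking missing cells.
#' @param attribute_name short name of the attribute the grid carries.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_lat, origin_lon,
                        resolution = 1 / 120, nodata = -9999,
                        attribute_name = "attribute") {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("raster values must be non-empty")
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be a positive number of degrees")
  }
  structure(
    list(values = values, origin_lat = origin_lat, origin_lon = origin_lon,
         resolution = resolution, nodata = nodata,
         attribute_name = attribute_name),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid '%s'> %d x %d cells, res %.6g deg, UL corner (%.4f, %.4f)\n",
    x$attribute_name, nrow(x$values), ncol(x$values), x$resolution,
    x$origin_lat, x$origin_lon))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster grid
#'
#' @param grid a `raster_grid`.
#' @return list with numeric vectors `lat` (one per row, north to south)
#'   and `lon` (one per column, west to east).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  list(
    lat = grid$origin_lat - (seq_len(nr) - 0.5) * grid$resolution,
    lon = grid$origin_lon + (seq_len(nc) - 0.5) * grid$resolution
  )
}

# South and east edges, for extent tests.
raster_extent_of <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  list(lat_min = grid$origin_lat - nr * grid$resolution,
       lat_max = grid$origin_lat,
       lon_min = grid$origin_lon,
       lon_max = grid$origin_lon + nc * grid$resolution)
}

#' Write a raster grid as an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so that write/read
#' round-trips are bit-exact for doubles.
#'
#' @param grid a `raster_grid`.
#' @param path file path (conventionally `.asc`).
#' @return the path, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin_lon),
    sprintf("yllcorner %.17g", grid$origin_lat - nr * grid$resolution),
    sprintf("cellsize %.17g", grid$resolution),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  rows <- apply(grid$values, 1L, function(v) {
    paste(sprintf("%.17g", v), collapse = " ")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file path.
#' @param attribute_name attribute label to attach; defaults to the file
#'   name without extension.
#' @return a `raster_grid`.
#' @export
read_ascii_grid <- function(path, attribute_name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  body <- lines[seq(i, length.out = nr)]
  vals <- matrix(
    as.numeric(unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE)),
    nrow = nr, ncol = nc, byrow = TRUE
  )
  raster_grid(
    vals,
    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
    origin_lon = hdr$xllcorner,
    resolution = hdr$cellsize,
    nodata = hdr$nodata_value %||% -9999,
    attribute_name = attribute_name %||%
      sub("\\.[^.]*$", "", basename(path))
  )
}
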