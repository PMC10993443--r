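# Synthetic two-wave child-anthropometry survey and landscape generator.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: two survey waves of several thousand under-five
# records; HAZ/WAZ/WHZ produced by a linear covariate model with
# district effects and Gaussian noise at realistic SDs (1.95 / 1.25 /
# 1.61); ~25-30% joint missingness of the three Z-scores; districts
# partitioned into intervention ("JP") and non-intervention groups with
# unequal baselines; and district-piecewise attribute rasters (drought
# index, altitude, slope, soils, population density, crop cover) over
# the survey extent. Districts are axis-aligned rectangles tiling the
# extent, so point-in-district tests are trivially invertible.
#
# One global seed feeds an explicit stream-splitting scheme (landscape /
# district effects / records / missingness), so each component can be
# regenerated independently and reproducibly.

STREAM_LANDSCAPE <- 1L
STREAM_DISTRICT <- 2L
STREAM_RECORDS <- 3L
STREAM_MISSING <- 4L

LANDSCAPE_ATTRS <- c("mvhi", "altitude", "slope", "soil_class",
                     "pop_density", "crop_cover")

#' Default covariate -> coefficient table
#'
#' Coefficients in Z-score units per unit (binary/continuous) or per
#' level against the stated reference (categorical). Magnitudes are at
#' the scale typical of explanatory child-anthropometry regressions:
#' sex and season effects of 0.1-0.35 SD, child-age effects near 1 SD,
#' maternal-BMI and wealth gradients of 0.1-0.5 SD. `noise_bin` is a
#' deliberate pure-noise covariate (all coefficients zero) used to probe
#' false-selection rates.
#'
#' @return data.frame with columns `variable`, `level` (NA for
#'   non-categorical), `haz`, `waz`, `whz`.
#' @export
default_coef_table <- function() {
  rbind(
    data.frame(variable = "female", level = NA,
               haz = 0.35, waz = 0.11, whz = 0),
    data.frame(variable = "hungry_season", level = NA,
               haz = 0.28, waz = 0, whz = -0.13),
    data.frame(variable = "suppl_food", level = NA,
               haz = 0, waz = -0.16, whz = 0),
    data.frame(variable = "noise_bin", level = NA,
               haz = 0, waz = 0, whz = 0),
    data.frame(variable = "age_cat", level = c("1", "2", "3", "4"),
               haz = c(-1.03, -0.77, -1.02, -0.83),
               waz = c(-0.82, -1.04, -1.14, -1.22),
               whz = c(-0.64, -0.74, -0.62, -0.90)),
    data.frame(variable = "bmi_class", level = c("normal", "overweight"),
               haz = c(0, 0), waz = c(0.33, 0.47), whz = c(0.29, 0.45)),
    data.frame(variable = "wealth",
               level = c("poorer", "middle", "richer", "richest"),
               haz = 0, waz = c(0.08, 0, 0.14, 0.23), whz = 0)
  )
}

default_covariates <- function() {
  list(
    female = list(type = "binary", prev = 0.5),
    hungry_season = list(type = "binary", prev = 0.5),
    suppl_food = list(type = "binary", prev = 0.5),
    noise_bin = list(type = "binary", prev = 0.5),
    age_cat = list(type = "categorical",
                   levels = c("0", "1", "2", "3", "4")),
    bmi_class = list(type = "categorical",
                     levels = c("underweight", "normal", "overweight")),
    wealth = list(type = "categorical",
                  levels = c("poorest", "poorer", "middle", "richer",
                             "richest")),
    household_size = list(type = "continuous", mean = 6, sd = 2)
  )
}

#' Generator configuration
#'
#' All defaults describe the study conditions the pipeline is designed
#' for: 5000 children per wave across 13 districts (4 of them in the
#' intervention group), outcome noise SDs 1.95/1.25/1.61 (HAZ/WAZ/WHZ),
#' joint Z-score missingness of 24.8% (baseline wave) and 29.6%
#' (endline wave), a 30-arcsecond raster over a Timor-Leste-sized
#' extent, unequal baselines between exposure groups, and an additive
#' intervention-district wave-2 shift (the program-effect truth) of
#' -0.20 HAZ, +0.12 WAZ, +0.37 WHZ.
#'
#' @param n_children_per_wave children per wave.
#' @param n_districts number of districts (axis-aligned rectangles).
#' @param jp_district_ids 0-based ids of intervention districts.
#' @param coef_table see [default_coef_table()].
#' @param covariates covariate distribution spec; see
#'   [default_covariates()] (binary = Bernoulli(prev), categorical =
#'   uniform over levels, continuous = Normal(mean, sd)).
#' @param intercepts,noise_sd,wave_effect,jp_effect,jp_baseline_offset
#'   named numeric vectors over `haz`, `waz`, `whz` (Z-score units).
#' @param district_effect_sd SD of the random district intercepts.
#' @param missing_frac named fractions in [0,1) per wave label.
#' @param wave_labels the two wave labels (baseline, endline).
#' @param raster_extent list `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   (decimal degrees, WGS84).
#' @param resolution_arcsec raster cell size in arcseconds (default 30).
#' @param attr_means optional named list, attribute -> per-district mean
#'   values (overrides the seeded draws).
#' @param attr_rel_jitter relative amplitude of the smooth
#'   within-district attribute variation (0 gives piecewise-constant
#'   maps).
#' @param seed integer master seed.
#' @return validated list of class `gen_config`.
#' @export
gen_config <- function(n_children_per_wave = 5000,
                       n_districts = 13,
                       jp_district_ids = c(0, 1, 8, 10),
                       coef_table = default_coef_table(),
                       covariates = default_covariates(),
                       intercepts = c(haz = -1.29, waz = -1.31, whz = -1.54),
                       noise_sd = c(haz = 1.95, waz = 1.25, whz = 1.61),
                       wave_effect = c(haz = 0, waz = 0, whz = 0),
                       jp_effect = c(haz = -0.20, waz = 0.12, whz = 0.37),
                       jp_baseline_offset = c(haz = 0.78, waz = 0,
                                              whz = -0.66),
                       district_effect_sd = 0.5,
                       missing_frac = c("2009" = 0.248, "2016" = 0.296),
                       wave_labels = c("2009", "2016"),
                       raster_extent = list(lat_min = -9.5, lat_max = -8.1,
                                            lon_min = 124.0,
                                            lon_max = 127.3),
                       resolution_arcsec = 30,
                       attr_means = NULL,
                       attr_rel_jitter = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_children_per_wave = n_children_per_wave, n_districts = n_districts,
    jp_district_ids = jp_district_ids, coef_table = coef_table,
    covariates = covariates, intercepts = intercepts, noise_sd = noise_sd,
    wave_effect = wave_effect, jp_effect = jp_effect,
    jp_baseline_offset = jp_baseline_offset,
    district_effect_sd = district_effect_sd,
    missing_frac = missing_frac, wave_labels = wave_labels,
    raster_extent = raster_extent,
    resolution_arcsec = resolution_arcsec, attr_means = attr_means,
    attr_rel_jitter = attr_rel_jitter, seed = seed)
  validate_gen_config(cfg)
}

validate_gen_config <- function(cfg) {
  stopifnot(cfg$n_children_per_wave >= 1, cfg$n_districts >= 1)
  if (!all(cfg$jp_district_ids %in% seq(0, cfg$n_districts - 1))) {
    stop("jp_district_ids must be a subset of 0..n_districts-1")
  }
  if (!all(cfg$noise_sd > 0)) stop("noise_sd must be positive")
  if (!all(cfg$missing_frac >= 0 & cfg$missing_frac < 1)) {
    stop("missing_frac must lie in [0, 1)")
  }
  ex <- cfg$raster_extent
  if (ex$lat_max <= ex$lat_min || ex$lon_max <= ex$lon_min) {
    stop("degenerate raster extent: zero or negative width/height")
  }
  if (cfg$resolution_arcsec <= 0) stop("resolution must be positive")
  if (length(cfg$wave_labels) != 2L) stop("exactly two wave labels required")
  if (!is.null(cfg$coef_table) && nrow(cfg$coef_table) == 0L) {
    stop("coefficient table must not be empty")
  }
  structure(cfg, class = "gen_config")
}

# Districts tile the extent as an nr x nc grid of rectangles with nc >=
# nr and nr the largest divisor of n_districts not exceeding sqrt(n);
# prime counts degenerate to vertical strips. Rows count from the north,
# columns from the west; 0-based id = (row-1)*nc + (col-1).
district_layout <- function(cfg) {
  n <- cfg$n_districts
  nr <- 1L
  for (k in seq_len(floor(sqrt(n)))) if (n %% k == 0L) nr <- k
  nc <- n %/% nr
  ex <- cfg$raster_extent
  list(nr = nr, nc = nc,
       dlat = (ex$lat_max - ex$lat_min) / nr,
       dlon = (ex$lon_max - ex$lon_min) / nc)
}

#' District id containing each point
#'
#' @param lat,lon coordinate vectors (inside the configured extent;
#'   boundary points are clamped inward).
#' @param cfg `gen_config`.
#' @return integer vector of 0-based district ids.
#' @export
district_of_point <- function(lat, lon, cfg) {
  lay <- district_layout(cfg)
  ex <- cfg$raster_extent
  r <- pmin(lay$nr, pmax(1, floor((ex$lat_max - lat) / lay$dlat) + 1))
  c <- pmin(lay$nc, pmax(1, floor((lon - ex$lon_min) / lay$dlon) + 1))
  as.integer((r - 1) * lay$nc + (c - 1))
}

#' Generate the attribute landscape
#'
#' One raster per attribute (`mvhi`, `altitude`, `slope`, `soil_class`,
#' `pop_density`, `crop_cover`), piecewise-constant by district plus a
#' smooth sinusoidal within-district variation of relative amplitude
#' `attr_rel_jitter` (classes such as `soil_class` stay constant).
#' Deterministic given the configured seed.
#'
#' @param cfg `gen_config`.
#' @return named list of `raster_grid`s sharing one geo-reference, with
#'   attribute `district_means` (matrix attribute x district).
#' @export
generate_landscape <- function(cfg) {
  cfg <- validate_gen_config(cfg)
  ex <- cfg$raster_extent
  res <- cfg$resolution_arcsec / 3600
  nr <- ceiling((ex$lat_max - ex$lat_min) / res - 1e-9)
  nc <- ceiling((ex$lon_max - ex$lon_min) / res - 1e-9)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, STREAM_LANDSCAPE))
  nd <- cfg$n_districts
  means <- rbind(
    mvhi = stats::runif(nd, 20, 60),
    altitude = stats::runif(nd, 100, 1500),
    slope = stats::runif(nd, 2, 35),
    soil_class = sample(1:5, nd, replace = TRUE),
    pop_density = exp(stats::runif(nd, log(10), log(1000))),
    crop_cover = stats::runif(nd, 0, 80))
  if (!is.null(cfg$attr_means)) {
    for (a in names(cfg$attr_means)) {
      means[a, ] <- rep_len(cfg$attr_means[[a]], nd)
    }
  }
  lat_c <- ex$lat_max - (seq_len(nr) - 0.5) * res
  lon_c <- ex$lon_min + (seq_len(nc) - 0.5) * res
  # district id of every cell centre (clamped at the ragged south/east
  # edge introduced by the ceiling)
  did <- outer(pmax(pmin(lat_c, ex$lat_max), ex$lat_min + 1e-12),
               pmax(pmin(lon_c, ex$lon_max - 1e-12), ex$lon_min),
               function(la, lo) district_of_point(la, lo, cfg))
  # smooth deterministic field in [-1, 1]
  u <- (matrix(lon_c, nr, nc, byrow = TRUE) - ex$lon_min) /
    (ex$lon_max - ex$lon_min)
  v <- (matrix(lat_c, nr, nc) - ex$lat_min) / (ex$lat_max - ex$lat_min)
  field <- sin(6 * pi * u) * cos(6 * pi * v)
  grids <- list()
  for (a in rownames(means)) {
    base <- matrix(means[a, did + 1L], nr, nc)
    vals <- if (a == "soil_class") base else
      base * (1 + cfg$attr_rel_jitter * field)
    grids[[a]] <- raster_grid(vals, origin_lat = ex$lat_max,
                              origin_lon = ex$lon_min, resolution = res,
                              attribute_name = a)
  }
  attr(grids, "district_means") <- means
  grids
}

draw_covariates <- function(cfg, n) {
  out <- list()
  for (v in names(cfg$covariates)) {
    sp <- cfg$covariates[[v]]
    out[[v]] <- switch(
      sp$type,
      binary = stats::rbinom(n, 1L, sp$prev %||% 0.5),
      categorical = factor(sample(sp$levels, n, replace = TRUE),
                           levels = sp$levels),
      continuous = stats::rnorm(n, sp$mean %||% 0, sp$sd %||% 1),
      stop("unknown covariate type '", sp$type, "'"))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Linear predictor contribution of the covariates for one outcome.
coef_contribution <- function(cov_df, coef_table, outcome) {
  eta <- numeric(nrow(cov_df))
  for (i in seq_len(nrow(coef_table))) {
    b <- coef_table[[outcome]][i]
    if (b == 0) next
    v <- coef_table$variable[i]
    x <- cov_df[[v]]
    if (is.null(x)) stop("coefficient refers to absent covariate '", v, "'")
    if (is.na(coef_table$level[i])) {
      eta <- eta + b * as.numeric(x)
    } else {
      eta <- eta + b * (as.character(x) == coef_table$level[i])
    }
  }
  eta
}

#' Per-district random intercepts (reproducible truth)
#'
#' @param cfg `gen_config`.
#' @return matrix n_districts x 3 (haz, waz, whz).
#' @export
district_effects <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, STREAM_DISTRICT))
  matrix(stats::rnorm(cfg$n_districts * 3, 0, cfg$district_effect_sd),
         ncol = 3, dimnames = list(NULL, c("haz", "waz", "whz")))
}

#' Generate the two-wave child-record table
#'
#' Each record receives a district (uniform), coordinates uniform within
#' the district rectangle, covariates from the configured distributions,
#' and outcomes
#' `intercept + covariate effects + district effect + baseline offset
#' (JP districts) + wave-2 secular effect + wave-2 JP program effect +
#' Gaussian noise`. Z-scores are complete at this stage; apply
#' [inject_missingness()] for the observed pattern.
#'
#' @param cfg `gen_config`.
#' @param rasters ignored (the record generator needs only the extent;
#'   accepted so landscape and records can be produced in one call
#'   chain).
#' @return data.frame, one row per child, with `wave`, `district_id`,
#'   `jp`, `exposure`, `lat`, `lon`, `haz`, `waz`, `whz` and the
#'   covariate columns.
#' @export
generate_records <- function(cfg, rasters = NULL) {
  cfg <- validate_gen_config(cfg)
  if (is.null(cfg$coef_table) || nrow(cfg$coef_table) == 0L) {
    stop("coefficient table must not be empty")
  }
  deff <- district_effects(cfg)
  lay <- district_layout(cfg)
  ex <- cfg$raster_extent
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, STREAM_RECORDS))
  n <- cfg$n_children_per_wave
  total <- 2L * n
  wave <- rep(cfg$wave_labels, each = n)
  district <- sample.int(cfg$n_districts, total, replace = TRUE) - 1L
  row_d <- district %/% lay$nc
  col_d <- district %% lay$nc
  lat <- ex$lat_max - (row_d + stats::runif(total)) * lay$dlat
  lon <- ex$lon_min + (col_d + stats::runif(total)) * lay$dlon
  cov_df <- draw_covariates(cfg, total)
  jp <- district %in% cfg$jp_district_ids
  wave2 <- wave == cfg$wave_labels[2L]
  out <- data.frame(wave = wave, district_id = district, jp = jp,
                    exposure = ifelse(jp, "JP", "non-JP"),
                    lat = lat, lon = lon, stringsAsFactors = FALSE)
  for (o in c("haz", "waz", "whz")) {
    eta <- cfg$intercepts[[o]] +
      coef_contribution(cov_df, cfg$coef_table, o) +
      deff[district + 1L, o] +
      cfg$jp_baseline_offset[[o]] * jp +
      cfg$wave_effect[[o]] * wave2 +
      cfg$jp_effect[[o]] * (jp & wave2)
    out[[o]] <- eta + stats::rnorm(total, 0, cfg$noise_sd[[o]])
  }
  cbind(out, cov_df)
}

#' Mask Z-scores missing-completely-at-random
#'
#' The three Z-scores are masked jointly (a child either has all three
#' or none), per wave at the configured fraction. Record count and order
#' are preserved.
#'
#' @param records output of [generate_records()].
#' @param cfg `gen_config`.
#' @return records with NA Z-scores in the masked rows.
#' @export
inject_missingness <- function(records, cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, STREAM_MISSING))
  for (w in names(cfg$missing_frac)) {
    frac <- cfg$missing_frac[[w]]
    if (frac <= 0) next
    idx <- which(records$wave == w)
    mask <- idx[stats::runif(length(idx)) < frac]
    records[mask, c("haz", "waz", "whz")] <- NA_real_
  }
  records
}

#' Generate the full synthetic bundle
#'
#' @param cfg `gen_config`.
#' @param missingness apply the configured Z-score masking (default
#'   TRUE).
#' @return list of class `synthetic_bundle`: `records`, `rasters`,
#'   `truth` (config plus realized district effects and attribute
#'   means).
#' @export
generate_bundle <- function(cfg = gen_config(), missingness = TRUE) {
  cfg <- validate_gen_config(cfg)
  rasters <- generate_landscape(cfg)
  records <- generate_records(cfg, rasters)
  if (missingness) records <- inject_missingness(records, cfg)
  structure(list(
    records = records, rasters = rasters,
    truth = list(config = cfg,
                 district_effects = district_effects(cfg),
                 district_attr_means = attr(rasters, "district_means"))
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle as plain-text fixture files
#'
#' Records as CSV (empty cell = missing), rasters as ESRI ASCII grids,
#' truth as JSON. Round-trips losslessly through [read_fixture()].
#'
#' @param bundle `synthetic_bundle`.
#' @param directory output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  paths <- c(records = file.path(directory, "records.csv"),
             truth = file.path(directory, "truth.json"))
  utils::write.csv(bundle$records, paths[["records"]], row.names = FALSE,
                   na = "")
  for (a in names(bundle$rasters)) {
    p <- file.path(directory, paste0(a, ".asc"))
    write_ascii_grid(bundle$rasters[[a]], p)
    paths[[paste0("raster_", a)]] <- p
  }
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  truth$config$coef_table <- NULL  # kept reproducible via the seed
  truth$config$covariates <- NULL
  truth$config$missing_frac <- as.list(truth$config$missing_frac)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, matrix = "columnmajor")
  invisible(paths)
}

#' Restore canonical covariate types after a CSV round-trip
#'
#' CSV carries no factor metadata: ordered categorical covariates come
#' back as character (alphabetical levels) or numeric. This restores
#' the generator's level order (reference level first) for any of the
#' known categorical covariates present.
#'
#' @param records data.frame read from a records CSV.
#' @param covariates covariate spec; default [default_covariates()].
#' @return records with categorical covariates as factors in canonical
#'   level order.
#' @export
normalize_record_types <- function(records,
                                   covariates = default_covariates()) {
  for (v in names(covariates)) {
    sp <- covariates[[v]]
    if (sp$type == "categorical" && v %in% names(records)) {
      records[[v]] <- factor(as.character(records[[v]]),
                             levels = sp$levels)
    }
  }
  records
}

#' Read a fixture directory back into a bundle
#'
#' @param directory directory written by [write_fixture()].
#' @return list with `records`, `rasters`, `truth`.
#' @export
read_fixture <- function(directory) {
  records <- normalize_record_types(
    utils::read.csv(file.path(directory, "records.csv"),
                    stringsAsFactors = FALSE))
  asc <- list.files(directory, pattern = "\\.asc$", full.names = TRUE)
  rasters <- lapply(asc, read_ascii_grid)
  names(rasters) <- sub("\\.asc$", "", basename(asc))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  list(records = records, rasters = rasters, truth = truth)
}
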