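test_that("generator config is validated", {
  expect_error(gen_config(jp_district_ids = c(0, 99)), "subset")
  expect_error(gen_config(noise_sd = c(haz = 0, waz = 1, whz = 1)),
               "positive")
  expect_error(gen_config(missing_frac = c("2009" = 1, "2016" = 0.2)),
               "\\[0, 1\\)")
  expect_error(gen_config(raster_extent = list(lat_min = 0, lat_max = 0,
                                               lon_min = 0, lon_max = 1)),
               "degenerate")
})

test_that("landscape generation is deterministic and honours overrides", {
  cfg <- small_cfg(seed = 3)
  g1 <- generate_landscape(cfg)
  g2 <- generate_landscape(cfg)
  expect_identical(lapply(g1, `[[`, "values"), lapply(g2, `[[`, "values"))
  expect_setequal(names(g1), c("mvhi", "altitude", "slope", "soil_class",
                               "pop_density", "crop_cover"))
  # one district, constant altitude, no jitter -> constant field
  cfg1 <- gen_config(n_districts = 1, jp_district_ids = integer(0),
                     attr_means = list(altitude = 500),
                     attr_rel_jitter = 0, resolution_arcsec = 600,
                     seed = 3)
  flat <- generate_landscape(cfg1)
  expect_true(all(flat$altitude$values == 500))
})

test_that("district-mean altitude is recovered by brute-force masking", {
  cfg <- gen_config(n_districts = 2, jp_district_ids = 0,
                    attr_means = list(altitude = c(200, 1200)),
                    resolution_arcsec = 600, seed = 5)
  g <- generate_landscape(cfg)
  cc <- cell_centers(g$altitude)
  # brute-force mask: district of every cell centre from the rectangle
  # layout, independent of the generator's own indexing
  lay <- malnut:::district_layout(cfg)
  ex <- cfg$raster_extent
  for (d in 0:1) {
    mask <- matrix(FALSE, length(cc$lat), length(cc$lon))
    for (i in seq_along(cc$lat)) {
      for (j in seq_along(cc$lon)) {
        col <- min(lay$nc, floor((cc$lon[j] - ex$lon_min) / lay$dlon) + 1)
        row <- min(lay$nr, floor((ex$lat_max - cc$lat[i]) / lay$dlat) + 1)
        mask[i, j] <- ((row - 1) * lay$nc + col - 1) == d
      }
    }
    got <- mean(g$altitude$values[mask])
    expect_equal(got, c(200, 1200)[d + 1], tolerance = 0.01)
  }
})

test_that("degenerate noise recovers the intercept exactly", {
  ct <- default_coef_table()
  ct$haz <- 0; ct$waz <- 0; ct$whz <- 0
  cfg <- small_cfg(
    coef_table = ct,
    intercepts = c(haz = -1.3, waz = -1.3, whz = -1.3),
    noise_sd = c(haz = 1e-12, waz = 1e-12, whz = 1e-12),
    district_effect_sd = 0, jp_baseline_offset = c(haz = 0, waz = 0, whz = 0),
    jp_effect = c(haz = 0, waz = 0, whz = 0),
    missing_frac = c("2009" = 0, "2016" = 0))
  rec <- generate_records(cfg)
  expect_equal(rec$haz, rep(-1.3, nrow(rec)), tolerance = 1e-9)
})

test_that("a generating coefficient is recovered from the sample contrast", {
  cfg <- gen_config(n_children_per_wave = 5000, seed = 17,
                    missing_frac = c("2009" = 0, "2016" = 0))
  rec <- generate_records(cfg)
  w1 <- rec[rec$wave == "2009", ]
  d <- mean(w1$haz[w1$female == 1]) - mean(w1$haz[w1$female == 0])
  se <- 1.95 * sqrt(1 / sum(w1$female == 1) + 1 / sum(w1$female == 0))
  expect_lt(abs(d - 0.35), 3 * se)
})

test_that("OLS on the true design recovers every generating coefficient", {
  cfg <- gen_config(n_children_per_wave = 5000, seed = 29,
                    missing_frac = c("2009" = 0, "2016" = 0))
  rec <- generate_records(cfg)
  w1 <- rec[rec$wave == "2009", ]
  X <- build_design(w1, c("female", "hungry_season", "suppl_food",
                          "noise_bin", "age_cat", "bmi_class", "wealth"))
  # districts as additional dummies so the generating model is exact
  w1$district_id_f <- factor(w1$district_id)
  Xd <- build_design(w1, "district_id_f")
  ct <- default_coef_table()
  for (o in c("haz", "waz", "whz")) {
    fit <- fit_linear(w1[[o]], cbind(X, Xd))
    beta_hat <- fit$coefficients
    want <- ifelse(is.na(ct$level), ct$variable,
                   paste0(ct$variable, "=", ct$level))
    for (k in seq_along(want)) {
      row <- beta_hat[beta_hat$effect == want[k], ]
      expect_equal(nrow(row), 1L)
      expect_lt(abs(row$estimate - ct[[o]][k]), 3 * row$se)
    }
  }
})

test_that("missingness is jointly masked at the calibrated rate", {
  cfg <- gen_config(n_children_per_wave = 4903,  # 9806 records in total
                    missing_frac = c("2009" = 0.2476, "2016" = 0.2476),
                    seed = 23)
  rec <- inject_missingness(generate_records(cfg), cfg)
  n <- nrow(rec)
  complete <- !is.na(rec$haz) & !is.na(rec$waz) & !is.na(rec$whz)
  p <- 1 - 0.2476
  expect_lt(abs(mean(complete) - p), 3 * sqrt(p * (1 - p) / n))
  # expected complete count at survey scale: 9806 * (1 - 0.2476) = 7378
  expect_lt(abs(sum(complete) - 7378), 3 * sqrt(n * p * (1 - p)) + 1)
  # never a partial mask
  partial <- xor(is.na(rec$haz), is.na(rec$waz)) |
    xor(is.na(rec$haz), is.na(rec$whz))
  expect_false(any(partial))
  # zero fraction is the identity
  cfg0 <- small_cfg(missing_frac = c("2009" = 0, "2016" = 0))
  rec0 <- generate_records(cfg0)
  expect_identical(inject_missingness(rec0, cfg0), rec0)
})

test_that("bundles are deterministic and fixtures round-trip", {
  cfg <- small_cfg(seed = 41)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$records, b2$records)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(b1, d1)
  write_fixture(b2, d2)
  # byte-for-byte determinism after serialization
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  rt <- read_fixture(d1)
  expect_equal(nrow(rt$records), nrow(b1$records))
  expect_identical(rt$rasters$altitude$values, b1$rasters$altitude$values)
  expect_equal(rt$records$haz, b1$records$haz)
  expect_equal(rt$truth$config$seed, cfg$seed)
  expect_equal(rt$truth$config$n_children_per_wave,
               cfg$n_children_per_wave)
  expect_equal(unlist(rt$truth$config$missing_frac),
               unlist(as.list(cfg$missing_frac)))
})

test_that("all record coordinates fall inside the extent and district", {
  cfg <- small_cfg(seed = 2)
  rec <- generate_records(cfg)
  ex <- cfg$raster_extent
  expect_true(all(rec$lat >= ex$lat_min & rec$lat <= ex$lat_max))
  expect_true(all(rec$lon >= ex$lon_min & rec$lon <= ex$lon_max))
  expect_equal(district_of_point(rec$lat, rec$lon, cfg), rec$district_id)
})
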