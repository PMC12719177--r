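test_that("recording averages and setup features follow their closed forms", {
  const <- make_recording(100, 15000, 0)
  expect_equal(average_rp(const), 15)
  two <- ecdscan:::new_recording(c(10, 20), fs = 7000, location_id = 1L)
  expect_equal(average_rp(two), 15)
  expect_error(average_rp(ecdscan:::new_recording(numeric(0), fs = 7000)), "[Ee]mpty")

  expect_equal(setup_features(matrix(7, 4, 4)),
               tibble::tibble(range_kohm = 0, mean_kohm = 7))
  expect_equal(setup_features(matrix(1:16, 4, 4)),
               tibble::tibble(range_kohm = 15, mean_kohm = 8.5))
  expect_error(setup_features(1:9))
})

test_that("SNR is |mean difference| over baseline sd, offset-invariant", {
  set.seed(4)
  base <- make_recording(30000, 20000, 2)
  target <- make_recording(30000, 20500, 2)
  expect_equal(snr(base, target), 250, tolerance = 0.02)
  # adding a common constant changes nothing
  shift <- function(r, c) { r$rp_kohm <- r$rp_kohm + c; r }
  expect_equal(snr(shift(base, 3), shift(target, 3)), snr(base, target))
  # equal distributions give near-zero SNR; zero baseline sd is an error
  same <- make_recording(30000, 20000, 2)
  expect_lt(snr(base, same), 0.05)
  expect_error(snr(make_recording(10, 20000, 0), target), "zero variance")
})

test_that("treatment setups widen the per-setup range relative to controls", {
  nm <- calibrate_noise(dev9$tank, dev9$coil, "gelatin_air", dev9$snr_air)
  spec <- dataset_spec("9cm", "benchtop", standoff_cm = 0, n_lesion = 6, n_control = 6)
  ds <- generate_dataset(spec, noise = nm, seed = 9)
  f <- as.matrix(ds[, grep("^rp_", names(ds))])
  rng <- apply(f, 1, function(v) max(v) - min(v))
  expect_gt(min(rng[ds$lesion == "yes"]), max(rng[ds$lesion == "no"]))
})

test_that("heatmaps assemble, mirror involutively, and report missing locations", {
  vals <- tibble::tibble(location_id = 1:16, mean_rp_kohm = rnorm(16, 25))
  h <- build_heatmap(vals, layout = "grid4x4")
  expect_s3_class(h, "ecd_heatmap")
  expect_equal(attr(h, "orientation"), "as-scanned")
  m <- mirror_heatmap(h)
  expect_equal(attr(m, "orientation"), "radiology")
  expect_equal(mirror_heatmap(m)$col, h$col)
  expect_equal(m$mean_rp_kohm, h$mean_rp_kohm)  # values ride along, cells mirror
  rad <- build_heatmap(vals, layout = "grid4x4", orientation = "radiology")
  expect_equal(rad$col, 5L - h$col)
  expect_error(build_heatmap(vals[-3, ], layout = "grid4x4"), "3")
})

test_that("heatmap values are permutation-equivariant in the location labels", {
  vals <- tibble::tibble(location_id = 1:9, mean_rp_kohm = rnorm(9, 25))
  h1 <- build_heatmap(vals, layout = "head9")
  h2 <- build_heatmap(vals[sample(9), ], layout = "head9")
  expect_equal(tibble::as_tibble(h1), tibble::as_tibble(h2))
})

test_that("localization takes the Rp minimum with lowest-index tie-breaking", {
  v <- rep(25, 9); v[7] <- 24
  h <- build_heatmap(tibble::tibble(location_id = 1:9, mean_rp_kohm = v), "head9")
  expect_equal(localize_lesion(h), 7L)
  v2 <- rep(25, 9); v2[c(3, 6)] <- 24
  h2 <- build_heatmap(tibble::tibble(location_id = 1:9, mean_rp_kohm = v2), "head9")
  expect_equal(localize_lesion(h2), 3L)
})

test_that("a uniform control scan stays flat at the scale of the cell noise", {
  nm <- calibrate_noise(dev9$tank, dev9$coil, "gelatin_sphere", dev9$snr_sphere)
  scan <- scan_scene(dev9$tank, dev9$coil, build_phantom(phantom_spec()))
  cell_sd <- sqrt(nm$sd_slow^2 + nm$sd^2 / 70000)
  set.seed(21)
  v <- scan$rp_ohm + rnorm(9, 0, cell_sd)
  # background structure + noise: spread bounded by a few cell sds
  expect_lt(max(v) - min(v), 6 * cell_sd + (max(scan$rp_ohm) - min(scan$rp_ohm)))
})

test_that("feature rows convert to heatmaps with the right layout", {
  ds <- generate_dataset(dataset_spec("9cm", "phantom", n_lesion = 1, n_control = 1),
                         seed = 4)
  h <- features_to_heatmap(ds[1, ])
  expect_equal(attr(h, "layout"), "head9")
  expect_equal(nrow(h), 9L)
  expect_equal(h$mean_rp_kohm, as.numeric(ds[1, grep("^rp_", names(ds))]))
})
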