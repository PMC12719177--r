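test_that("a 10 s recording at 7 kHz has 70,000 samples; noiseless means are exact", {
  sc <- build_benchtop(one_red_pattern())
  set.seed(1)
  rec <- simulate_recording(dev9$tank, dev9$coil, sc, position = 6,
                            noise = noise_model(0))
  expect_equal(nrow(rec), 70000L)
  rp_true <- dev9$tank$L1 / (dev9$tank$R1 * dev9$tank$C1) +
    delta_rp(dev9$tank, dev9$coil, sc, position = 6)
  expect_true(all(rec$rp_kohm == rp_true / 1e3))  # zero noise: constant series
  # white-noise mean recovery within the CLT bound
  set.seed(2)
  noisy <- simulate_recording(dev9$tank, dev9$coil, sc, position = 6,
                              noise = noise_model(sd = 5, sd_slow = 0))
  expect_lt(abs(average_rp(noisy) * 1e3 - rp_true), 3 * 5 / sqrt(70000))
  expect_error(simulate_recording(dev9$tank, dev9$coil, sc, duration = 0))
})

test_that("quantization confines recorded values to the converter grid", {
  sc <- build_benchtop(one_red_pattern())
  set.seed(3)
  rec <- simulate_recording(dev9$tank, dev9$coil, sc, position = 6,
                            noise = noise_model(sd = 5), range = dev9$range)
  step <- (48 - 12) * 1e3 / (65536 - 1)
  offs <- (rec$rp_kohm * 1e3 - 12e3) / step
  expect_true(all(abs(offs - round(offs)) < 1e-6))
})

test_that("doubling the target SNR halves the calibrated noise", {
  n1 <- calibrate_noise(dev9$tank, dev9$coil, "gelatin_sphere", 10)
  n2 <- calibrate_noise(dev9$tank, dev9$coil, "gelatin_sphere", 20)
  expect_equal(n2$sd, n1$sd / 2)
  expect_equal(n2$sd_slow, n1$sd_slow / 2)
  expect_error(calibrate_noise(dev9$tank, dev9$coil, "gelatin_air", -1))
})

test_that("simulated characterizations recover all four printed SNRs within 5%", {
  set.seed(11)
  combos <- list(
    list(dev6, "gelatin_air", 253.92), list(dev9, "gelatin_air", 81.25),
    list(dev6, "gelatin_sphere", 53.22), list(dev9, "gelatin_sphere", 13.89)
  )
  for (cmb in combos) {
    dev <- cmb[[1]]
    nm <- calibrate_noise(dev$tank, dev$coil, cmb[[2]], cmb[[3]])
    tgt <- if (cmb[[2]] == "gelatin_air") build_gelatin_air() else build_gelatin_sphere(TRUE)
    base <- if (cmb[[2]] == "gelatin_air") NULL else build_gelatin_sphere(FALSE)
    # 45 replicate 30-minute characterizations; the SNR is sampling-rate
    # neutral, so they are simulated at 20 Hz
    reps <- replicate(45, {
      rb <- simulate_recording(dev$tank, dev$coil, base, 1, nm,
                               duration = 1800, fs = 20)
      rt <- simulate_recording(dev$tank, dev$coil, tgt, 1, nm,
                               duration = 1800, fs = 20)
      snr(rb, rt)
    })
    expect_equal(mean(reps), cmb[[3]], tolerance = 0.05)
  }
})

test_that("datasets carry the study census and are byte-reproducible", {
  ds <- generate_dataset(dataset_spec("9cm", "phantom"), seed = 5)
  expect_equal(sum(ds$lesion == "yes"), 12L)
  expect_equal(sum(ds$lesion == "no"), 10L)
  expect_equal(sum(grepl("^rp_\\d+$", names(ds))), 9L)
  ds6 <- generate_dataset(dataset_spec("6cm", "phantom"), seed = 5)
  expect_equal(as.vector(table(ds6$lesion)), c(8L, 11L))
  expect_identical(ds, generate_dataset(dataset_spec("9cm", "phantom"), seed = 5))
  expect_false(identical(ds, generate_dataset(dataset_spec("9cm", "phantom"), seed = 6)))
  # zero-lesion spec gives an all-control table
  ctl <- generate_dataset(dataset_spec("9cm", "phantom", n_lesion = 0, n_control = 4),
                          seed = 1)
  expect_true(all(ctl$lesion == "no"))
})

test_that("a benchtop stratum yields 16 features and the census counts", {
  ds <- generate_dataset(dataset_spec("9cm", "benchtop", standoff_cm = 1), seed = 2)
  expect_equal(sum(grepl("^rp_\\d+$", names(ds))), 16L)
  expect_equal(as.vector(table(ds$lesion)), c(15L, 45L))
  expect_true(all(ds$standoff_cm == 1))
})

test_that("exact-average and full-series generation agree distributionally", {
  spec <- dataset_spec("9cm", "phantom", n_lesion = 2, n_control = 2)
  nm <- noise_model(sd = 2, sd_slow = 0)
  fast <- generate_dataset(spec, noise = nm, seed = 3)
  full <- generate_dataset(spec, noise = nm, seed = 3, full_series = TRUE)
  feats <- grep("^rp_", names(fast))
  # same noiseless levels; both routes' averages agree to the CLT scale (kOhm)
  expect_equal(as.matrix(fast[, feats]), as.matrix(full[, feats]),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("class separability shrinks monotonically with benchtop standoff", {
  sep <- vapply(c(0, 1, 2, 3), function(so) {
    ds <- generate_dataset(dataset_spec("9cm", "benchtop", standoff_cm = so), seed = 2)
    X <- as.matrix(ds[, grep("^rp_", names(ds))])
    m1 <- colMeans(X[ds$lesion == "yes", ])
    m0 <- colMeans(X[ds$lesion == "no", ])
    sqrt(sum((m1 - m0)^2)) / mean(apply(X[ds$lesion == "no", ], 2, sd))
  }, numeric(1))
  expect_true(all(diff(sep) < 0))
})
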