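test_that("an empty scene reflects nothing", {
  sc <- build_benchtop(control_pattern())
  empty <- sc[0, ]
  load <- scene_reflected_load(dev9$coil, empty)
  expect_length(load$M, 0L)
  expect_equal(delta_rp(dev9$tank, dev9$coil, empty), 0)
  expect_equal(delta_rp(dev9$tank, dev9$coil, NULL), 0)
})

test_that("doubling conductivity halves R2 and leaves M unchanged", {
  base <- build_benchtop(control_pattern(), sigma_white = 0.18, sigma_red = 0.85)
  dbl <- build_benchtop(control_pattern(), sigma_white = 0.36, sigma_red = 1.7)
  l1 <- scene_reflected_load(dev9$coil, base)
  l2 <- scene_reflected_load(dev9$coil, dbl)
  expect_equal(l2$R2, l1$R2 / 2)
  expect_equal(l2$M, l1$M)
  expect_error(scene_reflected_load(dev9$coil,
                                    build_benchtop(control_pattern(), sigma_white = -1)))
})

test_that("a small on-axis eddy loop's M matches the flux-integral oracle within 1%", {
  r_e <- 0.002  # loop radius well under the 4.5 cm coil radius
  sc <- single_voxel_scene(z_depth = 0.02, edge = 2 * r_e, eddy_scale = r_e)
  M_got <- scene_reflected_load(dev9$coil, sc)$M
  # oracle: 2-D polar quadrature of the unit-current Bz over the loop disk
  unit <- coil_spec(dev9$coil$radius, dev9$coil$n_turns, 1, dev9$coil$freq)
  rr <- (seq_len(40) - 0.5) * r_e / 40
  th <- (seq_len(64) - 0.5) * 2 * pi / 64
  grid <- expand.grid(r = rr, th = th)
  bz <- coil_field_at_point(unit, cbind(grid$r * cos(grid$th),
                                        grid$r * sin(grid$th),
                                        0.02))$Bz
  flux <- sum(bz * grid$r) * (r_e / 40) * (2 * pi / 64)
  expect_equal(M_got, flux, tolerance = 0.01)
})

test_that("conductive scenes always lower Rp, superpose, and decay with standoff", {
  sc <- build_benchtop(one_red_pattern())
  drp <- vapply(1:16, function(p) delta_rp(dev9$tank, dev9$coil, sc, position = p),
                numeric(1))
  expect_true(all(drp < 0))
  # superposition over disjoint sub-scenes is exact by construction
  top <- sc[sc$z > -0.0127, ]
  bottom <- sc[sc$z <= -0.0127, ]
  expect_equal(delta_rp(dev9$tank, dev9$coil, top, position = 6) +
                 delta_rp(dev9$tank, dev9$coil, bottom, position = 6),
               delta_rp(dev9$tank, dev9$coil, sc, position = 6))
  # |dRp| shrinks monotonically with standoff 0 -> 3 cm
  mags <- vapply(c(0, 0.01, 0.02, 0.03), function(so) {
    abs(delta_rp(dev9$tank, dev9$coil, sc, standoff = so, position = 6))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("a red cube lowers Rp below the all-white control, monotonically in sigma", {
  ctrl <- build_benchtop(control_pattern())
  red <- build_benchtop(one_red_pattern(2, 2))
  expect_lt(delta_rp(dev9$tank, dev9$coil, red, position = 6),
            delta_rp(dev9$tank, dev9$coil, ctrl, position = 6))
  # elementwise monotone in conductivity
  sigmas <- c(0.2, 0.5, 0.85, 1.5)
  drps <- vapply(sigmas, function(s) {
    delta_rp(dev9$tank, dev9$coil,
             build_benchtop(one_red_pattern(2, 2), sigma_red = s), position = 6)
  }, numeric(1))
  expect_true(all(diff(drps) < 0))
})

test_that("depth attenuation suppresses deep voxels and calibration reports honestly", {
  sc <- build_phantom(phantom_spec(2, 5))
  with_att <- delta_rp(dev9$tank, dev9$coil, sc, position = 5, delta_eff = 0.02)
  without <- delta_rp(dev9$tank, dev9$coil, sc, position = 5)
  expect_lt(abs(with_att), abs(without))
  # geometric decay alone already beats the half-contrast target, so the
  # calibrated attenuation length is infinite
  delta <- suppressMessages(calibrate_depth_attenuation())
  expect_identical(unclass(delta)[1], Inf)
  expect_lt(attr(delta, "geometric_ratio"), 0.5)
})

test_that("the shallow phantom localizes noiselessly at the lesion; the deep one's
           contrast falls below the calibrated noise floor", {
  ctl <- scan_scene(dev9$tank, dev9$coil, build_phantom(phantom_spec()))
  s0 <- scan_scene(dev9$tank, dev9$coil, build_phantom(phantom_spec(0, 6)))
  expect_equal(s0$position[which.min(s0$rp_ohm)], 6L)
  noise <- calibrate_noise(dev9$tank, dev9$coil, "gelatin_sphere", dev9$snr_sphere)
  s4 <- scan_scene(dev9$tank, dev9$coil, build_phantom(phantom_spec(4, 5)))
  sig4 <- s4$delta_rp_ohm - ctl$delta_rp_ohm   # lesion-specific differential
  expect_lt(max(sig4) - min(sig4), noise$sd_slow)
})
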