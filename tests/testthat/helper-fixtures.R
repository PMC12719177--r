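# Shared fixtures. Forward-model results are memoized inside the package, so
# rebuilding identical scenes across tests is cheap after first evaluation.

dev9 <- device_preset("9cm")
dev6 <- device_preset("6cm")

control_pattern <- function(standoff_cm = 0) {
  benchtop_pattern(matrix(FALSE, 4, 4), standoff_cm = standoff_cm)
}

one_red_pattern <- function(row = 2, col = 3, standoff_cm = 0) {
  g <- matrix(FALSE, 4, 4)
  g[row, col] <- TRUE
  benchtop_pattern(g, standoff_cm = standoff_cm)
}

# a bare synthetic recording at a given mean/sd in ohm
make_recording <- function(n, mean_ohm, sd_ohm, fs = 7000, location = 1L) {
  ecdscan:::new_recording(rnorm(n, mean_ohm, sd_ohm) / 1e3,
                          fs = fs, location_id = location)
}

# single-voxel scene builder for forward-model unit checks
single_voxel_scene <- function(z_depth, edge, eddy_scale, sigma = 0.85,
                               x = 0, y = 0) {
  ecdscan:::new_ecd_scene(
    data.frame(x = x, y = y, z = -z_depth, sigma = sigma,
               volume = edge^3, depth = z_depth),
    eddy_scale = eddy_scale, label = sigma > 0.5,
    meta = list(type = "unit"),
    scan_points = tibble::tibble(id = 1L, x = 0, y = 0, z = 0,
                                 ax = 0, ay = 0, az = -1)
  )
}

# independent two-loop impedance oracle: drive the coupled circuit with a
# unit voltage, solve the mesh equations numerically, convert the series
# input impedance to the tank's equivalent parallel resistance
rp_impedance_oracle <- function(tank, L2, R2, M, omega) {
  Z <- matrix(c(tank$R1 + 1i * omega * tank$L1, 1i * omega * M,
                1i * omega * M, R2 + 1i * omega * L2), 2, 2)
  currents <- solve(Z, c(1 + 0i, 0))
  z_in <- 1 / currents[1]
  (Im(z_in) / omega) / (Re(z_in) * tank$C1)
}

# simulate localization: noiseless scan + per-placement noise on the 10 s
# location means, then heatmap argmin
simulate_localizations <- function(dev, scene, noise, n_sim, seed0) {
  scan <- scan_scene(dev$tank, dev$coil, scene)
  cell_sd <- sqrt(noise$sd_slow^2 + noise$sd^2 / 70000)
  vapply(seq_len(n_sim), function(s) {
    set.seed(seed0 + s)
    v <- scan$rp_ohm + rnorm(nrow(scan), 0, cell_sd)
    h <- build_heatmap(
      data.frame(location_id = scan$position, mean_rp_kohm = v / 1e3),
      layout = "head9"
    )
    localize_lesion(h)
  }, integer(1))
}
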