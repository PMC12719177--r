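# Conductivity scenes: the benchtop cube grid, the phantom head, and the two
# SNR-characterization geometries, all voxelized into tidy tables.

SIGMA_WHITE <- 0.18  # S/m, healthy-brain simulating gel
SIGMA_RED <- 0.85    # S/m, hemorrhage simulating gel
CUBE_EDGE <- 0.0254  # m, benchtop gel cube edge (1 inch)
HOUSING_GAP <- 0.005 # m, coil plane recess behind the device contact face
SHELL_GAP <- 0.003   # m, plastic skull / sphere shell thickness

new_ecd_scene <- function(voxels, eddy_scale, label, meta, scan_points) {
  stopifnot(all(c("x", "y", "z", "sigma", "volume", "depth") %in% names(voxels)))
  if (nrow(voxels) > 0 && any(voxels$sigma <= 0)) abort("All voxel conductivities must be > 0.")
  tibble::new_tibble(voxels,
    eddy_scale = eddy_scale, label = label, meta = meta,
    scan_points = scan_points, nrow = nrow(voxels),
    class = "ecd_scene"
  )
}

#' @export
print.ecd_scene <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<ecd_scene: %s> %d voxels, %s, lesion = %s\n",
              m$type, nrow(x),
              sprintf("%.0f mL gel", sum(x$volume) * 1e6),
              ifelse(scene_label(x), "yes", "no")))
  NextMethod()
}

#' Scene accessors
#'
#' `scene_label()` gives the binary lesion label (`TRUE` iff any voxel
#' carries lesion-class conductivity, i.e. above the 0.5 S/m midpoint between
#' the two gel classes); `scene_scan_points()` the tibble of scan locations
#' (`id`, coil-center coordinates `x`, `y`, `z` in metres, and the unit coil
#' axis `ax`, `ay`, `az` pointing into the target — the device is held normal
#' to the local surface); `scene_meta()` the scene descriptor.
#'
#' @param scene An `ecd_scene`.
#' @return A logical, tibble, or list respectively.
#' @export
scene_label <- function(scene) {
  stopifnot(inherits(scene, "ecd_scene"))
  nrow(scene) > 0 && any(scene$sigma > 0.5)
}

#' @rdname scene_label
#' @export
scene_scan_points <- function(scene) attr(scene, "scan_points")

#' @rdname scene_label
#' @export
scene_meta <- function(scene) attr(scene, "meta")

# centers of an n-per-edge subdivision of [-e/2, e/2]
sub_centers <- function(center, edge, n) {
  off <- (seq_len(n) - (n + 1) / 2) * (edge / n)
  center + off
}

#' Benchtop cube-grid pattern
#'
#' A scanning setup of brain-tissue-simulating gel cubes: a 4 x 4 core of
#' red (hemorrhagic, 0.85 S/m) or white (healthy, 0.18 S/m) cubes, always
#' surrounded by a one-cube white frame to suppress edge effects, scanned at
#' a standoff of 0-3 cm.
#'
#' @param grid A 4 x 4 logical matrix (`TRUE` = red cube) or character matrix
#'   of `"red"`/`"white"`.
#' @param standoff_cm Sensor standoff above the cube tops, cm (0, 1, 2 or 3).
#' @return An object of class `ecd_benchtop_pattern`.
#' @examples
#' ctrl <- benchtop_pattern(matrix(FALSE, 4, 4))
#' one <- benchtop_pattern(matrix(c(TRUE, rep(FALSE, 15)), 4, 4), standoff_cm = 1)
#' @export
benchtop_pattern <- function(grid, standoff_cm = 0) {
  if (is.character(grid)) {
    if (!all(grid %in% c("red", "white"))) abort('Character grids must contain only "red"/"white".')
    grid <- grid == "red"
  }
  if (!is.matrix(grid) || !identical(dim(grid), c(4L, 4L)) || !is.logical(grid)) {
    abort("`grid` must be a 4 x 4 logical (red = TRUE) matrix.")
  }
  if (!standoff_cm %in% c(0, 1, 2, 3)) abort("`standoff_cm` must be one of 0, 1, 2, 3.")
  structure(list(grid = grid, standoff_cm = standoff_cm),
            class = "ecd_benchtop_pattern")
}

#' Build the benchtop cube-grid scene
#'
#' Voxelizes a [benchtop_pattern()]: 16 core cubes plus the 20 white frame
#' cubes of the surrounding 6 x 6 perimeter, each 1-inch cube subdivided into
#' `sub_div^3` voxels. The coordinate frame has z pointing up with the cube
#' tops at `z = 0`; the 16 scan points sit over the core cube centers at the
#' pattern's standoff. The eddy correlation scale of the scene is half the
#' cube edge (the characteristic conductor dimension).
#'
#' @param pattern A [benchtop_pattern()].
#' @param sub_div Sub-voxels per cube edge (default 3, an accuracy/speed
#'   compromise; halving the sub-voxel edge moves the forward response by
#'   well under 2 percent).
#' @param sigma_white,sigma_red Gel conductivities, S/m.
#' @return An `ecd_scene`.
#' @export
build_benchtop <- function(pattern, sub_div = 3L,
                           sigma_white = SIGMA_WHITE, sigma_red = SIGMA_RED) {
  stopifnot(inherits(pattern, "ecd_benchtop_pattern"))
  sub_div <- as.integer(sub_div)
  cube_idx <- tidyr::expand_grid(row = 1:6, col = 1:6)
  core <- cube_idx$row %in% 2:5 & cube_idx$col %in% 2:5
  red <- logical(nrow(cube_idx))
  red[core] <- pattern$grid[cbind(cube_idx$row[core] - 1L, cube_idx$col[core] - 1L)]

  # cube centers; x along columns, y along rows (row 1 at +y)
  cx <- (cube_idx$col - 3.5) * CUBE_EDGE
  cy <- (3.5 - cube_idx$row) * CUBE_EDGE
  sub <- tidyr::expand_grid(i = seq_len(sub_div), j = seq_len(sub_div), k = seq_len(sub_div))
  off <- function(i) (i - (sub_div + 1) / 2) * (CUBE_EDGE / sub_div)

  vox <- purrr::map_dfr(seq_len(nrow(cube_idx)), function(c_i) {
    tibble::tibble(
      x = cx[c_i] + off(sub$i),
      y = cy[c_i] + off(sub$j),
      z = -CUBE_EDGE / 2 + off(sub$k),
      sigma = ifelse(red[c_i], sigma_red, sigma_white),
      cube_row = cube_idx$row[c_i], cube_col = cube_idx$col[c_i]
    )
  })
  vox$volume <- (CUBE_EDGE / sub_div)^3
  vox$depth <- -vox$z  # gel overburden above the voxel

  core_rc <- tidyr::expand_grid(row = 1:4, col = 1:4)
  scan_points <- tibble::tibble(
    id = seq_len(16L),
    x = (core_rc$col + 1 - 3.5) * CUBE_EDGE,
    y = (3.5 - (core_rc$row + 1)) * CUBE_EDGE,
    z = pattern$standoff_cm / 100 + HOUSING_GAP,
    ax = 0, ay = 0, az = -1
  )
  new_ecd_scene(vox,
    eddy_scale = CUBE_EDGE / 2,
    label = any(pattern$grid),
    meta = list(type = "benchtop", pattern = pattern$grid,
                standoff_cm = pattern$standoff_cm, sub_div = sub_div),
    scan_points = scan_points
  )
}

#' Phantom head specification
#'
#' A hemiellipsoidal gel head (flat face down, dome up) holding an optional
#' 30 mL cylindrical hemorrhagic lesion. The lesion is a vertical cylinder of
#' 2 cm height (the phantom gel is cut into 2 cm slabs) whose top face lies
#' `lesion_depth_cm` below the inner skull surface directly under the chosen
#' scan location. Nine scan points cover the dome in a 3 x 3 layout.
#'
#' @param lesion_depth_cm Depth of the lesion's top face below the inner
#'   surface, cm (0, 2 or 4); ignored for control heads.
#' @param lesion_location Scan-point index 1-9 under which the lesion sits,
#'   or `NULL` for a lesion-free control head.
#' @param semi_axes_cm Ellipsoid semi-axes (x, y, z), cm. The default
#'   8.5 x 7 x 6.5 is adult-skull scale.
#' @param lesion_volume_ml Lesion volume, mL (default 30).
#' @param sensor_gap_cm Gap between the coil plane and the inner gel surface
#'   along the surface normal (plastic skull shell plus the coil's recess
#'   behind the device contact face; default 0.8 cm).
#' @return An object of class `ecd_phantom_spec`.
#' @export
phantom_spec <- function(lesion_depth_cm = 0, lesion_location = NULL,
                         semi_axes_cm = c(8.5, 7, 6.5), lesion_volume_ml = 30,
                         sensor_gap_cm = 100 * (SHELL_GAP + HOUSING_GAP)) {
  if (!is.null(lesion_location) &&
      (!lesion_location %in% 1:9)) abort("`lesion_location` must be in 1..9 (or NULL).")
  if (!lesion_depth_cm %in% c(0, 2, 4)) abort("`lesion_depth_cm` must be 0, 2 or 4.")
  if (length(semi_axes_cm) != 3 || any(semi_axes_cm <= 0)) abort("`semi_axes_cm` must be 3 positive values.")
  structure(list(lesion_depth_cm = lesion_depth_cm, lesion_location = lesion_location,
                 semi_axes_cm = semi_axes_cm, lesion_volume_ml = lesion_volume_ml,
                 sensor_gap_cm = sensor_gap_cm),
            class = "ecd_phantom_spec")
}

# nine scan points on the dome; the device is held normal to the local
# surface at a `gap` along the outward normal (skull shell plus housing)
phantom_scan_layout <- function(a, b, c_ax, gap) {
  pts <- tidyr::expand_grid(ry = c(0.45, 0, -0.45), rx = c(-0.45, 0, 0.45))
  sx <- pts$rx * a
  sy <- pts$ry * b
  zs <- c_ax * sqrt(pmax(0, 1 - (sx / a)^2 - (sy / b)^2))
  nx <- sx / a^2; ny <- sy / b^2; nz <- zs / c_ax^2
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  tibble::tibble(
    id = 1:9,
    surface_x = sx, surface_y = sy, surface_z = zs,
    x = sx + gap * nx, y = sy + gap * ny, z = zs + gap * nz,
    ax = -nx, ay = -ny, az = -nz
  )
}

#' Build the phantom head scene
#'
#' Voxelizes a [phantom_spec()] on a uniform grid (default 0.85 cm edge).
#' Lesion membership is computed with sub-voxel sampling so the discretized
#' lesion volume stays within 1 percent of the nominal 30 mL; boundary voxels
#' get a volume-weighted mixed conductivity. Coordinates: z up, flat face at
#' `z = 0`, dome apex at `z = c`.
#'
#' @param spec A [phantom_spec()].
#' @param edge_cm Voxel edge, cm (default 0.85).
#' @param sigma_white,sigma_red Gel conductivities, S/m.
#' @return An `ecd_scene` with nine scan points.
#' @export
build_phantom <- function(spec, edge_cm = 0.85,
                          sigma_white = SIGMA_WHITE, sigma_red = SIGMA_RED) {
  stopifnot(inherits(spec, "ecd_phantom_spec"))
  ax <- spec$semi_axes_cm / 100
  a <- ax[1]; b <- ax[2]; c_ax <- ax[3]
  h <- edge_cm / 100
  gx <- sub_centers(0, 2 * ceiling(a / h + 1) * h, 2 * ceiling(a / h + 1))
  gy <- sub_centers(0, 2 * ceiling(b / h + 1) * h, 2 * ceiling(b / h + 1))
  gz <- (seq_len(ceiling(c_ax / h) + 1L) - 0.5) * h
  vox <- tidyr::expand_grid(x = gx, y = gy, z = gz)
  inside_head <- function(x, y, z) {
    (x / a)^2 + (y / b)^2 + (z / c_ax)^2 <= 1 & z >= 0
  }
  # keep any voxel whose cube touches the head (center or a corner inside)
  corner_in <- matrix(FALSE, nrow(vox), 8L)
  ci <- 0L
  for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
    ci <- ci + 1L
    corner_in[, ci] <- inside_head(vox$x + sx * h / 2, vox$y + sy * h / 2,
                                   vox$z + sz * h / 2)
  }
  n_corners <- rowSums(corner_in)
  keep <- n_corners > 0L | inside_head(vox$x, vox$y, vox$z)
  vox <- vox[keep, ]
  boundary <- n_corners[keep] < 8L
  vox$head_frac <- 1
  vox$lesion_frac <- 0

  scan_points <- phantom_scan_layout(a, b, c_ax, spec$sensor_gap_cm / 100)

  lesion_in <- NULL
  if (!is.null(spec$lesion_location)) {
    p0 <- scan_points[scan_points$id == spec$lesion_location, ]
    p <- list(x = p0$surface_x, y = p0$surface_y)  # lesion axis under the scan spot
    h_les <- 0.02
    r_les <- sqrt(spec$lesion_volume_ml * 1e-6 / (pi * h_les))
    d_les <- spec$lesion_depth_cm / 100
    # the carved gel piece conforms to the dome: within the cylindrical
    # footprint, each vertical column spans [zs - d - h, zs - d] measured
    # from the local inner surface height zs(x, y)
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    for (rr in c(r_les, r_les / 2)) {
      px <- p$x + rr * cos(th); py <- p$y + rr * sin(th)
      zs_f <- c_ax^2 * (1 - (px / a)^2 - (py / b)^2)  # (zs)^2, negative if outside
      if (any(zs_f < (d_les + h_les)^2) || any(zs_f < 0)) {
        abort(sprintf(
          "Lesion (depth %g cm, location %d) is not containable inside the head.",
          spec$lesion_depth_cm, spec$lesion_location
        ))
      }
    }
    lesion_in <- function(x, y, z) {
      zs_loc <- c_ax * sqrt(pmax(0, 1 - (x / a)^2 - (y / b)^2))
      ((x - p$x)^2 + (y - p$y)^2 <= r_les^2) &
        (z >= zs_loc - d_les - h_les) & (z <= zs_loc - d_les) & z >= 0
    }
  }

  # sub-voxel sampling (5^3 points) of head and lesion membership wherever a
  # voxel straddles either boundary; shares are measured against the same
  # sample set so gel volume and lesion volume stay mutually consistent
  ns <- 5L
  cand <- boundary
  if (!is.null(lesion_in)) {
    cand <- cand | (abs(vox$x - p$x) < r_les + h & abs(vox$y - p$y) < r_les + h)
  }
  so <- (seq_len(ns) - (ns + 1) / 2) * (h / ns)
  sg <- tidyr::expand_grid(dx = so, dy = so, dz = so)
  for (i in which(cand)) {
    sx <- vox$x[i] + sg$dx; sy <- vox$y[i] + sg$dy; sz <- vox$z[i] + sg$dz
    hin <- inside_head(sx, sy, sz)
    vox$head_frac[i] <- mean(hin)
    if (!is.null(lesion_in) && any(hin)) {
      vox$lesion_frac[i] <- mean(lesion_in(sx, sy, sz) & hin) / vox$head_frac[i]
    }
  }
  vox <- vox[vox$head_frac > 0, ]
  vox$volume <- vox$head_frac * h^3
  vox$sigma <- sigma_white + vox$lesion_frac * (sigma_red - sigma_white)
  zs_v <- c_ax * sqrt(pmax(0, 1 - (vox$x / a)^2 - (vox$y / b)^2))
  vox$depth <- pmax(zs_v - vox$z, 0)
  vox <- vox[, c("x", "y", "z", "sigma", "volume", "depth", "lesion_frac")]

  new_ecd_scene(as.data.frame(vox),
    eddy_scale = 0.01,  # half the 2 cm lesion/slab height
    label = !is.null(spec$lesion_location),
    meta = list(type = "phantom", depth_cm = spec$lesion_depth_cm,
                location = spec$lesion_location, spec = spec, edge_cm = edge_cm),
    scan_points = scan_points
  )
}

#' SNR characterization geometries
#'
#' `build_gelatin_air()`: a 30 mL saline-gelatin cylinder (2 cm tall) alone in
#' air, its top face just under the coil — the low-background geometry.
#' `build_gelatin_sphere()`: a saline-filled sphere (0.2 S/m, brain-mimicking
#' background) with an optional 30 mL gelatin lesion attached to its top inner
#' surface — the high-background geometry. Both have a single scan point on
#' top.
#'
#' @param volume_ml Target volume of the gel, mL.
#' @param sigma Gel conductivity, S/m.
#' @param edge_cm Voxel edge, cm.
#' @param gap_cm Coil-to-gel gap, cm (the device rests on the gel, so the
#'   coil recess alone separates them).
#' @return An `ecd_scene`.
#' @export
build_gelatin_air <- function(volume_ml = 30, sigma = SIGMA_RED, edge_cm = 0.5,
                              gap_cm = 100 * HOUSING_GAP) {
  h_cyl <- 0.02
  r_cyl <- sqrt(volume_ml * 1e-6 / (pi * h_cyl))
  h <- edge_cm / 100
  n_xy <- 2 * ceiling(r_cyl / h)
  gx <- sub_centers(0, n_xy * h, n_xy)
  gz <- -(seq_len(ceiling(h_cyl / h)) - 0.5) * (h_cyl / ceiling(h_cyl / h))
  vox <- tidyr::expand_grid(x = gx, y = gx, z = gz)
  vox <- vox[vox$x^2 + vox$y^2 <= r_cyl^2, ]
  vox$sigma <- sigma
  vox$volume <- volume_ml * 1e-6 / nrow(vox)  # cylinder volume spread exactly
  vox$depth <- -vox$z
  new_ecd_scene(as.data.frame(vox),
    eddy_scale = h_cyl / 2, label = sigma > 0.5,
    meta = list(type = "gelatin_air", volume_ml = volume_ml),
    scan_points = tibble::tibble(id = 1L, x = 0, y = 0, z = gap_cm / 100,
                                 ax = 0, ay = 0, az = -1)
  )
}

#' @rdname build_gelatin_air
#' @param lesion Include the 30 mL lesion attached to the top inner surface?
#' @param radius_cm Sphere radius, cm.
#' @param sigma_saline Background saline conductivity, S/m (0.2, mimicking
#'   brain tissue).
#' @param sigma_lesion Lesion gel conductivity, S/m.
#' @export
build_gelatin_sphere <- function(lesion = TRUE, radius_cm = 8, sigma_saline = 0.2,
                                 sigma_lesion = SIGMA_RED, volume_ml = 30,
                                 edge_cm = 0.85,
                                 gap_cm = 100 * (SHELL_GAP + HOUSING_GAP)) {
  rs <- radius_cm / 100
  h <- edge_cm / 100
  n <- 2 * ceiling(rs / h)
  g <- sub_centers(0, n * h, n)
  vox <- tidyr::expand_grid(x = g, y = g, dz = g)
  # sphere center at z = -rs so the top pole touches z = 0
  vox$z <- vox$dz - rs
  vox <- vox[vox$x^2 + vox$y^2 + vox$dz^2 <= rs^2, c("x", "y", "z")]
  vox$sigma <- sigma_saline
  vox$volume <- h^3
  vox$depth <- -vox$z
  if (lesion) {
    h_cyl <- 0.02
    r_cyl <- sqrt(volume_ml * 1e-6 / (pi * h_cyl))
    in_les <- vox$x^2 + vox$y^2 <= r_cyl^2 & vox$z >= -h_cyl
    vox$sigma[in_les] <- sigma_lesion
  }
  new_ecd_scene(as.data.frame(vox),
    eddy_scale = 0.01, label = lesion,
    meta = list(type = "gelatin_sphere", lesion = lesion, radius_cm = radius_cm),
    scan_points = tibble::tibble(id = 1L, x = 0, y = 0, z = gap_cm / 100,
                                 ax = 0, ay = 0, az = -1)
  )
}

#' Enumerate the benchtop cube configurations
#'
#' A deterministic, seeded list of 52 distinct 4 x 4 patterns stratified
#' across lesion counts 0-16: the all-white control first, the all-red
#' extreme last, and seeded draws of distinct intermediate patterns (three
#' per count 1-15, plus one extra for counts 1-5). The exact census of
#' configurations used in the original benchtop campaign is not published;
#' this generator stands in for it reproducibly.
#'
#' @param seed Integer seed for the pattern draws.
#' @param standoff_cm Standoff attached to every returned pattern.
#' @return A list of 52 [benchtop_pattern()] objects (first = control).
#' @export
enumerate_benchtop_configs <- function(seed = 1L, standoff_cm = 0) {
  counts <- c(rep(1:15, each = 3L), 1:5)
  withr::with_seed(seed, {
    seen <- character()
    mats <- list(matrix(FALSE, 4, 4))
    seen <- "0"
    for (n_red in sort(counts)) {
      repeat {
        g <- matrix(FALSE, 4, 4)
        g[sample.int(16L, n_red)] <- TRUE
        key <- paste(which(g), collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          mats[[length(mats) + 1L]] <- g
          break
        }
      }
    }
    mats[[length(mats) + 1L]] <- matrix(TRUE, 4, 4)
    purrr::map(mats, benchtop_pattern, standoff_cm = standoff_cm)
  })
}
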