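# Scan analysis: per-location averages, setup features, SNR, heatmaps,
# lesion localization.

#' Average Rp of a recording
#'
#' @param rec An `ecd_recording` (see [simulate_recording()]).
#' @return Arithmetic mean of the samples, kOhm.
#' @export
average_rp <- function(rec) {
  stopifnot(inherits(rec, "ecd_recording"))
  if (nrow(rec) == 0L) abort("Empty recording.")
  mean(rec$rp_kohm)
}

#' Per-setup summary features of a benchtop scan
#'
#' The two quantities used to separate lesion setups from controls:
#' the data range (max - min) and the average signal over all 16 cubes.
#'
#' @param values The 16 per-cube mean Rp values (kOhm), as a 4 x 4 matrix or
#'   length-16 vector.
#' @return A one-row tibble with `range_kohm` and `mean_kohm`.
#' @export
setup_features <- function(values) {
  v <- as.numeric(values)
  if (length(v) != 16L || any(!is.finite(v))) {
    abort("`values` must be 16 finite per-cube means (a 4 x 4 matrix).")
  }
  tibble::tibble(range_kohm = max(v) - min(v), mean_kohm = mean(v))
}

#' Signal-to-noise ratio of a target recording against baseline
#'
#' Signal is the difference in average Rp between the target-present and
#' baseline recordings; noise is the standard deviation of the baseline
#' recording: `SNR = |mean(target) - mean(baseline)| / sd(baseline)`.
#' Invariant to a common offset; scales inversely with the baseline sd.
#'
#' @param baseline,target `ecd_recording` objects.
#' @return The dimensionless SNR.
#' @export
snr <- function(baseline, target) {
  stopifnot(inherits(baseline, "ecd_recording"), inherits(target, "ecd_recording"))
  if (nrow(baseline) == 0L || nrow(target) == 0L) abort("Recordings must be non-empty.")
  s <- sd(baseline$rp_kohm)
  if (s == 0) abort("Baseline has zero variance: SNR is infinite.")
  abs(mean(target$rp_kohm) - mean(baseline$rp_kohm)) / s
}

heatmap_layouts <- list(
  grid4x4 = tidyr::expand_grid(row = 1:4, col = 1:4) |>
    dplyr::mutate(location_id = dplyr::row_number()),
  head9 = tidyr::expand_grid(row = 1:3, col = 1:3) |>
    dplyr::mutate(location_id = dplyr::row_number())
)

#' Assemble a conductivity heatmap from per-location scans
#'
#' Arranges per-location mean Rp values on the scan layout: the 4 x 4
#' benchtop grid or the 9-point head layout (ids 1-9, row-major from the
#' front-left). `"radiology"` orientation mirrors the map left-right so it
#' matches the display convention of CT/MRI images; mirroring twice is the
#' identity.
#'
#' @param scans Either a list of `ecd_recording`s covering every location or
#'   a data frame with `location_id` and `mean_rp_kohm` columns.
#' @param layout `"grid4x4"` or `"head9"`.
#' @param orientation `"as-scanned"` or `"radiology"`.
#' @return An object of class `ecd_heatmap`: a tibble with `location_id`,
#'   `row`, `col`, `mean_rp_kohm`.
#' @export
build_heatmap <- function(scans, layout = c("grid4x4", "head9"),
                          orientation = c("as-scanned", "radiology")) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  grid <- heatmap_layouts[[layout]]
  if (is.data.frame(scans)) {
    vals <- tibble::tibble(location_id = scans$location_id,
                           mean_rp_kohm = scans$mean_rp_kohm)
  } else {
    vals <- purrr::map_dfr(scans, function(r) {
      tibble::tibble(location_id = attr(r, "location_id"), mean_rp_kohm = average_rp(r))
    })
  }
  missing <- setdiff(grid$location_id, vals$location_id)
  if (length(missing) > 0) {
    abort(sprintf("Missing scan locations: %s.", paste(missing, collapse = ", ")))
  }
  out <- dplyr::inner_join(grid, vals, by = "location_id") |>
    dplyr::arrange(.data$location_id)
  out <- tibble::new_tibble(out, layout = layout, orientation = "as-scanned",
                            nrow = nrow(out), class = "ecd_heatmap")
  if (orientation == "radiology") out <- mirror_heatmap(out) else out
}

#' @rdname build_heatmap
#' @param h An `ecd_heatmap`.
#' @export
mirror_heatmap <- function(h) {
  stopifnot(inherits(h, "ecd_heatmap"))
  nc <- max(h$col)
  h$col <- nc + 1L - h$col
  attr(h, "orientation") <- setdiff(c("as-scanned", "radiology"), attr(h, "orientation"))
  h
}

#' Localize the lesion on a heatmap
#'
#' The scan point with the lowest mean Rp marks the highest local
#' conductivity, i.e. the most lesion-like location. Ties (measure-zero
#' under noise) are broken toward the lowest location id.
#'
#' @param h An `ecd_heatmap`.
#' @return The winning `location_id` (integer).
#' @export
localize_lesion <- function(h) {
  stopifnot(inherits(h, "ecd_heatmap"))
  h$location_id[which.min(h$mean_rp_kohm)]
}

#' Heatmap from a dataset feature row
#'
#' Convenience bridge from one [generate_dataset()] row to an `ecd_heatmap`.
#'
#' @param row A one-row data frame with `rp_*` feature columns.
#' @inheritParams build_heatmap
#' @return An `ecd_heatmap`.
#' @export
features_to_heatmap <- function(row, layout = NULL,
                                orientation = c("as-scanned", "radiology")) {
  feats <- as.numeric(row[1, grepl("^rp_\\d+$", names(row))])
  layout <- layout %||% if (length(feats) == 16L) "grid4x4" else "head9"
  build_heatmap(
    tibble::tibble(location_id = seq_along(feats), mean_rp_kohm = feats),
    layout = layout, orientation = orientation
  )
}
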