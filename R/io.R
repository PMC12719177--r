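# Readers and writers: the evaluation-board recording log dialect, feature
# tables, and the metrics report bundle.

#' Write / read an evaluation-board recording log
#'
#' The log dialect is a comment header of `#key=value` lines (device, Rp
#' range, sampling rate, timestamp) followed by CSV columns
#' `index,Rp_kOhm,L_uH` (the converter's Rp+L streaming mode; the inductance
#' column is optional and retained as metadata).
#'
#' @param rec An `ecd_recording`.
#' @param path File path.
#' @param range Optional [rp_range()] recorded in the header and used for
#'   out-of-range warnings on read.
#' @return `write_evm_csv()` returns `path` invisibly; `read_evm_csv()`
#'   returns an `ecd_recording`.
#' @export
write_evm_csv <- function(rec, path, range = NULL) {
  stopifnot(inherits(rec, "ecd_recording"))
  header <- c(
    sprintf("#device=%s", attr(rec, "device")),
    sprintf("#fs_hz=%g", attr(rec, "fs")),
    sprintf("#location=%s", attr(rec, "location_id")),
    if (!is.null(range)) sprintf("#rp_range_kohm=%g,%g", range$lo_kohm, range$hi_kohm)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("index,Rp_kOhm,L_uH", con)
  writeLines(sprintf("%d,%.17g,", rec$sample, rec$rp_kohm), con)
  invisible(path)
}

#' @rdname write_evm_csv
#' @export
read_evm_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort(sprintf("Empty recording log: %s", path))
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  n_skip <- length(hdr)
  if (length(lines) <= n_skip) abort(sprintf("Recording log has no data rows: %s", path))
  body_lines <- if (n_skip > 0L) lines[-seq_len(n_skip)] else lines
  df <- suppressWarnings(
    readr::read_csv(I(body_lines), col_types = "idd", progress = FALSE)
  )
  if (nrow(df) == 0L) abort(sprintf("Recording log has no data rows: %s", path))
  probs <- readr::problems(df)
  probs <- probs[probs$expected != "3 columns", ]  # trailing empty L column is fine
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed row at line %d of %s: expected %s, got %s.",
                  probs$row[1] + n_skip + 1L, path, probs$expected[1], probs$actual[1]))
  }
  if (is.unsorted(df$index, strictly = TRUE)) {
    abort(sprintf("Sample index in %s is not strictly increasing.", path))
  }
  # re-parse the Rp field with R's correctly rounded parser so that
  # write -> read round-trips are bit-exact
  df$Rp_kOhm <- as.numeric(vapply(strsplit(body_lines[-1L], ",", fixed = TRUE),
                                  `[`, "", 2L))
  if (!is.null(meta$rp_range_kohm)) {
    rg <- as.numeric(strsplit(meta$rp_range_kohm, ",")[[1]])
    out_of_range <- df$Rp_kOhm < rg[1] | df$Rp_kOhm > rg[2]
    if (any(out_of_range)) {
      warn(sprintf("%d Rp values in %s fall outside the device range [%g, %g] kOhm; kept as-is.",
                   sum(out_of_range), path, rg[1], rg[2]))
    }
  }
  rec <- new_recording(df$Rp_kOhm,
                       fs = as.numeric(meta$fs_hz %||% NA),
                       location_id = as.integer(meta$location %||% NA),
                       device = meta$device %||% NA_character_)
  attr(rec, "L_uH") <- df$L_uH
  rec
}

#' Load a deposited feature-table CSV
#'
#' Best-effort reader for externally deposited per-experiment feature tables
#' (one row per experiment: metadata, 9 or 16 Rp features in kOhm, and a
#' binary lesion label). The expected default layout has feature columns
#' matching `rp_*` (or `V1..V16`) and a label column named `Lesion` (or
#' `lesion`) coded Yes/No; deviations can be bridged with `col_map`.
#'
#' @param path CSV file path.
#' @param col_map Optional named list mapping `label` and `features` to the
#'   file's column names.
#' @return A tibble in [generate_dataset()] layout (features `rp_01`, ...,
#'   label factor `lesion`).
#' @export
load_mendeley_dataset <- function(path, col_map = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  label_col <- col_map$label %||%
    intersect(c("Lesion", "lesion", "label"), names(df))[1]
  if (is.na(label_col) || is.null(label_col) || !label_col %in% names(df)) {
    abort(paste(
      "No label column found: expected one of 'Lesion', 'lesion', 'label'",
      "(Yes/No coded), or a `col_map$label` entry naming it."
    ))
  }
  feat_cols <- col_map$features %||% {
    fc <- grep("^(rp_?\\d+|V\\d+)$", names(df), value = TRUE, ignore.case = TRUE)
    fc
  }
  if (!length(feat_cols) %in% c(9L, 16L)) {
    abort(sprintf(
      "Expected 9 or 16 feature columns (rp_* or V*), found %d; pass `col_map$features`.",
      length(feat_cols)
    ))
  }
  feats <- df[, feat_cols]
  names(feats) <- sprintf("rp_%02d", seq_along(feat_cols))
  lab <- tolower(as.character(df[[label_col]]))
  if (!all(lab %in% c("yes", "no"))) abort("Label column must be coded Yes/No.")
  dplyr::bind_cols(
    tibble::tibble(id = seq_len(nrow(df)),
                   lesion = factor(lab, levels = c("no", "yes"))),
    feats
  )
}

#' Write a metrics report bundle
#'
#' Writes a schema-versioned `metrics.json` (per-result AUC and
#' confusion-matrix metrics, the run seed, and a config echo), one ROC CSV
#' per result, and optional heatmap cell-value CSVs. Output is deterministic
#' for fixed inputs.
#'
#' @param results A named list of `ecd_eval` objects.
#' @param dir Output directory (created if needed).
#' @param seed The run seed to record.
#' @param config A list echoed verbatim into the JSON.
#' @param heatmaps Optional named list of `ecd_heatmap` objects.
#' @return The path of `metrics.json`, invisibly.
#' @export
write_report <- function(results, dir, seed = NA_integer_, config = list(),
                         heatmaps = NULL) {
  if (inherits(results, "ecd_eval")) results <- list(result = results)
  stopifnot(all(purrr::map_lgl(results, inherits, "ecd_eval")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- purrr::map(results, function(r) {
    as.list(glance(r))
  })
  json_path <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    list(schema_version = "1.0", seed = seed, config = config, metrics = metrics),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (nm in names(results)) {
    readr::write_csv(results[[nm]]$roc, file.path(dir, sprintf("roc_%s.csv", nm)))
  }
  for (nm in names(heatmaps)) {
    readr::write_csv(tibble::as_tibble(heatmaps[[nm]]),
                     file.path(dir, sprintf("heatmap_%s.csv", nm)))
  }
  invisible(json_path)
}
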