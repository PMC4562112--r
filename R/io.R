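#' Read and write landmark annotation CSV files
#'
#' The landmark CSV is the package's exchange format for clicked points:
#' columns `image_id`, `tooth_id`, `root`, `label`, `aspect`, `x_px`,
#' `y_px`, UTF-8, header row, dot decimal separator.  Simulated and
#' hand-annotated data use the identical format.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a data frame with those columns.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_input("landmark file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop_input("cannot parse landmark CSV %s: %s",
                                   path, conditionMessage(e)))
  need <- c("image_id", "tooth_id", "root", "label", "aspect", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop_input("landmark CSV %s is missing column(s): %s",
               path, paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stop_input("landmark CSV %s contains no landmarks", path)
  for (col in c("image_id", "tooth_id", "root", "label", "aspect")) {
    df[[col]] <- as.character(df[[col]])
  }
  bad <- which(!is.finite(df$x_px) | !is.finite(df$y_px))
  if (length(bad)) {
    stop_input("landmark CSV %s: non-numeric coordinates on data line(s) %s",
               path, paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_landmarks
#' @param landmarks Data frame with columns `image_id`, `tooth_id`, `root`,
#'   `label`, `aspect` and either `x`/`y` or `x_px`/`y_px`.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- as.data.frame(landmarks)
  if ("x" %in% names(df) && !"x_px" %in% names(df)) {
    df$x_px <- df$x; df$y_px <- df$y
  }
  df <- df[, c("image_id", "tooth_id", "root", "label", "aspect", "x_px", "y_px")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write calibration sidecar JSON
#'
#' A calibration sidecar maps image ids to their pixel size:
#' `[{"image_id": ..., "mm_per_px": ...}, ...]` (a single object is also
#' accepted).
#'
#' @param path File path.
#' @return `read_calibrations()` returns a data frame with columns
#'   `image_id`, `mm_per_px`.
#' @export
read_calibrations <- function(path) {
  if (!file.exists(path)) stop_input("calibration file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_input("cannot parse calibration JSON %s: %s",
                                                 path, conditionMessage(e)))
  df <- as.data.frame(obj, stringsAsFactors = FALSE)
  if (!all(c("image_id", "mm_per_px") %in% names(df))) {
    stop_input("calibration JSON %s must provide image_id and mm_per_px", path)
  }
  if (any(!is.finite(df$mm_per_px)) || any(df$mm_per_px <= 0)) {
    stop_input("calibration JSON %s: mm_per_px must be positive", path)
  }
  df[, intersect(c("image_id", "mm_per_px", "acquired_date"), names(df))]
}

#' @rdname read_calibrations
#' @param calibrations Data frame with columns `image_id`, `mm_per_px`.
#' @export
write_calibrations <- function(calibrations, path) {
  jsonlite::write_json(as.data.frame(calibrations), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write long-format reading tables
#'
#' Columns `site`, `examiner`, `repeat`, `angle`, `metric`, `value` — the
#' reliability module's input format.
#'
#' @param path File path.
#' @return `read_readings()` returns a `relrbl_readings` data frame.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop_input("readings file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_input("cannot parse readings CSV %s: %s",
                                   path, conditionMessage(e)))
  df <- validate_readings(df)
  df$site <- as.character(df$site)
  df$metric <- as.character(df$metric)
  class(df) <- c("relrbl_readings", "data.frame")
  df
}

#' @rdname read_readings
#' @param readings Long-format data frame.
#' @export
write_readings <- function(readings, path) {
  df <- as.data.frame(readings)
  df <- df[, c("site", "examiner", "repeat", "angle", "metric", "value")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Group a landmark table into site_annotation objects, one per
# image_id x tooth_id, attaching each image's calibration.
landmarks_to_sites <- function(landmarks, calibrations) {
  keys <- unique(landmarks[, c("image_id", "tooth_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- landmarks$image_id == keys$image_id[i] &
      landmarks$tooth_id == keys$tooth_id[i]
    sub <- landmarks[sel, , drop = FALSE]
    mmpp <- calibrations$mm_per_px[match(keys$image_id[i], calibrations$image_id)]
    if (is.na(mmpp)) {
      stop_input("no calibration for image '%s' (no silent default is applied)",
                 keys$image_id[i])
    }
    pts <- data.frame(label = sub$label, aspect = sub$aspect, root = sub$root,
                      x = sub$x_px, y = sub$y_px, stringsAsFactors = FALSE)
    site_annotation(keys$image_id[i], keys$tooth_id[i], pts, calibration(mmpp))
  })
}
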