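## canonical 23-column tracking-table layout; head and tail triplets mirror
## the body (no two-ellipse decomposition), curvature is a placeholder
tracking_columns <- c(
  "xHead", "yHead", "tHead", "xTail", "yTail", "tTail",
  "xBody", "yBody", "tBody", "curvature",
  "areaBody", "perimeterBody",
  "headMajorAxisLength", "headMinorAxisLength", "headExcentricity",
  "tailMajorAxisLength", "tailMinorAxisLength", "tailExcentricity",
  "bodyMajorAxisLength", "bodyMinorAxisLength", "bodyExcentricity",
  "imageNumber", "id"
)

#' Write a trajectory set as a plain-text tracking table
#'
#' One row per object per frame, 23 tab-separated named columns, rows sorted
#' by `imageNumber` then `id`, floating values with 6 significant digits.
#' The main columns are the body position and direction (`xBody`, `yBody`,
#' `tBody`, radians in `[0, 2*pi)`), `areaBody`, `perimeterBody`, the object
#' identity `id` and the frame index `imageNumber`; head/tail triplets and
#' ellipse descriptors duplicate the body values, and `curvature` is 0.
#'
#' @param traj A non-empty `trajectory_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tracking <- function(traj, path) {
  if (nrow(traj) == 0) abort("refusing to write an empty trajectory set")
  df <- as_tibble(traj)
  major <- if ("major" %in% names(df) && !anyNA(df$major)) df$major else sqrt(df$area / pi)
  minor <- if ("minor" %in% names(df) && !anyNA(df$minor)) df$minor else sqrt(df$area / pi)
  ecc <- sqrt(pmax(1 - (minor / pmax(major, 1e-12))^2, 0))
  out <- tibble(
    xHead = df$x, yHead = df$y, tHead = df$theta,
    xTail = df$x, yTail = df$y, tTail = df$theta,
    xBody = df$x, yBody = df$y, tBody = df$theta,
    curvature = 0,
    areaBody = df$area, perimeterBody = df$perimeter,
    headMajorAxisLength = major, headMinorAxisLength = minor,
    headExcentricity = ecc,
    tailMajorAxisLength = major, tailMinorAxisLength = minor,
    tailExcentricity = ecc,
    bodyMajorAxisLength = major, bodyMinorAxisLength = minor,
    bodyExcentricity = ecc,
    imageNumber = df$frame, id = df$id
  )
  out <- dplyr::arrange(out, .data$imageNumber, .data$id)
  fmt <- vapply(out, function(col) {
    if (is.numeric(col)) sprintf("%.6g", col) else as.character(col)
  }, character(nrow(out)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(tracking_columns, collapse = "\t"), con)
  writeLines(apply(matrix(fmt, nrow = nrow(out)), 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a plain-text tracking table
#'
#' Header-driven (column order is irrelevant); requires at least `xBody`,
#' `yBody`, `imageNumber` and `id`, and maps the canonical columns back to a
#' trajectory set. Missing optional columns are filled with `NA`.
#'
#' @param path Path to a tab-separated tracking table.
#' @return A `trajectory_set` tibble.
#' @export
read_tracking <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  required <- c("xBody", "yBody", "imageNumber", "id")
  miss <- setdiff(required, hdr)
  if (length(miss) > 0)
    abort(paste0("missing required column: ", paste(miss, collapse = ", ")))
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  pr <- readr::problems(df)
  if (nrow(pr) > 0)
    abort(paste0("non-numeric cell in row ", pr$row[1], ", column ", pr$col[1]))
  grab <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
  out <- tibble(
    frame = as.integer(df$imageNumber), id = as.integer(df$id),
    x = df$xBody, y = df$yBody,
    theta = grab("tBody"), area = grab("areaBody"),
    perimeter = grab("perimeterBody"),
    major = grab("bodyMajorAxisLength"), minor = grab("bodyMinorAxisLength")
  )
  new_trajectory_set(dplyr::arrange(out, .data$frame, .data$id))
}

## ---- flat key = value configuration -------------------------------------

config_keys <- c(
  "n_objects", "n_frames", "roi_width", "roi_height", "step_sigma",
  "angle_sigma", "semi_major", "semi_minor", "noise_sigma", "polarity",
  "appearance_rate", "seed",
  "background_method", "n_background_frames", "detection_polarity",
  "threshold", "min_area", "max_area",
  "s_r", "s_alpha", "s_A", "s_p", "h_r", "h_alpha", "h_A", "h_p", "h_t",
  "tolerance", "max_iter", "delta", "n_angles", "max_frames",
  "scan_h_r", "scan_h_t", "scan_s_r", "scan_s_alpha"
)

#' Read or write a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values parse as numbers when possible, comma-separated lists as numeric
#' vectors, anything else as strings. Unknown keys are rejected by name.
#'
#' @param path File path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("malformed config line: ", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% config_keys)
      abort(paste0("unknown configuration key: ", key))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  bad <- setdiff(names(config), config_keys)
  if (length(bad) > 0)
    abort(paste0("unknown configuration key: ", paste(bad, collapse = ", ")))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 10), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
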