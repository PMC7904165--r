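#' Frame stacks
#'
#' A `frame_stack` is an ordered list of 2D grayscale matrices (rows = y,
#' columns = x, intensities in `[0, 255]`) with strictly increasing integer
#' frame indices stored in attribute `frames`.
#'
#' @param mats List of numeric matrices, all the same shape.
#' @param frames Integer frame indices (default `0:(length(mats)-1)`).
#' @return A `frame_stack`.
#' @export
frame_stack <- function(mats, frames = seq_along(mats) - 1L) {
  if (length(mats) == 0) abort("a frame stack needs at least one frame")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all frames must have the same shape")
  frames <- as.integer(frames)
  if (length(frames) != length(mats) || is.unsorted(frames, strictly = TRUE))
    abort("frame indices must be strictly increasing, one per frame")
  structure(mats, frames = frames, class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat("<frame_stack> ", length(x), " frames of ", d[2], "x", d[1],
      " px (x by y)\n", sep = "")
  invisible(x)
}

frame_indices <- function(stack) attr(stack, "frames")

#' Write a frame stack as numbered image files
#'
#' Frames are written as 8-bit grayscale `frame_NNNNNN.png` (or plain-text
#' PGM, `P2`) files with left-padded zero numbering so lexicographic order is
#' frame order.
#'
#' @param stack A [frame_stack()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"pgm"`.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(stack, dir, format = c("png", "pgm")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- frame_indices(stack)
  paths <- character(length(stack))
  for (i in seq_along(stack)) {
    f <- file.path(dir, sprintf("frame_%06d.%s", idx[i], format))
    m <- round(pmin(pmax(stack[[i]], 0), 255))
    if (format == "png") {
      png::writePNG(m / 255, f)
    } else {
      con <- file(f, "w")
      writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
      write(t(m), con, ncolumns = ncol(m))
      close(con)
    }
    paths[i] <- f
  }
  invisible(paths)
}

#' Read an image sequence into a frame stack
#'
#' Reads all `.png`/`.pgm` files in a directory, sorted by filename (the
#' zero-padded naming convention of [write_frames()] guarantees frame order),
#' as 8-bit grayscale. RGB images are averaged over channels.
#'
#' @param dir Directory containing numbered image files.
#' @return A [frame_stack()]; frame indices are parsed from `frame_NNNNNN`
#'   names when present, else `0:(n-1)`.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|pgm)$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no image files found in ", dir))
  mats <- lapply(files, read_gray_image)
  nums <- suppressWarnings(as.integer(sub("^frame_0*([0-9]+)\\..*$", "\\1",
                                          basename(files))))
  if (anyNA(nums) || any(duplicated(nums))) nums <- seq_along(files) - 1L
  frame_stack(mats, nums)
}

read_gray_image <- function(path) {
  if (grepl("\\.png$", path)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
    a * 255
  } else {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") abort("only plain (P2) PGM files are supported")
    w <- as.integer(txt[2]); h <- as.integer(txt[3])
    vals <- as.numeric(txt[-(1:4)])
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
}
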