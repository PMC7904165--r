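#' Detection parameters
#'
#' Settings for turning raw frames into per-frame blobs. The background is
#' estimated as the per-pixel `min`, `max` or `mean` over `n_background_frames`
#' frames sampled at regular intervals (stride `floor(T/n)`, starting at the
#' first frame), unless supplied explicitly. `polarity` states whether the
#' background is lighter or darker than the objects; the difference in the
#' stated direction is thresholded, an ordered list of morphological
#' operations is applied, and 8-connected components with filled pixel count
#' in `[min_area, max_area]` become blobs.
#'
#' @param background_method One of `"min"`, `"max"`, `"mean"`.
#' @param n_background_frames Number of frames sampled for the background.
#' @param polarity `"lighter"` (background lighter than objects) or
#'   `"darker"`.
#' @param threshold Binarization threshold, intensity units.
#' @param morph_ops List of operations, each `list(op =, shape =, size =)`;
#'   see [morph_filter()].
#' @param min_area,max_area Area filter bounds, pixels.
#' @param roi Optional axis-aligned rectangle `c(x0, y0, x1, y1)` (0-based
#'   pixel coordinates, inclusive); pixels outside are ignored. Default: full
#'   image.
#' @return A `detection_params` list.
#' @export
detection_params <- function(background_method = c("max", "min", "mean"),
                             n_background_frames = 10L,
                             polarity = c("lighter", "darker"),
                             threshold = 50,
                             morph_ops = list(),
                             min_area = 10, max_area = Inf,
                             roi = NULL) {
  background_method <- match.arg(background_method)
  polarity <- match.arg(polarity)
  if (n_background_frames < 1) abort("`n_background_frames` must be >= 1.")
  if (min_area <= 0 || min_area > max_area)
    abort("require 0 < min_area <= max_area")
  structure(
    list(background_method = background_method,
         n_background_frames = as.integer(n_background_frames),
         polarity = polarity, threshold = threshold,
         morph_ops = morph_ops, min_area = min_area, max_area = max_area,
         roi = roi),
    class = "detection_params"
  )
}

#' Estimate the background image of a movie
#'
#' Per-pixel reduction (`min`, `max` or `mean`) over `n` frames sampled at
#' regular intervals: stride `floor(T/n)` starting at the first frame. With a
#' static light background and moving dark objects, `max` recovers the clean
#' background (and `min` the converse).
#'
#' @param stack A [frame_stack()].
#' @param method `"min"`, `"max"` or `"mean"`.
#' @param n Number of frames to sample (`n <= length(stack)`).
#' @return A matrix of the same shape as the frames.
#' @export
estimate_background <- function(stack, method = c("max", "min", "mean"), n = 10L) {
  method <- match.arg(method)
  if (length(stack) == 0) abort("empty frame stack")
  n <- min(as.integer(n), length(stack))
  if (n < 1) abort("`n` must be >= 1")
  stride <- max(1L, floor(length(stack) / n))
  sel <- seq(1L, by = stride, length.out = n)
  sel <- sel[sel <= length(stack)]
  mats <- stack[sel]
  out <- mats[[1]]
  if (method == "min") {
    for (m in mats[-1]) out <- pmin(out, m)
  } else if (method == "max") {
    for (m in mats[-1]) out <- pmax(out, m)
  } else {
    out <- Reduce(`+`, mats) / length(mats)
  }
  out
}

#' Estimate a translational drift by pyramidal phase correlation
#'
#' The Fourier shift theorem turns a translation into a phase ramp; the peak
#' of the inverse transform of the normalised cross-power spectrum locates the
#' shift. Estimation is coarse-to-fine: it starts on images downsampled by 4
#' per extra pyramid level (robust to large drifts) and is refined at full
#' resolution, with subpixel refinement by parabolic interpolation around the
#' correlation peak.
#'
#' @param reference,moving Grayscale matrices of identical shape.
#' @param pyramid_levels Number of pyramid levels (>= 1; 2 = one x4
#'   downsampled pass plus full resolution).
#' @return Named numeric `c(dx, dy)`: the estimated translation of `moving`
#'   relative to `reference`, so shifting `moving` by `(-dx, -dy)` aligns it.
#' @export
register_phase_correlation <- function(reference, moving, pyramid_levels = 2L) {
  if (!all(dim(reference) == dim(moving))) abort("images must have the same shape")
  if (pyramid_levels < 1) abort("`pyramid_levels` must be >= 1")
  if (sd(reference) == 0 || sd(moving) == 0)
    abort("phase correlation is undefined for a constant image")
  total <- c(0, 0)
  factors <- 4^((pyramid_levels - 1):0)
  cur <- moving
  for (li in seq_along(factors)) {
    f <- factors[li]
    r <- if (f > 1) downsample(reference, f) else reference
    m <- if (f > 1) downsample(cur, f) else cur
    s <- phase_corr_peak(r, m) * f
    if (li < length(factors)) {
      # coarse levels only pre-align by an integer shift; the residual is
      # re-measured at the next level, so accumulate exactly what was applied
      s <- round(s)
      cur <- circ_shift(cur, -s)
    }
    total <- total + s
  }
  c(dx = unname(total[1]), dy = unname(total[2]))
}

## block-mean downsampling by integer factor
downsample <- function(m, f) {
  nr <- floor(nrow(m) / f) * f
  nc <- floor(ncol(m) / f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # average f x f blocks
  m <- rowsum(m, rep(seq_len(nr / f), each = f)) / f
  t(rowsum(t(m), rep(seq_len(nc / f), each = f)) / f)
}

## circular shift by integer (dx, dy): content moves +dx columns, +dy rows
circ_shift <- function(m, s) {
  dx <- s[1] %% ncol(m); dy <- s[2] %% nrow(m)
  if (dx != 0) m <- m[, c((ncol(m) - dx + 1):ncol(m), seq_len(ncol(m) - dx)), drop = FALSE]
  if (dy != 0) m <- m[c((nrow(m) - dy + 1):nrow(m), seq_len(nrow(m) - dy)), , drop = FALSE]
  m
}

phase_corr_peak <- function(ref, mov) {
  Fr <- fft(ref); Fm <- fft(mov)
  R <- Fr * Conj(Fm)
  mag <- Mod(R)
  mag[mag < .Machine$double.eps] <- 1
  corr <- Re(fft(R / mag, inverse = TRUE))
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  nr <- nrow(corr); nc <- ncol(corr)
  # subpixel: 3-point parabola along each axis, circular indexing
  sub1 <- function(vals) {
    d <- (vals[3] - vals[1]) / (2 * (2 * vals[2] - vals[1] - vals[3]))
    if (!is.finite(d) || abs(d) > 1) 0 else d
  }
  rr <- c((pk[1] - 2) %% nr + 1, pk[1], pk[1] %% nr + 1)
  cc <- c((pk[2] - 2) %% nc + 1, pk[2], pk[2] %% nc + 1)
  py <- pk[1] - 1 + sub1(corr[rr, pk[2]])
  px <- pk[2] - 1 + sub1(corr[pk[1], cc])
  # wrap to signed shifts
  if (px > nc / 2) px <- px - nc
  if (py > nr / 2) py <- py - nr
  c(-px, -py)
}

#' Binarize a frame against a background
#'
#' The thresholded difference in the polarity direction: with a lighter
#' background the mask is `background - frame > threshold`, with a darker one
#' `frame - background > threshold`. Pixels outside the ROI are forced to 0.
#'
#' @param frame,background Grayscale matrices of identical shape.
#' @param polarity `"lighter"` or `"darker"` (background relative to objects).
#' @param threshold Intensity threshold.
#' @param roi Optional `c(x0, y0, x1, y1)` rectangle, 0-based inclusive.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(frame, background, polarity = c("lighter", "darker"),
                     threshold, roi = NULL) {
  polarity <- match.arg(polarity)
  if (!all(dim(frame) == dim(background))) abort("shapes must match")
  diffm <- if (polarity == "lighter") background - frame else frame - background
  mask <- (diffm > threshold) * 1L
  if (!is.null(roi)) {
    keep <- matrix(0L, nrow(mask), ncol(mask))
    r0 <- max(1L, roi[2] + 1L); r1 <- min(nrow(mask), roi[4] + 1L)
    c0 <- max(1L, roi[1] + 1L); c1 <- min(ncol(mask), roi[3] + 1L)
    keep[r0:r1, c0:c1] <- 1L
    mask <- mask * keep
  }
  mask
}

make_kernel <- function(shape = c("rectangle", "cross", "ellipse"), size) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1) abort("kernel size must be >= 1")
  if (size %% 2 == 0) size <- size + 1L
  if (shape == "rectangle") return(matrix(1, size, size))
  c0 <- (size + 1) / 2
  idx <- expand.grid(r = seq_len(size), c = seq_len(size))
  k <- matrix(0, size, size)
  if (shape == "cross") {
    k[c0, ] <- 1; k[, c0] <- 1
  } else {
    rad <- (size - 1) / 2
    inside <- ((idx$r - c0)^2 + (idx$c - c0)^2) <= rad^2 + 1e-9
    k[cbind(idx$r, idx$c)[inside, , drop = FALSE]] <- 1
  }
  k
}

#' Morphological filtering of a binary mask
#'
#' Applies an ordered list of standard morphological operations, each with a
#' rectangular, cross-shaped or elliptical kernel of the given size. Supported
#' operations: `erosion`, `dilatation`, `closing`, `opening`, `gradient`
#' (dilation minus erosion), `tophat` (mask minus opening), `blackhat`
#' (closing minus mask) and `hitmiss` (with the all-ones structuring elements
#' used here the miss set is empty, so this coincides with erosion).
#' Grayscale morphology is delegated to EBImage.
#'
#' @param mask Integer/logical 0-1 matrix.
#' @param ops List of `list(op =, shape =, size =)` entries, applied in order.
#' @return Filtered 0/1 integer matrix.
#' @export
morph_filter <- function(mask, ops) {
  m <- (mask > 0) * 1
  known <- c("erosion", "dilatation", "closing", "opening",
             "gradient", "tophat", "blackhat", "hitmiss")
  for (o in ops) {
    if (!o$op %in% known)
      abort(paste0("unknown morphological operation: ", o$op))
    k <- make_kernel(o$shape %||% "rectangle", o$size %||% 3L)
    m <- switch(o$op,
      erosion    = EBImage::erode(m, k),
      dilatation = EBImage::dilate(m, k),
      opening    = EBImage::opening(m, k),
      closing    = EBImage::closing(m, k),
      gradient   = pmax(EBImage::dilate(m, k) - EBImage::erode(m, k), 0),
      tophat     = pmax(m - EBImage::opening(m, k), 0),
      blackhat   = pmax(EBImage::closing(m, k) - m, 0),
      hitmiss    = EBImage::erode(m, k)
    )
    m <- (as.matrix(m) > 0) * 1
  }
  matrix(as.integer(m), nrow(mask), ncol(mask))
}

## 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
## diagonally are merged with a union-find pass over the two diagonal offsets.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]       # (r,c) ~ (r+1,c+1)
  a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]       # (r+1,c) ~ (r,c+1)
  pr <- c(as.vector(a1), as.vector(a2))
  pc <- c(as.vector(b1), as.vector(b2))
  keep <- pr > 0L & pc > 0L & pr != pc
  pr <- pr[keep]; pc <- pc[keep]
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(pr)) {
    ra <- find(pr[k]); rb <- find(pc[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nmax), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

## Moore border-following (clockwise, Jacob's stopping criterion) on one
## component; returns the outer contour as 0-based (x, y) pixel centres.
trace_contour <- function(comp) {
  pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp > 0
  # clockwise neighbour order (y down): E, SE, S, SW, W, NW, N, NE
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  px <- which(pad, arr.ind = TRUE)
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  s <- as.integer(px[1, ])                      # topmost-leftmost pixel
  # one tracing step from (cur, backtrack direction db): scan the Moore
  # neighbourhood clockwise starting just after the backtrack cell
  step <- function(cur, db) {
    for (k in 1:8) {
      d <- ((db + k - 1L) %% 8L) + 1L
      q <- c(cur[1] + dr[d], cur[2] + dc[d])
      if (pad[q[1], q[2]]) {
        dprev <- ((db + k - 2L) %% 8L) + 1L
        b <- c(cur[1] + dr[dprev], cur[2] + dc[dprev])
        delta <- b - q
        return(list(q = q, db = which(dr == delta[1] & dc == delta[2])))
      }
    }
    NULL
  }
  st <- step(s, 5L)                             # initial backtrack: W
  if (is.null(st))
    return(cbind(x = s[2] - 2L, y = s[1] - 2L)) # isolated pixel
  second <- st$q
  path <- vector("list", 4L * sum(pad) + 8L)
  path[[1]] <- s; np <- 1L
  cur <- st$q; db <- st$db
  while (np < length(path)) {
    nxt <- step(cur, db)
    # closed: back at the start about to repeat the first move
    if (all(cur == s) && all(nxt$q == second)) break
    np <- np + 1L
    path[[np]] <- cur
    cur <- nxt$q; db <- nxt$db
  }
  path <- do.call(rbind, path[seq_len(np)])
  # drop padding offset and convert to 0-based (x, y)
  cbind(x = path[, 2] - 2L, y = path[, 1] - 2L)
}

#' Extract blobs from a binary mask
#'
#' Labels 8-connected components, keeps those whose filled pixel count lies in
#' `[min_area, max_area]` (small artifacts and merged/overlapping objects are
#' both removed), and extracts each survivor's outer contour by Moore border
#' following; holes are ignored.
#'
#' @param mask Binary 0/1 matrix.
#' @param min_area,max_area Pixel-count bounds, inclusive.
#' @param frame_index Frame index to stamp on each blob.
#' @return List of `blob` objects, each with `contour` (0-based `(x, y)`
#'   pixel-centre polygon, closed implicitly), `pixels` (filled pixel
#'   coordinates), `area` (pixel count) and `frame`.
#' @export
extract_blobs <- function(mask, min_area = 1, max_area = Inf, frame_index = 0L) {
  if (min_area > max_area) abort("require min_area <= max_area")
  lab <- label_components8(mask)
  if (max(lab) == 0) return(list())
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_area & counts <= max_area)
  out <- vector("list", length(keep))
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  for (i in seq_along(keep)) {
    l <- keep[i]
    pts <- idx[labs == l, , drop = FALSE]
    # trace on the component's bounding box only, then shift back
    r0 <- min(pts[, 1]); c0 <- min(pts[, 2])
    comp <- matrix(FALSE, max(pts[, 1]) - r0 + 1L, max(pts[, 2]) - c0 + 1L)
    comp[cbind(pts[, 1] - r0 + 1L, pts[, 2] - c0 + 1L)] <- TRUE
    contour <- trace_contour(comp)
    contour[, 1] <- contour[, 1] + c0 - 1L
    contour[, 2] <- contour[, 2] + r0 - 1L
    out[[i]] <- structure(
      list(contour = contour,
           pixels = cbind(x = pts[, 2] - 1L, y = pts[, 1] - 1L),
           area = nrow(pts), frame = as.integer(frame_index)),
      class = "blob"
    )
  }
  out
}

#' @export
print.blob <- function(x, ...) {
  cat("<blob> frame ", x$frame, ", ", x$area, " px, ",
      nrow(x$contour), " contour points\n", sep = "")
  invisible(x)
}

#' Detect objects in a movie
#'
#' Runs the full detection front-end: background estimation (unless one is
#' supplied), per-frame binarization, morphological filtering, 8-connected
#' component extraction with the area filter, and kinematic parameter
#' extraction on every blob.
#'
#' @param stack A [frame_stack()].
#' @param params A [detection_params()].
#' @param background Optional background matrix overriding estimation.
#' @return A tibble of detections with columns `frame`, `x`, `y`, `theta`,
#'   `area`, `perimeter`, `major`, `minor`.
#' @export
detect_objects <- function(stack, params = detection_params(), background = NULL) {
  if (is.null(background))
    background <- estimate_background(stack, params$background_method,
                                      params$n_background_frames)
  idx <- frame_indices(stack)
  res <- purrr::map2(stack, idx, function(fr, fi) {
    mask <- binarize(fr, background, params$polarity, params$threshold, params$roi)
    if (length(params$morph_ops) > 0) mask <- morph_filter(mask, params$morph_ops)
    blobs <- extract_blobs(mask, params$min_area, params$max_area, fi)
    blob_kinematics(blobs)
  })
  dplyr::bind_rows(res)
}

## registration methods beyond phase correlation are not provided
#' @rdname register_phase_correlation
#' @param method Registration backend; only `"phase_correlation"` is
#'   implemented. `"ecc"` and `"features"` name standard published algorithms
#'   that this package does not provide.
#' @export
register_frames <- function(reference, moving, method = "phase_correlation",
                            pyramid_levels = 2L) {
  if (method != "phase_correlation")
    abort(paste0("registration method '", method, "' is not implemented"))
  register_phase_correlation(reference, moving, pyramid_levels)
}
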