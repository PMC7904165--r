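#' Equivalent ellipse of a blob from contour moments
#'
#' Centroid and second-order central moments are computed from the blob's
#' outer contour polygon with Green's theorem (line integrals around the
#' boundary stand in for the area integrals), which is much cheaper than
#' summing over all filled pixels. The equivalent ellipse is the one sharing
#' those moments: its axis angle is `0.5 * atan2(2*mu11, mu20 - mu02)` mapped
#' to `[0, pi)`, and its semi-axes are `2*sqrt(lambda)` for the two
#' eigenvalues of the normalised central moment matrix. The reported area is
#' the filled pixel count (robust to contour discretization) and the
#' perimeter is the polygonal arc length of the closed contour.
#'
#' @param blob A `blob` from [extract_blobs()].
#' @return Named list: `xc`, `yc`, `axis_angle` (radians in `[0, pi)`),
#'   `major`, `minor` (semi-axes, px), `area` (px^2), `perimeter` (px).
#' @export
equivalent_ellipse <- function(blob) {
  ct <- blob$contour
  if (nrow(ct) < 3) abort("degenerate blob: contour has fewer than 3 points")
  # the object's boundary polygon is the union of the exposed pixel edges
  # (pixel squares of side 1 centred on the pixel coordinates); Green's
  # theorem turns the area integrals into sums over these directed segments,
  # in any order, since together they form the closed boundary loops
  e <- boundary_edges(blob$pixels)
  x <- e$x1; y <- e$y1; xn <- e$x2; yn <- e$y2
  cross <- x * yn - xn * y
  A <- sum(cross) / 2                               # signed boundary area
  if (abs(A) < 1e-9) abort("degenerate blob: zero-variance contour")
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  # raw second moments about the origin, then centralised and normalised
  sxx <- sum((x^2 + x * xn + xn^2) * cross) / (12 * A)
  syy <- sum((y^2 + y * yn + yn^2) * cross) / (12 * A)
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / (24 * A)
  mu20 <- sxx - cx^2
  mu02 <- syy - cy^2
  mu11 <- sxy - cx * cy
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (ang < 0) ang <- ang + pi
  if (ang >= pi) ang <- ang - pi
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max((tr / 2)^2 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  cx_ <- ct[, 1]; cy_ <- ct[, 2]
  per <- sum(sqrt(diff(c(cx_, cx_[1]))^2 + diff(c(cy_, cy_[1]))^2))
  list(xc = cx, yc = cy, axis_angle = ang,
       major = 2 * sqrt(l1), minor = 2 * sqrt(l2),
       area = blob$area, perimeter = per)
}

## directed boundary segments of the union of unit pixel squares: each pixel
## edge not shared with a foreground neighbour, oriented so that the
## enclosed (signed) area is positive in y-down image coordinates
boundary_edges <- function(pixels) {
  x <- pixels[, 1]; y <- pixels[, 2]
  stride <- max(x) - min(x) + 3
  key <- (x - min(x)) + (y - min(y)) * stride
  has <- function(dx, dy) ((x + dx - min(x)) + (y + dy - min(y)) * stride) %in% key
  top <- !has(0, -1); right <- !has(1, 0)
  bottom <- !has(0, 1); left <- !has(-1, 0)
  x1 <- c((x - 0.5)[top], (x + 0.5)[right], (x + 0.5)[bottom], (x - 0.5)[left])
  y1 <- c((y - 0.5)[top], (y - 0.5)[right], (y + 0.5)[bottom], (y + 0.5)[left])
  x2 <- c((x + 0.5)[top], (x + 0.5)[right], (x - 0.5)[bottom], (x - 0.5)[left])
  y2 <- c((y - 0.5)[top], (y + 0.5)[right], (y + 0.5)[bottom], (y - 0.5)[left])
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Disambiguate a blob's direction along its major axis
#'
#' The equivalent-ellipse axis angle only lives in `[0, pi)`. The full
#' direction in `[0, 2*pi)` is fixed by the sign of the skewness of the
#' blob's filled pixels projected onto the major axis: the direction is
#' chosen so that the third standardised moment of the signed projections is
#' non-positive ("heavy side forward"). A mirror-symmetric blob (|skewness| <
#' 1e-6) keeps `theta = axis_angle`.
#'
#' @param blob A `blob` (its `pixels` field is used).
#' @param axis_angle Axis angle in `[0, pi)` from [equivalent_ellipse()].
#' @return `theta` in `[0, 2*pi)`, equal to `axis_angle` or `axis_angle + pi`.
#' @export
disambiguate_direction <- function(blob, axis_angle) {
  u <- c(cos(axis_angle), sin(axis_angle))
  px <- blob$pixels
  t_ <- (px[, 1] - mean(px[, 1])) * u[1] + (px[, 2] - mean(px[, 2])) * u[2]
  s <- sqrt(mean((t_ - mean(t_))^2))
  if (s == 0) return(axis_angle %% (2 * pi))
  skew <- mean(((t_ - mean(t_)) / s)^3)
  theta <- if (skew > 1e-6) axis_angle + pi else axis_angle
  theta %% (2 * pi)
}

#' Kinematic parameters of a list of blobs
#'
#' Applies [equivalent_ellipse()] and [disambiguate_direction()] to each blob
#' and assembles the per-object kinematic states consumed by the matcher.
#' Blobs whose moments are degenerate (e.g. single-pixel lines) are dropped.
#'
#' @param blobs List of `blob` objects (possibly empty).
#' @return Tibble with columns `frame`, `x`, `y`, `theta`, `area`,
#'   `perimeter`, `major`, `minor`.
#' @export
blob_kinematics <- function(blobs) {
  if (length(blobs) == 0)
    return(tibble(frame = integer(), x = double(), y = double(),
                  theta = double(), area = double(), perimeter = double(),
                  major = double(), minor = double()))
  rows <- purrr::map(blobs, function(b) {
    ell <- tryCatch(equivalent_ellipse(b), error = function(e) NULL)
    if (is.null(ell)) return(NULL)
    tibble(frame = b$frame, x = ell$xc, y = ell$yc,
           theta = disambiguate_direction(b, ell$axis_angle),
           area = ell$area, perimeter = ell$perimeter,
           major = ell$major, minor = ell$minor)
  })
  dplyr::bind_rows(rows)
}
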