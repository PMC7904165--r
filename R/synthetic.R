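#' Simulation configuration for synthetic movies
#'
#' Bundles every knob of the synthetic-movie generator: `n_objects`
#' area-conserving elliptical objects perform a persistent random walk inside a
#' `roi_width` x `roi_height` rectangle with reflective walls. Per-axis
#' position increments are i.i.d. Gaussian with scale `step_sigma` (so the
#' step length follows the chi distribution with 2 degrees of freedom, i.e. a
#' Rayleigh law of scale `step_sigma`), heading increments are Gaussian with
#' scale `angle_sigma` wrapped to `[0, 2*pi)`. Objects are rendered as filled
#' ellipses with semi-axes `semi_major`/`semi_minor`, dark on a light
#' background or the reverse, with additive Gaussian pixel noise of scale
#' `noise_sigma`. When `appearance_rate > 0`, each visible object disappears
#' permanently with that per-frame probability and a new object (fresh id,
#' uniform location) enters with the same probability, so the population
#' turns over while staying stationary on average.
#'
#' @param n_objects Number of objects at frame 0 (>= 1).
#' @param n_frames Number of frames T (>= 1).
#' @param roi_width,roi_height Extents of the region of interest, pixels.
#' @param step_sigma Per-axis Gaussian step scale, pixels/frame.
#' @param angle_sigma Heading noise per frame, radians.
#' @param semi_major,semi_minor Ellipse semi-axes, pixels.
#' @param noise_sigma Additive intensity noise scale (8-bit units).
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @param appearance_rate Per-frame appearance/disappearance probability in
#'   `[0, 1]`.
#' @param arrangement Initial positions: `"uniform"` at random or
#'   `"hexagonal"` on an equal-spacing lattice (guaranteed well separated).
#' @param seed Integer seed; identical configurations give bit-identical
#'   ground truth.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_objects = 10, n_frames = 100,
                       roi_width = 512, roi_height = 512,
                       step_sigma = 2, angle_sigma = 0.3,
                       semi_major = 8, semi_minor = 4,
                       noise_sigma = 0, polarity = c("dark_on_light", "light_on_dark"),
                       appearance_rate = 0,
                       arrangement = c("uniform", "hexagonal"), seed = 1L) {
  polarity <- match.arg(polarity)
  arrangement <- match.arg(arrangement)
  if (n_objects < 1) abort("`n_objects` must be >= 1.")
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  if (roi_width <= 0 || roi_height <= 0) abort("ROI extents must be > 0.")
  if (step_sigma < 0 || angle_sigma < 0 || noise_sigma < 0)
    abort("Noise scales must be >= 0.")
  if (semi_major <= 0 || semi_minor <= 0 || semi_minor > semi_major)
    abort("Require 0 < semi_minor <= semi_major.")
  if (appearance_rate < 0 || appearance_rate > 1)
    abort("`appearance_rate` must be a probability in [0, 1].")
  structure(
    list(n_objects = as.integer(n_objects), n_frames = as.integer(n_frames),
         roi_width = roi_width, roi_height = roi_height,
         step_sigma = step_sigma, angle_sigma = angle_sigma,
         semi_major = semi_major, semi_minor = semi_minor,
         noise_sigma = noise_sigma, polarity = polarity,
         appearance_rate = appearance_rate, arrangement = arrangement,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_objects, " objects, ", x$n_frames, " frames, ",
      x$roi_width, "x", x$roi_height, " px ROI\n", sep = "")
  cat("  step_sigma = ", x$step_sigma, " px, angle_sigma = ", x$angle_sigma,
      " rad, ellipse ", x$semi_major, "/", x$semi_minor, " px\n", sep = "")
  cat("  noise_sigma = ", x$noise_sigma, ", polarity = ", x$polarity,
      ", appearance_rate = ", x$appearance_rate, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate a point configuration inside a rectangle
#'
#' Either `n` points uniform at random, or a (triangular) hexagonal lattice
#' whose nearest-neighbour distances are all equal, filled row-major. When `n`
#' does not tile the lattice exactly, the lattice is filled row-major with the
#' first `n` sites; a lattice with fewer realizable sites than requested
#' returns the realizable sites with a warning reporting the actual count.
#'
#' @param n Number of points (>= 1).
#' @param roi Numeric `c(width, height)` of the rectangle, pixels.
#' @param arrangement `"uniform"` or `"hexagonal"`.
#' @param seed Integer seed (used by the uniform arrangement).
#' @return Tibble with columns `x`, `y`; for hexagonal arrangements the
#'   lattice constant is attached as attribute `"spacing"`.
#' @export
generate_point_configuration <- function(n, roi, arrangement = c("uniform", "hexagonal"),
                                         seed = 1L) {
  arrangement <- match.arg(arrangement)
  if (n < 1) abort("`n` must be >= 1.")
  w <- roi[[1]]; h <- roi[[2]]
  if (w <= 0 || h <= 0) abort("`roi` must be non-degenerate.")
  if (arrangement == "uniform") {
    withr::with_seed(seed, {
      tibble(x = runif(n, 0, w), y = runif(n, 0, h))
    })
  } else {
    # equal-spacing triangular lattice: rows dy = a * sqrt(3)/2 apart, odd
    # rows shifted by a/2; a chosen so that ceiling(sqrt(n)) columns and the
    # matching number of rows fit inside the rectangle
    ncol_ <- ceiling(sqrt(n))
    nrow_ <- ceiling(n / ncol_)
    a <- min(w / (ncol_ + 0.5), if (nrow_ > 1) h / ((nrow_ - 1) * sqrt(3) / 2 + 1) else h)
    xs <- ys <- numeric(0)
    for (r in seq_len(nrow_) - 1L) {
      off <- if (r %% 2 == 1) a / 2 else 0
      cx <- off + a * (seq_len(ncol_) - 0.5)
      cy <- rep(a / 2 + r * a * sqrt(3) / 2, ncol_)
      keep <- cx <= w & cy <= h
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    if (length(xs) < n)
      warn(paste0("hexagonal lattice realizes only ", length(xs),
                  " of the requested ", n, " points"))
    k <- min(n, length(xs))
    out <- tibble(x = xs[seq_len(k)], y = ys[seq_len(k)])
    attr(out, "spacing") <- a
    out
  }
}

## area-conserving ellipse perimeter (Ramanujan's second approximation)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

## reflect a coordinate into [0, L] (specular reflection of the overshoot)
reflect_into <- function(x, L) {
  # fold the real line onto [0, L] with period 2L
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate ground-truth trajectories
#'
#' Persistent random walk of `cfg$n_objects` ellipses with reflective walls.
#' Per-axis increments are i.i.d. Gaussian (`step_sigma`) before reflection,
#' heading increments Gaussian (`angle_sigma`) wrapped to `[0, 2*pi)`, areas
#' and perimeters constant per object. Frame indices are 0-based.
#'
#' @param cfg A [sim_config()].
#' @return A `trajectory_set` tibble with columns `frame`, `id`, `x`, `y`,
#'   `theta`, `area`, `perimeter`.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  W <- cfg$roi_width; H <- cfg$roi_height
  area0 <- pi * cfg$semi_major * cfg$semi_minor
  per0 <- ellipse_perimeter(cfg$semi_major, cfg$semi_minor)
  withr::with_seed(cfg$seed, {
    n <- cfg$n_objects
    if (cfg$arrangement == "hexagonal") {
      p0 <- suppressWarnings(
        generate_point_configuration(n, c(W, H), "hexagonal")
      )
      if (nrow(p0) < n) abort("hexagonal lattice cannot realize n_objects")
      x <- p0$x; y <- p0$y
    } else {
      x <- runif(n, 0, W); y <- runif(n, 0, H)
    }
    th <- runif(n, 0, 2 * pi)
    ids <- seq_len(n)
    alive <- rep(TRUE, n)
    next_id <- n + 1L
    rows <- vector("list", cfg$n_frames)
    for (f in seq_len(cfg$n_frames) - 1L) {
      if (f > 0) {
        live <- which(alive)
        nl <- length(live)
        x[live] <- reflect_into(x[live] + rnorm(nl, 0, cfg$step_sigma), W)
        y[live] <- reflect_into(y[live] + rnorm(nl, 0, cfg$step_sigma), H)
        th[live] <- (th[live] + rnorm(nl, 0, cfg$angle_sigma)) %% (2 * pi)
        if (cfg$appearance_rate > 0) {
          gone <- live[runif(nl) < cfg$appearance_rate]
          alive[gone] <- FALSE
          if (runif(1) < cfg$appearance_rate) {
            ids <- c(ids, next_id); next_id <- next_id + 1L
            alive <- c(alive, TRUE)
            x <- c(x, runif(1, 0, W)); y <- c(y, runif(1, 0, H))
            th <- c(th, runif(1, 0, 2 * pi))
          }
        }
      }
      live <- which(alive)
      rows[[f + 1L]] <- tibble(
        frame = f, id = ids[live], x = x[live], y = y[live],
        theta = th[live], area = area0, perimeter = per0
      )
    }
    new_trajectory_set(dplyr::bind_rows(rows))
  })
}

new_trajectory_set <- function(df) {
  df <- as_tibble(df)
  class(df) <- unique(c("trajectory_set", class(df)))
  df
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", dplyr::n_distinct(x$id), " trajectories, ",
      dplyr::n_distinct(x$frame), " frames, ", nrow(x), " states\n", sep = "")
  NextMethod()
}

#' Render a synthetic movie from ground-truth trajectories
#'
#' Each object is drawn as a filled ellipse of its configured semi-axes,
#' rotated to its heading, by pixel-centre-in-ellipse rasterization (no
#' anti-aliasing, so pixel counts are deterministic). The background is
#' uniform; `dark_on_light` draws intensity-30 objects on a 220 background and
#' `light_on_dark` is the exact 8-bit inversion (255 - frame) of the same
#' content. Additive Gaussian noise of scale `noise_sigma` is applied last and
#' the result clipped to `[0, 255]`.
#'
#' @param gt A `trajectory_set` (typically from [simulate_trajectories()]).
#' @param cfg The matching [sim_config()].
#' @return A `frame_stack` (list of matrices with attribute `frames`).
#' @export
render_movie <- function(gt, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  W <- as.integer(cfg$roi_width); H <- as.integer(cfg$roi_height)
  if (2 * cfg$semi_major > min(W, H))
    abort("objects larger than the ROI cannot be rendered")
  bg <- 220; fg <- 30
  frames <- sort(unique(gt$frame))
  by_frame <- split(gt, gt$frame)
  mats <- withr::with_seed(cfg$seed + 1L, {
    lapply(frames, function(f) {
      m <- matrix(bg, nrow = H, ncol = W)
      d <- by_frame[[as.character(f)]]
      for (i in seq_len(nrow(d))) {
        m <- draw_ellipse(m, d$x[i], d$y[i], d$theta[i],
                          cfg$semi_major, cfg$semi_minor, fg)
      }
      if (cfg$polarity == "light_on_dark") m <- 255 - m
      if (cfg$noise_sigma > 0)
        m <- m + matrix(rnorm(H * W, 0, cfg$noise_sigma), H, W)
      pmin(pmax(m, 0), 255)
    })
  })
  frame_stack(mats, frames)
}

## paint a filled rotated ellipse into matrix m (rows = y, cols = x, 0-based
## pixel-centre coordinates)
draw_ellipse <- function(m, xc, yc, theta, a, b, value) {
  H <- nrow(m); W <- ncol(m)
  c0 <- max(1L, floor(xc - a) + 1L); c1 <- min(W, ceiling(xc + a) + 1L)
  r0 <- max(1L, floor(yc - a) + 1L); r1 <- min(H, ceiling(yc + a) + 1L)
  if (c0 > c1 || r0 > r1) return(m)
  cols <- c0:c1; rows <- r0:r1
  px <- matrix(cols - 1, nrow = length(rows), ncol = length(cols), byrow = TRUE) - xc
  py <- matrix(rows - 1, nrow = length(rows), ncol = length(cols)) - yc
  u <- px * cos(theta) + py * sin(theta)
  v <- -px * sin(theta) + py * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- m[rows, cols, drop = FALSE]
  sub[inside] <- value
  m[rows, cols] <- sub
  m
}
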