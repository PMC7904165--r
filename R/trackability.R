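#' Geometric probability of incursion versus reduced displacement
#'
#' For each object in a frame, the Voronoi cell is the set of points closer
#' to it than to any other object. An endpoint placed at distance
#' `rho / sqrt(d)` (with `d` the object density, so `rho` is the
#' dimensionless reduced displacement) in a given direction makes an
#' *incursion* when it falls in another object's cell while staying inside
#' the ROI; endpoints leaving the ROI count as non-incursions, which is what
#' caps the large-`rho` asymptote below 1 in small reflective-wall systems.
#' `p_inc(rho)` is the fraction of `n_angles` uniformly spaced directions
#' that make an incursion, averaged over all objects of the sampled frames
#' (cells are recomputed at each sampled frame). Because Voronoi cells are
#' convex, the per-direction cell-exit distance is obtained exactly from the
#' nearest perpendicular-bisector crossing.
#'
#' @param points Tibble with `x`, `y` and optionally `frame` (all frames are
#'   used unless `frames` selects a subset).
#' @param roi Numeric `c(width, height)`.
#' @param rho_grid Grid of reduced displacements (must start at 0).
#' @param n_angles Number of uniformly spaced directions (>= 8).
#' @param frames Optional frame indices to sample (default: up to
#'   `max_frames` evenly strided frames).
#' @param max_frames Cap on the number of sampled frames.
#' @return An `incursion_profile` tibble (`rho`, `p`) with attributes
#'   `density` and `n_cells_used`.
#' @export
incursion_profile <- function(points, roi, rho_grid = seq(0, 2, by = 0.05),
                              n_angles = 360L, frames = NULL,
                              max_frames = 10L) {
  if (n_angles < 8) abort("`n_angles` must be >= 8")
  if (rho_grid[1] != 0) rho_grid <- c(0, rho_grid)
  pts <- as_tibble(points)
  if (!"frame" %in% names(pts)) pts$frame <- 0L
  all_frames <- sort(unique(pts$frame))
  if (is.null(frames)) {
    stride <- max(1L, floor(length(all_frames) / max_frames))
    frames <- all_frames[seq(1L, length(all_frames), by = stride)]
    frames <- head(frames, max_frames)
  }
  counts <- pts |> dplyr::count(.data$frame)
  d <- mean(counts$n) / (roi[1] * roi[2])
  angles <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  ux <- cos(angles); uy <- sin(angles)
  n_cells <- 0L
  inc_frac <- matrix(0, nrow = 0, ncol = length(rho_grid))
  acc <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    p <- pts[pts$frame == frames[fi], c("x", "y")]
    n <- nrow(p)
    if (n < 4) abort("need at least 4 points per frame")
    if (point_rank(p$x, p$y) < 2) abort("degenerate tessellation: collinear points")
    ex <- exit_distances(p$x, p$y, ux, uy, roi)  # list(cell, roi) n x n_angles
    n_cells <- n_cells + n
    r_of_rho <- rho_grid / sqrt(d)
    # incursion for direction k at radius r: exits the cell but not the ROI
    frac <- vapply(r_of_rho, function(r) {
      mean(ex$cell < r & r <= ex$roi)
    }, numeric(1))
    acc[[fi]] <- frac
  }
  pvals <- Reduce(`+`, acc) / length(acc)
  out <- tibble(rho = rho_grid, p = pvals)
  attr(out, "density") <- d
  attr(out, "n_cells_used") <- n_cells
  class(out) <- unique(c("incursion_profile", class(out)))
  out
}

#' Numerically locate the inflection of an incursion profile
#'
#' Fits the sigmoid `L / (1 + exp(-k * (rho - rho0)))` to the profile by
#' least squares and returns `rho0`, the inflection point of the fitted
#' curve. For random planar configurations this sits close to `rho = 1/2`,
#' the typical reduced distance to a Voronoi cell boundary.
#'
#' @param profile An [incursion_profile()].
#' @return The inflection location `rho0`.
#' @export
profile_inflection <- function(profile) {
  df <- as_tibble(profile)
  fit <- minpack.lm::nlsLM(
    p ~ L / (1 + exp(-k * (rho - rho0))), data = df,
    start = list(L = max(df$p), k = 10,
                 rho0 = stats::weighted.mean(df$rho, c(0, pmax(diff(df$p), 0)))),
    lower = c(L = 1e-6, k = 1e-6, rho0 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  unname(coef(fit)["rho0"])
}

point_rank <- function(x, y) {
  m <- cbind(x - mean(x), y - mean(y))
  qr(m)$rank
}

## per-object, per-direction distances at which a ray leaves its generator's
## Voronoi cell (nearest forward bisector crossing) and the ROI rectangle
exit_distances <- function(x, y, ux, uy, roi) {
  n <- length(x); na <- length(ux)
  cell <- matrix(Inf, n, na)
  roi_d <- matrix(Inf, n, na)
  for (i in seq_len(n)) {
    dxj <- x[-i] - x[i]; dyj <- y[-i] - y[i]
    d2 <- dxj^2 + dyj^2
    # ray p_i + t*u crosses the bisector of (i, j) at t = |p_j-p_i|^2 /
    # (2 u.(p_j-p_i)) when the dot product is positive
    dot <- outer(ux, dxj) + outer(uy, dyj)       # na x (n-1)
    tt <- matrix(rep(d2, each = na), na, n - 1) / (2 * dot)
    tt[dot <= 0] <- Inf
    cell[i, ] <- apply(tt, 1, min)
    # ROI exit: smallest positive crossing with x = 0, x = W, y = 0, y = H
    tx <- ifelse(ux > 0, (roi[1] - x[i]) / ux,
                 ifelse(ux < 0, -x[i] / ux, Inf))
    ty <- ifelse(uy > 0, (roi[2] - y[i]) / uy,
                 ifelse(uy < 0, -y[i] / uy, Inf))
    roi_d[i, ] <- pmin(tx, ty)
  }
  list(cell = cell, roi = roi_d)
}

#' Reduced displacements of trajectories at a sampling timescale
#'
#' For integer `tau >= 1`, displacements between frames `t` and `t + tau` on
#' the strided frame set (one frame kept every `tau`); for `tau < 1`,
#' single-frame displacements linearly interpolated, i.e. scaled by `tau`.
#' Displacements are made dimensionless as `rho = r * sqrt(d)`.
#'
#' @param traj A `trajectory_set`.
#' @param tau Positive timescale; values >= 1 must be integers.
#' @param d Object density (objects per px^2).
#' @return Numeric vector of `rho` samples.
#' @export
displacement_samples <- function(traj, tau, d) {
  if (tau <= 0) abort("`tau` must be > 0")
  scale <- 1
  if (tau < 1) {
    scale <- tau
    tau_i <- 1L
  } else {
    if (abs(tau - round(tau)) > 1e-9) abort("`tau` >= 1 must be an integer")
    tau_i <- as.integer(round(tau))
  }
  f0 <- min(traj$frame)
  sub <- traj[(traj$frame - f0) %% tau_i == 0, ]
  r <- sub |>
    dplyr::arrange(.data$id, .data$frame) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(dframe = .data$frame - dplyr::lag(.data$frame),
                  dr = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                              (.data$y - dplyr::lag(.data$y))^2)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dframe), .data$dframe == tau_i) |>
    dplyr::pull(.data$dr)
  if (length(r) == 0) abort("no displacement samples at this timescale")
  r * scale * sqrt(d)
}

#' Probability of incursion at a timescale
#'
#' Empirical-measure evaluation of the incursion probability: the mean of
#' the geometric profile `p_inc(rho)` interpolated at the observed reduced
#' displacements (equivalent to integrating `R(rho) * p_inc(rho)` over the
#' displacement distribution). The profile is extrapolated flat beyond its
#' grid.
#'
#' @param samples Reduced displacements from [displacement_samples()].
#' @param profile An [incursion_profile()].
#' @return `P_inc` in `[0, 1]`.
#' @export
p_incursion <- function(samples, profile) {
  if (length(samples) == 0) abort("empty displacement samples")
  mean(approx(profile$rho, profile$p, xout = samples, rule = 2)$y)
}

#' Fit the logistic law of incursion probability versus timescale
#'
#' Least squares in log-log space for `P_inc(tau) = L / (1 + (tau0/tau)^k)`
#' (equivalently a logistic in `log(tau)` with `tau0 = exp(x0)`):
#' Levenberg-Marquardt on the residuals `log(P_inc) - log(Phat)`. Zero
#' `P_inc` values carry no information on a log scale and are excluded; at
#' least 4 positive points are required. Initial guesses: `L = max(P)`,
#' `k = 2`, `tau0` at half maximum.
#'
#' @param taus,pincs Positive timescales and their incursion probabilities.
#' @return A `logistic_fit` list: `L`, `k`, `tau0`, `residual` (RMS of log
#'   residuals), `n`.
#' @export
fit_logistic <- function(taus, pincs) {
  keep <- pincs > 0 & is.finite(pincs) & taus > 0
  tau <- taus[keep]; p <- pincs[keep]
  if (length(tau) < 4) abort("need at least 4 strictly positive (tau, P_inc) points")
  if (sd(log(p)) < 1e-12)
    abort("P_inc is constant: the steepness k is unidentifiable")
  L0 <- max(p)
  t0 <- tau[which.min(abs(p - L0 / 2))]
  dat <- tibble(tau = tau, lp = log(p))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lp ~ log(L) - log(1 + (tau0 / tau)^k),
      data = dat,
      start = list(L = min(L0, 1), k = 2, tau0 = t0),
      lower = c(L = 1e-8, k = 1e-8, tau0 = 1e-8),
      upper = c(L = 1, k = Inf, tau0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(paste0("logistic fit did not converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  res <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(L = unname(cf["L"]), k = unname(cf["k"]),
                 tau0 = unname(cf["tau0"]), residual = res,
                 n = length(tau)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> L = %.4g, k = %.4g, tau0 = %.4g (log-RMS %.3g, n = %d)\n",
              x$L, x$k, x$tau0, x$residual, x$n))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("L", "k", "tau0"), estimate = c(x$L, x$k, x$tau0))
}

#' @rdname fit_logistic
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(L = x$L, k = x$k, tau0 = x$tau0, residual = x$residual, n = x$n)
}

#' Predict the fitted incursion probability
#'
#' @param object A `logistic_fit`.
#' @param tau Timescales.
#' @param ... Unused.
#' @return `L / (1 + (tau0/tau)^k)`.
#' @export
predict.logistic_fit <- function(object, tau, ...) {
  object$L / (1 + (object$tau0 / tau)^object$k)
}

#' Critical resampling timescale
#'
#' The timescale at which the fitted incursion probability reaches
#' `1 / N_obj`, the probability of a single incursion over the whole movie:
#' `tau1 = tau0 * (L*N_obj - 1)^(-1/k)`. Movies with `tau1 > 1` are
#' oversampled (the framerate could be reduced by that factor without
#' triggering incursions), movies with `tau1 < 1` undersampled. When
#' `L * N_obj <= 1` the fitted probability never reaches `1 / N_obj` and
#' `tau1` is `+Inf` with attribute `never_reached`.
#'
#' @param fit A [fit_logistic()] result.
#' @param N_obj Total number of objects over all frames (>= 1).
#' @return `tau1`; satisfies `predict(fit, tau1) * N_obj == 1`.
#' @export
tau_one <- function(fit, N_obj) {
  if (N_obj < 1) abort("`N_obj` must be >= 1")
  if (fit$L * N_obj <= 1) {
    out <- Inf
    attr(out, "never_reached") <- TRUE
    return(out)
  }
  fit$tau0 * (fit$L * N_obj - 1)^(-1 / fit$k)
}

#' Trackability analysis of a trajectory set
#'
#' Computes the full incursion characterisation: object density, the
#' geometric incursion profile (static Voronoi cells recomputed at a sample
#' of start frames), `P_inc` across a grid of sampling timescales, the
#' logistic fit, and the critical resampling factor `tau1` with the
#' oversampled/undersampled verdict.
#'
#' @param traj A `trajectory_set` (ground truth or an ad hoc tracking; the
#'   measure is resilient to a small rate of identity errors).
#' @param roi Numeric `c(width, height)`.
#' @param taus Timescale grid; default `{0.125, 0.25, 0.5}` plus log-spaced
#'   integers up to a tenth of the movie length.
#' @param ... Passed to [incursion_profile()].
#' @return A `trackability_report`: `series` (tibble `tau`, `P_inc`),
#'   `fit`, `profile`, `density`, `N_obj`, `tau1`, `sampling_class`.
#' @export
trackability <- function(traj, roi, taus = NULL, ...) {
  T_ <- dplyr::n_distinct(traj$frame)
  if (is.null(taus)) {
    tmax <- max(2, floor(T_ / 10))
    ints <- unique(round(exp(seq(log(1), log(tmax), length.out = 8))))
    taus <- c(0.125, 0.25, 0.5, ints)
  }
  profile <- incursion_profile(traj, roi, ...)
  d <- attr(profile, "density")
  series <- purrr::map_dfr(taus, function(tt) {
    s <- tryCatch(displacement_samples(traj, tt, d), error = function(e) NULL)
    if (is.null(s)) return(tibble(tau = tt, P_inc = NA_real_))
    tibble(tau = tt, P_inc = p_incursion(s, profile))
  })
  ok <- series[!is.na(series$P_inc), ]
  fit <- fit_logistic(ok$tau, ok$P_inc)
  N_obj <- nrow(traj)
  t1 <- tau_one(fit, N_obj)
  structure(
    list(series = series, fit = fit, profile = profile, density = d,
         N_obj = N_obj, tau1 = t1,
         sampling_class = if (is.finite(t1) && t1 > 1) "oversampled" else "undersampled"),
    class = "trackability_report"
  )
}

#' @export
print.trackability_report <- function(x, ...) {
  cat("<trackability_report> N_obj = ", x$N_obj,
      ", density = ", signif(x$density, 4), " objects/px^2\n", sep = "")
  print(x$fit)
  cat("  tau1 = ", signif(x$tau1, 5), " -> ", x$sampling_class, "\n", sep = "")
  invisible(x)
}

#' @rdname trackability
#' @param x A `trackability_report`.
#' @export
tidy.trackability_report <- function(x, ...) x$series

#' @rdname trackability
#' @export
glance.trackability_report <- function(x, ...) {
  tibble(L = x$fit$L, k = x$fit$k, tau0 = x$fit$tau0, tau1 = x$tau1,
         N_obj = x$N_obj, density = x$density,
         sampling_class = x$sampling_class)
}

#' Voronoi neighbours of one point
#'
#' Indices of the generators whose Voronoi cells share an edge with point
#' `i`'s cell. Adjacency is decided exactly: points `i` and `j` are
#' neighbours iff some point of their perpendicular bisector is at least as
#' close to them as to every other generator, a 1-D linear feasibility
#' problem along the bisector.
#'
#' @param x,y Coordinates of all generators.
#' @param i Index of the query point.
#' @return Integer vector of neighbour indices.
#' @export
voronoi_neighbors <- function(x, y, i) {
  n <- length(x)
  out <- integer(0)
  for (j in setdiff(seq_len(n), i)) {
    mid <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
    dir <- c(-(y[j] - y[i]), x[j] - x[i])
    dir <- dir / sqrt(sum(dir^2))
    lo <- -Inf; hi <- Inf
    feasible <- TRUE
    for (k in setdiff(seq_len(n), c(i, j))) {
      # |m(t)-p_k|^2 - |m(t)-p_i|^2 >= 0 is linear in t: a*t + b >= 0
      b <- sum((mid - c(x[k], y[k]))^2) - sum((mid - c(x[i], y[i]))^2)
      a <- 2 * sum(dir * (c(x[i], y[i]) - c(x[k], y[k])))
      if (abs(a) < 1e-12) {
        if (b < -1e-9) { feasible <- FALSE; break }
      } else if (a > 0) {
        lo <- max(lo, -b / a)
      } else {
        hi <- min(hi, -b / a)
      }
      if (lo > hi + 1e-9) { feasible <- FALSE; break }
    }
    if (feasible && lo <= hi + 1e-9) out <- c(out, j)
  }
  out
}

#' Degrade trajectories by random identity swaps
#'
#' Introduces `round(delta * N_obj)` artificial swaps (with `N_obj` the total
#' number of objects over all frames): each swap draws a uniform frame and
#' object, draws one of its Voronoi neighbours in that frame, and exchanges
#' the two ids from that frame onward. Used to probe the robustness of the
#' trackability analysis to imperfect input trajectories.
#'
#' @param gt A `trajectory_set`.
#' @param delta Degradation rate (swaps per object-frame, >= 0).
#' @param seed Integer seed; the degradation is reproducible.
#' @return A degraded `trajectory_set`.
#' @export
degrade <- function(gt, delta, seed = 1L) {
  if (delta < 0) abort("`delta` must be >= 0")
  n_swaps <- round(delta * nrow(gt))
  if (n_swaps == 0) return(gt)
  out <- gt
  withr::with_seed(seed, {
    frames <- sort(unique(out$frame))
    for (s in seq_len(n_swaps)) {
      for (try in 1:50) {
        f <- sample(frames, 1)
        here <- which(out$frame == f)
        if (length(here) >= 2) break
      }
      if (length(here) < 2)
        abort("fewer than 2 coexisting objects: cannot swap")
      pick <- sample(seq_along(here), 1)
      nb <- voronoi_neighbors(out$x[here], out$y[here], pick)
      if (length(nb) == 0) next
      j <- if (length(nb) == 1) nb else sample(nb, 1)
      id_a <- out$id[here[pick]]; id_b <- out$id[here[j]]
      sel <- out$frame >= f
      ida_sel <- sel & out$id == id_a
      idb_sel <- sel & out$id == id_b
      out$id[ida_sel] <- id_b
      out$id[idb_sel] <- id_a
    }
  })
  dplyr::arrange(out, .data$frame, .data$id)
}
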