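#' Gaussian scale of signed increments
#'
#' Maximum-likelihood scale of a Gaussian fitted to a signed increment
#' distribution (angle, area or perimeter changes): the population standard
#' deviation about the sample mean. Centring on the sample mean rather than
#' zero keeps the estimate meaningful for drifting systems.
#'
#' @param samples Numeric vector, length >= 10.
#' @return The ML scale (same units as the samples).
#' @export
estimate_sigma_signed <- function(samples) {
  if (length(samples) < 10) abort("need at least 10 samples")
  s <- sqrt(mean((samples - mean(samples))^2))
  if (s == 0) abort("degenerate fit: all samples identical")
  s
}

#' Rayleigh (chi, 2 dof) scale of displacement magnitudes
#'
#' If per-axis displacements are independent Gaussians of common scale `s_r`,
#' the planar step length follows the chi distribution with 2 degrees of
#' freedom, `f(dr) = (dr/s_r^2) * exp(-dr^2 / (2*s_r^2))`. Its
#' maximum-likelihood scale has the closed form `sqrt(mean(dr^2)/2)`.
#'
#' @param samples Non-negative numeric vector, length >= 10.
#' @return The ML scale `s_r` (px); 0 with attribute `degenerate = TRUE` when
#'   every sample is zero.
#' @export
estimate_sigma_chi2 <- function(samples) {
  if (length(samples) < 10) abort("need at least 10 samples")
  if (any(samples < 0)) abort("displacement magnitudes must be >= 0")
  s <- sqrt(mean(samples^2) / 2)
  if (s == 0) {
    attr(s, "degenerate") <- TRUE
    warn("degenerate displacement distribution: all samples are zero")
  }
  s
}

## pool one-frame increments from a trajectory set (consecutive-frame links
## only: links across gaps would inflate the scales)
increment_pool <- function(traj) {
  traj |>
    dplyr::arrange(.data$id, .data$frame) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      dframe = .data$frame - dplyr::lag(.data$frame),
      dr = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                  (.data$y - dplyr::lag(.data$y))^2),
      dalpha = signed_angle_diff(dplyr::lag(.data$theta), .data$theta),
      dA = .data$area - dplyr::lag(.data$area),
      dp = .data$perimeter - dplyr::lag(.data$perimeter)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dframe), .data$dframe == 1) |>
    dplyr::select("dr", "dalpha", "dA", "dp")
}

## signed circular difference t2 - t1 wrapped to (-pi, pi]
signed_angle_diff <- function(t1, t2) {
  d <- (t2 - t1) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Iterative estimation of the soft matching parameters
#'
#' Alternates tracking and scale estimation: the movie is tracked with the
#' current parameters, the one-frame increments `dr`, `dalpha`, `dA` (and
#' `dp` when enabled) are pooled over all trajectories, new soft parameters
#' are set to the maximum-likelihood scales ([estimate_sigma_chi2()] for the
#' displacement, [estimate_sigma_signed()] for the signed increments), and
#' the loop repeats until every soft parameter's relative change falls below
#' `tolerance`. During iteration the hard thresholds ride along at 5x the
#' corresponding soft value and `h_t` is held at 10 frames, keeping the
#' increment pool representative without letting distant pairs in. An
#' increment family with zero variance (e.g. strictly constant areas) is
#' disabled (set to `+Inf`) rather than fitted.
#'
#' @param x Detections tibble or [frame_stack()] (at least 2 frames).
#' @param seed_params Starting [match_params()]; parameters discarded there
#'   (soft and hard both `+Inf`) stay discarded.
#' @param tolerance Relative convergence criterion (default `1e-3`).
#' @param max_iter Iteration cap.
#' @param det_params,background Passed to detection for frame-stack input.
#' @return An `autoparam_result`: `params` (converged [match_params()]),
#'   `history` (per-iteration soft values), `iterations`, `converged`.
#' @export
iterate_autoparams <- function(x, seed_params = match_params(),
                               tolerance = 1e-3, max_iter = 20L,
                               det_params = detection_params(),
                               background = NULL) {
  det <- if (inherits(x, "frame_stack")) {
    detect_objects(x, det_params, background)
  } else {
    as_tibble(x)
  }
  if (dplyr::n_distinct(det$frame) < 2) abort("need at least 2 frames")
  p <- seed_params
  en <- list(
    r = !(is.infinite(p$s_r) && is.infinite(p$h_r)),
    alpha = !(is.infinite(p$s_alpha) && is.infinite(p$h_alpha)),
    A = !(is.infinite(p$s_A) && is.infinite(p$h_A)),
    p = !(is.infinite(p$s_p) && is.infinite(p$h_p))
  )
  hist_rows <- list()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # hard thresholds follow the current soft values during iteration
    p_it <- match_params(
      s_r = p$s_r, s_alpha = p$s_alpha, s_A = p$s_A, s_p = p$s_p,
      h_r = if (en$r && is.finite(p$s_r)) 5 * p$s_r else Inf,
      h_alpha = if (en$alpha && is.finite(p$s_alpha)) min(5 * p$s_alpha, pi) else Inf,
      h_A = if (en$A && is.finite(p$s_A)) 5 * p$s_A else Inf,
      h_p = if (en$p && is.finite(p$s_p)) 5 * p$s_p else Inf,
      h_t = 10L
    )
    traj <- track(det, p_it)
    inc <- increment_pool(traj)
    if (nrow(inc) < 10) abort("tracking yields fewer than 10 increments")
    new_p <- p
    if (en$r) {
      s <- estimate_sigma_chi2(inc$dr)
      if (s == 0) abort("degenerate displacement distribution: static objects")
      new_p$s_r <- as.numeric(s)
    }
    upd <- function(enabled, samples, old) {
      if (!enabled) return(Inf)
      if (sd(samples) == 0) return(Inf)  # zero-variance family: disable
      estimate_sigma_signed(samples)
    }
    new_p$s_alpha <- upd(en$alpha, inc$dalpha, p$s_alpha)
    new_p$s_A <- upd(en$A, inc$dA, p$s_A)
    new_p$s_p <- upd(en$p, inc$dp, p$s_p)
    en$alpha <- is.finite(new_p$s_alpha)
    en$A <- is.finite(new_p$s_A)
    en$p <- is.finite(new_p$s_p)
    hist_rows[[it]] <- tibble(iteration = it, s_r = new_p$s_r,
                              s_alpha = new_p$s_alpha, s_A = new_p$s_A,
                              s_p = new_p$s_p)
    rel <- function(old, new) {
      if (is.infinite(old) && is.infinite(new)) return(0)
      if (!is.finite(old) || !is.finite(new) || new == 0) return(Inf)
      abs(new - old) / new
    }
    drel <- c(rel(p$s_r, new_p$s_r), rel(p$s_alpha, new_p$s_alpha),
              rel(p$s_A, new_p$s_A), rel(p$s_p, new_p$s_p))
    p <- new_p
    if (all(drel < tolerance)) { converged <- TRUE; break }
  }
  final <- match_params(
    s_r = p$s_r, s_alpha = p$s_alpha, s_A = p$s_A, s_p = p$s_p,
    h_r = if (is.finite(p$s_r)) 5 * p$s_r else Inf,
    h_alpha = if (is.finite(p$s_alpha)) min(5 * p$s_alpha, pi) else Inf,
    h_A = if (is.finite(p$s_A)) 5 * p$s_A else Inf,
    h_p = if (is.finite(p$s_p)) 5 * p$s_p else Inf,
    h_t = 10L
  )
  structure(
    list(params = final, history = dplyr::bind_rows(hist_rows),
         iterations = it, converged = converged),
    class = "autoparam_result"
  )
}

#' @export
print.autoparam_result <- function(x, ...) {
  cat("<autoparam_result> ", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iteration(s)\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @rdname iterate_autoparams
#' @param x An `autoparam_result`.
#' @param ... Unused.
#' @export
tidy.autoparam_result <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"iteration",
                      names_to = "parameter", values_to = "value")
}

#' @rdname iterate_autoparams
#' @export
glance.autoparam_result <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         s_r = x$params$s_r, s_alpha = x$params$s_alpha,
         s_A = x$params$s_A, s_p = x$params$s_p)
}
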