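#' Matching parameters
#'
#' The cost of pairing two kinematic states is the sum, over the enabled
#' kinematic parameters, of the parameter's increment divided by its *soft*
#' normalisation (`s_r`, `s_alpha`, `s_A`, `s_p`), and becomes `+Inf` as soon
#' as any enabled increment exceeds its *hard* threshold (`h_r`, `h_alpha`,
#' `h_A`, `h_p`). A kinematic parameter is discarded from the cost exactly
#' when both its soft and hard values are `+Inf`. `h_t` is the temporal hard
#' parameter: the maximal number of frames an object may stay lost while its
#' last state is still offered to the matcher as a pseudo-occurrence.
#'
#' @param s_r,s_alpha,s_A,s_p Soft normalisations (px, rad, px^2, px);
#'   `+Inf` allowed.
#' @param h_r,h_alpha,h_A,h_p Hard thresholds, same units; `+Inf` allowed.
#' @param h_t Maximal disappearance time, frames (>= 1).
#' @return A `match_params` list.
#' @export
match_params <- function(s_r = 20, s_alpha = 0.5, s_A = 100, s_p = Inf,
                         h_r = Inf, h_alpha = Inf, h_A = Inf, h_p = Inf,
                         h_t = 10L) {
  vals <- c(s_r, s_alpha, s_A, s_p, h_r, h_alpha, h_A, h_p, h_t)
  if (any(vals < 0)) abort("matching parameters must be >= 0")
  structure(
    list(s_r = s_r, s_alpha = s_alpha, s_A = s_A, s_p = s_p,
         h_r = h_r, h_alpha = h_alpha, h_A = h_A, h_p = h_p,
         h_t = as.integer(h_t)),
    class = "match_params"
  )
}

#' @export
print.match_params <- function(x, ...) {
  cat("<match_params>\n")
  cat(sprintf("  soft: s_r = %g px, s_alpha = %g rad, s_A = %g px^2, s_p = %g px\n",
              x$s_r, x$s_alpha, x$s_A, x$s_p))
  cat(sprintf("  hard: h_r = %g, h_alpha = %g, h_A = %g, h_p = %g, h_t = %d frames\n",
              x$h_r, x$h_alpha, x$h_A, x$h_p, x$h_t))
  invisible(x)
}

#' Circular angular difference
#'
#' Absolute angular difference between two directions, folded into `[0, pi]`.
#'
#' @param t1,t2 Angles in radians.
#' @return Difference in `[0, pi]` (vectorised).
#' @export
circular_angle_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Pairing cost between two kinematic states
#'
#' Sum over enabled kinematic parameters of increment / soft normalisation;
#' `+Inf` as soon as any enabled increment reaches its hard threshold (the
#' hard term is 1 only while the increment stays strictly below the
#' threshold). Parameters discarded via [match_params()] (soft and hard both
#' `+Inf`) contribute nothing and never veto.
#'
#' @param a,b Rows (or lists) with `x`, `y`, `theta`, `area`, `perimeter`.
#' @param p A [match_params()].
#' @return Non-negative cost, possibly `+Inf`.
#' @export
pairwise_cost <- function(a, b, p) {
  dr <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  da <- circular_angle_diff(a$theta, b$theta)
  dA <- abs(a$area - b$area)
  dp <- abs(a$perimeter - b$perimeter)
  cost_components(dr, da, dA, dp, p)
}

## vectorised core shared by pairwise_cost and the cost-matrix builder
cost_components <- function(dr, da, dA, dp, p) {
  en_r <- !(is.infinite(p$s_r) && is.infinite(p$h_r))
  en_a <- !(is.infinite(p$s_alpha) && is.infinite(p$h_alpha))
  en_A <- !(is.infinite(p$s_A) && is.infinite(p$h_A))
  en_p <- !(is.infinite(p$s_p) && is.infinite(p$h_p))
  c_ <- 0
  if (en_r) c_ <- c_ + dr / p$s_r
  if (en_a) c_ <- c_ + da / p$s_alpha
  if (en_A) c_ <- c_ + dA / p$s_A
  if (en_p) c_ <- c_ + dp / p$s_p
  bad <- (en_r & dr >= p$h_r) | (en_a & da >= p$h_alpha) |
    (en_A & dA >= p$h_A) | (en_p & dp >= p$h_p)
  ifelse(bad, Inf, c_)
}

## cost matrix between candidate predecessor states (rows) and detections
## (columns), both as data frames with x, y, theta, area, perimeter
build_cost_matrix <- function(cand, det, p) {
  n <- nrow(cand); m <- nrow(det)
  dr <- sqrt(outer(cand$x, det$x, `-`)^2 + outer(cand$y, det$y, `-`)^2)
  da <- outer(cand$theta, det$theta, circular_angle_diff)
  dA <- abs(outer(cand$area, det$area, `-`))
  dp <- abs(outer(cand$perimeter, det$perimeter, `-`))
  matrix(cost_components(as.vector(dr), as.vector(da), as.vector(dA),
                         as.vector(dp), p), n, m)
}

## internal tracker state: a data frame of candidates (one per live or
## recently lost trajectory) with id, frame of last sighting, kinematics,
## and age = number of consecutive frames missed so far (0 = active)
new_tracker_state <- function() {
  list(cand = tibble(id = integer(), frame = integer(), x = double(),
                     y = double(), theta = double(), area = double(),
                     perimeter = double(), age = integer()),
       next_id = 1L, n_ap = 0L)
}

#' Advance trajectories by one frame of detections
#'
#' One step of the frame-by-frame matcher. Candidates are the last known
#' states of active trajectories plus those lost for fewer than `h_t` frames
#' (pseudo-occurrences, compared from their frozen last state with unmodified
#' thresholds). The candidate-by-detection cost matrix is solved exactly with
#' the Kuhn-Munkres algorithm; matched detections extend their trajectory
#' (gaps preserved, no interpolation), unmatched candidates age by one frame
#' and are retired permanently once their age reaches `h_t`, and unmatched
#' detections found new trajectories with fresh ids (counted in `n_ap`).
#'
#' @param state Tracker state from [new_tracker_state()] / a previous call.
#' @param detections Tibble of detections, all at frame `frame`.
#' @param p A [match_params()].
#' @param frame Integer frame index.
#' @return List with updated `state` and `links` (tibble `id`, detection row).
#' @keywords internal
advance_tracks <- function(state, detections, p, frame) {
  det <- detections
  cand <- state$cand
  links <- tibble(id = integer(), det = integer())
  if (nrow(cand) > 0 && nrow(det) > 0) {
    cm <- build_cost_matrix(cand, det, p)
    asg <- solve_assignment(cm)
    links <- tibble(id = cand$id[asg$row], det = asg$col)
  }
  matched_c <- match(links$id, cand$id)
  matched_d <- links$det
  # matched candidates: refresh state
  if (length(matched_c) > 0) {
    cand$frame[matched_c] <- frame
    cand$x[matched_c] <- det$x[matched_d]
    cand$y[matched_c] <- det$y[matched_d]
    cand$theta[matched_c] <- det$theta[matched_d]
    cand$area[matched_c] <- det$area[matched_d]
    cand$perimeter[matched_c] <- det$perimeter[matched_d]
    cand$age[matched_c] <- 0L
  }
  # unmatched candidates age; retire at h_t
  un <- setdiff(seq_len(nrow(cand)), matched_c)
  cand$age[un] <- cand$age[un] + 1L
  cand <- cand[cand$age < p$h_t, , drop = FALSE]
  # unmatched detections found new trajectories
  newd <- setdiff(seq_len(nrow(det)), matched_d)
  if (length(newd) > 0) {
    ids <- state$next_id + seq_along(newd) - 1L
    cand <- dplyr::bind_rows(cand, tibble(
      id = ids, frame = frame, x = det$x[newd], y = det$y[newd],
      theta = det$theta[newd], area = det$area[newd],
      perimeter = det$perimeter[newd], age = 0L))
    state$next_id <- state$next_id + length(newd)
    state$n_ap <- state$n_ap + length(newd)
    links <- dplyr::bind_rows(links, tibble(id = ids, det = newd))
  }
  state$cand <- cand
  list(state = state, links = links)
}

#' Track objects across a movie
#'
#' Full tracking pipeline: for a [frame_stack()] input, detection and
#' kinematic extraction are run first (see [detect_objects()]); a detections
#' tibble (columns `frame`, `x`, `y`, `theta`, `area`, `perimeter`) is
#' consumed directly. Frames are then matched in increasing order with
#' [match_params()] semantics: exact Kuhn-Munkres assignment between the new
#' detections and the last states of active or recently lost trajectories.
#' Only past and current information is used; the result is deterministic.
#'
#' @param x A `frame_stack` or a detections tibble.
#' @param match_params A [match_params()].
#' @param det_params A [detection_params()] (used for frame-stack input).
#' @param background Optional background image for detection.
#' @return A `trajectory_set` tibble (`frame`, `id`, `x`, `y`, `theta`,
#'   `area`, `perimeter`), ids in order of first appearance; attribute
#'   `n_ap` counts trajectory births.
#' @export
track <- function(x, match_params = mot2d::match_params(),
                  det_params = detection_params(), background = NULL) {
  det <- if (inherits(x, "frame_stack")) {
    detect_objects(x, det_params, background)
  } else {
    as_tibble(x)
  }
  req <- c("frame", "x", "y", "theta", "area", "perimeter")
  miss <- setdiff(req, names(det))
  if (length(miss) > 0)
    abort(paste0("detections lack columns: ", paste(miss, collapse = ", ")))
  state <- new_tracker_state()
  empty <- tibble(frame = integer(), id = integer(), x = double(),
                  y = double(), theta = double(), area = double(),
                  perimeter = double())
  out <- list(empty)
  if (nrow(det) > 0) {
    # every frame of the observed range advances the tracker, including
    # frames with no detections (lost candidates age there)
    frames <- seq(min(det$frame), max(det$frame))
    by_frame <- split(det, factor(det$frame, levels = frames))
    out <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      f <- frames[k]
      d <- by_frame[[k]]
      step <- advance_tracks(state, d, match_params, f)
      state <- step$state
      out[[k]] <- tibble(frame = f, id = step$links$id,
                         x = d$x[step$links$det], y = d$y[step$links$det],
                         theta = d$theta[step$links$det],
                         area = d$area[step$links$det],
                         perimeter = d$perimeter[step$links$det])
    }
  }
  res <- dplyr::bind_rows(empty, out)
  res <- dplyr::arrange(res, .data$frame, .data$id)
  res <- new_trajectory_set(res)
  attr(res, "n_ap") <- state$n_ap
  res
}

## number of trajectory births in a trajectory set
n_appearances <- function(traj) {
  attr(traj, "n_ap") %||% dplyr::n_distinct(traj$id)
}
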