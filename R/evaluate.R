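#' Identity-swap probability of a tracking against ground truth
#'
#' Each tracked state is matched to the nearest ground-truth object of the
#' same frame; a match further than half the minimal ground-truth
#' inter-object distance of that frame is counted as undetected (this radius
#' makes the matching unambiguous). `N_swap` counts, within each tracked
#' trajectory, the transitions between successively matched states whose
#' ground-truth identity changes — one physical exchange between two
#' trajectories therefore contributes two counted transitions. With
#' `N_obj` the total number of tracked states and `n_ap` the number of
#' trajectory births, the per-opportunity swap probability is
#' `P_swap = N_swap / (N_obj - n_ap)`; for a constant number `n` of objects
#' over `T` frames the denominator reduces to `n * (T - 1)`. The accuracy
#' `A = (n_obj*n_img - (2*N_swap + N_undetected)) / (n_obj*n_img)`, clipped
#' at 0, is reported alongside.
#'
#' @param tracked A `trajectory_set` produced by [track()] (or any table
#'   with `frame`, `id`, `x`, `y`).
#' @param gt The complete ground-truth `trajectory_set` on the same frames.
#' @return A `swap_report` list: `N_swap`, `n_ap`, `N_obj`, `N_undetected`,
#'   `P_swap`, `accuracy`, `n_obj`, `n_img`.
#' @export
p_swap <- function(tracked, gt) {
  if (nrow(tracked) == 0) abort("empty tracked set")
  if (min(tracked$frame) < min(gt$frame) || max(tracked$frame) > max(gt$frame))
    abort("tracked frames extend outside the ground-truth frame range")
  gt_by_frame <- split(as_tibble(gt), gt$frame)
  tr <- as_tibble(tracked)
  tr$gt_id <- NA_integer_
  tr_by_frame <- split(seq_len(nrow(tr)), tr$frame)
  n_matched_gt <- 0L
  for (f in names(tr_by_frame)) {
    g <- gt_by_frame[[f]]
    if (is.null(g)) next
    rows <- tr_by_frame[[f]]
    if (nrow(g) >= 2) {
      dg <- as.matrix(stats::dist(cbind(g$x, g$y)))
      diag(dg) <- Inf
      radius <- min(dg) / 2
    } else {
      radius <- Inf
    }
    dx <- outer(tr$x[rows], g$x, `-`)
    dy <- outer(tr$y[rows], g$y, `-`)
    dd <- sqrt(dx^2 + dy^2)
    nearest <- apply(dd, 1, which.min)
    ok <- dd[cbind(seq_along(rows), nearest)] <= radius
    tr$gt_id[rows[ok]] <- g$id[nearest[ok]]
  }
  # swaps: per tracked trajectory, transitions between successive matched
  # states with differing ground-truth identity
  swaps <- tr |>
    dplyr::filter(!is.na(.data$gt_id)) |>
    dplyr::arrange(.data$id, .data$frame) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(s = sum(.data$gt_id != dplyr::lag(.data$gt_id),
                             na.rm = TRUE)) |>
    dplyr::pull(.data$s)
  N_swap <- sum(swaps)
  n_ap <- n_appearances(tracked)
  N_obj <- nrow(tr)
  # ground-truth states never matched by any tracked state
  matched_keys <- unique(paste(tr$frame[!is.na(tr$gt_id)],
                               tr$gt_id[!is.na(tr$gt_id)]))
  gt_keys <- paste(gt$frame, gt$id)
  N_undetected <- sum(!gt_keys %in% matched_keys)
  n_img <- dplyr::n_distinct(gt$frame)
  n_obj <- round(nrow(gt) / n_img)
  denom <- N_obj - n_ap
  P <- if (denom > 0) N_swap / denom else 0
  A <- swap_accuracy_value(N_swap, N_undetected, n_obj, n_img)
  structure(
    list(N_swap = as.integer(N_swap), n_ap = as.integer(n_ap),
         N_obj = as.integer(N_obj), N_undetected = as.integer(N_undetected),
         P_swap = P, accuracy = A, n_obj = n_obj, n_img = n_img),
    class = "swap_report"
  )
}

swap_accuracy_value <- function(N_swap, N_undetected, n_obj, n_img) {
  max((n_obj * n_img - (2 * N_swap + N_undetected)) / (n_obj * n_img), 0)
}

#' Tracking accuracy
#'
#' `A = (n_obj*n_img - (2*N_swap + N_undetected)) / (n_obj*n_img)`, clipped
#' at 0: every swap spoils two object-frames, every missed detection one.
#'
#' @param report A [p_swap()] `swap_report`.
#' @param n_obj Number of objects per frame.
#' @param n_img Number of frames.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(report, n_obj = report$n_obj, n_img = report$n_img) {
  if (n_obj < 1 || n_img < 1) abort("`n_obj` and `n_img` must be >= 1")
  swap_accuracy_value(report$N_swap, report$N_undetected, n_obj, n_img)
}

#' @export
print.swap_report <- function(x, ...) {
  cat("<swap_report>\n")
  cat(sprintf("  N_swap = %d, n_ap = %d, N_obj = %d, N_undetected = %d\n",
              x$N_swap, x$n_ap, x$N_obj, x$N_undetected))
  cat(sprintf("  P_swap = %.6g, accuracy = %.6g\n", x$P_swap, x$accuracy))
  invisible(x)
}

#' @rdname p_swap
#' @param x A `swap_report`.
#' @param ... Unused.
#' @export
glance.swap_report <- function(x, ...) {
  tibble(N_swap = x$N_swap, n_ap = x$n_ap, N_obj = x$N_obj,
         N_undetected = x$N_undetected, P_swap = x$P_swap,
         accuracy = x$accuracy)
}
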