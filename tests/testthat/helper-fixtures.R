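# shared fixtures and independent oracles, built in code at test time

# rasterize a filled rotated ellipse into a 0/1 matrix (pixel-centre test,
# same convention as the package but written independently)
raster_ellipse <- function(xc, yc, a, b, th, W = 120, H = 120) {
  cg <- expand.grid(r = seq_len(H), c = seq_len(W))
  dx <- cg$c - 1 - xc
  dy <- cg$r - 1 - yc
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  m <- matrix(0L, H, W)
  m[cbind(cg$r, cg$c)[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]] <- 1L
  m
}

# circularly shift matrix content by (dx, dy): +dx columns right, +dy rows down
circshift_mat <- function(m, dx, dy) {
  m <- m[, ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1, drop = FALSE]
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1, , drop = FALSE]
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# exhaustive oracle for the rectangular assignment problem with +Inf
# forbidden entries: sentinel-pad to square, enumerate all permutations,
# keep the minimum padded total, and report the stripped finite cost
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  M <- 1 + sum(cost[is.finite(cost)])
  a <- cost
  a[!is.finite(a)] <- M
  k <- max(n, m)
  sq <- matrix(0, k, k)
  sq[seq_len(n), seq_len(m)] <- a
  best <- Inf
  best_strip <- Inf
  for (p in all_perms(k)) {
    tot <- sum(sq[cbind(seq_len(k), p)])
    if (tot < best - 1e-12) {
      best <- tot
      pairs <- cbind(seq_len(k), p)
      pairs <- pairs[pairs[, 1] <= n & pairs[, 2] <= m, , drop = FALSE]
      vals <- cost[pairs]
      best_strip <- sum(vals[is.finite(vals)])
    }
  }
  best_strip
}

# 8-connected flood fill component count (queue-based, independent of the
# package's label-merge implementation)
flood_fill_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  ncomp <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (mask[r0, c0] > 0 && !seen[r0, c0]) {
      ncomp <- ncomp + 1L
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
              mask[r, c] > 0 && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  ncomp
}

# a small noiseless movie of well-separated slow ellipses + its ground truth
make_separated_movie <- function(n_objects = 10, n_frames = 30, roi = 600,
                                 step_sigma = 0.8, seed = 3) {
  cfg <- sim_config(n_objects = n_objects, n_frames = n_frames,
                    roi_width = roi, roi_height = roi,
                    step_sigma = step_sigma, arrangement = "hexagonal",
                    seed = seed)
  gt <- simulate_trajectories(cfg)
  list(cfg = cfg, gt = gt, stack = render_movie(gt, cfg),
       background = matrix(220, roi, roi))
}

sep_det_params <- function() detection_params(threshold = 80, min_area = 20)
sep_match_params <- function() match_params(s_r = 5, s_alpha = 0.5, s_A = 50,
                                            h_r = 30)
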