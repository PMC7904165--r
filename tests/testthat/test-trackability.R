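test_that("incursion probability vanishes at zero displacement", {
  pts <- generate_point_configuration(50, c(1, 1), "uniform", seed = 61)
  prof <- incursion_profile(pts, c(1, 1), rho_grid = seq(0, 1, by = 0.1),
                            n_angles = 36)
  expect_equal(prof$p[prof$rho == 0], 0)
  expect_true(all(prof$p >= 0 & prof$p <= 1))
})

test_that("the interior cell of a 3x3 lattice is always exited at rho = 1.5", {
  s <- 10
  g <- expand.grid(x = s * c(0.5, 1.5, 2.5), y = s * c(0.5, 1.5, 2.5))
  angles <- 2 * pi * (0:359) / 360
  ex <- mot2d:::exit_distances(g$x, g$y, cos(angles), sin(angles), c(3 * s, 3 * s))
  centre <- which(g$x == 1.5 * s & g$y == 1.5 * s)
  d <- 9 / (3 * s)^2
  r <- 1.5 / sqrt(d)
  # every direction exits the unit cell and none leaves the ROI first
  expect_true(all(ex$cell[centre, ] < r))
  expect_true(all(ex$roi[centre, ] >= r - 1e-9))
})

test_that("cell exit distances agree with a brute-force endpoint oracle", {
  set.seed(62)
  pts <- tibble::tibble(x = runif(12, 0, 1), y = runif(12, 0, 1))
  angles <- 2 * pi * (0:23) / 24
  ex <- mot2d:::exit_distances(pts$x, pts$y, cos(angles), sin(angles), c(1, 1))
  for (r in c(0.05, 0.15, 0.4)) {
    for (i in seq_len(nrow(pts))) {
      qx <- pts$x[i] + r * cos(angles)
      qy <- pts$y[i] + r * sin(angles)
      # oracle: the endpoint is in another cell iff its nearest generator
      # is not its own
      oracle <- vapply(seq_along(angles), function(k) {
        dd <- (qx[k] - pts$x)^2 + (qy[k] - pts$y)^2
        which.min(dd) != i
      }, logical(1))
      expect_equal(unname(ex$cell[i, ] < r), oracle)
    }
  }
})

test_that("p_inc rises near rho = 1/2, steeper for hexagonal than uniform", {
  grid <- seq(0, 1.5, by = 0.05)
  pu <- incursion_profile(generate_point_configuration(400, c(1, 1), "uniform",
                                                       seed = 63),
                          c(1, 1), grid, n_angles = 90)
  ph <- incursion_profile(generate_point_configuration(400, c(1, 1), "hexagonal"),
                          c(1, 1), grid, n_angles = 90)
  infl <- profile_inflection(pu)
  expect_gt(infl, 0.4)
  expect_lt(infl, 0.6)
  expect_true(all(diff(stats::filter(pu$p, rep(1 / 3, 3), sides = 2)[2:25]) >
                    -0.02))
  # hexagonal cells are stereotyped: the rise through the midpoint is steeper
  slope_at <- function(pr) {
    i <- which.min(abs(pr$p - 0.5 * max(pr$p)))
    (pr$p[i + 1] - pr$p[i - 1]) / (pr$rho[i + 1] - pr$rho[i - 1])
  }
  expect_gt(slope_at(ph), slope_at(pu))
})

test_that("reflective walls cap the large-rho asymptote below 1 for small n", {
  grid <- c(seq(0, 1, by = 0.25), 2, 3)
  small <- incursion_profile(generate_point_configuration(9, c(1, 1), "uniform",
                                                          seed = 64),
                             c(1, 1), grid, n_angles = 180)
  big <- incursion_profile(generate_point_configuration(400, c(1, 1), "uniform",
                                                        seed = 64),
                           c(1, 1), grid, n_angles = 180)
  expect_lt(max(small$p), 1)
  expect_gt(max(big$p), max(small$p))
})

test_that("displacement samples follow the stated striding and scaling rules", {
  # constant-velocity object: r is linear in tau
  traj <- tibble::tibble(frame = 0:20, id = 1L, x = 3 * (0:20), y = 0,
                         theta = 0, area = 1, perimeter = 1)
  d <- 4
  expect_equal(unique(displacement_samples(traj, 2, d)), 6 * sqrt(d))
  expect_equal(unique(displacement_samples(traj, 0.5, d)), 1.5 * sqrt(d))
  expect_error(displacement_samples(traj, 1.5, d), "integer")
  expect_error(displacement_samples(traj[1, ], 1, d), "no displacement")

  # Brownian: diffusive scaling of the second moment
  cfg <- sim_config(n_objects = 30, n_frames = 400, roi_width = 2000,
                    roi_height = 2000, step_sigma = 2, seed = 65)
  gt <- simulate_trajectories(cfg)
  dd <- 30 / 2000^2
  s1 <- displacement_samples(gt, 1, dd)
  s4 <- displacement_samples(gt, 4, dd)
  expect_lt(abs(mean(s4^2) / mean(s1^2) - 4) / 4, 0.10)
})

test_that("the empirical incursion mean matches quadrature of the density", {
  grid <- seq(0, 2, by = 0.05)
  prof <- structure(tibble::tibble(rho = grid, p = pmin(grid, 1)^2 / 4),
                    class = c("incursion_profile", "tbl_df", "tbl", "data.frame"))
  expect_equal(p_incursion(rep(0, 5), prof), 0)
  flat <- structure(tibble::tibble(rho = grid, p = rep(1, length(grid))),
                    class = class(prof))
  expect_equal(p_incursion(runif(100), flat), 1)
  set.seed(66)
  samp <- abs(rnorm(1e5, 0.5, 0.2))
  # quadrature of the folded-normal sample density against the profile
  quad <- stats::integrate(function(r) {
    (stats::dnorm(r, 0.5, 0.2) + stats::dnorm(-r, 0.5, 0.2)) *
      approx(prof$rho, prof$p, r, rule = 2)$y
  }, 0, 3, subdivisions = 500)$value
  expect_lt(abs(p_incursion(samp, prof) - quad) / quad, 0.01)
})

test_that("the logistic fit recovers its own generator", {
  taus <- exp(seq(log(0.2), log(50), length.out = 20))
  p <- 0.8 / (1 + (7 / taus)^3)
  f <- fit_logistic(taus, p)
  expect_lt(abs(f$L - 0.8) / 0.8, 1e-4)
  expect_lt(abs(f$k - 3) / 3, 1e-4)
  expect_lt(abs(f$tau0 - 7) / 7, 1e-4)

  set.seed(67)
  pn <- p * exp(rnorm(20, 0, 0.05))
  fn <- fit_logistic(taus, pn)
  expect_lt(abs(fn$L - 0.8) / 0.8, 0.10)
  expect_lt(abs(fn$k - 3) / 3, 0.10)
  expect_lt(abs(fn$tau0 - 7) / 7, 0.10)

  expect_error(fit_logistic(taus, rep(0.5, 20)), "unidentifiable")
  expect_error(fit_logistic(1:3, c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("tau1 satisfies its defining identity", {
  f <- structure(list(L = 1, k = 2.3, tau0 = 5), class = "logistic_fit")
  expect_equal(tau_one(f, 2), 5)
  f2 <- structure(list(L = 0.5, k = 1, tau0 = 10), class = "logistic_fit")
  expect_equal(tau_one(f2, 4), 10)
  set.seed(68)
  for (i in 1:100) {
    ft <- structure(list(L = runif(1, 0.05, 1), k = runif(1, 0.5, 6),
                         tau0 = runif(1, 0.5, 50)), class = "logistic_fit")
    N <- sample(2:5000, 1)
    t1 <- tau_one(ft, N)
    if (is.finite(t1)) {
      expect_lt(abs(predict(ft, t1) * N - 1), 1e-10)
    } else {
      expect_lte(ft$L * N, 1)
      expect_true(isTRUE(attr(t1, "never_reached")))
    }
  }
  flow <- structure(list(L = 0.1, k = 2, tau0 = 5), class = "logistic_fit")
  expect_true(is.infinite(tau_one(flow, 5)))
})

test_that("P_inc(tau) collapses onto the standard sigmoid across densities", {
  # integer subsampling only: sub-unit timescales use the linear scaling
  # convention, which deviates from the diffusive sqrt(tau) law by design
  for (n in c(60, 120, 240)) {
    cfg <- sim_config(n_objects = n, n_frames = 300, roi_width = 256,
                      roi_height = 256, step_sigma = 3, seed = 70 + n)
    gt <- simulate_trajectories(cfg)
    rep_ <- trackability(gt, c(256, 256),
                         taus = c(1, 2, 3, 5, 8, 12, 20, 30),
                         n_angles = 90, max_frames = 4)
    ok <- rep_$series[rep_$series$P_inc > 0, ]
    xx <- rep_$fit$k * log(ok$tau / rep_$fit$tau0)
    resid <- ok$P_inc / rep_$fit$L - 1 / (1 + exp(-xx))
    expect_lt(sqrt(mean(resid^2)), 0.05)
  }
})

test_that("degradation is reproducible, countable and leaves delta = 0 alone", {
  cfg <- sim_config(n_objects = 10, n_frames = 40, roi_width = 200,
                    roi_height = 200, step_sigma = 2, seed = 71)
  gt <- simulate_trajectories(cfg)
  expect_identical(degrade(gt, 0, 1), gt)
  d1 <- degrade(gt, 0.01, seed = 5)
  d2 <- degrade(gt, 0.01, seed = 5)
  expect_identical(d1, d2)
  d3 <- degrade(gt, 0.01, seed = 6)
  expect_false(identical(d1, d3))
  # positions are untouched, only identities move
  expect_equal(dplyr::arrange(dplyr::select(d1, frame, x, y), frame, x),
               dplyr::arrange(dplyr::select(gt, frame, x, y), frame, x))
})

test_that("one forced swap on a 2-object toy gives the hand-counted P_swap", {
  cfg <- sim_config(n_objects = 2, n_frames = 10, roi_width = 100,
                    roi_height = 100, step_sigma = 1, seed = 72)
  gt <- simulate_trajectories(cfg)
  dg <- degrade(gt, delta = 1 / 20, seed = 3)  # exactly one exchange
  rep_ <- p_swap(dg, gt)
  # both trajectories change identity once at the swap frame
  expect_equal(rep_$N_swap, 2)
  expect_equal(rep_$P_swap, 2 / (2 * 9))
})

test_that("the logistic fit resists a small degradation rate", {
  cfg <- sim_config(n_objects = 50, n_frames = 500, roi_width = 256,
                    roi_height = 256, step_sigma = 3, seed = 8)
  gt <- simulate_trajectories(cfg)
  taus <- c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 25, 50)
  r0 <- trackability(gt, c(256, 256), taus = taus, n_angles = 90,
                     max_frames = 4)
  r1 <- trackability(degrade(gt, 1e-3, seed = 9), c(256, 256), taus = taus,
                     n_angles = 90, max_frames = 4)
  expect_lt(abs(r1$fit$L - r0$fit$L) / r0$fit$L, 0.10)
  expect_lt(abs(r1$fit$k - r0$fit$k) / r0$fit$k, 0.10)
  expect_lt(abs(r1$fit$tau0 - r0$fit$tau0) / r0$fit$tau0, 0.10)
})
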