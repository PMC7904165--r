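kin <- function(x, y, theta = 0, area = 50, perimeter = 30) {
  list(x = x, y = y, theta = theta, area = area, perimeter = perimeter)
}

test_that("the pairing cost sums normalised increments and hard-gates", {
  p <- match_params(s_r = 4, s_alpha = 0.2, s_A = 2, s_p = Inf,
                    h_r = 10, h_alpha = pi, h_A = 100, h_p = Inf)
  a <- kin(0, 0, 0.0, 10)
  expect_equal(pairwise_cost(a, a, p), 0)
  b <- kin(2, 0, 0.1, 11)   # dr = 2, dalpha = 0.1, dA = 1, perimeter discarded
  expect_equal(pairwise_cost(a, b, p), 2 / 4 + 0.1 / 0.2 + 1 / 2)
  # crossing the hard radius makes the pairing impossible
  b2 <- kin(10 + 1e-9, 0)
  expect_equal(pairwise_cost(a, b2, p), Inf)
  # a discarded parameter neither costs nor vetoes
  pd <- match_params(s_r = 4, s_alpha = Inf, s_A = Inf, s_p = Inf,
                     h_r = Inf, h_alpha = Inf, h_A = Inf, h_p = Inf)
  far_angle <- kin(1, 0, theta = 3, area = 1e6, perimeter = 1e6)
  expect_equal(pairwise_cost(a, far_angle, pd), 0.25)
})

test_that("circular angular differences fold into [0, pi]", {
  expect_equal(circular_angle_diff(0.1, 0.1), 0)
  expect_equal(circular_angle_diff(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(circular_angle_diff(0, pi), pi)
  expect_true(all(circular_angle_diff(runif(50, 0, 2 * pi),
                                      runif(50, 0, 2 * pi)) <= pi))
})

test_that("a single object yields a single full-length trajectory", {
  det <- tibble::tibble(frame = 0:19, x = cumsum(rnorm(20)), y = 0,
                        theta = 0, area = 50, perimeter = 30)
  tr <- track(det, match_params(h_t = 3))
  expect_equal(dplyr::n_distinct(tr$id), 1)
  expect_equal(nrow(tr), 20)
  expect_equal(attr(tr, "n_ap"), 1)
})

test_that("empty input gives an empty trajectory set", {
  det <- tibble::tibble(frame = integer(), x = double(), y = double(),
                        theta = double(), area = double(), perimeter = double())
  expect_equal(nrow(track(det)), 0)
})

test_that("short disappearances below h_t keep the identity, longer ones do not", {
  base <- tibble::tibble(frame = 0:9, x = 10, y = 10, theta = 0,
                         area = 50, perimeter = 30)
  p <- match_params(s_r = 5, h_r = 20, h_t = 3)
  # lost at frame 3 (last seen frame 3), reappears at frame 6: gap of 2 missed
  det_gap2 <- dplyr::filter(base, !frame %in% c(4, 5))
  tr <- track(det_gap2, p)
  expect_equal(dplyr::n_distinct(tr$id), 1)
  expect_equal(attr(tr, "n_ap"), 1)
  expect_false(any(tr$frame %in% c(4, 5)))  # gap preserved, no interpolation

  # lost at frame 3, reappears at frame 8: 4 missed frames >= h_t
  det_gap5 <- dplyr::filter(base, !frame %in% 4:7)
  tr2 <- track(det_gap5, p)
  expect_equal(dplyr::n_distinct(tr2$id), 2)
  expect_equal(attr(tr2, "n_ap"), 2)
})

test_that("each detection joins exactly one trajectory, ids unique per frame", {
  set.seed(41)
  cfg <- sim_config(n_objects = 12, n_frames = 40, roi_width = 300,
                    roi_height = 300, step_sigma = 2,
                    arrangement = "hexagonal", seed = 13)
  gt <- simulate_trajectories(cfg)
  det <- dplyr::select(gt, -id)
  tr <- track(det, match_params(s_r = 3, h_r = 20))
  expect_equal(nrow(tr), nrow(det))
  expect_equal(max(tr |> dplyr::count(frame, id) |> dplyr::pull(n)), 1)
})

test_that("detection order within a frame does not change the trajectories", {
  set.seed(42)
  cfg <- sim_config(n_objects = 8, n_frames = 25, roi_width = 300,
                    roi_height = 300, step_sigma = 2,
                    arrangement = "hexagonal", seed = 14)
  det <- dplyr::select(simulate_trajectories(cfg), -id)
  tr1 <- track(det, match_params(s_r = 3, h_r = 20))
  det_shuf <- det[sample(nrow(det)), ]
  tr2 <- track(det_shuf, match_params(s_r = 3, h_r = 20))
  # compare the partition of states into trajectories, not the labels
  key <- function(tr) {
    tr |>
      dplyr::arrange(id, frame) |>
      dplyr::group_by(id) |>
      dplyr::summarise(sig = paste(frame, round(x, 9), round(y, 9),
                                   collapse = ";")) |>
      dplyr::pull(sig) |>
      sort()
  }
  expect_equal(key(tr1), key(tr2))
})

test_that("the full pipeline tracks a noiseless movie without swaps", {
  mv <- make_separated_movie(n_objects = 8, n_frames = 30)
  tr <- track(mv$stack, sep_match_params(), sep_det_params(),
              background = mv$background)
  rep <- p_swap(tr, mv$gt)
  expect_equal(rep$N_swap, 0)
  expect_equal(rep$P_swap, 0)
})
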