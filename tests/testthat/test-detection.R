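test_that("background estimation reduces sampled frames as stated", {
  const <- matrix(7, 10, 10)
  st <- frame_stack(list(const, const, const))
  expect_equal(estimate_background(st, "mean", 3), const)
  expect_equal(estimate_background(st, "min", 2), const)

  # dark object moving on a white field: max removes the transients
  white <- matrix(255, 20, 20)
  f1 <- white; f1[5:8, 5:8] <- 0
  f2 <- white; f2[12:15, 12:15] <- 0
  expect_equal(estimate_background(frame_stack(list(f1, f2)), "max", 2), white)

  a <- matrix(10, 4, 4); b <- matrix(20, 4, 4)
  expect_equal(estimate_background(frame_stack(list(a, b)), "mean", 2)[1, 1], 15)

  expect_error(estimate_background(frame_stack(list(a)), "min", 0), ">= 1")
})

test_that("phase correlation recovers translations coarse-to-fine", {
  set.seed(1)
  ref <- matrix(runif(128 * 128), 128, 128)
  expect_equal(unname(register_phase_correlation(ref, ref, 1)), c(0, 0),
               tolerance = 1e-6)
  mov <- circshift_mat(ref, 3, -2)
  for (lv in 1:2) {
    s <- register_phase_correlation(ref, mov, lv)
    expect_lt(abs(s[["dx"]] - 3), 0.5)
    expect_lt(abs(s[["dy"]] + 2), 0.5)
  }
  # transposing both images swaps the estimated coordinates
  s <- register_phase_correlation(ref, mov, 1)
  st <- register_phase_correlation(t(ref), t(mov), 1)
  expect_equal(unname(s[["dx"]]), unname(st[["dy"]]), tolerance = 0.2)
  expect_equal(unname(s[["dy"]]), unname(st[["dx"]]), tolerance = 0.2)

  expect_error(register_phase_correlation(matrix(1, 8, 8), ref[1:8, 1:8]),
               "constant")
  expect_error(register_frames(ref, mov, method = "ecc"), "not implemented")
})

test_that("binarization thresholds the polarity-signed difference inside the ROI", {
  bg <- matrix(200, 30, 30)
  fr <- bg
  expect_equal(sum(binarize(fr, bg, "lighter", 10)), 0)
  fr[10:15, 10:15] <- 50
  mask <- binarize(fr, bg, "lighter", 100)
  expect_equal(which(mask == 1, arr.ind = TRUE),
               which(fr == 50, arr.ind = TRUE))
  expect_equal(sum(binarize(fr, bg, "lighter", 255)), 0)
  # ROI forces outside pixels to zero
  m2 <- binarize(fr, bg, "lighter", 100, roi = c(0, 0, 11, 11))
  expect_true(all(which(m2 == 1, arr.ind = TRUE) <= 12))
})

test_that("binarize after render is polarity-symmetric", {
  cfg <- sim_config(n_objects = 4, n_frames = 1, roi_width = 80,
                    roi_height = 80, seed = 5)
  gt <- simulate_trajectories(cfg)
  dark <- render_movie(gt, cfg)[[1]]
  cfg$polarity <- "light_on_dark"
  light <- render_movie(gt, cfg)[[1]]
  m1 <- binarize(dark, matrix(220, 80, 80), "lighter", 80)
  m2 <- binarize(light, matrix(255 - 220, 80, 80), "darker", 80)
  expect_identical(m1, m2)
})

test_that("morphological filtering follows the listed order and identities", {
  m <- matrix(0L, 20, 20)
  m[5:12, 5:12] <- 1L
  m[8, 15] <- 1L  # isolated pixel
  expect_identical(morph_filter(m, list()), m)

  op <- list(list(op = "opening", shape = "rectangle", size = 3))
  once <- morph_filter(m, op)
  expect_identical(morph_filter(once, op), once)  # idempotence
  expect_equal(once[8, 15], 0L)                   # sub-kernel speck removed

  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_equal(sum(morph_filter(single, list(
    list(op = "erosion", shape = "rectangle", size = 3)))), 0)

  expect_error(morph_filter(m, list(list(op = "sharpen", size = 3))),
               "unknown morphological operation")
})

test_that("blob extraction uses 8-connectivity and the area filter", {
  m <- matrix(0L, 12, 12)
  m[3:7, 4:8] <- 1L
  b <- extract_blobs(m, 1, 100, 0)
  expect_length(b, 1)
  expect_equal(b[[1]]$area, 25)
  expect_length(extract_blobs(m, 1, 20, 0), 0)
  expect_length(extract_blobs(m, 26, 100, 0), 0)

  diagm <- matrix(0L, 8, 8)
  diagm[2, 2] <- 1L; diagm[3, 3] <- 1L
  expect_length(extract_blobs(diagm, 1, Inf, 0), 1)
  expect_equal(flood_fill_components(diagm), 1)  # oracle agreement
})

test_that("component count matches the flood-fill oracle on random masks", {
  set.seed(11)
  for (k in 1:10) {
    m <- matrix(rbinom(30 * 30, 1, 0.25), 30, 30)
    expect_equal(length(extract_blobs(m, 1, Inf, 0)),
                 flood_fill_components(m))
  }
})

test_that("boundary-derived area equals flood-fill pixel count for convex shapes", {
  set.seed(12)
  for (k in 1:20) {
    a <- runif(1, 4, 20); b <- runif(1, 3, a); th <- runif(1, 0, pi)
    m <- raster_ellipse(40, 40, a, b, th, 80, 80)
    bl <- extract_blobs(m, 1, Inf, 0)[[1]]
    expect_equal(bl$area, sum(m))
    e <- equivalent_ellipse(bl)
    expect_equal(e$area, sum(m))
  }
})

test_that("detection on a noiseless movie recovers ground truth", {
  mv <- make_separated_movie(n_objects = 8, n_frames = 5)
  det <- detect_objects(mv$stack, sep_det_params(), background = mv$background)
  counts <- det |> dplyr::count(frame)
  expect_true(all(counts$n == 8))
  g0 <- dplyr::filter(mv$gt, frame == 0)
  d0 <- dplyr::filter(det, frame == 0)
  for (i in seq_len(nrow(g0))) {
    dd <- sqrt((d0$x - g0$x[i])^2 + (d0$y - g0$y[i])^2)
    j <- which.min(dd)
    expect_lt(dd[j], 0.5)
    expect_lt(abs(d0$area[j] - g0$area[i]) / g0$area[i], 0.10)
  }
})
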