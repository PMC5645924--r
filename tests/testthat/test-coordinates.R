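test_that("scale factor averages the first qualifying frames deterministically", {
  rec1 <- make_recording(list(
    coin_a = cbind(0, 0), coin_b = cbind(24, 0),
    hyoid = cbind(80, 190)
  ))
  s <- compute_scale_factor(rec1, reference_length_mm = 24, n_frames = 1)
  expect_equal(s$s, 1.0)

  # separations 40, 41, 42 px over three frames -> mean 41
  rec3 <- make_recording(list(
    coin_a = cbind(c(0, 0, 0), c(0, 0, 0)),
    coin_b = cbind(c(40, 41, 42), c(0, 0, 0)),
    hyoid = cbind(c(80, 80, 80), c(190, 190, 190))
  ))
  s3 <- compute_scale_factor(rec3, reference_length_mm = 24, n_frames = 3)
  expect_equal(s3$s, 24 / 41)
  expect_equal(s3$frames_used, 0:2)
  # mean of distances, not distance of means, and first-3 selection:
  rec4 <- make_recording(list(
    coin_a = cbind(c(0, 0, 0, 0), 0), coin_b = cbind(c(40, 41, 42, 100), 0),
    hyoid = cbind(rep(80, 4), rep(190, 4))
  ))
  expect_equal(compute_scale_factor(rec4, 24, 3)$s, 24 / 41)
})

test_that("degenerate or insufficient calibration is an error", {
  rec <- make_recording(list(coin_a = cbind(5, 5), coin_b = cbind(5, 5),
                             hyoid = cbind(80, 190)))
  expect_error(compute_scale_factor(rec, 24, 1), "degenerate calibration")
  rec1 <- make_recording(list(coin_a = cbind(0, 0), coin_b = cbind(24, 0),
                              hyoid = cbind(80, 190)))
  expect_error(compute_scale_factor(rec1, 24, 3), "found 1")
  expect_error(compute_scale_factor(rec1, -5, 1), "positive")
})

test_that("frame_pose builds the documented axes and rejects a degenerate cervical axis", {
  p <- frame_pose(c2 = c(100, 180), c4 = c(100, 200))
  expect_equal(p$R, diag(2))
  expect_equal(p$p, c(100, 200))

  q <- frame_pose(c2 = c(10, -10), c4 = c(0, 0))
  expect_equal(q$R[, 2], c(1, 1) / sqrt(2))
  expect_equal(q$R[, 1], c(1, -1) / sqrt(2))

  expect_error(frame_pose(c(5, 5), c(5, 5)), "degenerate cervical axis")
})

test_that("frame_pose rotations are always proper orthonormal", {
  withr::local_seed(11)
  for (i in 1:50) {
    c2 <- stats::runif(2, 0, 500); c4 <- stats::runif(2, 0, 500)
    p <- frame_pose(c2, c4)
    expect_lt(max(abs(crossprod(p$R) - diag(2))), 1e-12)
    expect_lt(abs(det(p$R) - 1), 1e-12)
  }
})

test_that("to_anatomical maps the origin, the vertical axis, and the image-left sign", {
  p <- frame_pose(c2 = c(100, 180), c4 = c(100, 200))
  expect_equal(to_anatomical(c(100, 200), p, 1), c(x = 0, y = 0))
  expect_equal(to_anatomical(c(100, 180), p, 1), c(x = 0, y = 20))
  expect_equal(to_anatomical(c(90, 200), p, 1), c(x = 10, y = 0))
})

test_that("the transform is an isometry up to scale and C2 maps onto the y axis", {
  withr::local_seed(12)
  for (i in 1:25) {
    c2 <- stats::runif(2, 0, 500); c4 <- stats::runif(2, 0, 500)
    s <- stats::runif(1, 0.05, 2)
    pose <- frame_pose(c2, c4)
    a <- stats::runif(2, 0, 500); b <- stats::runif(2, 0, 500)
    da <- to_anatomical(a, pose, s) - to_anatomical(b, pose, s)
    expect_equal(sqrt(sum(da^2)), s * sqrt(sum((a - b)^2)), tolerance = 1e-9)
    expect_equal(to_anatomical(c2, pose, s),
                 c(x = 0, y = s * sqrt(sum((c2 - c4)^2))))
  }
})

test_that("a common rigid motion of point and landmarks leaves anatomical output unchanged", {
  withr::local_seed(13)
  for (i in 1:25) {
    c2 <- c(100, 180); c4 <- c(100, 200); q <- stats::runif(2, 0, 300)
    alpha <- stats::runif(1, -pi, pi); b <- stats::runif(2, -50, 50)
    before <- to_anatomical(q, frame_pose(c2, c4), 0.5)
    after <- to_anatomical(
      rigid_in_flipped(q, alpha, b),
      frame_pose(rigid_in_flipped(c2, alpha, b), rigid_in_flipped(c4, alpha, b)),
      0.5
    )
    expect_equal(after, before, tolerance = 1e-9)
  }
})

test_that("transform_recording recomputes the pose per frame", {
  # static everything -> constant anatomical series
  n <- 5
  rec <- make_recording(list(hyoid = cbind(rep(80, n), rep(190, n))))
  out <- transform_recording(rec, 1)
  h <- out[out$marker == "hyoid", ]
  expect_equal(h$x_mm, rep(h$x_mm[1], n))
  expect_equal(h$y_mm, rep(h$y_mm[1], n))
  expect_equal(h$time_s, (0:4) / 30)

  # static pixel marker + translating c2/c4 -> equal-and-opposite motion
  drift <- cbind(0:4, rep(0, 5))
  rec2 <- make_recording(list(
    hyoid = cbind(rep(80, 5), rep(190, 5)),
    c2 = cbind(100 + drift[, 1], 180), c4 = cbind(100 + drift[, 1], 200)
  ))
  h2 <- transform_recording(rec2, 1)
  h2 <- h2[h2$marker == "hyoid", ]
  # frame moves right by 1 px/frame; anatomical x (image-left) grows equally
  expect_equal(h2$x_mm, (100 - 80) + 0:4)
  expect_equal(h2$y_mm, rep(h2$y_mm[1], 5))

  # marker moving rigidly with the landmarks -> constant anatomical series
  alpha <- seq(0, 0.3, length.out = 5); b <- cbind(seq(0, 8, length.out = 5),
                                                   seq(0, -6, length.out = 5))
  mv <- function(uv) t(sapply(1:5, function(i) rigid_in_flipped(uv, alpha[i], b[i, ])))
  rec3 <- make_recording(list(hyoid = mv(c(80, 190)), c2 = mv(c(100, 180)),
                              c4 = mv(c(100, 200))))
  h3 <- transform_recording(rec3, 1)
  h3 <- h3[h3$marker == "hyoid", ]
  expect_lt(max(abs(h3$x_mm - h3$x_mm[1])), 1e-9)
  expect_lt(max(abs(h3$y_mm - h3$y_mm[1])), 1e-9)
})

test_that("frames with analysis markers but no cervical landmarks are an error", {
  rows <- tibble::tibble(
    frame = c(0L, 0L, 0L, 1L),
    marker = c("c2", "c4", "hyoid", "hyoid"),
    u = c(100, 100, 80, 81), v = c(180, 200, 190, 191)
  )
  rec <- vfss_recording(rows, fps = 30)
  expect_error(transform_recording(rec, 1), "missing c2 or c4: 1")
})
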