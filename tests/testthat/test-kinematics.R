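test_that("finite differences follow forward/central/backward formulas exactly", {
  expect_equal(finite_difference_velocity(c(0, 1, 2, 3), 1), rep(1, 4))
  expect_equal(finite_difference_velocity(c(0, 1, 4, 9), 1), c(1, 2, 4, 5))
  expect_equal(finite_difference_velocity(rep(2, 6), 0.5), rep(0, 6))
  expect_error(finite_difference_velocity(1, 1), "at least 2")
  expect_error(finite_difference_velocity(c(1, NA, 3), 1), "NA")
})

test_that("the differentiator is exact on affine series and on quadratics at interior samples", {
  dt <- 1 / 30
  t <- (0:40) * dt
  aff <- 2 - 5 * t
  expect_equal(finite_difference_velocity(aff, dt), rep(-5, 41), tolerance = 1e-9)
  quad <- 1 + 2 * t + 3 * t^2
  v <- finite_difference_velocity(quad, dt)
  expect_equal(v[2:40], (2 + 6 * t)[2:40], tolerance = 1e-9)
})

test_that("interior error on a sinusoid respects the (dt^2/6) max|x'''| bound", {
  dt <- 1 / 30
  t <- (0:60) * dt
  a <- 7; w <- 2 * pi * 1.3
  x <- a * sin(w * t)
  v <- finite_difference_velocity(x, dt)
  true_v <- a * w * cos(w * t)
  bound <- dt^2 / 6 * a * w^3  # max third derivative of a sin(w t)
  expect_lt(max(abs(v - true_v)[2:60]), bound + 1e-12)
})

test_that("trapezoidal re-integration of the velocity recovers affine displacement", {
  dt <- 0.1
  x <- 4 + 3 * (0:20) * dt
  v <- finite_difference_velocity(x, dt)
  reint <- x[1] + c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt))
  expect_equal(reint[2:20], x[2:20], tolerance = 1e-9)
})

test_that("displacement components obey the Pythagorean relation and norm inequality", {
  traj <- tibble::tibble(x = c(0, 3, -1), y = c(0, 4, 2))
  d <- displacement_components(traj)
  expect_equal(d$vertical, c(0, 4, 2))
  expect_equal(d$horizontal, c(0, 3, -1))
  expect_equal(d$planar_magnitude, c(0, 5, sqrt(5)))
  expect_true(all(d$planar_magnitude >= abs(d$vertical) - 1e-12))
  expect_true(all(d$planar_magnitude >= abs(d$horizontal) - 1e-12))

  same <- tibble::tibble(x = rep(2, 4), y = rep(-1, 4))
  expect_true(all(as.matrix(displacement_components(same)) == 0))
  expect_error(displacement_components(tibble::tibble(x = NA_real_, y = NA_real_)),
               "all-NA")
})

test_that("tilt angles measure from the y axis unsigned and from the initial pose signed clockwise", {
  base <- tibble::tibble(x = rep(0, 4), y = rep(0, 4))
  tip <- tibble::tibble(x = c(0, 1, 1, -1), y = c(1, 1, 0, 1))
  ay <- tilt_angle_series(base, tip, "from_y_axis")
  expect_equal(ay, c(0, 45, 90, 45))
  ai <- tilt_angle_series(base, tip, "from_initial")
  expect_equal(ai[1], 0)         # reference frame is zero by construction
  expect_equal(ai[2], 45)        # toward +x = clockwise = positive
  expect_equal(ai[4], -45)       # toward -x = counter-clockwise = negative
  expect_error(
    tilt_angle_series(tibble::tibble(x = c(0, 0), y = c(0, 0)),
                      tibble::tibble(x = c(0, 0), y = c(1, 0)), "from_y_axis"),
    "zero-length"
  )
})

test_that("separation distance is the symmetric per-frame Euclidean distance with NA passthrough", {
  a <- tibble::tibble(x = c(0, 1, NA), y = c(0, 1, 2))
  b <- tibble::tibble(x = c(3, 1, 0), y = c(4, 1, 0))
  d <- separation_distance_series(a, b)
  expect_equal(d, c(5, 0, NA))
  expect_equal(separation_distance_series(b, a), d)
})

test_that("peak extraction keeps the sign, breaks ties early, and skips NAs", {
  expect_equal(peak_summary(c(0, 3, -5, 2), frames = 0:3, signed = TRUE),
               list(value = -5, frame = 2))
  expect_equal(peak_summary(c(1, 1, 1), frames = 0:2), list(value = 1, frame = 0))
  expect_equal(peak_summary(c(NA, 2, NA), frames = 0:2), list(value = 2, frame = 1))
  expect_equal(peak_summary(c(-9, 5), frames = 0:1, signed = FALSE),
               list(value = 5, frame = 1))
  expect_error(peak_summary(c(NA_real_, NA_real_)), "all-NA")
})

test_that("transit time divides frame differences by the frame rate", {
  ev <- tibble::tibble(event = c("bolus cross the mandible angle",
                                 "bolus tail cross the UES"),
                       frame = c(30L, 60L))
  expect_equal(transit_time(ev, "bolus cross the mandible angle",
                            "bolus tail cross the UES", 30), 1.0)
  ev2 <- tibble::tibble(event = c("event_03", "event_04"), frame = c(5L, 5L))
  expect_equal(transit_time(ev2, "event_03", "event_04", 30), 0)
  ev3 <- tibble::tibble(event = c("event_03", "event_04"), frame = c(10L, 11L))
  expect_equal(transit_time(ev3, "event_03", "event_04", 30), 1 / 30)
  expect_warning(transit_time(ev, "bolus tail cross the UES",
                              "bolus cross the mandible angle", 30), "reverse")
  expect_error(transit_time(ev, "event_07", "bolus tail cross the UES", 30),
               "not recorded")
})

test_that("a pure vertical hyoid ramp yields the analytic peak parameters", {
  n <- 31  # 1 s at 30 fps
  # 10 mm ramp = 10 px upward at 1 px/mm (v decreases as the hyoid rises)
  rec <- make_recording(list(
    hyoid = cbind(rep(80, n), 190 - seq(0, 10, length.out = n))
  ))
  s <- compute_scale_factor(rec, 24, 1)
  expect_equal(s$s, 1.0)
  an <- analyze_recording(rec, s, config = analysis_config(smoothing_spec("none")),
                          structures = "hyoid")
  sm <- an$summary
  get <- function(p) sm$value[sm$parameter == p]
  expect_equal(get("max_disp_vert"), 10, tolerance = 1e-9)
  expect_equal(get("max_disp_horiz"), 0, tolerance = 1e-12)
  expect_equal(get("max_disp_2d"), 10, tolerance = 1e-9)
  expect_equal(get("max_vel_vert"), 10, tolerance = 1e-9)  # 10 mm over 1 s
})

test_that("a static recording has identically zero peaks", {
  n <- 6
  rec <- make_recording(list(
    hyoid = cbind(rep(80, n), rep(190, n)),
    larynx = cbind(rep(85, n), rep(210, n)),
    ues_anterior = cbind(rep(88, n), rep(215, n)),
    ues_posterior = cbind(rep(95, n), rep(215, n)),
    epiglottis_base = cbind(rep(90, n), rep(195, n)),
    epiglottis_tip = cbind(rep(92, n), rep(185, n))
  ))
  an <- analyze_recording(rec, 1, config = analysis_config(smoothing_spec("none")))
  moving <- an$summary[!grepl("opening", an$summary$parameter) &
                         !grepl("from_y_axis", an$summary$parameter), ]
  expect_true(all(abs(moving$value) < 1e-9))
  expect_equal(an$summary$value[an$summary$parameter == "max_opening_dist"], 7)
})

test_that("structures with a marker gap carry NA through series and still report peaks", {
  uv <- cbind(c(80, NA, 82, 83), c(190, NA, 188, 187))
  rec <- make_recording(list(hyoid = uv))
  an <- analyze_recording(rec, 1, config = analysis_config(smoothing_spec("none")),
                          structures = "hyoid")
  vert <- an$series[an$series$parameter == "disp_vert", ]
  expect_true(is.na(vert$value[vert$frame == 1]))
  expect_equal(sum(!is.na(vert$value)), 3L)
  expect_true(all(is.finite(an$summary$value)))
})

test_that("sampling the same motion at 30 and 60 fps gives consistent peaks", {
  motion <- function(fps) {
    t <- seq(0, 1, by = 1 / fps)
    make_recording(list(
      hyoid = cbind(rep(80, length(t)), 190 - 8 * sin(pi * t))
    ), fps = fps)
  }
  cfg <- analysis_config(smoothing_spec("none"))
  p30 <- tidy(analyze_recording(motion(30), 1, cfg, "hyoid"))
  p60 <- tidy(analyze_recording(motion(60), 1, cfg, "hyoid"))
  d30 <- p30$value[p30$parameter == "max_disp_vert"]
  d60 <- p60$value[p60$parameter == "max_disp_vert"]
  max_speed <- 8 * pi
  expect_lt(abs(d30 - d60), max_speed / 30)  # one-sample motion bound
  v30 <- p30$value[p30$parameter == "max_vel_vert"]
  v60 <- p60$value[p60$parameter == "max_vel_vert"]
  expect_lt(abs(v60 - max_speed), abs(v30 - max_speed))  # second-order convergence
})

test_that("summary units match the reporting convention", {
  sim <- simulate_recording(phantom_config(duration = 1))
  an <- analyze_recording(sim$recording, structures = c("hyoid", "epiglottis"))
  sm <- an$summary
  expect_setequal(unique(sm$units[grepl("disp", sm$parameter)]), "mm")
  expect_setequal(unique(sm$units[grepl("vel_", sm$parameter)]), "mm/s")
  expect_setequal(unique(sm$units[grepl("tilt", sm$parameter)]), "degree")
  expect_setequal(unique(sm$units[grepl("angvel", sm$parameter)]), "degree/s")
})
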