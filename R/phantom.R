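#' Phantom configuration
#'
#' Parameters of the instrumental swallowing phantom: an in-line
#' slider-crank whose slider reciprocates along the anatomical vertical
#' axis (mimicking hyoid excursion) and a belt-pulley pair whose follower
#' rotates an epiglottis-like two-point arm (mimicking epiglottic tilt).
#' The scene also contains a 24 mm calibration coin and static (or
#' rigidly drifting) C2/C4 landmarks, rendered to pixel coordinates with
#' optional Gaussian marking noise.
#'
#' @param crank_radius_r Crank radius (mm); slider stroke is twice this.
#' @param rod_length_l Connecting-rod length (mm), must exceed the radius.
#' @param angular_speed_omega Crank angular speed (rad/s).
#' @param crank_phase_theta0 Crank phase at t = 0 (rad).
#' @param pulley_ratio Driver radius / follower radius; the follower turns
#'   at `pulley_ratio * angular_speed_omega`.
#' @param epiglottis_arm_mm Base-to-tip distance of the rotating arm (mm).
#' @param fps Frames per second.
#' @param duration Recording length (s).
#' @param noise_sigma_px SD of i.i.d. Gaussian pixel noise added to every
#'   marker coordinate (manual-marking jitter); 0 disables noise.
#' @param seed RNG seed recorded in the output metadata; `NULL` leaves the
#'   RNG state alone.
#' @param px_per_mm Rendering scale (pixels per scene mm).
#' @param c2_c4_drift `NULL` for a static scene, a number for a sinusoidal
#'   whole-scene rigid translation of that amplitude (mm), or a list
#'   `list(translation_mm =, rotation_deg =)` adding a sinusoidal rotation.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(crank_radius_r = 10, rod_length_l = 50,
                           angular_speed_omega = pi, crank_phase_theta0 = 0,
                           pulley_ratio = 0.25, epiglottis_arm_mm = 25,
                           fps = 30, duration = 2,
                           noise_sigma_px = 0, seed = NULL,
                           px_per_mm = 4, c2_c4_drift = NULL) {
  if (!(rod_length_l > crank_radius_r) || crank_radius_r <= 0) {
    stop("mechanism locks: need rod_length_l > crank_radius_r > 0")
  }
  stopifnot(fps > 0, duration > 0, noise_sigma_px >= 0, px_per_mm > 0,
            pulley_ratio > 0, epiglottis_arm_mm > 0)
  if (is.numeric(c2_c4_drift)) {
    c2_c4_drift <- list(translation_mm = c2_c4_drift, rotation_deg = 0)
  }
  structure(
    list(crank_radius_r = crank_radius_r, rod_length_l = rod_length_l,
         angular_speed_omega = angular_speed_omega,
         crank_phase_theta0 = crank_phase_theta0,
         pulley_ratio = pulley_ratio, epiglottis_arm_mm = epiglottis_arm_mm,
         fps = fps, duration = duration, noise_sigma_px = noise_sigma_px,
         seed = seed, px_per_mm = px_per_mm, c2_c4_drift = c2_c4_drift),
    class = "phantom_config"
  )
}

#' Slider position of an in-line slider-crank
#'
#' Distance from the crank center to the slider pin along the slide axis:
#' `d(theta) = r cos(theta) + sqrt(l^2 - r^2 sin(theta)^2)`. Extremes are
#' `l + r` at top dead center (theta = 0) and `l - r` at bottom dead center
#' (theta = pi).
#'
#' @param theta Crank angle (rad), vectorized.
#' @param r Crank radius (mm), `r >= 0`.
#' @param l Rod length (mm), `l > r`.
#' @return Slider position (mm).
#' @export
slider_position <- function(theta, r, l) {
  if (l <= r || r < 0) stop("mechanism locks: need l > r >= 0")
  r * cos(theta) + sqrt(l^2 - r^2 * sin(theta)^2)
}

#' Slider velocity of an in-line slider-crank
#'
#' Analytic time derivative of [slider_position()] with
#' `theta(t) = theta0 + omega t`:
#' `d'(t) = -r omega sin(theta) (1 + r cos(theta) / sqrt(l^2 - r^2 sin(theta)^2))`.
#'
#' @param t Time (s), vectorized.
#' @param r Crank radius (mm).
#' @param l Rod length (mm), `l > r`.
#' @param omega Crank angular speed (rad/s).
#' @param theta0 Crank phase at t = 0 (rad).
#' @return Slider velocity (mm/s).
#' @export
slider_velocity <- function(t, r, l, omega, theta0 = 0) {
  if (l <= r || r < 0) stop("mechanism locks: need l > r >= 0")
  th <- theta0 + omega * t
  -r * omega * sin(th) * (1 + r * cos(th) / sqrt(l^2 - r^2 * sin(th)^2))
}

#' Follower angle of a rigid belt-pulley transmission
#'
#' `phi(t) = phi0 + ratio * omega * t`, reported in degrees; the angular
#' velocity is the constant `ratio * omega` (converted to degree/s).
#'
#' @param t Time (s), vectorized.
#' @param ratio Driver/follower radius ratio, > 0.
#' @param omega Driver angular speed (rad/s).
#' @param phi0 Follower angle at t = 0 (rad).
#' @return Follower angle (degrees).
#' @export
pulley_angle <- function(t, ratio, omega, phi0 = 0) {
  if (ratio <= 0) stop("pulley ratio must be positive")
  (phi0 + ratio * omega * t) * 180 / pi
}

# Scene layout (mm, Y up; anatomical x = -X, y = Y when the cervical axis is
# vertical at X = 0).
phantom_scene_layout <- function(cfg) {
  list(
    c4 = c(0, 0), c2 = c(0, 40),
    hyoid_x = -15, hyoid_y_off = 20 - cfg$rod_length_l,
    epi_base = c(-10, 10),
    coin_a = c(25, -15), coin_b = c(25 + 24, -15)
  )
}

#' Simulate a phantom recording
#'
#' Samples the mechanism at the recording's frame times, renders the scene
#' to pixel coordinates (v increasing downward), optionally applies a
#' whole-scene rigid drift and per-marker Gaussian noise, and returns the
#' recording together with the noise-free analytic ground truth.
#'
#' @param cfg A [phantom_config()].
#' @return List with `recording` (a [vfss_recording()]) and `ground_truth`
#'   (tibble: `frame`, `time_s`, `slider_disp_mm`, `slider_vel_mmps`,
#'   `follower_angle_deg`, `follower_angvel_degps`) carrying a `peaks`
#'   attribute with the sampled peak values.
#' @export
simulate_recording <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- floor(cfg$fps * cfg$duration) + 1L
  frames <- 0:(n - 1L)
  t <- frames / cfg$fps
  theta <- cfg$crank_phase_theta0 + cfg$angular_speed_omega * t
  d <- slider_position(theta, cfg$crank_radius_r, cfg$rod_length_l)
  dv <- slider_velocity(t, cfg$crank_radius_r, cfg$rod_length_l,
                        cfg$angular_speed_omega, cfg$crank_phase_theta0)
  phi_deg <- pulley_angle(t, cfg$pulley_ratio, cfg$angular_speed_omega)
  phi_rad <- phi_deg * pi / 180
  angvel <- cfg$pulley_ratio * cfg$angular_speed_omega * 180 / pi

  lay <- phantom_scene_layout(cfg)
  arm <- cfg$epiglottis_arm_mm
  # scene points per frame, columns X, Y (mm)
  pts <- list(
    c2 = cbind(rep(lay$c2[1], n), rep(lay$c2[2], n)),
    c4 = cbind(rep(lay$c4[1], n), rep(lay$c4[2], n)),
    coin_a = cbind(rep(lay$coin_a[1], n), rep(lay$coin_a[2], n)),
    coin_b = cbind(rep(lay$coin_b[1], n), rep(lay$coin_b[2], n)),
    hyoid = cbind(rep(lay$hyoid_x, n), lay$hyoid_y_off + d),
    epiglottis_base = cbind(rep(lay$epi_base[1], n), rep(lay$epi_base[2], n)),
    epiglottis_tip = cbind(lay$epi_base[1] - arm * sin(phi_rad),
                           lay$epi_base[2] + arm * cos(phi_rad))
  )

  if (!is.null(cfg$c2_c4_drift)) {
    ph <- 2 * pi * t / cfg$duration
    tx <- cfg$c2_c4_drift$translation_mm * sin(ph)
    ty <- cfg$c2_c4_drift$translation_mm * cos(ph) - cfg$c2_c4_drift$translation_mm
    al <- cfg$c2_c4_drift$rotation_deg * pi / 180 * sin(ph)
    ca <- cos(al); sa <- sin(al)
    pts <- lapply(pts, function(p) {
      cbind(ca * p[, 1] - sa * p[, 2] + tx, sa * p[, 1] + ca * p[, 2] + ty)
    })
  }

  u0 <- 300; v0 <- 300
  rows <- purrr::imap_dfr(pts, function(p, nm) {
    tibble::tibble(frame = frames, marker = nm,
                   u = u0 + cfg$px_per_mm * p[, 1],
                   v = v0 - cfg$px_per_mm * p[, 2])
  })
  add_noise <- function(df) {
    df$u <- df$u + stats::rnorm(nrow(df), 0, cfg$noise_sigma_px)
    df$v <- df$v + stats::rnorm(nrow(df), 0, cfg$noise_sigma_px)
    df
  }
  if (cfg$noise_sigma_px > 0) {
    rows <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, add_noise(rows))
            else add_noise(rows)
  }

  meta <- c(
    seed = if (is.null(cfg$seed)) "none" else as.character(cfg$seed),
    px_per_mm = fmt_num(cfg$px_per_mm),
    noise_sigma_px = fmt_num(cfg$noise_sigma_px),
    crank_radius_r = fmt_num(cfg$crank_radius_r),
    rod_length_l = fmt_num(cfg$rod_length_l),
    angular_speed_omega = fmt_num(cfg$angular_speed_omega),
    pulley_ratio = fmt_num(cfg$pulley_ratio)
  )
  rec <- vfss_recording(rows, fps = cfg$fps, meta = meta)
  rec <- set_events(rec, tibble::tibble(
    event = c("bolus cross the mandible angle", "bolus tail cross the UES"),
    frame = c(0L, frames[n])
  ))

  gt <- tibble::tibble(
    frame = frames, time_s = t,
    slider_disp_mm = d, slider_vel_mmps = dv,
    follower_angle_deg = phi_deg,
    follower_angvel_degps = rep(angvel, n)
  )
  attr(gt, "peaks") <- tibble::tibble(
    parameter = c("slider_peak_disp_mm", "slider_peak_vel_mmps",
                  "follower_peak_angle_deg", "follower_angvel_degps"),
    value = c(max(abs(d - d[1])), max(abs(dv)),
              max(abs(phi_deg - phi_deg[1])), abs(angvel))
  )
  list(recording = rec, ground_truth = gt)
}
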