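#' Finite-difference velocity
#'
#' Velocity is approximated by the sequence of finite differences of the
#' displacement: a forward difference at the first sample, central
#' differences at interior samples, and a backward difference at the last
#' sample. Exact for affine motion everywhere and for quadratic motion at
#' interior samples; the interior truncation error for smooth motion is
#' bounded by (dt^2 / 6) * max |x'''|.
#'
#' @param x Numeric displacement series on a uniform grid (no NAs; gaps must
#'   be handled upstream by splitting into contiguous runs).
#' @param dt Sampling interval in seconds (1 / fps), > 0.
#' @return Velocity series of the same length.
#' @export
finite_difference_velocity <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  if (anyNA(x)) stop("NA in series: split into contiguous runs before differentiating")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) {
    i <- 2:(n - 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  v
}

# Velocity with interior NAs: computed independently per contiguous non-NA
# run (no interpolation across gaps); runs of length 1 stay NA.
velocity_with_gaps <- function(x, dt) {
  v <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(v)
  runs <- split(which(ok), cumsum(c(1, diff(which(ok)) != 1)))
  for (idx in runs) {
    if (length(idx) >= 2L) v[idx] <- finite_difference_velocity(x[idx], dt)
  }
  v
}

#' Displacement components relative to a reference frame
#'
#' @param traj Data frame with columns `x` and `y` (mm, anatomical frame),
#'   one row per frame; NAs mark frames where the structure was not marked.
#' @param reference Row index of the reference sample; default the first
#'   non-NA row.
#' @return Tibble with columns `vertical`, `horizontal` (signed mm) and
#'   `planar_magnitude` (their Euclidean norm).
#' @export
displacement_components <- function(traj, reference = NULL) {
  x <- traj$x; y <- traj$y
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("all-NA trajectory")
  if (is.null(reference)) reference <- which(ok)[1]
  if (is.na(x[reference]) || is.na(y[reference])) {
    stop("reference frame has no sample for this structure")
  }
  vert <- y - y[reference]
  horiz <- x - x[reference]
  tibble::tibble(
    vertical = vert,
    horizontal = horiz,
    planar_magnitude = sqrt(vert^2 + horiz^2)
  )
}

# Wrap-free accumulation of an angle series given in degrees.
unwrap_deg <- function(a) {
  ok <- which(!is.na(a))
  if (length(ok) < 2L) return(a)
  d <- diff(a[ok])
  d <- d - 360 * round(d / 360)
  a[ok] <- a[ok][1] + c(0, cumsum(d))
  a
}

#' Tilt-angle series of a two-point structure
#'
#' The orientation at each frame is the vector from base to tip.
#' `from_y_axis` gives the unsigned angle between that vector and the +y
#' (C4 toward C2) axis, in \[0, 180\] degrees. `from_initial` gives the
#' signed angle from the orientation at the reference frame (the first
#' non-NA frame), positive for clockwise rotation in the anatomical frame
#' (tilting from upright toward posterior-inferior), in (-180, 180\].
#'
#' @param base,tip Data frames with columns `x`, `y` (mm), same length.
#' @param mode `"from_initial"` or `"from_y_axis"`.
#' @return Numeric angle series in degrees, NA where either point is NA.
#' @export
tilt_angle_series <- function(base, tip, mode = c("from_initial", "from_y_axis")) {
  mode <- match.arg(mode)
  dx <- tip$x - base$x
  dy <- tip$y - base$y
  ok <- !is.na(dx) & !is.na(dy)
  if (any(ok & dx == 0 & dy == 0)) {
    stop("zero-length orientation vector at frame(s) ",
         paste(which(ok & dx == 0 & dy == 0), collapse = ", "))
  }
  out <- rep(NA_real_, length(dx))
  if (mode == "from_y_axis") {
    nrm <- sqrt(dx^2 + dy^2)
    out[ok] <- (180 / pi) * acos(pmin(1, pmax(-1, dy[ok] / nrm[ok])))
  } else {
    if (!any(ok)) stop("all-NA orientation series")
    r <- which(ok)[1]
    ax <- dx[r]; ay <- dy[r]
    # clockwise-positive signed angle from the reference orientation
    out[ok] <- (180 / pi) * atan2(ay * dx[ok] - ax * dy[ok],
                                  ax * dx[ok] + ay * dy[ok])
  }
  out
}

#' Per-frame separation distance between two point series
#'
#' @param a,b Data frames with columns `x`, `y` (mm), same length.
#' @return Numeric distance series (mm), NA where either input is NA.
#' @export
separation_distance_series <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Peak of a series
#'
#' Signed mode returns the sample of greatest absolute value with its sign
#' preserved (suitable for signed displacement/velocity components);
#' unsigned mode returns the maximum (suitable for magnitude series). Ties
#' are broken by the earliest frame; NAs are skipped.
#'
#' @param values Numeric series.
#' @param frames Frame indices aligned with `values`; default 0-based
#'   positions.
#' @param signed If `TRUE`, greatest-magnitude-with-sign; else plain max.
#' @return List with `value` and `frame`.
#' @export
peak_summary <- function(values, frames = seq_along(values) - 1L, signed = TRUE) {
  ok <- which(!is.na(values))
  if (length(ok) == 0L) stop("all-NA series: no peak")
  key <- if (signed) abs(values[ok]) else values[ok]
  i <- ok[which.max(key)]  # which.max takes the earliest tie
  list(value = values[i], frame = frames[i])
}

#' Elapsed time between two recorded events
#'
#' @param events Event tibble (`event`, `frame`).
#' @param start_name,end_name Event names, both present in `events`.
#' @param fps Frames per second.
#' @return Elapsed time in seconds; negative (with a warning) if the events
#'   are in reverse order.
#' @export
transit_time <- function(events, start_name, end_name, fps) {
  stopifnot(fps > 0)
  get_frame <- function(nm) {
    i <- which(events$event == nm)
    if (length(i) == 0L) stop("event not recorded: '", nm, "'")
    events$frame[i]
  }
  dt <- (get_frame(end_name) - get_frame(start_name)) / fps
  if (dt < 0) warning("events are in reverse order; returning negative elapsed time")
  dt
}
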