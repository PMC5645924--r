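#' Pixel-to-millimetre scale factor
#'
#' The scale factor is the ratio between the true length of a reference
#' object (a coin of known diameter, by default 24.0 mm) and its length
#' observed in the image. The per-frame pixel distance between the two coin
#' marks is averaged over the first `n_frames` frames in which both marks
#' are present; the selection is deterministic.
#'
#' @param rec A [vfss_recording()].
#' @param reference_length_mm True length of the calibration object (mm).
#' @param n_frames Number of frames to average (default 3).
#' @return A list of class `scale_factor` with fields `s` (mm per pixel),
#'   `reference_length_mm`, `n_frames`, and `frames_used`.
#' @export
compute_scale_factor <- function(rec, reference_length_mm = 24.0, n_frames = 3L) {
  stopifnot(inherits(rec, "vfss_recording"))
  if (!is.finite(reference_length_mm) || reference_length_mm <= 0) {
    stop("reference_length_mm must be positive")
  }
  if (n_frames < 1L) stop("n_frames must be >= 1")
  coin <- rec$frames[rec$frames$marker %in% c("coin_a", "coin_b"), ]
  wide <- tidyr::pivot_wider(
    coin, id_cols = "frame", names_from = "marker", values_from = c("u", "v")
  )
  need <- c("u_coin_a", "v_coin_a", "u_coin_b", "v_coin_b")
  if (!all(need %in% names(wide))) wide <- wide[0, ]
  wide <- wide[stats::complete.cases(wide[, need, drop = FALSE]), , drop = FALSE]
  if (nrow(wide) < n_frames) {
    stop("calibration needs ", n_frames, " frame(s) with both coin markers; found ",
         nrow(wide))
  }
  wide <- wide[order(wide$frame), ][seq_len(n_frames), ]
  d <- sqrt((wide$u_coin_a - wide$u_coin_b)^2 + (wide$v_coin_a - wide$v_coin_b)^2)
  if (any(d == 0)) {
    stop("degenerate calibration: zero coin separation in frame(s) ",
         paste(wide$frame[d == 0], collapse = ", "))
  }
  structure(
    list(
      s = reference_length_mm / mean(d),
      reference_length_mm = reference_length_mm,
      n_frames = as.integer(n_frames),
      frames_used = wide$frame
    ),
    class = "scale_factor"
  )
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor> s = %.6g mm/px (%g mm reference over %d frame(s))\n",
              x$s, x$reference_length_mm, x$n_frames))
  invisible(x)
}

#' Pose of the anatomical frame in image coordinates
#'
#' The anatomical frame has its origin at the anteroinferior vertex of C4;
#' its vertical axis points toward the anteroinferior vertex of C2; its
#' horizontal axis points to the image left (anteriorly in a standard
#' lateral view). In v-flipped image coordinates (u, -v) the rotation's
#' columns are the frame's unit axes.
#'
#' @param c2,c4 Numeric length-2 pixel points `c(u, v)`.
#' @return List of class `frame_pose` with `R` (2x2 proper rotation) and
#'   `p` (the C4 pixel point).
#' @export
frame_pose <- function(c2, c4) {
  c2 <- as.numeric(c2); c4 <- as.numeric(c4)
  stopifnot(length(c2) == 2L, length(c4) == 2L)
  d <- c(c2[1] - c4[1], -(c2[2] - c4[2]))  # v-flipped C4 -> C2
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("degenerate cervical axis: c2 and c4 coincide")
  e_y <- d / nrm
  e_x <- c(e_y[2], -e_y[1])  # 90 deg clockwise from e_y (to the image right)
  structure(list(R = cbind(e_x, e_y, deparse.level = 0), p = c4),
            class = "frame_pose")
}

#' Transform a pixel point into the anatomical frame
#'
#' Applies the v-flip, the rigid change of frame, the x-axis negation
#' (the anatomical horizontal axis points image-left, opposite to
#' conventional frames) and the scale. The C4 origin maps to (0, 0) and C2
#' to (0, s * |C2 - C4|).
#'
#' @param q Numeric length-2 pixel point `c(u, v)`.
#' @param pose A [frame_pose()].
#' @param s Scale factor in mm per pixel (a number or a `scale_factor`).
#' @return Numeric `c(x, y)` in mm.
#' @export
to_anatomical <- function(q, pose, s = 1) {
  if (inherits(s, "scale_factor")) s <- s$s
  q <- as.numeric(q)
  qf <- c(q[1], -q[2])
  pf <- c(pose$p[1], -pose$p[2])
  w <- drop(crossprod(pose$R, qf - pf))
  c(x = -s * w[1], y = s * w[2])
}

#' Transform a recording into per-frame anatomical coordinates
#'
#' The anatomical frame is not fixed in space: a fresh pose is computed from
#' each frame's C2/C4 marks and applied to every marker present in that
#' frame. Frames that contain analysis markers but lack C2 or C4 are an
#' error.
#'
#' @param rec A [vfss_recording()].
#' @param s Scale factor (mm/px number or `scale_factor`).
#' @return Tibble with columns `frame`, `time_s`, `marker`, `x_mm`, `y_mm`.
#' @export
transform_recording <- function(rec, s) {
  stopifnot(inherits(rec, "vfss_recording"))
  if (inherits(s, "scale_factor")) s <- s$s
  f <- rec$frames
  by_frame <- split(f, f$frame)
  missing_cv <- vapply(by_frame, function(ff) {
    others <- setdiff(ff$marker, c("c2", "c4"))
    length(others) > 0L && !all(c("c2", "c4") %in% ff$marker)
  }, logical(1))
  if (any(missing_cv)) {
    stop("frame(s) with analysis markers but missing c2 or c4: ",
         paste(names(by_frame)[missing_cv], collapse = ", "))
  }
  keep <- vapply(by_frame, function(ff) all(c("c2", "c4") %in% ff$marker), logical(1))
  out <- purrr::map_dfr(by_frame[keep], function(ff) {
    c2 <- unlist(ff[ff$marker == "c2", c("u", "v")], use.names = FALSE)
    c4 <- unlist(ff[ff$marker == "c4", c("u", "v")], use.names = FALSE)
    pose <- frame_pose(c2, c4)
    xy <- t(vapply(seq_len(nrow(ff)),
                   function(i) to_anatomical(c(ff$u[i], ff$v[i]), pose, s),
                   numeric(2)))
    tibble::tibble(frame = ff$frame, marker = ff$marker,
                   x_mm = xy[, 1], y_mm = xy[, 2])
  })
  out$time_s <- out$frame / rec$fps
  dplyr::arrange(out[, c("frame", "time_s", "marker", "x_mm", "y_mm")],
                 .data$frame, match(.data$marker, marker_catalogue()))
}
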