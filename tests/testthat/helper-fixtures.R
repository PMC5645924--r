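# Build a recording from a named list of per-marker u/v matrices
# (one row per frame). Static C2/C4 and coin are added unless supplied.
make_recording <- function(markers, fps = 30, frames = NULL,
                           add_frame = TRUE) {
  if (add_frame) {
    n <- nrow(markers[[1]])
    defaults <- list(
      c2 = cbind(rep(100, n), rep(180, n)),
      c4 = cbind(rep(100, n), rep(200, n)),
      coin_a = cbind(rep(10, n), rep(10, n)),
      coin_b = cbind(rep(34, n), rep(10, n))
    )
    for (nm in names(defaults)) {
      if (!nm %in% names(markers)) markers[[nm]] <- defaults[[nm]]
    }
  }
  rows <- dplyr::bind_rows(lapply(names(markers), function(nm) {
    m <- markers[[nm]]
    fr <- if (is.null(frames)) seq_len(nrow(m)) - 1L else frames
    keep <- stats::complete.cases(m)
    tibble::tibble(frame = fr[keep], marker = nm,
                   u = m[keep, 1], v = m[keep, 2])
  }))
  vfss_recording(rows, fps = fps)
}

# Apply one rigid motion (rotation alpha + translation b), expressed in
# v-flipped image coordinates, to pixel points given as c(u, v).
rigid_in_flipped <- function(uv, alpha, b) {
  q <- c(uv[1], -uv[2])
  R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2)
  w <- drop(R %*% q) + b
  c(w[1], -w[2])
}
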