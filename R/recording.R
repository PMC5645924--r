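#' Marker catalogue
#'
#' The closed, case-sensitive set of landmark tokens understood by the
#' package. Paired tokens represent two-point structures: the calibration
#' coin (`coin_a`/`coin_b` across its diameter), the epiglottis
#' (`epiglottis_base`/`epiglottis_tip`) and the upper esophageal sphincter
#' (`ues_anterior`/`ues_posterior`).
#'
#' @return Character vector of valid marker names.
#' @export
marker_catalogue <- function() {
  c(
    "coin_a", "coin_b", "c2", "c4",
    "hyoid", "mandible", "maxilla", "larynx", "arytenoid",
    "epiglottis_base", "epiglottis_tip",
    "ues_anterior", "ues_posterior",
    "bolus_head"
  )
}

#' Default event-name catalogue
#'
#' Twenty editable event names. The first two are the pharyngeal-transit
#' anchors (bolus crossing the mandible angle, bolus tail clearing the UES);
#' the remaining eighteen are placeholders meant to be replaced in a config.
#'
#' @param n Catalogue size, default 20.
#' @return Character vector of event names.
#' @export
default_event_catalogue <- function(n = 20L) {
  stopifnot(n >= 2L)
  base <- c("bolus cross the mandible angle", "bolus tail cross the UES")
  if (n > 2L) base <- c(base, sprintf("event_%02d", 3:n))
  base[seq_len(n)]
}

#' Construct a VFSS recording
#'
#' The unit of analysis: a frame-indexed table of marker pixel positions,
#' a frame rate, an event log and free-form metadata. Frame indices are
#' 0-based. Markers may be absent in any frame (structure invisible);
#' absence is represented by the row simply not existing.
#'
#' @param frames Data frame with columns `frame` (non-negative integer),
#'   `marker` (token from [marker_catalogue()]), `u`, `v` (pixel coordinates,
#'   `u` increasing rightward, `v` downward; fractional values allowed).
#' @param fps Frames per second, > 0.
#' @param events Optional data frame with columns `event`, `frame`
#'   (see [read_events()]).
#' @param meta Named character vector of free-form metadata.
#' @return An object of class `vfss_recording`.
#' @export
vfss_recording <- function(frames, fps, events = NULL, meta = character()) {
  frames <- tibble::as_tibble(frames)
  stopifnot(all(c("frame", "marker", "u", "v") %in% names(frames)))
  if (nrow(frames) == 0L) stop("no frames: recording has an empty data section")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number")
  }
  bad <- setdiff(unique(frames$marker), marker_catalogue())
  if (length(bad) > 0L) {
    stop("unknown marker token(s): ", paste(bad, collapse = ", "))
  }
  if (any(frames$frame < 0) || any(frames$frame != floor(frames$frame))) {
    stop("frame indices must be non-negative integers")
  }
  if (!all(is.finite(frames$u)) || !all(is.finite(frames$v))) {
    stop("pixel coordinates must be finite")
  }
  dup <- duplicated(frames[, c("frame", "marker")])
  if (any(dup)) {
    d <- frames[dup, ]
    stop(
      "duplicate (frame, marker) pair(s): ",
      paste(sprintf("(%d, %s)", d$frame, d$marker), collapse = ", ")
    )
  }
  frames$frame <- as.integer(frames$frame)
  frames <- dplyr::arrange(frames, .data$frame, match(.data$marker, marker_catalogue()))
  rec <- structure(
    list(
      frames = frames[, c("frame", "marker", "u", "v")],
      fps = as.numeric(fps),
      events = tibble::tibble(event = character(), frame = integer()),
      meta = meta
    ),
    class = "vfss_recording"
  )
  if (!is.null(events)) rec <- set_events(rec, events)
  rec
}

#' @export
print.vfss_recording <- function(x, ...) {
  rng <- range(x$frames$frame)
  cat(sprintf(
    "<vfss_recording> %d annotated frame(s) [%d..%d] @ %g fps, %d marker(s), %d event(s)\n",
    dplyr::n_distinct(x$frames$frame), rng[1], rng[2], x$fps,
    dplyr::n_distinct(x$frames$marker), nrow(x$events)
  ))
  invisible(x)
}

#' Attach an event log to a recording
#'
#' @param rec A `vfss_recording`.
#' @param events Data frame with columns `event`, `frame`.
#' @param catalogue Permitted event names.
#' @return The recording with validated events attached.
#' @export
set_events <- function(rec, events, catalogue = default_event_catalogue()) {
  stopifnot(inherits(rec, "vfss_recording"))
  events <- tibble::as_tibble(events)
  stopifnot(all(c("event", "frame") %in% names(events)))
  bad <- setdiff(events$event, catalogue)
  if (length(bad) > 0L) {
    stop(
      "unknown event name(s): ", paste(bad, collapse = "; "),
      "\ncatalogue: ", paste(catalogue, collapse = "; ")
    )
  }
  if (anyDuplicated(events$event)) {
    stop("duplicate event name(s): ",
         paste(unique(events$event[duplicated(events$event)]), collapse = "; "))
  }
  rng <- range(rec$frames$frame)
  out <- events$frame < rng[1] | events$frame > rng[2]
  if (any(out)) {
    stop("event frame(s) outside the recording's frame range [",
         rng[1], ", ", rng[2], "]: ",
         paste(events$event[out], collapse = "; "))
  }
  rec$events <- tibble::tibble(event = events$event, frame = as.integer(events$frame))
  rec
}

# Exact decimal text for a double: round-trips through as.numeric().
fmt_num <- function(x) sprintf("%.17g", x)

#' Read a marker table
#'
#' Parses the package's delimited marker format: UTF-8, comma-separated,
#' header `frame,marker,u,v`, `#`-prefixed comment lines, and an optional
#' `# fps=<float>` comment. Rows may appear in any order; frames need not be
#' contiguous. An `fps` argument overrides the header comment.
#'
#' @param path Path to the marker CSV.
#' @param fps Frames per second; if `NULL`, taken from a `# fps=` comment.
#' @return A [vfss_recording()].
#' @export
read_recording <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  header_fps <- NA_real_
  meta <- character()
  is_comment <- grepl("^\\s*#", lines)
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", cm))[[1]]
    if (length(m) == 3L) {
      if (m[2] == "fps") header_fps <- as.numeric(m[3]) else meta[m[2]] <- m[3]
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) stop("no frames: file has no data rows (", path, ")")
  hdr_line <- body_idx[1]
  if (trimws(lines[hdr_line]) != "frame,marker,u,v") {
    stop("line ", hdr_line, ": header must be 'frame,marker,u,v', got '",
         trimws(lines[hdr_line]), "'")
  }
  data_idx <- body_idx[-1]
  if (length(data_idx) == 0L) stop("no frames: file has a header but no data rows")
  parts <- strsplit(trimws(lines[data_idx]), ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4L)) {
    i <- data_idx[which(nfield != 4L)[1]]
    stop("line ", i, ": malformed row (expected 4 comma-separated fields): '",
         trimws(lines[i]), "'")
  }
  mat <- do.call(rbind, parts)
  frame <- suppressWarnings(as.numeric(mat[, 1]))
  u <- suppressWarnings(as.numeric(mat[, 3]))
  v <- suppressWarnings(as.numeric(mat[, 4]))
  bad <- !is.finite(frame) | !is.finite(u) | !is.finite(v)
  if (any(bad)) {
    i <- data_idx[which(bad)[1]]
    stop("line ", i, ": non-numeric frame or coordinate: '", trimws(lines[i]), "'")
  }
  marker <- mat[, 2]
  unk <- !marker %in% marker_catalogue()
  if (any(unk)) {
    i <- data_idx[which(unk)[1]]
    stop("line ", i, ": unknown marker token '", marker[which(unk)[1]], "'")
  }
  fps_eff <- if (!is.null(fps)) fps else header_fps
  if (is.na(fps_eff)) stop("fps not given and no '# fps=' header comment present")
  vfss_recording(
    tibble::tibble(frame = frame, marker = marker, u = u, v = v),
    fps = fps_eff, meta = meta
  )
}

#' Write a marker table
#'
#' Inverse of [read_recording()]: coordinates round-trip at full double
#' precision, and absent markers are simply omitted rows.
#'
#' @param rec A `vfss_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vfss_recording"))
  f <- rec$frames
  lines <- c(
    paste0("# fps=", fmt_num(rec$fps)),
    if (length(rec$meta) > 0L) paste0("# ", names(rec$meta), "=", rec$meta),
    "frame,marker,u,v",
    sprintf("%d,%s,%s,%s", f$frame, f$marker, fmt_num(f$u), fmt_num(f$v))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an event log
#'
#' Two-column CSV `event,frame`; names are validated against the catalogue.
#' An empty file (or header only) yields an empty log.
#'
#' @param path Path to the event CSV.
#' @param catalogue Permitted event names; default [default_event_catalogue()].
#' @return Tibble with columns `event`, `frame`.
#' @export
read_events <- function(path, catalogue = default_event_catalogue()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0L && trimws(lines[1]) == "event,frame") lines <- lines[-1]
  if (length(lines) == 0L) return(tibble::tibble(event = character(), frame = integer()))
  parts <- strsplit(lines, ",", fixed = TRUE)
  ev <- vapply(parts, function(p) paste(p[-length(p)], collapse = ","), "")
  fr <- suppressWarnings(as.numeric(vapply(parts, function(p) p[length(p)], "")))
  if (any(!is.finite(fr))) stop("non-numeric frame index in event file")
  bad <- setdiff(ev, catalogue)
  if (length(bad) > 0L) {
    stop("unknown event name(s): ", paste(bad, collapse = "; "),
         "\ncatalogue: ", paste(catalogue, collapse = "; "))
  }
  if (anyDuplicated(ev)) {
    stop("duplicate event name(s): ", paste(unique(ev[duplicated(ev)]), collapse = "; "))
  }
  tibble::tibble(event = ev, frame = as.integer(fr))
}

#' Write an event log
#'
#' @param events Tibble with columns `event`, `frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("event", "frame") %in% names(events)))
  writeLines(
    c("event,frame", sprintf("%s,%d", events$event, as.integer(events$frame))),
    path, useBytes = TRUE
  )
  invisible(path)
}
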