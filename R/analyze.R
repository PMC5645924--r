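#' Analysis configuration
#'
#' @param smoothing Default [smoothing_spec()] applied to every component
#'   series before differentiation (moving average, span 5, by default).
#' @param structure_smoothing Named list of per-structure [smoothing_spec()]
#'   overrides, e.g. `list(hyoid = smoothing_spec("savitzky_golay", 7, 2))`.
#' @param motion_start_event Optional event name; if recorded, its frame is
#'   used as the displacement reference instead of the first marked frame.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(smoothing = smoothing_spec(),
                            structure_smoothing = list(),
                            motion_start_event = NULL) {
  stopifnot(inherits(smoothing, "smoothing_spec"))
  structure(list(smoothing = smoothing,
                 structure_smoothing = structure_smoothing,
                 motion_start_event = motion_start_event),
            class = "analysis_config")
}

# Structure registry: which markers feed which kinematic model.
structure_registry <- function() {
  list(
    hyoid      = list(type = "linear",   markers = "hyoid"),
    mandible   = list(type = "linear",   markers = "mandible"),
    maxilla    = list(type = "linear",   markers = "maxilla"),
    larynx     = list(type = "linear",   markers = "larynx"),
    arytenoid  = list(type = "linear",   markers = "arytenoid"),
    epiglottis = list(type = "angular",  markers = c("epiglottis_base", "epiglottis_tip")),
    ues        = list(type = "distance", markers = c("ues_anterior", "ues_posterior")),
    bolus      = list(type = "speed",    markers = "bolus_head")
  )
}

# Align one marker's anatomical positions onto the full frame grid (NA at
# unannotated frames).
marker_on_grid <- function(anat, marker, grid) {
  m <- anat[anat$marker == marker, ]
  i <- match(grid, m$frame)
  tibble::tibble(x = m$x_mm[i], y = m$y_mm[i])
}

series_row <- function(structure, parameter, units, grid, fps, values) {
  tibble::tibble(structure = structure, parameter = parameter,
                 frame = grid, time_s = grid / fps,
                 value = values, units = units)
}

peak_row <- function(structure, parameter, units, values, grid, signed) {
  pk <- peak_summary(values, frames = grid, signed = signed)
  tibble::tibble(structure = structure, parameter = parameter,
                 value = pk$value, units = units, frame = pk$frame)
}

#' Analyze a recording
#'
#' Full per-structure pipeline: pixel marks are transformed into the moving
#' C2-C4 anatomical frame, component series are smoothed, then
#' displacement / tilt-angle / opening-distance series and their
#' finite-difference velocities are computed, and the peak of each
#' parameter is extracted. Hyoid, larynx, arytenoid (and mandible/maxilla
#' if marked) get vertical/horizontal/two-dimensional linear kinematics;
#' the epiglottis gets angular kinematics only; the UES its opening
#' distance; the bolus head its planar speed.
#'
#' @param rec A [vfss_recording()].
#' @param s Scale factor (`scale_factor` or mm/px number); if `NULL`,
#'   computed from the coin markers with defaults.
#' @param config An [analysis_config()].
#' @param structures Structure names to analyze (see the registry in the
#'   package vignette); default all whose markers are present.
#' @return Object of class `swallow_analysis`: a list with tibbles `series`
#'   (long: structure, parameter, frame, time_s, value, units), `summary`
#'   (peak values with frames), `superimposed` (wide vertical-displacement
#'   table), `animation` (smoothed anatomical marker positions), plus `fps`
#'   and the effective `config`.
#' @export
analyze_recording <- function(rec, s = NULL, config = analysis_config(),
                              structures = NULL) {
  stopifnot(inherits(rec, "vfss_recording"))
  if (is.null(s)) s <- compute_scale_factor(rec)
  reg <- structure_registry()
  present <- unique(rec$frames$marker)
  avail <- names(reg)[vapply(reg, function(r) all(r$markers %in% present), logical(1))]
  if (is.null(structures)) {
    structures <- avail
  } else {
    missing <- setdiff(structures, avail)
    if (length(missing) > 0L) {
      stop("structure(s) requested but required markers absent: ",
           paste(missing, collapse = ", "))
    }
  }
  if (length(structures) == 0L) stop("no analyzable structures in the recording")

  anat <- transform_recording(rec, s)
  grid <- seq(min(anat$frame), max(anat$frame))
  fps <- rec$fps
  dt <- 1 / fps

  ref_row <- NULL
  if (!is.null(config$motion_start_event) &&
      config$motion_start_event %in% rec$events$event) {
    ev_frame <- rec$events$frame[rec$events$event == config$motion_start_event]
    ref_row <- match(ev_frame, grid)
  }
  spec_for <- function(st) {
    sp <- config$structure_smoothing[[st]]
    if (is.null(sp)) config$smoothing else sp
  }
  smooth_xy <- function(pt, sp) {
    tibble::tibble(x = smooth_series(pt$x, sp), y = smooth_series(pt$y, sp))
  }

  series <- list(); summary <- list(); vertical <- list(); anim <- list()

  for (st in structures) {
    info <- reg[[st]]
    sp <- spec_for(st)
    tryCatch({
      if (info$type %in% c("linear", "speed")) {
        pt <- smooth_xy(marker_on_grid(anat, info$markers, grid), sp)
        disp <- displacement_components(pt, reference = ref_row)
        vv <- velocity_with_gaps(disp$vertical, dt)
        vh <- velocity_with_gaps(disp$horizontal, dt)
        v2 <- sqrt(vv^2 + vh^2)
        series[[paste0(st, "_d")]] <- dplyr::bind_rows(
          series_row(st, "disp_vert", "mm", grid, fps, disp$vertical),
          series_row(st, "disp_horiz", "mm", grid, fps, disp$horizontal),
          series_row(st, "disp_2d", "mm", grid, fps, disp$planar_magnitude),
          series_row(st, "vel_vert", "mm/s", grid, fps, vv),
          series_row(st, "vel_horiz", "mm/s", grid, fps, vh),
          series_row(st, "vel_2d", "mm/s", grid, fps, v2)
        )
        vertical[[st]] <- disp$vertical
        anim[[st]] <- tibble::tibble(frame = grid, time_s = grid / fps,
                                     marker = info$markers, x_mm = pt$x, y_mm = pt$y)
        if (info$type == "linear") {
          summary[[st]] <- dplyr::bind_rows(
            peak_row(st, "max_disp_vert", "mm", disp$vertical, grid, TRUE),
            peak_row(st, "max_disp_horiz", "mm", disp$horizontal, grid, TRUE),
            peak_row(st, "max_disp_2d", "mm", disp$planar_magnitude, grid, FALSE),
            peak_row(st, "max_vel_vert", "mm/s", vv, grid, TRUE),
            peak_row(st, "max_vel_horiz", "mm/s", vh, grid, TRUE),
            peak_row(st, "max_vel_2d", "mm/s", v2, grid, FALSE)
          )
        } else {
          summary[[st]] <- peak_row(st, "max_vel_2d", "mm/s", v2, grid, FALSE)
        }
      } else if (info$type == "angular") {
        base <- marker_on_grid(anat, info$markers[1], grid)
        tip <- marker_on_grid(anat, info$markers[2], grid)
        a_init <- smooth_series(tilt_angle_series(base, tip, "from_initial"), sp)
        a_yax <- smooth_series(tilt_angle_series(base, tip, "from_y_axis"), sp)
        av <- velocity_with_gaps(unwrap_deg(a_init), dt)
        series[[paste0(st, "_a")]] <- dplyr::bind_rows(
          series_row(st, "tilt_from_initial", "degree", grid, fps, a_init),
          series_row(st, "tilt_from_y_axis", "degree", grid, fps, a_yax),
          series_row(st, "angvel", "degree/s", grid, fps, av)
        )
        summary[[st]] <- dplyr::bind_rows(
          peak_row(st, "max_tilt_from_initial", "degree", a_init, grid, TRUE),
          peak_row(st, "max_tilt_from_y_axis", "degree", a_yax, grid, FALSE),
          peak_row(st, "max_angvel", "degree/s", av, grid, TRUE)
        )
        anim[[st]] <- dplyr::bind_rows(
          tibble::tibble(frame = grid, time_s = grid / fps,
                         marker = info$markers[1], x_mm = base$x, y_mm = base$y),
          tibble::tibble(frame = grid, time_s = grid / fps,
                         marker = info$markers[2], x_mm = tip$x, y_mm = tip$y)
        )
      } else if (info$type == "distance") {
        a <- smooth_xy(marker_on_grid(anat, info$markers[1], grid), sp)
        b <- smooth_xy(marker_on_grid(anat, info$markers[2], grid), sp)
        d <- separation_distance_series(a, b)
        series[[paste0(st, "_s")]] <- series_row(st, "opening_dist", "mm", grid, fps, d)
        summary[[st]] <- peak_row(st, "max_opening_dist", "mm", d, grid, FALSE)
        anim[[st]] <- dplyr::bind_rows(
          tibble::tibble(frame = grid, time_s = grid / fps,
                         marker = info$markers[1], x_mm = a$x, y_mm = a$y),
          tibble::tibble(frame = grid, time_s = grid / fps,
                         marker = info$markers[2], x_mm = b$x, y_mm = b$y)
        )
      }
    }, error = function(e) {
      stop("structure '", st, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  superimposed <- tibble::tibble(frame = grid, time_s = grid / fps)
  for (st in names(vertical)) superimposed[[paste0(st, "_disp_vert_mm")]] <- vertical[[st]]

  structure(
    list(
      series = dplyr::bind_rows(series),
      summary = dplyr::bind_rows(summary),
      superimposed = superimposed,
      animation = dplyr::bind_rows(anim),
      fps = fps,
      scale = if (inherits(s, "scale_factor")) s$s else s,
      config = config,
      structures = structures
    ),
    class = "swallow_analysis"
  )
}

#' @export
print.swallow_analysis <- function(x, ...) {
  cat(sprintf("<swallow_analysis> %d structure(s): %s; %d frames @ %g fps\n",
              length(x$structures), paste(x$structures, collapse = ", "),
              dplyr::n_distinct(x$series$frame), x$fps))
  print(x$summary)
  invisible(x)
}

unit_suffix <- function(u) {
  c("mm" = "mm", "mm/s" = "mmps", "degree" = "deg", "degree/s" = "degps")[[u]]
}

#' Export an analysis as a plain-text table
#'
#' Tab-separated table with one row per frame (`time_s`, `frame`, then one
#' unit-annotated column per structure parameter, e.g.
#' `hyoid_disp_vert_mm`, `epiglottis_angvel_degps`), followed by a trailing
#' summary block of peak values. Missing samples are rendered as `NA`. The
#' effective configuration is echoed in `#` header comments.
#'
#' @param analysis A `swallow_analysis`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_analysis_table <- function(analysis, path) {
  stopifnot(inherits(analysis, "swallow_analysis"))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(
      analysis$series,
      col = paste0(.data$structure, "_", .data$parameter, "_",
                   vapply(.data$units, unit_suffix, ""))
    ),
    id_cols = c("frame", "time_s"), names_from = "col", values_from = "value"
  )
  num <- function(x) ifelse(is.na(x), "NA", fmt_num(x))
  hdr <- c(
    paste0("# deglukin analysis export"),
    paste0("# fps=", fmt_num(analysis$fps)),
    paste0("# scale_mm_per_px=", fmt_num(analysis$scale)),
    paste0("# smoothing.method=", analysis$config$smoothing$method),
    paste0("# smoothing.span=", analysis$config$smoothing$span),
    paste0("# smoothing.degree=", analysis$config$smoothing$degree),
    paste0("# structures=", paste(analysis$structures, collapse = ","))
  )
  data_lines <- c(
    paste(c("time_s", "frame", names(wide)[-(1:2)]), collapse = "\t"),
    vapply(seq_len(nrow(wide)), function(i) {
      paste(c(fmt_num(wide$time_s[i]), wide$frame[i],
              vapply(as.numeric(wide[i, -(1:2)]), num, "")), collapse = "\t")
    }, "")
  )
  sm <- analysis$summary
  sum_lines <- c(
    "# summary",
    paste(c("parameter", "value", "units", "frame"), collapse = "\t"),
    sprintf("%s_%s\t%s\t%s\t%d", sm$structure, sm$parameter,
            vapply(sm$value, fmt_num, ""), sm$units, sm$frame)
  )
  writeLines(c(hdr, data_lines, "", sum_lines), path, useBytes = TRUE)
  invisible(path)
}

#' Re-read an exported analysis table
#'
#' @param path Path written by [export_analysis_table()].
#' @return List with tibbles `data` (per-frame) and `summary` (peaks).
#' @export
read_analysis_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sum_at <- which(lines == "# summary")
  if (length(sum_at) != 1L) stop("not an analysis export: missing summary block")
  body <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  split_at <- which(grepl("^parameter\t", body))
  data_lines <- body[seq_len(split_at - 1L)]
  sum_lines <- body[(split_at):length(body)]
  parse_tsv <- function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)
    hdr <- parts[[1]]
    out <- as.data.frame(do.call(rbind, parts[-1]), stringsAsFactors = FALSE)
    names(out) <- hdr
    tibble::as_tibble(out)
  }
  d <- parse_tsv(data_lines)
  d[] <- lapply(d, function(col) suppressWarnings(as.numeric(col)))
  s <- parse_tsv(sum_lines)
  s$value <- as.numeric(s$value)
  s$frame <- as.integer(s$frame)
  list(data = d, summary = s)
}
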