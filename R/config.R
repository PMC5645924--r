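#' Default run configuration
#'
#' Flat dotted-key configuration shared by the command-line subcommands.
#' Defaults: a 24.0 mm calibration reference measured over 3 frames, and
#' moving-average smoothing with span 5.
#'
#' @return Named list of default configuration values.
#' @export
default_config <- function() {
  list(
    `calibration.reference_length_mm` = 24.0,
    `calibration.n_frames` = 3,
    `smoothing.method` = "moving_average",
    `smoothing.span` = 5,
    `smoothing.degree` = 2,
    `events.catalogue_size` = 20,
    `events.motion_start` = ""
  )
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; unknown keys are
#' kept (per-structure smoothing overrides use keys like
#' `smoothing.hyoid.method`). Values that parse as numbers become numeric.
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @return Named list: defaults overridden by the file's entries.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: '", ln, "'")
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    cfg[[m[2]]] <- if (!is.na(num)) num else val
  }
  cfg
}

# Build an analysis_config from a flat config list.
config_to_analysis <- function(cfg) {
  base <- smoothing_spec(cfg$`smoothing.method`,
                         span = cfg$`smoothing.span`,
                         degree = cfg$`smoothing.degree`)
  overrides <- list()
  keys <- grep("^smoothing\\.[a-z_]+\\.method$", names(cfg), value = TRUE)
  for (k in keys) {
    st <- sub("^smoothing\\.([a-z_]+)\\.method$", "\\1", k)
    sp <- cfg[[paste0("smoothing.", st, ".span")]]
    dg <- cfg[[paste0("smoothing.", st, ".degree")]]
    overrides[[st]] <- smoothing_spec(
      cfg[[k]],
      span = if (is.null(sp)) cfg$`smoothing.span` else sp,
      degree = if (is.null(dg)) cfg$`smoothing.degree` else dg
    )
  }
  mse <- cfg$`events.motion_start`
  analysis_config(
    smoothing = base,
    structure_smoothing = overrides,
    motion_start_event = if (is.null(mse) || identical(mse, "")) NULL else mse
  )
}
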