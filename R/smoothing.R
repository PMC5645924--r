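#' Smoothing specification
#'
#' A validated choice of trajectory-smoothing method. Seven methods are
#' offered besides `none`: moving average (default, span 5), global
#' polynomial fit, Savitzky-Golay, and the locally weighted regression
#' family (LOWESS = local degree 1, LOESS = local degree 2, each with a
#' robust bisquare variant).
#'
#' @param method One of `"none"`, `"moving_average"`, `"polynomial"`,
#'   `"savitzky_golay"`, `"lowess"`, `"loess"`, `"robust_lowess"`,
#'   `"robust_loess"`.
#' @param span Window length. For `moving_average`/`savitzky_golay`: an odd
#'   integer >= 3. For the lowess family: a fraction of the series length in
#'   (0, 1] or an absolute neighbor count >= 3. Ignored by `none` and
#'   `polynomial`.
#' @param degree Polynomial degree (`polynomial` and `savitzky_golay`).
#' @return List of class `smoothing_spec`.
#' @export
smoothing_spec <- function(method = "moving_average", span = 5L, degree = 2L) {
  methods <- c("none", "moving_average", "polynomial", "savitzky_golay",
               "lowess", "loess", "robust_lowess", "robust_loess")
  method <- match.arg(method, methods)
  if (method %in% c("moving_average", "savitzky_golay")) {
    if (!is.finite(span) || span < 3 || span %% 2 == 0) {
      stop("span must be an odd integer >= 3 for ", method, " (got ", span, ")")
    }
    span <- as.integer(span)
  }
  if (method == "savitzky_golay") {
    if (!is.finite(degree) || degree < 0 || degree >= span) {
      stop("savitzky_golay degree must satisfy 0 <= degree < span")
    }
    degree <- as.integer(degree)
  }
  if (method == "polynomial" && (!is.finite(degree) || degree < 0)) {
    stop("polynomial degree must be >= 0")
  }
  if (method %in% c("lowess", "loess", "robust_lowess", "robust_loess")) {
    if (!is.finite(span) || span <= 0) stop("lowess-family span must be positive")
  }
  structure(list(method = method, span = span, degree = degree),
            class = "smoothing_spec")
}

#' Smooth a scalar series
#'
#' Dispatches on the spec's method. NAs are excluded from the fit and
#' re-inserted as NA at the same positions in the output; the non-NA
#' samples keep their original index positions as the abscissa, so values
#' separated by a gap are treated as distant, not adjacent. `method =
#' "none"` is the identity. Output length always equals input length.
#'
#' @param y Numeric series, possibly with NAs.
#' @param spec A [smoothing_spec()].
#' @return Numeric series of the same length.
#' @export
smooth_series <- function(y, spec = smoothing_spec()) {
  if (!inherits(spec, "smoothing_spec")) stop("spec must be a smoothing_spec")
  if (spec$method == "none") return(y)
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop("series must have at least 2 non-NA samples")
  t_ok <- which(ok)
  y_ok <- y[ok]
  sm <- switch(spec$method,
    moving_average = moving_average(y_ok, spec$span),
    savitzky_golay = savitzky_golay(y_ok, spec$span, spec$degree),
    polynomial     = polynomial_fit(y_ok, spec$degree, t = t_ok),
    lowess         = lowess_family(y_ok, spec$span, "lowess", t = t_ok),
    loess          = lowess_family(y_ok, spec$span, "loess", t = t_ok),
    robust_lowess  = lowess_family(y_ok, spec$span, "robust_lowess", t = t_ok),
    robust_loess   = lowess_family(y_ok, spec$span, "robust_loess", t = t_ok)
  )
  out <- rep(NA_real_, length(y))
  out[ok] <- sm
  out
}

#' Centered moving average with shrinking edge windows
#'
#' Interior samples are replaced by the mean over `span` neighbors; near the
#' edges the window shrinks symmetrically to the largest odd width that
#' fits, so the first and last samples are returned unchanged.
#'
#' @param y Numeric series (no NAs).
#' @param span Odd integer window length >= 3.
#' @return Smoothed series, same length.
#' @export
moving_average <- function(y, span = 5L) {
  if (span %% 2 == 0 || span < 3) stop("span must be an odd integer >= 3")
  n <- length(y)
  h <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)  # symmetric shrink at edges
    mean(y[(i - hi):(i + hi)])
  }, numeric(1))
}

#' Savitzky-Golay filter
#'
#' Local least-squares polynomial smoothing: at each interior sample a
#' degree-`degree` polynomial is fitted over the centered `span`-sample
#' window and evaluated at the window center. Near the edges the window is
#' truncated to the series and the fit is evaluated at the edge sample
#' itself (the local degree is capped at the truncated window length minus
#' one). With `degree = 0` this reduces to the moving average at interior
#' points.
#'
#' @param y Numeric series (no NAs).
#' @param span Odd integer window length >= 3.
#' @param degree Polynomial degree, < span.
#' @return Smoothed series, same length.
#' @export
savitzky_golay <- function(y, span = 5L, degree = 2L) {
  if (span %% 2 == 0 || span < 3) stop("span must be an odd integer >= 3")
  if (degree >= span) stop("degree must be < span")
  n <- length(y)
  h <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    idx <- lo:hi
    d <- min(degree, length(idx) - 1L)
    tt <- idx - i  # center abscissa at the evaluation sample
    X <- outer(tt, 0:d, `^`)
    drop(qr.coef(qr(X), y[idx]))[1]  # polynomial value at tt = 0
  }, numeric(1))
}

#' Global polynomial smoothing
#'
#' Fits one least-squares polynomial of the given degree to the whole
#' series (in sample index or supplied time) and evaluates it at every
#' sample.
#'
#' @param y Numeric series (no NAs).
#' @param degree Degree, < length(y).
#' @param t Abscissa; defaults to the sample index.
#' @return Fitted series, same length.
#' @export
polynomial_fit <- function(y, degree, t = seq_along(y)) {
  n <- length(y)
  if (degree >= n) stop("degree must be < series length")
  if (anyDuplicated(t)) stop("rank-deficient design: duplicate times")
  if (degree == 0) return(rep(mean(y), n))
  X <- cbind(1, stats::poly(t, degree))  # orthogonal basis: stable at high degree
  fit <- stats::lm.fit(X, y)
  drop(X %*% fit$coefficients)
}

# Weighted polynomial fit evaluated at one point; abscissa pre-centered there.
wls_at_zero <- function(tt, yy, w, degree) {
  keep <- w > 0
  tt <- tt[keep]; yy <- yy[keep]; w <- w[keep]
  d <- min(degree, length(unique(tt)) - 1L)
  X <- outer(tt, 0:d, `^`)
  sw <- sqrt(w)
  drop(qr.coef(qr(X * sw), yy * sw))[1]
}

#' Locally weighted regression (LOWESS / LOESS) smoothing
#'
#' At each sample, a polynomial (degree 1 for LOWESS, 2 for LOESS) is fitted
#' by weighted least squares over the k nearest neighbors in time, with
#' tricube weights, and evaluated at the sample. Robust variants follow with
#' a fixed five iterations of bisquare re-weighting of the residuals.
#'
#' @param y Numeric series (no NAs).
#' @param span Fraction of the series length in (0, 1] or an absolute
#'   neighbor count >= 3.
#' @param variant One of `"lowess"`, `"loess"`, `"robust_lowess"`,
#'   `"robust_loess"`.
#' @param t Abscissa; defaults to the sample index.
#' @param iterations Robust re-weighting iterations (robust variants only).
#' @return Smoothed series, same length.
#' @export
lowess_family <- function(y, span = 0.3,
                          variant = c("lowess", "loess", "robust_lowess", "robust_loess"),
                          t = seq_along(y), iterations = 5L) {
  variant <- match.arg(variant)
  n <- length(y)
  k <- if (span <= 1) max(3L, as.integer(ceiling(span * n))) else as.integer(span)
  if (k < 3L) stop("lowess-family neighbor count must be >= 3")
  if (k > n) stop("neighbor count k = ", k, " exceeds series length ", n)
  degree <- if (variant %in% c("lowess", "robust_lowess")) 1L else 2L
  robust <- variant %in% c("robust_lowess", "robust_loess")

  tricube <- function(d, dmax) {
    if (dmax == 0) rep(1, length(d)) else pmax(0, (1 - (d / dmax)^3))^3
  }
  fit_pass <- function(rw) {
    vapply(seq_len(n), function(i) {
      d <- abs(t - t[i])
      ord <- order(d, seq_len(n))  # earliest-index tie-break
      idx <- ord[seq_len(k)]
      w <- tricube(d[idx], max(d[idx])) * rw[idx]
      if (sum(w > 0) < degree + 1L) {
        # robust downweighting emptied the window: fall back to the nearest
        # points that still carry positive robust weight
        cand <- ord[rw[ord] > 0]
        if (length(cand) >= degree + 1L) {
          idx <- cand[seq_len(min(k, length(cand)))]
          w <- tricube(d[idx], max(d[idx])) * rw[idx]
        } else {
          w <- tricube(d[idx], max(d[idx]))
        }
      }
      wls_at_zero(t[idx] - t[i], y[idx], w, degree)
    }, numeric(1))
  }

  rw <- rep(1, n)
  fit <- fit_pass(rw)
  if (robust) {
    for (it in seq_len(iterations)) {
      r <- y - fit
      s <- stats::median(abs(r))
      if (s == 0) break
      rw <- pmax(0, 1 - (r / (6 * s))^2)^2
      fit <- fit_pass(rw)
    }
  }
  fit
}
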