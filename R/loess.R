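#' Locally weighted scatterplot smoothing (tricube LOESS)
#'
#' Local polynomial regression as used for the seasonal canopy trend: at
#' each evaluation point the `ceiling(span * n)` nearest observations (by
#' distance in `x`) receive tricube weights `(1 - (d/h)^3)^3`, where `h`
#' is the distance to the farthest included neighbour, and a weighted
#' polynomial of degree 1 (default) or 2 is fitted and evaluated there.
#' Missing `y` values are excluded before fitting, so the span is a
#' fraction of the *present* points. Optional robustness iterations
#' (`robust_iter = 2` gives the classic robust fit) downweight outliers
#' with Tukey's bisquare on the residuals; the default is the plain
#' least-squares fit.
#'
#' This direct implementation matches `stats::loess(degree = 1,
#' family = "gaussian", surface = "direct")` when `span * n` is an
#' integer; it exists so the neighbourhood rule and evaluation grid are
#' explicit and testable.
#'
#' @param x numeric predictor (e.g. fractional day of year).
#' @param y numeric response; `NA`s dropped.
#' @param span fraction of present points in each local fit, in `(0, 1]`.
#' @param degree local polynomial degree, 1 or 2.
#' @param eval points at which to evaluate the smooth (default: the
#'   observation points).
#' @param robust_iter number of bisquare robustness iterations (>= 0).
#' @return Numeric vector of fitted values at `eval`.
#' @export
#' @examples
#' x <- seq(0, 10, length.out = 50)
#' y <- sin(x) + rnorm(50, sd = 0.2)
#' loess_smooth(x, y, span = 0.5)
loess_smooth <- function(x, y, span = 0.4, degree = 1, eval = x,
                         robust_iter = 0) {
  stopifnot(length(x) == length(y), is.numeric(span), length(span) == 1L)
  if (is.na(span) || span <= 0 || span > 1)
    stop("'span' must be in (0, 1]", call. = FALSE)
  if (!degree %in% c(1, 2))
    stop("'degree' must be 1 or 2", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < max(degree + 2, 10))
    stop("need at least ", max(degree + 2, 10),
         " non-missing points for loess_smooth", call. = FALSE)
  q <- min(n, ceiling(span * n))
  rw <- rep(1, n)
  if (robust_iter > 0) {
    for (it in seq_len(robust_iter)) {
      fit_x <- loess_eval(x, y, q, degree, x, rw)
      r <- y - fit_x
      s <- stats::median(abs(r))
      rw <- if (s > 0) pmax(0, 1 - (r / (6 * s))^2)^2 else rep(1, n)
    }
  }
  loess_eval(x, y, q, degree, eval, rw)
}

# weighted local polynomial solve at each eval point
loess_eval <- function(x, y, q, degree, eval, rw) {
  n <- length(x)
  out <- numeric(length(eval))
  for (j in seq_along(eval)) {
    x0 <- eval[j]
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      sel <- d == 0
      out[j] <- sum(rw[sel] * y[sel]) / sum(rw[sel])
      next
    }
    sel <- d < h | abs(d - h) < 1e-12 * max(h, 1)
    w <- pmax(0, 1 - (d[sel] / h)^3)^3 * rw[sel]
    if (sum(w > 0) <= degree) {
      out[j] <- sum(w * y[sel]) / sum(w)
      next
    }
    xs <- x[sel] - x0
    ys <- y[sel]
    if (degree == 1) {
      sw <- sum(w)
      xm <- sum(w * xs) / sw
      ym <- sum(w * ys) / sw
      sxx <- sum(w * (xs - xm)^2)
      b <- if (sxx > 0) sum(w * (xs - xm) * (ys - ym)) / sxx else 0
      out[j] <- ym - b * xm
    } else {
      X <- cbind(1, xs, xs^2)
      fit <- stats::lm.wfit(X, ys, w)
      out[j] <- fit$coefficients[1]
    }
  }
  out
}

#' Seasonal extrema of a smoothed series
#'
#' Peak and trough of smoothed values with their day of year. Ties are
#' broken by the earliest day.
#'
#' @param day numeric day-of-year axis (sorted ascending).
#' @param smoothed fitted values on `day`.
#' @return Named numeric vector: `peak_value`, `peak_day`, `trough_value`,
#'   `trough_day`.
#' @export
extract_extrema <- function(day, smoothed) {
  stopifnot(length(day) == length(smoothed), length(day) > 0)
  ord <- order(day)
  day <- day[ord]; smoothed <- smoothed[ord]
  i_max <- which.max(smoothed)
  i_min <- which.min(smoothed)
  c(peak_value = smoothed[i_max], peak_day = day[i_max],
    trough_value = smoothed[i_min], trough_day = day[i_min])
}

#' Cross-sensor summary of seasonal extrema
#'
#' Mean and standard error (sample SD / sqrt(n)) across sensors of the
#' peak/trough values and days. With a single sensor the mean is the value
#' and the SE is `NA`.
#'
#' @param extrema matrix or data.frame with one row per sensor and
#'   columns `peak_value`, `peak_day`, `trough_value`, `trough_day`.
#' @return List with `n_sensors`, `mean` and `se` (named vectors).
#' @export
summarize_sensors <- function(extrema) {
  extrema <- as.matrix(extrema)
  if (nrow(extrema) == 0L)
    stop("no sensor extrema to summarize", call. = FALSE)
  n <- nrow(extrema)
  m <- colMeans(extrema)
  se <- if (n >= 2) apply(extrema, 2, stats::sd) / sqrt(n)
        else stats::setNames(rep(NA_real_, ncol(extrema)),
                             colnames(extrema))
  list(n_sensors = n, mean = m, se = se)
}
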