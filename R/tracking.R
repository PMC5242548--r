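#' Cross-correlation lag between settings and the omniscient criterion
#'
#' Correlates an observer's criterion settings with the omniscient
#' criterion (the midpoint of the true category means on each trial) at
#' non-negative trial lags and returns the lag maximizing the normalized
#' cross-correlation — an estimate of how quickly the observer follows
#' changes in the category means. Both series are unwrapped (cumulative
#' shortest-arc differences) before correlating, since dynamic walks escape
#' the representable orientation range. Ties resolve to the smallest lag.
#'
#' @param settings numeric vector of criterion settings in degrees.
#' @param omniscient numeric vector of the same length: the true-mean
#'   midpoint per trial (see [omniscient_criterion()]).
#' @param max_lag largest lag searched (default 20 trials).
#' @return A list with `lag` (peak lag), `correlation` (at the peak), and
#'   `ccf` (tibble of lag, correlation).
#' @export
cross_correlation_lag <- function(settings, omniscient, max_lag = 20) {
  stopifnot(length(settings) == length(omniscient),
            length(settings) > max_lag + 2)
  x <- unwrap_orientation(settings)
  y <- unwrap_orientation(omniscient)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series: cross-correlation undefined", call. = FALSE)
  }
  n <- length(x)
  cc <- vapply(0:max_lag, function(k) {
    stats::cor(x[(k + 1):n], y[1:(n - k)])
  }, numeric(1))
  peak <- which.max(cc)  # which.max returns the first (smallest lag) maximum
  list(lag = peak - 1L, correlation = cc[peak],
       ccf = tibble::tibble(lag = 0:max_lag, correlation = cc))
}

#' Omniscient criterion of a session
#'
#' The midpoint of the true category means on each trial; the reference
#' series for tracking analyses.
#'
#' @param session a session tibble with `mu_A`, `mu_B` columns.
#' @return Numeric vector of criterion orientations in degrees.
#' @export
omniscient_criterion <- function(session) {
  wrap_orientation(session$mu_A + arc_diff(session$mu_B, session$mu_A) / 2)
}

#' Root-mean-square error from the optimal criterion
#'
#' RMS of the shortest-arc deviation between the criterion settings and the
#' optimal (true-mean midpoint) criterion over trials.
#'
#' @param settings criterion settings in degrees.
#' @param session a session tibble supplying the true means (or a numeric
#'   vector of optimal criteria).
#' @return RMSE in degrees.
#' @export
rmse_from_optimal <- function(settings, session) {
  opt <- if (is.numeric(session)) session else omniscient_criterion(session)
  stopifnot(length(settings) == length(opt))
  sqrt(mean(arc_diff(settings, opt)^2))
}
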