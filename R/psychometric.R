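#' Fit a psychometric function to 2IFC discrimination data
#'
#' Maximum-likelihood fit of a cumulative normal with lapses,
#' `psi(d) = lambda/2 + (1 - lambda) * Phi((d - mu) / sigma)`, to the
#' probability of choosing interval one as a function of the signed
#' orientation difference between the intervals. The sensory noise SD is
#' derived from the fitted slope by the two-interval correction: the fitted
#' `sigma` is the SD of the *difference* of two noisy measurements, so the
#' per-stimulus SD is `sigma / sqrt(2)` (a `"half"` convention, dividing by
#' 2, is available for comparability with conventions that halve instead).
#'
#' @param responses a tibble/data.frame with columns `signed_delta`
#'   (degrees) and `choice_interval` (1 or 2), e.g. from
#'   [simulate_discrimination_staircase()].
#' @param lapse_max upper bound on the lapse rate (default 0.1).
#' @param correction `"sqrt2"` (default) or `"half"`.
#' @return An object of class `psychometric_fit`: a list with `mu`,
#'   `sigma_fit`, `lambda`, `sigma_v`, `logLik`, `n`, `convergence`,
#'   `correction`, `data`.
#' @export
fit_psychometric <- function(responses, lapse_max = 0.1,
                             correction = c("sqrt2", "half")) {
  correction <- match.arg(correction)
  stopifnot(all(c("signed_delta", "choice_interval") %in% names(responses)))
  d <- responses$signed_delta
  y <- as.integer(responses$choice_interval == 1)
  if (nrow(responses) < 20 || length(unique(abs(d))) < 3) {
    stop("need at least 20 trials spanning at least 3 difference levels",
         call. = FALSE)
  }
  opt <- psy_fit_core(d, y, lapse_max)
  sigma_fit <- exp(opt$par[2])
  structure(list(mu = opt$par[1], sigma_fit = sigma_fit,
                 lambda = lapse_max * stats::plogis(opt$par[3]),
                 sigma_v = sigma_fit / ifelse(correction == "sqrt2",
                                              sqrt(2), 2),
                 logLik = -opt$objective, n = length(y),
                 convergence = opt$convergence, correction = correction,
                 lapse_max = lapse_max,
                 data = tibble::tibble(signed_delta = d, choice1 = y)),
            class = "psychometric_fit")
}

# maximum-likelihood core on binomial counts per unique level; the
# likelihood is identical to the per-trial form up to a data-only constant
psy_fit_core <- function(d, y, lapse_max) {
  lev <- sort(unique(d))
  li <- match(d, lev)
  k <- tabulate(li[y == 1L], length(lev))
  m <- tabulate(li, length(lev))
  psy_fit_counts(lev, k, m, lapse_max, sd0 = stats::sd(d))
}

psy_fit_counts <- function(lev, k, m, lapse_max, sd0) {
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    lambda <- lapse_max * stats::plogis(par[3])
    p <- lambda / 2 + (1 - lambda) * stats::pnorm((lev - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (m - k) * log1p(-p))
  }
  start <- c(0, log(max(sd0 / 2, 0.5)), stats::qlogis(0.2))
  opt <- stats::nlminb(start, nll)
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 500))
    if (opt2$value <= opt$objective) {
      opt <- list(par = opt2$par, objective = opt2$value,
                  convergence = opt2$convergence)
    }
  }
  opt
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_fit> n = %d\n  mu = %.2f deg, ",
                     "sigma = %.2f deg, lambda = %.3f, sigma_v = %.2f deg ",
                     "(%s correction)\n"),
              x$n, x$mu, x$sigma_fit, x$lambda, x$sigma_v, x$correction))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x a `psychometric_fit`.
#' @param ... unused.
#' @return `tidy()` returns one row per parameter; `glance()` a one-row fit
#'   summary.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma_fit", "lambda", "sigma_v"),
                 estimate = c(x$mu, x$sigma_fit, x$lambda, x$sigma_v))
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(sigma_v = x$sigma_v, logLik = x$logLik, n = x$n,
                 convergence = x$convergence)
}

# simulate one synthetic 2IFC data set from fitted parameters at the same
# difference levels (parametric bootstrap draw)
simulate_psychometric <- function(fit, signed_delta) {
  p <- fit$lambda / 2 +
    (1 - fit$lambda) * stats::pnorm((signed_delta - fit$mu) / fit$sigma_fit)
  choice1 <- stats::runif(length(p)) < p
  tibble::tibble(signed_delta = signed_delta,
                 choice_interval = ifelse(choice1, 1L, 2L))
}

#' Parametric bootstrap confidence intervals for a psychometric fit
#'
#' The fitted parameters generate `n_boot` synthetic experiments at the
#' observed difference levels; each is re-fit, and per-parameter 2.5 and
#' 97.5 percentiles of the re-fitted values form the interval.
#'
#' @param fit a [fit_psychometric()] object.
#' @param n_boot number of bootstrap replicates (the study-scale value is
#'   10000; default 500 keeps a single call in the seconds range).
#' @param seed optional integer seed.
#' @return A tibble with `term`, `estimate`, `conf_low`, `conf_high`, plus
#'   attribute `n_ok` (successful refits).
#' @export
bootstrap_ci <- function(fit, n_boot = 500, seed = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!is.null(seed)) set.seed(seed)
  d <- fit$data$signed_delta
  p_hat <- fit$lambda / 2 +
    (1 - fit$lambda) * stats::pnorm((d - fit$mu) / fit$sigma_fit)
  corr_div <- if (fit$correction == "sqrt2") sqrt(2) else 2
  vals <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("mu", "sigma_fit", "lambda",
                                         "sigma_v")))
  lev <- sort(unique(d))
  li <- match(d, lev)
  m <- tabulate(li, length(lev))
  sd0 <- stats::sd(d)
  for (i in seq_len(n_boot)) {
    y_sim <- stats::runif(length(d)) < p_hat
    k <- tabulate(li[y_sim], length(lev))
    opt <- tryCatch(psy_fit_counts(lev, k, m, fit$lapse_max, sd0),
                    error = function(e) NULL)
    if (is.null(opt)) next
    sg <- exp(opt$par[2])
    vals[i, ] <- c(opt$par[1], sg, fit$lapse_max * stats::plogis(opt$par[3]),
                   sg / corr_div)
  }
  ok <- stats::complete.cases(vals)
  if (sum(ok) < 0.9 * n_boot) {
    warning(sprintf("only %d of %d bootstrap refits succeeded",
                    sum(ok), n_boot))
  }
  vals <- tibble::as_tibble(vals[ok, , drop = FALSE])
  est <- c(mu = fit$mu, sigma_fit = fit$sigma_fit, lambda = fit$lambda,
           sigma_v = fit$sigma_v)
  out <- purrr::map_dfr(names(est), function(nm) {
    q <- stats::quantile(vals[[nm]], c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = nm, estimate = unname(est[nm]),
                   conf_low = q[1], conf_high = q[2])
  })
  attr(out, "n_ok") <- nrow(vals)
  out
}

#' Adjustment noise from orientation-matching data
#'
#' The SD of the shortest-arc difference between settings and targets.
#'
#' @param pairs a tibble with `target_deg` and `setting_deg` columns (e.g.
#'   from [simulate_matching_session()]).
#' @return SD of the setting errors in degrees.
#' @export
matching_noise <- function(pairs) {
  stopifnot(all(c("target_deg", "setting_deg") %in% names(pairs)),
            nrow(pairs) >= 2)
  stats::sd(arc_diff(pairs$setting_deg, pairs$target_deg))
}
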