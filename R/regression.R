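#' Build the lagged design matrix for history regressions
#'
#' For each trial, the regressors are the orientations of the `n_lags` most
#' recently experienced ellipses from each category (lag counted within
#' category by feedback label, not within the trial sequence). For the
#' covert task the current stimulus is an additional regressor and the
#' response is the binary decision; for the overt task the response is the
#' criterion setting and the current stimulus is excluded (the setting
#' precedes the stimulus). Trials without `n_lags` prior ellipses in both
#' categories are dropped. Regressors and (for the overt task) the response
#' are centered on the block mean stimulus orientation.
#'
#' @param session a session tibble.
#' @param n_lags per-category history depth (default 9).
#' @param task `"covert"` or `"overt"`; defaults to the session's task.
#' @return A tibble of class `lagged_design` with a `response` column
#'   (factor A/B or degrees), `stim0` (covert only), and columns
#'   `A_lag1..A_lagk`, `B_lag1..B_lagk`.
#' @export
build_lagged_design <- function(session, n_lags = 9, task = NULL) {
  if (is.null(task)) task <- session$task[1]
  task <- match.arg(task, c("covert", "overt"))
  n <- nrow(session)
  s <- unwrap_orientation(session$stimulus_deg)
  ctr <- mean(s)
  s <- s - ctr
  is_A <- session$true_category == "A"
  lag_block <- function(in_cat) {
    xs <- s[in_cat]
    occ_before <- c(0L, cumsum(in_cat))[seq_len(n)]
    out <- matrix(NA_real_, n, n_lags)
    for (k in seq_len(n_lags)) {
      idx <- occ_before - k + 1L
      ok <- idx >= 1L
      out[ok, k] <- xs[idx[ok]]
    }
    out
  }
  A <- lag_block(is_A)
  B <- lag_block(!is_A)
  colnames(A) <- paste0("A_lag", seq_len(n_lags))
  colnames(B) <- paste0("B_lag", seq_len(n_lags))
  keep <- stats::complete.cases(A) & stats::complete.cases(B)
  if (sum(keep) < 5 * (2 * n_lags + 2)) {
    stop("session too short for ", n_lags, " per-category lags", call. = FALSE)
  }
  d <- tibble::as_tibble(cbind(A, B)[keep, , drop = FALSE])
  if (task == "covert") {
    d <- dplyr::bind_cols(tibble::tibble(stim0 = s[keep]), d)
    # success level is the counter-clockwise category B, so the weight on
    # the current stimulus is positive and history weights (which raise the
    # criterion and favor A) are negative
    d$response <- factor(session$response[keep], levels = c("A", "B"))
  } else {
    z <- unwrap_orientation(session$criterion_deg) - ctr
    d$response <- z[keep]
  }
  d$trial <- session$trial[keep]
  class(d) <- c("lagged_design", class(d))
  attr(d, "task") <- task
  attr(d, "n_lags") <- n_lags
  d
}

design_formula <- function(design) {
  terms <- setdiff(names(design), c("response", "trial"))
  stats::reformulate(terms, response = "response")
}

#' Lagged logistic regression on covert-criterion decisions
#'
#' Maximum-likelihood logistic regression of the binary decision (the
#' counter-clockwise category B coded as 1) on the current stimulus and the
#' per-category lagged orientations.
#' Complete separation is detected and reported; a ridge-penalized fit is
#' substituted in that case.
#'
#' @param design a covert [build_lagged_design()] tibble.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`; attribute `separation` flags a penalized refit.
#' @export
fit_lagged_logistic <- function(design) {
  stopifnot(attr(design, "task") == "covert")
  if (dplyr::n_distinct(design$response) < 2) {
    stop("responses are all identical; logistic regression undefined",
         call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(design_formula(design), family = stats::binomial(),
               data = design)
  )
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 50) ||
    max(fit$fitted.values) > 1 - 1e-8 || min(fit$fitted.values) < 1e-8
  if (sep) {
    warning("possible complete separation; substituting a ridge-penalized fit")
    terms <- setdiff(names(design), c("response", "trial"))
    xm <- as.matrix(design[terms])
    y <- as.integer(design$response == levels(design$response)[2])
    rg <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    est <- c(`(Intercept)` = as.numeric(rg$a0),
             stats::setNames(as.numeric(rg$beta), rownames(rg$beta)))
    out <- tibble::tibble(term = names(est), estimate = unname(est),
                          std_error = NA_real_, statistic = NA_real_,
                          p_value = NA_real_)
  } else {
    sm <- summary(fit)$coefficients
    out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                          std_error = sm[, 2], statistic = sm[, 3],
                          p_value = sm[, 4])
  }
  attr(out, "separation") <- sep
  out
}

#' Lagged linear regression on overt-criterion settings
#'
#' Ordinary least squares of the criterion setting on the per-category
#' lagged stimulus orientations.
#'
#' @param design an overt [build_lagged_design()] tibble.
#' @return A tibble as in [fit_lagged_logistic()]; attribute
#'   `rank_deficient` flags aliased columns.
#' @export
fit_lagged_linear <- function(design) {
  stopifnot(attr(design, "task") == "overt")
  fit <- stats::lm(design_formula(design), data = design)
  rank_def <- anyNA(stats::coef(fit))
  if (rank_def) warning("rank-deficient lagged design; aliased terms dropped")
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], statistic = sm[, 3],
                        p_value = sm[, 4])
  attr(out, "rank_deficient") <- rank_def
  out
}

#' Group-level tests of lagged regression weights
#'
#' One-sample two-sided t-test per term across subjects, flagged at the
#' uncorrected 0.05 level.
#'
#' @param per_subject_betas a tibble with columns `subject`, `term`,
#'   `estimate` (e.g. row-bound outputs of [fit_lagged_logistic()]).
#' @return A tibble with `term`, `mean`, `se`, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
group_beta_tests <- function(per_subject_betas) {
  stopifnot(all(c("subject", "term", "estimate") %in%
                  names(per_subject_betas)))
  per_subject_betas |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      t = ifelse(stats::sd(.data$estimate) == 0, 0,
                 mean(.data$estimate) / (stats::sd(.data$estimate) /
                                           sqrt(dplyr::n()))),
      df = dplyr::n() - 1,
      p_value = ifelse(stats::sd(.data$estimate) == 0, 1,
                       2 * stats::pt(-abs(.data$t), df = .data$df)),
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = .data$p_value < 0.05)
}

#' Plot group-average lagged regression weights
#'
#' @param group_betas output of [group_beta_tests()].
#' @return A ggplot object: mean weight per within-category lag, one line
#'   per category, error bars of one SE.
#' @export
plot_lagged_betas <- function(group_betas) {
  df <- group_betas |>
    dplyr::filter(grepl("^[AB]_lag", .data$term)) |>
    dplyr::mutate(category = substr(.data$term, 1, 1),
                  lag = as.integer(sub("^[AB]_lag", "", .data$term)))
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$mean,
                                   linetype = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::scale_x_continuous(breaks = sort(unique(df$lag))) +
    ggplot2::labs(x = "lag (ellipses back, within category)",
                  y = "mean regression weight",
                  linetype = "category")
}
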