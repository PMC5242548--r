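#' Best-fitting model tie set for one observer
#'
#' The best model is the one with the lowest DIC; models with a DIC less
#' than 7 above the minimum are tied with it, and models 7 or more above
#' are considered poor fits.
#'
#' @param dic_row named numeric vector of per-model DIC scores.
#' @param threshold tie threshold in DIC units (default 7).
#' @return Character vector of tied model ids (always contains the argmin).
#' @examples
#' tie_sets(c(m1 = 100, m2 = 106, m3 = 108))
#' @export
tie_sets <- function(dic_row, threshold = 7) {
  stopifnot(all(is.finite(dic_row)), !is.null(names(dic_row)))
  names(dic_row)[dic_row < min(dic_row) + threshold]
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across observers: model
#' frequencies in the population carry a Dirichlet prior (concentration
#' `alpha0` per model) and per-observer model assignments are latent. The
#' posterior over frequencies is approximated by the standard variational
#' scheme, and the exceedance probability of each model (the posterior
#' probability that it is the most frequent in the population) is estimated
#' by Monte-Carlo draws from the Dirichlet posterior. Log model evidence per
#' observer is approximated by `-DIC/2` upstream.
#'
#' @param log_evidence observers x models matrix of log model evidence
#'   (column names are model ids).
#' @param alpha0 prior Dirichlet concentration per model (default 1).
#' @param n_draws Monte-Carlo draws for the exceedance probabilities.
#' @param max_iter,tol variational iteration controls.
#' @param seed integer seed for the Monte-Carlo stage.
#' @return A list with `alpha` (posterior Dirichlet concentrations),
#'   `exceedance` (per-model probabilities summing to 1), `model_prob`
#'   (posterior assignment probabilities, observers x models), and
#'   `expected_frequency`.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, n_draws = 1e5,
                    max_iter = 200, tol = 1e-6, seed = 1) {
  le <- as.matrix(log_evidence)
  stopifnot(ncol(le) >= 2, all(is.finite(le)))
  if (is.null(colnames(le))) colnames(le) <- paste0("model", seq_len(ncol(le)))
  K <- ncol(le)
  alpha <- rep(alpha0, K)
  g <- matrix(NA_real_, nrow(le), K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lu <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) {
    stop("random-effects BMS did not converge after ", max_iter,
         " iterations", call. = FALSE)
  }
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  n_draws, K)
  winner <- max.col(draws, ties.method = "first")
  exceedance <- tabulate(winner, K) / n_draws
  names(exceedance) <- names(alpha) <- colnames(le)
  colnames(g) <- colnames(le)
  list(alpha = alpha, exceedance = exceedance, model_prob = g,
       expected_frequency = alpha / sum(alpha))
}

#' Compare fitted models across observers
#'
#' Builds the per-observer DIC table with the tie rule, group mean DIC, and
#' group-level random-effects model selection (exceedance probabilities)
#' from per-observer log evidence `-DIC/2`.
#'
#' @param fits either a tibble with columns `observer`, `model_id`, `dic`,
#'   or a list of lists of `criterion_fit` objects (one inner list per
#'   observer).
#' @param threshold DIC tie threshold (default 7).
#' @param seed seed for the exceedance Monte-Carlo stage.
#' @return An object of class `criterion_comparison`: `dic` (observers x
#'   models matrix), `ties` (list of tie sets), `group_mean`, `bms` (the
#'   [rfx_bms()] result).
#' @export
compare_observer_models <- function(fits, threshold = 7, seed = 1) {
  if (inherits(fits, "data.frame")) {
    tab <- fits
  } else {
    tab <- purrr::map_dfr(seq_along(fits), function(i) {
      purrr::map_dfr(fits[[i]], function(f) {
        tibble::tibble(observer = i, model_id = f$model_id, dic = f$dic)
      })
    })
  }
  stopifnot(all(c("observer", "model_id", "dic") %in% names(tab)))
  wide <- tidyr::pivot_wider(tab[c("observer", "model_id", "dic")],
                             names_from = "model_id", values_from = "dic")
  if (anyNA(wide)) {
    miss <- wide$observer[!stats::complete.cases(wide)]
    stop("incomplete model coverage for observer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$observer
  ties <- apply(m, 1, tie_sets, threshold = threshold, simplify = FALSE)
  bms <- rfx_bms(-m / 2, seed = seed)
  structure(list(dic = m, ties = ties, group_mean = colMeans(m),
                 threshold = threshold, bms = bms),
            class = "criterion_comparison")
}

#' @export
print.criterion_comparison <- function(x, ...) {
  cat("<criterion_comparison>", nrow(x$dic), "observers x", ncol(x$dic),
      "models\n")
  marked <- x$dic
  disp <- matrix(sprintf("%.0f", marked), nrow(marked), ncol(marked),
                 dimnames = dimnames(marked))
  for (i in seq_len(nrow(marked))) {
    best <- x$ties[[i]]
    disp[i, best] <- paste0(disp[i, best], "*")
  }
  print(rbind(disp,
              `mean DIC` = sprintf("%.0f", x$group_mean),
              `exceedance` = sprintf("%.3f", x$bms$exceedance)),
        quote = FALSE)
  cat("(* marks the tie set: DIC within", x$threshold,
      "of the observer's best model)\n")
  invisible(x)
}

#' Tidy a model comparison
#'
#' @param x a `criterion_comparison`.
#' @param ... unused.
#' @return A tibble with one row per observer x model: `observer`,
#'   `model_id`, `dic`, `delta_dic` (to the observer's best model), and
#'   `best` (tie-set membership).
#' @export
tidy.criterion_comparison <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$dic)), function(i) {
    tibble::tibble(observer = rownames(x$dic)[i],
                   model_id = colnames(x$dic),
                   dic = x$dic[i, ],
                   delta_dic = x$dic[i, ] - min(x$dic[i, ]),
                   best = colnames(x$dic) %in% x$ties[[i]])
  })
}

#' @rdname tidy.criterion_comparison
#' @return `glance()` returns one row per model with `group_mean_dic`,
#'   `exceedance`, `expected_frequency`, `n_best` (observers whose tie set
#'   contains the model).
#' @export
glance.criterion_comparison <- function(x, ...) {
  tibble::tibble(model_id = colnames(x$dic),
                 group_mean_dic = unname(x$group_mean),
                 exceedance = unname(x$bms$exceedance),
                 expected_frequency = unname(x$bms$expected_frequency),
                 n_best = vapply(colnames(x$dic), function(m) {
                   sum(vapply(x$ties, function(tt) m %in% tt, logical(1)))
                 }, numeric(1)))
}

#' Exceedance-probability bar plot
#'
#' @param object a `criterion_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.criterion_comparison <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$model_id, .data$exceedance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "exceedance probability",
                  title = "Group-level random-effects model selection")
}
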