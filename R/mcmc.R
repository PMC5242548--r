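# Adaptive random-walk Metropolis-within-Gibbs sampler, split-chain
# convergence diagnostics, and DIC. Proposals are component-wise Gaussian
# on transformed scales (log for SDs and the Kalman ratio, logit for alpha
# and beta); proposal SDs adapt toward a 20-50% acceptance rate during the
# adaptation phase and are frozen afterwards.

#' Chain plan for MCMC fits
#'
#' The default "desk" plan (3 chains of 500 adaptation, 500 burn-in and
#' 2000 retained draws) keeps a single fit in the seconds range;
#' `full_chain_plan()` is the study-scale plan (1000/1000/10000).
#'
#' @param n_chains,n_adapt,n_burn,n_samples chain counts and lengths.
#' @return A named list.
#' @export
chain_plan <- function(n_chains = 3, n_adapt = 500, n_burn = 500,
                       n_samples = 2000) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_burn >= 0, n_samples >= 1)
  list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
       n_burn = as.integer(n_burn), n_samples = as.integer(n_samples))
}

#' @rdname chain_plan
#' @export
full_chain_plan <- function() chain_plan(3, 1000, 1000, 10000)

# log-posterior closure factory; returns function(theta_trans) -> c(lp, ll)
make_log_post <- function(model_id, task, session, free, fixed, cache) {
  infos <- lapply(free, param_info)
  names(infos) <- free
  loglik_fun <- if (task == "covert") loglik_covert else loglik_overt
  function(theta) {
    params <- fixed
    lj <- 0
    for (i in seq_along(free)) {
      params[[free[i]]] <- from_transformed(theta[i], infos[[i]])
      lj <- lj + log_jacobian(theta[i], infos[[i]])
    }
    lpri <- log_prior(params, free)
    if (!is.finite(lpri)) return(c(-Inf, -Inf))
    ll <- loglik_fun(model_id, params, session, cache)
    c(ll + lpri + lj, ll)
  }
}

run_one_chain <- function(log_post, free, plan, seed) {
  set.seed(seed)
  infos <- lapply(free, param_info)
  p <- length(free)
  # init uniformly on the transformed support (logit inits in a central band)
  init_one <- function() {
    vapply(seq_len(p), function(i) {
      info <- infos[[i]]
      if (info$transform == "log") {
        stats::runif(1, log(info$lower * 1.5), log(info$upper / 1.5))
      } else {
        stats::qlogis(stats::runif(1, 0.05, 0.95))
      }
    }, numeric(1))
  }
  theta <- init_one()
  cur <- log_post(theta)
  tries <- 0
  while (!is.finite(cur[1]) && tries < 50) {
    theta <- init_one()
    cur <- log_post(theta)
    tries <- tries + 1
  }
  if (!is.finite(cur[1])) {
    stop("could not initialize chain: log-posterior is -Inf everywhere tried",
         call. = FALSE)
  }
  prop_sd <- rep(0.5, p)
  n_total <- plan$n_adapt + plan$n_burn + plan$n_samples
  draws <- matrix(NA_real_, plan$n_samples, p)
  deviance <- numeric(plan$n_samples)
  lp_trace <- numeric(plan$n_samples)
  acc <- integer(p)
  win <- 25L
  for (it in seq_len(n_total)) {
    for (j in seq_len(p)) {
      cand <- theta
      cand[j] <- theta[j] + stats::rnorm(1, 0, prop_sd[j])
      new <- log_post(cand)
      if (is.finite(new[1]) &&
          log(stats::runif(1)) < new[1] - cur[1]) {
        theta <- cand
        cur <- new
        acc[j] <- acc[j] + 1L
      }
    }
    if (it <= plan$n_adapt && it %% win == 0L) {
      rate <- acc / win
      prop_sd <- ifelse(rate > 0.5, prop_sd * 1.4,
                        ifelse(rate < 0.2, prop_sd / 1.4, prop_sd))
      acc <- integer(p)
    }
    k <- it - plan$n_adapt - plan$n_burn
    if (k >= 1L) {
      draws[k, ] <- vapply(seq_len(p),
                           function(i) from_transformed(theta[i], infos[[i]]),
                           numeric(1))
      deviance[k] <- -2 * cur[2]
      lp_trace[k] <- cur[1]
    }
  }
  list(draws = draws, deviance = deviance, lp = lp_trace, prop_sd = prop_sd)
}

#' Run the MCMC sampler for one (model, task, session) fit
#'
#' @param model_id an id from [model_registry()].
#' @param session a session tibble.
#' @param task `"covert"` or `"overt"`.
#' @param fixed named list of fixed parameter values (e.g. `sigma_cat` for
#'   the Kalman variance reference; overt fits may carry `sigma_v` here).
#' @param plan a [chain_plan()].
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param cache optional ideal-observer trajectory cache.
#' @return A list of class `posterior_samples`: `draws` (array
#'   n_samples x n_chains x n_params, natural scale), `deviance`
#'   (n_samples x n_chains), `free`, `fixed`, and the fit metadata.
#' @export
run_mcmc <- function(model_id, session, task = c("covert", "overt"),
                     fixed = list(), plan = chain_plan(), seed = 1,
                     cache = NULL) {
  assert_model_id(model_id)
  task <- match.arg(task)
  free <- setdiff(free_parameters(model_id, task), names(fixed))
  if (length(free) == 0) stop("no free parameters to sample", call. = FALSE)
  log_post <- make_log_post(model_id, task, session, free, fixed, cache)
  chains <- lapply(seq_len(plan$n_chains), function(cc) {
    run_one_chain(log_post, free, plan, seed = seed + cc)
  })
  draws <- array(NA_real_, c(plan$n_samples, plan$n_chains, length(free)),
                 dimnames = list(NULL, NULL, free))
  deviance <- matrix(NA_real_, plan$n_samples, plan$n_chains)
  lp <- matrix(NA_real_, plan$n_samples, plan$n_chains)
  for (cc in seq_along(chains)) {
    draws[, cc, ] <- chains[[cc]]$draws
    deviance[, cc] <- chains[[cc]]$deviance
    lp[, cc] <- chains[[cc]]$lp
  }
  structure(list(draws = draws, deviance = deviance, lp = lp, free = free,
                 fixed = fixed, model_id = model_id, task = task,
                 plan = plan, seed = seed, log_post = log_post),
            class = "posterior_samples")
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed per parameter from the resulting 2m half-chains. Values near 1
#' indicate convergence; the conventional bar is 1.1.
#'
#' @param samples a `posterior_samples` object, or an iterations x chains
#'   matrix for a single parameter.
#' @return Named numeric vector of R-hat values (`NA` for zero-variance
#'   parameters).
#' @export
gelman_rubin <- function(samples) {
  if (inherits(samples, "posterior_samples")) {
    out <- vapply(seq_along(samples$free),
                  function(i) gelman_rubin(samples$draws[, , i, drop = TRUE]),
                  numeric(1))
    names(out) <- samples$free
    return(out)
  }
  m <- as.matrix(samples)
  n <- nrow(m)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(m)), function(cc) {
    cbind(m[seq_len(half), cc], m[(n - half + 1):n, cc])
  }))
  nn <- nrow(splits)
  w <- mean(apply(splits, 2, stats::var))
  b <- nn * stats::var(colMeans(splits))
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Deviance Information Criterion
#'
#' `p_D = mean(D) - D(posterior mean)`, `DIC = mean(D) + p_D`; lower is
#' better. The deviance at the posterior mean is recomputed from the
#' stored log-posterior closure.
#'
#' @param samples a `posterior_samples` object.
#' @return A list with `dic`, `p_d`, `mean_deviance`, `deviance_at_mean`.
#' @export
dic <- function(samples) {
  dbar <- mean(samples$deviance)
  post_mean <- apply(samples$draws, 3, mean)
  theta_bar <- vapply(seq_along(samples$free), function(i) {
    to_transformed(post_mean[i], param_info(samples$free[i]))
  }, numeric(1))
  at_mean <- samples$log_post(theta_bar)
  if (!is.finite(at_mean[2])) {
    stop("deviance at the posterior mean is not finite", call. = FALSE)
  }
  d_hat <- -2 * at_mean[2]
  p_d <- dbar - d_hat
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar,
       deviance_at_mean = d_hat)
}

#' Maximum a posteriori estimate
#'
#' Starts from the sampled draw with the highest posterior density and
#' refines it by local optimization on the transformed scale. Falls back to
#' the best sampled draw (with a warning) if the optimizer fails.
#'
#' @param samples a `posterior_samples` object.
#' @return Named list of parameter values at the posterior mode.
#' @export
map_estimate <- function(samples) {
  free <- samples$free
  infos <- lapply(free, param_info)
  flat <- matrix(aperm(samples$draws, c(1, 2, 3)),
                 ncol = length(free), dimnames = list(NULL, free))
  lp_of <- function(theta) samples$log_post(theta)[1]
  best <- which.max(as.vector(samples$lp))
  best_lp <- as.vector(samples$lp)[best]
  theta0 <- vapply(seq_along(free),
                   function(i) to_transformed(flat[best, i], infos[[i]]),
                   numeric(1))
  neg_lp <- function(th) {
    v <- -lp_of(th)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- tryCatch(
    if (length(theta0) == 1) {
      stats::optim(theta0, neg_lp, method = "Brent",
                   lower = theta0 - 10, upper = theta0 + 10)
    } else {
      stats::optim(theta0, neg_lp, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8))
    },
    error = function(e) NULL
  )
  theta_hat <- if (!is.null(opt) && is.finite(opt$value) &&
                   -opt$value >= best_lp - 1e-8) {
    opt$par
  } else {
    if (is.null(opt)) warning("MAP refinement failed; using best sampled draw")
    theta0
  }
  out <- lapply(seq_along(free),
                function(i) from_transformed(theta_hat[i], infos[[i]]))
  names(out) <- free
  out
}

# effective sample size by initial positive sequence of autocorrelations,
# pooled across chains
effective_size <- function(samples) {
  vapply(seq_along(samples$free), function(i) {
    m <- samples$draws[, , i, drop = TRUE]
    m <- as.matrix(m)
    n <- nrow(m)
    rho <- rowMeans(vapply(seq_len(ncol(m)), function(cc) {
      a <- stats::acf(m[, cc], lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
      as.numeric(a)
    }, numeric(min(100, n - 2))))
    pos <- which(rho < 0.05)
    k <- if (length(pos)) pos[1] - 1 else length(rho)
    ess <- n * ncol(m) / (1 + 2 * sum(rho[seq_len(k)]))
    max(1, min(ess, n * ncol(m)))
  }, numeric(1)) |> stats::setNames(samples$free)
}
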