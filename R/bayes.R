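#' Settings for the Metropolis-within-Gibbs sampler
#'
#' @param n_burn_max Maximum burn-in iterations; burn-in ends earlier if the
#'   stationarity test passes.
#' @param n_stationary Iterations of the stationary phase kept for posterior
#'   summaries (no thinning).
#' @param ctype Convergence-test flavour; `3` tests the log-posterior, the
#'   fixed effects, the IIV variances and the residual variance for a
#'   significant linear trend; `0` disables the test (full burn-in is used).
#' @param test_interval Iterations between burn-in stationarity tests.
#' @param proposal_adapt_target Target acceptance rate for the adaptive
#'   random-walk proposals (adaptation runs during burn-in only).
#' @param prior_a0,prior_b0 Shape and rate of the inverse-gamma priors on
#'   each IIV variance and on the residual variance (weakly informative by
#'   default); the prior on the log fixed effects is flat.
#' @param seed Optional seed applied at the start of sampling.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_burn_max = 4000, n_stationary = 10000,
                          ctype = 3, test_interval = 500,
                          proposal_adapt_target = 0.3,
                          prior_a0 = 0.01, prior_b0 = 0.01,
                          seed = NULL) {
  stopifnot(n_burn_max >= 0, n_stationary >= 1, test_interval >= 10,
            proposal_adapt_target > 0, proposal_adapt_target < 1,
            prior_a0 > 0, prior_b0 > 0)
  structure(list(n_burn_max = as.integer(n_burn_max),
                 n_stationary = as.integer(n_stationary),
                 ctype = ctype, test_interval = as.integer(test_interval),
                 proposal_adapt_target = proposal_adapt_target,
                 prior_a0 = prior_a0, prior_b0 = prior_b0, seed = seed),
            class = "mcmc_settings")
}

dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

# Observation log-likelihood rows under the proportional error model.
ll_rows <- function(y, f, sigma2) {
  bad <- !is.finite(f) | f <= 0
  v <- sigma2 * f^2
  out <- -0.5 * (log(2 * pi * v) + (y - f)^2 / v)
  out[bad] <- -Inf
  out
}

#' Joint log-posterior of the hierarchical PK model
#'
#' Evaluates
#' \deqn{\sum_{ij} \log N(y_{ij}; f_{ij}, \sigma^2 f_{ij}^2)
#'  + \sum_i \log N(\eta_i; 0, \Omega)
#'  + \log p(\omega^2) + \log p(\sigma^2),}
#' with inverse-gamma priors on the variances and a flat (improper) prior on
#' the log fixed effects. Used by the sampler and available directly for
#' diagnostics.
#'
#' @param data Dataset in NONMEM-style layout.
#' @param params A [pop_params()] holding the current \eqn{\theta},
#'   \eqn{\omega^2} and \eqn{\sigma^2}.
#' @param eta Matrix of subject random effects (subjects x active effects,
#'   columns in `active_etas(params)` order), or `NULL` for all-zero.
#' @param prior_a0,prior_b0 Inverse-gamma hyperparameters (see
#'   [mcmc_settings()]).
#' @return The log-posterior (up to the flat-prior constant); `-Inf` when a
#'   predicted concentration is non-positive at an observation.
#' @export
log_posterior <- function(data, params, eta = NULL,
                          prior_a0 = 0.01, prior_b0 = 0.01) {
  stopifnot(inherits(params, "pk_pop_params"))
  obs <- obs_rows(data)
  dose <- dose_of(data)
  ids <- sort(unique(obs$ID))
  etas <- active_etas(params)
  k <- length(etas)
  if (is.null(eta)) eta <- matrix(0, length(ids), k)
  eta <- matrix(eta, ncol = k, dimnames = list(NULL, etas))
  om <- omega2_vector(params, etas)
  idx <- match(obs$ID, ids)
  f <- conc_onecpt(dose, obs$TIME,
                   ka = params$ka * exp(if ("ka" %in% etas) eta[idx, "ka"] else 0),
                   v  = params$v_f * exp(if ("v" %in% etas) eta[idx, "v"] else 0),
                   cl = params$cl_f * exp(if ("cl" %in% etas) eta[idx, "cl"] else 0))
  ll <- sum(ll_rows(obs$DV, f, params$sigma2))
  if (!is.finite(ll)) return(-Inf)
  lp_eta <- -0.5 * sum(sweep(eta^2, 2, om, "/") +
                         matrix(log(2 * pi * om), nrow(eta), k, byrow = TRUE))
  lp_var <- sum(dinvgamma_log(om, prior_a0, prior_b0)) +
    dinvgamma_log(params$sigma2, prior_a0, prior_b0)
  ll + lp_eta + lp_var
}

# Long-run variance by Geyer's initial-positive-sequence estimator: sum
# autocovariances in adjacent pairs while the pair sums stay positive.
lrv_ips <- function(x) {
  n <- length(x)
  gam <- as.numeric(stats::acf(x, lag.max = min(n - 2, 200), type = "covariance",
                               plot = FALSE, demean = TRUE)$acf)
  s <- gam[1]
  m <- 1
  while (m + 1 < length(gam)) {
    pair <- gam[m + 1] + gam[m + 2]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + 2 * pair
    m <- m + 2
  }
  s
}

# Least-squares slope test for a monitored chain series: p-value for
# H0 slope = 0. MCMC draws are autocorrelated, so the slope's standard
# error uses the long-run variance of the detrended series (initial
# positive sequence estimator, as in Heidelberger-Welch-style stationarity
# diagnostics) instead of the i.i.d. residual variance, and the t reference
# has effective-sample-size degrees of freedom.
slope_p_value <- function(y) {
  n <- length(y)
  if (n < 20 || stats::sd(y) < 1e-12) return(1)
  x <- seq_len(n)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  b <- sum(xc * (y - mean(y))) / sxx
  res <- y - mean(y) - b * xc
  v <- stats::var(res)
  if (v < 1e-300) return(1)
  s0 <- lrv_ips(res)
  if (!is.finite(s0) || s0 <= 0) s0 <- v
  se <- sqrt(s0 / sxx)
  ess <- max(8, n * v / s0)
  2 * stats::pt(-abs(b / se), df = ess - 2)
}

#' Fit the population model by Metropolis-within-Gibbs MCMC
#'
#' Samples the joint posterior of \eqn{(\theta, \omega^2, \sigma^2,
#' \{\eta_i\})} with, per iteration: (1) a random-walk Metropolis update of
#' each subject's \eqn{\eta_i} (proposal scales adapt during burn-in toward
#' the target acceptance rate); (2) a conjugate inverse-gamma draw of each
#' IIV variance given the current \eqn{\eta} (skipped when `fix_omega`);
#' (3) a componentwise random-walk Metropolis update of \eqn{\log\theta},
#' followed by an exact recentering (interweaving) Gibbs draw of each
#' \eqn{\log\theta} component that carries a random effect, holding the
#' subject-level log-parameters fixed — this decouples \eqn{\theta} from
#' the \eqn{\eta} field and removes the slow random-walk drift of the
#' centered parameterisation; (4) a
#' conjugate inverse-gamma draw of \eqn{\sigma^2} given the proportional
#' residuals. Burn-in ends early when, over the most recent half of the
#' burn-in so far, none of the monitored series (log-posterior, \eqn{\theta},
#' \eqn{\omega^2}, \eqn{\sigma^2}) shows a significant linear trend
#' (slope t-test, alpha = 0.01), and at `n_burn_max` otherwise. Point
#' estimates are posterior means over the stationary phase.
#'
#' @param data Dataset in NONMEM-style layout.
#' @param initials A [pop_params()] giving the chain's starting values (and
#'   the fixed IIV variances when `fix_omega = TRUE`).
#' @param settings An [mcmc_settings()].
#' @param fix_omega Hold the IIV variances at their initial values for the
#'   whole chain (the fixed-omega method variant).
#' @return An object of class `pk_fit_bayes`/`pk_fit`; in addition to the
#'   common fit fields it carries `chain` (a tibble of stationary-phase
#'   samples), `burn_in_used`, `converged_burn_in`, `acceptance_rates` and
#'   posterior medians (`theta_med`, `omega2_med`, `sigma2_med`).
#' @examples
#' \donttest{
#' truth <- pop_params(2, 40, 10, omega2_v = cv_to_omega2(30),
#'                     omega2_cl = cv_to_omega2(30), sigma2 = 0.01)
#' d <- simulate_pk_dataset(study_design(), truth, seed = 7)
#' fit <- fit_bayes(d, truth, mcmc_settings(n_burn_max = 500,
#'                                          n_stationary = 1000, seed = 1))
#' glance(fit)
#' }
#' @export
fit_bayes <- function(data, initials, settings = mcmc_settings(),
                      fix_omega = FALSE) {
  stopifnot(inherits(initials, "pk_pop_params"),
            inherits(settings, "mcmc_settings"))
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(settings$seed)) set.seed(settings$seed)
  obs <- obs_rows(data)
  dose <- dose_of(data)
  ids <- sort(unique(obs$ID))
  n <- length(ids)
  idx <- match(obs$ID, ids)
  y <- obs$DV; tt <- obs$TIME
  n_obs <- length(y)
  etas <- active_etas(initials)
  k <- length(etas)
  if (k == 0L || initials$sigma2 <= 0) {
    stop("`initials` must carry positive omega2 components and sigma2.",
         call. = FALSE)
  }
  a0 <- settings$prior_a0; b0 <- settings$prior_b0
  target <- settings$proposal_adapt_target

  # state
  ltheta <- log(c(ka = initials$ka, v_f = initials$v_f, cl_f = initials$cl_f))
  om <- omega2_vector(initials, etas)
  s2 <- initials$sigma2
  eta <- matrix(0, n, k, dimnames = list(NULL, etas))

  conc_all <- function(ltheta, eta) {
    conc_onecpt(dose, tt,
                ka = exp(ltheta[[1]] + if ("ka" %in% etas) eta[idx, "ka"] else 0),
                v  = exp(ltheta[[2]] + if ("v" %in% etas) eta[idx, "v"] else 0),
                cl = exp(ltheta[[3]] + if ("cl" %in% etas) eta[idx, "cl"] else 0))
  }
  sub_sum <- function(x) as.numeric(rowsum(x, idx, reorder = TRUE))
  eta_prior_sub <- function(eta, om) {
    drop(eta^2 %*% (1 / om)) * -0.5 - 0.5 * sum(log(2 * pi * om))
  }

  theta_slot <- c(ka = 1L, v = 2L, cl = 3L)
  f <- conc_all(ltheta, eta)
  eta_ls <- rep(log(0.5), n)     # per-subject log proposal scale (x sqrt(om))
  th_ls <- rep(log(0.1), 3)      # log proposal sd per log-theta component
  acc_eta <- rep(0, n); acc_th <- rep(0, 3); n_prop <- 0
  batch <- 0L

  n_burn <- settings$n_burn_max
  n_stat <- settings$n_stationary
  mon <- matrix(NA_real_, n_burn, 2 + 3 + k)   # logpost, theta, om, s2
  draws <- matrix(NA_real_, n_stat, 3 + k + 2) # theta, om, s2, logpost
  colnames(draws) <- c(names(ltheta), paste0("omega2_", etas), "sigma2",
                       "log_posterior")
  burn_in_used <- n_burn
  converged <- settings$ctype == 0 || n_burn == 0

  step <- function(adapt) {
    # (1) subject-level eta RW-MH, all subjects in parallel
    ll_sub <- sub_sum(ll_rows(y, f, s2))
    pr_sub <- eta_prior_sub(eta, om)
    scale <- exp(eta_ls)
    prop_sd <- outer(scale, pmax(sqrt(om), 0.05))
    eta_p <- eta + prop_sd * matrix(stats::rnorm(n * k), n, k)
    f_p <- conc_all(ltheta, eta_p)
    ll_sub_p <- sub_sum(ll_rows(y, f_p, s2))
    logr <- (ll_sub_p + eta_prior_sub(eta_p, om)) - (ll_sub + pr_sub)
    acc <- log(stats::runif(n)) < logr
    if (any(acc)) {
      eta[acc, ] <<- eta_p[acc, ]
      rows <- acc[idx]
      f[rows] <<- f_p[rows]
      ll_sub[acc] <- ll_sub_p[acc]
    }
    acc_eta <<- acc_eta + acc

    # (2) conjugate IIV-variance draws
    if (!fix_omega) {
      ssq <- colSums(eta^2)
      om <<- (b0 + ssq / 2) / stats::rgamma(k, shape = a0 + n / 2)
    }

    # (3) componentwise RW-MH on log theta (flat prior on the log scale)
    ll_tot <- sum(ll_sub)
    for (j in 1:3) {
      lth_p <- ltheta
      lth_p[j] <- lth_p[j] + exp(th_ls[j]) * stats::rnorm(1)
      f_t <- conc_all(lth_p, eta)
      d_ll <- sum(ll_rows(y, f_t, s2)) - ll_tot
      if (is.finite(d_ll) && log(stats::runif(1)) < d_ll) {
        ltheta <<- lth_p
        f <<- f_t
        ll_tot <- ll_tot + d_ll
        acc_th[j] <<- acc_th[j] + 1
      }
    }
    n_prop <<- n_prop + 1

    # (3b) recentering Gibbs move: with a flat prior on log theta and the
    # subject-level log parameters c_i = log theta + eta_i held fixed (so the
    # likelihood is untouched), log theta | c, omega2 ~ N(mean(c), omega2/n).
    # Drawing it exactly and shifting eta by the complement breaks the strong
    # theta-eta random-walk coupling of the centered parameterisation.
    for (j in seq_along(etas)) {
      ti <- theta_slot[[etas[j]]]
      ci <- ltheta[[ti]] + eta[, j]
      newm <- stats::rnorm(1, mean(ci), sqrt(om[[j]] / n))
      eta[, j] <<- ci - newm
      ltheta[[ti]] <<- newm
    }

    # (4) conjugate residual-variance draw
    res2 <- sum(((y - f) / f)^2)
    s2 <<- (b0 + res2 / 2) / stats::rgamma(1, shape = a0 + n_obs / 2)

    if (adapt && n_prop %% 50 == 0) {
      batch <<- batch + 1L
      delta <- min(0.1, 1 / sqrt(batch))
      eta_ls <<- eta_ls + ifelse(acc_eta / 50 > target, delta, -delta)
      th_ls <<- th_ls + ifelse(acc_th / 50 > target, delta, -delta)
      acc_eta <<- rep(0, n); acc_th <<- rep(0, 3)
    }

    sum(ll_rows(y, f, s2)) + sum(eta_prior_sub(eta, om)) +
      sum(dinvgamma_log(om, a0, b0)) + dinvgamma_log(s2, a0, b0)
  }

  # burn-in with stationarity testing
  if (n_burn > 0) {
    for (it in seq_len(n_burn)) {
      lp <- step(adapt = TRUE)
      mon[it, ] <- c(lp, ltheta, om, s2)
      if (settings$ctype != 0 && it %% settings$test_interval == 0) {
        win <- mon[seq(floor(it / 2) + 1, it), , drop = FALSE]
        pvals <- apply(win, 2, slope_p_value)
        if (all(pvals > 0.01)) {
          burn_in_used <- it
          converged <- TRUE
          break
        }
      }
    }
    if (!converged && settings$ctype != 0) burn_in_used <- n_burn
  } else {
    burn_in_used <- 0L
  }

  acc_eta <- rep(0, n); acc_th <- rep(0, 3)
  for (it in seq_len(n_stat)) {
    lp <- step(adapt = FALSE)
    draws[it, ] <- c(exp(ltheta), om, s2, lp)
  }
  acc_rates <- list(eta = acc_eta / n_stat, theta = acc_th / n_stat)

  est <- colMeans(draws)
  med <- apply(draws, 2, stats::median)
  th_names <- c("ka", "v_f", "cl_f")

  fit <- new_pk_fit(
    subclass = "pk_fit_bayes",
    method = if (fix_omega) "BAYES(F)" else "BAYES",
    theta_hat = stats::setNames(est[1:3], th_names),
    omega2_hat = stats::setNames(est[3 + seq_len(k)], etas),
    sigma2_hat = est[["sigma2"]],
    ofv = -2 * est[["log_posterior"]],
    minimization_success = converged,
    covariance_success = TRUE,
    eta_hat = eta,
    n_func_evals = n_prop,
    runtime_s = proc.time()[["elapsed"]] - t0,
    initials = initials, settings = settings,
    theta_med = stats::setNames(med[1:3], th_names),
    omega2_med = stats::setNames(med[3 + seq_len(k)], etas),
    sigma2_med = med[["sigma2"]],
    burn_in_used = burn_in_used,
    converged_burn_in = converged,
    acceptance_rates = acc_rates,
    chain = tibble::as_tibble(cbind(iteration = seq_len(n_stat), draws))
  )
  fit
}

#' Composite FOCE-I + MCMC fit
#'
#' Runs [fit_foce()] first and starts the MCMC chain from its estimates
#' (or from its last iterate when the minimisation did not converge); on a
#' hard FOCE-I failure the chain falls back to the user initials and the
#' result is flagged. The returned fit is the Bayesian-phase result labeled
#' `"BAYES(C)"`, with the FOCE-I stage attached as `$foce_stage` for audit.
#'
#' @inheritParams fit_bayes
#' @param foce_settings A [foce_settings()] for the first stage.
#' @return A `pk_fit_bayes` object (see [fit_bayes()]) with `$foce_stage`.
#' @export
fit_bayes_composite <- function(data, initials, settings = mcmc_settings(),
                                foce_settings = pksse::foce_settings()) {
  stage1 <- tryCatch(fit_foce(data, initials, foce_settings),
                     error = function(e) NULL)
  fell_back <- is.null(stage1) ||
    !all(is.finite(c(stage1$theta_hat, stage1$omega2_hat, stage1$sigma2_hat)))
  if (fell_back) {
    start <- initials
  } else {
    oh <- stage1$omega2_hat
    start <- pop_params(
      ka = stage1$theta_hat[["ka"]], v_f = stage1$theta_hat[["v_f"]],
      cl_f = stage1$theta_hat[["cl_f"]],
      omega2_v = if ("v" %in% names(oh)) oh[["v"]] else 0,
      omega2_cl = if ("cl" %in% names(oh)) oh[["cl"]] else 0,
      omega2_ka = if ("ka" %in% names(oh)) oh[["ka"]] else 0,
      sigma2 = stage1$sigma2_hat
    )
  }
  fit <- fit_bayes(data, start, settings, fix_omega = FALSE)
  fit$method <- "BAYES(C)"
  fit$foce_stage <- stage1
  fit$foce_fallback <- fell_back
  fit$initials <- initials
  fit
}
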