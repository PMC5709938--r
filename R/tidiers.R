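#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population-PK fit
#'
#' One row per estimated parameter, broom-style. For Bayesian fits the
#' posterior standard deviation and a central 95% credible interval are
#' included.
#'
#' @param x A `pk_fit` from [fit_foce()], [fit_bayes()] or
#'   [fit_bayes_composite()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, for Bayesian fits,
#'   `std.error`, `conf.low`, `conf.high` (2.5% and 97.5% posterior
#'   quantiles).
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$theta_hat),
             paste0("omega2_", names(x$omega2_hat)), "sigma2"),
    estimate = unname(c(x$theta_hat, x$omega2_hat, x$sigma2_hat))
  )
}

#' @rdname tidy.pk_fit
#' @export
tidy.pk_fit_bayes <- function(x, ...) {
  out <- tidy.pk_fit(x)
  ch <- as.matrix(x$chain[, out$term])
  out$std.error <- apply(ch, 2, stats::sd)
  qs <- apply(ch, 2, stats::quantile, probs = c(0.025, 0.975))
  out$conf.low <- qs[1, ]
  out$conf.high <- qs[2, ]
  out
}

#' Glance at a population-PK fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the method label, objective value,
#'   success flags, number of function evaluations (or proposals) and
#'   runtime.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    ofv = x$ofv,
    minimization_success = x$minimization_success,
    covariance_success = x$covariance_success,
    n_func_evals = x$n_func_evals,
    runtime_s = x$runtime_s
  )
}
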