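#' Settings for the FOCE-I estimator
#'
#' @param sig_digits Significant digits used by the convergence proxy: the
#'   optimum must be stable to roughly `0.5 * 10^-sig_digits` relative.
#' @param inner_tol Gradient-norm tolerance for the per-subject
#'   conditional-mode (empirical Bayes) optimisation.
#' @param max_outer_iter Iteration cap for the outer quasi-Newton search.
#' @param fd_step Relative step for outer finite-difference derivatives
#'   (gradient check and covariance-step Hessian).
#' @param covariance Run the covariance step (finite-difference Hessian of
#'   the objective, positive-definiteness check) after minimisation.
#' @return A list of class `foce_settings`.
#' @export
foce_settings <- function(sig_digits = 3, inner_tol = 1e-6,
                          max_outer_iter = 300, fd_step = 1e-4,
                          covariance = TRUE) {
  stopifnot(sig_digits >= 1, inner_tol > 0, fd_step > 0, max_outer_iter >= 1)
  structure(list(sig_digits = sig_digits, inner_tol = inner_tol,
                 max_outer_iter = max_outer_iter, fd_step = fd_step,
                 covariance = covariance),
            class = "foce_settings")
}

# Split a NONMEM-style dataset into per-subject observation blocks.
split_subjects <- function(data) {
  obs <- obs_rows(data)
  dose <- dose_of(data)
  subs <- lapply(split(obs, obs$ID), function(d) {
    list(y = d$DV, t = d$TIME)
  })
  list(subjects = subs, dose = dose)
}

# Conditional (FOCE-I) per-subject objective: -2 log of the joint density of
# (y_i, eta_i) up to the 2*pi constant, with the proportional-error variance
# evaluated at the current eta (the eta-epsilon interaction).
inner_objective <- function(eta, sub, dose, theta, omega2, sigma2, etas) {
  if (any(!is.finite(eta)) || any(abs(eta) > 100)) {
    return(1e10 + sum(pmin(eta^2, 1e8)))
  }
  names(eta) <- etas
  ka <- theta[["ka"]] * exp(if ("ka" %in% etas) eta[["ka"]] else 0)
  v  <- theta[["v_f"]] * exp(if ("v" %in% etas) eta[["v"]] else 0)
  cl <- theta[["cl_f"]] * exp(if ("cl" %in% etas) eta[["cl"]] else 0)
  f <- conc_onecpt(dose, sub$t, ka, v, cl)
  if (any(!is.finite(f)) || any(f <= 1e-250)) return(1e10 + sum(eta^2))
  sum(log(sigma2 * f^2) + (sub$y - f)^2 / (sigma2 * f^2)) +
    sum(eta^2 / omega2)
}

inner_gradient <- function(eta, sub, dose, theta, omega2, sigma2, etas) {
  if (any(!is.finite(eta)) || any(abs(eta) > 100)) {
    return(2 * pmax(pmin(eta, 1e4), -1e4))
  }
  names(eta) <- etas
  ka <- theta[["ka"]] * exp(if ("ka" %in% etas) eta[["ka"]] else 0)
  v  <- theta[["v_f"]] * exp(if ("v" %in% etas) eta[["v"]] else 0)
  cl <- theta[["cl_f"]] * exp(if ("cl" %in% etas) eta[["cl"]] else 0)
  fg <- conc_onecpt_grad(dose, sub$t, ka, v, cl, which = etas)
  f <- fg$f
  if (any(!is.finite(f)) || any(f <= 1e-250)) return(rep(0, length(eta)))
  r <- sub$y - f
  dg_df <- 2 / f - 2 * r / (sigma2 * f^2) - 2 * r^2 / (sigma2 * f^3)
  as.numeric(crossprod(fg$grad, dg_df)) + 2 * eta / omega2
}

#' Conditional mode (empirical Bayes estimate) of a subject's random effects
#'
#' Minimises the subject-level conditional objective
#' \deqn{g(\eta) = \sum_j \left[\log(\sigma^2 f_j(\eta)^2) +
#'   \frac{(y_j - f_j(\eta))^2}{\sigma^2 f_j(\eta)^2}\right] +
#'   \eta' \Omega^{-1} \eta,}
#' i.e. the FOCE-I posterior mode with the residual variance evaluated at
#' the current \eqn{\eta} (the interaction term).
#'
#' @param subject_data Rows for one subject in NONMEM-style layout (a dosing
#'   row plus observation rows), or a dataset from which the subject's rows
#'   are taken if it contains a single ID.
#' @param params A [pop_params()] with the current population values; its
#'   positive omega components define which random effects are estimated.
#' @param eta_init Optional warm start (named vector).
#' @param inner_tol Gradient-norm tolerance.
#' @return A list with `eta` (named conditional mode), `value` (objective at
#'   the mode), and `convergence` flag.
#' @export
conditional_mode <- function(subject_data, params, eta_init = NULL,
                             inner_tol = 1e-6) {
  stopifnot(inherits(params, "pk_pop_params"))
  if (length(unique(subject_data$ID)) != 1L) {
    stop("`subject_data` must contain exactly one subject.", call. = FALSE)
  }
  sp <- split_subjects(subject_data)
  etas <- active_etas(params)
  if (length(etas) == 0L) stop("No random effects are active.", call. = FALSE)
  theta <- c(ka = params$ka, v_f = params$v_f, cl_f = params$cl_f)
  res <- solve_inner(sp$subjects[[1]], sp$dose, theta,
                     omega2_vector(params, etas), params$sigma2, etas,
                     eta_init, inner_tol)
  res
}

# Scalar-parameter concentration over a time vector (one subject).
conc_sub <- function(dose, t, ka, v, cl) {
  ke <- cl / v
  if (abs(ka - ke) < .ka_ke_tol * ka) {
    dose * ka * t / v * exp(-ka * t)
  } else {
    dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
}

# Objective, gradient, model matrix G and Gauss-Newton curvature weights of
# the conditional objective at eta, for one subject. `etas` is the vector of
# active effect names in c("v","cl","ka") order.
inner_eval <- function(eta, sub, dose, theta, omega2, sigma2, etas,
                       value_only = FALSE) {
  if (any(!is.finite(eta)) || any(abs(eta) > 100)) {
    return(list(g = 1e10 + sum(pmin(eta^2, 1e8))))
  }
  e <- stats::setNames(numeric(3), c("v", "cl", "ka"))
  e[etas] <- eta
  ka <- theta[[1]] * exp(e[["ka"]])
  v  <- theta[[2]] * exp(e[["v"]])
  cl <- theta[[3]] * exp(e[["cl"]])
  t <- sub$t; y <- sub$y
  ke <- cl / v
  d <- ka - ke
  lim <- abs(d) < .ka_ke_tol * ka
  if (lim) {
    f <- dose * ka * t / v * exp(-ka * t)
  } else {
    e1 <- exp(-ke * t); e2 <- exp(-ka * t)
    f <- dose * ka / (v * d) * (e1 - e2)
  }
  if (any(!is.finite(f)) || any(f <= 1e-250)) {
    return(list(g = 1e10 + sum(eta^2)))
  }
  v2 <- sigma2 * f^2
  r <- y - f
  g <- sum(log(v2) + r^2 / v2) + sum(eta^2 / omega2)
  if (value_only) return(list(g = g))

  if (!lim) {
    df_dke <- dose * ka / v * ((e1 - e2) / d^2 - t * e1 / d)
    df_dka <- dose / v * (-(e1 - e2) * ke / d^2 + ka * t * e2 / d)
    cols <- list(v = -f - ke * df_dke, cl = ke * df_dke, ka = ka * df_dka)
    G <- do.call(cbind, cols[etas])
  } else {
    # flip-flop point: central FD in eta (rare)
    h <- 1e-6
    G <- vapply(seq_along(eta), function(j) {
      ep <- eta; ep[j] <- ep[j] + h
      em <- eta; em[j] <- em[j] - h
      (inner_eval_f(ep, sub, dose, theta, etas) -
         inner_eval_f(em, sub, dose, theta, etas)) / (2 * h)
    }, numeric(length(t)))
    G <- matrix(G, nrow = length(t))
  }
  dg_df <- 2 / f - 2 * r / v2 - 2 * r^2 / (v2 * f)
  grad <- as.numeric(crossprod(G, dg_df)) + 2 * eta / omega2
  curv <- -2 / f^2 + 2 / v2 + 8 * r / (v2 * f) + 6 * r^2 / (v2 * f^2)
  list(g = g, grad = grad, f = f, G = G, curv = curv)
}

inner_eval_f <- function(eta, sub, dose, theta, etas) {
  e <- stats::setNames(numeric(3), c("v", "cl", "ka"))
  e[etas] <- eta
  conc_sub(dose, sub$t, theta[[1]] * exp(e[["ka"]]),
           theta[[2]] * exp(e[["v"]]), theta[[3]] * exp(e[["cl"]]))
}

# Damped Gauss-Newton search for the conditional mode, warm-startable; falls
# back to BFGS if the gradient norm tolerance is not met.
solve_inner <- function(sub, dose, theta, omega2, sigma2, etas,
                        eta_init = NULL, inner_tol = 1e-6,
                        want_model = FALSE) {
  k <- length(etas)
  theta <- theta[c("ka", "v_f", "cl_f")]
  eta <- eta_init %||% rep(0, k)
  ev <- inner_eval(eta, sub, dose, theta, omega2, sigma2, etas)
  if (is.null(ev$grad)) {  # bad warm start: restart from zero
    eta <- rep(0, k)
    ev <- inner_eval(eta, sub, dose, theta, omega2, sigma2, etas)
  }
  for (iter in seq_len(40)) {
    gn <- sqrt(sum(ev$grad^2))
    if (!is.finite(gn) || gn < inner_tol) break
    H <- crossprod(ev$G * ev$curv, ev$G)
    if (k == 2L) {
      h11 <- H[1L] + 2 / omega2[1L]; h22 <- H[4L] + 2 / omega2[2L]
      h12 <- H[2L]
      det <- h11 * h22 - h12 * h12
      step <- if (is.finite(det) && det > 1e-300) {
        -c(h22 * ev$grad[1L] - h12 * ev$grad[2L],
           h11 * ev$grad[2L] - h12 * ev$grad[1L]) / det
      } else NULL
    } else {
      H[seq(1, k * k, by = k + 1)] <- H[seq(1, k * k, by = k + 1)] + 2 / omega2
      step <- tryCatch(-solve(H, ev$grad), error = function(e) NULL)
    }
    if (is.null(step) || !all(is.finite(step)) || sum(step * ev$grad) >= 0) {
      step <- -ev$grad / max(1, gn)
    }
    slope <- sum(step * ev$grad)
    tt <- 1
    accepted <- NULL
    repeat {
      cand <- eta + tt * step
      evc <- inner_eval(cand, sub, dose, theta, omega2, sigma2, etas,
                        value_only = tt != 1)
      if (is.finite(evc$g) && evc$g <= ev$g + 1e-4 * tt * slope) {
        accepted <- evc
        break
      }
      if (tt < 1e-8) break
      tt <- tt / 2
    }
    if (is.null(accepted) || accepted$g >= ev$g) break
    eta <- cand
    ev <- if (!is.null(accepted$grad)) accepted
          else inner_eval(eta, sub, dose, theta, omega2, sigma2, etas)
    if (is.null(ev$grad)) break
  }
  gn <- if (is.null(ev$grad)) Inf else sqrt(sum(ev$grad^2))
  if (!is.finite(gn) || gn > max(inner_tol, 1e-5)) {
    # robust fallback on the rare hard subject
    fit <- stats::optim(rep(0, k), inner_objective, inner_gradient,
                        sub = sub, dose = dose, theta = theta,
                        omega2 = omega2, sigma2 = sigma2, etas = etas,
                        method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-14))
    if (fit$value <= ev$g) {
      eta <- fit$par
      ev <- inner_eval(eta, sub, dose, theta, omega2, sigma2, etas)
      gn <- if (is.null(ev$grad)) Inf else sqrt(sum(ev$grad^2))
    }
  }
  out <- list(eta = stats::setNames(eta, etas), value = ev$g,
              convergence = is.finite(gn) && gn <= max(inner_tol, 1e-3))
  if (want_model) {
    out$f <- ev$f
    out$G <- ev$G
  }
  out
}

# Per-subject FOCE-I contribution: log det C + r' C^-1 r with
# C = G Omega G' + H, H = diag(sigma2 f(eta_hat)^2), r = y - f(eta_hat) + G eta_hat.
subject_ofv <- function(y, f, G, omega2, sigma2, eta_hat) {
  if (is.null(f) || any(!is.finite(f)) || any(f <= 1e-250)) return(NA_real_)
  H <- sigma2 * f^2
  C <- G %*% (omega2 * t(G))            # G diag(omega2) G'
  diag(C) <- diag(C) + H
  r <- y - f + as.numeric(G %*% eta_hat)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    diag(C) <- diag(C) + 1e-10 * mean(diag(C))
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
  }
  z <- backsolve(ch, r, transpose = TRUE)
  2 * sum(log(diag(ch))) + sum(z^2)
}

#' FOCE-I objective function value
#'
#' Computes the linearised marginal -2 log-likelihood: per-subject
#' conditional modes are found, the model is linearised about them
#' (\eqn{G_i = \partial f_i / \partial \eta} at \eqn{\hat\eta_i}), and the
#' Gaussian approximation
#' \deqn{OFV = \sum_i \log\det C_i + r_i' C_i^{-1} r_i, \quad
#'   C_i = G_i \Omega G_i' + diag(\sigma^2 f_{ij}(\hat\eta_i)^2)}
#' is evaluated with \eqn{r_i = y_i - f_i(\hat\eta_i) + G_i \hat\eta_i}.
#' The residual variance is evaluated at the conditional mode, not at zero
#' (the eta-epsilon interaction). The additive \eqn{n \log 2\pi} constant is
#' omitted, following the NONMEM reporting convention.
#'
#' @inheritParams conditional_mode
#' @param data Dataset in NONMEM-style layout (see [simulate_pk_dataset()]).
#' @return The objective value, with the matrix of conditional modes in
#'   attribute `eta`.
#' @export
foce_objective <- function(data, params, inner_tol = 1e-6) {
  stopifnot(inherits(params, "pk_pop_params"))
  sp <- split_subjects(data)
  etas <- active_etas(params)
  theta <- c(ka = params$ka, v_f = params$v_f, cl_f = params$cl_f)
  om <- omega2_vector(params, etas)
  eta_mat <- matrix(0, length(sp$subjects), length(etas),
                    dimnames = list(names(sp$subjects), etas))
  ofv <- 0
  for (i in seq_along(sp$subjects)) {
    cm <- solve_inner(sp$subjects[[i]], sp$dose, theta, om, params$sigma2,
                      etas, inner_tol = inner_tol, want_model = TRUE)
    eta_mat[i, ] <- cm$eta
    ofv <- ofv + subject_ofv(sp$subjects[[i]]$y, cm$f, cm$G, om,
                             params$sigma2, cm$eta)
  }
  structure(ofv, eta = eta_mat)
}

#' Fit the population model by FOCE with interaction
#'
#' Maximum-likelihood estimation of the fixed effects, IIV variances and
#' residual variance by minimising the FOCE-I objective
#' (see [foce_objective()]) over the log-transformed parameter vector with a
#' quasi-Newton (PORT/`nlminb`) outer search. Inner conditional-mode
#' problems are warm-started from the previous outer iterate. The
#' covariance step computes a finite-difference Hessian of the objective at
#' the optimum and declares success when it is positive definite.
#'
#' @param data Dataset in NONMEM-style layout.
#' @param initials A [pop_params()] with the starting values; its positive
#'   omega components determine which random effects are estimated.
#' @param settings A [foce_settings()].
#' @return An object of class `pk_fit` with elements `method` (`"FOCE-I"`),
#'   `theta_hat`, `omega2_hat`, `sigma2_hat`, `ofv`, `minimization_success`,
#'   `covariance_success`, `eta_hat`, `n_func_evals` and `runtime_s`.
#' @examples
#' \donttest{
#' truth <- pop_params(2, 40, 10, omega2_v = cv_to_omega2(30),
#'                     omega2_cl = cv_to_omega2(30), sigma2 = 0.01)
#' d <- simulate_pk_dataset(study_design(), truth, seed = 7)
#' fit <- fit_foce(d, truth)
#' tidy(fit)
#' }
#' @export
fit_foce <- function(data, initials, settings = foce_settings()) {
  stopifnot(inherits(initials, "pk_pop_params"),
            inherits(settings, "foce_settings"))
  t0 <- proc.time()[["elapsed"]]
  sp <- split_subjects(data)
  etas <- active_etas(initials)
  if (length(etas) == 0L) {
    stop("`initials` must carry at least one positive omega2.", call. = FALSE)
  }
  if (initials$sigma2 <= 0) {
    stop("`initials` must carry a positive sigma2.", call. = FALSE)
  }
  theta_names <- c("ka", "v_f", "cl_f")
  p0 <- log(c(initials$ka, initials$v_f, initials$cl_f,
              omega2_vector(initials, etas), initials$sigma2))
  names(p0) <- c(theta_names, paste0("omega2_", etas), "sigma2")
  k <- length(etas)

  state <- new.env(parent = emptyenv())
  state$eta <- matrix(0, length(sp$subjects), k)
  state$evals <- 0L

  ofv_fn <- function(p) {
    state$evals <- state$evals + 1L
    if (any(!is.finite(p)) || any(p > 50) || any(p < -50)) return(1e10)
    theta <- stats::setNames(exp(p[1:3]), theta_names)
    om <- stats::setNames(exp(p[3 + seq_len(k)]), etas)
    s2 <- exp(p[4 + k])
    tot <- 0
    for (i in seq_along(sp$subjects)) {
      cm <- solve_inner(sp$subjects[[i]], sp$dose, theta, om, s2, etas,
                        eta_init = state$eta[i, ],
                        inner_tol = settings$inner_tol, want_model = TRUE)
      state$eta[i, ] <- cm$eta
      v <- subject_ofv(sp$subjects[[i]]$y, cm$f, cm$G, om, s2, cm$eta)
      if (!is.finite(v)) return(1e10)
      tot <- tot + v
    }
    tot
  }

  opt <- tryCatch(
    stats::nlminb(p0, ofv_fn,
                  control = list(iter.max = settings$max_outer_iter,
                                 eval.max = 10 * settings$max_outer_iter,
                                 rel.tol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    opt <- list(par = p0, objective = ofv_fn(p0), convergence = 1L)
  }
  p_hat <- opt$par
  ofv <- opt$objective

  # convergence proxy for "stable to sig_digits significant digits":
  # optimizer reports convergence and the scaled FD gradient is small.
  h <- settings$fd_step
  grad <- vapply(seq_along(p_hat), function(j) {
    pp <- p_hat; pp[j] <- pp[j] + h
    pm <- p_hat; pm[j] <- pm[j] - h
    (ofv_fn(pp) - ofv_fn(pm)) / (2 * h)
  }, numeric(1))
  grad_ok <- all(is.finite(grad)) &&
    max(abs(grad)) < 0.5 * 10^(-settings$sig_digits) * (abs(ofv) + 1)
  minimization_success <- is.finite(ofv) && ofv < 1e9 &&
    (opt$convergence == 0 || grad_ok)

  covariance_success <- NA
  if (settings$covariance) {
    He <- tryCatch(
      stats::optimHess(p_hat, ofv_fn,
                       control = list(ndeps = rep(h, length(p_hat)))),
      error = function(e) NULL
    )
    covariance_success <- !is.null(He) && all(is.finite(He)) &&
      all(eigen(He, symmetric = TRUE, only.values = TRUE)$values > 0)
  }

  theta_hat <- stats::setNames(exp(p_hat[1:3]), theta_names)
  omega2_hat <- stats::setNames(exp(p_hat[3 + seq_len(k)]), etas)
  sigma2_hat <- exp(p_hat[[4 + k]])
  eta_hat <- state$eta
  dimnames(eta_hat) <- list(names(sp$subjects), etas)

  new_pk_fit(
    method = "FOCE-I",
    theta_hat = theta_hat, omega2_hat = omega2_hat, sigma2_hat = sigma2_hat,
    ofv = ofv,
    minimization_success = minimization_success,
    covariance_success = covariance_success,
    eta_hat = eta_hat,
    n_func_evals = state$evals,
    runtime_s = proc.time()[["elapsed"]] - t0,
    initials = initials, settings = settings
  )
}

new_pk_fit <- function(..., subclass = character()) {
  structure(list(...), class = c(subclass, "pk_fit"))
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit: %s>\n", x$method))
  est <- c(x$theta_hat, stats::setNames(x$omega2_hat,
                                        paste0("omega2_", names(x$omega2_hat))),
           sigma2 = x$sigma2_hat)
  print(signif(est, 4))
  if (!is.null(x$ofv) && is.finite(x$ofv)) cat(sprintf("OFV: %.4f\n", x$ofv))
  cat(sprintf("minimization: %s; covariance: %s\n",
              x$minimization_success, x$covariance_success))
  invisible(x)
}
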