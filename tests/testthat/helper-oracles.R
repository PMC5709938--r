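# Independent oracles used across the test files.

# Numerical integration of the depot/central two-ODE system with deSolve;
# the reference the closed-form solution is checked against.
ode_concentration <- function(dose, times, ka, v, cl, rtol = 1e-12) {
  rhs <- function(t, state, p) {
    list(c(-p$ka * state[1], p$ka * state[1] - p$cl / p$v * state[2]))
  }
  tt <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(c(a_depot = dose, a_central = 0), tt, rhs,
                        list(ka = ka, v = v, cl = cl),
                        rtol = rtol, atol = 1e-20)
  conc <- out[match(times, out[, "time"]), "a_central"] / v
  unname(conc)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of e^{-x^2} f(x) dx = sum w_i f(x_i)).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# -2 log marginal likelihood of a NONMEM-style dataset under the hierarchical
# model, by adaptive Gauss-Hermite quadrature over the per-subject etas
# (independent of the FOCE code path: its own mode search via Nelder-Mead
# and finite-difference Hessian).
agh_minus2ll <- function(data, params, n_nodes = 41) {
  obs <- dplyr::filter(data, EVID == 0L)
  dose <- unique(stats::na.omit(data$AMT[data$EVID == 1L]))
  etas <- if (params$omega2_ka > 0) c("v", "cl", "ka") else c("v", "cl")
  om <- c(v = params$omega2_v, cl = params$omega2_cl, ka = params$omega2_ka)[etas]
  gh <- gauss_hermite(n_nodes)
  k <- length(etas)
  stopifnot(k == 2)   # 2-D toy models only

  log_joint <- function(eta, y, tt) {
    f <- predict_concentration(params, dose, tt,
                               eta_v = eta[1], eta_cl = eta[2])
    if (any(f <= 0)) return(-Inf)
    sum(stats::dnorm(y, f, sqrt(params$sigma2) * f, log = TRUE)) +
      sum(stats::dnorm(eta, 0, sqrt(om), log = TRUE))
  }

  total <- 0
  for (id in unique(obs$ID)) {
    y <- obs$DV[obs$ID == id]
    tt <- obs$TIME[obs$ID == id]
    opt <- stats::optim(c(0, 0), function(e) -log_joint(e, y, tt),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    m <- opt$par
    h <- 1e-4
    H <- matrix(0, 2, 2)
    for (a in 1:2) for (b in 1:2) {
      ea <- eb <- eab <- m
      ea[a] <- ea[a] + h; eb[b] <- eb[b] + h
      eab[a] <- eab[a] + h; eab[b] <- eab[b] + h
      H[a, b] <- (log_joint(eab, y, tt) - log_joint(ea, y, tt) -
                    log_joint(eb, y, tt) + log_joint(m, y, tt)) / h^2
    }
    H <- -(H + t(H)) / 2
    L <- t(chol(solve(H)))
    # log integral of exp(log_joint) over eta
    terms <- matrix(NA_real_, n_nodes, n_nodes)
    for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) {
      z <- c(gh$nodes[a], gh$nodes[b])
      eta <- m + sqrt(2) * as.numeric(L %*% z)
      terms[a, b] <- log(gh$weights[a]) + log(gh$weights[b]) +
        log_joint(eta, y, tt) + sum(z^2)
    }
    mx <- max(terms)
    li <- mx + log(sum(exp(terms - mx))) + log(2) / 2 * 2 +
      determinant(L)$modulus[1]
    total <- total + li
  }
  -2 * total
}

base_truth <- function(cv = 30, sigma2 = 0.01) {
  pop_params(2, 40, 10, omega2_v = cv_to_omega2(cv),
             omega2_cl = cv_to_omega2(cv), sigma2 = sigma2)
}
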