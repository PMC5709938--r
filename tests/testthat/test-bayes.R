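mcse <- function(x) sqrt(pksse:::lrv_ips(x) / length(x))

test_that("log-posterior is additive over subjects and flat priors cancel", {
  des <- study_design(n_subjects = 2, sampling_times = c(1, 3, 8, 16),
                      iiv_levels = 30, n_replicates = 1)
  tr <- base_truth(30)
  d <- simulate_pk_dataset(des, tr, seed = 71)
  eta <- matrix(c(0.1, -0.2, 0.05, 0.3), 2, 2)
  lp <- log_posterior(d, tr, eta)
  # duplicate one subject (with its eta): adds exactly that subject's terms
  extra <- dplyr::mutate(dplyr::filter(d, ID == 1), ID = 3L)
  d3 <- dplyr::bind_rows(d, extra)
  lp3 <- log_posterior(d3, tr, rbind(eta, eta[1, ]))
  only1 <- dplyr::mutate(dplyr::filter(d, ID == 1), ID = 1L)
  lp1 <- log_posterior(only1, tr, eta[1, , drop = FALSE])
  lp2 <- log_posterior(dplyr::filter(d, ID == 2), tr, eta[2, , drop = FALSE])
  # the variance priors enter once per evaluation, so lp - (lp1 + lp2) is
  # minus one copy of them; the duplicate adds subject 1's likelihood and
  # eta-prior terms only
  prior_const <- lp - (lp1 + lp2)
  expect_equal(lp3 - lp, lp1 + prior_const, tolerance = 1e-9)

  # with eta = 0, theta differences equal fixed-effects Gaussian loglik
  # differences (priors on the variances cancel)
  p2 <- pop_params(2.4, 35, 11, omega2_v = tr$omega2_v,
                   omega2_cl = tr$omega2_cl, sigma2 = tr$sigma2)
  obs <- dplyr::filter(d, EVID == 0)
  direct <- function(p) {
    f <- predict_concentration(p, 320, obs$TIME)
    sum(stats::dnorm(obs$DV, f, sqrt(p$sigma2) * f, log = TRUE))
  }
  expect_equal(log_posterior(d, p2) - log_posterior(d, tr),
               direct(p2) - direct(tr), tolerance = 1e-9)
})

test_that("fix_omega holds the IIV variances at their initial values", {
  tr <- base_truth(20)
  d <- simulate_pk_dataset(study_design(), tr, seed = 72)
  fit <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 200, n_stationary = 300,
                                        seed = 1), fix_omega = TRUE)
  expect_equal(fit$method, "BAYES(F)")
  expect_true(all(fit$chain$omega2_v == tr$omega2_v))
  expect_true(all(fit$chain$omega2_cl == tr$omega2_cl))
  expect_equal(unname(fit$omega2_hat), c(tr$omega2_v, tr$omega2_cl))
  expect_true(fit$covariance_success)
})

test_that("posterior of an IIV variance matches the conjugate closed form when eta is pinned", {
  # with near-zero residual error the data pin each subject's log-parameter
  # sum theta + eta_i; with a flat prior on log theta the marginal posterior
  # of omega2 is then exactly IG(a0 + (n-1)/2, b0 + S/2), S the centered sum
  # of squares of the pinned effects
  des <- study_design(n_subjects = 20)
  tr <- pop_params(2, 40, 10, omega2_v = cv_to_omega2(30),
                   omega2_cl = cv_to_omega2(30), sigma2 = 1e-8)
  d <- simulate_pk_dataset(des, tr, seed = 73)
  eta_true <- attr(d, "etas")
  fit <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 500,
                                        n_stationary = 3000, seed = 2))
  a0 <- b0 <- 0.01
  for (k in c("v", "cl")) {
    e <- eta_true[, k]
    S <- sum((e - mean(e))^2)
    closed <- (b0 + S / 2) / (a0 + (20 - 1) / 2 - 1)
    ch <- fit$chain[[paste0("omega2_", k)]]
    expect_lt(abs(mean(ch) - closed), 3 * mcse(ch) + 0.002 * closed)
  }
})

test_that("posterior means are reproducible across seeds within Monte-Carlo error", {
  tr <- base_truth(30)
  d <- simulate_pk_dataset(study_design(), tr, seed = 74)
  s <- mcmc_settings(n_burn_max = 500, n_stationary = 3000)
  s1 <- s; s1$seed <- 11
  s2 <- s; s2$seed <- 22
  f1 <- fit_bayes(d, tr, s1)
  f2 <- fit_bayes(d, tr, s2)
  for (p in c("cl_f", "v_f")) {
    tol <- 3 * (mcse(f1$chain[[p]]) + mcse(f2$chain[[p]]))
    expect_lt(abs(f1$theta_hat[[p]] - f2$theta_hat[[p]]), tol)
  }
})

test_that("posterior concentrates near the truth with many subjects", {
  tr <- base_truth(30)
  d <- simulate_pk_dataset(study_design(n_subjects = 150), tr, seed = 75)
  fit <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 500,
                                        n_stationary = 1500, seed = 3))
  expect_lt(abs(fit$theta_hat[["ka"]] / 2 - 1), 0.1)
  expect_lt(abs(fit$theta_hat[["v_f"]] / 40 - 1), 0.05)
  expect_lt(abs(fit$theta_hat[["cl_f"]] / 10 - 1), 0.05)
  expect_lt(abs(fit$omega2_hat[["cl"]] / tr$omega2_cl - 1), 0.45)
  expect_lt(abs(fit$sigma2_hat / 0.01 - 1), 0.3)
})

test_that("the composite method seeds the chain from the FOCE-I stage", {
  tr <- base_truth(30)
  d <- simulate_pk_dataset(study_design(), tr, seed = 76)
  s <- mcmc_settings(n_burn_max = 300, n_stationary = 1500, seed = 5)
  fitc <- fit_bayes_composite(d, tr, s,
                              foce_settings = foce_settings(covariance = FALSE))
  expect_equal(fitc$method, "BAYES(C)")
  expect_s3_class(fitc$foce_stage, "pk_fit")
  expect_false(fitc$foce_fallback)
  # audit trail: the user initials are preserved, the chain started from the
  # FOCE estimates
  expect_equal(fitc$initials, tr)
  # same stationary distribution as the plain sampler (same seed stream)
  fitb <- fit_bayes(d, tr, s)
  for (p in c("v_f", "cl_f")) {
    tol <- 3 * (mcse(fitb$chain[[p]]) + mcse(fitc$chain[[p]]))
    expect_lt(abs(fitb$theta_hat[[p]] - fitc$theta_hat[[p]]), tol)
  }
})

test_that("burn-in trend test flags a stationary chain as converged", {
  tr <- base_truth(30)
  d <- simulate_pk_dataset(study_design(), tr, seed = 77)
  fit <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 1500,
                                        n_stationary = 500,
                                        test_interval = 250, seed = 6))
  expect_true(fit$converged_burn_in)
  expect_lte(fit$burn_in_used, 1500)
  expect_true(fit$minimization_success)
  # ctype = 0 disables the test and uses the whole burn-in
  fit0 <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 200,
                                         n_stationary = 200, ctype = 0,
                                         seed = 7))
  expect_equal(fit0$burn_in_used, 200L)
})

test_that("tidy() on a Bayesian fit reports posterior spread", {
  tr <- base_truth(30)
  d <- simulate_pk_dataset(study_design(), tr, seed = 78)
  fit <- fit_bayes(d, tr, mcmc_settings(n_burn_max = 200, n_stationary = 400,
                                        seed = 8))
  td <- tidy(fit)
  expect_true(all(c("std.error", "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low < td$conf.high))
  expect_equal(nrow(fit$chain), 400L)
})
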