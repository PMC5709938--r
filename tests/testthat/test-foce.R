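toy_dataset <- function(n_subjects = 2, cv = 10, sigma2 = 0.01, seed = 31,
                        times = c(1, 3, 8, 16)) {
  des <- study_design(n_subjects = n_subjects, sampling_times = times,
                      iiv_levels = cv, n_replicates = 1)
  tr <- pop_params(2, 40, 10, omega2_v = cv_to_omega2(cv),
                   omega2_cl = cv_to_omega2(cv), sigma2 = sigma2)
  simulate_pk_dataset(des, tr, seed = seed)
}

test_that("conditional mode matches a brute-force grid search", {
  d2 <- toy_dataset(n_subjects = 2, cv = 30, seed = 41)
  p <- attr(d2, "truth")
  d <- dplyr::filter(d2, ID == 1L)
  cm <- conditional_mode(d, p)

  sp <- pksse:::split_subjects(d)
  obj <- function(ev, ec) {
    pksse:::inner_objective(c(ev, ec), sp$subjects[[1]], sp$dose,
                            c(ka = p$ka, v_f = p$v_f, cl_f = p$cl_f),
                            c(p$omega2_v, p$omega2_cl), p$sigma2,
                            c("v", "cl"))
  }
  # coarse pass over [-2, 2]^2, then 1e-3 refinement around the winner
  g1 <- seq(-2, 2, by = 0.02)
  vals <- outer(g1, g1, Vectorize(obj))
  w <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  g2v <- seq(g1[w[1]] - 0.02, g1[w[1]] + 0.02, by = 0.001)
  g2c <- seq(g1[w[2]] - 0.02, g1[w[2]] + 0.02, by = 0.001)
  vals2 <- outer(g2v, g2c, Vectorize(obj))
  w2 <- which(vals2 == min(vals2), arr.ind = TRUE)[1, ]
  expect_lt(abs(cm$eta[["v"]] - g2v[w2[1]]), 1.5e-3)
  expect_lt(abs(cm$eta[["cl"]] - g2c[w2[2]]), 1.5e-3)
  expect_lte(cm$value, vals2[w2[1], w2[2]] + 1e-8)
})

test_that("conditional mode collapses to zero in the tight-prior limit", {
  d <- dplyr::filter(toy_dataset(n_subjects = 2, cv = 30, seed = 42),
                     ID == 1L)
  p0 <- pop_params(2, 40, 10, omega2_v = 1e-12, omega2_cl = 1e-12,
                   sigma2 = 0.01)
  cm <- conditional_mode(d, p0)
  expect_lt(max(abs(cm$eta)), 1e-4)
})

test_that("FOCE-I objective doubles when the dataset is duplicated subject-wise", {
  d <- toy_dataset(n_subjects = 3, cv = 20, seed = 43)
  p <- attr(d, "truth")
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, ID = ID + 10L))
  o1 <- foce_objective(d, p)
  o2 <- foce_objective(d2, p)
  expect_equal(as.numeric(o2), 2 * as.numeric(o1), tolerance = 1e-8)
})

test_that("FOCE-I objective is invariant to relabeling, reordering, and unit rescaling", {
  d <- toy_dataset(n_subjects = 4, cv = 30, seed = 44)
  p <- attr(d, "truth")
  o <- as.numeric(foce_objective(d, p))
  # shuffle rows and relabel subjects
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  d2$ID <- c(9L, 3L, 5L, 7L)[d2$ID]
  expect_equal(as.numeric(foce_objective(d2, p)), o, tolerance = 1e-8)
  # time in days, rate parameters per day: identical concentrations
  d3 <- dplyr::mutate(d, TIME = TIME / 24)
  p3 <- pop_params(p$ka * 24, p$v_f, p$cl_f * 24,
                   omega2_v = p$omega2_v, omega2_cl = p$omega2_cl,
                   sigma2 = p$sigma2)
  expect_equal(as.numeric(foce_objective(d3, p3)), o, tolerance = 1e-6)
})

test_that("FOCE-I objective approaches the fixed-effects WLS -2LL as omega -> 0", {
  d <- toy_dataset(n_subjects = 3, cv = 5, seed = 45)
  tr <- attr(d, "truth")
  p0 <- pop_params(2, 40, 10, omega2_v = 1e-12, omega2_cl = 1e-12,
                   sigma2 = tr$sigma2)
  obs <- dplyr::filter(d, EVID == 0)
  f0 <- predict_concentration(p0, 320, obs$TIME)
  wls <- sum(log(p0$sigma2 * f0^2) + (obs$DV - f0)^2 / (p0$sigma2 * f0^2))
  expect_equal(as.numeric(foce_objective(d, p0)), wls, tolerance = 1e-6)
})

test_that("OFV differences agree with adaptive Gauss-Hermite quadrature", {
  d <- toy_dataset(n_subjects = 2, cv = 10, seed = 46)
  tr <- attr(d, "truth")
  p_b <- pop_params(2.5, 34, 12,
                    omega2_v = tr$omega2_v, omega2_cl = tr$omega2_cl,
                    sigma2 = tr$sigma2)
  d_foce <- as.numeric(foce_objective(d, p_b)) - as.numeric(foce_objective(d, tr))
  d_agh <- agh_minus2ll(d, p_b) - agh_minus2ll(d, tr)
  expect_lt(abs(d_foce - d_agh) / abs(d_agh), 0.02)
})

test_that("fit_foce recovers the truth in the near-noiseless limit", {
  des <- study_design()
  tr <- pop_params(2, 40, 10, omega2_v = 1e-8, omega2_cl = 1e-8,
                   sigma2 = 1e-8)
  d <- simulate_pk_dataset(des, tr, seed = 47)
  fit <- fit_foce(d, tr, foce_settings(covariance = FALSE))
  expect_lt(abs(fit$theta_hat[["ka"]] / 2 - 1), 1e-3)
  expect_lt(abs(fit$theta_hat[["v_f"]] / 40 - 1), 1e-3)
  expect_lt(abs(fit$theta_hat[["cl_f"]] / 10 - 1), 1e-3)
})

test_that("optimisation achieves descent from the initial values", {
  d <- toy_dataset(n_subjects = 6, cv = 30, seed = 48,
                   times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24))
  tr <- attr(d, "truth")
  fit <- fit_foce(d, tr, foce_settings(covariance = FALSE))
  expect_true(fit$minimization_success)
  expect_lte(fit$ofv, as.numeric(foce_objective(d, tr)) + 1e-6)
})

test_that("fit results carry tidy/glance interfaces and the covariance flag", {
  d <- toy_dataset(n_subjects = 6, cv = 30, seed = 49,
                   times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24))
  tr <- attr(d, "truth")
  fit <- fit_foce(d, tr)
  td <- tidy(fit)
  expect_equal(td$term, c("ka", "v_f", "cl_f", "omega2_v", "omega2_cl",
                          "sigma2"))
  expect_true(all(td$estimate > 0))
  gl <- glance(fit)
  expect_equal(gl$method, "FOCE-I")
  expect_true(is.logical(gl$covariance_success))
  expect_equal(dim(fit$eta_hat), c(6L, 2L))
})
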