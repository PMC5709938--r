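test_that("CV% <-> omega^2 conversion is exact and self-inverse", {
  expect_equal(cv_to_omega2(0), 0)
  expect_equal(cv_to_omega2(80), log(1.64))
  expect_equal(omega2_to_cv(log(1.64)), 80)
  expect_equal(omega2_to_cv(log(1.0025)), 5)
  for (cv in c(5, 10, 20, 30, 50, 80)) {
    expect_equal(omega2_to_cv(cv_to_omega2(cv)), cv)
  }
  expect_error(cv_to_omega2(-5), "non-negative")
  expect_error(omega2_to_cv(-0.1), "non-negative")
})

test_that("simulated datasets have the NONMEM-style record layout", {
  d <- simulate_pk_dataset(study_design(), base_truth(), seed = 1)
  expect_equal(nrow(d), 6 * 9)
  obs <- dplyr::filter(d, EVID == 0)
  dose <- dplyr::filter(d, EVID == 1)
  expect_equal(nrow(obs), 48)            # 6 subjects x 8 samples
  expect_equal(nrow(dose), 6)
  expect_true(all(dose$TIME == 0 & dose$MDV == 1 & is.na(dose$DV) &
                    dose$AMT == 320))
  expect_true(all(obs$MDV == 0 & is.na(obs$AMT) & !is.na(obs$DV)))
  expect_equal(as.integer(table(obs$ID)), rep(8L, 6))
})

test_that("zero variability reproduces the deterministic population curve", {
  tr <- pop_params(2, 40, 10, omega2_v = 0, omega2_cl = 0, sigma2 = 0)
  d <- simulate_pk_dataset(study_design(), tr, seed = 3)
  obs <- dplyr::filter(d, EVID == 0, ID == 4)
  expect_equal(obs$DV, predict_concentration(tr, 320, obs$TIME))
})

test_that("lognormal IIV reproduces the target CV and distribution", {
  des <- study_design(n_subjects = 10000)
  tr <- base_truth(cv = 50, sigma2 = 0)
  d <- simulate_pk_dataset(des, tr, seed = 7)
  etas <- attr(d, "etas")
  cl_i <- 10 * exp(etas[, "cl"])
  expect_lt(abs(100 * stats::sd(cl_i) / mean(cl_i) - 50), 2)
  ks <- stats::ks.test(etas[, "cl"], "pnorm", 0, sqrt(cv_to_omega2(50)))
  expect_gt(ks$p.value, 0.01)
  # independence of the two effects across subjects
  expect_lt(abs(stats::cor(etas[, "v"], etas[, "cl"])), 0.05)
})

test_that("study generation counts, uniqueness and determinism", {
  des <- study_design(iiv_levels = c(10, 30), n_replicates = 3, seed = 5)
  sets <- generate_study(des, pop_params(2, 40, 10, sigma2 = 0.01))
  expect_length(sets, 6)
  dv <- purrr::map(sets, ~.x$DV[.x$EVID == 0])
  expect_equal(length(unique(dv)), 6)    # all replicates distinct
  sets2 <- generate_study(des, pop_params(2, 40, 10, sigma2 = 0.01))
  expect_identical(sets, sets2)
  lv <- purrr::map_dbl(sets, ~attr(.x, "iiv_level"))
  expect_equal(lv, rep(c(10, 30), each = 3))
  om <- purrr::map_dbl(sets, ~attr(.x, "truth")$omega2_cl)
  expect_equal(om, cv_to_omega2(lv))
})

test_that("NONMEM-style CSV writer/reader round-trips both dialects", {
  d <- simulate_pk_dataset(study_design(), base_truth(), seed = 9)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_nonmem_csv(d, f1)
  r1 <- read_nonmem_csv(f1)
  expected <- as.data.frame(d[c("ID", "TIME", "AMT", "EVID", "MDV", "DV")])
  attr(expected, "truth") <- attr(expected, "etas") <- NULL
  attr(expected, "replicate_id") <- attr(expected, "iiv_level") <- NULL
  expect_equal(as.data.frame(r1), expected)
  hdr <- readLines(f1, n = 2)
  expect_equal(hdr[1], "ID,TIME,AMT,EVID,MDV,DV")
  expect_match(hdr[2], ",320,1,1,$")     # dose row: empty DV
  # long dialect with a REP column
  d2 <- simulate_pk_dataset(study_design(), base_truth(), seed = 10)
  long <- dplyr::bind_rows(dplyr::mutate(d, REP = 1L),
                           dplyr::mutate(d2, REP = 2L))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_nonmem_csv(long, f2)
  r2 <- read_nonmem_csv(f2)
  expect_equal(unique(r2$REP), c(1L, 2L))
  expect_equal(r2$DV[r2$REP == 2L], long$DV[long$REP == 2L])
})

test_that("study configuration files override defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 12", "dose: 100", "iiv_levels: [10, 30]",
               "ka: 1.5", "v_f: 30", "cl_f: 8", "sigma2: 0.02"), f)
  cfg <- read_study_config(f)
  expect_equal(cfg$design$n_subjects, 12L)
  expect_equal(cfg$design$dose, 100)
  expect_equal(cfg$design$sampling_times, c(0.25, 0.5, 1, 2, 4, 8, 12, 24))
  expect_equal(cfg$truth$ka, 1.5)
  expect_equal(cfg$truth$sigma2, 0.02)
})

test_that("the theophylline preset carries the case-study parameterisation", {
  tp <- theo_params()
  expect_equal(tp$cl_f, 2.88)
  expect_equal(tp$v_f, 33.01)
  expect_equal(tp$ka, 1.46)
  expect_equal(omega2_to_cv(tp$omega2_cl), 25.69)
  expect_equal(omega2_to_cv(tp$omega2_v), 13.48)
  expect_equal(omega2_to_cv(tp$omega2_ka), 65.39)
  # eta on ka is active for this model only
  d <- simulate_pk_dataset(study_design(n_subjects = 500), tp, seed = 2)
  expect_gt(stats::sd(attr(d, "etas")[, "ka"]), 0)
})
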