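#' Study design for simulated population-PK datasets
#'
#' Describes the sampling design of the simulation study: number of
#' subjects, single oral dose, observation schedule, the grid of
#' inter-individual-variability (IIV) levels to sweep, and the number of
#' replicate datasets per level.
#'
#' The defaults reproduce the small-sample design this package studies:
#' 6 subjects, a 320 mg single oral dose, 8 samples within 24 h, IIV levels
#' of 5, 10, 20, 30, 50 and 80 CV%, and 100 replicates per level.
#'
#' @param n_subjects Number of subjects per dataset (>= 2).
#' @param dose Oral dose (mg) given at time 0.
#' @param sampling_times Strictly increasing observation times (h), all > 0.
#' @param iiv_levels IIV levels to simulate, as CV%.
#' @param n_replicates Replicate datasets per IIV level (>= 1).
#' @param seed Base RNG seed for the study.
#' @return An object of class `pk_study_design`.
#' @examples
#' study_design()
#' study_design(n_subjects = 12, iiv_levels = c(10, 30))
#' @export
study_design <- function(n_subjects = 6,
                         dose = 320,
                         sampling_times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                         iiv_levels = c(5, 10, 20, 30, 50, 80),
                         n_replicates = 100,
                         seed = 1L) {
  stopifnot(n_subjects >= 2, n_replicates >= 1, dose >= 0)
  if (any(sampling_times <= 0) || is.unsorted(sampling_times, strictly = TRUE)) {
    stop("`sampling_times` must be strictly increasing and positive.",
         call. = FALSE)
  }
  if (any(iiv_levels < 0)) stop("`iiv_levels` must be non-negative.", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), dose = dose,
         sampling_times = sampling_times, iiv_levels = iiv_levels,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "pk_study_design"
  )
}

#' @export
print.pk_study_design <- function(x, ...) {
  cat("<pk_study_design>\n")
  cat(sprintf("  %d subjects, dose %g mg, %d samples in (0, %g] h\n",
              x$n_subjects, x$dose, length(x$sampling_times),
              max(x$sampling_times)))
  cat(sprintf("  IIV levels (CV%%): %s; %d replicates each; seed %d\n",
              paste(x$iiv_levels, collapse = ", "), x$n_replicates, x$seed))
  invisible(x)
}

#' Simulate one replicate dataset
#'
#' Draws subject-level random effects \eqn{\eta \sim N(0, \omega^2)}
#' independently per subject and parameter, computes the predicted
#' concentration at each sampling time, and applies i.i.d. proportional
#' residual error \eqn{DV = C_{pred}(1 + \varepsilon)},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. Negative DVs that the unbounded
#' normal error can produce are kept, so the records are draws from the
#' stated generative model with no truncation.
#'
#' @param design A [study_design()].
#' @param truth A [pop_params()] object used as the generative truth
#'   (its `omega2_*`/`sigma2` components are the simulation variances).
#' @param replicate_id Integer label stored with the dataset.
#' @param iiv_level Optional CV% label stored with the dataset (metadata
#'   only; the variances come from `truth`).
#' @param seed Optional seed applied before drawing (left untouched if `NULL`).
#' @return A tibble in NONMEM-style long format with columns
#'   `ID`, `TIME`, `AMT`, `EVID`, `MDV`, `DV`: one dosing row per subject
#'   (`EVID = 1`, `MDV = 1`, `DV` missing) followed by one row per
#'   observation (`EVID = 0`, `MDV = 0`, `AMT` missing). The generative
#'   truth, replicate id, IIV level and drawn etas are attached as
#'   attributes (`truth`, `replicate_id`, `iiv_level`, `etas`).
#' @examples
#' d <- simulate_pk_dataset(study_design(), pop_params(2, 40, 10,
#'   omega2_v = cv_to_omega2(30), omega2_cl = cv_to_omega2(30),
#'   sigma2 = 0.01), seed = 42)
#' dplyr::count(d, EVID)
#' @export
simulate_pk_dataset <- function(design, truth, replicate_id = 1L,
                                iiv_level = NULL, seed = NULL) {
  stopifnot(inherits(design, "pk_study_design"),
            inherits(truth, "pk_pop_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  tt <- design$sampling_times
  etas <- cbind(
    v  = stats::rnorm(n, 0, sqrt(truth$omega2_v)),
    cl = stats::rnorm(n, 0, sqrt(truth$omega2_cl)),
    ka = if (truth$omega2_ka > 0) stats::rnorm(n, 0, sqrt(truth$omega2_ka)) else rep(0, n)
  )
  obs <- purrr::map_dfr(seq_len(n), function(i) {
    cp <- predict_concentration(truth, design$dose, tt,
                                eta_v = etas[i, "v"], eta_cl = etas[i, "cl"],
                                eta_ka = etas[i, "ka"])
    eps <- stats::rnorm(length(tt), 0, sqrt(truth$sigma2))
    tibble::tibble(ID = i, TIME = tt, AMT = NA_real_, EVID = 0L, MDV = 0L,
                   DV = cp * (1 + eps))
  })
  dose_rows <- tibble::tibble(ID = seq_len(n), TIME = 0, AMT = design$dose,
                              EVID = 1L, MDV = 1L, DV = NA_real_)
  out <- dplyr::arrange(dplyr::bind_rows(dose_rows, obs), .data$ID, .data$TIME,
                        dplyr::desc(.data$EVID))
  attr(out, "truth") <- truth
  attr(out, "replicate_id") <- as.integer(replicate_id)
  attr(out, "iiv_level") <- iiv_level
  attr(out, "etas") <- etas
  out
}

#' Simulate the full replicate sweep across IIV levels
#'
#' For each IIV level in the design, simulates `n_replicates` datasets with
#' \eqn{\omega^2_V = \omega^2_{CL}} set from the level via [cv_to_omega2()].
#' Each (level, replicate) cell gets its own deterministic RNG stream derived
#' from the design seed, so any subset of the sweep can be regenerated in
#' isolation and the full sweep is byte-reproducible.
#'
#' @param design A [study_design()].
#' @param truth_base A [pop_params()] giving the fixed effects and `sigma2`;
#'   its omega components are overridden level by level.
#' @return A list of dataset tibbles (see [simulate_pk_dataset()]), one per
#'   (level, replicate), in level-major order.
#' @examples
#' sets <- generate_study(study_design(iiv_levels = 10, n_replicates = 3),
#'                        pop_params(2, 40, 10, sigma2 = 0.01))
#' length(sets)
#' @export
generate_study <- function(design, truth_base) {
  stopifnot(inherits(design, "pk_study_design"),
            inherits(truth_base, "pk_pop_params"))
  grid <- tidyr::expand_grid(level = design$iiv_levels,
                             rep = seq_len(design$n_replicates))
  purrr::pmap(grid, function(level, rep) {
    om <- cv_to_omega2(level)
    truth <- pop_params(truth_base$ka, truth_base$v_f, truth_base$cl_f,
                        omega2_v = om, omega2_cl = om,
                        sigma2 = truth_base$sigma2,
                        omega2_ka = if (truth_base$omega2_ka > 0)
                          cv_to_omega2(level) else 0)
    simulate_pk_dataset(design, truth, replicate_id = rep, iiv_level = level,
                        seed = derive_seed(design$seed, "sim", level, rep))
  })
}

obs_rows <- function(data) dplyr::filter(data, .data$EVID == 0L)
dose_of <- function(data) {
  d <- unique(data$AMT[data$EVID == 1L])
  d <- d[!is.na(d)]
  if (length(d) != 1L) stop("Expected a single dose amount.", call. = FALSE)
  d
}

#' Read and write NONMEM-style CSV datasets
#'
#' The on-disk dialect is a comma-separated table with header
#' `ID,TIME,AMT,EVID,MDV,DV` (dose rows `EVID = 1`, `MDV = 1`, empty `DV`;
#' observation rows `EVID = 0`, `MDV = 0`, empty `AMT`). A replicate column
#' `REP` is written when the data carry one and recognised on read, so both
#' the one-file-per-replicate and single-long-file dialects round-trip.
#'
#' @param data A dataset tibble as produced by [simulate_pk_dataset()], or a
#'   long table of several replicates with a `REP` column.
#' @param path File path.
#' @return `read_nonmem_csv()` returns a tibble with the same column layout;
#'   `write_nonmem_csv()` returns `path` invisibly.
#' @export
write_nonmem_csv <- function(data, path) {
  cols <- intersect(c("REP", "ID", "TIME", "AMT", "EVID", "MDV", "DV"),
                    names(data))
  readr::write_csv(data[cols], path, na = "")
  invisible(path)
}

#' @rdname write_nonmem_csv
#' @export
read_nonmem_csv <- function(path) {
  out <- readr::read_csv(path, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_double()))
  need <- c("ID", "TIME", "AMT", "EVID", "MDV", "DV")
  if (!all(need %in% names(out))) {
    stop("Dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(c("ID", "EVID", "MDV", "REP"), names(out))) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  out
}

#' Read a study configuration file
#'
#' Reads a YAML key-value file describing the design and generative truth
#' and returns ready-to-use objects. Recognised keys mirror the arguments of
#' [study_design()] (`n_subjects`, `dose`, `sampling_times`, `iiv_levels`,
#' `n_replicates`, `seed`) and [pop_params()] (`ka`, `v_f`, `cl_f`,
#' `omega2_v`, `omega2_cl`, `sigma2`, `omega2_ka`); omitted keys fall back
#' to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `design` and `truth`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dn <- intersect(names(cfg), names(formals(study_design)))
  pn <- intersect(names(cfg), names(formals(pop_params)))
  list(design = do.call(study_design, cfg[dn]),
       truth = do.call(pop_params, cfg[pn]))
}
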