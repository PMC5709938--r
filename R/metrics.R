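#' Relative estimation error
#'
#' Signed percent deviation of an estimate from the truth,
#' \eqn{REE = 100 (P_{est} - P_{true}) / P_{true}}. The median REE over
#' replicates measures an estimator's bias; the spread of REE its
#' precision.
#'
#' @param p_est Estimated value(s).
#' @param p_true True value(s), non-zero.
#' @return REE in percent (vectorised).
#' @examples
#' ree(8, 10)   # -20
#' ree(10, 8)   # +25
#' @export
ree <- function(p_est, p_true) {
  if (any(p_true == 0)) stop("`p_true` must be non-zero.", call. = FALSE)
  100 * (p_est - p_true) / p_true
}

#' Relative root mean squared error
#'
#' The conventional relative RMSE over a set of replicate estimates,
#' \deqn{rRMSE = \sqrt{\frac{1}{n} \sum_r
#'   \left(\frac{P_{est,r} - P_{true}}{P_{true}}\right)^2},}
#' a combined measure of bias and imprecision. `rrmse_printed()` computes
#' the alternative normalisation
#' \eqn{\sqrt{\sum (P_{est}-P_{true})^2 / P_{true} / n^2}} that divides the
#' squared error by the truth (not its square) and by \eqn{n^2}; it is
#' dimensionally inconsistent and kept only for side-by-side transparency —
#' all comparisons in this package use the conventional form.
#'
#' @param estimates Vector of replicate estimates (non-empty; `NA`s are
#'   dropped).
#' @param p_true True value, positive.
#' @return A single non-negative number.
#' @examples
#' rrmse(c(11, 9), 10)          # 0.1
#' rrmse_printed(c(11, 9), 10)  # 0.2236...
#' @export
rrmse <- function(estimates, p_true) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0) stop("`estimates` is empty.", call. = FALSE)
  if (p_true <= 0) stop("`p_true` must be positive.", call. = FALSE)
  sqrt(mean(((estimates - p_true) / p_true)^2))
}

#' @rdname rrmse
#' @export
rrmse_printed <- function(estimates, p_true) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0) stop("`estimates` is empty.", call. = FALSE)
  if (p_true <= 0) stop("`p_true` must be positive.", call. = FALSE)
  n <- length(estimates)
  sqrt(sum((estimates - p_true)^2 / p_true) / n^2)
}

#' Summarise an SSE table into performance metrics
#'
#' Per (parameter, method, IIV level): the conventional rRMSE, the
#' alternative printed-form rRMSE, and the median and quartiles of the
#' signed REE, computed over replicates whose minimisation succeeded
#' (`n_used` records how many). Groups where no fit succeeded are kept with
#' missing metrics rather than dropped. Quantiles use the type-7
#' linear-interpolation rule.
#'
#' @param table An `sse_table` from [run_sse()].
#' @return A tibble of class `pk_metrics` with columns `parameter`,
#'   `method`, `iiv_level`, `rrmse`, `rrmse_variant_printed`,
#'   `median_ree`, `ree_q1`, `ree_q3` (percent) and `n_used`.
#' @export
summarize_sse <- function(table) {
  if (nrow(table) == 0) stop("`table` is empty.", call. = FALSE)
  summarise_group <- function(df, key) {
    est <- df$estimate[df$minimization_success & !is.na(df$estimate)]
    truth <- df$true_value[1]
    n_used <- length(est)
    if (n_used == 0) {
      return(tibble::tibble(rrmse = NA_real_,
                            rrmse_variant_printed = NA_real_,
                            median_ree = NA_real_, ree_q1 = NA_real_,
                            ree_q3 = NA_real_, n_used = 0L))
    }
    re <- ree(est, truth)
    q <- stats::quantile(re, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(rrmse = rrmse(est, truth),
                   rrmse_variant_printed = rrmse_printed(est, truth),
                   median_ree = q[2], ree_q1 = q[1], ree_q3 = q[3],
                   n_used = n_used)
  }
  out <- table |>
    dplyr::group_by(.data$parameter, .data$method, .data$iiv_level) |>
    dplyr::group_modify(summarise_group) |>
    dplyr::ungroup()
  class(out) <- c("pk_metrics", class(out))
  out
}

#' Long REE table for box-plot style displays
#'
#' One row per successful (replicate, method, level, parameter) with the
#' signed REE in percent — the tidy input behind [plot_ree()].
#'
#' @param table An `sse_table` from [run_sse()].
#' @return A tibble with columns `parameter`, `method`, `iiv_level`,
#'   `replicate_id`, `ree`.
#' @export
ree_table <- function(table) {
  table |>
    dplyr::filter(.data$minimization_success, !is.na(.data$estimate)) |>
    dplyr::mutate(ree = ree(.data$estimate, .data$true_value)) |>
    dplyr::select("parameter", "method", "iiv_level", "replicate_id", "ree")
}
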