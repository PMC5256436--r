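#' Extract ROC operating points from a rate table
#'
#' Orders the (F, H) pairs of a rate table from the most conservative
#' criterion to the most liberal, the conventional direction for tracing an
#' ROC from the (0, 0) corner outward.
#'
#' @param rates A `rate_table` from one of the [procedures], or any data frame
#'   with columns `criterion`, `F`, `H`.
#' @return A tibble of class `roc_curve` with columns `criterion`, `F`, `H`
#'   and a logical `monotone` attribute (`TRUE` iff both `F` and `H` are
#'   non-decreasing along the curve).
#' @export
roc_points <- function(rates) {
  stopifnot(all(c("criterion", "F", "H") %in% names(rates)))
  out <- tibble::as_tibble(rates[, c("criterion", "F", "H")])
  out <- dplyr::arrange(out, dplyr::desc(.data$criterion))
  class(out) <- c("roc_curve", class(out))
  attr(out, "monotone") <- !is.unsorted(out$F) && !is.unsorted(out$H)
  for (col in c("procedure", "rule", "lineup_size")) {
    if (col %in% names(rates) && length(unique(rates[[col]])) == 1L) {
      attr(out, col) <- rates[[col]][1]
    }
  }
  out
}

#' Build an empirical ROC from a confidence-binned count table
#'
#' Standard cumulative construction: the operating point for confidence level
#' `j` pools all positive responses made with confidence `>= j`, scanning
#' from the highest-confidence bin down. A leading (0, 0) point is prepended.
#'
#' @param counts Data frame with columns `confidence` (bin labels, any
#'   orderable values), `tp` (suspect identifications from target-present
#'   trials in that bin) and `ta` (innocent-suspect identifications from
#'   target-absent trials; apply any lineup-size correction before calling).
#' @param n_tp,n_ta Total numbers of TP and TA trials.
#' @return A `roc_curve` tibble with columns `confidence`, `F`, `H`.
#' @examples
#' counts <- data.frame(confidence = c(7, 6, 5), tp = c(30, 20, 10),
#'                      ta = c(2, 3, 5))
#' empirical_roc(counts, n_tp = 100, n_ta = 100)
#' @export
empirical_roc <- function(counts, n_tp, n_ta) {
  stopifnot(all(c("confidence", "tp", "ta") %in% names(counts)))
  n_tp <- .check_count(n_tp, "n_tp")
  n_ta <- .check_count(n_ta, "n_ta")
  if (any(counts$tp < 0) || any(counts$ta < 0)) {
    stop("counts must be non-negative.", call. = FALSE)
  }
  if (sum(counts$tp) > n_tp || sum(counts$ta) > n_ta) {
    stop("counts exceed the number of trials.", call. = FALSE)
  }
  ord <- order(counts$confidence, decreasing = TRUE)
  tp <- cumsum(counts$tp[ord])
  ta <- cumsum(counts$ta[ord])
  keep <- counts$tp[ord] + counts$ta[ord] > 0
  out <- tibble::tibble(
    confidence = c(Inf, counts$confidence[ord][keep]),
    F = c(0, ta[keep] / n_ta),
    H = c(0, tp[keep] / n_tp)
  )
  class(out) <- c("roc_curve", class(out))
  attr(out, "monotone") <- TRUE
  out
}

#' Partial area under an ROC curve
#'
#' Trapezoidal area between `F = 0` and `F = f_max`, with linear
#' interpolation at `f_max`. A curve whose largest observed false alarm rate
#' falls short of `f_max` (as lineup curves do, terminating near `1/N`) is
#' extended horizontally at its last hit rate. A curve whose hit rate folds
#' back on itself (the first-identification sequential rule) is first reduced
#' to its upper envelope in `F`, with a warning: the area under a self-folding
#' path is not well defined. The area is reported raw (no rescaling), so a
#' chance curve has `pAUC = f_max^2 / 2`.
#'
#' @param roc An ROC curve: output of [roc_points()] or [empirical_roc()], a
#'   `rate_table`, or any data frame with `F` and `H` columns (ordered
#'   conservative to liberal, or carrying a `criterion` column to order by).
#' @param f_max Upper false-alarm limit of the integration, in `(0, 1]`.
#' @return A single number in `[0, f_max]`.
#' @examples
#' chance <- data.frame(criterion = 1:11, F = seq(1, 0, -0.1), H = seq(1, 0, -0.1))
#' pauc(chance, f_max = 0.16)  # 0.16^2 / 2
#' @export
pauc <- function(roc, f_max) {
  if (!is.numeric(f_max) || length(f_max) != 1L || is.na(f_max) ||
      f_max <= 0 || f_max > 1) {
    stop("`f_max` must be a single number in (0, 1].", call. = FALSE)
  }
  stopifnot(all(c("F", "H") %in% names(roc)))
  if ("criterion" %in% names(roc)) {
    o <- order(roc$criterion, decreasing = TRUE)
    f <- roc$F[o]; h <- roc$H[o]
  } else {
    f <- roc$F; h <- roc$H
  }
  .pauc_fh(f, h, f_max)
}

# Core trapezoid on (F, H) ordered conservative -> liberal.
.pauc_fh <- function(f, h, f_max, warn = TRUE) {
  keep <- !is.na(f) & !is.na(h)
  f <- f[keep]; h <- h[keep]
  if (length(f) < 1L) stop("ROC curve has no points.", call. = FALSE)
  o <- order(f, h)
  f <- f[o]; h <- h[o]
  if (is.unsorted(h)) {
    if (warn) {
      warning("nonmonotone ROC: integrating its upper envelope in F.",
              call. = FALSE)
    }
    h <- cummax(h)
  }
  f <- c(0, f); h <- c(0, h)
  if (max(f) < f_max) {
    f <- c(f, f_max)
    h <- c(h, h[length(h)])
  }
  h_at <- stats::approx(f, h, xout = f_max, ties = "ordered")$y
  inside <- f < f_max
  fg <- c(f[inside], f_max)
  hg <- c(h[inside], h_at)
  sum(diff(fg) * (utils::head(hg, -1) + utils::tail(hg, -1)) / 2)
}

#' Analytic equal-variance ROC with a given full AUC
#'
#' The Gaussian equal-variance ROC whose full area under the curve is `auc`:
#' `H = pnorm(sqrt(2) * qnorm(auc) + qnorm(F))`. A chance-level `auc = 0.5`
#' gives `H = F`.
#'
#' @param auc Full area under the curve, strictly inside (0, 1).
#' @param f_grid False alarm rates at which to evaluate, each strictly inside
#'   (0, 1).
#' @return A tibble with columns `F` and `H`.
#' @export
analytic_roc_from_auc <- function(auc, f_grid) {
  if (!is.numeric(auc) || length(auc) != 1L || is.na(auc) ||
      auc <= 0 || auc >= 1) {
    stop("`auc` must be strictly inside (0, 1).", call. = FALSE)
  }
  if (!is.numeric(f_grid) || any(is.na(f_grid)) ||
      any(f_grid <= 0) || any(f_grid >= 1)) {
    stop("`f_grid` values must be strictly inside (0, 1).", call. = FALSE)
  }
  tibble::tibble(
    F = as.numeric(f_grid),
    H = stats::pnorm(sqrt(2) * stats::qnorm(auc) + stats::qnorm(f_grid))
  )
}

#' Single-point accuracy and bias statistics
#'
#' For an operating point (H, F): the Gaussian discriminability estimate
#' `d' = z(H) - z(F)`, the response-bias statistic `c = -0.5 (z(H) + z(F))`
#' (0 is neutral, positive is conservative), and the diagnosticity ratio
#' `D = H / F`. With trial counts supplied, rates are clamped to
#' `[1/(2n), 1 - 1/(2n)]` before the quantile transform so that empirical 0
#' or 1 rates give finite statistics. `F = 0` leaves `D` as `NA` with a
#' warning rather than reporting an infinite ratio.
#'
#' @param H,F Hit and false alarm rates in `[0, 1]` (vectors recycle).
#' @param n_tp,n_ta Optional trial counts behind `H` and `F`, used for
#'   clamping.
#' @return A tibble with columns `H`, `F`, `d_prime_est`, `c`, `D`.
#' @examples
#' bias_stats(H = 0.6915, F = 0.3085)  # c = 0, d' = 1
#' @export
bias_stats <- function(H, F, n_tp = NULL, n_ta = NULL) {
  if (any(H < 0 | H > 1, na.rm = TRUE) || any(F < 0 | F > 1, na.rm = TRUE)) {
    stop("`H` and `F` must lie in [0, 1].", call. = FALSE)
  }
  Hc <- if (is.null(n_tp)) H else pmin(pmax(H, 1 / (2 * n_tp)), 1 - 1 / (2 * n_tp))
  Fc <- if (is.null(n_ta)) F else pmin(pmax(F, 1 / (2 * n_ta)), 1 - 1 / (2 * n_ta))
  zH <- stats::qnorm(Hc)
  zF <- stats::qnorm(Fc)
  D <- ifelse(F == 0, NA_real_, H / F)
  if (any(F == 0)) {
    warning("diagnosticity is undefined at F = 0; returning NA there.",
            call. = FALSE)
  }
  tibble::tibble(
    H = as.numeric(H), F = as.numeric(F),
    d_prime_est = zH - zF,
    c = -0.5 * (zH + zF),
    D = D
  )
}

#' Diagnosticity as a function of response bias at fixed accuracy
#'
#' Traces the analytic equal-variance ROC for each AUC level and evaluates
#' the diagnosticity ratio and the bias statistic `c` along it. At any fixed
#' AUC the diagnosticity ratio falls as responding grows more liberal
#' (rises with `c`), which is the demonstration that diagnosticity confounds
#' accuracy with response bias: every point on one of these curves reflects
#' the same true accuracy.
#'
#' @param auc_levels Full-AUC levels to trace (default 0.6, 0.7, 0.8, 0.9).
#' @param f_grid False alarm rates spanning conservative to liberal
#'   responding (default 0.01 to 0.99).
#' @return A tibble with columns `auc`, `F`, `H`, `c`, `D`.
#' @export
diagnosticity_bias_curves <- function(auc_levels = c(0.6, 0.7, 0.8, 0.9),
                                      f_grid = seq(0.01, 0.99, by = 0.01)) {
  tidyr::expand_grid(auc = auc_levels, F = as.numeric(f_grid)) |>
    dplyr::mutate(
      H = analytic_roc_from_auc_vec(.data$auc, .data$F),
      c = -0.5 * (stats::qnorm(.data$H) + stats::qnorm(.data$F)),
      D = .data$H / .data$F
    )
}

# vectorised core of analytic_roc_from_auc (auc and f same length)
analytic_roc_from_auc_vec <- function(auc, f) {
  stats::pnorm(sqrt(2) * stats::qnorm(auc) + stats::qnorm(f))
}
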