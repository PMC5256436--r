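#' Bootstrap confidence interval for a partial AUC
#'
#' Resamples target-present and target-absent trials with replacement,
#' independently of each other, rebuilds the full criterion-swept ROC for
#' each replicate, and returns the percentile confidence interval of the
#' partial AUC (2.5th and 97.5th percentiles at the default 95% level).
#'
#' @param trials Trial pool from [sample_trials()].
#' @param procedure Which identification procedure to rebuild per replicate.
#'   `"sequential_any"` is the any-identification sequential rule (identical
#'   operating characteristics to the absolute simultaneous rule);
#'   first-identification sequential curves fold back on themselves and have
#'   no well-defined pAUC, so they are not offered here.
#' @param f_max Upper false-alarm limit of the partial area (default 0.10).
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param criteria Criterion sweep; defaults to [criterion_sweep()] of the
#'   pool's model.
#' @param rule,delta,ta_convention Passed to the simultaneous-lineup decision
#'   stage where relevant.
#' @param conf_level Confidence level for the percentile interval.
#' @param seed Optional seed for the resampling stream.
#'
#' @return An object of class `pauc_boot`: a list with elements `pauc`,
#'   `f_max`, `ci_low`, `ci_high`, `n_boot`, `n_tp`, `n_ta`, `conf_level`,
#'   `procedure`, `replicates` (the bootstrap pAUC draws) and `seed`.
#'   [generics::tidy()] and [generics::glance()] methods return one-row
#'   tibbles.
#' @examples
#' pool <- sample_trials(evidence_model(1.5), 400, 400, lineup_size = 1, seed = 1)
#' b <- bootstrap_pauc(pool, "showup", f_max = 0.1, n_boot = 50, seed = 2)
#' tidy(b)
#' @export
bootstrap_pauc <- function(trials,
                           procedure = c("showup", "simultaneous", "sequential_any", "2afc"),
                           f_max = 0.10, n_boot = 2000, criteria = NULL,
                           rule = "absolute", delta = 0.15,
                           ta_convention = c("divide_by_n", "designated_innocent"),
                           conf_level = 0.95, seed = NULL) {
  procedure <- match.arg(procedure)
  ta_convention <- match.arg(ta_convention)
  n_boot <- .check_count(n_boot, "n_boot", min = 2)
  criteria <- if (procedure == "2afc" && is.null(criteria)) {
    .afc_sweep(attr(trials, "model"))
  } else {
    .default_criteria(trials, criteria)
  }
  pool <- .pool_from_trials(trials)
  s <- switch(procedure,
    showup = {
      if (pool$N != 1L) stop("showup pools must have lineup_size = 1.", call. = FALSE)
      list(dv_tp = as.vector(pool$tp), win_tp = rep(TRUE, nrow(pool$tp)),
           dv_ta = as.vector(pool$ta), win_ta = rep(TRUE, nrow(pool$ta)),
           N = 1L)
    },
    simultaneous = .decision_summary(pool, rule, delta),
    sequential_any = .decision_summary(pool, "absolute"),
    `2afc` = {
      if (pool$N != 2L) stop("2AFC pools must have lineup_size = 2.", call. = FALSE)
      g <- pool$tp[cbind(seq_len(nrow(pool$tp)), pool$guilty_pos)]
      l <- pool$tp[cbind(seq_len(nrow(pool$tp)), 3L - pool$guilty_pos)]
      list(dv_tp = g - l, win_tp = rep(TRUE, nrow(pool$tp)),
           dv_ta = l - g, win_ta = rep(TRUE, nrow(pool$tp)), N = 1L)
    }
  )
  n_tp <- length(s$dv_tp)
  n_ta <- length(s$dv_ta)
  if (n_tp < 1L || n_ta < 1L) {
    stop("both TP and TA pools must be non-empty.", call. = FALSE)
  }
  crit_desc <- sort(criteria, decreasing = TRUE)
  divide_n <- if (ta_convention == "divide_by_n") s$N else 1L

  pauc_of <- function(dv_tp, win_tp, dv_ta, win_ta) {
    sw <- sort(dv_tp[win_tp])
    h <- (length(sw) - findInterval(crit_desc, sw)) / n_tp
    sa <- if (ta_convention == "divide_by_n") sort(dv_ta) else sort(dv_ta[win_ta])
    f <- (length(sa) - findInterval(crit_desc, sa)) / n_ta / divide_n
    .pauc_fh(f, h, f_max, warn = FALSE)
  }

  run <- function() {
    reps <- vapply(seq_len(n_boot), function(b) {
      itp <- sample.int(n_tp, replace = TRUE)
      ita <- sample.int(n_ta, replace = TRUE)
      pauc_of(s$dv_tp[itp], s$win_tp[itp], s$dv_ta[ita], s$win_ta[ita])
    }, numeric(1))
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  structure(
    list(
      pauc = pauc_of(s$dv_tp, s$win_tp, s$dv_ta, s$win_ta),
      f_max = f_max, ci_low = ci[1], ci_high = ci[2],
      n_boot = n_boot, n_tp = n_tp, n_ta = n_ta,
      conf_level = conf_level, procedure = procedure,
      replicates = reps, seed = seed
    ),
    class = "pauc_boot"
  )
}

#' @export
print.pauc_boot <- function(x, ...) {
  cat(sprintf(
    "<pauc_boot> %s: pAUC = %.5f over F in [0, %.2f], %g%% CI [%.5f, %.5f] (%d boot, %d TP / %d TA)\n",
    x$procedure, x$pauc, x$f_max, 100 * x$conf_level,
    x$ci_low, x$ci_high, x$n_boot, x$n_tp, x$n_ta
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bootstrap_pauc
#' @param x A `pauc_boot` object.
#' @param ... Unused.
#' @export
tidy.pauc_boot <- function(x, ...) {
  tibble::tibble(
    estimate = x$pauc,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @rdname bootstrap_pauc
#' @export
glance.pauc_boot <- function(x, ...) {
  tibble::tibble(
    procedure = x$procedure, f_max = x$f_max, conf.level = x$conf_level,
    n_boot = x$n_boot, n_tp = x$n_tp, n_ta = x$n_ta
  )
}
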