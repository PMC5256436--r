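#' Replicate a canonical simulation experiment
#'
#' Orchestrates the package's standard simulation studies end to end:
#' sampling, criterion sweeps, bootstrap, and tabular output, with a single
#' seed and a full configuration echo so any bundle can be re-run exactly.
#'
#' @details
#' The named experiments are:
#' * `"roc_tasks"` -- ROCs for five tasks at the same true discriminability:
#'   showup, simultaneous lineups of size 2, 3 and 6 (absolute rule,
#'   TA rates divided by lineup size), and 2AFC.
#' * `"pauc_ci"` -- partial AUCs with bootstrap CIs for the showup and the
#'   six-person lineup at each `d_prime_levels` value and each `f_max`.
#' * `"diagnosticity"` -- analytic diagnosticity-versus-bias curves at fixed
#'   AUC levels (no simulation).
#' * `"info_gain"` -- Bayesian posterior-of-guilt and information-gain curves
#'   for each combination of `bayes_d_primes` and criterion `offsets`.
#' * `"decision_rules"` -- absolute, relative-reject and relative-guess rules
#'   for the six-person simultaneous lineup on one shared trial pool.
#' * `"seq_vs_sim"` -- simultaneous (absolute) versus sequential (first-ID
#'   and any-ID stopping rules) six-person lineups on one shared pool,
#'   including the nonmonotone first-ID branch.
#'
#' @param figure Experiment name (see Details).
#' @param model Evidence model for the simulated tasks (default
#'   `evidence_model(1.5)`, equal variance).
#' @param n_trials Trials per trial type and condition (default 10000).
#' @param n_boot Bootstrap replicates for `"pauc_ci"` (default 2000).
#' @param f_max Partial-area limits for `"pauc_ci"` (default 0.10 and 0.16).
#' @param delta Relative-rule margin (default 0.15).
#' @param lineup_sizes Sizes for `"roc_tasks"` (default 1, 2, 3, 6; 1 is the
#'   showup).
#' @param d_prime_levels Discriminability levels for `"pauc_ci"` (default
#'   1.0, 1.5, 2.0).
#' @param bayes_d_primes,offsets Curve families for `"info_gain"`.
#' @param sweep_points Criterion-grid resolution (default 161).
#' @param seed Integer seed for all sampling in the experiment.
#' @param out_dir Optional directory: each table is written as CSV (with the
#'   seed echoed in a `seed` column) plus a `config.json` echo.
#'
#' @return An object of class `lineup_experiment`: a list with elements
#'   `figure`, `config` and `tables` (named tibbles).
#' @examples
#' ex <- replicate_figure("decision_rules", n_trials = 500, seed = 1)
#' names(ex$tables)
#' @export
replicate_figure <- function(figure = c("roc_tasks", "pauc_ci", "diagnosticity",
                                        "info_gain", "decision_rules", "seq_vs_sim"),
                             model = evidence_model(1.5),
                             n_trials = 10000, n_boot = 2000,
                             f_max = c(0.10, 0.16), delta = 0.15,
                             lineup_sizes = c(1, 2, 3, 6),
                             d_prime_levels = c(1.0, 1.5, 2.0),
                             bayes_d_primes = c(1.0, 1.5),
                             offsets = c(0, 1),
                             sweep_points = 161,
                             seed = 1, out_dir = NULL) {
  figure <- match.arg(figure)
  stopifnot(inherits(model, "evidence_model"))
  seed <- .check_count(seed, "seed", min = 0)
  config <- list(
    figure = figure, d_prime = model$d_prime, sigma_guilty = model$sigma_guilty,
    n_trials = n_trials, n_boot = n_boot, f_max = f_max, delta = delta,
    lineup_sizes = lineup_sizes, d_prime_levels = d_prime_levels,
    bayes_d_primes = bayes_d_primes, offsets = offsets,
    sweep_points = sweep_points, seed = seed
  )

  tables <- withr::with_seed(seed, switch(
    figure,
    roc_tasks = {
      sweeps <- criterion_sweep(model, n = sweep_points)
      rates <- purrr::map_dfr(lineup_sizes, function(N) {
        pool <- sample_trials(model, n_trials, n_trials, lineup_size = N)
        if (N == 1) run_showup(pool, sweeps) else run_simultaneous(pool, sweeps)
      })
      pairs <- sample_trials(model, n_trials, 0, lineup_size = 2)
      list(rates = dplyr::bind_rows(rates, run_2afc(pairs)),
           analytic_2afc = roc_2afc_analytic(model))
    },
    pauc_ci = {
      rows <- purrr::map_dfr(d_prime_levels, function(d) {
        m <- evidence_model(d, model$sigma_guilty)
        show_pool <- sample_trials(m, n_trials, n_trials, lineup_size = 1)
        line_pool <- sample_trials(m, n_trials, n_trials, lineup_size = 6)
        purrr::map_dfr(f_max, function(fm) {
          bs <- bootstrap_pauc(show_pool, "showup", f_max = fm, n_boot = n_boot)
          bl <- bootstrap_pauc(line_pool, "simultaneous", f_max = fm,
                               n_boot = n_boot)
          dplyr::bind_rows(
            dplyr::mutate(tidy(bs), procedure = "showup"),
            dplyr::mutate(tidy(bl), procedure = "lineup6")
          ) |>
            dplyr::mutate(d_prime = d, f_max = fm, n_boot = n_boot)
        })
      })
      list(pauc = rows)
    },
    diagnosticity = list(curves = diagnosticity_bias_curves()),
    info_gain = {
      curves <- purrr::map_dfr(bayes_d_primes, function(d) {
        information_gain_curve(evidence_model(d, model$sigma_guilty),
                               offsets = offsets)
      })
      list(curves = curves)
    },
    decision_rules = {
      pool <- sample_trials(model, n_trials, n_trials, lineup_size = 6)
      sweeps <- criterion_sweep(model, n = sweep_points)
      list(rates = dplyr::bind_rows(
        run_simultaneous(pool, sweeps, rule = "absolute"),
        run_simultaneous(pool, sweeps, rule = "relative_reject", delta = delta),
        run_simultaneous(pool, sweeps, rule = "relative_guess", delta = delta)
      ))
    },
    seq_vs_sim = {
      pool <- sample_trials(model, n_trials, n_trials, lineup_size = 6)
      sweeps <- criterion_sweep(model, n = sweep_points)
      list(rates = dplyr::bind_rows(
        run_simultaneous(pool, sweeps, rule = "absolute"),
        run_sequential(pool, sweeps, variant = "first_id"),
        run_sequential(pool, sweeps, variant = "any_id")
      ))
    }
  ))

  out <- structure(list(figure = figure, config = config, tables = tables),
                   class = "lineup_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      readr::write_csv(dplyr::mutate(tables[[nm]], seed = seed),
                       file.path(out_dir, paste0(figure, "_", nm, ".csv")))
    }
    jsonlite::write_json(config, file.path(out_dir, paste0(figure, "_config.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.lineup_experiment <- function(x, ...) {
  cat(sprintf("<lineup_experiment> %s (seed %d)\n", x$figure, x$config$seed))
  for (nm in names(x$tables)) {
    cat(sprintf("  $tables$%s: %d x %d\n", nm, nrow(x$tables[[nm]]),
                ncol(x$tables[[nm]])))
  }
  invisible(x)
}
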