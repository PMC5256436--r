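#' Simulated identification procedures
#'
#' @description
#' Each `run_*()` function takes a trial pool from [sample_trials()] and a set
#' of decision criteria (a sweep grid or a fixed confidence scale) and returns
#' a *rate table*: one row per criterion with the response-category rates for
#' target-present (TP) and target-absent (TA) trials.
#'
#' * `run_showup()` -- single-photo procedure: a positive identification is
#'   made whenever the sampled strength exceeds the criterion.
#' * `run_simultaneous()` -- all photos at once. Under the `absolute` rule the
#'   strongest above-criterion photo is identified. Under `relative_reject`
#'   an identification additionally requires the strongest photo to exceed
#'   the runner-up by at least `delta`; otherwise the lineup is rejected.
#'   Under `relative_guess` a too-small margin leads instead to a uniform
#'   guess between the two strongest photos.
#' * `run_sequential()` -- photos one at a time in the pool's position order
#'   (randomized per trial at sampling time). `first_id`: the first
#'   above-criterion photo is identified and the procedure stops (single
#'   lap). `any_id`: every above-criterion photo is flagged and the strongest
#'   flagged photo is the final choice.
#'
#' In a TA lineup any of the `N` fillers can be identified; under the default
#' `divide_by_n` convention the innocent-*suspect* false-ID rate is the TA
#' identification rate divided by `N`. Under `designated_innocent`, position 1
#' of every TA trial plays the innocent suspect and `F` is the rate of
#' identifying that position.
#'
#' Rates at the j-th criterion of a fixed confidence scale equal the
#' cumulative rates of responses at confidence levels `> j` (see
#' [assign_confidence()]), so the same functions serve sweep mode and
#' confidence-rated mode.
#'
#' @param trials Trial pool from [sample_trials()]; all functions reuse the
#'   same evidence values at every criterion.
#' @param criteria Criterion locations. Defaults to [criterion_sweep()] of the
#'   pool's evidence model.
#' @param rule Decision rule for the simultaneous lineup.
#' @param delta Minimum winning margin for the relative rules (ignored by the
#'   absolute rule). Default 0.15.
#' @param ta_convention How the TA suspect false-ID rate is formed (see
#'   above).
#' @param variant Stopping rule for the sequential lineup.
#'
#' @return A tibble of class `rate_table` with columns `procedure`, `rule`,
#'   `lineup_size`, `d_prime`, `sigma_guilty`, `criterion`, `H`, `F`,
#'   `filler_id_rate_tp`, `rejection_rate_tp`, `filler_id_rate_ta`,
#'   `rejection_rate_ta`, `n_tp`, `n_ta`. `H` is the TP suspect-ID (hit)
#'   rate; `F` the TA innocent-suspect ID rate.
#' @examples
#' pool <- sample_trials(evidence_model(1.5), 500, 500, lineup_size = 6, seed = 1)
#' rates <- run_simultaneous(pool)
#' head(roc_points(rates))
#' @name procedures
NULL

#' @rdname procedures
#' @export
run_showup <- function(trials, criteria = NULL) {
  criteria <- .default_criteria(trials, criteria)
  pool <- .pool_from_trials(trials)
  if (pool$N != 1L) stop("a showup pool must have lineup_size = 1.", call. = FALSE)
  s <- list(
    dv_tp = as.vector(pool$tp), win_tp = rep(TRUE, nrow(pool$tp)),
    dv_ta = as.vector(pool$ta), win_ta = rep(TRUE, nrow(pool$ta)),
    N = 1L
  )
  .rate_table(.rates_from_summary(s, criteria, "divide_by_n"),
              "showup", "absolute", pool)
}

#' @rdname procedures
#' @export
run_simultaneous <- function(trials, criteria = NULL,
                             rule = c("absolute", "relative_reject", "relative_guess"),
                             delta = 0.15,
                             ta_convention = c("divide_by_n", "designated_innocent")) {
  rule <- match.arg(rule)
  ta_convention <- match.arg(ta_convention)
  criteria <- .default_criteria(trials, criteria)
  pool <- .pool_from_trials(trials)
  if (pool$N == 1L) return(run_showup(trials, criteria))
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("`delta` must be a single non-negative number.", call. = FALSE)
  }
  s <- .decision_summary(pool, rule, delta)
  .rate_table(.rates_from_summary(s, criteria, ta_convention),
              "simultaneous", rule, pool)
}

#' @rdname procedures
#' @export
run_sequential <- function(trials, criteria = NULL,
                           variant = c("first_id", "any_id"),
                           ta_convention = c("divide_by_n", "designated_innocent")) {
  variant <- match.arg(variant)
  ta_convention <- match.arg(ta_convention)
  criteria <- .default_criteria(trials, criteria)
  pool <- .pool_from_trials(trials)
  walker <- if (variant == "first_id") .walk_first_id else .walk_any_id
  rows <- purrr::map_dfr(criteria, function(cc) {
    tp <- walker(pool$tp, cc)
    ta <- walker(pool$ta, cc)
    n_tp <- nrow(pool$tp)
    n_ta <- nrow(pool$ta)
    hit <- mean(tp$chosen == pool$guilty_pos & tp$chosen > 0L)
    filler_tp <- mean(tp$chosen > 0L) - hit
    id_ta <- ta$chosen > 0L
    if (ta_convention == "divide_by_n") {
      f <- mean(id_ta) / pool$N
      filler_ta <- mean(id_ta) * (pool$N - 1) / pool$N
    } else {
      f <- mean(ta$chosen == 1L)
      filler_ta <- mean(id_ta) - f
    }
    tibble::tibble(
      criterion = cc, H = hit, F = f,
      filler_id_rate_tp = filler_tp, rejection_rate_tp = 1 - hit - filler_tp,
      filler_id_rate_ta = filler_ta, rejection_rate_ta = 1 - mean(id_ta),
      n_tp = n_tp, n_ta = n_ta
    )
  })
  .rate_table(rows, "sequential", variant, pool)
}

#' Two-alternative forced choice on a target--lure pair
#'
#' Models the 2AFC task as a decision on the strength *difference*
#' target minus lure, distributed `N(d', sqrt(1 + sigma_guilty^2))`. The
#' rating ROC is swept on that difference: the hit rate is the probability of
#' an above-criterion preference for the target when the target leads, and
#' the false alarm rate is the probability of an equally strong preference
#' for the lure (the mirrored presentation of the same pairs, difference
#' `N(-d', .)`). The hit rate at criterion 0 is the classic 2AFC proportion
#' correct `pnorm(d'/sqrt(1 + sigma_guilty^2))`.
#'
#' @param trials TP trials of `lineup_size = 2` from [sample_trials()] (one
#'   guilty target, one filler lure per trial); TA rows are ignored.
#' @param criteria Criterion locations on the difference scale; by default a
#'   161-point symmetric grid covering both difference distributions.
#' @return A `rate_table` tibble (filler columns are `NA`: a 2AFC trial has
#'   no reject option).
#' @examples
#' pairs <- sample_trials(evidence_model(1.5), 1000, 0, lineup_size = 2, seed = 1)
#' rates <- run_2afc(pairs)
#' rates$H[rates$criterion == 0]  # ~ pnorm(1.5 / sqrt(2)), proportion correct
#' @export
run_2afc <- function(trials, criteria = NULL) {
  pool <- .pool_from_trials(trials)
  if (pool$N != 2L) stop("2AFC pools must have lineup_size = 2.", call. = FALSE)
  if (nrow(pool$tp) < 1L) stop("2AFC needs target-present pairs.", call. = FALSE)
  model <- pool$model
  if (is.null(criteria)) {
    if (is.null(model)) stop("supply `criteria` or a pool with a model.", call. = FALSE)
    criteria <- .afc_sweep(model)
  } else {
    criteria <- criterion_set(criteria)
  }
  g <- pool$tp[cbind(seq_len(nrow(pool$tp)), pool$guilty_pos)]
  l <- pool$tp[cbind(seq_len(nrow(pool$tp)), 3L - pool$guilty_pos)]
  d <- g - l
  s <- list(dv_tp = d, win_tp = rep(TRUE, length(d)),
            dv_ta = -d, win_ta = rep(TRUE, length(d)), N = 1L)
  out <- .rates_from_summary(s, criteria, "divide_by_n")
  out$filler_id_rate_tp <- NA_real_
  out$filler_id_rate_ta <- NA_real_
  .rate_table(out, "2afc", "difference", pool)
}

#' Analytic 2AFC rating ROC
#'
#' Closed-form counterpart of [run_2afc()]: `H = pnorm((d' - c)/s_d)` and
#' `F = pnorm((-d' - c)/s_d)` with `s_d = sqrt(1 + sigma_guilty^2)`. The full
#' area under this curve is `pnorm(2 d' / sqrt(2 (1 + sigma_guilty^2)))`.
#'
#' @inheritParams run_2afc
#' @param model An [evidence_model()].
#' @return A tibble with columns `criterion`, `F`, `H`.
#' @export
roc_2afc_analytic <- function(model, criteria = NULL) {
  stopifnot(inherits(model, "evidence_model"))
  if (is.null(criteria)) criteria <- .afc_sweep(model)
  sd2 <- sqrt(1 + model$sigma_guilty^2)
  tibble::tibble(
    criterion = criteria,
    F = stats::pnorm((-model$d_prime - criteria) / sd2),
    H = stats::pnorm((model$d_prime - criteria) / sd2)
  )
}

# --- internal ---------------------------------------------------------------

.afc_sweep <- function(model, n = 161) {
  sd2 <- sqrt(1 + model$sigma_guilty^2)
  hw <- abs(model$d_prime) + 3 * sd2
  seq(-hw, hw, length.out = n)
}

# Per-trial decision variable + suspect-win flags for threshold-style rules.
# Every rule here reduces to "identify iff dv > criterion; the identified
# photo is the suspect iff win". The first_id sequential rule does not reduce
# this way and is handled by .walk_first_id().
.decision_summary <- function(pool, rule, delta = 0.15) {
  tp <- .top_two(pool$tp)
  ta <- .top_two(pool$ta)
  win_tp <- tp$idx1 == pool$guilty_pos
  win_ta <- ta$idx1 == 1L  # designated innocent sits at position 1
  dv_tp <- tp$top1
  dv_ta <- ta$top1
  if (rule == "relative_reject") {
    # margin below delta -> rejection at every criterion
    dv_tp <- ifelse(tp$top1 - tp$top2 >= delta, tp$top1, -Inf)
    dv_ta <- ifelse(ta$top1 - ta$top2 >= delta, ta$top1, -Inf)
  } else if (rule == "relative_guess") {
    # margin below delta -> uniform guess between the two strongest; one coin
    # per trial so the whole sweep sees a single consistent witness
    guess_tp <- tp$top1 - tp$top2 < delta
    guess_ta <- ta$top1 - ta$top2 < delta
    pick2_tp <- stats::runif(length(guess_tp)) < 0.5
    pick2_ta <- stats::runif(length(guess_ta)) < 0.5
    chosen_tp <- ifelse(guess_tp & pick2_tp, tp$idx2, tp$idx1)
    chosen_ta <- ifelse(guess_ta & pick2_ta, ta$idx2, ta$idx1)
    win_tp <- chosen_tp == pool$guilty_pos
    win_ta <- chosen_ta == 1L
  }
  list(dv_tp = dv_tp, win_tp = win_tp, dv_ta = dv_ta, win_ta = win_ta,
       N = pool$N)
}

# Row-wise two largest values and their column indices, without apply().
.top_two <- function(m) {
  n <- nrow(m)
  top1 <- rep(-Inf, n); top2 <- rep(-Inf, n)
  idx1 <- rep(1L, n); idx2 <- rep(1L, n)
  for (j in seq_len(ncol(m))) {
    s <- m[, j]
    beats1 <- s > top1
    top2[beats1] <- top1[beats1]; idx2[beats1] <- idx1[beats1]
    top1[beats1] <- s[beats1]; idx1[beats1] <- j
    beats2 <- !beats1 & s > top2
    top2[beats2] <- s[beats2]; idx2[beats2] <- j
  }
  list(top1 = top1, top2 = top2, idx1 = idx1, idx2 = idx2)
}

# Counting-based rate computation shared with the bootstrap fast path.
.rates_from_summary <- function(s, criteria, ta_convention) {
  n_tp <- length(s$dv_tp)
  n_ta <- length(s$dv_ta)
  count_above <- function(x, crit) {
    sx <- sort(x)
    length(sx) - findInterval(crit, sx)
  }
  id_tp <- count_above(s$dv_tp, criteria) / max(n_tp, 1L)
  hit <- count_above(s$dv_tp[s$win_tp], criteria) / max(n_tp, 1L)
  id_ta <- count_above(s$dv_ta, criteria) / max(n_ta, 1L)
  if (ta_convention == "divide_by_n") {
    f <- id_ta / s$N
    filler_ta <- id_ta * (s$N - 1) / s$N
  } else {
    f <- count_above(s$dv_ta[s$win_ta], criteria) / max(n_ta, 1L)
    filler_ta <- id_ta - f
  }
  tibble::tibble(
    criterion = criteria, H = hit, F = f,
    filler_id_rate_tp = id_tp - hit, rejection_rate_tp = 1 - id_tp,
    filler_id_rate_ta = filler_ta, rejection_rate_ta = 1 - id_ta,
    n_tp = n_tp, n_ta = n_ta
  )
}

# Sequential, stop at first above-criterion photo (single lap).
.walk_first_id <- function(m, cc) {
  n <- nrow(m)
  chosen <- rep(0L, n)
  for (j in rev(seq_len(ncol(m)))) {
    chosen[m[, j] > cc] <- j
  }
  list(chosen = chosen)
}

# Sequential, all above-criterion photos flagged; strongest flagged photo is
# the final choice (walked in presentation order).
.walk_any_id <- function(m, cc) {
  n <- nrow(m)
  best <- rep(-Inf, n)
  chosen <- rep(0L, n)
  for (j in seq_len(ncol(m))) {
    s <- m[, j]
    f <- s > cc & s > best
    best[f] <- s[f]
    chosen[f] <- j
  }
  list(chosen = chosen)
}

.rate_table <- function(rows, procedure, rule, pool) {
  model <- pool$model
  out <- tibble::tibble(
    procedure = procedure, rule = rule, lineup_size = pool$N,
    d_prime = if (is.null(model)) NA_real_ else model$d_prime,
    sigma_guilty = if (is.null(model)) NA_real_ else model$sigma_guilty,
    rows
  )
  class(out) <- c("rate_table", class(out))
  attr(out, "seed") <- pool$seed
  out
}
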