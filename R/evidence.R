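#' Gaussian evidence model for identification decisions
#'
#' The signal-detection "world" every simulation in this package samples from.
#' Fillers and innocent suspects draw memory strengths from a standard normal
#' distribution, `N(0, 1)`; the guilty suspect draws from
#' `N(d_prime, sigma_guilty)`. The filler distribution is fixed by convention
#' and is not a parameter.
#'
#' @param d_prime Mean of the guilty-suspect strength distribution, in SD
#'   units of the filler distribution. The true discriminability of guilty
#'   from innocent faces. Typical values in simulation work are 0.5--2.
#' @param sigma_guilty Standard deviation of the guilty-suspect distribution;
#'   1 for equal-variance models, often 1.2 for unequal variance. Must be
#'   positive.
#'
#' @return An object of class `evidence_model`: a list with elements
#'   `d_prime` and `sigma_guilty`.
#' @examples
#' evidence_model(1.5)
#' evidence_model(2, sigma_guilty = 1.2)
#' @export
evidence_model <- function(d_prime, sigma_guilty = 1) {
  if (!is.numeric(d_prime) || length(d_prime) != 1L || !is.finite(d_prime)) {
    stop("`d_prime` must be a single finite number.", call. = FALSE)
  }
  if (!is.numeric(sigma_guilty) || length(sigma_guilty) != 1L ||
      !is.finite(sigma_guilty) || sigma_guilty <= 0) {
    stop("`sigma_guilty` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(d_prime = as.numeric(d_prime), sigma_guilty = as.numeric(sigma_guilty)),
    class = "evidence_model"
  )
}

#' @export
print.evidence_model <- function(x, ...) {
  cat(sprintf(
    "<evidence_model> guilty ~ N(%g, %g); fillers ~ N(0, 1)\n",
    x$d_prime, x$sigma_guilty
  ))
  invisible(x)
}

#' The fixed seven-criterion confidence scale
#'
#' The set of decision criteria `{0.18, 0.23, 0.27, 0.39, 0.67, 1.15, 1.53}`
#' used in earlier simulation work on showups and lineups. Any strength above
#' the lowest criterion (0.18) counts as a positive identification; the
#' criteria partition the strength axis into confidence bins (see
#' [assign_confidence()]).
#'
#' @return A strictly increasing numeric vector of length 7.
#' @export
lampinen_criteria <- function() {
  c(0.18, 0.23, 0.27, 0.39, 0.67, 1.15, 1.53)
}

#' Validate a set of decision criteria
#'
#' @param criteria Numeric vector of criterion locations; must be finite and
#'   strictly increasing, with at least one element.
#' @return The criteria as a plain numeric vector, invisibly validated.
#' @export
criterion_set <- function(criteria) {
  if (!is.numeric(criteria) || length(criteria) < 1L || anyNA(criteria) ||
      any(!is.finite(criteria))) {
    stop("`criteria` must be a non-empty vector of finite numbers.", call. = FALSE)
  }
  if (length(criteria) > 1L && any(diff(criteria) <= 0)) {
    stop("`criteria` must be strictly increasing.", call. = FALSE)
  }
  as.numeric(criteria)
}

#' Default criterion sweep grid for mapping a full ROC
#'
#' Evenly spaced criterion locations spanning from well below the filler
#' distribution to well above the guilty-suspect distribution, so the swept
#' ROC runs from the (0, 0) corner to its liberal endpoint.
#'
#' @param model An [evidence_model()].
#' @param n Number of grid points (default 161).
#' @param lower,upper Grid end points. By default `lower = -3` and
#'   `upper = d_prime + 3 * max(1, sigma_guilty)`.
#' @return Numeric vector of length `n`, increasing.
#' @export
criterion_sweep <- function(model, n = 161, lower = -3, upper = NULL) {
  stopifnot(inherits(model, "evidence_model"))
  if (is.null(upper)) {
    upper <- model$d_prime + 3 * max(1, model$sigma_guilty)
  }
  seq(lower, upper, length.out = n)
}

#' Map memory strengths to confidence levels
#'
#' Confidence is the 1-based index of the interval the strength falls into:
#' a strength between the fifth and sixth criteria is level 6, one above the
#' highest of `k` criteria is level `k + 1`, and one at or below the lowest
#' criterion is level 1, meaning *no identification*. A strength exactly equal
#' to a criterion falls in the lower interval (identification requires
#' strictly exceeding the lowest criterion). Positive identification is
#' therefore `confidence >= 2`.
#'
#' @param strength Numeric vector of memory strengths.
#' @param criteria Strictly increasing criterion locations (see
#'   [criterion_set()]); defaults to [lampinen_criteria()].
#' @return Integer vector of confidence levels in `1..(length(criteria) + 1)`.
#' @examples
#' assign_confidence(1.0)  # between the 5th and 6th criteria -> level 6
#' assign_confidence(0.1)  # below the lowest criterion -> level 1, no ID
#' @export
assign_confidence <- function(strength, criteria = lampinen_criteria()) {
  criteria <- criterion_set(criteria)
  findInterval(strength, criteria, left.open = TRUE) + 1L
}

#' Sample a pool of identification trials
#'
#' Draws independent memory strengths for `n_tp` target-present (TP) and
#' `n_ta` target-absent (TA) trials of a given lineup size. Each TP trial
#' contains exactly one draw from the guilty-suspect distribution, placed at a
#' uniformly random position; all other draws are fillers from `N(0, 1)`. TA
#' trials are all fillers. The position order doubles as the presentation
#' order for sequential procedures.
#'
#' The returned pool is meant to be sampled once per condition and reused
#' across an entire criterion sweep, so that every operating point of an ROC
#' (and every procedure compared on it) sees the very same evidence values.
#'
#' @param model An [evidence_model()].
#' @param n_tp,n_ta Number of target-present / target-absent trials.
#' @param lineup_size Number of photographs per trial; 1 is a showup.
#' @param seed Optional integer seed. If supplied, sampling happens in a local
#'   RNG scope (via [withr::with_seed()]) and the seed is recorded in the
#'   result's attributes.
#'
#' @return A tibble with one row per photograph and columns `trial_id`,
#'   `trial_type` (`"tp"`/`"ta"`), `lineup_size`, `position`, `strength`,
#'   `is_guilty`, carrying the generating `model` and `seed` as attributes.
#' @examples
#' trials <- sample_trials(evidence_model(1.5), n_tp = 100, n_ta = 100,
#'                         lineup_size = 6, seed = 1)
#' dplyr::count(trials, trial_type, is_guilty)
#' @export
sample_trials <- function(model, n_tp, n_ta, lineup_size = 6, seed = NULL) {
  stopifnot(inherits(model, "evidence_model"))
  n_tp <- .check_count(n_tp, "n_tp", min = 0)
  n_ta <- .check_count(n_ta, "n_ta", min = 0)
  if (n_tp + n_ta < 1L) stop("need at least one trial.", call. = FALSE)
  N <- .check_count(lineup_size, "lineup_size", min = 1)

  draw <- function() {
    guilty_pos <- if (n_tp > 0) sample.int(N, n_tp, replace = TRUE) else integer()
    tp <- matrix(stats::rnorm(n_tp * N), nrow = n_tp, ncol = N)
    if (n_tp > 0) {
      tp[cbind(seq_len(n_tp), guilty_pos)] <-
        stats::rnorm(n_tp, mean = model$d_prime, sd = model$sigma_guilty)
    }
    ta <- matrix(stats::rnorm(n_ta * N), nrow = n_ta, ncol = N)
    list(tp = tp, ta = ta, guilty_pos = guilty_pos)
  }
  drawn <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  tp_tbl <- if (n_tp > 0) {
    tibble::tibble(
      trial_id = rep(seq_len(n_tp), each = N),
      trial_type = "tp",
      lineup_size = N,
      position = rep(seq_len(N), times = n_tp),
      strength = as.vector(t(drawn$tp)),
      is_guilty = rep(seq_len(N), times = n_tp) ==
        rep(drawn$guilty_pos, each = N)
    )
  } else {
    NULL
  }
  ta_tbl <- if (n_ta > 0) {
    tibble::tibble(
      trial_id = rep(n_tp + seq_len(n_ta), each = N),
      trial_type = "ta",
      lineup_size = N,
      position = rep(seq_len(N), times = n_ta),
      strength = as.vector(t(drawn$ta)),
      is_guilty = FALSE
    )
  } else {
    NULL
  }
  out <- dplyr::bind_rows(tp_tbl, ta_tbl)
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  out
}

#' Write / read a trial pool as CSV
#'
#' Thin [readr] wrappers for the on-disk trial-table format (`trial_id`,
#' `trial_type`, `lineup_size`, `position`, `strength`, `is_guilty`). Model
#' parameters are not stored in the CSV; pass them again on read if downstream
#' code needs a default criterion sweep.
#'
#' @param trials A trial tibble from [sample_trials()].
#' @param path File path.
#' @param model Optional [evidence_model()] to attach on read.
#' @return `write_trials()` returns `trials` invisibly; `read_trials()`
#'   returns the trial tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, c("trial_id", "trial_type", "lineup_size",
                              "position", "strength", "is_guilty")], path)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, model = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial_id = readr::col_integer(),
                           trial_type = readr::col_character(),
                           lineup_size = readr::col_integer(),
                           position = readr::col_integer(),
                           strength = readr::col_double(),
                           is_guilty = readr::col_logical()
                         ))
  if (!is.null(model)) attr(out, "model") <- model
  out
}

# --- internal ---------------------------------------------------------------

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d.", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Reshape a long trial tibble into per-trial strength matrices.
.pool_from_trials <- function(trials) {
  required <- c("trial_id", "trial_type", "position", "strength", "is_guilty")
  if (!all(required %in% names(trials))) {
    stop("`trials` must contain columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  N <- unique(trials$lineup_size)
  if (length(N) != 1L) stop("`trials` mixes lineup sizes.", call. = FALSE)
  mat_for <- function(type) {
    sub <- trials[trials$trial_type == type, ]
    if (nrow(sub) == 0L) {
      return(list(m = matrix(numeric(), 0, N), guilty_pos = integer()))
    }
    o <- order(sub$trial_id, sub$position)
    sub <- sub[o, ]
    m <- matrix(sub$strength, ncol = N, byrow = TRUE)
    gp <- if (any(sub$is_guilty)) {
      matrix(sub$is_guilty, ncol = N, byrow = TRUE)
    } else {
      NULL
    }
    guilty_pos <- if (is.null(gp)) integer() else max.col(gp, ties.method = "first")
    list(m = m, guilty_pos = guilty_pos)
  }
  if (any(trials$trial_type == "tp")) {
    sub <- trials[trials$trial_type == "tp", ]
    per_trial <- tapply(sub$is_guilty, sub$trial_id, sum)
    if (any(per_trial != 1L)) {
      stop("every TP trial must contain exactly one guilty sample.", call. = FALSE)
    }
  }
  tp <- mat_for("tp")
  ta <- mat_for("ta")
  list(
    tp = tp$m, ta = ta$m, guilty_pos = tp$guilty_pos, N = N,
    model = attr(trials, "model"), seed = attr(trials, "seed")
  )
}

.default_criteria <- function(trials, criteria) {
  if (!is.null(criteria)) return(criterion_set(criteria))
  model <- attr(trials, "model")
  if (is.null(model)) {
    stop("supply `criteria`, or a trial pool carrying its evidence model.",
         call. = FALSE)
  }
  criterion_sweep(model)
}
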