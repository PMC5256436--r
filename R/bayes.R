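#' Posterior probability of guilt after a witness response
#'
#' Bayes' rule applied to an identification outcome. With prior (base rate)
#' `b` that the lineup contains the guilty suspect, hit rate `H` and innocent
#' suspect false-ID rate `F`:
#' * after a suspect identification: `b H / (b H + (1 - b) F)`;
#' * after a non-identification (filler pick or rejection pooled):
#'   `b (1 - H) / (b (1 - H) + (1 - b)(1 - F))`.
#' A 0/0 denominator (a response that can occur under neither hypothesis)
#' returns the prior unchanged.
#'
#' @param base_rate Prior probability the lineup contains the guilty suspect,
#'   in `[0, 1]`.
#' @param H,F Hit and innocent-suspect false alarm rates in `[0, 1]`.
#' @param response `"id"` for a suspect identification, `"no_id"` for a
#'   filler identification or lineup rejection.
#' @return Numeric vector of posterior probabilities (inputs recycle).
#' @examples
#' posterior_guilt(0.5, H = 0.69, F = 0.16, response = "id")  # ~0.812
#' @export
posterior_guilt <- function(base_rate, H, F, response = c("id", "no_id")) {
  response <- match.arg(response)
  if (any(base_rate < 0 | base_rate > 1, na.rm = TRUE)) {
    stop("`base_rate` must lie in [0, 1].", call. = FALSE)
  }
  if (any(H < 0 | H > 1, na.rm = TRUE) || any(F < 0 | F > 1, na.rm = TRUE)) {
    stop("`H` and `F` must lie in [0, 1].", call. = FALSE)
  }
  if (response == "id") {
    num <- base_rate * H
    den <- num + (1 - base_rate) * F
  } else {
    num <- base_rate * (1 - H)
    den <- num + (1 - base_rate) * (1 - F)
  }
  out <- num / den
  ifelse(den == 0, base_rate, out)
}

#' Posterior-of-guilt and information-gain curves over the base rate
#'
#' For a showup-style equal-rule criterion placed `k` standard deviations
#' above the guilty-suspect mean (criterion location `c = d' + k`; negative
#' `k` is liberal, positive conservative), the model implies
#' `H = pnorm(-k / sigma_guilty)` and `F = pnorm(-(d' + k))`. The curves give
#' the posterior probability of guilt after a suspect identification and
#' after a non-identification (filler pick or rejection pooled), plus the
#' *information gain* -- posterior minus base rate -- across the grid of
#' prior probabilities that the lineup contains the guilty suspect. Both
#' discriminability and response bias shape these curves, which is why
#' neither posterior measure isolates witness accuracy.
#'
#' @param model An [evidence_model()].
#' @param offsets Criterion offsets `k` from the guilty-suspect mean, in SD
#'   units of the filler distribution (default `c(0, 1)`; one curve family
#'   per offset).
#' @param base_rate Grid of prior probabilities in `[0, 1]`.
#' @return A tibble of class `bayes_curve` with columns `d_prime`, `k`,
#'   `criterion`, `H`, `F`, `base_rate`, `posterior_id`, `posterior_no_id`,
#'   `gain_id`, `gain_no_id`.
#' @examples
#' information_gain_curve(evidence_model(1.5), offsets = 1)
#' @export
information_gain_curve <- function(model, offsets = c(0, 1),
                                   base_rate = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(model, "evidence_model"))
  if (any(base_rate < 0 | base_rate > 1)) {
    stop("`base_rate` grid must lie in [0, 1].", call. = FALSE)
  }
  out <- tidyr::expand_grid(k = as.numeric(offsets),
                            base_rate = as.numeric(base_rate)) |>
    dplyr::mutate(
      d_prime = model$d_prime,
      criterion = model$d_prime + .data$k,
      H = stats::pnorm(-.data$k / model$sigma_guilty),
      F = stats::pnorm(-.data$criterion),
      posterior_id = posterior_guilt(.data$base_rate, .data$H, .data$F, "id"),
      posterior_no_id = posterior_guilt(.data$base_rate, .data$H, .data$F, "no_id"),
      gain_id = .data$posterior_id - .data$base_rate,
      gain_no_id = .data$posterior_no_id - .data$base_rate
    ) |>
    dplyr::select("d_prime", "k", "criterion", "H", "F", "base_rate",
                  "posterior_id", "posterior_no_id", "gain_id", "gain_no_id")
  class(out) <- c("bayes_curve", class(out))
  out
}
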