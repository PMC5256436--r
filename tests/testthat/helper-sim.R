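# Shared fixtures: small pools are sampled fresh per test with fixed seeds so
# the suite stays deterministic without stored data.

eq_model <- function(d = 1.5) evidence_model(d, sigma_guilty = 1)

# 4 * binomial SE tolerance for a rate estimated from n trials
rate_tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)
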