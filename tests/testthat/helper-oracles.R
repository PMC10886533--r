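# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain summations, literal formula transcriptions,
# and brute-force enumeration.

# random valid differential DVH on an irregular grid
random_dvh <- function(n_bins = sample(3:40, 1), max_dose = runif(1, 5, 40)) {
  edges <- c(0, sort(runif(n_bins, 0, max_dose)))
  vols <- runif(n_bins, 0, 100)
  dvh("random", edges, vols)
}

# brute-force generalized mean of bin-midpoint doses
gmean_oracle <- function(d, a) {
  v <- d$bin_volume / sum(d$bin_volume)
  mids <- (d$edges[-length(d$edges)] + d$edges[-1]) / 2
  s <- 0
  for (i in seq_along(v)) s <- s + v[i] * mids[i]^a
  s^(1 / a)
}

# literal transcription of the mechanistic risk-equivalent dose formula
mech_oracle <- function(D, d, alpha, R, ab = 3) {
  ap <- alpha * (1 + d / ab)
  exp(-ap * D) / (ap * R) *
    (1 - 2 * R + R^2 * exp(ap * D) - (1 - R)^2 * exp(-ap * R * D / (1 - R)))
}

# brute-force bin loop for the organ equivalent dose
oed_loop_oracle <- function(d, params, n_fractions) {
  v <- d$bin_volume / sum(d$bin_volume)
  mids <- (d$edges[-length(d$edges)] + d$edges[-1]) / 2
  tot <- 0
  for (i in seq_along(v))
    tot <- tot + v[i] * red(mids[i], mids[i] / n_fractions, params)
  tot
}

# year-by-year lifetime-risk accumulation
lar_loop_oracle <- function(oed_value, params, agex, projection = 70,
                            latency = 5) {
  tot <- 0
  a <- agex + latency
  while (a <= projection) {
    mu <- exp(params$gamma_e * (agex - 30) + params$gamma_a * log(a / 70))
    tot <- tot + params$beta_ear * oed_value * mu / 1e4
    a <- a + 1
  }
  100 * tot
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
# (valid for untied nonzero differences)
wilcoxon_enum_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  w_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (w_obs > n * (n + 1) / 4) p <- 2 * mean(w_all >= w_obs)
  else p <- 2 * mean(w_all <= w_obs)
  min(1, p)
}
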