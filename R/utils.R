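# Internal numeric helpers shared across modules.

# Population-moment skewness g1 = m3 / m2^(3/2); a constant sample is
# reported as 0 so degenerate phantoms do not poison feature tables.
sample_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < .Machine$double.eps) return(0)
  e1071::skewness(x, type = 1)
}

# Excess kurtosis g2 = m4 / m2^2 - 3 (normal -> 0); constant sample -> 0.
sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < .Machine$double.eps) return(0)
  e1071::kurtosis(x, type = 1)
}

# Population standard deviation sqrt(m2) to match the moment conventions.
sample_std <- function(x) sqrt(mean((x - mean(x))^2))

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
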