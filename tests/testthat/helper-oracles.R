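# Brute-force reference for the k-of-n deregulation rule: walk the animals
# one by one and tally threshold exceedances directly. Kept deliberately
# naive and independent of the vectorized caller it cross-checks.
brute_force_call <- function(values, threshold = 1, min_qualifying = 4) {
  n_up <- 0L
  n_down <- 0L
  for (x in values) {
    if (is.na(x)) next
    if (x >= threshold) n_up <- n_up + 1L
    if (x <= -threshold) n_down <- n_down + 1L
  }
  if (n_up >= min_qualifying) "up"
  else if (n_down >= min_qualifying) "down"
  else "none"
}

# Random fold-change vectors that exercise boundaries and missingness.
random_fc_vectors <- function(n_vectors, n_animals = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_vectors), function(i) {
    v <- sample(c(
      stats::rnorm(n_animals, 0, 2),
      c(1, -1, 0.999, -0.999, 0, NA)
    ), n_animals)
    v
  })
}
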