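# Independent oracles used across test files. These deliberately use
# brute-force or numeric-integration routes, not the package's own code
# paths.

# HD weight for order statistic i of n at level q, by numeric
# integration of the Beta density over ((i-1)/n, i/n).
hd_weight_oracle <- function(i, n, q) {
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  integrate(function(u) dbeta(u, a, b), (i - 1) / n, i / n,
            rel.tol = 1e-12)$value
}

hd_oracle <- function(x, q) {
  n <- length(x)
  w <- vapply(seq_len(n), hd_weight_oracle, numeric(1), n = n, q = q)
  sum(w * sort(x))
}

# GMD by explicit enumeration of all ordered pairs.
gmd_oracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) s <- s + abs(x[i] - x[j])
  s / (n * (n - 1))
}

# Cliff's delta by explicit pair counting.
delta_oracle <- function(x, y) {
  gt <- lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

withr_like_tempdir <- function() {
  td <- tempfile("thermolimits-test-")
  dir.create(td)
  td
}

# Small standard synthetic cohort used by several pipeline tests.
make_small_cohort <- function(n_asd = 25, n_td = 20, seed = 11, ...) {
  cfg <- synthetic_config(n_asd = n_asd, n_td = n_td, seed = seed, ...)
  subjects <- generate_cohort(cfg)
  trials <- generate_trials(subjects, cfg)
  list(cfg = cfg, subjects = subjects, trials = trials)
}
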