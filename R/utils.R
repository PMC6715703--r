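# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_param(field, "must be a single number in [0, 1]")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_param(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

check_numeric_vec <- function(x, field, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len)
    stop(sprintf("`%s` must be numeric with at least %d value(s)",
                 field, min_len), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", field), call. = FALSE)
  as.numeric(x)
}

# Group-wise sums of `v` by integer index `g` in 1..len, zero-filled.
sum_by <- function(v, g, len) {
  out <- numeric(len)
  if (length(v)) {
    r <- rowsum(v, g)
    out[as.integer(rownames(r))] <- r
  }
  out
}

# Mean shift (in SD units, times sigma) between two homoskedastic normals
# that yields a population Cliff's delta of `delta`:
# delta = 2*Phi(shift/(sigma*sqrt(2))) - 1  =>  shift = sqrt(2)*qnorm((delta+1)/2)*sigma
delta_to_shift <- function(delta, sigma = 1) {
  if (!is.numeric(delta) || any(abs(delta) >= 1))
    stop_param("delta", "must lie strictly inside (-1, 1)")
  sqrt(2) * qnorm((delta + 1) / 2) * sigma
}
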