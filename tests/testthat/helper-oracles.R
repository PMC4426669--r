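# Independent oracles, deliberately coded differently from the package
# internals they check.

# Mann-Whitney U by direct pair counting (no ranks).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Exact two-sided p by bitmask enumeration of group assignments.
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  pool <- c(x, y)
  u_obs <- oracle_u(x, y)
  us <- c()
  for (mask in 0:(2^N - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(N - 1))) > 0)
    if (length(idx) != n) next
    us <- c(us, oracle_u(pool[idx], pool[-idx]))
  }
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Construct (x, y) with distinct values realizing a given U for sizes
# (n, m): each x_i sits above exactly a_i of the y values.
mw_instance <- function(n, m, u) {
  a <- integer(n)
  rem <- u
  for (i in seq_len(n)) {
    a[i] <- min(m, rem)
    rem <- rem - a[i]
  }
  stopifnot(rem == 0)
  # distinct x values strictly inside the (y_a, y_a+1) gaps
  list(x = a + seq_len(n) / (n + 1), y = seq_len(m))
}

# Weighted mean fraction of a normalized profile (for shift checks).
oracle_wmean <- function(profile, fractions) sum(fractions * profile)
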