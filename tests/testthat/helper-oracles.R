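# Intentionally naive reference implementations, kept independent of the
# package internals. They share mean()/min() with production (same
# floating-point evaluation order) but re-derive all indexing from scratch.

naive_sweep <- function(v, halfwidth, direction) {
  n <- length(v)
  positions <- if (direction == "left-to-right") 1:n else n:1
  for (j in positions) {
    a <- halfwidth
    if (j - 1 < a) a <- j - 1
    if (n - j < a) a <- n - j
    m <- mean(v[(j - a):(j + a)])
    if (m < v[j]) v[j] <- m
  }
  v
}

naive_suppress <- function(v, halfwidths) {
  for (hw in halfwidths) {
    v <- naive_sweep(v, hw, "left-to-right")
    v <- naive_sweep(v, hw, "right-to-left")
  }
  v
}

naive_subsample_min <- function(y, starts, ends) {
  out <- numeric(length(starts))
  for (j in seq_along(starts)) {
    m <- Inf
    for (k in starts[j]:ends[j]) if (y[k] < m) m <- y[k]
    out[j] <- m
  }
  out
}

# Closed-form ordinary least-squares straight line through y.
ols_line <- function(y) {
  x <- seq_along(y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  a + b * x
}

# Penalized Whittaker objective, evaluated directly.
whittaker_objective <- function(y, z, lambda_log10) {
  sum((y - z)^2) + 10^lambda_log10 * sum(diff(z, differences = 2)^2)
}
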