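# Shared fixtures and independent oracles.

# the five-element worked-example series (printed in the method's tables)
tab <- list(
  ds1 = c(100, 101, 102, 103, 104),      # clean line
  ds2 = c(100, 101, 102, 103, 104.01),   # slight max outlier
  ds3 = c(100, 101, 102, 103, 204),      # gross max outlier
  ds4 = c(99.99, 101, 102, 103, 104),    # slight min outlier
  ds5 = c(1, 101, 102, 103, 104),        # gross min outlier
  ds6 = c(100, 101, 102, 103.6, 104)     # interior outlier (Bad Detection)
)

iseries <- function(values, indices = seq_along(values) - 1L, ...) {
  indexed_series(indices, values, ...)
}

# one unit in the last printed decimal: printed-precision agreement
expect_printed <- function(value, printed, digits = 3) {
  expect_lt(abs(value - printed), 10^(-digits))
}

# --- independent brute-force oracles, coded straight from the definitions ---

oracle_mms <- function(v) {
  n <- length(v)
  r <- max(v) - min(v)
  if (r == 0) return(c(max = NA_real_, min = NA_real_))
  c(max = r / (sum(v) - min(v) * n),
    min = r / (max(v) * n - sum(v)))
}

oracle_mms_verdict <- function(v, r_w) {
  s <- oracle_mms(v)
  if (is.na(s["max"])) return("none")
  fmax <- s["max"] > r_w
  fmin <- s["min"] > r_w
  if (fmax && (!fmin || s["max"] >= s["min"])) "max" else
    if (fmin) "min" else "none"
}

oracle_emms <- function(v, x = seq_along(v) - 1) {
  y_t <- v - v[1]
  x_t <- x - x[1]
  m <- sum(y_t) / sum(x_t)
  ytt <- abs(y_t - x_t * m)
  n <- length(v)
  a <- max(ytt)
  if (a == 0) return(list(ytt = ytt, max = NA_real_, min = NA_real_,
                          argmax = NA_integer_))
  list(ytt = ytt, max = a / sum(ytt), min = a / (a * n - sum(ytt)),
       argmax = x[which.max(ytt)])
}

# a series whose constant-value transform is an exact arithmetic progression
# 0, t, 2t, ..., (n-1)t: residual signs are chosen to sum to zero so the
# fitted slope stays m. Needs n(n-1)/2 even (n = 0 or 1 mod 4).
ap_residual_series <- function(n, t = 1, m = 0, ref_val = 0) {
  total <- n * (n - 1) / 2
  stopifnot(total %% 2 == 0)
  target <- total / 2
  s <- rep(-1, n)
  for (k in (n - 1):1) {       # greedy subset achieving half the sum
    if (target >= k) {
      s[k + 1] <- 1
      target <- target - k
    }
  }
  stopifnot(target == 0)
  x <- 0:(n - 1)
  iseries(ref_val + m * x + s * x * t, x)
}
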