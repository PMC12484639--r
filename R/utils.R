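# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# run code under a seeded RNG without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# derive a child seed from a base seed and a label, staying inside 32-bit range
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# least-squares slope of y over time t; 0 when under-determined
ls_slope <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom <= 0) return(0)
  sum(tc * (y - mean(y))) / denom
}

# trapezoid integral of regularly sampled y with step dt
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# sign indicator with a numerical deadband: a T amplitude below 1e-9 mV is
# an absent T wave, not an inversion
t_sign <- function(amp) {
  if (abs(amp) <= 1e-9) 0 else sign(amp)
}
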