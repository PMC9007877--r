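`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Derive sub-seeds from a master seed; kept under 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopif <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

## Population (divide-by-n) variance; the convention used for every
## aggregated feature in this package.
pop_var <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

## Shannon entropy in bits of a probability vector; 0 * log2(0) := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

## Von Mises sampler (Best-Fisher rejection scheme); mu and result in radians.
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2L] < cc * (2 - cc) || u[2L] <= cc * exp(1 - cc)) {
      i <- i + 1L
      out[i] <- mu + sign(u[3L] - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}
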