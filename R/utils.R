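# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

# Truncated-normal draws by rejection; bounds must admit reasonable mass.
rnorm_bounded <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("invalid bounds: lower >= upper", call. = FALSE)
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lower & draw < upper])
    tries <- tries + 1L
    if (tries > 1000L) {
      # pathological config: fall back to clamping inside the open interval
      eps <- (upper - lower) * 1e-6
      out <- c(out, pmin(pmax(stats::rnorm(n, mean, sd), lower + eps), upper - eps))
    }
  }
  out[seq_len(n)]
}

# Runs of TRUE in a logical vector -> matrix of (start index, end index).
bool_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Centered moving average, ends handled by shrinking window.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

stop_vw <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "vasowave_error")))
}
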