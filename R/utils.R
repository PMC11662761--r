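# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so generators are pure functions of their parameters and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Linear interpolation over invalid samples; edge gaps take the nearest valid
# value (rule = 2). Interpolated values never leave the convex hull of the two
# bounding valid samples.
fill_gaps <- function(v, valid) {
  n <- length(v)
  if (all(valid)) return(v)
  if (sum(valid) < 2L) stop("fewer than two valid samples; cannot interpolate")
  stats::approx(x = which(valid), y = v[valid], xout = seq_len(n),
                method = "linear", rule = 2)$y
}

# Centered moving average with edge padding by the first/last value, so the
# output has the same length and no NA.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  sm <- as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))
  sm[(half + 1L):(half + length(x))]
}

# Central-difference velocity in units of x per second; one-sided at the edges.
central_velocity <- function(x, fps) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples for a velocity")
  v <- numeric(n)
  if (n > 2L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2 * fps
  v[1L] <- (x[2L] - x[1L]) * fps
  v[n] <- (x[n] - x[n - 1L]) * fps
  v
}

# Tolerant scalar checks used by constructors.
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
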