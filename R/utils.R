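# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (divides by n, not n - 1).
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Circular mean of angles in degrees
#'
#' Averages directional data (e.g. wind direction) on the circle, so that
#' 350 and 10 degrees average to 0 rather than 180.
#'
#' @param deg numeric vector of angles in degrees.
#' @param na.rm drop missing values before averaging.
#' @return a single angle in `[0, 360)`; `NA` if no finite input remains.
#' @examples
#' circular_mean(c(350, 10))  # 0
#' @export
circular_mean <- function(deg, na.rm = TRUE) {
  if (na.rm) deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  ang <- ang %% 360
  # collapse floating-point residue at the wrap point onto 0
  if (ang > 360 - 1e-9) ang <- 0
  ang
}

# Piecewise-linear phase warp mapping hour-of-day to a sine phase whose
# maximum falls at `peak_hour` and minimum at `trough_hour` while keeping
# the full peak-to-trough range of the sinusoid. Returns sin(phase).
diurnal_shape <- function(hour, trough_hour = 5, peak_hour = 14) {
  h <- hour %% 24
  rise <- (peak_hour - trough_hour) %% 24   # hours from trough to peak
  fall <- 24 - rise                         # hours from peak back to trough
  dt <- (h - trough_hour) %% 24
  phase <- ifelse(
    dt <= rise,
    -pi / 2 + pi * dt / rise,
    pi / 2 + pi * (dt - rise) / fall
  )
  sin(phase)
}

# First-order autoregressive Gaussian noise, mean zero.
ar1_noise <- function(n, sd, rho = 0.8) {
  if (sd <= 0 || n == 0L) return(rep(0, n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  stats::filter(innov, rho, method = "recursive")[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
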