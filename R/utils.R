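#' @import data.table
#' @importFrom stats coef glm lm median na.omit pnorm predict qnorm quantile
#'   rbeta rbinom rexp rgamma rlnorm rnorm rpois runif sd setNames var
#'   binomial quasibinomial as.formula model.matrix
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

SECONDS_PER_DAY <- 86400
GPS_CADENCE_S <- 300  # nominal 5-minute sampling

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed
#'
#' Mixes a base seed with arbitrary string/integer tokens into a seed in
#' `[1, 2^31 - 2]`, so that each stage, participant or trial gets an
#' independent but fully reproducible RNG stream.
#'
#' @param seed Integer base seed.
#' @param ... Character or integer tokens identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (tok in list(...)) {
    if (is.character(tok)) {
      for (cc in utf8ToInt(paste(tok, collapse = "|"))) {
        s <- (s * 69069 + cc) %% 2147483647
      }
    } else {
      s <- (s * 69069 + (as.double(tok) %% 2147483647)) %% 2147483647
    }
  }
  as.integer(max(1, s))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG stream,
#' so seeded simulations never perturb surrounding randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Great-circle distance between GPS coordinates
#'
#' Vectorized haversine distance in meters.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distances in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- 6371000
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Local equirectangular projection to meters around a reference latitude.
equirect_xy <- function(lat, lon, lat0 = mean(lat)) {
  r <- 6371000
  list(x = r * (lon * pi / 180) * cos(lat0 * pi / 180),
       y = r * (lat * pi / 180))
}

# Circular mean of clock times (hours on a `period`-hour circle).
circular_mean_hours <- function(h, period = 24) {
  ang <- h / period * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  r <- (m / (2 * pi) * period) %% period
  if (period - r < 1e-9) r <- 0
  r
}

# Allocate an integer total across items proportionally to weights using
# largest-remainder rounding, respecting a per-item cap.
largest_remainder_alloc <- function(total, weights, cap = 3L) {
  k <- length(weights)
  stopifnot(total >= 0, total <= k * cap)
  w <- weights / sum(weights)
  target <- total * w
  base <- pmin(floor(target), cap)
  left <- total - sum(base)
  # hand out remaining units by descending fractional remainder (stable ties)
  frac <- target - floor(target)
  ord <- order(-frac, seq_len(k))
  i <- 1
  while (left > 0) {
    j <- ord[(i - 1) %% k + 1]
    if (base[j] < cap) {
      base[j] <- base[j] + 1
      left <- left - 1
    }
    i <- i + 1
  }
  as.integer(base)
}

#' Least-squares spectral power of an irregularly sampled series
#'
#' For each trial period, fits `y ~ sin(2*pi*t/P) + cos(2*pi*t/P)` by
#' ordinary least squares on the mean-removed series and reports the
#' explained sum of squares. This is the classical least-squares
#' periodogram, suitable for GPS traces with missing fixes.
#'
#' @param t_hours Sample times in hours.
#' @param y Signal values.
#' @param periods Trial periods in hours.
#' @return Numeric vector of explained sums of squares, one per period.
#' @export
ls_spectrum <- function(t_hours, y, periods) {
  y <- y - mean(y)
  ang <- outer(t_hours, 2 * pi / periods)
  S <- sin(ang)
  C <- cos(ang)
  # closed-form 2x2 least squares per frequency: explained SS = b' X'y
  sss <- colSums(S * S)
  scc <- colSums(C * C)
  ssc <- colSums(S * C)
  ssy <- as.vector(crossprod(S, y))
  scy <- as.vector(crossprod(C, y))
  det <- sss * scc - ssc^2
  ok <- det > 1e-10
  b1 <- ifelse(ok, (scc * ssy - ssc * scy) / det, 0)
  b2 <- ifelse(ok, (sss * scy - ssc * ssy) / det, 0)
  pmax(b1 * ssy + b2 * scy, 0)
}

# Fraction of least-squares spectral power in a period band.
ls_band_fraction <- function(t_hours, y, band = c(23.5, 24.5),
                             range = c(2, 26), step = 0.25) {
  periods <- seq(range[1], range[2], by = step)
  if (length(t_hours) < 8 || sd(y) < 1e-12) return(NA_real_)
  p <- ls_spectrum(t_hours, y, periods)
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  sum(p[periods >= band[1] & periods <= band[2]]) / tot
}

# ISO-8601 (timezone-naive local time) <-> seconds since study start.
iso_from_seconds <- function(sec, study_start) {
  format(as.POSIXct(study_start, tz = "UTC") + sec, "%Y-%m-%dT%H:%M:%S",
         tz = "UTC")
}

seconds_from_iso <- function(iso, study_start) {
  as.numeric(as.POSIXct(iso, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S") -
               as.POSIXct(study_start, tz = "UTC"), units = "secs")
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
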