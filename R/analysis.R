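#' Construct a uniformly sampled series
#'
#' @param time Strictly increasing, uniformly spaced time grid (min).
#' @param values One value per grid point.
#' @return A `sampled_series` list with `time`, `values`, `dt`.
#' @export
sampled_series <- function(time, values) {
  if (length(time) < 2 || length(time) != length(values))
    stop("need matching time/value vectors of length >= 2")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-8 * mean(dt))
    stop("time grid must be strictly increasing and uniform")
  structure(list(time = time, values = values, dt = mean(dt)),
            class = "sampled_series")
}

#' Extract one species from a trajectory as a sampled series
#'
#' @param x A `downscale_run`, `trajectory_chunk`, or a sample matrix whose
#'   first column is `time`.
#' @param species Species name.
#' @return A [sampled_series()].
#' @export
trajectory_series <- function(x, species) {
  m <- if (inherits(x, "downscale_run")) x$trajectory
       else if (inherits(x, "trajectory_chunk")) x$samples else x
  if (!species %in% colnames(m)) stop("species '", species, "' not in trajectory")
  sampled_series(m[, "time"], m[, species])
}

#' Resample an event-driven path onto a uniform grid
#'
#' Zero-order-hold (previous value) interpolation, exact for the
#' piecewise-constant paths produced by event-driven simulation.
#'
#' @param time Event times (increasing).
#' @param values Value holding from each event time until the next.
#' @param dt Output cadence.
#' @param t0,t1 Output range; default spans the input.
#' @return A [sampled_series()].
#' @export
resample_series <- function(time, values, dt, t0 = time[1], t1 = time[length(time)]) {
  grid <- seq(t0, t1, by = dt)
  idx <- findInterval(grid, time)
  idx[idx < 1] <- 1
  sampled_series(grid, values[idx])
}

#' Autocorrelation-based power spectral density
#'
#' Removes the mean, forms the biased autocovariance estimate (normalised by
#' the full series length) to a maximum lag of half the series length,
#' applies a Bartlett (triangular) lag window -- the classical
#' Blackman-Tukey estimator, whose Fejer-kernel smoothing guarantees a
#' nonnegative spectrum -- and takes a discrete cosine transform.  The
#' windowed autocovariance is zero-padded by `pad_factor` before the
#' transform so that peak positions are resolved on a grid finer than
#' `1/(N*dt)`.
#'
#' @param series A [sampled_series()].
#' @param pad_factor Zero-padding multiple for the cosine transform (>= 1).
#' @return A `spectral_density` list with `frequency` (1/min, from 0 to
#'   Nyquist), `density`, `peaks` (interior local maxima, sorted by
#'   magnitude) and `var` (series variance, for Parseval checks).
#' @export
spectral_density <- function(series, pad_factor = 4) {
  if (!inherits(series, "sampled_series")) stop("need a sampled_series")
  x <- series$values - mean(series$values)
  N <- length(x)
  L <- floor(N / 2)
  # biased autocovariance r[0..L] via FFT
  M <- stats::nextn(2L * N)
  X <- stats::fft(c(x, rep(0, M - N)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(L + 1)] / M / N
  r <- r * (1 - (0:L) / (L + 1))  # Bartlett lag window (lag 0 untouched)
  # even (cosine) transform of the zero-padded windowed autocovariance
  K <- stats::nextn(max(ceiling(pad_factor) * (L + 1L), 2048L))
  v <- numeric(2L * K)
  v[seq_len(L + 1)] <- r
  v[2L * K + 1L - seq_len(L)] <- r[-1]
  S <- Re(stats::fft(v))[seq_len(K + 1)]
  S[S < 0] <- 0  # guard against roundoff only; the estimator is nonnegative
  freq <- (0:K) / (2 * K * series$dt)
  i <- 2:K
  is_peak <- S[i] > S[i - 1] & S[i] >= S[i + 1] & S[i] > 0
  peaks <- data.frame(frequency = freq[i][is_peak], density = S[i][is_peak])
  peaks <- peaks[order(-peaks$density), , drop = FALSE]
  structure(list(frequency = freq, density = S, peaks = peaks,
                 var = r[1], dt = series$dt, n = N),
            class = "spectral_density")
}

#' Dominant (nonzero) frequency of a spectral density
#'
#' @param sd A [spectral_density()].
#' @return Frequency (1/min) of the largest interior spectral peak,
#'   excluding the zero-frequency bin.
#' @export
dominant_frequency <- function(sd) {
  if (nrow(sd$peaks) == 0) stop("no interior spectral peak found")
  sd$peaks$frequency[1]
}

#' Oscillation period estimate
#'
#' The inverse of the dominant spectral frequency of the series.
#'
#' @param series A [sampled_series()] spanning at least two cycles.
#' @param pad_factor Passed to [spectral_density()].
#' @return Period in minutes.
#' @export
estimate_period <- function(series, pad_factor = 4) {
  1 / dominant_frequency(spectral_density(series, pad_factor))
}

#' Empirical probability mass function of an integer-valued series
#'
#' @param x A [sampled_series()], a numeric vector of integer-valued samples,
#'   or a trajectory matrix (then give `species`).
#' @param species Species name when `x` is a trajectory matrix or run.
#' @return Named numeric vector: probability per observed value; sums to 1.
#' @export
species_pmf <- function(x, species = NULL) {
  v <- if (inherits(x, "sampled_series")) x$values
       else if (!is.null(species)) trajectory_series(x, species)$values
       else x
  if (length(v) == 0) stop("empty series")
  if (any(v != round(v))) stop("samples must be integer-valued")
  tab <- table(v)
  stats::setNames(as.numeric(tab) / length(v), names(tab))
}

#' Total-variation distance between two PMFs
#'
#' @param p,q Named probability vectors (names are the support values).
#' @return `0.5 * sum |p - q|` over the union support.
#' @export
total_variation <- function(p, q) {
  support <- union(names(p), names(q))
  pv <- ifelse(support %in% names(p), p[support], 0)
  qv <- ifelse(support %in% names(q), q[support], 0)
  sum(abs(pv - qv)) / 2
}

#' Compare an original and a downscaled trajectory
#'
#' The validation harness: dominant oscillation frequencies and their ratio,
#' period estimates, and per-species PMF total-variation distances.
#'
#' @param original,downscaled Trajectory matrices or `downscale_run`s.
#' @param species Character vector of species to compare PMFs for.
#' @param pad_factor Passed to [spectral_density()].
#' @param freq_species Species whose series carries the oscillation.
#' @return A `trajectory_comparison` list.
#' @export
compare_runs <- function(original, downscaled, species = c("Y", "X", "X2"),
                         freq_species = "Y", pad_factor = 4) {
  so <- trajectory_series(original, freq_species)
  sd_ <- trajectory_series(downscaled, freq_species)
  spo <- spectral_density(so, pad_factor)
  spd <- spectral_density(sd_, pad_factor)
  f_o <- dominant_frequency(spo); f_d <- dominant_frequency(spd)
  tv <- vapply(species, function(s)
    total_variation(species_pmf(original, s), species_pmf(downscaled, s)),
    numeric(1))
  structure(list(frequency_original = f_o, frequency_downscaled = f_d,
                 frequency_ratio = f_d / f_o,
                 period_original = 1 / f_o, period_downscaled = 1 / f_d,
                 frequency_bin = spo$frequency[2] - spo$frequency[1],
                 pmf_total_variation = tv,
                 spectra = list(original = spo, downscaled = spd)),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf("dominant frequency: %.4g vs %.4g 1/min (ratio %.4f)\n",
              x$frequency_original, x$frequency_downscaled, x$frequency_ratio))
  cat(sprintf("period: %.4g vs %.4g min\n", x$period_original, x$period_downscaled))
  cat("PMF total-variation distances:\n")
  print(round(x$pmf_total_variation, 4))
  invisible(x)
}
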