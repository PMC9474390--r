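# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a root seed
#'
#' All stochastic generators in the package draw from named substreams so that
#' e.g. adding units to a simulation does not perturb spike trains of existing
#' units. Substreams are derived by mixing the root seed with a stream index;
#' the result always fits in a 32-bit signed integer.
#'
#' @param seed root seed (single integer).
#' @param stream non-negative integer stream index.
#' @return an integer usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) == 1L, stream >= 0)
  # multiplicative mixing in double precision; exact below 2^53
  as.integer(((seed %% 2147483647) * 48271 + stream * 16807 + 1) %% 2147483647)
}

# Normalized Gaussian kernel on a bin grid, truncated at +/- trunc_sd SDs.
gaussian_kernel <- function(sd_bins, trunc_sd = 4) {
  if (sd_bins <= 0) return(1)
  half <- max(1L, ceiling(sd_bins * trunc_sd))
  x <- seq(-half, half)
  k <- exp(-0.5 * (x / sd_bins)^2)
  k / sum(k)
}

# Convolve a series with a kernel, renormalizing the kernel mass that falls
# inside the signal at the edges (so a constant input maps to itself).
smooth_convolve <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  xp <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(xp, kernel, sides = 2)[(half + 1L):(half + n)]
  mp <- c(rep(0, half), rep(1, n), rep(0, half))
  mass <- stats::filter(mp, kernel, sides = 2)[(half + 1L):(half + n)]
  as.numeric(num / mass)
}

# Linear resampling of a regularly sampled waveform to a higher rate.
resample_wave <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  stats::spline(t_in, x, xout = t_out)$y
}

# Trough (most negative sample) amplitude per row of a channels x samples
# matrix, as a positive depth in the input units.
trough_depth <- function(waveform) {
  apply(waveform, 1L, function(w) -min(w))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}
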