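#' Welch power spectral density over burst periods
#'
#' Averages modified periodograms (Hann window, default 1 s segments with
#' 50% overlap) over all burst windows, per channel group, on the
#' (down-sampled) local field potential. Windows shorter than one Welch
#' segment are skipped with a warning.
#'
#' @param lfp a `burst_lfp` object from [simulate_burst_lfp()], or a
#'   groups x samples numeric matrix / numeric vector of a continuous
#'   recording starting at t = 0.
#' @param fs sampling rate of `lfp` (ignored for `burst_lfp` input).
#' @param windows data.frame of burst `onset`/`offset` (s); required for
#'   matrix/vector input, ignored for `burst_lfp` input.
#' @param fs_target analysis rate (Hz); input at a higher rate is decimated
#'   (default 1000).
#' @param seg_s Welch segment length (s), default 1.
#' @param overlap segment overlap fraction, default 0.5.
#' @param by_window also return one PSD per burst window (for per-burst peak
#'   pooling).
#' @return list of class `welch_psd`: `freq` (Hz), `psd` (groups x freq,
#'   averaged over all segments), and if `by_window` a list `per_window`.
#' @export
welch_psd <- function(lfp, fs = NULL, windows = NULL, fs_target = 1000,
                      seg_s = 1, overlap = 0.5, by_window = FALSE) {
  if (inherits(lfp, "burst_lfp")) {
    segs <- lfp$segments
    fs <- lfp$fs
  } else {
    if (is.null(fs) || is.null(windows))
      stop("`fs` and `windows` are required for raw-signal input")
    if (is.vector(lfp)) lfp <- matrix(lfp, nrow = 1)
    segs <- lapply(seq_len(nrow(windows)), function(w) {
      i0 <- max(1L, floor(windows$onset[w] * fs) + 1L)
      i1 <- min(ncol(lfp), floor(windows$offset[w] * fs))
      lfp[, i0:i1, drop = FALSE]
    })
  }
  if (fs > fs_target) {
    q <- round(fs / fs_target)
    segs <- lapply(segs, function(m)
      t(apply(m, 1, function(x) signal::decimate(x, q))))
    fs <- fs / q
  }
  nperseg <- round(seg_s * fs)
  step <- max(1L, round(nperseg * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)) # Hann
  u <- sum(win^2)
  nf <- nperseg %/% 2 + 1L
  freq <- seq(0, nf - 1) * fs / nperseg

  pgram <- function(x) {           # one-sided PSD of one segment
    xw <- (x - mean(x)) * win
    p <- abs(stats::fft(xw))^2 / (fs * u)
    p <- p[1:nf]
    if (nperseg %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    else p[2:nf] <- 2 * p[2:nf]
    p
  }
  welch_one <- function(m) {       # groups x samples -> groups x freq or NULL
    n <- ncol(m)
    if (n < nperseg) return(NULL)
    starts <- seq(1L, n - nperseg + 1L, by = step)
    out <- matrix(0, nrow = nrow(m), ncol = nf)
    for (g in seq_len(nrow(m))) {
      acc <- numeric(nf)
      for (s0 in starts) acc <- acc + pgram(m[g, s0:(s0 + nperseg - 1L)])
      out[g, ] <- acc / length(starts)
    }
    out
  }

  per <- lapply(segs, welch_one)
  skipped <- vapply(per, is.null, logical(1))
  if (any(skipped))
    warning(sprintf("%d burst window(s) shorter than one Welch segment skipped",
                    sum(skipped)))
  per <- per[!skipped]
  if (!length(per)) stop("no burst window long enough for a Welch segment")
  avg <- Reduce(`+`, per) / length(per)
  out <- list(freq = freq, psd = avg)
  if (by_window) out$per_window <- per
  structure(out, class = "welch_psd")
}

#' Parametrize a power spectrum into aperiodic and oscillatory components
#'
#' Iteratively fits, in log10 power over log10 frequency, an aperiodic
#' component `offset - exponent * log10(f)` plus Gaussian oscillatory peaks,
#' then refits all components jointly. Peaks are extracted tallest-first
#' from the aperiodic-flattened residual and retained only if their fitted
#' power above the aperiodic component is at least `min_peak_power` (log10
#' power units). Up to `max_n_peaks` peaks are fitted with Gaussian SD
#' bounded by `peak_width_limits`. If the joint fit fails, the aperiodic-only
#' model is returned with a warning.
#'
#' @param freq frequencies (Hz) of `psd`.
#' @param psd power values (one channel group); must be positive on
#'   `f_range`.
#' @param f_range frequency range (Hz) to fit/detect peaks in, default
#'   c(2, 100).
#' @param min_peak_power minimum peak power above the aperiodic fit (log10
#'   units), default 0.3.
#' @param max_n_peaks maximum number of peaks, default 6.
#' @param peak_width_limits Gaussian width (SD, Hz) bounds, default c(1, 12).
#' @return list of class `spectral_model`: `offset`, `exponent`, `peaks`
#'   (data.frame `center_hz`, `power`, `bandwidth_hz`), `r_squared`, and the
#'   fitted curve (`freq`, `fitted_log10`).
#' @export
parametrize_spectrum <- function(freq, psd, f_range = c(2, 100),
                                 min_peak_power = 0.3, max_n_peaks = 6,
                                 peak_width_limits = c(1, 12)) {
  sel <- freq >= f_range[1] & freq <= f_range[2]
  f <- freq[sel]; p <- psd[sel]
  if (length(f) < 5) stop("too few frequency bins in `f_range`")
  if (any(p <= 0)) stop("psd must be strictly positive on `f_range`")
  lf <- log10(f); lp <- log10(p)

  ap_fit <- function(y) {          # robust aperiodic: refit on lower half
    c1 <- stats::coef(stats::lm(y ~ lf))
    res <- y - (c1[1] + c1[2] * lf)
    keep <- res <= stats::median(res)
    c2 <- stats::coef(stats::lm(y[keep] ~ lf[keep]))
    c(offset = unname(c2[1]), exponent = unname(-c2[2]))
  }
  ap_curve <- function(par) par[1] - par[2] * lf

  ap <- ap_fit(lp)
  resid <- lp - ap_curve(ap)

  peaks <- NULL
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(resid)
    h <- resid[i]
    if (h < min_peak_power || h < 2 * stats::sd(resid)) break
    # half-height width guess, bounded
    above <- resid >= h / 2
    run <- range(which(above & cumsum(!above) == cumsum(!above)[i]))
    w0 <- max(peak_width_limits[1],
              min(peak_width_limits[2], (f[run[2]] - f[run[1]]) / 2.355 + 1e-6))
    g <- function(par) sum((resid - par[2] *
                              exp(-0.5 * ((f - par[1]) / par[3])^2))^2)
    o <- stats::optim(c(f[i], h, w0), g, method = "L-BFGS-B",
                      lower = c(f_range[1], 0, peak_width_limits[1]),
                      upper = c(f_range[2], Inf, peak_width_limits[2]))
    peaks <- rbind(peaks, o$par)
    resid <- resid - o$par[2] * exp(-0.5 * ((f - o$par[1]) / o$par[3])^2)
  }

  model_fun <- function(par) {     # par = (offset, exponent, c,h,w, ...)
    y <- par[1] - par[2] * lf
    np <- (length(par) - 2) / 3
    for (k in seq_len(np)) {
      q <- par[2 + (k - 1) * 3 + 1:3]
      y <- y + q[2] * exp(-0.5 * ((f - q[1]) / q[3])^2)
    }
    y
  }
  par0 <- c(ap[1], ap[2], if (!is.null(peaks)) as.vector(t(peaks)))
  np <- if (is.null(peaks)) 0L else nrow(peaks)
  lower <- c(-Inf, -Inf,
             rep(c(f_range[1], 0, peak_width_limits[1]), np))
  upper <- c(Inf, Inf, rep(c(f_range[2], Inf, peak_width_limits[2]), np))
  fit <- tryCatch(
    stats::optim(par0, function(par) sum((lp - model_fun(par))^2),
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("joint spectral fit failed; returning aperiodic-only model")
    fit <- list(par = c(ap[1], ap[2]))
    np <- 0L
  }
  par <- fit$par
  pk_df <- data.frame(center_hz = numeric(), power = numeric(),
                      bandwidth_hz = numeric())
  if (np > 0) {
    for (k in seq_len(np)) {
      q <- par[2 + (k - 1) * 3 + 1:3]
      pk_df <- rbind(pk_df, data.frame(center_hz = q[1], power = q[2],
                                       bandwidth_hz = q[3]))
    }
    pk_df <- pk_df[pk_df$power >= min_peak_power &
                     pk_df$center_hz > f_range[1] &
                     pk_df$center_hz < f_range[2], , drop = FALSE]
    pk_df <- pk_df[order(-pk_df$power), , drop = FALSE]
    rownames(pk_df) <- NULL
  }
  yhat <- model_fun(par)
  r2 <- 1 - sum((lp - yhat)^2) / sum((lp - mean(lp))^2)
  structure(list(offset = unname(par[1]), exponent = unname(par[2]),
                 peaks = pk_df, r_squared = r2,
                 freq = f, fitted_log10 = yhat),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model> exponent %.3g, offset %.3g, %d peak(s)\n",
              x$exponent, x$offset, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Pool oscillatory peak frequencies and find the most likely peak
#'
#' Fits the aperiodic+peaks model to every per-burst, per-group PSD, pools
#' all retained peak center frequencies, and returns the mode of their
#' distribution (kernel density maximum) — the "most likely peak frequency"
#' of a recording.
#'
#' @param psd_by_window list of groups x freq PSD matrices (one per burst),
#'   e.g. `welch_psd(..., by_window = TRUE)$per_window`.
#' @param freq frequency axis shared by all PSDs.
#' @param ... passed to [parametrize_spectrum()].
#' @return list: `peak_freqs` (all pooled centers, Hz), `most_likely_hz`
#'   (density mode, NA if no peaks), `models` (list of spectral models).
#' @export
pool_spectral_peaks <- function(psd_by_window, freq, ...) {
  models <- list()
  centers <- numeric()
  for (m in psd_by_window) {
    for (g in seq_len(nrow(m))) {
      sm <- tryCatch(parametrize_spectrum(freq, m[g, ], ...),
                     error = function(e) NULL)
      if (is.null(sm)) next
      models[[length(models) + 1L]] <- sm
      if (nrow(sm$peaks)) centers <- c(centers, sm$peaks$center_hz)
    }
  }
  ml <- NA_real_
  if (length(centers) >= 2) {
    d <- stats::density(centers, bw = "SJ-ste")
    ml <- d$x[which.max(d$y)]
  } else if (length(centers) == 1) ml <- centers
  list(peak_freqs = centers, most_likely_hz = ml, models = models)
}
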