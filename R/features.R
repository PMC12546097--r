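#' Estimate the individual alpha frequency (IAF)
#'
#' The IAF is the center of gravity of the occipital-average Welch PSD within
#' the extended alpha band (7.5-12.5 Hz), estimated on the eyes-closed
#' baseline epoch:
#' \deqn{IAF = \sum_f f \bar P(f) / \sum_f \bar P(f)}
#' over the frequency bins falling in \eqn{[7.5, 12.5]} Hz.
#'
#' @param baseline Baseline [epoch()].
#' @param occipital Channel labels to average over (default [occipital_channels()]).
#' @param window_len,overlap Welch settings, see [welch_psd()].
#' @return IAF in Hz.
#' @export
estimate_iaf <- function(baseline, occipital = occipital_channels(),
                         window_len = 1, overlap = 0.5) {
  missing_ch <- setdiff(occipital, baseline$channel_names)
  if (length(missing_ch))
    stop(sprintf("occipital channels not present in epoch: %s",
                 paste(missing_ch, collapse = ", ")))
  psd <- welch_psd(baseline, window_len = window_len, overlap = overlap)
  pbar <- colMeans(psd$power[occipital, , drop = FALSE])
  sel <- psd$freqs >= 7.5 & psd$freqs <= 12.5
  if (!any(sel)) stop("no PSD bins inside the 7.5-12.5 Hz alpha band")
  p <- pbar[sel]
  f <- psd$freqs[sel]
  if (sum(p) <= 0) stop("all-zero PSD in the alpha band: center of gravity undefined")
  sum(f * p) / sum(p)
}

#' Subject-specific frequency bands anchored to the IAF
#'
#' The five contiguous bands
#' delta = \[0, IAF-6\], theta = \[IAF-6, IAF-2\], alpha = \[IAF-2, IAF+2\],
#' beta = \[IAF+2, IAF+16\], gamma = \[IAF+16, IAF+25\] (Hz).
#'
#' @param iaf Individual alpha frequency in Hz; must exceed 6 Hz so the delta
#'   band is non-degenerate.
#' @return A `band_scheme`: list with `iaf` and `intervals` (named list of
#'   `c(low, high)` pairs).
#' @export
#' @examples
#' define_bands(10)$intervals$alpha  # 8 12
define_bands <- function(iaf) {
  stopifnot(is.numeric(iaf), length(iaf) == 1, is.finite(iaf))
  if (iaf <= 6)
    stop(sprintf("iaf = %g Hz makes the delta band [0, IAF-6] degenerate (IAF must exceed 6 Hz)", iaf))
  intervals <- list(
    delta = c(0, iaf - 6),
    theta = c(iaf - 6, iaf - 2),
    alpha = c(iaf - 2, iaf + 2),
    beta  = c(iaf + 2, iaf + 16),
    gamma = c(iaf + 16, iaf + 25)
  )
  structure(list(iaf = iaf, intervals = intervals), class = "band_scheme")
}

#' Band names in canonical order
#' @return Character vector delta..gamma.
#' @export
band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")

#' Normalized spectral band powers
#'
#' For each channel C and band B, \eqn{p_{C,B}} is the ratio of the PSD
#' integral over B to the integral over the full estimated range
#' \[0, fs/2\]. Integrals use the trapezoidal rule on the Welch grid; a band
#' edge falling between bins is handled by linear interpolation of the
#' cumulative integral, so p varies continuously with the IAF. A gamma band
#' extending past the Nyquist frequency is truncated with a warning.
#'
#' @param psd A `psd_estimate`.
#' @param bands A `band_scheme` from [define_bands()].
#' @return A channels x 5 matrix of normalized powers (rows sum to <= 1).
#' @export
band_powers <- function(psd, bands) {
  stopifnot(inherits(psd, "psd_estimate"), inherits(bands, "band_scheme"))
  fmax <- max(psd$freqs)
  ints <- bands$intervals
  if (ints$gamma[2] > fmax + 1e-9) {
    warning(sprintf("gamma band upper edge %.2f Hz exceeds Nyquist %.2f Hz; truncated",
                    ints$gamma[2], fmax))
    ints$gamma[2] <- fmax
  }
  for (b in names(ints))
    if (ints[[b]][2] > fmax + 1e-9)
      stop(sprintf("band '%s' upper edge %.2f Hz exceeds the PSD range %.2f Hz",
                   b, ints[[b]][2], fmax))
  nch <- nrow(psd$power)
  out <- matrix(NA_real_, nch, length(ints),
                dimnames = list(psd$channel_names, names(ints)))
  for (ch in seq_len(nch)) {
    cum <- c(pracma::cumtrapz(psd$freqs, psd$power[ch, ]))
    total <- cum[length(cum)]
    if (total <= 0)
      stop(sprintf("channel '%s' has zero total power: normalized band powers undefined",
                   psd$channel_names[ch]))
    cum_at <- function(f) stats::approx(psd$freqs, cum, xout = f, rule = 2)$y
    out[ch, ] <- vapply(ints, function(iv) (cum_at(iv[2]) - cum_at(iv[1])) / total,
                        numeric(1))
  }
  pmin(pmax(out, 0), 1)
}

#' Hjorth temporal parameters
#'
#' Per channel: activity \eqn{A = \sigma\{x\}} (temporal variance, uV^2);
#' mobility \eqn{M = \sqrt{\sigma\{x'\}/\sigma\{x\}}} (rad/s); complexity
#' \eqn{C = M\{x'\}/M\{x\}} (dimensionless, >= 1 by Cauchy-Schwarz).
#' Derivatives are first differences scaled by the sample rate, so mobility
#' approximates the angular frequency of the dominant rhythm (a pure f Hz
#' sinusoid gives M close to 2*pi*f; divide by 2*pi for Hz).
#'
#' @param x An [epoch()] with at least 3 samples per channel.
#' @return A channels x 3 matrix with columns `A`, `M`, `C`.
#' @export
hjorth <- function(x) {
  stopifnot(inherits(x, "eeg_epoch"))
  if (ncol(x$data) < 3) stop("hjorth requires at least 3 samples per channel")
  out <- matrix(NA_real_, nrow(x$data), 3,
                dimnames = list(x$channel_names, c("A", "M", "C")))
  for (ch in seq_len(nrow(x$data))) {
    s <- x$data[ch, ]
    d1 <- diff(s) * x$fs
    d2 <- diff(d1) * x$fs
    v0 <- stats::var(s); v1 <- stats::var(d1); v2 <- stats::var(d2)
    if (v0 <= 0 || v1 <= 0)
      stop(sprintf("channel '%s' is constant (zero variance): Hjorth parameters undefined",
                   x$channel_names[ch]))
    m <- sqrt(v1 / v0)
    out[ch, ] <- c(v0, m, sqrt(v2 / v1) / m)
  }
  out
}

#' Extract the 304-long EEG feature vector of one epoch
#'
#' Concatenates normalized spectral powers (channels x 5 bands, channel-major)
#' and Hjorth parameters (channels x A/M/C, channel-major) into a named
#' vector: `<channel>.p_<band>` then `<channel>.hjorth_<A|M|C>`.
#'
#' @param x An [epoch()].
#' @param bands A `band_scheme` for the recorded subject.
#' @param window_len,overlap Welch settings.
#' @return Named numeric vector of length `n_channels * 8`.
#' @export
extract_epoch_features <- function(x, bands, window_len = 1, overlap = 0.5) {
  psd <- welch_psd(x, window_len = window_len, overlap = overlap)
  bp <- band_powers(psd, bands)
  hj <- hjorth(x)
  spec <- as.vector(t(bp))
  names(spec) <- as.vector(t(outer(rownames(bp), paste0("p_", colnames(bp)),
                                   paste, sep = ".")))
  temp <- as.vector(t(hj))
  names(temp) <- as.vector(t(outer(rownames(hj), paste0("hjorth_", colnames(hj)),
                                   paste, sep = ".")))
  c(spec, temp)
}
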