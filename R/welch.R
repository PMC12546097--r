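#' Welch power spectral density estimate
#'
#' Averaged modified periodogram per channel: the signal is cut into
#' Hamming-windowed segments of `window_len` seconds with fractional
#' `overlap`, each segment's one-sided periodogram is computed, and the
#' periodograms are averaged. Density scaling is used, so the trapezoidal
#' integral of the PSD over frequency approximates the time-domain variance
#' of the signal (Parseval).
#'
#' @param x An [epoch()].
#' @param window_len Window length in seconds (default 1).
#' @param overlap Fractional overlap between consecutive windows (default 0.5).
#' @return A `psd_estimate`: list with `freqs` (Hz, from 0 to fs/2),
#'   `power` (channels x frequencies matrix, uV^2/Hz), `fs`, `window_len`,
#'   `overlap`, `channel_names`.
#' @export
#' @examples
#' e <- epoch(matrix(sin(2 * pi * 10 * (0:5119) / 512), 1), 512, "Cz", "BSL")
#' p <- welch_psd(e)
#' p$freqs[which.max(p$power[1, ])]  # 10 Hz
welch_psd <- function(x, window_len = 1, overlap = 0.5) {
  stopifnot(inherits(x, "eeg_epoch"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- round(window_len * x$fs)
  n <- ncol(x$data)
  if (n < L)
    stop(sprintf("epoch (%d samples) shorter than the Welch window (%d samples)", n, L))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- signal::hamming(L)
  U <- sum(w^2)                      # window energy for density normalization
  nfreq <- L %/% 2 + 1L
  # segment index matrix reused across channels
  idx <- outer(seq_len(L), starts - 1L, `+`)
  pow <- matrix(0, nrow = nrow(x$data), ncol = nfreq)
  for (ch in seq_len(nrow(x$data))) {
    segs <- matrix(x$data[ch, idx], nrow = L) * w
    ft <- stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
    p <- Mod(ft)^2 / (x$fs * U)
    scale <- rep(2, nfreq)           # one-sided: double all but DC (and Nyquist)
    scale[1] <- 1
    if (L %% 2 == 0) scale[nfreq] <- 1
    pow[ch, ] <- rowMeans(p) * scale
  }
  rownames(pow) <- x$channel_names
  structure(list(freqs = seq(0, x$fs / 2, length.out = nfreq),
                 power = pow, fs = x$fs,
                 window_len = window_len, overlap = overlap,
                 channel_names = x$channel_names),
            class = "psd_estimate")
}

#' Construct a PSD estimate from explicit values
#'
#' Mainly useful for analytical checks (e.g. flat spectra with known band
#' ratios) and for feeding externally computed spectra into [band_powers()].
#'
#' @param freqs Strictly increasing frequency grid starting at 0 (Hz).
#' @param power Channels x frequencies matrix of nonnegative densities, or a
#'   single numeric vector for one channel.
#' @param channel_names Optional channel labels.
#' @return A `psd_estimate`.
#' @export
psd_estimate <- function(freqs, power, channel_names = NULL) {
  if (is.vector(power)) power <- matrix(power, nrow = 1)
  if (length(freqs) != ncol(power))
    stop("length(freqs) must equal ncol(power)")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (freqs[1] != 0) stop("freqs must start at 0")
  if (any(power < 0)) stop("power must be nonnegative")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(power)))
  rownames(power) <- channel_names
  structure(list(freqs = freqs, power = power, fs = 2 * max(freqs),
                 window_len = NA_real_, overlap = NA_real_,
                 channel_names = channel_names),
            class = "psd_estimate")
}
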