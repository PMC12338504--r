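#' Multichannel EEG recording container
#'
#' @param data channels x samples matrix (volts)
#' @param fs sampling rate (Hz)
#' @param labels channel labels (unique, one per row)
#' @param events data.frame with columns `sample` (1-based) and `code`
#' @param reference label of the online reference channel, if present
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, labels, events = NULL,
                          reference = NULL) {
  data <- as.matrix(data)
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(events)) events <- data.frame(sample = integer(0),
                                            code = character(0))
  if (nrow(events) && (min(events$sample) < 1L ||
                       max(events$sample) > ncol(data)))
    stop("events outside record bounds")
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 events = events, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

# zero-phase FIR filtering by FFT convolution with group-delay
# compensation; channels are transformed in blocks (mvfft) to bound the
# size of the complex temporaries on long recordings
fir_apply <- function(X, b, block = 8L) {
  nb <- length(b)
  delay <- (nb - 1L) %/% 2L
  n <- ncol(X)
  L <- stats::nextn(n + nb)
  fb <- fft(c(b, rep(0, L - nb)))
  out <- matrix(0, nrow(X), n)
  for (s in seq(1L, nrow(X), by = block)) {
    ch <- s:min(s + block - 1L, nrow(X))
    Xp <- rbind(t(X[ch, , drop = FALSE]), matrix(0, L - n, length(ch)))
    Y <- Re(stats::mvfft(stats::mvfft(Xp) * fb, inverse = TRUE)) / L
    out[ch, ] <- t(Y[(delay + 1L):(delay + n), , drop = FALSE])
  }
  out
}

#' Zero-phase FIR bandpass filter
#'
#' Linear-phase FIR (Hamming-windowed, [signal::fir1()]) applied by FFT
#' convolution with group-delay compensation, so the output is zero-phase.
#' The default tap count puts the transition width at the lower band edge,
#' which keeps DC attenuation beyond 40 dB.
#'
#' @param rec an `eeg_recording`
#' @param low,high band edges (Hz), 0 < low < high < fs/2
#' @param n_taps filter length (odd); default `ceiling(3.3 * fs / low)`
#' @return the filtered `eeg_recording`
#' @export
bandpass_filter <- function(rec, low, high, n_taps = NULL) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (is.null(n_taps)) n_taps <- ceiling(3.3 * fs / low)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  b <- signal::fir1(n_taps - 1L, c(low, high) / (fs / 2), type = "pass")
  rec$data <- fir_apply(rec$data, b)
  rec
}

#' Welch power spectral density
#'
#' Mean modified periodogram over Hann-windowed segments.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param seg_len segment length in seconds (default 4, i.e. 0.25 Hz bins)
#' @param overlap fractional overlap between segments
#' @return list with `freq` (Hz) and `psd` (power per Hz)
#' @export
welch_psd <- function(x, fs, seg_len = 4, overlap = 0.5) {
  nper <- round(seg_len * fs)
  if (nper > length(x)) stop("segment longer than the signal")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  norm <- sum(w^2) * fs
  nf <- nper %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / norm
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]  # one-sided
  list(freq = (seq_len(nf) - 1L) * fs / nper, psd = psd)
}

#' Individual alpha peak frequency from resting EEG
#'
#' Band-pass 2-45 Hz, drop caller-listed bad channels, common average
#' reference, restrict to the occipital channels, cut non-overlapping
#' epochs (dropping the first and last), Welch PSD per channel and epoch,
#' average, Savitzky-Golay smoothing, and take the peak inside the alpha
#' band. A maximum sitting on the band boundary is refused (no clear
#' peak).
#'
#' @param rec resting-state `eeg_recording`
#' @param occipital_labels channels the alpha estimate is read from
#' @param epoch_len epoch length in seconds (default 30)
#' @param bad_channels labels to drop before re-referencing
#' @param band alpha search band (Hz)
#' @param seg_len,sg_window,sg_order Welch segment length (s) and
#'   Savitzky-Golay window (bins) / polynomial order
#' @return the alpha peak frequency (Hz)
#' @export
estimate_iapf <- function(rec, occipital_labels, epoch_len = 30,
                          bad_channels = character(), band = c(8, 13),
                          seg_len = 4, sg_window = 11, sg_order = 3) {
  if (!all(occipital_labels %in% rec$labels))
    stop("unknown occipital channel label")
  rec <- bandpass_filter(rec, 2, 45)
  keep <- !(rec$labels %in% bad_channels)
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$labels <- rec$labels[keep]
  rec <- common_average_reference(rec)
  occ <- rec$data[match(occipital_labels, rec$labels), , drop = FALSE]
  nper <- round(epoch_len * rec$fs)
  n_ep <- floor(ncol(occ) / nper)
  if (n_ep - 2L < 3L)
    stop("need at least 3 epochs after dropping the first and last")
  use <- 2:(n_ep - 1L)
  psd <- NULL
  for (e in use) {
    idx <- ((e - 1L) * nper + 1L):(e * nper)
    for (ch in seq_len(nrow(occ))) {
      w <- welch_psd(occ[ch, idx], rec$fs, seg_len = seg_len)
      if (is.null(psd)) { psd <- w$psd; freq <- w$freq; cnt <- 1L }
      else { psd <- psd + w$psd; cnt <- cnt + 1L }
    }
  }
  psd <- psd / cnt
  sm <- signal::sgolayfilt(psd, p = sg_order, n = sg_window)
  inb <- which(freq >= band[1L] & freq <= band[2L])
  pk <- inb[which.max(sm[inb])]
  if (pk == inb[1L] || pk == inb[length(inb)])
    stop("no alpha peak strictly inside the band")
  freq[pk]
}

#' Cut a recording into fixed-length epochs
#'
#' Stimulation epochs span `[tmin, tmax)` around each event (time 0 =
#' event onset); baseline epochs start at the event (inter-trial break
#' onset) and are capped at `max_epochs` (20 by default, matching the
#' study's baseline-extraction rule). Epochs reaching outside the record
#' are dropped.
#'
#' @param rec an `eeg_recording`
#' @param events event sample indices (1-based); default: the recording's
#'   events with code "flash" (stimulation) or "break" (baseline)
#' @param tmin,tmax epoch window in seconds relative to the event
#' @param kind "stimulation" or "baseline"
#' @param max_epochs cap on the number of epochs (baseline default 20)
#' @return object of class `eeg_epochs`: array (epochs x channels x
#'   samples), `times`, `labels`, `fs`, `kind`
#' @export
make_epochs <- function(rec, events = NULL, tmin = -0.05, tmax = 0.2,
                        kind = c("stimulation", "baseline"),
                        max_epochs = NULL) {
  kind <- match.arg(kind)
  if (kind == "baseline") {
    if (missing(tmin)) tmin <- 0
    if (missing(tmax)) tmax <- 3.5
    if (is.null(max_epochs)) max_epochs <- 20L
  } else if (is.null(max_epochs)) max_epochs <- Inf
  if (is.null(events)) {
    code <- if (kind == "stimulation") "flash" else "break"
    events <- rec$events$sample[rec$events$code == code]
  }
  if (!length(events)) stop("no events to epoch")
  if (tmin >= tmax) stop("tmin must be smaller than tmax")
  fs <- rec$fs
  i0 <- round(tmin * fs)
  ns <- round((tmax - tmin) * fs)
  keep <- (events + i0 >= 1L) & (events + i0 + ns - 1L <= ncol(rec$data))
  events <- events[keep]
  if (!length(events)) stop("all epochs fall outside the record")
  if (length(events) > max_epochs) events <- events[seq_len(max_epochs)]
  arr <- array(0, c(length(events), nrow(rec$data), ns))
  for (e in seq_along(events)) {
    idx <- (events[e] + i0):(events[e] + i0 + ns - 1L)
    arr[e, , ] <- rec$data[, idx]
  }
  structure(list(data = arr, times = (i0 + seq_len(ns) - 1L) / fs,
                 labels = rec$labels, fs = fs, kind = kind,
                 events = events),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("eeg_epochs (%s): %d epochs x %d channels x %d samples [%g, %g) s\n",
              x$kind, dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L],
              x$times[1L], x$times[length(x$times)] + 1 / x$fs))
  invisible(x)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean over channels from every channel, for
#' recordings, epochs, or plain channel x samples matrices. Idempotent.
#'
#' @param x `eeg_recording`, `eeg_epochs`, or matrix
#' @return same type as the input
#' @export
common_average_reference <- function(x) {
  if (inherits(x, "eeg_recording")) {
    if (nrow(x$data) < 2L) stop("need at least 2 channels")
    x$data <- sweep(x$data, 2L, colMeans(x$data))
    x
  } else if (inherits(x, "eeg_epochs")) {
    if (dim(x$data)[2L] < 2L) stop("need at least 2 channels")
    m <- apply(x$data, c(1L, 3L), mean)
    x$data <- x$data - aperm(array(m, c(dim(x$data)[1L], dim(x$data)[3L],
                                        dim(x$data)[2L])), c(1L, 3L, 2L))
    x
  } else {
    if (nrow(x) < 2L) stop("need at least 2 channels")
    sweep(x, 2L, colMeans(x))
  }
}

#' Noise covariance from baseline epochs
#'
#' Pooled empirical covariance over baseline epochs (per-epoch channel
#' means removed) with diagonal shrinkage
#' \eqn{\Sigma = (1-\alpha) S + \alpha (tr S / M) I}, and its inverse
#' square root (whitener) on the retained eigenspace. Rank deficiency from
#' common-average referencing is handled by discarding eigenvalues below
#' `1e-10` of the largest.
#'
#' @param baseline `eeg_epochs` of kind "baseline"
#' @param shrinkage alpha in [0, 1] (default 0.05)
#' @return object of class `noise_covariance` with `sigma`, `whitener`,
#'   `rank`, `labels`, `shrinkage`
#' @export
estimate_noise_covariance <- function(baseline, shrinkage = 0.05) {
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  d <- dim(baseline$data)
  M <- d[2L]
  total <- d[1L] * d[3L]
  if (total < 5L * M)
    stop("insufficient baseline samples (need at least 5 per channel)")
  S <- matrix(0, M, M)
  for (e in seq_len(d[1L])) {
    X <- baseline$data[e, , ]
    X <- X - rowMeans(X)
    S <- S + tcrossprod(X)
  }
  S <- S / (total - d[1L])
  sig <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / M) * diag(M)
  e <- eigen(sig, symmetric = TRUE)
  keep <- e$values > 1e-10 * e$values[1L]
  W <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep]))
  structure(list(sigma = sig, whitener = W, rank = sum(keep),
                 labels = baseline$labels, shrinkage = shrinkage),
            class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("noise_covariance: %d channels, rank %d, shrinkage %.2f\n",
              nrow(x$sigma), x$rank, x$shrinkage))
  invisible(x)
}

#' Average stimulation epochs into an evoked response
#'
#' @param stim `eeg_epochs`
#' @return object of class `evoked`: `data` (channels x samples), `times`,
#'   `labels`, `fs`, `n_epochs`
#' @export
evoked_average <- function(stim) {
  if (dim(stim$data)[1L] < 1L) stop("no epochs")
  structure(list(data = apply(stim$data, c(2L, 3L), mean),
                 times = stim$times, labels = stim$labels, fs = stim$fs,
                 n_epochs = dim(stim$data)[1L]),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("evoked: %d channels x %d samples (average of %d epochs)\n",
              nrow(x$data), ncol(x$data), x$n_epochs))
  invisible(x)
}

#' Global field power
#'
#' Per-sample standard deviation across channels.
#' @param evoked an `evoked` (or channels x samples matrix)
#' @return numeric vector, one value per sample
#' @export
global_field_power <- function(evoked) {
  X <- if (inherits(evoked, "evoked")) evoked$data else evoked
  apply(X, 2L, stats::sd)
}

#' Latency of the visual P100 component
#'
#' Latency of the global-field-power maximum inside the search window
#' (default 65-155 ms, spanning the latencies typically reported for the
#' P100). Ties break toward the earliest sample.
#'
#' @param evoked an `evoked`
#' @param window search window in seconds
#' @return latency in seconds
#' @export
find_p100_latency <- function(evoked, window = c(0.065, 0.155)) {
  gfp <- global_field_power(evoked)
  sel <- which(evoked$times >= window[1L] & evoked$times <= window[2L])
  if (!length(sel)) stop("window outside the epoch time axis")
  g <- gfp[sel]
  if (diff(range(g)) == 0) stop("flat global field power: no peak")
  evoked$times[sel[which.max(g)]]
}
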