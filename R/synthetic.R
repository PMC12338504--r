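#' Photic-stimulation paradigm description
#'
#' Defaults reproduce the study paradigm: 20 trials of 80 flashes at half
#' the individual alpha peak frequency with 50% duty cycle, 5-second
#' inter-trial breaks, 1000 Hz sampling.
#'
#' @param n_trials number of trials
#' @param flashes_per_trial flashes per trial
#' @param iapf individual alpha peak frequency (Hz); the stimulation
#'   frequency defaults to `iapf / 2`
#' @param frequency stimulation frequency (Hz)
#' @param duty duty cycle in (0, 1)
#' @param break_s inter-trial break (s)
#' @param fs sampling rate (Hz)
#' @return object of class `paradigm_spec`
#' @export
paradigm_spec <- function(n_trials = 20, flashes_per_trial = 80,
                          iapf = 10, frequency = iapf / 2, duty = 0.5,
                          break_s = 5, fs = 1000) {
  if (duty <= 0 || duty >= 1) stop("duty cycle must be inside (0, 1)")
  if (frequency >= fs / 2) stop("stimulation frequency must be below fs/2")
  if (n_trials < 1 || flashes_per_trial < 1) stop("counts must be >= 1")
  structure(list(n_trials = n_trials,
                 flashes_per_trial = flashes_per_trial, iapf = iapf,
                 frequency = frequency, duty = duty, break_s = break_s,
                 fs = fs),
            class = "paradigm_spec")
}

#' Flash and break events for a paradigm
#'
#' Within each trial, flashes occur at the stimulation period; trials are
#' separated by the break. One "break" event marks the start of each
#' inter-trial break (including after the last trial).
#'
#' @param spec a `paradigm_spec`
#' @return data.frame with columns `sample` (1-based) and `code`
#'   ("flash" / "break"); `n_trials * flashes_per_trial` flash events
#' @export
generate_paradigm <- function(spec) {
  trial_dur <- spec$flashes_per_trial / spec$frequency
  flash <- break_on <- NULL
  for (t in seq_len(spec$n_trials)) {
    t0 <- (t - 1) * (trial_dur + spec$break_s)
    flash <- c(flash, t0 + (seq_len(spec$flashes_per_trial) - 1) /
                 spec$frequency)
    break_on <- c(break_on, t0 + trial_dur)
  }
  ev <- rbind(data.frame(sample = round(flash * spec$fs) + 1L,
                         code = "flash"),
              data.frame(sample = round(break_on * spec$fs) + 1L,
                         code = "break"))
  ev[order(ev$sample), , drop = FALSE]
}

# 1/f ("pink") noise via spectral shaping, unit variance
pink_noise <- function(n, fs) {
  L <- stats::nextn(n)
  w <- rnorm(L)
  f <- c(1, seq_len(L - 1L))
  shape <- 1 / sqrt(pmax(f * fs / L, 1))
  shape[1L] <- 0
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / L
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# smooth positive envelope (lowpassed white noise, mean 1)
slow_envelope <- function(n, fs, cutoff = 0.5) {
  L <- stats::nextn(n)
  w <- rnorm(L)
  f <- (seq_len(L) - 1L) * fs / L
  f <- pmin(f, fs - f)
  h <- as.numeric(f < cutoff)
  x <- Re(fft(fft(w) * h, inverse = TRUE)) / L
  x <- x[seq_len(n)]
  x <- x / stats::sd(x)
  pmax(0, 1 + 0.5 * x)
}

#' Biphasic evoked source waveform
#'
#' Gaussian-windowed cosine burst peaking `peak_latency` seconds after the
#' flash; the default 12.7 ms Gaussian sigma gives a 30 ms full width at
#' half maximum.
#'
#' @param t time axis (s, relative to flash onset)
#' @param amplitude peak source strength (A m)
#' @param peak_latency peak time (s)
#' @param sigma Gaussian width (s)
#' @param f0 carrier frequency (Hz) controlling the biphasic side lobes
#' @return numeric vector of source strengths
#' @export
vep_waveform <- function(t, amplitude = 1e-8, peak_latency = 0.1,
                         sigma = 0.0127, f0 = 8) {
  amplitude * exp(-(t - peak_latency)^2 / (2 * sigma^2)) *
    cos(2 * pi * f0 * (t - peak_latency))
}

#' Simulate a photic-stimulation EEG recording
#'
#' Sensor data are the direct lead field applied to a planted cortical
#' patch (every source within `patch_radius` of `patch_center` emits the
#' biphasic waveform after each flash), plus spatially correlated pink
#' noise and an amplitude-modulated alpha rhythm at the paradigm's iAPF on
#' the posterior channels. The recording carries one zero reference
#' channel (last row) and all flash/break events; everything is seeded and
#' reproducible.
#'
#' @param L_direct `leadfield` whose columns cover the active patch
#'   (build with [build_direct_leadfield()]; `source_index` is honored)
#' @param patch_center 3-vector (m)
#' @param patch_radius patch radius (m)
#' @param spec a `paradigm_spec`
#' @param amplitude per-source peak strength (A m)
#' @param noise_rms pink-noise RMS per channel (V)
#' @param alpha_amp alpha-rhythm RMS on posterior channels (V)
#' @param posterior_labels channels carrying the alpha rhythm; default:
#'   channels in the x < 0 half of the montage (the synthetic cap's
#'   "occipital" side)
#' @param seed RNG seed
#' @return list with `recording` (`eeg_recording`) and `truth` (list of
#'   class `ground_truth`)
#' @export
simulate_vep_recording <- function(L_direct, patch_center, patch_radius,
                                   spec = paradigm_spec(),
                                   amplitude = 1e-8, noise_rms = 15e-6,
                                   alpha_amp = 5e-6,
                                   posterior_labels = NULL, seed = 1L) {
  set.seed(seed)
  ss <- L_direct$source_space
  pos <- ss$positions
  d2 <- (pos[, 1L] - patch_center[1L])^2 + (pos[, 2L] - patch_center[2L])^2 +
    (pos[, 3L] - patch_center[3L])^2
  active <- which(d2 <= patch_radius^2)
  if (!length(active)) stop("patch does not intersect the source space")
  if (!all(active %in% L_direct$source_index))
    stop("L_direct does not cover all patch sources")
  cols <- match(active, L_direct$source_index)
  ev <- generate_paradigm(spec)
  flashes <- ev$sample[ev$code == "flash"]
  trial_dur <- spec$flashes_per_trial / spec$frequency
  T <- round((spec$n_trials * (trial_dur + spec$break_s) + 1) * spec$fs)
  # per-flash waveform stamped on a shared source time course
  wlen <- round(0.25 * spec$fs)
  wt <- (seq_len(wlen) - 1L) / spec$fs
  w <- vep_waveform(wt, amplitude = amplitude)
  x <- numeric(T)
  for (s in flashes) {
    idx <- s:(s + wlen - 1L)
    ok <- idx <= T
    x[idx[ok]] <- x[idx[ok]] + w[ok]
  }
  Lg <- L_direct$matrix[, cols, drop = FALSE]
  clean <- rowSums(Lg) %o% x   # identical time course on all patch sources
  labels <- c(L_direct$channel_labels, L_direct$ref_label)
  nch <- length(labels)
  data <- rbind(clean, 0)
  if (noise_rms > 0) {
    K <- 20L
    mix <- matrix(rnorm(nch * K), nch, K) / sqrt(K)
    src <- vapply(seq_len(K), function(k) pink_noise(T, spec$fs),
                  numeric(T))
    noise <- mix %*% t(src) * noise_rms
    noise <- sweep(noise, 2L, noise[nch, ])  # re-reference to the ref row
    data <- data + noise
  }
  if (alpha_amp > 0) {
    mon <- L_direct$montage
    if (is.null(posterior_labels)) {
      px <- mon$x[match(L_direct$channel_labels, mon$label)]
      posterior_labels <- L_direct$channel_labels[px < 0]
    }
    tt <- (seq_len(T) - 1L) / spec$fs
    carrier <- sin(2 * pi * spec$iapf * tt + runif(1) * 2 * pi)
    env <- slow_envelope(T, spec$fs)
    alpha <- carrier * env
    alpha <- alpha / stats::sd(alpha) * alpha_amp
    rows <- match(posterior_labels, labels)
    gains <- 0.5 + runif(length(rows))
    data[rows, ] <- data[rows, ] + gains %o% alpha
  }
  rec <- eeg_recording(data, spec$fs, labels, ev,
                       reference = L_direct$ref_label)
  truth <- structure(list(active = active, patch_center = patch_center,
                          patch_radius = patch_radius,
                          amplitude = amplitude, peak_latency = 0.1,
                          iapf = spec$iapf, events = flashes,
                          seed = seed),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate resting-state EEG with a planted alpha peak
#'
#' Pink noise on all channels plus an amplitude-modulated sinusoid at the
#' requested alpha frequency on the occipital channels; used to validate
#' the alpha-peak estimator against a known ground truth.
#'
#' @param labels channel labels
#' @param occipital_labels channels carrying the alpha rhythm
#' @param duration recording length (s)
#' @param fs sampling rate (Hz)
#' @param iapf planted alpha peak frequency (Hz)
#' @param noise_rms pink-noise RMS (V)
#' @param alpha_amp alpha RMS on occipital channels (V)
#' @param seed RNG seed
#' @return an `eeg_recording`
#' @export
simulate_resting_recording <- function(labels, occipital_labels,
                                       duration = 300, fs = 1000,
                                       iapf = 10.2, noise_rms = 15e-6,
                                       alpha_amp = 10e-6, seed = 1L) {
  set.seed(seed)
  T <- round(duration * fs)
  nch <- length(labels)
  K <- min(20L, nch)
  mix <- matrix(rnorm(nch * K), nch, K) / sqrt(K)
  src <- vapply(seq_len(K), function(k) pink_noise(T, fs), numeric(T))
  data <- mix %*% t(src) * noise_rms
  tt <- (seq_len(T) - 1L) / fs
  carrier <- sin(2 * pi * iapf * tt + runif(1) * 2 * pi)
  env <- slow_envelope(T, fs)
  alpha <- carrier * env
  alpha <- alpha / stats::sd(alpha) * alpha_amp
  rows <- match(occipital_labels, labels)
  if (anyNA(rows)) stop("occipital labels not in labels")
  gains <- 0.7 + 0.6 * runif(length(rows))
  data[rows, ] <- data[rows, ] + gains %o% alpha
  eeg_recording(data, fs, labels)
}

#' Localization error of a source estimate
#'
#' Distance between the position of the strongest estimated source (max
#' |activity| over time) and the true patch center.
#'
#' @param est a `source_estimate`
#' @param truth a `ground_truth`
#' @param method "euclidean" (default) or "geodesic" (great-circle on the
#'   spherical source shell)
#' @return distance in meters
#' @export
localization_error <- function(est, truth, method = c("euclidean",
                                                      "geodesic")) {
  method <- match.arg(method)
  amp <- apply(abs(est$data), 1L, max)
  ipk <- est$source_index[which.max(amp)]
  p <- est$source_space$positions[ipk, ]
  q <- truth$patch_center
  if (method == "euclidean") {
    sqrt(sum((p - q)^2))
  } else {
    rp <- sqrt(sum(p^2)); rq <- sqrt(sum(q^2))
    r <- (rp + rq) / 2
    ang <- acos(pmin(1, pmax(-1, sum(p * q) / (rp * rq))))
    r * ang
  }
}
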