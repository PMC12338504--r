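test_that("bandpass filter rejects DC and passes mid-band tones", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  rec <- eeg_recording(rbind(rep(1, length(t)), sin(2 * pi * 10 * t)),
                       fs, c("dc", "tone"))
  out <- bandpass_filter(rec, 2, 45)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_lt(max(abs(out$data[1L, mid])), 0.01)            # DC gone
  expect_lt(abs(max(out$data[2L, mid]) - 1), 0.05)        # 10 Hz intact
  expect_error(bandpass_filter(rec, 0, 45), "band")
  expect_error(bandpass_filter(rec, 2, 300), "band")
})

test_that("filtering is linear", {
  fs <- 250
  set.seed(13)
  x <- matrix(rnorm(2 * 2500), 2)
  r1 <- bandpass_filter(eeg_recording(x, fs, c("a", "b")), 2, 45)
  r3 <- bandpass_filter(eeg_recording(3 * x, fs, c("a", "b")), 2, 45)
  expect_equal(r3$data, 3 * r1$data, tolerance = 1e-10)
})

test_that("Welch PSD localizes a planted tone at the design resolution", {
  fs <- 200
  t <- seq(1 / fs, 60, by = 1 / fs)
  x <- sin(2 * pi * 10.25 * t) + 0.1 * rnorm(length(t))
  w <- welch_psd(x, fs, seg_len = 4)
  expect_equal(w$freq[2L] - w$freq[1L], 0.25)
  expect_equal(w$freq[which.max(w$psd)], 10.25)
})

test_that("alpha peak is recovered from synthetic resting EEG", {
  labels <- sprintf("C%02d", 1:12)
  occ <- labels[9:12]
  rec <- simulate_resting_recording(labels, occ, duration = 210, fs = 250,
                                    iapf = 10.2, seed = 21)
  f <- estimate_iapf(rec, occ)
  expect_lt(abs(f - 10.2), 0.25)
  # amplitude invariance
  rec2 <- rec; rec2$data <- rec2$data * 7
  expect_equal(estimate_iapf(rec2, occ), f)
})

test_that("a pure sinusoid gives its own frequency as the alpha peak", {
  fs <- 250
  t <- seq(1 / fs, 210, by = 1 / fs)
  X <- rbind(sin(2 * pi * 11 * t), sin(2 * pi * 11 * t + 1),
             0.01 * rnorm(length(t)), 0.01 * rnorm(length(t)))
  rec <- eeg_recording(X, fs, c("O1", "O2", "F1", "F2"))
  expect_lt(abs(estimate_iapf(rec, c("O1", "O2")) - 11), 0.25)
})

test_that("iAPF estimation demands enough epochs and a true interior peak", {
  labels <- c("O1", "O2", "F1")
  short <- eeg_recording(matrix(rnorm(3 * 250 * 60), 3), 250, labels)
  expect_error(estimate_iapf(short, c("O1", "O2")), "epochs")
})

test_that("epoching honors windows, bounds and the baseline cap", {
  fs <- 1000
  X <- matrix(rnorm(2 * 200000), 2)
  ev <- seq(1000, 199000, by = 1000)
  rec <- eeg_recording(X, fs, c("a", "b"),
                       events = data.frame(sample = ev, code = "flash"))
  ep <- make_epochs(rec, kind = "stimulation")
  expect_equal(dim(ep$data)[3L], 250L)          # 250 ms at 1000 Hz
  expect_true(any(abs(ep$times) < 1e-12))      # time axis includes onset

  # event too close to the start is dropped
  rec2 <- eeg_recording(X, fs, c("a", "b"),
                        events = data.frame(sample = c(10L, 5000L),
                                            code = "flash"))
  ep2 <- make_epochs(rec2, kind = "stimulation")
  expect_equal(dim(ep2$data)[1L], 1L)

  # 25 breaks of 3.5 s capped at 20 baseline epochs
  brk <- seq(1000, 1000 + 24 * 4000, by = 4000)
  rec3 <- eeg_recording(matrix(rnorm(2 * 150000), 2), fs, c("a", "b"),
                        events = data.frame(sample = brk, code = "break"))
  bl <- make_epochs(rec3, kind = "baseline")
  expect_equal(dim(bl$data)[1L], 20L)
  expect_equal(dim(bl$data)[3L], 3500L)

  expect_error(make_epochs(rec, events = 1e7, kind = "stimulation"),
               "outside")
})

test_that("common average reference removes offsets and is idempotent", {
  X <- matrix(rnorm(4 * 100), 4) + 3
  rec <- eeg_recording(X, 100, letters[1:4])
  car <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-12)
  car2 <- common_average_reference(car)
  expect_equal(car2$data, car$data, tolerance = 1e-12)
  expect_error(common_average_reference(
    eeg_recording(X[1, , drop = FALSE], 100, "a")), "2 channels")
})

test_that("noise covariance estimation matches its contracts", {
  set.seed(14)
  # alpha = 1: exactly a scaled identity
  ep <- structure(list(data = array(rnorm(5 * 6 * 500), c(5, 6, 500)),
                       labels = letters[1:6], fs = 100, kind = "baseline"),
                  class = "eeg_epochs")
  nc1 <- estimate_noise_covariance(ep, shrinkage = 1)
  expect_equal(nc1$sigma, diag(6) * nc1$sigma[1, 1], tolerance = 1e-12)

  # white unit noise, alpha = 0: close to identity at 10^4 samples
  ep2 <- structure(list(data = array(rnorm(5 * 6 * 2000), c(5, 6, 2000)),
                        labels = letters[1:6], fs = 100, kind = "baseline"),
                   class = "eeg_epochs")
  nc0 <- estimate_noise_covariance(ep2, shrinkage = 0)
  expect_lt(norm(nc0$sigma - diag(6), "2"), 0.1)
  # whitener really whitens on the retained subspace
  W <- nc0$whitener
  expect_lt(norm(W %*% nc0$sigma %*% W - diag(6), "2"), 1e-8)

  # CAR'd data lose one dimension
  ep3 <- ep2
  for (e in 1:5) ep3$data[e, , ] <- sweep(ep3$data[e, , ], 2L,
                                          colMeans(ep3$data[e, , ]))
  ncc <- estimate_noise_covariance(ep3, shrinkage = 0)
  expect_equal(ncc$rank, 5L)

  tiny <- structure(list(data = array(rnorm(1 * 6 * 10), c(1, 6, 10)),
                         labels = letters[1:6], fs = 100,
                         kind = "baseline"), class = "eeg_epochs")
  expect_error(estimate_noise_covariance(tiny), "insufficient")
})

test_that("evoked averaging reduces noise like 1/sqrt(n)", {
  set.seed(15)
  mk <- function(n) structure(list(
    data = array(rnorm(n * 3 * 200), c(n, 3, 200)), labels = letters[1:3],
    fs = 100, kind = "stimulation", times = (0:199) / 100),
    class = "eeg_epochs")
  ep1 <- mk(1)
  expect_equal(evoked_average(ep1)$data, ep1$data[1, , ], tolerance = 1e-14)
  s100 <- sd(evoked_average(mk(100))$data)
  expect_lt(abs(s100 / 0.1 - 1), 0.2)
})

test_that("P100 latency is read from the global field power peak", {
  fs <- 1000
  times <- seq(-0.05, 0.2, by = 1 / fs)
  peak <- exp(-(times - 0.1)^2 / (2 * 0.01^2))
  topo <- c(1, -0.5, 0.8, -1.2)
  ev <- structure(list(data = topo %o% peak, times = times,
                       labels = letters[1:4], fs = fs, n_epochs = 1L),
                  class = "evoked")
  expect_lt(abs(find_p100_latency(ev) - 0.1), 0.002)

  # two equal peaks: the earlier one wins
  peak2 <- peak + exp(-(times - 0.14)^2 / (2 * 0.01^2))
  ev2 <- ev; ev2$data <- topo %o% peak2
  expect_lt(find_p100_latency(ev2), 0.12)

  flat <- ev; flat$data <- matrix(1, 4, length(times))
  expect_error(find_p100_latency(flat), "flat")
})
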