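# Artifact rejection, epoching, band-pass filtering.

test_that("clean recordings pass rejection unchanged with an empty report", {
  rec <- sine_recording()
  out <- reject_artifacts(rec)
  expect_equal(out$values, rec$values)
  expect_length(out$rejection$removed_blocks, 0)
  expect_equal(out$rejection$retained_seconds, 10)
})

test_that("a 12 pT spike removes exactly its 2-s block", {
  rec <- sine_recording(fs = 50, duration = 10)   # blocks: 0-2, 2-4, 4-6, ...
  rec$values[1, 5 * 50] <- 12e-12                  # spike at t = 5 s
  out <- reject_artifacts(rec)
  expect_equal(out$rejection$removed_blocks, 3L)   # the 4-6 s block
  expect_equal(out$rejection$retained_seconds, 8)
  # surviving samples are the untouched blocks, concatenated in order
  keep <- setdiff(seq_len(500), 201:300)
  expect_equal(out$values, rec$values[, keep])
})

test_that("an infinite threshold never removes anything", {
  rec <- sine_recording()
  rec$values[2, 17] <- 5e-9
  out <- reject_artifacts(rec, threshold = Inf)
  expect_equal(out$values, rec$values)
})

test_that("rejection is idempotent and errors when nothing survives", {
  rec <- sine_recording(fs = 50, duration = 10)
  rec$values[1, c(30, 270, 460)] <- 2e-11
  once <- reject_artifacts(rec)
  twice <- reject_artifacts(once)
  expect_equal(once$values, twice$values)
  expect_length(twice$rejection$removed_blocks, 0)
  allbad <- sine_recording(amp = 5e-11)
  expect_error(reject_artifacts(allbad), class = "megspect_no_data")
  expect_error(reject_artifacts(allbad), "S01")
})

test_that("epoch counts follow the floor rule", {
  fs <- 10
  expect_equal(dim(segment_epochs(
    meg_recording(matrix(0, 1, 112 * fs), fs))$epochs)[1], 56)
  expect_equal(dim(segment_epochs(
    meg_recording(matrix(0, 1, 30 * fs), fs))$epochs)[1], 15)
  ep <- segment_epochs(meg_recording(matrix(rnorm(49), 1), fs))
  expect_equal(dim(ep$epochs)[1], 2)   # 4.9 s -> 2 epochs, 0.9 s dropped
  expect_error(segment_epochs(meg_recording(matrix(0, 1, 5), fs)),
               class = "megspect_too_short")
})

test_that("epochs tile the recording without overlap", {
  fs <- 25
  rec <- meg_recording(matrix(seq_len(3 * 130), 3), fs)
  ep <- segment_epochs(rec, epoch_length = 2)
  expect_equal(dim(ep$epochs), c(2, 3, 50))
  expect_equal(ep$epochs[1, , ], rec$values[, 1:50])
  expect_equal(ep$epochs[2, , ], rec$values[, 51:100])
  expect_equal(dim(ep$epochs)[1] * ep$epoch_length, 4)
  expect_lte(dim(ep$epochs)[1] * ep$epoch_length, ncol(rec$values) / fs)
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  fs <- 250
  tt <- seq_len(10 * fs) / fs
  x <- matrix(sin(2 * pi * 9 * tt), 1)
  mid <- (2 * fs):(8 * fs)
  a1 <- bandpass_filter(x, meg_bands()[3, ], sampling_rate = fs)
  expect_gt(max(abs(a1[mid])), 0.95)       # < 5% attenuation in alpha1
  bt <- bandpass_filter(x, meg_bands()[5, ], sampling_rate = fs)
  expect_lt(max(abs(bt[mid])), 0.10)       # > 90% attenuation in beta
  expect_equal(bandpass_filter(matrix(0, 2, 500), meg_bands()[1, ],
                               sampling_rate = fs),
               matrix(0, 2, 500))
})

test_that("filtering is linear and zero-phase", {
  fs <- 100
  set.seed(4)
  x <- matrix(rnorm(2 * 1000), 2)
  y <- matrix(rnorm(2 * 1000), 2)
  b <- meg_bands()[3, ]
  fx <- bandpass_filter(x, b, sampling_rate = fs)
  fy <- bandpass_filter(y, b, sampling_rate = fs)
  fxy <- bandpass_filter(x + 2 * y, b, sampling_rate = fs)
  expect_equal(fxy, fx + 2 * fy, tolerance = 1e-10)
  # narrowband input passes with zero lag
  xc <- ccf(fx[1, 200:800], x[1, 200:800], lag.max = 10, plot = FALSE)
  expect_equal(xc$lag[which.max(abs(xc$acf))], 0)
})

test_that("the frequency-domain filter matches forward-backward Butterworth filtering", {
  skip_if_not_installed("signal")
  fs <- 250
  set.seed(1)
  r <- rnorm(2500)
  bf <- signal::butter(4, c(8, 10) / (fs / 2), "pass")
  ff <- signal::filtfilt(bf, r)
  mine <- as.numeric(bandpass_filter(matrix(r, 1), meg_bands()[3, ],
                                     sampling_rate = fs))
  mid <- 500:2000
  expect_gt(cor(mine[mid], ff[mid]), 0.999)
  expect_equal(sd(mine[mid]) / sd(ff[mid]), 1, tolerance = 0.01)
})

test_that("band edges above Nyquist are rejected", {
  expect_error(bandpass_filter(matrix(0, 1, 100), meg_bands()[5, ],
                               sampling_rate = 30),
               class = "megspect_nyquist")
  expect_error(band_spec("bad", 10, 5), class = "megspect_invalid_band")
})

test_that("epoch filtering equals filtering each epoch separately", {
  fs <- 50
  rec <- meg_recording(matrix(rnorm(3 * 500), 3), fs)
  ep <- segment_epochs(rec)
  epb <- bandpass_filter(ep, meg_bands()[2, ])
  one <- bandpass_filter(ep$epochs[2, , ], meg_bands()[2, ],
                         sampling_rate = fs)
  expect_equal(epb$epochs[2, , ], one, tolerance = 1e-12)
  expect_equal(epb$band, "theta2")
})
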