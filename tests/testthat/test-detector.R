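test_that("band-pass response passes the band and rejects out-of-band tones", {
  fs <- 200000
  t <- (1:fs) / fs
  p <- detector_params()
  in_band <- sin(2 * pi * 50000 * t)
  out <- bandpass(in_band, fs, p)
  rms_ratio_db <- 20 * log10(sd(out[1000:199000]) / sd(in_band[1000:199000]))
  expect_lt(abs(rms_ratio_db), 1)
  low <- sin(2 * pi * 1000 * t)
  out_low <- bandpass(low, fs, p)
  atten_db <- 20 * log10(sd(out_low[5000:195000]) / sd(low))
  expect_lt(atten_db, -40)
  expect_equal(bandpass(numeric(1000), fs, p), numeric(1000))
})

test_that("the filter is stable across supported sample rates", {
  for (fs in c(64000, 96000, 200000, 500000)) {
    p <- detector_params_for_fs(fs)
    imp <- c(1, numeric(fs %/% 10))
    h <- bandpass(imp, fs, p)
    expect_true(all(is.finite(h)))
    expect_lt(max(abs(tail(h, 100))), 1e-6)
  }
})

test_that("threshold crossing honours the peak-to-peak criterion", {
  fs <- 200000
  p <- detector_params()
  spec <- click_class_spec("c", 40000, 8000, 400e-6, 0.1)
  place_click <- function(rl) {
    x <- numeric(fs %/% 10)  # 100 ms
    w <- synth_click(spec, fs, rl)
    x[10000:(9999 + length(w))] <- w
    x
  }
  ev_hi <- detect_events(bandpass(place_click(125), fs, p), fs = fs, params = p)
  expect_identical(nrow(ev_hi), 1L)
  # a click 1 dB under threshold must not fire
  ev_lo <- detect_events(bandpass(place_click(119), fs, p), fs = fs, params = p)
  expect_identical(nrow(ev_lo), 0L)
  # plain noise well below threshold: nothing
  noise <- rnorm(fs %/% 10, sd = sqrt(10^(50 / 10) * fs / 2))
  ev_n <- detect_events(bandpass(noise, fs, p), fs = fs, params = p)
  expect_identical(nrow(ev_n), 0L)
})

test_that("events within the merge gap collapse and the merge is idempotent", {
  ev <- data.frame(start_s = c(0, 150e-6), end_s = c(100e-6, 250e-6),
                   peak_s = c(50e-6, 200e-6), peak_amp = c(1, 2))
  m <- merge_events(ev, 100e-6)
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$start_s, m$end_s), c(0, 250e-6))
  expect_equal(m$peak_s, 200e-6)  # the stronger member's peak
  expect_identical(merge_events(m, 100e-6), m)
  # a 200 us gap stays split
  ev2 <- data.frame(start_s = c(0, 300e-6), end_s = c(100e-6, 400e-6),
                    peak_s = c(50e-6, 350e-6), peak_amp = c(1, 1))
  expect_identical(nrow(merge_events(ev2, 100e-6)), 2L)
  empty <- ev[0, ]
  expect_identical(nrow(merge_events(empty, 100e-6)), 0L)
})

test_that("duration gating removes events outside 30-1200 us", {
  mk <- function(dur) data.frame(start_s = 0, end_s = dur, peak_s = dur / 2,
                                 peak_amp = 1)
  p <- detector_params()
  expect_identical(nrow(duration_filter(mk(20e-6), p)), 0L)
  expect_identical(nrow(duration_filter(mk(1500e-6), p)), 0L)
  expect_identical(nrow(duration_filter(mk(300e-6), p)), 1L)
})

test_that("extraction reports calibrated levels and spectra on the 500-Hz grid", {
  fs <- 200000
  p <- detector_params()
  # a pure sine snippet of amplitude 1 uPa has pp level 20 log10(2)
  t <- (1:2000) / fs
  x <- sin(2 * pi * 50000 * t)
  ev <- data.frame(start_s = 900 / fs, end_s = 1100 / fs, peak_s = 1000 / fs,
                   peak_amp = 1)
  d <- extract_detection(x, ev, fs, p)
  expect_equal(d$meta$rl_pp_db, 20 * log10(2), tolerance = 0.01)
  # spectrum length (100000 - 5000)/500 + 1
  expect_identical(ncol(d$spectrum), 191L)
  expect_equal(d$spectrum_freqs, seq(5000, 100000, by = 500))
  # a synthetic 40 kHz click peaks at the 40-kHz bin
  spec <- click_class_spec("c", 40000, 8000, 400e-6, 0.1)
  x2 <- numeric(4000)
  w <- synth_click(spec, fs, 130)
  x2[1900:(1899 + length(w))] <- w
  ev2 <- detect_events(x2, fs = fs, params = p)
  d2 <- extract_detection(x2, ev2, fs, p)
  f_peak <- d2$spectrum_freqs[which.max(d2$spectrum[1, ])]
  expect_lte(abs(f_peak - 40000), 500)
})

test_that("detector output does not depend on the streaming chunk size", {
  fx <- small_two_class_scene()
  aud <- read_audio(fx$scene$wav)
  whole <- detect_samples(aud$samples, aud$fs, fx$params)
  for (chunk in c(2.1, 5)) {
    chunked <- detect_file(fx$scene$wav, fx$params, chunk_seconds = chunk)
    expect_identical(nrow(chunked$meta), nrow(whole$meta))
    expect_equal(chunked$meta$time_s, whole$meta$time_s, tolerance = 1e-6)
    expect_equal(chunked$meta$rl_pp_db, whole$meta$rl_pp_db,
                 tolerance = 1e-6)
  }
})

test_that("the received-level diagnostic separates healthy from censored detectors", {
  rl <- sample_received_levels(2e4, 120, 170, seed = 55)
  expect_identical(rl_distribution_diagnostic(rl, 120)$flag, "pass")
  censored <- rl[rl >= 123]
  expect_identical(rl_distribution_diagnostic(censored, 120)$flag, "fail")
  expect_identical(rl_distribution_diagnostic(rl[1:50], 120)$flag,
                   "insufficient data")
})
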