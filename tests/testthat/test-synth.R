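test_that("synthesized pulses have the requested amplitude, length and spectral peak", {
  spec <- click_class_spec("t", center_freq = 40000, bandwidth = 10000,
                           duration = 300e-6, modal_idi = 0.1)
  # peak-to-peak amplitude is exact by construction
  w <- synth_click(spec, fs = 200000, rl_pp = 20 * log10(2))
  expect_equal(max(w) - min(w), 2.0, tolerance = 1e-6)
  # duration times sample rate sets the length
  expect_length(w, 60)
  # FFT peak lands within one bin of the requested centre frequency
  nfft <- 4096
  X <- Mod(fft(c(w, rep(0, nfft - length(w)))))[seq_len(nfft / 2)]
  f_peak <- (which.max(X) - 1) * 200000 / nfft
  expect_lt(abs(f_peak - 40000), 200000 / nfft + 1e-9)
})

test_that("pulse synthesis rejects out-of-band and malformed specifications", {
  spec <- click_class_spec("t", 40000, 10000, 300e-6, 0.1)
  expect_error(synth_click(spec, fs = 80000, rl_pp = 130), "Nyquist")
  expect_error(click_class_spec("bad", 40000, 10000, 10e-6, 0.1), "duration")
  expect_error(click_class_spec("bad", 40000, 10000, 300e-6, 1e-4), "modal_idi")
  expect_error(click_class_spec("bad", 3000, 10000, 300e-6, 0.1), "bandwidth")
})

test_that("received levels follow the uniform-area model", {
  rl <- sample_received_levels(1e5, min_rl = 120, source_level = 180,
                               seed = 31)
  h <- hist(rl, breaks = seq(120, 180, by = 1), plot = FALSE)$counts
  # counts rise monotonically toward the threshold (ignore the sparse
  # high-RL tail)
  expect_true(all(diff(h[1:20]) <= 0))
  # slope: counts drop by 10^(1/10) per dB above threshold
  expect_equal(h[1] / h[4], 10^(3 / 10), tolerance = 0.1)
  # truncation
  rl2 <- sample_received_levels(1000, 179.5, 180, seed = 4)
  expect_true(all(rl2 >= 179.5 & rl2 <= 180))
  expect_identical(sample_received_levels(0, 120, 180), numeric(0))
  expect_error(sample_received_levels(5, 180, 150), "below")
})

test_that("scene rendering is deterministic and schedules follow the modal IDI", {
  cls <- click_class_spec("c", 20000, 5000, 300e-6, modal_idi = 0.1,
                          idi_jitter = 0, source_level = 150)
  cfg <- scene_config(fs = 64000, total_duration = 11, noise_floor = 30,
                      classes = list(cls),
                      encounters = data.frame(class = "c", start = 0.5,
                                              end = 10.5),
                      min_rl = 130, seed = 5)
  d1 <- synth_scene(cfg, file.path(tempdir(), "det1"))
  # deterministic schedule: 10 s at 0.1 s spacing
  expect_true(abs(nrow(d1$truth) - 100) <= 1)
  expect_equal(diff(d1$truth$time_s), rep(0.1, nrow(d1$truth) - 1),
               tolerance = 1e-9)
  # identical seed, byte-identical WAV and truth
  d2 <- synth_scene(cfg, file.path(tempdir(), "det2"))
  expect_identical(readBin(d1$wav, "raw", file.size(d1$wav)),
                   readBin(d2$wav, "raw", file.size(d2$wav)))
  expect_identical(d1$truth, d2$truth)
})

test_that("an encounter-free scene yields no detections", {
  cfg <- scene_config(fs = 64000, total_duration = 5, noise_floor = 50,
                      classes = list(), encounters = NULL, min_rl = 120,
                      seed = 9, full_scale_db = 160)
  sc <- synth_scene(cfg, file.path(tempdir(), "noise_only"))
  expect_identical(nrow(sc$truth), 0L)
  det <- detect_file(sc$wav, detector_params_for_fs(64000))
  expect_identical(nrow(det$meta), 0L)
})

test_that("clipping scenes fail loudly instead of wrapping", {
  cls <- click_class_spec("loud", 20000, 5000, 300e-6, modal_idi = 0.1,
                          idi_jitter = 0, source_level = 180)
  cfg <- scene_config(fs = 64000, total_duration = 2, noise_floor = 30,
                      classes = list(cls),
                      encounters = data.frame(class = "loud", start = 0.2,
                                              end = 1.8),
                      min_rl = 179, seed = 2, full_scale_db = 170)
  expect_error(synth_scene(cfg, file.path(tempdir(), "clip")), "clipping")
})

test_that("injected levels are recovered within 0.5 dB on noise-free scenes", {
  cls <- click_class_spec("c", 20000, 5000, 300e-6, modal_idi = 0.15,
                          idi_jitter = 0.02, source_level = 160)
  cfg <- scene_config(fs = 64000, total_duration = 20, noise_floor = -20,
                      classes = list(cls),
                      encounters = data.frame(class = "c", start = 0.5,
                                              end = 19.5),
                      min_rl = 125, seed = 13)
  sc <- synth_scene(cfg, file.path(tempdir(), "rlacc"))
  det <- detect_file(sc$wav, detector_params_for_fs(64000))
  m <- match_truth(det$meta$time_s, sc$truth)
  expect_false(anyNA(m$class))
  expect_lt(max(abs(det$meta$rl_pp_db - m$rl_pp_db)), 0.5)
})
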