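# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; heavy scenes are only rendered when a test first asks
# for them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)()
  .fixtures[[name]]
}

# A small two-class scene (5 minutes, 64 kHz) exercising detection and
# phase-1 clustering quickly.
small_two_class_scene <- function() {
  fixture("small2", function() {
    classes <- list(
      click_class_spec("lowf", 9000, 4000, 350e-6, modal_idi = 0.12,
                       idi_jitter = 0.015, source_level = 160),
      click_class_spec("highf", 20000, 5000, 280e-6, modal_idi = 0.18,
                       idi_jitter = 0.02, source_level = 160)
    )
    cfg <- scene_config(
      fs = 64000, total_duration = 300, noise_floor = 50, classes = classes,
      encounters = data.frame(class = c("lowf", "highf"),
                              start = c(5, 10), end = c(290, 295)),
      min_rl = 125, seed = 2024
    )
    sc <- synth_scene(cfg, file.path(tempdir(), "small2"))
    det <- detect_file(sc$wav, detector_params_for_fs(cfg$fs))
    list(scene = sc, det = det, params = detector_params_for_fs(cfg$fs))
  })
}

# The received-level validation scene (10 min, 200 kHz, ~500 clicks at
# >= 121 dB pp over a 50 dB noise floor).
rl_validation_fixture <- function(seed = 123) {
  fixture("rlv", function() {
    sc <- synth_scene(scene_rl_validation(seed), file.path(tempdir(), "rlv"))
    det <- detect_file(sc$wav)
    list(scene = sc, det = det)
  })
}

# The two-hour class-discovery scene plus the full unsupervised pipeline;
# by far the most expensive fixture, shared by the end-to-end acceptance
# tests.
discovery_fixture <- function(seed = 77) {
  fixture("discovery", function() {
    sc <- synth_scene(scene_class_discovery(seed), file.path(tempdir(), "disc"))
    det <- detect_file(sc$wav, detector_params_for_fs(sc$config$fs))
    cfg <- discovery_reference_analysis()
    res <- discover_classes(det, cfg$p1, cfg$p2, seed = seed)
    lab <- template_truth_labels(res$templates, res$summaries, det, sc$truth)
    list(scene = sc, det = det, res = res, lab = lab)
  })
}

# Fabricated in-memory detection sets (no audio): Gaussian spectral bumps
# with additive noise, for clustering tests that do not need the detector.
fake_detections <- function(n_per_class, centers, times = NULL, fs = 64000,
                            noise = 1, seed = 99) {
  freqs <- seq(5000, 30000, by = 500)
  snip_n <- round(1e-3 * fs)
  n <- sum(n_per_class)
  stopifnot(length(n_per_class) == length(centers))
  cls <- rep(seq_along(centers), n_per_class)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  spectrum <- t(vapply(seq_len(n), function(i) {
    60 + 40 * exp(-(freqs - centers[cls[i]])^2 / (2 * 2000^2)) +
      rnorm(length(freqs), sd = noise)
  }, numeric(length(freqs))))
  tt <- seq_len(snip_n) / fs
  snippet <- t(vapply(seq_len(n), function(i) {
    1e5 * exp(-(tt - 5e-4)^2 / (2 * 1e-4^2)) * cos(2 * pi * centers[cls[i]] * tt)
  }, numeric(snip_n)))
  envelope <- t(apply(snippet, 1, analytic_envelope))
  if (is.null(times)) times <- sort(runif(n, 0, 299))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  meta <- data.frame(
    id = seq_len(n), file = "fake", time_s = times,
    start_s = times, end_s = times + 3e-4, rl_pp_db = 126,
    duration_us = 300
  )
  list(det = detection_set(meta, snippet, envelope, spectrum, fs, freqs),
       class = cls)
}

# Linearly separable Gaussian blobs for classifier tests.
blob_training_data <- function(n_per_class, dim = 24, n_classes = 2,
                               sep = 6, sd = 1, seed = 7,
                               centers_seed = 424242) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(centers_seed + dim * 1000 + n_classes)
  centers <- matrix(rnorm(n_classes * dim), n_classes, dim)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    matrix(rnorm(n_per_class * dim, sd = sd), n_per_class, dim) +
      matrix(centers[k, ], n_per_class, dim, byrow = TRUE)
  }))
  y <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  ord <- sample(length(y))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(x = x[ord, ], y = y[ord])
}

as_training_set <- function(x, y, class_names = NULL, encounter = NULL) {
  if (is.null(class_names)) class_names <- as.character(sort(unique(y)))
  structure(list(x = x, y = as.integer(y), class_names = class_names,
                 encounter = encounter %||% rep(NA_integer_, length(y)),
                 resampled = logical(0)),
            class = "training_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
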