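# Synthetic acoustic scenes with known ground truth.
#
# Scenes emulate the statistical structure a click-detection pipeline assumes:
# several impulsive signal classes with distinct spectral shapes and modal
# inter-detection intervals, received levels drawn from a uniform-area spatial
# model around a stationary sensor, encounter/bout temporal structure, and
# broadband or narrowband interferers, all over Gaussian background noise.

#' Specification of one synthetic signal class
#'
#' Defines the acoustic kernel of a class: a Gabor pulse (Gaussian-windowed
#' cosine) for echolocation-click and sonar-like kinds, or a noise-carrier
#' burst for ship-like broadband interferers. `bandwidth` is the -3 dB full
#' width of the Gaussian magnitude spectrum; `duration` is the generated
#' window length (the envelope-crossing duration measured by a detector is
#' shorter, and grows with received level).
#'
#' @param name class label.
#' @param center_freq spectral peak, Hz.
#' @param bandwidth -3 dB spectral width, Hz.
#' @param duration kernel window length, s. Click kinds must lie in
#'   30--1200 us, the duration gate of a typical generic impulse detector.
#' @param modal_idi modal inter-detection interval within an encounter, s.
#' @param idi_jitter standard deviation of IDI jitter, s.
#' @param source_level peak-to-peak source level at the nominal 1-m
#'   reference, dB re 1 uPa.
#' @param class_kind one of `"click"`, `"ship_like"`, `"sonar_like"`.
#' @return a `click_class_spec` list.
#' @export
click_class_spec <- function(name, center_freq, bandwidth, duration,
                             modal_idi, idi_jitter = 0, source_level = 170,
                             class_kind = c("click", "ship_like", "sonar_like")) {
  class_kind <- match.arg(class_kind)
  check_scalar(center_freq, "center_freq")
  check_scalar(bandwidth, "bandwidth")
  check_scalar(duration, "duration")
  check_scalar(modal_idi, "modal_idi")
  if (center_freq - bandwidth / 2 <= 0) {
    stopf("class '%s': bandwidth extends to or below 0 Hz", name)
  }
  if (class_kind == "click" && (duration < 30e-6 || duration > 1200e-6)) {
    stopf("class '%s': click duration must be within 30-1200 us", name)
  }
  if (modal_idi <= duration) stopf("class '%s': modal_idi must exceed duration", name)
  structure(list(
    name = as.character(name), center_freq = center_freq,
    bandwidth = bandwidth, duration = duration, modal_idi = modal_idi,
    idi_jitter = idi_jitter, source_level = source_level,
    class_kind = class_kind
  ), class = "click_class_spec")
}

#' Synthesize one calibrated pulse
#'
#' Generates the waveform of a single event of class `spec` at sample rate
#' `fs`, scaled so its peak-to-peak pressure is exactly
#' `10^(rl_pp/20)` uPa. Click and sonar kinds are deterministic Gabor
#' kernels; ship-like kinds draw a noise carrier from the current RNG
#' stream and spectrally shape it around `center_freq`.
#'
#' @param spec a [click_class_spec()].
#' @param fs sample rate, Hz.
#' @param rl_pp desired peak-to-peak level, dB re 1 uPa.
#' @return pressure waveform, uPa, of length `round(duration * fs)`.
#' @export
synth_click <- function(spec, fs, rl_pp) {
  if (spec$center_freq + spec$bandwidth / 2 >= fs / 2) {
    stopf("class '%s': spectrum reaches Nyquist at fs = %g Hz", spec$name, fs)
  }
  n <- max(4L, round(spec$duration * fs))
  t <- (seq_len(n) - (n + 1) / 2) / fs
  if (spec$class_kind %in% c("click", "sonar_like")) {
    # Gaussian sigma giving a -3 dB spectral full width of `bandwidth`
    sigma <- sqrt(log(2)) / (pi * spec$bandwidth)
    x <- exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * spec$center_freq * t)
  } else {
    # broadband burst: decaying envelope, noise carrier shaped in frequency
    carrier <- rnorm(n)
    f <- (seq_len(n) - 1) / n * fs
    f <- pmin(f, fs - f)
    shape <- exp(-((f - spec$center_freq)^2) / (2 * (spec$bandwidth / 1.2)^2))
    carrier <- Re(fft(fft(carrier) * shape, inverse = TRUE) / n)
    x <- exp(-abs(t) / (spec$duration / 5)) * carrier
  }
  pp <- max(x) - min(x)
  x / pp * db_to_amp(rl_pp)
}

#' Draw received levels for uniformly distributed sources
#'
#' Ranges are drawn with density proportional to range (sources uniform over
#' area around a stationary sensor) out to the range at which spherical
#' spreading from `source_level` reaches `min_rl`; levels follow
#' `RL = SL - 20 log10(r / 1 m)`. Consequently the expected count per 1-dB
#' bin rises toward `min_rl` as `10^((SL - RL)/10)`, i.e. log-linearly with
#' slope 1/10 per dB.
#'
#' @param n number of draws; `n <= 0` returns an empty vector.
#' @param min_rl truncation level, dB pp re 1 uPa.
#' @param source_level source level, dB pp re 1 uPa at 1 m.
#' @param seed optional integer seed (NULL uses the ambient RNG stream).
#' @return numeric vector of received levels in `[min_rl, source_level]`.
#' @export
sample_received_levels <- function(n, min_rl, source_level, seed = NULL) {
  if (n <= 0) return(numeric(0))
  if (min_rl >= source_level) stopf("min_rl must be below source_level")
  with_seed(seed, {
    r_max <- 10^((source_level - min_rl) / 20)
    r <- r_max * sqrt(runif(n))
    source_level - 20 * log10(pmax(r, 1))
  })
}

#' Scene configuration
#'
#' @param fs sample rate, Hz; must exceed twice the highest class frequency.
#' @param total_duration scene length, s.
#' @param noise_floor background noise spectral density, dB re 1 uPa^2/Hz
#'   (white across the band).
#' @param classes list of [click_class_spec()] objects.
#' @param encounters data.frame with columns `class`, `start`, `end`
#'   (seconds); overlapping encounters of different classes are allowed.
#' @param min_rl lowest received level injected, dB pp re 1 uPa.
#' @param seed integer seed controlling the whole scene.
#' @param full_scale_db peak pressure level mapped to WAV full scale, dB re
#'   1 uPa; defaults to the loudest source level, leaving 6 dB of headroom
#'   over a single on-axis arrival.
#' @return a `scene_config` list.
#' @export
scene_config <- function(fs, total_duration, noise_floor, classes, encounters,
                         min_rl = 120, seed = 1L, full_scale_db = NULL) {
  check_scalar(fs, "fs"); check_scalar(total_duration, "total_duration")
  if (!is.data.frame(encounters) && length(encounters)) {
    encounters <- do.call(rbind, lapply(encounters, as.data.frame))
  }
  if (is.null(encounters) || !nrow(encounters)) {
    encounters <- data.frame(class = character(), start = numeric(), end = numeric())
  }
  names(classes) <- vapply(classes, `[[`, "", "name")
  for (sp in classes) {
    if (sp$center_freq + sp$bandwidth / 2 >= fs / 2) {
      stopf("class '%s' exceeds the Nyquist frequency", sp$name)
    }
  }
  if (nrow(encounters)) {
    bad <- !(encounters$class %in% names(classes))
    if (any(bad)) stopf("encounter class '%s' not defined", encounters$class[bad][1])
    if (any(encounters$start < 0 | encounters$end > total_duration |
              encounters$start >= encounters$end)) {
      stopf("encounters must satisfy 0 <= start < end <= total_duration")
    }
  }
  if (is.null(full_scale_db)) {
    full_scale_db <- if (length(classes)) {
      max(vapply(classes, `[[`, 0, "source_level"))
    } else 160
  }
  structure(list(
    fs = fs, total_duration = total_duration, noise_floor = noise_floor,
    classes = classes, encounters = encounters, min_rl = min_rl,
    seed = as.integer(seed), full_scale_db = full_scale_db
  ), class = "scene_config")
}

# Draw the click schedule for all encounters; deterministic given the RNG
# state. Returns the truth table plus per-click waveforms.
schedule_scene <- function(config) {
  rows <- list(); waves <- list(); k <- 0L
  for (e in seq_len(nrow(config$encounters))) {
    enc <- config$encounters[e, ]
    spec <- config$classes[[enc$class]]
    t <- enc$start + runif(1) * spec$modal_idi
    times <- numeric(0)
    while (t < enc$end - spec$duration) {
      times <- c(times, t)
      step <- spec$modal_idi + rnorm(1, 0, spec$idi_jitter)
      t <- t + max(step, spec$duration * 2, spec$modal_idi * 0.1)
    }
    n <- length(times)
    if (!n) next
    rl <- sample_received_levels(n, config$min_rl, spec$source_level)
    for (i in seq_len(n)) {
      k <- k + 1L
      waves[[k]] <- synth_click(spec, config$fs, rl[i])
      rows[[k]] <- data.frame(
        time_s = times[i], class = spec$name, rl_pp_db = rl[i], encounter_id = e
      )
    }
  }
  truth <- if (k) do.call(rbind, rows) else
    data.frame(time_s = numeric(), class = character(),
               rl_pp_db = numeric(), encounter_id = integer())
  list(truth = truth, waves = waves)
}

#' Render a synthetic scene to WAV plus ground truth
#'
#' Draws the click schedule and received levels, sums all events with
#' Gaussian background noise at the configured spectral density, and streams
#' the quantized pressure series to a 16-bit PCM WAV with a calibration
#' sidecar. Audio is generated chunk-wise so scenes of hours need not fit in
#' memory; the chunking is fixed, so a given seed yields a byte-identical
#' file. Clipping at WAV full scale raises an error rather than wrapping.
#'
#' @param config a [scene_config()].
#' @param out_dir output directory (created if needed).
#' @param name basename for the WAV/CSV/JSON outputs.
#' @return list with `wav`, `calibration`, `truth_csv` paths and the truth
#'   data.frame (`time_s`, `class`, `rl_pp_db`, `encounter_id`).
#' @export
synth_scene <- function(config, out_dir = tempfile("scene"), name = "scene") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fs <- config$fs
  n_total <- round(config$total_duration * fs)
  counts_per_upa <- 32000 / db_to_amp(config$full_scale_db)
  sensitivity_db <- amp_to_db(counts_per_upa)
  noise_sd <- sqrt(10^(config$noise_floor / 10) * fs / 2)

  wav_path <- file.path(out_dir, paste0(name, ".wav"))
  cal_path <- file.path(out_dir, paste0(name, "_calibration.json"))
  csv_path <- file.path(out_dir, paste0(name, "_truth.csv"))

  with_seed(config$seed, {
    sched <- schedule_scene(config)
    truth <- sched$truth
    ord <- order(truth$time_s)
    waves <- sched$waves[ord]
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    # absolute start sample of each click waveform
    lens <- vapply(waves, length, 0L)
    starts <- round(truth$time_s * fs) - floor(lens / 2) + 1
    ends <- starts + lens - 1
    wr <- wav_writer(wav_path, fs, n_total, bits = 16L)
    chunk_n <- as.integer(2^20)
    c0 <- 1
    while (c0 <= n_total) {
      c1 <- min(c0 + chunk_n - 1, n_total)
      x <- rnorm(c1 - c0 + 1, sd = noise_sd)
      idx <- which(starts <= c1 & ends >= c0)
      for (i in idx) {
        w <- waves[[i]]
        s0 <- starts[i]; s1 <- s0 + length(w) - 1L
        a <- max(s0, c0); b <- min(s1, c1)
        x[(a - c0 + 1L):(b - c0 + 1L)] <- x[(a - c0 + 1L):(b - c0 + 1L)] +
          w[(a - s0 + 1L):(b - s0 + 1L)]
      }
      wr$write(round(x * counts_per_upa))
      c0 <- c1 + 1L
    }
    wr$close()
  })

  write_calibration(cal_path, fs, sensitivity_db)
  data.table::fwrite(truth, csv_path)
  list(wav = wav_path, calibration = cal_path, truth_csv = csv_path,
       truth = truth, config = config)
}
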