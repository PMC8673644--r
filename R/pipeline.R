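# End-to-end drivers and reference synthetic study conditions, used by the
# examples, the test-suite and the acceptance script alike.

#' Reference scene: received-level validation
#'
#' A 10-minute single-class scene at the detector's native configuration
#' (200 kHz sampling, 5--100 kHz band): roughly 1600 echolocation clicks
#' with received levels from the uniform-area model truncated at 116 dB pp
#' re 1 uPa -- well below the 120-dB detection threshold, so the
#' detector's *measured* level histogram (whose weakest clicks carry about
#' +1 dB of noise-induced bias) is a clean threshold truncation -- over a
#' 50 dB re 1 uPa^2/Hz noise floor. About 500 of the injected clicks lie
#' at or above 121 dB (threshold + 1 dB), the population on which detector
#' recovery and received-level accuracy are measured.
#'
#' @param seed scene seed.
#' @return a [scene_config()].
#' @export
scene_rl_validation <- function(seed = 1L) {
  cls <- click_class_spec("delphinid", center_freq = 35000, bandwidth = 6000,
                          duration = 400e-6, modal_idi = 0.375,
                          idi_jitter = 0.1, source_level = 165,
                          class_kind = "click")
  scene_config(
    fs = 200000, total_duration = 600, noise_floor = 50,
    classes = list(cls),
    encounters = data.frame(class = "delphinid", start = 2, end = 598),
    min_rl = 116, seed = seed
  )
}

#' Reference scene: class discovery
#'
#' A two-hour scene at 64 kHz with four echolocation click classes of
#' distinct spectral shapes and modal inter-detection intervals plus one
#' narrowband sonar-like interferer. Each class occurs in six four-minute
#' encounters separated by more than 15 minutes of class silence, with
#' encounters of different classes overlapping in time; received levels
#' follow the uniform-area model down to 125 dB pp.
#'
#' @param seed scene seed.
#' @return a [scene_config()].
#' @export
scene_class_discovery <- function(seed = 1L) {
  classes <- list(
    click_class_spec("click_a", 9000, 4000, 350e-6, modal_idi = 0.12,
                     idi_jitter = 0.015, source_level = 160),
    click_class_spec("click_b", 14000, 5000, 300e-6, modal_idi = 0.08,
                     idi_jitter = 0.010, source_level = 160),
    click_class_spec("click_c", 20000, 5000, 280e-6, modal_idi = 0.18,
                     idi_jitter = 0.020, source_level = 160),
    click_class_spec("click_d", 25500, 4000, 320e-6, modal_idi = 0.25,
                     idi_jitter = 0.030, source_level = 160),
    click_class_spec("sonar", 6500, 1500, 1000e-6, modal_idi = 1.2,
                     idi_jitter = 0.05, source_level = 150,
                     class_kind = "sonar_like")
  )
  enc <- do.call(rbind, lapply(0:4, function(k) {
    data.frame(class = classes[[k + 1]]$name,
               start = (0:5) * 1200 + k * 160,
               end = (0:5) * 1200 + k * 160 + 240)
  }))
  scene_config(fs = 64000, total_duration = 7200, noise_floor = 50,
               classes = classes, encounters = enc, min_rl = 125,
               seed = seed)
}

#' Reference analysis configuration for the class-discovery scene
#'
#' Desk-scale analysis parameters paired with [scene_class_discovery()]:
#' phase-1 bins are capped at 2000 detections before pairwise comparison,
#' and phase 2 keeps the top 20% of edges with a minimum template size of 5
#' summaries. A two-hour scene yields only a few dozen bin summaries, so
#' the 2--10% edge retention appropriate for datasets of tens of thousands
#' of bins would leave too few edges to connect five clusters; 20% matches
#' the expected within-class pair share at this scale.
#'
#' @return list with `p1` ([phase1_params()]) and `p2` ([phase2_params()]).
#' @export
discovery_reference_analysis <- function() {
  list(p1 = phase1_params(max_nodes = 2000),
       p2 = phase2_params(min_size = 5, retain_fraction = 0.2))
}

#' Detector parameters matched to a scene's sample rate
#'
#' The full-band defaults assume 200 kHz audio; for scenes sampled slower
#' the band top is pulled under Nyquist while keeping every other default.
#'
#' @param fs scene sample rate, Hz.
#' @param ... overrides passed to [detector_params()].
#' @export
detector_params_for_fs <- function(fs, ...) {
  over <- list(...)
  if (is.null(over$band_high)) {
    over$band_high <- if (fs >= 200000) 100000 else
      floor(fs * 0.47 / 500) * 500
  }
  do.call(detector_params, over)
}

#' Match detections to a scene truth table
#'
#' Each detection is matched to the nearest truth click in time within
#' `tol_s`; unmatched detections get `NA` (noise or interferer overlap).
#'
#' @param det_times detection times, s.
#' @param truth truth data.frame from [synth_scene()].
#' @param tol_s matching tolerance, s.
#' @return data.frame with `truth_row`, `class`, `rl_pp_db`, `dt` per
#'   detection (NA when unmatched).
#' @export
match_truth <- function(det_times, truth, tol_s = 5e-4) {
  ord <- order(truth$time_s)
  tt <- truth$time_s[ord]
  pos <- findInterval(det_times, tt)
  lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(tt))
  d_lo <- abs(det_times - tt[lo]); d_hi <- abs(det_times - tt[hi])
  pick <- ifelse(d_hi < d_lo, hi, lo)
  dt <- abs(det_times - tt[pick])
  ok <- dt <= tol_s & length(tt) > 0
  row <- ifelse(ok, ord[pick], NA_integer_)
  data.frame(truth_row = row,
             class = ifelse(ok, truth$class[row], NA_character_),
             rl_pp_db = ifelse(ok, truth$rl_pp_db[row], NA_real_),
             dt = ifelse(ok, dt, NA_real_))
}

#' Unsupervised class discovery on a detection set
#'
#' Runs phase-1 per-bin clustering followed by phase-2 template formation.
#'
#' @param det a [detection_set()].
#' @param p1,p2 [phase1_params()] / [phase2_params()].
#' @param seed integer seed split between the two phases.
#' @return list with `summaries`, `templates`, `partition`, `duplicates`.
#' @export
discover_classes <- function(det, p1 = phase1_params(),
                             p2 = phase2_params(), seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  summaries <- cluster_phase1(det, p1, seed = seeds[1])
  if (!length(summaries)) {
    return(list(summaries = summaries, templates = list(), partition = NULL,
                duplicates = empty_dup_table()))
  }
  res <- cluster_summaries(summaries, p2, seed = seeds[2])
  c(list(summaries = summaries), res)
}

#' Train and evaluate both classifiers from labelled templates
#'
#' The supervised half of the workflow: labels attached to phase-2
#' templates are propagated to member detections and member summaries,
#' events are split into encounters (15-minute class silences) which are
#' assigned 60/10/30 to train/validation/test, balanced input sets are
#' assembled, and the fixed 4x512 network is trained twice -- once on
#' standardized individual detections, once on bin-level average vectors --
#' and evaluated on the held-out encounters. Encounter leakage across the
#' three splits is asserted, not assumed.
#'
#' @param det the [detection_set()].
#' @param summaries,templates from [discover_classes()].
#' @param label_map template labels (analyst map or
#'   [template_truth_labels()]).
#' @param seed integer seed driving splitting, balancing and training.
#' @param n_detection train/val/test detections per class.
#' @param n_bin train/val/test bin summaries per class.
#' @param bin_duration phase-1 bin length, s (for bin timestamps).
#' @param max_epochs training epoch cap.
#' @return list with `detection` and `bin`, each holding `model`,
#'   `accuracy` (held-out), `confusion`, `preds`, `truth`; plus
#'   `detections` (the labelled detection table with split assignment).
#' @export
classification_study <- function(det, summaries, templates, label_map,
                                 seed = 1L,
                                 n_detection = c(2000, 500, 1000),
                                 n_bin = c(500, 100, 200),
                                 bin_duration = 300, max_epochs = 15) {
  seeds <- derive_seeds(seed, 6L)
  labelled <- assign_labels(templates, summaries, label_map)
  ddf <- labelled$detections
  if (!nrow(ddf)) stopf("no labelled detections to learn from")
  ddf$time_s <- det$meta$time_s[match(ddf$detection_id, det$meta$id)]
  classes <- sort(unique(ddf$label))

  enc <- split_encounters(ddf$time_s, ddf$label, gap_s = 900)
  part <- partition_encounters(enc, seed = seeds[1])
  ddf$encounter <- part$encounter
  ddf$set <- part$set
  assert_no_leakage(ddf$encounter[ddf$set == "train"],
                    ddf$encounter[ddf$set == "val"],
                    ddf$encounter[ddf$set == "test"])

  det_set <- function(which_set, n_per_class, s) {
    rows <- which(ddf$set == which_set)
    ridx <- match(ddf$detection_id[rows], det$meta$id)
    x <- build_detection_input(det$spectrum[ridx, , drop = FALSE],
                               det$snippet[ridx, , drop = FALSE])
    build_training_set(x, ddf$label[rows], ddf$encounter[rows],
                       n_per_class, seed = s, classes = classes)
  }
  tr <- det_set("train", n_detection[1], seeds[2])
  va <- det_set("val", n_detection[2], seeds[2] + 1L)
  te <- det_set("test", n_detection[3], seeds[2] + 2L)
  model_d <- train_mlp(mlp_spec(ncol(tr$x), length(classes)),
                       train_config(batch_size = 2000, seed = seeds[3],
                                    max_epochs = max_epochs), tr, va)
  preds_d <- predict(model_d, te$x)
  truth_d <- classes[te$y + 1L]
  cm_d <- confusion(truth_d, preds_d$label, classes)

  # bin level: one item per labelled summary
  sdf <- data.frame(
    idx = which(!is.na(labelled$summary_labels)),
    label = labelled$summary_labels[!is.na(labelled$summary_labels)]
  )
  sdf$bin <- vapply(summaries[sdf$idx], `[[`, 0, "bin")
  sdf$time_s <- sdf$bin * bin_duration
  enc_b <- split_encounters(sdf$time_s, sdf$label, gap_s = 900)
  part_b <- partition_encounters(enc_b, seed = seeds[4])
  sdf$encounter <- part_b$encounter
  sdf$set <- part_b$set
  assert_no_leakage(sdf$encounter[sdf$set == "train"],
                    sdf$encounter[sdf$set == "val"],
                    sdf$encounter[sdf$set == "test"])
  bin_inputs <- t(vapply(summaries[sdf$idx], build_bin_input,
                         build_bin_input(summaries[[sdf$idx[1]]])))
  bin_set <- function(which_set, n_per_class, s) {
    rows <- which(sdf$set == which_set)
    build_training_set(bin_inputs[rows, , drop = FALSE], sdf$label[rows],
                       sdf$encounter[rows], n_per_class, seed = s,
                       classes = classes)
  }
  tr_b <- bin_set("train", n_bin[1], seeds[5])
  va_b <- bin_set("val", n_bin[2], seeds[5] + 1L)
  te_b <- bin_set("test", n_bin[3], seeds[5] + 2L)
  model_b <- train_mlp(mlp_spec(ncol(tr_b$x), length(classes)),
                       train_config(batch_size = 100, seed = seeds[6],
                                    max_epochs = max_epochs), tr_b, va_b)
  preds_b <- predict(model_b, te_b$x)
  truth_b <- classes[te_b$y + 1L]
  cm_b <- confusion(truth_b, preds_b$label, classes)

  list(
    detection = list(model = model_d, accuracy = cm_d$accuracy,
                     confusion = cm_d, preds = preds_d, truth = truth_d),
    bin = list(model = model_b, accuracy = cm_b$accuracy,
               confusion = cm_b, preds = preds_b, truth = truth_b,
               summary_table = sdf, inputs = bin_inputs),
    detections = ddf, classes = classes
  )
}

#' Name templates from ground truth (synthetic analyst)
#'
#' For synthetic scenes the expert-review step is emulated by majority
#' vote: each template is named after the truth class of the majority of
#' its member detections. Real deployments replace this with an analyst
#' label map.
#'
#' @param templates,summaries from [discover_classes()].
#' @param det the [detection_set()] the summaries index into.
#' @param truth scene truth table.
#' @return list with `label_map` (named character), `purity` (majority
#'   fraction per template), `majority` (class per template).
#' @export
template_truth_labels <- function(templates, summaries, det, truth) {
  mt <- match_truth(det$meta$time_s, truth)
  cls_by_id <- mt$class[match(seq_len(nrow(det$meta)), det$meta$id)]
  label_map <- character(); purity <- numeric(); majority <- character()
  for (tpl in templates) {
    ids <- unlist(lapply(summaries[tpl$summary_idx], `[[`, "member_ids"))
    cls <- cls_by_id[match(ids, det$meta$id)]
    cls <- cls[!is.na(cls)]
    if (!length(cls)) {
      label_map[as.character(tpl$class_id)] <- "unlabeled"
      purity <- c(purity, NA_real_); majority <- c(majority, NA_character_)
      next
    }
    tab <- sort(table(cls), decreasing = TRUE)
    label_map[as.character(tpl$class_id)] <- names(tab)[1]
    purity <- c(purity, as.numeric(tab[1]) / sum(tab))
    majority <- c(majority, names(tab)[1])
  }
  list(label_map = label_map, purity = purity, majority = majority)
}
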