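# Encounter-aware train/validation/test splitting and balanced assembly of
# standardized input vectors for the detection-level and bin-level networks.

#' Split labelled events into encounters
#'
#' Within each class, events sorted by time are cut into encounters wherever
#' the gap to the previous event reaches `gap_s` (15 minutes by default).
#' Encounters are the unit of train/test splitting, preventing leakage of
#' nearly identical neighbouring events across sets.
#'
#' @param times event times, s.
#' @param labels class label per event.
#' @param gap_s minimum silent gap separating encounters of one class, s.
#' @return data.frame with `time_s`, `label`, `encounter` (id unique across
#'   classes), in the input order.
#' @export
split_encounters <- function(times, labels, gap_s = 900) {
  stopifnot(length(times) == length(labels))
  encounter <- integer(length(times))
  next_id <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    ord <- idx[order(times[idx])]
    gaps <- c(Inf, diff(times[ord]))
    enc <- cumsum(gaps >= gap_s) + next_id
    encounter[ord] <- enc
    next_id <- max(enc)
  }
  data.frame(time_s = times, label = labels, encounter = encounter)
}

#' Assign encounters to train/validation/test
#'
#' Encounters of each class are shuffled and allotted to the three sets in
#' the given proportions (largest-remainder rounding). When a class has at
#' least three encounters every set receives at least one; with fewer, the
#' assignment degrades gracefully (train and test first) with a warning.
#'
#' @param encounters data.frame from [split_encounters()].
#' @param fractions train/validation/test proportions, summing to 1.
#' @param seed integer seed.
#' @return the input data.frame with a `set` column
#'   (`"train"`/`"val"`/`"test"`).
#' @export
partition_encounters <- function(encounters, fractions = c(0.6, 0.1, 0.3),
                                 seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  set_names <- c("train", "val", "test")
  enc_class <- unique(encounters[c("label", "encounter")])
  assignment <- character(0)
  with_seed(seed, {
    for (cl in unique(enc_class$label)) {
      ids <- sample(enc_class$encounter[enc_class$label == cl])
      n <- length(ids)
      counts <- floor(fractions * n)
      rem <- fractions * n - counts
      for (k in order(rem, decreasing = TRUE)) {
        if (sum(counts) == n) break
        counts[k] <- counts[k] + 1L
      }
      if (n >= 3 && any(counts == 0)) {
        # guarantee each split at least one encounter
        for (k in which(counts == 0)) {
          donor <- which.max(counts)
          counts[k] <- 1L; counts[donor] <- counts[donor] - 1L
        }
      }
      if (n < 3) {
        warning(sprintf(
          "class '%s' has only %d encounter(s); cannot fill all three splits",
          cl, n), call. = FALSE)
        counts <- if (n == 2) c(1L, 0L, 1L) else c(n, 0L, 0L)
      }
      sets <- rep(set_names, counts)
      assignment[as.character(ids)] <- sets
    }
  })
  encounters$set <- assignment[as.character(encounters$encounter)]
  encounters
}

#' Balanced per-class sampling
#'
#' Draws exactly `n_per_class` items from each class: without replacement
#' when the pool suffices, with replacement otherwise (flagged per class).
#'
#' @param labels class label per pool item.
#' @param n_per_class rows drawn per class.
#' @param seed integer seed.
#' @param classes classes to sample; defaults to all present.
#' @return list with `idx` (pool row indices), `labels`, and `resampled`
#'   (named logical: TRUE where replacement was needed).
#' @export
sample_balanced <- function(labels, n_per_class, seed = 1L,
                            classes = sort(unique(labels))) {
  if (n_per_class <= 0) {
    return(list(idx = integer(), labels = character(),
                resampled = logical(0)))
  }
  with_seed(seed, {
    idx <- integer(0); resampled <- logical(0)
    for (cl in classes) {
      pool <- which(labels == cl)
      if (!length(pool)) stopf("class '%s' has no items to sample", cl)
      short <- length(pool) < n_per_class
      take <- if (short) sample(pool, n_per_class, replace = TRUE) else
        sample(pool, n_per_class)
      idx <- c(idx, take)
      resampled[cl] <- short
    }
    list(idx = idx, labels = labels[idx], resampled = resampled)
  })
}

#' Standardized input vector for one detection
#'
#' Concatenates the spectrum, shifted by a static low value (70 dB re
#' 1 uPa^2/Hz) and divided by a static high value (130 dB), with the
#' waveform snippet divided by a typical maximum pressure amplitude. The
#' static constants keep amplitude information between detections while
#' placing most values inside \[-1, 1\].
#'
#' @param spectrum spectrum in dB re 1 uPa^2/Hz (vector or matrix rows).
#' @param snippet waveform in uPa (vector or matrix rows).
#' @param spec_low,spec_high spectrum standardization constants, dB.
#' @param waveform_max waveform divisor, uPa; the default is the amplitude
#'   of a 132 dB pp signal.
#' @return numeric vector (or matrix), length `ncol(spectrum) +
#'   ncol(snippet)`.
#' @export
build_detection_input <- function(spectrum, snippet, spec_low = 70,
                                  spec_high = 130,
                                  waveform_max = 10^(132 / 20)) {
  if (is.matrix(spectrum)) {
    return(cbind((spectrum - spec_low) / spec_high, snippet / waveform_max))
  }
  c((spectrum - spec_low) / spec_high, snippet / waveform_max)
}

#' Standardized input vector for one bin-cluster summary
#'
#' Concatenates the min-max normalized mean spectrum, the IDI histogram
#' rescaled to a maximum of 1, and the normalized mean envelope, all in
#' \[0, 1\].
#'
#' @param summary a `bin_cluster_summary`.
#' @return numeric vector of length `spectrum + idi + envelope`.
#' @export
build_bin_input <- function(summary) {
  idi <- summary$idi_hist
  if (max(idi) > 0) idi <- idi / max(idi)
  c(summary$mean_spectrum, idi, summary$mean_envelope)
}

#' Assemble a balanced training matrix
#'
#' @param inputs matrix of standardized vectors (one row per item).
#' @param labels class label per row.
#' @param encounter encounter id per row (for provenance/leakage checks).
#' @param n_per_class rows per class after balancing.
#' @param seed integer seed.
#' @param classes class name ordering shared across train/val/test sets.
#' @return a `training_set`: `x` (matrix), `y` (integer codes 0..N-1),
#'   `class_names`, `encounter`, `resampled`.
#' @export
build_training_set <- function(inputs, labels, encounter = NULL,
                               n_per_class, seed = 1L,
                               classes = sort(unique(labels))) {
  s <- sample_balanced(labels, n_per_class, seed, classes)
  structure(list(
    x = inputs[s$idx, , drop = FALSE],
    y = match(s$labels, classes) - 1L,
    class_names = classes,
    encounter = if (is.null(encounter)) rep(NA_integer_, length(s$idx))
                else encounter[s$idx],
    resampled = s$resampled
  ), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d x %d, %d classes (%s)\n",
              nrow(x$x), ncol(x$x), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Assert that no encounter leaks across splits
#'
#' @param ... two or more vectors of encounter ids (e.g. from the train,
#'   validation and test sets).
#' @return TRUE invisibly; errors if any id appears in more than one set.
#' @export
assert_no_leakage <- function(...) {
  sets <- list(...)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) {
      common <- intersect(unique(sets[[i]]), unique(sets[[j]]))
      common <- common[!is.na(common)]
      if (length(common)) {
        stopf("encounter leakage between splits: ids %s",
              paste(head(common, 5), collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}
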