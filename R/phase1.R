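# Phase 1: cluster detections within successive time bins and summarize each
# bin-level cluster by its mean spectrum, mean envelope and inter-detection
# interval (IDI) histogram.

#' Phase-1 parameters
#'
#' @param bin_duration analysis bin length, s (five minutes by default).
#' @param min_bin_count bins with fewer detections are skipped.
#' @param min_cluster_size clusters below this detection count are dropped.
#' @param max_nodes random subsampling cap on detections per bin before
#'   pairwise comparison.
#' @param retain_fraction fraction of strongest edges retained for
#'   clustering (edge pruning).
#' @param dup_threshold similarity at which detections are merged as near
#'   duplicates.
#' @param idi_edges histogram bin edges for inter-detection intervals, s.
#'   The default 0--1 s in 10-ms steps spans delphinid click rates (modal
#'   intervals near 0.06 s) through slower beaked-whale clicking.
#' @param cw_max_iter Chinese Whispers iteration cap.
#' @param feature phase-1 similarity feature: spectra (default) or
#'   envelopes.
#' @export
phase1_params <- function(bin_duration = 300, min_bin_count = 50,
                          min_cluster_size = 50, max_nodes = 1e4,
                          retain_fraction = 0.1, dup_threshold = 0.98,
                          idi_edges = seq(0, 1, by = 0.01),
                          cw_max_iter = 25,
                          feature = c("spectrum", "envelope")) {
  structure(list(
    bin_duration = bin_duration, min_bin_count = min_bin_count,
    min_cluster_size = min_cluster_size, max_nodes = max_nodes,
    retain_fraction = retain_fraction, dup_threshold = dup_threshold,
    idi_edges = idi_edges, cw_max_iter = cw_max_iter,
    feature = match.arg(feature)
  ), class = "phase1_params")
}

#' Assign detections to time bins
#'
#' Bins tile the recording as half-open intervals
#' `[k * bin_duration, (k + 1) * bin_duration)`; each detection falls in
#' exactly one bin by `floor(time / bin_duration)`. Empty bins are omitted.
#'
#' @param meta detection metadata with a `time_s` column.
#' @param bin_duration bin length, s.
#' @return data.frame with `bin` (integer index, 0-based), `start_s` and a
#'   list-column `rows` of detection row indices.
#' @export
assign_bins <- function(meta, bin_duration = 300) {
  if (!nrow(meta)) {
    return(data.frame(bin = integer(), start_s = numeric(),
                      rows = I(list())))
  }
  b <- floor(meta$time_s / bin_duration)
  rows <- split(seq_len(nrow(meta)), b)
  bins <- as.integer(names(rows))
  data.frame(bin = bins, start_s = bins * bin_duration,
             rows = I(unname(rows)))
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Summarize one bin-level cluster
#'
#' Averages the member spectra (in the dB domain) and envelopes, min-max
#' normalizes each to \[0, 1\], and histograms the successive time
#' differences between member detections (IDIs) on fixed edges, normalized
#' to sum to 1. Intervals beyond the last edge are discarded.
#'
#' @param times member detection times, s.
#' @param spectra,envelopes member feature matrices (rows match `times`).
#' @param idi_edges histogram edges, s.
#' @param bin bin index the cluster came from.
#' @param member_ids detection ids of the members.
#' @return a `bin_cluster_summary` list with `mean_spectrum`,
#'   `mean_envelope`, `idi_hist`, `n_members`, `member_ids`, `bin`.
#' @export
summarize_cluster <- function(times, spectra, envelopes,
                              idi_edges = seq(0, 1, by = 0.01),
                              bin = NA_integer_, member_ids = NULL) {
  ord <- order(times)
  idi <- diff(times[ord])
  h <- graphics::hist(idi[idi >= idi_edges[1] & idi <= max(idi_edges)],
                      breaks = idi_edges, plot = FALSE)$counts
  idi_hist <- if (sum(h) > 0) h / sum(h) else rep(0, length(h))
  structure(list(
    bin = bin,
    mean_spectrum = minmax_scale(colMeans(spectra)),
    mean_envelope = minmax_scale(colMeans(envelopes)),
    idi_hist = idi_hist,
    n_members = length(times),
    member_ids = if (is.null(member_ids)) seq_along(times) else member_ids,
    member_times = times[ord]
  ), class = "bin_cluster_summary")
}

#' Cluster the detections of one time bin
#'
#' Runs the phase-1 pipeline on a set of detections from a single bin:
#' random subsampling to `max_nodes`, pairwise correlation similarity on
#' the chosen feature, near-duplicate merging, edge pruning, Chinese
#' Whispers, a minimum-size gate, and summarization of each surviving
#' cluster. Detections in a bin may fail to form any cluster, giving an
#' empty result.
#'
#' @param det a [detection_set()].
#' @param rows detection row indices belonging to the bin.
#' @param params [phase1_params()].
#' @param bin bin index (bookkeeping only).
#' @param seed integer seed for subsampling and label propagation.
#' @return list of [summarize_cluster()] results (possibly empty).
#' @export
cluster_bin <- function(det, rows, params = phase1_params(),
                        bin = NA_integer_, seed = NULL) {
  if (length(rows) < params$min_bin_count) {
    message(sprintf("bin %s: %d detections < minimum %d, skipped",
                    bin, length(rows), params$min_bin_count))
    return(list())
  }
  seeds <- derive_seeds(seed %||% 1L, 2L)
  rows <- subsample_nodes(rows, params$max_nodes, seed = seeds[1])
  feats <- if (params$feature == "spectrum") det$spectrum else det$envelope
  g <- correlation_similarity(feats[rows, , drop = FALSE], ids = rows)
  md <- merge_near_duplicates(g, params$dup_threshold)
  gp <- prune_edges(md$graph, params$retain_fraction)
  part <- chinese_whispers(gp, max_iter = params$cw_max_iter,
                           seed = seeds[2])
  # expand representative labels back to the original detections
  full_labels <- integer(length(rows))
  for (r in seq_along(md$members)) {
    full_labels[md$members[[r]]] <- part$labels[r]
  }
  out <- list()
  for (cl in unique(full_labels)) {
    m <- which(full_labels == cl)
    if (length(m) < params$min_cluster_size) next
    dr <- rows[m]
    out[[length(out) + 1L]] <- summarize_cluster(
      det$meta$time_s[dr], det$spectrum[dr, , drop = FALSE],
      det$envelope[dr, , drop = FALSE], params$idi_edges, bin = bin,
      member_ids = det$meta$id[dr]
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-1 clustering over a whole detection set
#'
#' Assigns detections to time bins and clusters each sufficiently occupied
#' bin independently.
#'
#' @param det a [detection_set()].
#' @param params [phase1_params()].
#' @param seed integer seed; each bin derives its own child seed.
#' @return list of `bin_cluster_summary` objects across all bins.
#' @export
cluster_phase1 <- function(det, params = phase1_params(), seed = 1L) {
  bins <- assign_bins(det$meta, params$bin_duration)
  if (!nrow(bins)) return(list())
  seeds <- derive_seeds(seed, nrow(bins))
  out <- list()
  for (i in seq_len(nrow(bins))) {
    if (length(bins$rows[[i]]) < params$min_bin_count) next
    s <- cluster_bin(det, bins$rows[[i]], params, bin = bins$bin[i],
                     seed = seeds[i])
    out <- c(out, s)
  }
  out
}
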