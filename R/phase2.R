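# Phase 2: cluster bin-level summaries across the whole dataset into
# candidate signal classes, select a consensus partition over repeated runs,
# and attach analyst labels that propagate down to individual detections.

#' Phase-2 parameters
#'
#' @param min_size templates with fewer member summaries are dropped.
#' @param retain_fraction edge-pruning retain fraction.
#' @param weak_fraction fraction of most weakly connected nodes removed
#'   from each cluster after partition selection.
#' @param n_repeats independent Chinese Whispers runs; the consensus
#'   partition is kept.
#' @param max_nodes subsampling cap on the number of summaries clustered
#'   simultaneously.
#' @param cw_max_iter Chinese Whispers iteration cap.
#' @param dup_report_threshold pairs of templates whose mean features are
#'   at least this similar are flagged as likely duplicates for review.
#' @export
phase2_params <- function(min_size = 50, retain_fraction = 0.1,
                          weak_fraction = 0.1, n_repeats = 5,
                          max_nodes = 3e4, cw_max_iter = 25,
                          dup_report_threshold = 0.95) {
  structure(list(
    min_size = min_size, retain_fraction = retain_fraction,
    weak_fraction = weak_fraction, n_repeats = n_repeats,
    max_nodes = max_nodes, cw_max_iter = cw_max_iter,
    dup_report_threshold = dup_report_threshold
  ), class = "phase2_params")
}

#' Similarity between two bin-cluster summaries
#'
#' The unweighted mean of the clipped Pearson correlations of the mean
#' spectra and of the mean envelopes. IDI histograms are deliberately not
#' part of the phase-2 feature set (they encourage duplicate clusters split
#' by click rate) but remain available downstream for bin-level classifier
#' inputs.
#'
#' @param a,b `bin_cluster_summary` objects.
#' @return similarity in \[0, 1\].
#' @export
bin_similarity <- function(a, b) {
  r1 <- suppressWarnings(cor(a$mean_spectrum, b$mean_spectrum))
  r2 <- suppressWarnings(cor(a$mean_envelope, b$mean_envelope))
  mean(c(max(r1, 0, na.rm = TRUE), max(r2, 0, na.rm = TRUE)))
}

# Dense similarity graph over summaries; one cor() call per feature block.
summary_similarity_graph <- function(summaries) {
  sp <- t(vapply(summaries, `[[`, summaries[[1]]$mean_spectrum, "mean_spectrum"))
  en <- t(vapply(summaries, `[[`, summaries[[1]]$mean_envelope, "mean_envelope"))
  r1 <- suppressWarnings(cor(t(sp))); r1[is.na(r1)] <- 0
  r2 <- suppressWarnings(cor(t(en))); r2[is.na(r2)] <- 0
  w <- (pmax(r1, 0) + pmax(r2, 0)) / 2
  ut <- which(upper.tri(w), arr.ind = TRUE)
  similarity_graph(length(summaries),
                   data.frame(i = ut[, 1], j = ut[, 2], w = w[ut]))
}

#' Cluster bin summaries into signal-class templates
#'
#' Builds the summary similarity network ([bin_similarity()] weights),
#' prunes weak edges, runs Chinese Whispers `n_repeats` times, keeps the
#' consensus partition ([select_best_partition()]), removes the most weakly
#' connected members of each cluster, drops clusters below `min_size`, and
#' emits one template per surviving cluster. Pairs of templates with nearly
#' identical mean features are flagged in `$duplicates` for analyst review.
#'
#' @param summaries list of `bin_cluster_summary` objects.
#' @param params [phase2_params()].
#' @param seed integer seed; repeat runs derive independent child seeds.
#' @return list with `templates` (list of `class_template`), `partition`,
#'   `duplicates` (data.frame of flagged template pairs).
#' @export
cluster_summaries <- function(summaries, params = phase2_params(),
                              seed = 1L) {
  n <- length(summaries)
  if (n < 2) {
    warning("fewer than 2 summaries; no templates formed", call. = FALSE)
    return(list(templates = list(), partition = NULL,
                duplicates = empty_dup_table()))
  }
  seeds <- derive_seeds(seed, params$n_repeats + 1L)
  if (n > params$max_nodes) {
    keep <- subsample_nodes(seq_len(n), params$max_nodes,
                            seed = seeds[params$n_repeats + 1L])
    summaries <- summaries[keep]
    n <- length(summaries)
  }
  g <- summary_similarity_graph(summaries)
  gp <- prune_edges(g, params$retain_fraction)
  runs <- lapply(seq_len(params$n_repeats), function(r) {
    chinese_whispers(gp, max_iter = params$cw_max_iter, seed = seeds[r])
  })
  best <- select_best_partition(runs)
  best <- prune_weak_nodes(gp, best, params$weak_fraction)
  templates <- list()
  for (cl in seq_len(best$n_clusters)) {
    m <- which(!is.na(best$labels) & best$labels == cl)
    if (length(m) < params$min_size) next
    sp <- t(vapply(summaries[m], `[[`, summaries[[1]]$mean_spectrum,
                   "mean_spectrum"))
    en <- t(vapply(summaries[m], `[[`, summaries[[1]]$mean_envelope,
                   "mean_envelope"))
    id <- t(vapply(summaries[m], `[[`, summaries[[1]]$idi_hist, "idi_hist"))
    templates[[length(templates) + 1L]] <- structure(list(
      class_id = length(templates) + 1L,
      label = "unlabeled",
      summary_idx = m,
      n_summaries = length(m),
      n_detections = sum(vapply(summaries[m],
                                function(s) as.numeric(s$n_members), 0)),
      mean_spectrum = minmax_scale(colMeans(sp)),
      mean_envelope = minmax_scale(colMeans(en)),
      mean_idi_hist = colMeans(id)
    ), class = "class_template")
  }
  if (!length(templates)) {
    warning("no phase-2 cluster reached the minimum size; 0 templates",
            call. = FALSE)
  }
  duplicates <- empty_dup_table()
  nt <- length(templates)
  if (nt > 1) {
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      s <- bin_similarity(templates[[i]], templates[[j]])
      if (s >= params$dup_report_threshold) {
        duplicates <- rbind(duplicates, data.frame(
          template_a = i, template_b = j, similarity = s))
      }
    }
  }
  list(templates = templates, partition = best, duplicates = duplicates)
}

empty_dup_table <- function() {
  data.frame(template_a = integer(), template_b = integer(),
             similarity = numeric())
}

#' @export
print.class_template <- function(x, ...) {
  cat(sprintf("<class_template %d> label '%s': %d summaries, %d detections\n",
              x$class_id, x$label, x$n_summaries, x$n_detections))
  invisible(x)
}

#' Write templates to JSON for review and labelling
#'
#' Serializes class ids, current labels, member summary indices and mean
#' feature vectors. The `label_map` slot is a template for the analyst:
#' fill in names and feed it back to [assign_labels()].
#'
#' @param templates template list from [cluster_summaries()].
#' @param path output JSON path.
#' @export
write_templates <- function(templates, path) {
  jsonlite::write_json(list(
    templates = lapply(templates, function(t) {
      list(class_id = t$class_id, label = t$label,
           n_summaries = t$n_summaries, n_detections = t$n_detections,
           summary_idx = t$summary_idx, mean_spectrum = t$mean_spectrum,
           mean_envelope = t$mean_envelope, mean_idi_hist = t$mean_idi_hist)
    }),
    label_map = stats::setNames(
      as.list(rep("", length(templates))),
      vapply(templates, function(t) as.character(t$class_id), ""))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Review image of the summaries behind each template
#'
#' Draws, per template, its member summaries' normalized mean spectra as a
#' heat map (one row per summary), the standard visual for judging whether
#' a template is coherent or hides several signal types. Writes a PNG when
#' `file` is given, otherwise draws on the current device.
#'
#' @param templates,summaries from [cluster_summaries()].
#' @param file optional PNG path.
#' @param width,height device size in pixels when writing a file.
#' @export
plot_class_templates <- function(templates, summaries, file = NULL,
                                 width = 900, height = 250 * length(templates)) {
  if (!length(templates)) {
    warning("no templates to plot", call. = FALSE)
    return(invisible(NULL))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(length(templates), 1),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (tpl in templates) {
    sp <- t(vapply(summaries[tpl$summary_idx], `[[`,
                   summaries[[1]]$mean_spectrum, "mean_spectrum"))
    graphics::image(t(sp), axes = FALSE, useRaster = TRUE,
                    main = sprintf("template %d (%s): %d summaries",
                                   tpl$class_id, tpl$label, tpl$n_summaries),
                    ylab = "summary")
  }
  invisible(file)
}

#' Attach analyst labels to templates and propagate them to detections
#'
#' `label_map` names templates after review (e.g. `c("1" = "UD",
#' "2" = "sonar")`). Several templates may share one name, merging them into
#' a single class; unmapped templates keep the label `"unlabeled"` and are
#' retained. Labels propagate to every member detection of every member
#' summary of each template.
#'
#' @param templates template list from [cluster_summaries()].
#' @param summaries the summary list the templates index into.
#' @param label_map named character vector, names = template class_ids.
#' @return list with `templates` (labelled), `detections` (data.frame of
#'   `detection_id`, `label`, `template`, `bin`), `summary_labels`
#'   (character per summary, NA when unclustered).
#' @export
assign_labels <- function(templates, summaries, label_map = character()) {
  det_rows <- list()
  summary_labels <- rep(NA_character_, length(summaries))
  for (k in seq_along(templates)) {
    tpl <- templates[[k]]
    nm <- label_map[as.character(tpl$class_id)]
    if (!is.null(nm) && length(nm) == 1 && !is.na(nm)) tpl$label <- unname(nm)
    templates[[k]] <- tpl
    summary_labels[tpl$summary_idx] <- tpl$label
    for (si in tpl$summary_idx) {
      s <- summaries[[si]]
      det_rows[[length(det_rows) + 1L]] <- data.frame(
        detection_id = unname(s$member_ids), label = unname(tpl$label),
        template = tpl$class_id, bin = s$bin
      )
    }
  }
  detections <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame(detection_id = integer(), label = character(),
               template = integer(), bin = integer())
  list(templates = templates, detections = detections,
       summary_labels = summary_labels)
}
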