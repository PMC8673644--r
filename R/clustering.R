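# Correlation-similarity networks and Chinese Whispers label propagation,
# shared by both clustering phases.
#
# A similarity graph is a list with:
#   n       node count
#   edges   data.frame(i, j, w) with i < j, weights in [0, 1], no self-edges
#   ids     payload identifiers, length n
#   size    node multiplicity (detections represented by each node)

similarity_graph <- function(n, edges, ids = seq_len(n), size = rep(1L, n),
                             self_w = numeric(n)) {
  structure(list(n = n, edges = edges, ids = ids, size = size,
                 self_w = self_w),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Pairwise correlation similarity
#'
#' Builds a dense similarity graph over the rows of a feature matrix, with
#' edge weight `max(Pearson r, 0)`: anticorrelated shapes carry no
#' attraction, giving weights on a 0--1 scale. Zero-variance rows get zero
#' similarity to all others, with a warning.
#'
#' @param features numeric matrix, one feature vector per row (at least 2).
#' @param ids optional node identifiers.
#' @return a `similarity_graph` with all `n (n - 1) / 2` off-diagonal pairs.
#' @export
correlation_similarity <- function(features, ids = seq_len(nrow(features))) {
  if (!is.matrix(features) || nrow(features) < 2) {
    stopf("correlation_similarity needs a matrix with at least 2 rows")
  }
  v <- apply(features, 1, stats::var)
  flat <- v == 0 | is.na(v)
  if (any(flat)) {
    warning(sprintf("%d zero-variance feature row(s): similarity set to 0",
                    sum(flat)), call. = FALSE)
  }
  r <- suppressWarnings(cor(t(features)))
  r[is.na(r)] <- 0
  if (any(flat)) { r[flat, ] <- 0; r[, flat] <- 0 }
  w <- pmax(r, 0)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], w = w[ut])
  similarity_graph(nrow(features), edges, ids)
}

#' Retain only the strongest edges
#'
#' Keeps the globally top `retain_fraction` of edge weights (ties at the
#' cutoff are all kept); everything weaker is removed. Nodes may become
#' isolated, which excludes highly dissimilar events from any cluster.
#'
#' @param graph a `similarity_graph`.
#' @param retain_fraction fraction of edges kept, in (0, 1].
#' @export
prune_edges <- function(graph, retain_fraction = 0.1) {
  if (retain_fraction <= 0 || retain_fraction > 1) {
    stopf("retain_fraction must be in (0, 1]")
  }
  if (retain_fraction == 1 || !nrow(graph$edges)) return(graph)
  k <- ceiling(retain_fraction * nrow(graph$edges))
  cutoff <- sort(graph$edges$w, decreasing = TRUE)[k]
  graph$edges <- graph$edges[graph$edges$w >= cutoff, , drop = FALSE]
  graph
}

#' Collapse near-duplicate nodes
#'
#' Nodes connected (transitively) by edges of weight at least
#' `dup_threshold` collapse to a single representative that carries the
#' member count, shrinking the network before label propagation. Edges
#' between representatives take the maximum weight over member pairs.
#'
#' @param graph a `similarity_graph`.
#' @param dup_threshold similarity at or above which nodes are duplicates.
#' @return list with `graph` (reduced) and `members` (list mapping each
#'   representative to the original node indices it carries).
#' @export
merge_near_duplicates <- function(graph, dup_threshold = 0.98) {
  e <- graph$edges
  dup <- e[e$w >= dup_threshold, , drop = FALSE]
  comp <- seq_len(graph$n)
  if (nrow(dup)) {
    # transitive closure by vectorized min-label propagation: each node
    # repeatedly adopts the smallest label among itself and its duplicate
    # neighbours (duplicate groups are near-cliques, so this converges in
    # a handful of passes)
    repeat {
      lab <- pmin(comp[dup$i], comp[dup$j])
      d <- data.table::data.table(node = c(dup$i, dup$j), lab = c(lab, lab))
      mins <- d[, list(lab = min(lab)), by = "node"]
      new_comp <- comp
      new_comp[mins$node] <- pmin(new_comp[mins$node], mins$lab)
      new_comp <- new_comp[new_comp]          # pointer jumping
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
  }
  reps <- sort(unique(comp))
  remap <- match(comp, reps)
  members <- split(seq_len(graph$n), remap)
  if (length(reps) == graph$n) {
    return(list(graph = graph, members = members))
  }
  ei <- remap[e$i]; ej <- remap[e$j]
  d <- data.table::data.table(i = pmin(ei, ej), j = pmax(ei, ej), w = e$w)
  intra <- d[d$i == d$j, ]
  d <- d[d$i != d$j, ]
  edges <- if (nrow(d)) {
    agg <- d[, list(w = max(w)), by = c("i", "j")]
    data.frame(i = agg$i, j = agg$j, w = agg$w)
  } else {
    data.frame(i = integer(), j = integer(), w = numeric())
  }
  size <- vapply(members, function(m) sum(graph$size[m]), 0)
  # a representative keeps the cohesion of the group it stands for as a
  # self-affinity: mean intra-group weight times (size - 1), so that in
  # label propagation a collapsed group is not outvoted by a single weak
  # external edge
  self_w <- numeric(length(reps))
  if (nrow(intra)) {
    mean_intra <- intra[, list(w = mean(w)), by = "i"]
    self_w[mean_intra$i] <- mean_intra$w * (size[mean_intra$i] - 1)
  }
  g <- similarity_graph(length(reps), edges, ids = graph$ids[reps],
                        size = as.integer(size), self_w = self_w)
  list(graph = g, members = members)
}

#' Random subsampling of nodes
#'
#' Uniformly subsamples to at most `max_n` items (identity when already
#' within the limit), used to cap network size before pairwise comparison.
#'
#' @param nodes vector of node indices or ids.
#' @param max_n size cap.
#' @param seed optional integer seed.
#' @export
subsample_nodes <- function(nodes, max_n = 1e4, seed = NULL) {
  if (length(nodes) <= max_n) return(nodes)
  with_seed(seed, sort(sample(nodes, max_n)))
}

#' Chinese Whispers label propagation
#'
#' Every node starts with a unique label; in each iteration, nodes are
#' visited in a fresh random order and adopt the label with the greatest
#' summed incident edge weight among their neighbours (node multiplicities
#' weight the votes, and a node collapsed from near-duplicates adds its
#' internal cohesion as a vote for its current label; ties are broken at
#' random). Iteration stops when a
#' full pass makes no reassignment or after `max_iter` passes. Isolated
#' nodes keep their singleton labels. The algorithm needs no preset number
#' of clusters.
#'
#' @param graph a `similarity_graph`.
#' @param max_iter maximum passes over the nodes.
#' @param seed integer seed controlling visit order and tie breaks.
#' @return a `partition`: list with `labels` (integer per node, relabelled
#'   to 1..k), `n_clusters`, `members` (list of node-index vectors), `ids`.
#' @export
chinese_whispers <- function(graph, max_iter = 25, seed = NULL) {
  n <- graph$n
  if (n == 0L) return(make_partition(integer(0), graph$ids))
  if (is.null(graph$self_w)) graph$self_w <- numeric(n)
  labels <- seq_len(n)
  e <- graph$edges
  if (nrow(e)) {
    # symmetric adjacency in flat arrays, grouped by node
    from <- c(e$i, e$j); to <- c(e$j, e$i); w <- c(e$w, e$w)
    ord <- order(from)
    from <- from[ord]; to <- to[ord]; w <- w[ord] * graph$size[to]
    first <- match(seq_len(n), from)
    cnt <- tabulate(from, n)
    with_seed(seed, {
      for (it in seq_len(max_iter)) {
        changed <- FALSE
        for (v in sample.int(n)) {
          if (cnt[v] == 0L) next
          sel <- first[v]:(first[v] + cnt[v] - 1L)
          votes <- rowsum(c(w[sel], graph$self_w[v]),
                          c(labels[to[sel]], labels[v]))
          top <- which(votes == max(votes))
          pick <- if (length(top) > 1L) top[sample.int(length(top), 1L)] else top
          new_lab <- as.integer(rownames(votes)[pick])
          if (new_lab != labels[v]) { labels[v] <- new_lab; changed <- TRUE }
        }
        if (!changed) break
      }
    })
  }
  make_partition(labels, graph$ids)
}

make_partition <- function(labels, ids = seq_along(labels)) {
  labels <- as.integer(factor(labels))
  structure(list(
    labels = labels, n_clusters = length(unique(labels)),
    members = split(seq_along(labels), labels), ids = ids
  ), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d items in %d clusters\n",
              length(x$labels), x$n_clusters))
  invisible(x)
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(p; q) / (H(p) + H(q))`, computed from the contingency table.
#' Identical partitions score 1 (including the degenerate all-in-one pair);
#' when exactly one partition is a single zero-entropy cluster against a
#' multi-cluster partner the score is defined as 0.
#'
#' @param p,q `partition` objects or integer label vectors over the same
#'   items.
#' @return value in \[0, 1\].
#' @export
normalized_mutual_information <- function(p, q) {
  lp <- if (inherits(p, "partition")) p$labels else as.integer(factor(p))
  lq <- if (inherits(q, "partition")) q$labels else as.integer(factor(q))
  if (length(lp) != length(lq)) stopf("partitions cover different item counts")
  n <- length(lp)
  if (n == 0L) return(NA_real_)
  tab <- table(lp, lq) / n
  ph <- rowSums(tab); qh <- colSums(tab)
  hp <- -sum(ph[ph > 0] * log(ph[ph > 0]))
  hq <- -sum(qh[qh > 0] * log(qh[qh > 0]))
  if (hp + hq == 0) return(1)      # both single clusters: identical
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(ph, qh)[nz]))
  2 * mi / (hp + hq)
}

#' Select the consensus partition from repeated clustering runs
#'
#' Chinese Whispers is stochastic, so clustering is repeated and one
#' partition kept. With `criterion = "consensus"` (default) the partition
#' maximizing mean NMI agreement with the other candidates is returned,
#' i.e. the most representative run; `"min-nmi"` returns the candidate with
#' minimal mean NMI instead (the most atypical run) for diagnostic use.
#'
#' @param partitions list of `partition` objects over the same items.
#' @param criterion `"consensus"` or `"min-nmi"`.
#' @return one of the input partitions (deterministic given inputs; ties go
#'   to the earliest candidate).
#' @export
select_best_partition <- function(partitions,
                                  criterion = c("consensus", "min-nmi")) {
  criterion <- match.arg(criterion)
  m <- length(partitions)
  if (m == 0L) stopf("no partitions supplied")
  if (m == 1L) return(partitions[[1]])
  nmi <- matrix(1, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    nmi[i, j] <- nmi[j, i] <-
      normalized_mutual_information(partitions[[i]], partitions[[j]])
  }
  score <- (rowSums(nmi) - 1) / (m - 1)   # mean NMI to the others
  pick <- if (criterion == "consensus") which.max(score) else which.min(score)
  partitions[[pick]]
}

#' Remove the most weakly connected members of each cluster
#'
#' Ranks each cluster's members by their summed within-cluster edge weight
#' and marks the weakest `fraction` (ceiling-rounded, but always leaving at
#' least one member) as unclustered (label `NA`).
#'
#' @param graph the `similarity_graph` the partition was computed on.
#' @param partition a `partition` over the graph's nodes.
#' @param fraction fraction of members removed per cluster, in \[0, 1).
#' @return a `partition` whose `labels` contain `NA` for removed nodes.
#' @export
prune_weak_nodes <- function(graph, partition, fraction = 0.1) {
  if (fraction <= 0) return(partition)
  if (fraction >= 1) stopf("fraction must be below 1")
  labels <- partition$labels
  e <- graph$edges
  strength <- numeric(graph$n)
  same <- !is.na(labels[e$i]) & !is.na(labels[e$j]) &
    labels[e$i] == labels[e$j]
  if (any(same)) {
    es <- e[same, , drop = FALSE]
    add <- tapply(c(es$w, es$w), c(es$i, es$j), sum)
    strength[as.integer(names(add))] <- add
  }
  for (cl in unique(labels[!is.na(labels)])) {
    idx <- which(labels == cl)
    n_remove <- min(ceiling(fraction * length(idx)), length(idx) - 1L)
    if (n_remove > 0) {
      drop_idx <- idx[order(strength[idx])[seq_len(n_remove)]]
      labels[drop_idx] <- NA_integer_
    }
  }
  out <- partition
  keep <- !is.na(labels)
  relab <- rep(NA_integer_, length(labels))
  relab[keep] <- as.integer(factor(labels[keep]))
  out$labels <- relab
  out$n_clusters <- length(unique(relab[keep]))
  out$members <- split(which(keep), relab[keep])
  out
}
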