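# Brute-force oracles for the graph operations, kept deliberately naive and
# independent of the package implementations.

pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

nmi_oracle <- function(p, q) {
  n <- length(p)
  tab <- table(p, q) / n
  hp <- -sum(ifelse(rowSums(tab) > 0, rowSums(tab) * log(rowSums(tab)), 0))
  hq <- -sum(ifelse(colSums(tab) > 0, colSums(tab) * log(colSums(tab)), 0))
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) {
      mi <- mi + tab[i, j] * log(tab[i, j] / (rowSums(tab)[i] * colSums(tab)[j]))
    }
  }
  unname(2 * mi / (hp + hq))
}

graph_from_matrix <- function(w) {
  diag(w) <- 0
  ut <- which(upper.tri(w), arr.ind = TRUE)
  clickchain:::similarity_graph(nrow(w),
                                data.frame(i = ut[, 1], j = ut[, 2],
                                           w = w[ut]))
}

test_that("correlation similarity equals the textbook Pearson formula, clipped at zero", {
  set.seed(10)
  f <- matrix(rnorm(5 * 10), 5, 10)
  g <- correlation_similarity(f)
  for (r in seq_len(nrow(g$edges))) {
    e <- g$edges[r, ]
    expect_equal(e$w, max(pearson_oracle(f[e$i, ], f[e$j, ]), 0),
                 tolerance = 1e-10)
  }
  # identical rows and negated rows hit the scale ends
  f2 <- rbind(1:10, 1:10, -(1:10))
  g2 <- correlation_similarity(f2)
  w12 <- g2$edges$w[g2$edges$i == 1 & g2$edges$j == 2]
  w13 <- g2$edges$w[g2$edges$i == 1 & g2$edges$j == 3]
  expect_equal(w12, 1.0)
  expect_equal(w13, 0.0)
  # zero-variance rows warn and get zero similarity
  f3 <- rbind(1:10, rep(2, 10), 10:1)
  expect_warning(g3 <- correlation_similarity(f3), "zero-variance")
  expect_true(all(g3$edges$w[g3$edges$i == 2 | g3$edges$j == 2] == 0))
})

test_that("edge pruning keeps exactly the strongest fraction, with ties kept", {
  set.seed(11)
  w <- matrix(runif(15^2), 15, 15); w <- (w + t(w)) / 2
  g <- graph_from_matrix(w)
  expect_identical(prune_edges(g, 1.0)$edges, g$edges)
  gp <- prune_edges(g, 0.1)
  k <- as.integer(ceiling(0.1 * nrow(g$edges)))
  expect_identical(nrow(gp$edges), k)
  expect_gte(min(gp$edges$w), max(setdiff(g$edges$w, gp$edges$w)))
  # ties at the cutoff all survive: k = 2 puts the cutoff at 0.5, and all
  # nine 0.5-weight edges tie with it
  wt <- matrix(0.5, 5, 5); wt[1, 2] <- wt[2, 1] <- 0.9
  gt <- prune_edges(graph_from_matrix(wt), 0.2)
  expect_identical(nrow(gt$edges), 10L)
})

test_that("edge pruning is monotone in the retained fraction", {
  set.seed(12)
  w <- matrix(runif(20^2), 20, 20); w <- (w + t(w)) / 2
  g <- graph_from_matrix(w)
  key <- function(gg) paste(gg$edges$i, gg$edges$j)
  for (pair in list(c(0.05, 0.2), c(0.1, 0.5), c(0.3, 1))) {
    small <- prune_edges(g, pair[1]); big <- prune_edges(g, pair[2])
    expect_true(all(key(small) %in% key(big)))
  }
})

test_that("near-duplicate merging groups by transitive closure", {
  f <- rbind(1:10, 1:10, 1:10, 10:1)
  g <- correlation_similarity(f)
  md <- merge_near_duplicates(g, 0.99)
  expect_identical(md$graph$n, 2L)
  sizes <- unname(sort(vapply(md$members, length, 0L)))
  expect_identical(sizes, c(1L, 3L))
  # chain a~b, b~c above threshold, a~c below: still one group of three
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.995; w[2, 3] <- w[3, 2] <- 0.995
  w[1, 3] <- w[3, 1] <- 0.5
  md2 <- merge_near_duplicates(graph_from_matrix(w), 0.99)
  expect_identical(md2$graph$n, 1L)
  expect_identical(length(md2$members[[1]]), 3L)
  # nothing above threshold: identity
  md3 <- merge_near_duplicates(graph_from_matrix(w), 0.999)
  expect_identical(md3$graph$n, 3L)
})

test_that("node subsampling caps size reproducibly", {
  expect_identical(subsample_nodes(1:5000, 10000), 1:5000)
  s1 <- subsample_nodes(1:20000, 10000, seed = 3)
  s2 <- subsample_nodes(1:20000, 10000, seed = 3)
  expect_identical(s1, s2)
  expect_identical(length(s1), 10000L)
  s3 <- subsample_nodes(1:20000, 10000, seed = 4)
  # different seeds give different subsets with overwhelming probability
  expect_lt(length(intersect(s1, s3)), 9000)
})

test_that("Chinese Whispers recovers disconnected cliques exactly", {
  w <- matrix(0, 10, 10)
  w[1:5, 1:5] <- 0.9; w[6:10, 6:10] <- 0.9
  p <- chinese_whispers(graph_from_matrix(w), seed = 21)
  expect_identical(p$n_clusters, 2L)
  expect_identical(length(unique(p$labels[1:5])), 1L)
  expect_identical(length(unique(p$labels[6:10])), 1L)
  # single node and empty graph degenerate cleanly
  single <- clickchain:::similarity_graph(
    1, data.frame(i = integer(), j = integer(), w = numeric()))
  expect_identical(chinese_whispers(single, seed = 1)$n_clusters, 1L)
  empty <- clickchain:::similarity_graph(
    0, data.frame(i = integer(), j = integer(), w = numeric()))
  expect_identical(chinese_whispers(empty, seed = 1)$n_clusters, 0L)
})

test_that("Chinese Whispers recovers planted block structure", {
  n_ok <- 0L
  for (seed in 1:20) {
    set.seed(seed + 500)
    lab <- rep(1:3, each = 30)
    w <- matrix(0.05, 90, 90)
    for (b in 1:3) w[lab == b, lab == b] <- 0.9
    jitter <- matrix(runif(90 * 90, 0.9, 1.1), 90, 90)
    w <- pmin(w * (jitter + t(jitter)) / 2, 1)
    p <- chinese_whispers(graph_from_matrix(w), seed = seed)
    ari <- mclust::adjustedRandIndex(p$labels, lab)
    if (ari >= 0.95) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 18L)
})

test_that("NMI matches direct entropy computation and its conventions", {
  p <- c(1, 1, 2, 2, 3, 3)
  q <- c(1, 1, 1, 2, 2, 3)
  expect_equal(normalized_mutual_information(p, q), nmi_oracle(p, q),
               tolerance = 1e-10)
  expect_equal(normalized_mutual_information(p, q),
               igraph::compare(p, q, method = "nmi"), tolerance = 1e-10)
})

test_that("NMI is symmetric, bounded, and label-invariant", {
  set.seed(14)
  for (i in 1:10) {
    p <- sample(1:4, 30, replace = TRUE)
    q <- sample(1:3, 30, replace = TRUE)
    v <- normalized_mutual_information(p, q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, normalized_mutual_information(q, p), tolerance = 1e-12)
    relab <- c(9, 5, 7, 2)[p]
    expect_equal(v, normalized_mutual_information(relab, q),
                 tolerance = 1e-12)
  }
  expect_equal(normalized_mutual_information(rep(1, 10), rep(1:2, each = 5)), 0)
  expect_equal(normalized_mutual_information(1:6, 1:6), 1)
})

test_that("consensus selection returns the representative repeat", {
  a <- clickchain:::make_partition(rep(1:2, each = 5))
  b <- clickchain:::make_partition(rep(1:2, each = 5))
  d <- clickchain:::make_partition(c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2))
  expect_identical(select_best_partition(list(a, a, a, a, a))$labels, a$labels)
  best <- select_best_partition(list(a, b, d, a, b))
  expect_identical(best$labels, a$labels)
  expect_identical(select_best_partition(list(d))$labels, d$labels)
  # the diagnostic direction picks the outlier instead
  expect_identical(select_best_partition(list(a, b, d), "min-nmi")$labels,
                   d$labels)
})

test_that("weak-node pruning removes the lowest-strength members", {
  set.seed(15)
  w <- matrix(runif(10^2, 0.5, 1), 10, 10); w <- (w + t(w)) / 2
  # node 10 connected weakly to everyone
  w[10, ] <- w[, 10] <- 0.01
  g <- graph_from_matrix(w)
  part <- clickchain:::make_partition(rep(1, 10))
  pruned <- prune_weak_nodes(g, part, 0.1)
  expect_identical(sum(!is.na(pruned$labels)), 9L)
  expect_true(is.na(pruned$labels[10]))
  # fraction 0 is the identity; singletons are never emptied
  expect_identical(prune_weak_nodes(g, part, 0)$labels, part$labels)
  single <- clickchain:::make_partition(1)
  gs <- clickchain:::similarity_graph(
    1, data.frame(i = integer(), j = integer(), w = numeric()))
  expect_identical(sum(!is.na(prune_weak_nodes(gs, single, 0.1)$labels)), 1L)
})

test_that("weak-node pruning matches a strength-sort oracle", {
  set.seed(16)
  w <- matrix(runif(12^2), 12, 12); w <- (w + t(w)) / 2; diag(w) <- 0
  g <- graph_from_matrix(w)
  part <- clickchain:::make_partition(rep(1:2, each = 6))
  pruned <- prune_weak_nodes(g, part, 0.2)
  for (cl in 1:2) {
    idx <- which(part$labels == cl)
    strength <- sapply(idx, function(v) {
      sum(w[v, setdiff(idx, v)])
    })
    expected_drop <- idx[order(strength)][seq_len(ceiling(0.2 * 6))]
    expect_identical(which(is.na(pruned$labels[idx])),
                     which(idx %in% expected_drop))
  }
})
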