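fake_summary <- function(center, n = 60, idi_bin = 10, seed = 1,
                         bin = 0L, ids = seq_len(n)) {
  set.seed(seed + round(center))
  freqs <- seq(5000, 30000, by = 500)
  sp <- exp(-(freqs - center)^2 / (2 * 2000^2)) + runif(length(freqs), 0, 0.03)
  en <- exp(-((1:64) - 20 - center / 5000)^2 / (2 * (4 + center / 10000)^2))
  idi <- numeric(100); idi[idi_bin] <- 1
  structure(list(
    bin = bin, mean_spectrum = sp / max(sp), mean_envelope = en / max(en),
    idi_hist = idi, n_members = n, member_ids = ids,
    member_times = sort(runif(n))
  ), class = "bin_cluster_summary")
}

test_that("bin similarity averages the two feature correlations", {
  a <- fake_summary(9000); b <- fake_summary(20000)
  expect_equal(bin_similarity(a, a), 1.0)
  # identical spectra but uncorrelated envelopes: exactly the mean of 1 and
  # the clipped envelope correlation
  c1 <- a; c2 <- a
  set.seed(5); c2$mean_envelope <- runif(64)
  r_env <- max(cor(c1$mean_envelope, c2$mean_envelope), 0)
  expect_equal(bin_similarity(c1, c2), (1 + r_env) / 2, tolerance = 1e-12)
  # component-wise oracle on an arbitrary pair
  r_sp <- max(cor(a$mean_spectrum, b$mean_spectrum), 0)
  r_en <- max(cor(a$mean_envelope, b$mean_envelope), 0)
  expect_equal(bin_similarity(a, b), (r_sp + r_en) / 2, tolerance = 1e-12)
})

test_that("summaries from distinct classes produce one template per class", {
  set.seed(8)
  centers <- c(8000, 13000, 19000, 25000)
  summaries <- list()
  truth <- integer()
  for (k in seq_along(centers)) {
    for (r in 1:15) {
      summaries[[length(summaries) + 1L]] <-
        fake_summary(centers[k], seed = r, bin = r)
      truth <- c(truth, k)
    }
  }
  res <- cluster_summaries(summaries, phase2_params(min_size = 5), seed = 31)
  expect_gte(length(res$templates), 4L)
  majors <- integer()
  for (tpl in res$templates) {
    tab <- table(truth[tpl$summary_idx])
    expect_gte(max(tab) / sum(tab), 0.9)
    majors <- c(majors, as.integer(names(which.max(tab))))
  }
  expect_setequal(majors, 1:4)
})

test_that("degenerate summary sets collapse or vanish as specified", {
  same <- rep(list(fake_summary(15000, seed = 1)), 20)
  res <- cluster_summaries(same, phase2_params(min_size = 5), seed = 2)
  expect_identical(length(res$templates), 1L)
  # too few summaries for the default 50-node minimum: no templates
  few <- lapply(1:30, function(i) fake_summary(15000, seed = i))
  expect_warning(res2 <- cluster_summaries(few, phase2_params(), seed = 2),
                 "minimum|templates")
  expect_identical(length(res2$templates), 0L)
})

test_that("repeated phase-2 runs with the same seeds are identical", {
  summaries <- c(lapply(1:12, function(i) fake_summary(9000, seed = i)),
                 lapply(1:12, function(i) fake_summary(21000, seed = i)))
  r1 <- cluster_summaries(summaries, phase2_params(min_size = 4), seed = 77)
  r2 <- cluster_summaries(summaries, phase2_params(min_size = 4), seed = 77)
  expect_identical(r1$partition$labels, r2$partition$labels)
  expect_identical(lapply(r1$templates, `[[`, "summary_idx"),
                   lapply(r2$templates, `[[`, "summary_idx"))
})

test_that("templates serialize for review with an empty label-map slot", {
  summaries <- c(lapply(1:6, function(i) fake_summary(9000, seed = i)),
                 lapply(1:6, function(i) fake_summary(21000, seed = i)))
  res <- cluster_summaries(summaries, phase2_params(min_size = 3), seed = 5)
  path <- file.path(tempdir(), "templates.json")
  write_templates(res$templates, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(length(back$templates$class_id), length(res$templates))
  expect_setequal(names(back$label_map),
                  as.character(seq_along(res$templates)))
  png_path <- file.path(tempdir(), "templates.png")
  plot_class_templates(res$templates, summaries, file = png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
})

test_that("analyst labels merge templates and propagate to all member detections", {
  summaries <- list(fake_summary(9000, n = 4, ids = 1:4, bin = 0L),
                    fake_summary(9500, n = 3, ids = 5:7, bin = 1L),
                    fake_summary(20000, n = 5, ids = 8:12, bin = 2L))
  templates <- list(
    structure(list(class_id = 1L, label = "unlabeled", summary_idx = 1:2,
                   n_summaries = 2L, n_detections = 7L), class = "class_template"),
    structure(list(class_id = 2L, label = "unlabeled", summary_idx = 3L,
                   n_summaries = 1L, n_detections = 5L), class = "class_template")
  )
  out <- assign_labels(templates, summaries, c("1" = "A", "2" = "A"))
  expect_identical(unique(out$detections$label), "A")
  expect_identical(nrow(out$detections), 12L)  # bookkeeping identity
  # unmapped templates stay, labelled "unlabeled"
  out2 <- assign_labels(templates, summaries, c("1" = "A"))
  expect_setequal(unique(out2$detections$label), c("A", "unlabeled"))
  expect_identical(sum(out2$detections$label == "unlabeled"), 5L)
})
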