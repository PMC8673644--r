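test_that("encounters are cut at 15-minute class silences, per class", {
  enc <- split_encounters(c(0, 600, 2000), rep("a", 3), gap_s = 900)
  expect_identical(length(unique(enc$encounter)), 2L)
  expect_identical(enc$encounter[1], enc$encounter[2])
  expect_false(enc$encounter[1] == enc$encounter[3])
  # interleaved classes are cut independently
  times <- c(0, 100, 1200, 50, 1000, 1100)
  labels <- c("a", "a", "a", "b", "b", "b")
  enc2 <- split_encounters(times, labels, gap_s = 900)
  expect_identical(length(unique(enc2$encounter[labels == "a"])), 2L)
  expect_identical(length(unique(enc2$encounter[labels == "b"])), 2L)
  # encounter ids never collide across classes
  expect_identical(anyDuplicated(
    unique(enc2[c("label", "encounter")])$encounter), 0L)
  expect_identical(length(unique(split_encounters(5, "a")$encounter)), 1L)
})

test_that("encounter partitioning hits the 60/10/30 split", {
  times <- rep(seq(0, by = 2000, length.out = 10), each = 3) +
    rep(c(0, 1, 2), 10)
  enc <- split_encounters(times, rep("a", 30), gap_s = 900)
  expect_identical(length(unique(enc$encounter)), 10L)
  part <- partition_encounters(enc, seed = 5)
  by_set <- table(unique(part[c("encounter", "set")])$set)
  expect_identical(as.integer(by_set[c("train", "val", "test")]),
                   c(6L, 1L, 3L))
  # reproducible under the same seed
  part2 <- partition_encounters(enc, seed = 5)
  expect_identical(part$set, part2$set)
  # two encounters: 1/0/1 with a warning
  enc3 <- split_encounters(c(0, 5000), c("a", "a"), gap_s = 900)
  expect_warning(p3 <- partition_encounters(enc3, seed = 1), "encounter")
  expect_setequal(p3$set, c("train", "test"))
  # three encounters: every split non-empty
  enc4 <- split_encounters(c(0, 5000, 10000), rep("a", 3), gap_s = 900)
  p4 <- partition_encounters(enc4, seed = 2)
  expect_setequal(unique(p4$set), c("train", "val", "test"))
})

test_that("balanced sampling resamples short classes and flags them", {
  labels <- c(rep("big", 1000), rep("small", 40))
  s <- sample_balanced(labels, 100, seed = 6)
  expect_identical(unname(table(s$labels)[c("big", "small")]),
                   table(factor(c(rep("big", 100), rep("small", 100))))[1:2] |>
                     unname())
  expect_false(s$resampled["big"])
  expect_true(s$resampled["small"])
  expect_identical(anyDuplicated(s$idx[s$labels == "big"]), 0L)
  expect_gt(anyDuplicated(s$idx[s$labels == "small"]), 0L)
  expect_identical(length(sample_balanced(labels, 0)$idx), 0L)
})

test_that("detection input standardization follows the static 70/130 constants", {
  spec <- rep(70, 191)
  snip <- numeric(200)
  v <- build_detection_input(spec, snip)
  expect_length(v, 391)
  expect_equal(v[1:191], rep(0, 191))
  v2 <- build_detection_input(rep(130, 191), snip)
  expect_equal(v2[1], (130 - 70) / 130, tolerance = 1e-12)
  # waveform scaled by the configured typical maximum
  v3 <- build_detection_input(spec, rep(10^(132 / 20), 200))
  expect_equal(v3[192], 1)
})

test_that("standardized detection inputs stay essentially inside [-1, 1]", {
  fx <- small_two_class_scene()
  det <- fx$det
  x <- build_detection_input(det$spectrum, det$snippet)
  expect_gte(mean(x >= -1 & x <= 1), 0.99)
})

test_that("bin-level inputs concatenate spectrum, IDI and envelope in [0, 1]", {
  s <- list(mean_spectrum = rep(0.5, 51), idi_hist = c(0.4, 0.6, numeric(98)),
            mean_envelope = seq(0, 1, length.out = 64))
  v <- build_bin_input(s)
  expect_length(v, 51 + 100 + 64)
  expect_equal(v[52:53], c(0.4, 0.6) / 0.6)
  expect_true(all(v >= 0 & v <= 1))
  # degenerate constant spectrum is the zero vector by convention
  s2 <- s; s2$mean_spectrum <- clickchain:::minmax_scale(rep(3, 51))
  expect_equal(build_bin_input(s2)[1:51], rep(0, 51))
  # a single occupied IDI bin maps to one 1.0
  s3 <- s; s3$idi_hist <- c(numeric(11), 1, numeric(88))
  expect_equal(sum(build_bin_input(s3)[52:151] == 1), 1)
})

test_that("leakage assertions catch shared encounters", {
  expect_true(assert_no_leakage(1:3, 4:5, 6:9))
  expect_error(assert_no_leakage(1:3, 3:5), "leakage")
})

test_that("balanced training sets are exactly balanced with 0..N-1 codes", {
  set.seed(20)
  x <- matrix(rnorm(300 * 4), 300, 4)
  labels <- sample(c("a", "b", "c"), 300, replace = TRUE)
  ts <- build_training_set(x, labels, n_per_class = 40, seed = 2)
  expect_identical(as.integer(table(ts$y)), rep(40L, 3))
  expect_identical(sort(unique(ts$y)), 0:2)
  expect_identical(ts$class_names, c("a", "b", "c"))
})
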