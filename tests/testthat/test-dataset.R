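test_that("extract_features yields the canonical 5468-vector, bit-identically", {
  set.seed(61)
  s <- seq_record("s1", rand_dna(1500))
  f1 <- extract_features(s)
  f2 <- extract_features(s)
  expect_length(f1, 5468)
  expect_identical(names(f1), feature_names())
  expect_identical(f1, f2)
  km <- f1[1:5460]
  expect_true(all(km >= 0 & km == round(km)))
  expect_error(extract_features(seq_record("pc", strrep("C", 1500))))
})

test_that("build_dataset assembles matrix, labels and class counts", {
  set.seed(62)
  recs <- simulate_labeled_set(4, 8, length = 500, seed = 5)
  ds <- build_dataset(recs)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(dim(ds$x), c(12, 5468))
  expect_equal(unname(ds$class_counts), c(4, 8))
  expect_identical(ds$feature_names, feature_names())
  # row-wise agreement with the per-sequence path
  expect_equal(ds$x[1, ], extract_features(recs[[1]]), tolerance = 1e-12)
  # duplicate ids rejected
  recs2 <- list(seq_record("x", rand_dna(500)), seq_record("x", rand_dna(500)))
  expect_error(build_dataset(recs2), "duplicate")
  # degenerate sequences dropped with a warning
  recs3 <- c(recs[1:3], list(seq_record("pc", strrep("C", 500),
                                        label = "negative")))
  expect_warning(ds3 <- build_dataset(recs3), "dropped")
  expect_equal(nrow(ds3$x), 3)
})

test_that("dataset CSV round-trips ids, features, labels", {
  recs <- simulate_labeled_set(2, 3, length = 400, seed = 6)
  ds <- build_dataset(recs)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f)
  expect_equal(back$ids, ds$ids)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$x, ds$x, tolerance = 1e-12)
})

test_that("null generation matches length exactly, GC within tolerance, no overlap", {
  genome <- make_toy_genome()
  set.seed(63)
  positives <- data.frame(
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample(0:10000, 20))
  positives$end <- positives$start + sample(c(300, 500, 800), 20,
                                            replace = TRUE)
  nulls <- generate_null_set(genome, positives, gc_tolerance = 0.02,
                             seed = 64)
  expect_length(nulls, 20)
  pos_seqs <- extract_intervals(genome, positives)
  for (i in seq_along(nulls)) {
    src <- nulls[[i]]$source
    expect_equal(nchar(nulls[[i]]$bases),
                 positives$end[i] - positives$start[i])
    expect_lte(abs(gc_content(nulls[[i]]) - gc_content(pos_seqs[[i]])),
               0.02)
    same <- positives$chrom == src$chrom
    overlap <- same & positives$start < src$end & positives$end > src$start
    expect_false(any(overlap))
    expect_equal(nulls[[i]]$label, "negative")
  }
  # reproducible under seed
  nulls2 <- generate_null_set(genome, positives, gc_tolerance = 0.02,
                              seed = 64)
  expect_identical(vapply(nulls, function(r) r$bases, ""),
                   vapply(nulls2, function(r) r$bases, ""))
})

test_that("unmatchable positives are skipped with a warning", {
  genome <- make_toy_genome(c(chr1 = 5000), gc = 0.5, seed = 7)
  # the positive blankets the chromosome: every same-length window
  # overlaps it, so no null can ever be placed
  positives <- data.frame(chrom = "chr1", start = 0, end = 4800)
  expect_warning(
    nulls <- generate_null_set(genome, positives,
                               max_tries_per_positive = 25, seed = 8),
    "skipped")
  expect_length(nulls, 0)
  expect_equal(attr(nulls, "n_skipped"), 1L)
})

test_that("simulate_labeled_set honors ratio, motif enrichment and seed", {
  recs <- simulate_labeled_set(100, 770, length = 500, seed = 65)
  labs <- vapply(recs, function(r) r$label, "")
  expect_equal(sum(labs == "positive"), 100)
  expect_equal(sum(labs == "negative"), 770)
  expect_equal(sum(labs == "negative") / sum(labs == "positive"), 7.7)
  lens <- vapply(recs, function(r) nchar(r$bases), 0)
  expect_true(all(lens == 500))

  count_motif <- function(r) count_kmers(r$bases, 5, 5)[["GGCAG"]]
  m_pos <- mean(vapply(recs[labs == "positive"], count_motif, 0))
  m_neg <- mean(vapply(recs[labs == "negative"], count_motif, 0))
  expect_gt(m_pos, m_neg)

  recs2 <- simulate_labeled_set(100, 770, length = 500, seed = 65)
  expect_identical(vapply(recs, function(r) r$bases, ""),
                   vapply(recs2, function(r) r$bases, ""))
  expect_error(simulate_labeled_set(2, 2, length = 4, motif = "GGCAG"),
               "motif")
})

test_that("GC-rich k-mer counts run higher in GC-rich positives", {
  set.seed(66)
  recs <- simulate_labeled_set(40, 40, length = 800, pos_motif_rate = 0,
                               gc_pos = 0.55, gc_neg = 0.40, seed = 67)
  ds <- build_dataset(recs)
  cg <- compare_groups(ds, c("GGCAG", "GC"))
  expect_true(all(cg$mean_pos > cg$mean_neg))
})

test_that("compare_groups reproduces the Welch t-test and its edge cases", {
  set.seed(68)
  x <- matrix(rnorm(200), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  x[1:50, 1] <- x[1:50, 1] + 1  # 1-SD shift in f1 for positives
  ds <- enhancerwalk:::new_labeled_dataset(
    x, paste0("s", 1:100), rep(c("positive", "negative"), each = 50))
  out <- compare_groups(ds, c("f1", "f2"))
  expect_equal(names(out),
               c("feature_name", "sd_pos", "mean_pos", "sd_neg",
                 "mean_neg", "t_statistic", "p_value"))
  tt <- t.test(x[1:50, 1], x[51:100, 1])
  expect_equal(out$t_statistic[1], unname(tt$statistic))
  expect_equal(out$p_value[1], tt$p.value)
  expect_lt(out$p_value[1], 0.001)

  # identical groups: t = 0, p = 1
  x2 <- rbind(x[1:50, ], x[1:50, ])
  ds2 <- enhancerwalk:::new_labeled_dataset(
    x2, paste0("s", 1:100), rep(c("positive", "negative"), each = 50))
  out2 <- compare_groups(ds2, "f1")
  expect_equal(out2$t_statistic, 0)
  expect_equal(out2$p_value, 1)

  expect_error(compare_groups(ds, "nope"), "unknown")
  ds3 <- enhancerwalk:::new_labeled_dataset(
    x[1:3, ], paste0("s", 1:3), c("positive", "negative", "negative"))
  expect_error(compare_groups(ds3, "f1"), "at least 2")
})

test_that("a 1-SD shift at n = 200/200 is detected (permutation oracle)", {
  set.seed(69)
  a <- rnorm(200) + 1
  b <- rnorm(200)
  ds <- enhancerwalk:::new_labeled_dataset(
    matrix(c(a, b), ncol = 1, dimnames = list(NULL, "f")),
    paste0("s", 1:400), rep(c("positive", "negative"), each = 200))
  p_welch <- compare_groups(ds, "f")$p_value
  expect_lt(p_welch, 0.001)
  # permutation oracle: observed |mean difference| never exceeded
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(500, {
    idx <- sample(400, 200)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  expect_lt(mean(perm >= obs), 0.01)
})

test_that("stratified split preserves sizes, proportions and determinism", {
  recs <- simulate_labeled_set(10, 70, length = 400, seed = 70)
  ds <- build_dataset(recs)
  sp <- split_dataset(ds, 0.25, seed = 71)
  expect_equal(nrow(sp$test$x), 20)
  expect_equal(nrow(sp$train$x), 60)
  n_pos_test <- sum(sp$test$labels == "positive")
  expect_true(n_pos_test >= 2 && n_pos_test <= 3)
  # disjoint, union = input
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)
  expect_setequal(c(sp$train$ids, sp$test$ids), ds$ids)

  sp2 <- split_dataset(ds, 0.25, seed = 71)
  expect_identical(sp$test$ids, sp2$test$ids)
  sp3 <- split_dataset(ds, 0.25, seed = 72)
  expect_false(identical(sp$test$ids, sp3$test$ids))

  # 100 samples at 0.25 -> 75/25
  recs2 <- simulate_labeled_set(50, 50, length = 400, seed = 73)
  ds2 <- build_dataset(recs2)
  sp4 <- split_dataset(ds2, 0.25, seed = 74)
  expect_equal(nrow(sp4$test$x), 25)
  expect_equal(nrow(sp4$train$x), 75)
})
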