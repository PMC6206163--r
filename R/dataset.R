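# Labeled feature datasets: per-sequence feature vectors, dataset
# assembly, GC/length-matched null generation, synthetic simulation,
# group comparison, and train/test splitting.

#' Full feature-name registry (5468 names)
#'
#' The 5460 k-mer names in canonical order followed by the 8 walk feature
#' names.
#'
#' @return Character vector of length 5468.
#' @export
feature_names <- function() {
  c(kmer_order(1L, 6L), walk_feature_names())
}

#' Extract the canonical 5468-dimensional feature vector of a sequence
#'
#' Concatenates the overlapping k-mer counts (k = 1..6, 5460 values) with
#' the eight walk features computed from the purine/pyrimidine walk.
#' Deterministic.
#'
#' @param seq A prepared [seq_record()] or character string (length >=
#'   302, A/C/G/T only).
#' @param strict If `TRUE` (default), an undefined walk feature raises an
#'   error; if `FALSE` it is left as `NA` (no-call).
#' @param ... Passed to [walk_features()].
#' @return Named numeric vector of length 5468.
#' @export
extract_features <- function(seq, strict = TRUE, ...) {
  wf <- walk_features(build_walk(seq), ...)
  if (strict && anyNA(wf)) {
    stop(sprintf("undefined walk feature(s) %s for sequence '%s'",
                 paste(names(wf)[is.na(wf)], collapse = ", "),
                 if (inherits(seq, "seq_record")) seq$id else "seq"))
  }
  out <- c(count_kmers(seq), wf)
  stopifnot(length(out) == 5468L)
  out
}

#' Assemble a labeled dataset from sequence records
#'
#' Computes the 5468-column feature matrix for a list of records. Records
#' whose walk features are undefined are dropped with a warning (`strict =
#' FALSE`) or raise an error (`strict = TRUE`).
#'
#' @param records List of prepared [seq_record()] objects, with `label`
#'   set for training data.
#' @param strict Error on feature failures instead of dropping.
#' @return Object of class `labeled_dataset`: list with `x` (numeric
#'   matrix, rownames = ids), `ids`, `labels` (character or `NA`),
#'   `feature_names`, `class_counts`.
#' @export
build_dataset <- function(records, strict = FALSE) {
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "))
  }
  km <- count_kmers_set(records)
  wf <- matrix(NA_real_, nrow = length(records), ncol = 8L,
               dimnames = list(ids, walk_feature_names()))
  failed <- logical(length(records))
  for (i in seq_along(records)) {
    res <- tryCatch(walk_features(build_walk(records[[i]])),
                    error = function(e) e)
    if (inherits(res, "error") || anyNA(res)) {
      if (strict) {
        stop(sprintf("feature extraction failed for '%s': %s", ids[i],
                     if (inherits(res, "error")) conditionMessage(res)
                     else "undefined walk feature"))
      }
      failed[i] <- TRUE
    } else {
      wf[i, ] <- res
    }
  }
  if (any(failed)) {
    warning(sprintf("dropped %d sequence(s) with undefined walk features",
                    sum(failed)))
  }
  keep <- !failed
  labels <- vapply(records, function(r) {
    if (is.null(r$label)) NA_character_ else r$label
  }, "")
  new_labeled_dataset(cbind(km, wf)[keep, , drop = FALSE],
                      ids[keep], labels[keep])
}

new_labeled_dataset <- function(x, ids, labels) {
  stopifnot(is.matrix(x), nrow(x) == length(ids),
            length(labels) == length(ids))
  structure(list(x = x, ids = ids, labels = labels,
                 feature_names = colnames(x),
                 class_counts = c(n_positive = sum(labels == "positive",
                                                   na.rm = TRUE),
                                  n_negative = sum(labels == "negative",
                                                   na.rm = TRUE))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$x), ncol(x$x), x$class_counts[1], x$class_counts[2]))
  invisible(x)
}

#' Write a labeled dataset as CSV
#'
#' First column `id`, then the feature columns in canonical order, last
#' column `label` (empty when unknown).
#'
#' @param ds A [build_dataset()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  df <- data.table::as.data.table(ds$x)
  df <- cbind(data.table::data.table(id = ds$ids), df,
              data.table::data.table(label = ifelse(is.na(ds$labels), "",
                                                    ds$labels)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a labeled dataset from CSV
#'
#' @param path CSV written by [write_dataset_csv()].
#' @return A `labeled_dataset`.
#' @export
read_dataset_csv <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!"id" %in% names(dt)) stop("dataset CSV lacks an 'id' column: ", path)
  labels <- if ("label" %in% names(dt)) {
    ifelse(nzchar(as.character(dt$label)), as.character(dt$label),
           NA_character_)
  } else rep(NA_character_, nrow(dt))
  feat <- setdiff(names(dt), c("id", "label"))
  x <- as.matrix(dt[, feat, drop = FALSE])
  rownames(x) <- dt$id
  new_labeled_dataset(x, dt$id, labels)
}

#' Generate GC- and length-matched null sequences
#'
#' For each positive interval (times `n_ratio`), rejection-samples a
#' genomic window of identical length, uniformly over the genome, until
#' its GC content lies within `gc_tolerance` of the positive's and it
#' overlaps no positive interval. Windows containing ambiguous bases are
#' rejected. Reproducible under `seed`.
#'
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param positives Data frame of positive intervals (`chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param gc_tolerance Maximum |GC_null - GC_positive| (default 0.02).
#' @param n_ratio Nulls per positive (default 1).
#' @param max_tries_per_positive Rejection-sampling budget (default 1000);
#'   unmatched positives are skipped with a warning.
#' @param seed Optional integer seed.
#' @return List of [seq_record()] objects labeled `"negative"`, each with
#'   its sampled interval in `source`; attribute `n_skipped` counts
#'   positives for which no match was found.
#' @export
generate_null_set <- function(genome, positives, gc_tolerance = 0.02,
                              n_ratio = 1, max_tries_per_positive = 1000L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- load_genome(genome)
  validate_intervals(positives)
  if (nrow(positives) == 0L) stop("no positive intervals supplied")
  chrom_len <- vapply(names(g), function(ch) length(g[[ch]]), integer(1))
  pos_seqs <- extract_intervals(g, positives[, c("chrom", "start", "end")])
  pos_gc <- vapply(pos_seqs, gc_content, numeric(1))
  overlaps_positive <- function(chrom, start, end) {
    same <- positives$chrom == chrom
    any(same & positives$start < end & positives$end > start)
  }
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(positives))) {
    w <- positives$end[i] - positives$start[i]
    eligible <- chrom_len >= w
    if (!any(eligible)) { n_skipped <- n_skipped + 1L; next }
    weights <- pmax(chrom_len[eligible] - w + 1L, 1L)
    for (rep_i in seq_len(round(n_ratio))) {
      found <- FALSE
      for (try_i in seq_len(max_tries_per_positive)) {
        ch <- sample(names(chrom_len)[eligible], 1L, prob = weights)
        start <- sample.int(chrom_len[ch] - w + 1L, 1L) - 1L
        end <- start + w
        if (overlaps_positive(ch, start, end)) next
        s <- as.character(Biostrings::subseq(g[[ch]], start + 1L, end))
        if (grepl("[^ACGT]", s)) next
        if (abs(gc_content(s) - pos_gc[i]) > gc_tolerance) next
        rec <- seq_record(sprintf("null_%d_%s:%d-%d", length(out) + 1L,
                                  ch, start, end),
                          s,
                          source = data.frame(chrom = ch, start = start,
                                              end = end, strand = "+",
                                              stringsAsFactors = FALSE),
                          label = "negative")
        out[[length(out) + 1L]] <- rec
        found <- TRUE
        break
      }
      if (!found) n_skipped <- n_skipped + 1L
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("no GC-matched window found for %d draw(s); skipped",
                    n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

# i.i.d. bases at a given GC content: P(G) = P(C) = gc/2,
# P(A) = P(T) = (1 - gc)/2.
random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a labeled two-class sequence set
#'
#' Synthetic stand-in for an enhancer training set: positives are i.i.d.
#' bases at GC content `gc_pos` with a Poisson(`pos_motif_rate`) number of
#' planted motif copies (overwritten at uniform positions); negatives are
#' i.i.d. bases at `gc_neg` with no planting. The defaults encode the
#' study conditions: 1500-bp sequences, GGCAG motif at rate 5, GC 0.55 vs
#' 0.40, and a class imbalance near 1:7.7 when called as
#' `simulate_labeled_set(200, 1540)`.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length Sequence length (default 1500).
#' @param motif Planted motif (default `"GGCAG"`).
#' @param pos_motif_rate Poisson mean of planted copies per positive
#'   (default 5).
#' @param gc_pos,gc_neg GC content of each class (defaults 0.55, 0.40).
#' @param seed Optional integer seed; same seed gives identical sets.
#' @return List of labeled [seq_record()] objects (positives first).
#' @export
simulate_labeled_set <- function(n_pos, n_neg, length = 1500L,
                                 motif = "GGCAG", pos_motif_rate = 5,
                                 gc_pos = 0.55, gc_neg = 0.40,
                                 seed = NULL) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, gc_pos >= 0, gc_pos <= 1,
            gc_neg >= 0, gc_neg <= 1, pos_motif_rate >= 0)
  if (nchar(motif) > length) stop("motif longer than sequence length")
  if (!is.null(seed)) set.seed(seed)
  mlen <- nchar(motif)
  pos <- lapply(seq_len(n_pos), function(i) {
    s <- random_dna(length, gc_pos)
    k <- rpois(1L, pos_motif_rate)
    if (k > 0L) {
      starts <- sample.int(length - mlen + 1L, min(k, length - mlen + 1L))
      for (st in starts) {
        substr(s, st, st + mlen - 1L) <- motif
      }
    }
    seq_record(sprintf("pos_%04d", i), s, label = "positive")
  })
  neg <- lapply(seq_len(n_neg), function(i) {
    seq_record(sprintf("neg_%04d", i), random_dna(length, gc_neg),
               label = "negative")
  })
  c(pos, neg)
}

#' Compare feature distributions between classes (Welch t-test)
#'
#' Per requested feature: class means and standard deviations, plus the
#' unpaired two-tailed Welch t statistic and p-value comparing positives
#' against negatives.
#'
#' @param ds A `labeled_dataset` with both classes present (>= 2 samples
#'   each).
#' @param features Character vector of feature names (default: the 8 walk
#'   features).
#' @return Data frame with columns `feature_name`, `sd_pos`, `mean_pos`,
#'   `sd_neg`, `mean_neg`, `t_statistic`, `p_value`.
#' @export
compare_groups <- function(ds, features = walk_feature_names()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  missing <- setdiff(features, ds$feature_names)
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  pos <- ds$x[ds$labels == "positive", , drop = FALSE]
  neg <- ds$x[ds$labels == "negative", , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("each class needs at least 2 samples for a t-test")
  }
  rows <- lapply(features, function(f) {
    a <- pos[, f]
    b <- neg[, f]
    tt <- if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
      list(statistic = 0, p.value = 1)  # identical groups: no evidence
    } else {
      t.test(a, b, var.equal = FALSE)
    }
    data.frame(feature_name = f, sd_pos = sd(a), mean_pos = mean(a),
               sd_neg = sd(b), mean_neg = mean(b),
               t_statistic = unname(tt$statistic),
               p_value = unname(tt$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint train and test parts whose union is the
#' input. Under stratification the per-class test counts are allocated by
#' largest remainder, so class proportions are preserved within one
#' sample.
#'
#' @param ds A `labeled_dataset`.
#' @param test_fraction Fraction assigned to the test part (default 0.25).
#' @param stratified Preserve class proportions (default `TRUE`).
#' @param seed Optional integer seed.
#' @return List with elements `train` and `test`, both `labeled_dataset`.
#' @export
split_dataset <- function(ds, test_fraction = 0.25, stratified = TRUE,
                          seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"),
            test_fraction > 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ds$x)
  n_test <- round(n * test_fraction)
  if (stratified) {
    classes <- unique(ds$labels)
    if (any(table(ds$labels) < 2L)) {
      stop("each class needs at least 2 samples for a stratified split")
    }
    exact <- vapply(classes, function(cl) sum(ds$labels == cl), 0) *
      test_fraction
    base <- floor(exact)
    rem <- n_test - sum(base)
    if (rem > 0) {
      order_by_frac <- order(exact - base, decreasing = TRUE)
      base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
    }
    test_idx <- unlist(lapply(seq_along(classes), function(j) {
      idx <- which(ds$labels == classes[j])
      sample(idx, base[j])
    }))
  } else {
    test_idx <- sample.int(n, n_test)
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  subset_ds <- function(idx) {
    new_labeled_dataset(ds$x[idx, , drop = FALSE], ds$ids[idx],
                        ds$labels[idx])
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}
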