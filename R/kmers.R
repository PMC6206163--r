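# The k-mer feature block: overlapping counts of all 4^k words, k = 1..6.

#' Canonical k-mer ordering
#'
#' All 4^k strings for each k from `k_min` to `k_max`, grouped by ascending
#' k and alphabetical within each k. For the default range 1..6 this yields
#' the canonical 5460-name feature registry.
#'
#' @param k_min,k_max Inclusive k range (defaults 1 and 6).
#' @return Character vector of k-mer strings.
#' @export
kmer_order <- function(k_min = 1L, k_max = 6L) {
  stopifnot(k_min >= 1L, k_min <= k_max)
  if (k_max > 12L) stop("k_max > 12 refused (4^k grows combinatorially)")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(k_min:k_max, function(k) {
    # expand.grid varies the first factor fastest; reversing the column
    # order makes the concatenation alphabetical.
    grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
    do.call(paste0, rev(grid))
  }), use.names = FALSE)
}

#' Count overlapping k-mers in a sequence
#'
#' Raw overlapping occurrence counts (not length-normalized) of every k-mer
#' for k in `k_min..k_max`, in [kmer_order()] order. For each k the counts
#' sum to `L - k + 1`. Counting is strand-specific.
#'
#' @param seq A [seq_record()] or character string over A/C/G/T.
#' @param k_min,k_max Inclusive k range (defaults 1 and 6).
#' @return Named integer vector of length `sum(4^(k_min:k_max))` (5460 for
#'   the default range).
#' @export
count_kmers <- function(seq, k_min = 1L, k_max = 6L) {
  bases <- as_bases(seq)
  if (nchar(bases) < k_max) {
    stop(sprintf("sequence of length %d too short for %d-mers",
                 nchar(bases), k_max))
  }
  d <- Biostrings::DNAString(bases)
  counts <- unlist(lapply(k_min:k_max, function(k) {
    Biostrings::oligonucleotideFrequency(d, width = k)
  }))
  expected <- kmer_order(k_min, k_max)
  stopifnot(identical(names(counts), expected))
  counts
}

# Matrix of k-mer counts for a list of records (rows = sequences), computed
# per k over the whole DNAStringSet at once.
count_kmers_set <- function(records, k_min = 1L, k_max = 6L) {
  seqs <- Biostrings::DNAStringSet(vapply(records, function(r) as_bases(r), ""))
  mats <- lapply(k_min:k_max, function(k) {
    Biostrings::oligonucleotideFrequency(seqs, width = k, simplify.as = "matrix")
  })
  out <- do.call(cbind, mats)
  stopifnot(identical(colnames(out), kmer_order(k_min, k_max)))
  rownames(out) <- vapply(records, function(r) if (inherits(r, "seq_record")) r$id else "seq", "")
  out
}
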