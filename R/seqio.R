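# Sequence input/output and normalization.
#
# Sequences are carried as lightweight `seq_record` objects (id, bases,
# optional genomic source interval, optional class label); sets of records
# are plain lists. Genomic intervals use the BED convention throughout:
# 0-based, half-open.

#' Construct a sequence record
#'
#' A `seq_record` holds one identified DNA sequence together with optional
#' genomic provenance (a 0-based half-open interval) and an optional class
#' label (`"positive"` = enhancer, `"negative"` = non-enhancer).
#'
#' @param id Character scalar, sequence identifier.
#' @param bases Character scalar, the sequence (stored uppercased).
#' @param source Optional one-row data frame with columns `chrom`, `start`,
#'   `end` and optionally `strand` (0-based half-open).
#' @param label Optional `"positive"` or `"negative"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, bases, source = NULL, label = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(bases), length(bases) == 1L)
  if (!is.null(label)) label <- match.arg(label, c("positive", "negative"))
  if (!is.null(source)) {
    stopifnot(is.data.frame(source), nrow(source) == 1L,
              all(c("chrom", "start", "end") %in% names(source)))
  }
  structure(list(id = id, bases = toupper(bases), source = source,
                 label = label),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  lab <- if (is.null(x$label)) "unlabeled" else x$label
  cat(sprintf("<seq_record> %s: %d bp (%s)\n", x$id, nchar(x$bases), lab))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$bases)

# Accept either a seq_record or a bare character string.
as_bases <- function(x) {
  if (inherits(x, "seq_record")) x$bases
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a seq_record or a single character string")
}

#' Read a FASTA file into a list of sequence records
#'
#' Sequences are uppercased; record order follows file order. Malformed
#' input (text before the first header, or a header with no sequence) is
#' reported with the offending line number.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A list of [seq_record()] objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) return(list())
  if (!startsWith(trimws(lines[content[1]]), ">")) {
    stop(sprintf("malformed FASTA %s: line %d precedes the first '>' header",
                 path, content[1]))
  }
  hdr <- content[startsWith(trimws(lines[content]), ">")]
  for (i in seq_along(hdr)) {
    nxt <- if (i < length(hdr)) hdr[i + 1] else length(lines) + 1L
    body <- content[content > hdr[i] & content < nxt]
    if (length(body) == 0L) {
      stop(sprintf("malformed FASTA %s: header at line %d has no sequence",
                   path, hdr[i]))
    }
    if (trimws(lines[hdr[i]]) == ">") {
      stop(sprintf("malformed FASTA %s: empty header at line %d",
                   path, hdr[i]))
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], toupper(as.character(set[[i]])))
  })
}

#' Write sequence records to a FASTA file
#'
#' Emits 60-column wrapped FASTA, one record per input in order.
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- Biostrings::BStringSet(vapply(records, function(r) r$bases, ""))
  names(seqs) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' @param path Path to a BED file (tab-separated, no header).
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand` (coordinates 0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(bed) <- cols[seq_len(min(ncol(bed), 6L))]
  validate_intervals(bed)
  bed
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  bad <- which(intervals$start < 0 | intervals$end <= intervals$start)
  if (length(bad)) {
    stop(sprintf("invalid interval %s:%d-%d (need 0 <= start < end)",
                 intervals$chrom[bad[1]], intervals$start[bad[1]],
                 intervals$end[bad[1]]))
  }
  invisible(TRUE)
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (!file.exists(genome)) stop("genome FASTA not found: ", genome)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract interval sequences from a genome FASTA
#'
#' Intervals are 0-based half-open; minus-strand intervals are returned
#' reverse-complemented. Coordinates in error messages are reported in the
#' input (BED) convention.
#'
#' @param genome Path to a genome FASTA or a `DNAStringSet`.
#' @param intervals Data frame of intervals as from [read_bed()].
#' @return List of [seq_record()] objects, one per interval, with `source`
#'   set to the originating interval.
#' @export
extract_intervals <- function(genome, intervals) {
  g <- load_genome(genome)
  validate_intervals(intervals)
  if (is.null(intervals$strand)) intervals$strand <- "+"
  lapply(seq_len(nrow(intervals)), function(i) {
    chrom <- intervals$chrom[i]
    start <- intervals$start[i]
    end <- intervals$end[i]
    strand <- intervals$strand[i]
    if (!chrom %in% names(g)) {
      stop(sprintf("interval %s:%d-%d: chromosome '%s' absent from genome",
                   chrom, start, end, chrom))
    }
    if (end > length(g[[chrom]])) {
      stop(sprintf("interval %s:%d-%d: beyond chromosome end (%d)",
                   chrom, start, end, length(g[[chrom]])))
    }
    s <- Biostrings::subseq(g[[chrom]], start + 1L, end)
    if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
    id <- sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
    seq_record(id, as.character(s),
               source = data.frame(chrom = chrom, start = start, end = end,
                                   strand = strand,
                                   stringsAsFactors = FALSE))
  })
}

#' Normalize a sequence record for feature extraction
#'
#' Applies the length and ambiguity policy: sequences longer than `max_len`
#' are truncated to their 5' prefix; non-ACGT characters are stripped
#' (default) provided they make up at most `max_ambiguous_frac` of the
#' sequence, otherwise the record is rejected. Sequences shorter than 302
#' bases after cleaning are rejected (the lag-300 autocorrelation is
#' undefined); those shorter than 400 trigger a warning.
#'
#' @param rec A [seq_record()] (or character string).
#' @param max_len Maximum retained length (default 1500).
#' @param ambiguous_policy `"strip"` (default) removes non-ACGT characters;
#'   `"reject"` errors on any ambiguity.
#' @param max_ambiguous_frac Maximum tolerated non-ACGT fraction under
#'   `"strip"` (default 0.05).
#' @param min_len Hard lower length bound (default 302).
#' @param warn_len Soft lower length bound (default 400).
#' @return The normalized [seq_record()].
#' @export
prepare_sequence <- function(rec, max_len = 1500L,
                             ambiguous_policy = c("strip", "reject"),
                             max_ambiguous_frac = 0.05,
                             min_len = 302L, warn_len = 400L) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  if (is.character(rec)) rec <- seq_record("seq", rec)
  bases <- toupper(rec$bases)
  if (!nzchar(bases)) stop("sequence '", rec$id, "' is empty")
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  ok <- chars %in% c("A", "C", "G", "T")
  amb_frac <- 1 - mean(ok)
  if (amb_frac > 0) {
    if (ambiguous_policy == "reject") {
      stop(sprintf("sequence '%s' rejected: contains %d ambiguous characters",
                   rec$id, sum(!ok)))
    }
    if (amb_frac > max_ambiguous_frac) {
      stop(sprintf(
        "sequence '%s' rejected: ambiguous fraction %.3f exceeds %.3f",
        rec$id, amb_frac, max_ambiguous_frac))
    }
    chars <- chars[ok]
  }
  if (length(chars) == 0L) {
    stop(sprintf("sequence '%s' rejected: no unambiguous bases", rec$id))
  }
  if (length(chars) > max_len) chars <- chars[seq_len(max_len)]
  if (length(chars) < min_len) {
    stop(sprintf(
      "sequence '%s' rejected: %d bases after cleaning (minimum %d)",
      rec$id, length(chars), min_len))
  }
  if (length(chars) < warn_len) {
    warning(sprintf("sequence '%s' is short (%d bases); long-lag features %s",
                    rec$id, length(chars), "will be noisy"))
  }
  rec$bases <- paste(chars, collapse = "")
  rec
}

#' Normalize a list of records, dropping failures
#'
#' Convenience wrapper applying [prepare_sequence()] to each record.
#' Records that fail the policy are dropped with a single summary warning
#' (strict = FALSE) or raise the first error (strict = TRUE).
#'
#' @param records List of [seq_record()] objects.
#' @param strict Error on the first rejection instead of dropping.
#' @param ... Passed to [prepare_sequence()].
#' @return List of normalized records; attribute `n_dropped` counts drops.
#' @export
prepare_set <- function(records, strict = FALSE, ...) {
  out <- vector("list", length(records))
  dropped <- character(0)
  for (i in seq_along(records)) {
    res <- if (strict) {
      prepare_sequence(records[[i]], ...)
    } else {
      tryCatch(suppressWarnings(prepare_sequence(records[[i]], ...)),
               error = function(e) e)
    }
    if (inherits(res, "error")) {
      dropped <- c(dropped, records[[i]]$id)
    } else {
      out[[i]] <- res
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(dropped)) {
    warning(sprintf("dropped %d sequence(s): %s", length(dropped),
                    paste(head(dropped, 5), collapse = ", ")))
  }
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar or [seq_record()] over A/C/G/T.
#' @return Character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_bases(x))))
}

#' GC content of a sequence
#'
#' @param seq A [seq_record()] or character string.
#' @return Fraction of G+C bases in \[0, 1\].
#' @export
gc_content <- function(seq) {
  bases <- as_bases(seq)
  if (!nzchar(bases)) stop("empty sequence")
  unname(Biostrings::letterFrequency(Biostrings::DNAString(bases), "GC",
                                     as.prob = TRUE)[1])
}
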