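# The purine/pyrimidine DNA walk encoding.

#' Build the purine/pyrimidine random walk of a sequence
#'
#' Each base contributes one step: pyrimidines (C, T) step +1, purines
#' (A, G) step -1. The walk is the running sum of the steps, starting at
#' `walk[1] = steps[1]` (no leading zero). The final walk value therefore
#' equals `(#C + #T) - (#A + #G)`.
#'
#' @param seq A [seq_record()] or character string over A/C/G/T.
#' @return An object of class `dna_walk`: list with `steps` (integer +/-1
#'   per base), `walk` (cumulative sum), `length`, and `id`.
#' @examples
#' w <- build_walk("CACA")
#' w$walk  # 1 0 1 0
#' @export
build_walk <- function(seq) {
  id <- if (inherits(seq, "seq_record")) seq$id else "seq"
  bases <- as_bases(seq)
  if (!nzchar(bases)) stop("cannot build a walk from an empty sequence")
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  steps <- ifelse(chars %in% c("C", "T"), 1L,
                  ifelse(chars %in% c("A", "G"), -1L, NA_integer_))
  if (anyNA(steps)) {
    pos <- which(is.na(steps))[1]
    stop(sprintf("non-ACGT character '%s' at position %d in '%s'",
                 chars[pos], pos, id))
  }
  structure(list(steps = steps, walk = cumsum(steps),
                 length = length(steps), id = id),
            class = "dna_walk")
}

#' @export
print.dna_walk <- function(x, ...) {
  cat(sprintf("<dna_walk> %s: %d steps, final displacement %d\n",
              x$id, x$length, x$walk[x$length]))
  invisible(x)
}

#' @export
as.data.frame.dna_walk <- function(x, ...) {
  data.frame(position = seq_len(x$length), step = x$steps, walk = x$walk)
}

#' Export a walk as a CSV of (position, step, walk) triples
#'
#' @param walk A [build_walk()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_walk_csv <- function(walk, path) {
  data.table::fwrite(as.data.frame(walk), path)
  invisible(path)
}
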