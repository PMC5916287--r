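# Putative-circle extraction: duplicated k-mers at a minimum span delimit
# one traversal of a circular molecule inside an artifact-laden scaffold.

#' Find duplicated k-mers at a minimum span
#'
#' Enumerates every ordered pair of identical k-mer occurrences on the
#' direct strand of a scaffold whose spacing (`right_start - left_start`)
#' is at least `min_span`. k-mers containing `N` never match. Only
#' same-orientation duplicates are considered: the duplication produced by
#' an assembler walking past the origin of a circle is on the same strand,
#' whereas reverse-complement hits indicate inverted repeats.
#'
#' @param scaffold A [seq_record()] or character scalar.
#' @param k k-mer length in bases (`1 <= k <= length(scaffold)`).
#' @param min_span Minimum distance between the two occurrences (`>= k`).
#' @return A `kmer_pairs` data frame with columns `k`, `left_start`,
#'   `right_start`, `span` (0-based starts), sorted by decreasing span then
#'   increasing `left_start`. Zero rows when nothing qualifies.
#' @export
find_duplicate_kmers <- function(scaffold, k, min_span) {
  s <- as_dna_string(scaffold)
  L <- nchar(s)
  stopifnot(k >= 1L, k <= L, min_span >= k)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  grp <- split(starts[keep] - 1L, kmers[keep])  # 0-based starts per k-mer
  grp <- grp[lengths(grp) >= 2L]
  out <- list()
  for (pos in grp) {
    pairs <- utils::combn(pos, 2L)  # all ordered pairs (i < j)
    span <- pairs[2L, ] - pairs[1L, ]
    ok <- span >= min_span
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        k = k, left_start = pairs[1L, ok], right_start = pairs[2L, ok],
        span = span[ok])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(k = integer(), left_start = integer(),
               right_start = integer(), span = integer())
  res <- res[order(-res$span, res$left_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("kmer_pairs", "data.frame")
  res
}

#' Extract the longest putative circular sequence
#'
#' Selects the duplicated k-mer pair with maximal span (ties: smallest
#' `left_start`) and extracts `scaffold[left_start, right_start)` — the
#' second copy of the k-mer is excluded, so the candidate carries exactly
#' one copy of the duplicated stretch and the implied junction is seamless.
#' The result is already flipped (see [flip()]).
#'
#' @inheritParams find_duplicate_kmers
#' @return A `putative_circle`: list with `sequence`, `source_interval`
#'   (0-based half-open on the scaffold), `k_used`, `flipped`,
#'   `flip_offset` and `junction_index`.
#' @export
extract_circle <- function(scaffold, k, min_span) {
  s <- as_dna_string(scaffold)
  pairs <- find_duplicate_kmers(s, k, min_span)
  if (nrow(pairs) == 0L) {
    all_pairs <- find_duplicate_kmers(s, k, min_span = k)
    largest <- if (nrow(all_pairs)) max(all_pairs$span) else NA_integer_
    stop(no_circularity_candidate(k, min_span, largest))
  }
  best <- pairs[1L, ]
  circ <- substr(s, best$left_start + 1L, best$right_start)
  fl <- flip(circ)
  structure(list(sequence = circ,
                 source_interval = c(best$left_start, best$right_start),
                 k_used = k,
                 flipped = fl$flipped,
                 flip_offset = fl$flip_offset,
                 junction_index = fl$junction_index),
            class = "putative_circle")
}

no_circularity_candidate <- function(k, min_span, largest_span) {
  structure(
    class = c("NoCircularityCandidate", "error", "condition"),
    list(message = paste0(
           "no duplicated ", k, "-mer at span >= ", min_span,
           if (!is.na(largest_span))
             paste0(" (largest span found: ", largest_span, ")")
           else " (no duplicated k-mer at all)"),
         call = NULL, k = k, min_span = min_span,
         largest_span = largest_span))
}

#' @export
print.putative_circle <- function(x, ...) {
  cat(sprintf(
    "<putative_circle> %d bp from scaffold [%d,%d) (k=%d)\n  flip_offset %d, junction between flipped positions %d|%d\n",
    nchar(x$sequence), x$source_interval[1], x$source_interval[2], x$k_used,
    x$flip_offset, x$junction_index, x$junction_index + 1L))
  invisible(x)
}

#' Flip (rotate) a circular candidate so its ends meet mid-sequence
#'
#' Rotates the sequence by `floor(L/2)` so the original 5' and 3' ends
#' become adjacent in the middle: `flipped = seq[flip_offset..] +
#' seq[..flip_offset]`. The junction lies between `junction_index` (the
#' original last base, 0-based) and `junction_index + 1` (the original
#' first base). Rotating the flipped sequence back by `L - flip_offset`
#' restores the input.
#'
#' @param circle_sequence DNA text (length >= 2) or a `seq_record`.
#' @return List with `flipped`, `flip_offset`, `junction_index`.
#' @export
flip <- function(circle_sequence) {
  s <- as_dna_string(circle_sequence)
  L <- nchar(s)
  if (L < 2L) stop("flip: sequence must have length >= 2")
  off <- L %/% 2L
  list(flipped = paste0(substr(s, off + 1L, L), substr(s, 1L, off)),
       flip_offset = off,
       junction_index = L - off - 1L)
}

#' Base composition of a sequence
#'
#' Percentages of A, C, G, T over non-N bases, each rounded to two
#' decimals; `GC` is `C% + G%` computed before rounding.
#'
#' @param sequence DNA text or `seq_record`.
#' @return Named numeric vector `A`, `C`, `G`, `T`, `GC`.
#' @export
base_composition <- function(sequence) {
  s <- as_dna_string(sequence)
  bases <- strsplit(s, "")[[1]]
  bases <- bases[bases != "N"]
  if (length(bases) == 0L)
    stop("base_composition: sequence is empty or all-N")
  n <- length(bases)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(bases == b), 0L)
  pct <- 100 * cnt / n
  c(round(pct, 2), GC = round(unname(pct["C"] + pct["G"]), 2))
}

# Rotate a linear representation of a circle left by `offset` bases.
rotate_sequence <- function(sequence, offset) {
  s <- as_dna_string(sequence)
  L <- nchar(s)
  offset <- offset %% L
  if (offset == 0L) return(s)
  paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
}

#' Are two sequences the same circle?
#'
#' Two linearisations represent the same circular molecule iff they have
#' equal length and one is a substring of the other's doubling.
#'
#' @param a,b DNA texts or `seq_record`s.
#' @return Logical scalar.
#' @export
rotation_equivalent <- function(a, b) {
  a <- as_dna_string(a); b <- as_dna_string(b)
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}
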