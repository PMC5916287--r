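# End-to-end read alignment against the flipped candidate. The scoring
# conventions follow the end-to-end defaults of the short-read mappers this
# pipeline emulates: score <= 0, 0 = perfect, quality-scaled mismatch
# penalties, affine gaps, and a length-dependent score floor below which a
# read is unmapped.

#' Scoring scheme for end-to-end alignment
#'
#' @param mismatch_min Penalty for a mismatch at base quality 0.
#' @param mismatch_max Penalty for a mismatch at quality >= 40. The penalty
#'   at quality Q is `mismatch_min + floor((mismatch_max - mismatch_min) *
#'   min(Q, 40) / 40)`.
#' @param n_penalty Penalty for any column involving an `N`.
#' @param gap_open Penalty to open a gap (read or reference).
#' @param gap_extend Penalty per gap base; a length-1 gap costs
#'   `gap_open + gap_extend`.
#' @param min_score Score floor; reads scoring below it are unmapped.
#'   `NULL` (default) uses `floor(-(0.6 + 0.6 * read_length))` per read.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(mismatch_min = 2L, mismatch_max = 6L,
                           n_penalty = 1L, gap_open = 5L, gap_extend = 3L,
                           min_score = NULL) {
  stopifnot(mismatch_min >= 0, mismatch_max >= mismatch_min,
            n_penalty >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(mismatch_min = as.integer(mismatch_min),
                 mismatch_max = as.integer(mismatch_max),
                 n_penalty = as.integer(n_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = if (is.null(min_score)) NULL
                             else as.integer(min_score)),
            class = "scoring_scheme")
}

min_score_for <- function(scheme, read_lengths) {
  if (!is.null(scheme$min_score))
    rep(scheme$min_score, length(read_lengths))
  else
    as.integer(floor(-(0.6 + 0.6 * read_lengths)))
}

#' Align reads end-to-end against a reference
#'
#' Aligns each read globally (every read base consumed, no clipping) at its
#' best-scoring placement within the reference. Candidate placements are
#' anchored by exact seeds of `seed_length` bases and resolved with
#' affine-gap dynamic programming over a window of `band` extra columns
#' around the anchored diagonal; references of at most `full_dp_max_ref`
#' bases are aligned by full dynamic programming without seeding. The first
#' and last alignment columns must consume reference, so reads overhanging
#' the reference ends are unmapped rather than aligned with dangling gaps.
#' Both orientations are tried and the better one kept (reverse-complement
#' placements are reported in forward reference coordinates with
#' `strand == "-"`). Ties are broken by smallest `ref_start`, then fewest
#' gap columns, then forward strand. Mates of a pair are aligned
#' independently.
#'
#' @param reads List of [seq_record()]s (qualities default to Q40 when
#'   absent).
#' @param reference DNA text or `seq_record`.
#' @param scheme A [scoring_scheme()].
#' @param seed_length Exact-seed length for anchoring (bases).
#' @param band Extra window columns around an anchored diagonal.
#' @param full_dp_max_ref Reference length up to which seeding is skipped.
#' @return A `read_alignments` data frame with one row per read: `read_id`,
#'   `ref_start`, `ref_end` (0-based half-open), `score` (<= 0), `mapped`,
#'   and `ops` (per-column string over `M`, `X`, `I`, `D`).
#' @export
align_all <- function(reads, reference, scheme = scoring_scheme(),
                      seed_length = 20L, band = 15L,
                      full_dp_max_ref = 2000L) {
  reads <- as_record_list(reads)
  ref <- as_dna_string(reference)
  if (nchar(ref) < 1L) stop("align_all: empty reference")
  if (length(reads) == 0L) return(empty_alignments())
  seqs <- vapply(reads, `[[`, "", "sequence")
  quals <- lapply(reads, function(r) {
    if (is.null(r$qualities)) rep(40L, nchar(r$sequence)) else r$qualities
  })
  ms <- min_score_for(scheme, nchar(seqs))
  res <- .cpp_align_batch(seqs, quals, ref, ms,
                          scheme$mismatch_min, scheme$mismatch_max,
                          scheme$n_penalty, scheme$gap_open,
                          scheme$gap_extend,
                          as.integer(seed_length), as.integer(band),
                          as.integer(full_dp_max_ref))
  out <- data.frame(read_id = vapply(reads, `[[`, "", "id"),
                    ref_start = res$ref_start, ref_end = res$ref_end,
                    score = res$score, mapped = res$mapped, ops = res$ops,
                    strand = res$strand, stringsAsFactors = FALSE)
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Align a single read end-to-end
#'
#' Convenience wrapper around [align_all()] for one read.
#'
#' @inheritParams align_all
#' @param read A [seq_record()].
#' @return A list (one `ReadAlignment`): `read_id`, `ref_start`, `ref_end`,
#'   `score`, `mapped`, `ops`.
#' @export
align_end_to_end <- function(read, reference, scheme = scoring_scheme(),
                             seed_length = 20L, band = 15L,
                             full_dp_max_ref = 2000L) {
  if (is.character(read)) read <- seq_record("read", read)
  if (nchar(read$sequence) < 1L) stop("align_end_to_end: empty read")
  a <- align_all(list(read), reference, scheme, seed_length, band,
                 full_dp_max_ref)
  as.list(a[1L, ])
}
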