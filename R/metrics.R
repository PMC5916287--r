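# Circularity metrics over the flipped candidate: per-position coverage and
# connectivity, average alignment score, similarity, and the PASS/FAIL
# verdict. Connectivity counts, for each position, the reads that support
# that base's adjacency to BOTH neighbours: the read must place bases on
# positions i-1, i and i+1 with those three columns consecutive in the read
# (no gap column between them). Reads that start or end at a position, or
# are gapped across it, do not support it; the first and last reference
# positions always have connectivity 0.

validate_alignments <- function(alignments, length) {
  stopifnot(inherits(alignments, "data.frame"))
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) &&
      (any(m$ref_start < 0L) || any(m$ref_end > length) ||
       any(m$ref_start >= m$ref_end)))
    stop("alignments outside [0, ", length, ") or empty intervals")
  invisible(m)
}

profiles_cpp <- function(alignments, length) {
  validate_alignments(alignments, length)
  .cpp_profiles(alignments$ops, as.integer(alignments$ref_start),
                alignments$mapped, as.integer(length))
}

#' Per-position coverage profile
#'
#' Position `i` counts mapped reads placing a read base (match or mismatch
#' column) on reference position `i`; deletion columns do not count.
#'
#' @param alignments A `read_alignments` table.
#' @param length Reference length in bases.
#' @return Integer vector of length `length`.
#' @export
coverage_profile <- function(alignments, length) {
  profiles_cpp(alignments, length)$coverage
}

#' Per-position connectivity profile
#'
#' Position `i` (for `1 <= i <= length - 2`) counts mapped reads placing
#' read bases on positions `i-1`, `i` and `i+1` with the three columns
#' consecutive in the read (mismatches allowed, gaps not). The reference
#' ends always have connectivity 0.
#'
#' @inheritParams coverage_profile
#' @return Integer vector of length `length`.
#' @export
connectivity_profile <- function(alignments, length) {
  profiles_cpp(alignments, length)$connectivity
}

#' Combined position profile
#'
#' @inheritParams coverage_profile
#' @return A `position_profile`: list with `length`, `coverage`,
#'   `connectivity`.
#' @export
position_profile <- function(alignments, length) {
  p <- profiles_cpp(alignments, length)
  structure(list(length = as.integer(length), coverage = p$coverage,
                 connectivity = p$connectivity),
            class = "position_profile")
}

#' Alignment similarity
#'
#' Percent of match columns among all match + mismatch columns over all
#' mapped reads; gap columns are excluded from the denominator.
#'
#' @param alignments A `read_alignments` table.
#' @return Numeric percentage in `[0, 100]`.
#' @export
similarity <- function(alignments) {
  m <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(m) == 0L)
    stop("similarity: no mapped reads")
  len <- max(m$ref_end, 0L)
  p <- .cpp_profiles(m$ops, as.integer(m$ref_start), m$mapped,
                     as.integer(len))
  100 * p$match_cols / (p$match_cols + p$mismatch_cols)
}

#' Verdict thresholds
#'
#' @param min_conn Minimum connectivity required at every position of the
#'   junction window (guards against a single chimeric read).
#' @param score_floor Average-alignment-score floor: the verdict is PASS
#'   only when the average score is strictly greater. `-3` follows the
#'   guidance that scores of -3 or lower warrant review.
#' @param window Junction half-window width in bases; `NULL` uses
#'   read length - 1, so every adjacency a junction-spanning read could
#'   attest is examined.
#' @return A `circ_thresholds` list.
#' @export
circ_thresholds <- function(min_conn = 2L, score_floor = -3.0,
                            window = NULL) {
  structure(list(min_conn = as.integer(min_conn),
                 score_floor = as.numeric(score_floor),
                 window = if (is.null(window)) NULL else as.integer(window)),
            class = "circ_thresholds")
}

# read-consuming columns per alignment (M, X, I)
read_lengths_of <- function(alignments) {
  vapply(alignments$ops, function(o) {
    if (is.na(o)) return(NA_integer_)
    nchar(gsub("D", "", o, fixed = TRUE))
  }, 0L, USE.NAMES = FALSE)
}

#' Summarise circularity evidence into a report
#'
#' Computes the summary metrics over a flipped candidate and renders the
#' verdict: PASS iff the minimum connectivity inside the junction window is
#' at least `min_conn` AND the average alignment score exceeds
#' `score_floor`. The junction window is
#' `[junction_index - w + 1, junction_index + w]` clipped to
#' `[1, length - 2]`, with `w` defaulting to read length - 1. Advisory
#' flags mark scores of -3 or lower and junction connectivity below 25% of
#' the profile-wide median.
#'
#' @param alignments A `read_alignments` table.
#' @param profile A [position_profile()] computed from the same alignments.
#' @param junction_index 0-based index of the original last base in the
#'   flipped sequence (see [flip()]).
#' @param thresholds A [circ_thresholds()].
#' @return A `circularity_report`: list with `mean_coverage`,
#'   `average_alignment_score`, `similarity`, `junction_window` (0-based
#'   inclusive bounds), `min_junction_connectivity`,
#'   `mean_junction_connectivity`, `verdict` ("PASS"/"FAIL"), `flags`,
#'   `n_mapped`, `n_unmapped`.
#' @export
summarize_circularity <- function(alignments, profile, junction_index,
                                  thresholds = circ_thresholds()) {
  L <- profile$length
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  n_mapped <- nrow(mapped)
  n_unmapped <- nrow(alignments) - n_mapped
  if (n_mapped == 0L) {
    return(structure(list(
      mean_coverage = 0, average_alignment_score = NA_real_,
      similarity = NA_real_, junction_window = c(NA_integer_, NA_integer_),
      min_junction_connectivity = 0L, mean_junction_connectivity = 0,
      verdict = "FAIL", flags = "no mapped reads",
      n_mapped = 0L, n_unmapped = n_unmapped),
      class = "circularity_report"))
  }
  w <- thresholds$window
  if (is.null(w)) {
    rl <- stats::median(read_lengths_of(mapped), na.rm = TRUE)
    w <- max(1L, as.integer(rl) - 1L)
  }
  lo <- max(1L, as.integer(junction_index) - w + 1L)
  hi <- min(L - 2L, as.integer(junction_index) + w)
  if (lo > hi) stop("summarize_circularity: junction window empty")
  jconn <- profile$connectivity[(lo + 1L):(hi + 1L)]  # 1-based subset
  min_jconn <- min(jconn)
  mean_jconn <- mean(jconn)
  avg_score <- mean(mapped$score)
  sim <- similarity(alignments)
  flags <- character()
  if (avg_score <= -3)
    flags <- c(flags, "score <= -3: review recommended")
  med_conn <- stats::median(profile$connectivity[2:(L - 1L)])
  if (med_conn > 0 && min_jconn < 0.25 * med_conn)
    flags <- c(flags,
               "junction connectivity < 25% of profile-wide median")
  verdict <- if (min_jconn >= thresholds$min_conn &&
                 avg_score > thresholds$score_floor) "PASS" else "FAIL"
  structure(list(
    mean_coverage = sum(profile$coverage) / L,
    average_alignment_score = avg_score,
    similarity = sim,
    junction_window = c(lo, hi),
    min_junction_connectivity = min_jconn,
    mean_junction_connectivity = mean_jconn,
    verdict = verdict, flags = flags,
    n_mapped = n_mapped, n_unmapped = n_unmapped),
    class = "circularity_report")
}

#' @export
print.circularity_report <- function(x, ...) {
  cat(sprintf(
    paste0("<circularity_report> verdict: %s\n",
           "  mean coverage        %.2f\n",
           "  avg alignment score  %s\n",
           "  similarity           %s%%\n",
           "  junction window      [%s, %s]\n",
           "  min junction conn.   %d\n",
           "  reads mapped/unmapped %d/%d\n"),
    x$verdict, x$mean_coverage,
    format(round(x$average_alignment_score, 3)),
    format(round(x$similarity, 2)),
    x$junction_window[1], x$junction_window[2],
    x$min_junction_connectivity, x$n_mapped, x$n_unmapped))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Write the per-position profile as TSV
#'
#' Columns: `position` (1-based), `base`, `coverage`, `connectivity`.
#'
#' @param profile A [position_profile()].
#' @param reference DNA text of the profiled reference.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, reference, path) {
  ref <- as_dna_string(reference)
  stopifnot(nchar(ref) == profile$length)
  df <- data.frame(position = seq_len(profile$length),
                   base = strsplit(ref, "")[[1]],
                   coverage = profile$coverage,
                   connectivity = profile$connectivity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
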