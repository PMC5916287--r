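# Independent brute-force oracles used to validate the optimised
# implementations on small inputs. These deliberately share no code with
# the package internals.

# Best end-to-end alignment score by exhaustive enumeration of placements:
# global in the read, local in the reference, first and last columns
# reference-consuming, affine gaps, bounded total gap columns.
oracle_align_score <- function(read, ref, qual = rep(40L, nchar(read)),
                               scheme = scoring_scheme(), max_gaps = 4L) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  n <- length(rd); m <- length(rf)
  if (n > m) return(NA_real_)  # unmapped by definition
  sub_pen <- function(i, j) {
    if (rd[i] == "N" || rf[j] == "N") return(scheme$n_penalty)
    if (rd[i] == rf[j]) return(0)
    scheme$mismatch_min +
      floor((scheme$mismatch_max - scheme$mismatch_min) *
              min(qual[i], 40) / 40)
  }
  best <- -Inf
  rec <- function(i, j, pen, last, gaps) {
    if (i > n) {
      if (last == "M") best <<- max(best, -pen)
      return(invisible(NULL))
    }
    if (-pen <= best) return(invisible(NULL))  # cannot improve
    if (j <= m)
      rec(i + 1L, j + 1L, pen + sub_pen(i, j), "M", gaps)
    if (last != "" && gaps < max_gaps) {
      rec(i + 1L, j,
          pen + scheme$gap_extend +
            if (last != "I") scheme$gap_open else 0,
          "I", gaps + 1L)
      if (j <= m)
        rec(i, j + 1L,
            pen + scheme$gap_extend +
              if (last != "D") scheme$gap_open else 0,
            "D", gaps + 1L)
    }
    invisible(NULL)
  }
  for (j0 in seq_len(m)) rec(1L, j0, 0, "", 0L)
  if (is.infinite(best)) NA_real_ else best
}

# All duplicated k-mer pairs by exhaustive all-pairs substring comparison.
oracle_kmer_pairs <- function(scaffold, k, min_span) {
  L <- nchar(scaffold)
  rows <- list()
  for (i in 0:(L - k)) {
    a <- substr(scaffold, i + 1, i + k)
    if (grepl("N", a, fixed = TRUE)) next
    for (j in 0:(L - k)) {
      if (j - i < min_span) next
      if (a == substr(scaffold, j + 1, j + k))
        rows[[length(rows) + 1]] <-
          data.frame(k = k, left_start = i, right_start = j, span = j - i)
    }
  }
  if (!length(rows))
    return(data.frame(k = integer(), left_start = integer(),
                      right_start = integer(), span = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$left_start), ]
  rownames(out) <- NULL
  out
}

# Coverage and connectivity by a direct per-position scan over expanded
# alignment columns.
oracle_profiles <- function(alignments, length) {
  cov <- integer(length)
  conn <- integer(length)
  for (idx in which(alignments$mapped)) {
    ops <- strsplit(alignments$ops[idx], "")[[1]]
    colref <- rep(NA_integer_, length(ops))
    colread <- rep(NA_integer_, length(ops))
    rp <- alignments$ref_start[idx]
    dp <- 0L
    for (t in seq_along(ops)) {
      o <- ops[t]
      if (o %in% c("M", "X")) {
        colref[t] <- rp; colread[t] <- dp; rp <- rp + 1L; dp <- dp + 1L
      } else if (o == "D") {
        colref[t] <- rp; rp <- rp + 1L
      } else {
        colread[t] <- dp; dp <- dp + 1L
      }
    }
    hasbase <- !is.na(colref) & !is.na(colread)
    for (t in which(hasbase)) cov[colref[t] + 1L] <- cov[colref[t] + 1L] + 1L
    if (length >= 3) for (i in 1:(length - 2L)) {
      t0 <- which(hasbase & colref == i - 1L)
      t1 <- which(hasbase & colref == i)
      t2 <- which(hasbase & colref == i + 1L)
      if (length(t0) == 1L && length(t1) == 1L && length(t2) == 1L &&
          colread[t1] == colread[t0] + 1L &&
          colread[t2] == colread[t1] + 1L)
        conn[i + 1L] <- conn[i + 1L] + 1L
    }
  }
  list(coverage = cov, connectivity = conn)
}

# Random DNA helpers for property-style tests.
random_dna <- function(n, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alph, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)),
        collapse = "")
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")

# strand-aware oracle: best of forward and reverse-complement placements
oracle_align_score2 <- function(read, ref, qual = rep(40L, nchar(read)),
                                scheme = scoring_scheme(), max_gaps = 6L) {
  f <- oracle_align_score(read, ref, qual, scheme, max_gaps)
  r <- oracle_align_score(oracle_revcomp(read), ref, rev(qual), scheme,
                          max_gaps)
  if (is.na(f)) return(r)
  if (is.na(r)) return(f)
  max(f, r)
}

# Hand-build an alignment table row without going through the aligner.
mk_aln <- function(read_id, ref_start, ops, score = 0, mapped = TRUE) {
  data.frame(read_id = read_id, ref_start = ref_start,
             ref_end = ref_start + sum(strsplit(ops, "")[[1]] %in%
                                         c("M", "X", "D")),
             score = score, mapped = mapped, ops = ops, strand = "+",
             stringsAsFactors = FALSE)
}

mk_alns <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("read_alignments", "data.frame")
  out
}

empty_alns <- function() {
  out <- mk_aln("x", 0, "M")[0, ]
  class(out) <- c("read_alignments", "data.frame")
  out
}
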