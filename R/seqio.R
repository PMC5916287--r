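#' @useDynLib mitocirc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal convention: all coordinates are 0-based, half-open. SAM's 1-based
# POS is converted on ingestion and converted back only when writing SAM.

#' Construct a sequence record
#'
#' A `seq_record` holds one named DNA sequence with optional per-base Phred
#' qualities. The sequence is normalised to uppercase and any symbol outside
#' `{A,C,G,T,N}` is mapped to `N`.
#'
#' @param id Character scalar, record label.
#' @param sequence Character scalar, DNA sequence (length >= 1).
#' @param qualities Optional integer vector of Phred scores, one per base.
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `sequence` and `qualities` (`NULL` when absent).
#' @examples
#' seq_record("x", "ac-gt")$sequence  # "ACNGT"
#' @export
seq_record <- function(id, sequence, qualities = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_dna(sequence)
  if (nchar(sequence) < 1L)
    stop("seq_record: sequence must have length >= 1")
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(sequence))
      stop("seq_record: qualities length (", length(qualities),
           ") does not match sequence length (", nchar(sequence), ")")
    if (any(qualities < 0L))
      stop("seq_record: Phred qualities must be >= 0")
  }
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp%s)\n", x$id, nchar(x$sequence),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

# Uppercase and map non-ACGTN symbols to N.
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# Accept either a seq_record or a bare character scalar.
as_dna_string <- function(x) {
  if (inherits(x, "seq_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(normalize_dna(x))
  stop("expected a seq_record or a single character string")
}

#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA into a list of [seq_record()]s,
#' order preserved, sequences normalised (uppercase, non-ACGTN to N).
#'
#' @param path Path to a FASTA file.
#' @return List of `seq_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("read_fasta: malformed FASTA in ", path, ": ",
                         conditionMessage(e)))
  if (length(set) == 0L)
    stop("read_fasta: no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mapply(function(i, s) seq_record(i, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA
#'
#' @param records A `seq_record` or list of them.
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_record_list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

as_record_list <- function(records) {
  if (inherits(records, "seq_record")) return(list(records))
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE, "seq_record")))
  records
}

#' Read short reads from FASTQ
#'
#' Reads single- or paired-end FASTQ (plain or gzipped, Phred+33). With two
#' files, mates are associated by order and tagged `/1` and `/2`; the files
#' must contain equal numbers of records.
#'
#' @param path1 FASTQ file of first mates (or all reads if single-end).
#' @param path2 Optional FASTQ file of second mates.
#' @return List of `seq_record` objects; for paired input mates are
#'   interleaved (`r1/1, r1/2, r2/1, ...`).
#' @export
read_reads <- function(path1, path2 = NULL) {
  r1 <- read_fastq_one(path1)
  if (is.null(path2)) return(r1)
  r2 <- read_fastq_one(path2)
  if (length(r1) != length(r2))
    stop("read_reads: mate files differ in record count (",
         length(r1), " vs ", length(r2), ")")
  out <- vector("list", 2L * length(r1))
  for (i in seq_along(r1)) {
    id <- sub("/[12]$", "", r1[[i]]$id)
    m1 <- r1[[i]]; m1$id <- paste0(id, "/1")
    m2 <- r2[[i]]; m2$id <- paste0(id, "/2")
    out[[2L * i - 1L]] <- m1
    out[[2L * i]] <- m2
  }
  out
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("read_reads: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e)
      stop("read_reads: malformed FASTQ in ", path, ": ",
           conditionMessage(e)))
  quals <- S4Vectors::mcols(set)$qualities
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  qstr <- as.character(quals)
  out <- vector("list", length(set))
  for (i in seq_along(out)) {
    q <- utf8ToInt(qstr[[i]]) - 33L
    if (length(q) != nchar(seqs[[i]]))
      stop("read_reads: quality/sequence length mismatch for record ",
           ids[[i]], " in ", path)
    out[[i]] <- seq_record(ids[[i]], seqs[[i]], q)
  }
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param records List of `seq_record`s with qualities (missing qualities
#'   are written as Q40).
#' @param path Output path (gzipped if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  records <- as_record_list(records)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (r in records) {
    q <- r$qualities
    if (is.null(q)) q <- rep(40L, nchar(r$sequence))
    writeLines(c(paste0("@", r$id), r$sequence, "+",
                 intToUtf8(pmin(q, 93L) + 33L)), con)
  }
  invisible(path)
}

#' Ingest alignments from a SAM file
#'
#' Converts mapped records of a SAM file into the package's internal
#' alignment table. The reference interval comes from `POS` + CIGAR
#' (converted to 0-based half-open), the score from the `AS:i` tag; records
#' without `AS:i` get their score recomputed from the `MD` tag, read
#' qualities and the active scoring scheme, or raise an error. Soft-clipped
#' bases are dropped (they contribute to no metric); hard clips and other
#' exotic CIGAR operations are rejected. Unmapped records are skipped.
#' `M` columns are split into match/mismatch using the `MD` tag when
#' present; without `MD` they are counted as matches.
#'
#' @param path Path to a SAM file with a header.
#' @param reference_id Name of the reference the alignments must target.
#' @param scheme [scoring_scheme()] used only to recompute missing scores.
#' @return A `read_alignments` data frame (see [align_all()]).
#' @export
read_sam_alignments <- function(path, reference_id,
                                scheme = scoring_scheme()) {
  if (!file.exists(path)) stop("read_sam_alignments: no such file: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!reference_id %in% names(targets))
    stop("read_sam_alignments: reference '", reference_id,
         "' absent from SAM header")
  ref_len <- unname(targets[[reference_id]])
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = c("AS", "MD"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  rows <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    if (bitwAnd(x$flag[i], 4L) != 0L) next  # unmapped
    if (is.na(x$rname[i]) || as.character(x$rname[i]) != reference_id) next
    cigar <- x$cigar[i]
    seqi <- as.character(x$seq[i])
    quali <- as.character(x$qual[i])
    q <- if (nzchar(quali) && quali != "*") utf8ToInt(quali) - 33L
         else rep(40L, nchar(seqi))
    parsed <- expand_sam_record(cigar, seqi, q, x$tag$MD[[i]])
    score <- x$tag$AS[[i]]
    if (is.null(score) || is.na(score)) {
      if (is.null(parsed$md_used) || !parsed$md_used)
        stop("read_sam_alignments: record ", x$qname[i],
             " lacks AS:i and has no MD tag to recompute a score from")
      score <- -score_columns(parsed$ops, parsed$read_bases, parsed$read_quals,
                              parsed$ref_n, scheme)
    }
    start0 <- x$pos[i] - 1L
    nref <- sum(strsplit(parsed$ops, "")[[1]] %in% c("M", "X", "D"))
    end0 <- start0 + nref
    if (start0 < 0L || end0 > ref_len)
      stop("read_sam_alignments: alignment for ", x$qname[i],
           " extends outside reference ", reference_id)
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      read_id = x$qname[i], ref_start = start0, ref_end = end0,
      score = as.numeric(score), mapped = TRUE, ops = parsed$ops,
      strand = if (bitwAnd(x$flag[i], 16L) != 0L) "-" else "+",
      stringsAsFactors = FALSE)
  }
  out <- if (kept == 0L) empty_alignments() else
    do.call(rbind, rows[seq_len(kept)])
  class(out) <- c("read_alignments", "data.frame")
  out
}

# Expand CIGAR (+ optional MD tag) into a per-column ops string over
# {M,X,I,D}. Soft clips are removed (and trimmed from seq/qual); hard clips
# and any other op are rejected.
expand_sam_record <- function(cigar, seq, qual, md) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L)
    stop("read_sam_alignments: malformed CIGAR '", cigar, "'")
  bad <- setdiff(ops, c("M", "=", "X", "I", "D", "S"))
  if (length(bad))
    stop("read_sam_alignments: unsupported CIGAR operation(s) ",
         paste(bad, collapse = ","), " in '", cigar, "'")
  # trim soft clips off the read
  sseq <- strsplit(seq, "")[[1]]
  if (ops[1] == "S") { sseq <- sseq[-seq_len(lens[1])]
                       qual <- qual[-seq_len(lens[1])]
                       ops <- ops[-1]; lens <- lens[-1] }
  k <- length(ops)
  if (k > 0L && ops[k] == "S") {
    nr <- length(sseq)
    drop <- (nr - lens[k] + 1L):nr
    sseq <- sseq[-drop]; qual <- qual[-drop]
    ops <- ops[-k]; lens <- lens[-k]
  }
  cols <- unlist(mapply(function(o, l) rep(o, l), ops, lens,
                        SIMPLIFY = FALSE), use.names = FALSE)
  cols[cols == "="] <- "M"
  md_used <- FALSE
  if (!is.null(md) && !is.na(md) && nzchar(md)) {
    cols <- apply_md(cols, md)
    md_used <- TRUE
  }
  # read bases / quals per column (NA for D columns)
  read_bases <- rep(NA_character_, length(cols))
  read_quals <- rep(NA_integer_, length(cols))
  ri <- 0L
  ref_n <- rep(FALSE, length(cols))  # unknown without reference; MD marks N
  for (j in seq_along(cols)) {
    if (cols[j] != "D") {
      ri <- ri + 1L
      read_bases[j] <- sseq[ri]
      read_quals[j] <- qual[ri]
    }
  }
  list(ops = paste(cols, collapse = ""), read_bases = read_bases,
       read_quals = read_quals, ref_n = ref_n, md_used = md_used)
}

# Reclassify M columns as X using the MD tag (matched-length runs of
# matches, mismatched reference bases, and ^-prefixed deletions).
apply_md <- function(cols, md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  aligned <- which(cols %in% c("M", "X", "D"))  # MD walks ref-consuming cols
  pos <- 1L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      pos <- pos + as.integer(t)
    } else if (startsWith(t, "^")) {
      pos <- pos + nchar(t) - 1L
    } else {
      idx <- aligned[pos]
      if (!is.na(idx) && cols[idx] == "M") cols[idx] <- "X"
      pos <- pos + 1L
    }
  }
  cols
}

# Penalty total for an expanded column vector under a scoring scheme.
score_columns <- function(ops, read_bases, read_quals, ref_n, scheme) {
  cols <- strsplit(ops, "")[[1]]
  pen <- 0
  in_gap <- FALSE
  for (j in seq_along(cols)) {
    op <- cols[j]
    if (op == "I" || op == "D") {
      pen <- pen + scheme$gap_extend + if (!in_gap) scheme$gap_open else 0
      in_gap <- TRUE
      next
    }
    in_gap <- FALSE
    if (op == "X") {
      if (!is.na(read_bases[j]) && read_bases[j] == "N" || isTRUE(ref_n[j])) {
        pen <- pen + scheme$n_penalty
      } else {
        q <- min(read_quals[j], 40L)
        pen <- pen + scheme$mismatch_min +
          floor((scheme$mismatch_max - scheme$mismatch_min) * q / 40)
      }
    } else if (op == "M" &&
               (isTRUE(ref_n[j]) ||
                (!is.na(read_bases[j]) && read_bases[j] == "N"))) {
      pen <- pen + scheme$n_penalty
    }
  }
  pen
}

empty_alignments <- function() {
  structure(
    data.frame(read_id = character(), ref_start = integer(),
               ref_end = integer(), score = numeric(), mapped = logical(),
               ops = character(), strand = character(),
               stringsAsFactors = FALSE),
    class = c("read_alignments", "data.frame"))
}

#' Write internal alignments as SAM
#'
#' Minimal SAM output (one `@SQ` line, `AS:i` tag populated) so internal
#' alignments can be inspected with standard tools.
#'
#' @param alignments A `read_alignments` table from [align_all()].
#' @param reads The reads that were aligned (for SEQ/QUAL columns).
#' @param reference_id,reference_length Header values for the target.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, reference_id, reference_length,
                      path) {
  reads <- as_record_list(reads)
  names(reads) <- vapply(reads, `[[`, "", "id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", reference_id,
                       as.integer(reference_length))), con)
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    r <- reads[[a$read_id]]
    seqs <- if (is.null(r)) "*" else r$sequence
    qual <- if (is.null(r) || is.null(r$qualities)) "*" else
      intToUtf8(pmin(r$qualities, 93L) + 33L)
    if (!a$mapped) {
      writeLines(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       seqs, qual, sep = "\t"), con)
    } else {
      is_rev <- identical(a$strand, "-")
      if (is_rev && seqs != "*") {    # SAM stores the forward projection
        seqs <- revcomp(seqs)
        if (qual != "*")
          qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
      }
      writeLines(paste(a$read_id, if (is_rev) 16L else 0L, reference_id,
                       a$ref_start + 1L, 255L,
                       ops_to_cigar(a$ops), "*", 0L, 0L, seqs, qual,
                       paste0("AS:i:", as.integer(a$score)), sep = "\t"), con)
    }
  }
  invisible(path)
}

# Collapse an expanded ops string into a CIGAR (match and mismatch as M).
ops_to_cigar <- function(ops) {
  cols <- strsplit(chartr("X", "M", ops), "")[[1]]
  r <- rle(cols)
  paste0(r$lengths, r$values, collapse = "")
}
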