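# Ground-truth simulator: circular genomes, wrap-around paired reads, and
# the scaffold artifacts (duplicated origin-adjacent stretch, spurious
# flanks) that baiting/iterative-mapping assemblers leave around a circular
# core. Reads are generated on the TRUE circle, not the scaffold: they
# attest the junction the linear scaffold hides.

BASES <- c("A", "C", "G", "T")

#' Simulate a circular genome
#'
#' i.i.d. bases with `P(G) + P(C) = gc` split equally and `P(A) = P(T)`.
#'
#' @param length Genome length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Optional RNG seed for reproducibility.
#' @return Character scalar DNA text (a linearisation of the circle).
#' @export
simulate_circular_genome <- function(length, gc = 0.4, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' Simulate paired-end reads over a circular genome
#'
#' Fragment starts are uniform on the circle, so reads may span the origin.
#' The pair count is `ceiling(coverage * length / (2 * read_length))`; the
#' second mate is reverse-complemented. Substitution errors are i.i.d. per
#' base at `sub_rate` (the erroneous base is drawn uniformly from the other
#' three). Base qualities are constant `base_quality` (Q40); bases carrying
#' a simulated error can optionally be down-weighted via `error_quality`.
#'
#' @param genome Circular DNA text (or `seq_record`).
#' @param coverage Target fold coverage.
#' @param read_length Read length in bases.
#' @param insert_mean,insert_sd Fragment-size model (bases); must satisfy
#'   `insert_mean >= read_length`.
#' @param sub_rate Per-base substitution error rate.
#' @param seed Optional RNG seed.
#' @param base_quality Phred quality assigned to every base.
#' @param error_quality Phred quality assigned to erroneous bases (base
#'   callers flag most miscalls with low confidence; `NULL` leaves errors
#'   at `base_quality`).
#' @return List of [seq_record()]s, mates interleaved and tagged `/1`,`/2`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100L,
                           insert_mean = 300, insert_sd = 30,
                           sub_rate = 0, seed = NULL,
                           base_quality = 40L, error_quality = 5L) {
  g <- as_dna_string(genome)
  L <- nchar(g)
  stopifnot(read_length <= L, coverage > 0, sub_rate >= 0, sub_rate <= 1)
  if (insert_mean < read_length)
    stop("simulate_reads: insert_mean must be >= read_length")
  if (!is.null(seed)) set.seed(seed)
  npairs <- ceiling(coverage * L / (2 * read_length))
  g2 <- paste0(g, g)  # doubled circle: wrap-around reads are substrings
  starts <- sample.int(L, npairs, replace = TRUE) - 1L   # 0-based
  isize <- pmin(pmax(round(stats::rnorm(npairs, insert_mean, insert_sd)),
                     read_length), L)
  out <- vector("list", 2L * npairs)
  for (i in seq_len(npairs)) {
    s <- starts[i]
    m1 <- substr(g2, s + 1L, s + read_length)
    e2 <- s + isize[i]                      # fragment end (exclusive)
    m2 <- revcomp(substr(g2, e2 - read_length + 1L, e2))
    id <- sprintf("sim_%06d", i)
    out[[2L * i - 1L]] <- mutate_read(m1, paste0(id, "/1"), sub_rate,
                                      base_quality, error_quality)
    out[[2L * i]] <- mutate_read(m2, paste0(id, "/2"), sub_rate,
                                 base_quality, error_quality)
  }
  out
}

mutate_read <- function(seq, id, sub_rate, base_quality, error_quality) {
  n <- nchar(seq)
  qual <- rep(as.integer(base_quality), n)
  if (sub_rate > 0) {
    hits <- which(stats::runif(n) < sub_rate)
    if (length(hits)) {
      s <- strsplit(seq, "")[[1]]
      for (h in hits)
        s[h] <- sample(setdiff(BASES, s[h]), 1L)
      seq <- paste(s, collapse = "")
      if (!is.null(error_quality)) qual[hits] <- as.integer(error_quality)
    }
  }
  seq_record(id, seq, qual)
}

#' Build a scaffold with assembler artifacts
#'
#' `scaffold = random(flank5) + R + R[0:dup_len] + random(flank3)` where
#' `R` is the genome rotated by `rotation`: the circular core, its first
#' `dup_len` bases duplicated at the 3' end (the assembler walking past the
#' origin), flanked by spurious random sequence.
#'
#' @param genome Circular DNA text (or `seq_record`).
#' @param rotation Linearisation offset in bases (`< length`).
#' @param dup_len Bases duplicated at the scaffold 3' end
#'   (`0 < dup_len < length`).
#' @param flank5,flank3 Lengths of random flanking sequence.
#' @param seed Optional RNG seed (flank sequence).
#' @return List with `record` (the scaffold as a [seq_record()]) and
#'   `truth` (a `sim_truth` list recording every construction parameter).
#' @export
build_artifact_scaffold <- function(genome, rotation = 0L, dup_len,
                                    flank5 = 0L, flank3 = 0L, seed = NULL) {
  g <- as_dna_string(genome)
  L <- nchar(g)
  stopifnot(dup_len > 0, dup_len < L, rotation >= 0, rotation < L)
  if (!is.null(seed)) set.seed(seed)
  R <- rotate_sequence(g, rotation)
  rnd <- function(n) if (n > 0)
    paste(sample(BASES, n, replace = TRUE), collapse = "") else ""
  scaf <- paste0(rnd(flank5), R, substr(R, 1L, dup_len), rnd(flank3))
  truth <- structure(list(genome = g, rotation = as.integer(rotation),
                          dup_len = as.integer(dup_len),
                          flank5 = as.integer(flank5),
                          flank3 = as.integer(flank3),
                          seed = seed),
                     class = "sim_truth")
  list(record = seq_record("scaffold_sim", scaf), truth = truth)
}
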