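# Permutation validation: perturb 50-bp windows at both ends of the
# proposed circular sequence with random insertions or deletions, re-flip,
# re-map the reads, and compare the metrics against the unmodified
# candidate. A sensitive verdict should reject essentially every perturbed
# sequence; surviving false positives should carry visibly worse scores.

#' Permutation study configuration
#'
#' Defaults reproduce the published design: 50-bp end windows, 1% and 5%
#' per-base modification chances, insertion and deletion operations, 100
#' iterations per (probability, operation) pair — 400 perturbed iterations
#' plus one unmodified baseline.
#'
#' @param window Bases perturbed at each end of the candidate.
#' @param probabilities Per-base modification chances.
#' @param operations Subset of `c("insertion", "deletion")`.
#' @param reps Iterations per (probability, operation) pair.
#' @param seed RNG seed for the whole study; per-iteration substreams are
#'   derived deterministically from it.
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(window = 50L,
                               probabilities = c(0.01, 0.05),
                               operations = c("insertion", "deletion"),
                               reps = 100L, seed = 1L) {
  stopifnot(all(probabilities >= 0), all(probabilities <= 1), reps >= 1,
            all(operations %in% c("insertion", "deletion")),
            length(operations) >= 1)
  structure(list(window = as.integer(window),
                 probabilities = as.numeric(probabilities),
                 operations = operations, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "permutation_config")
}

#' Perturb the ends of a sequence
#'
#' Each position in the first `window` and last `window` bases is
#' independently modified with probability `probability`: deletion removes
#' the base; insertion adds one uniformly random base immediately after it.
#' Positions outside the windows are untouched. Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param sequence DNA text (length >= 2 * window) or `seq_record`.
#' @param window End-window width in bases.
#' @param probability Per-base modification chance in `[0, 1]`.
#' @param operation `"insertion"` or `"deletion"`.
#' @return List with `sequence` (modified) and `edits_made`.
#' @export
perturb_ends <- function(sequence, window = 50L, probability,
                         operation = c("insertion", "deletion")) {
  operation <- match.arg(operation)
  s <- as_dna_string(sequence)
  L <- nchar(s)
  if (L < 2L * window)
    stop("perturb_ends: sequence shorter than 2 * window")
  stopifnot(probability >= 0, probability <= 1)
  idx <- c(seq_len(window), (L - window + 1L):L)
  hit <- idx[stats::runif(length(idx)) < probability]
  if (length(hit) == 0L)
    return(list(sequence = s, edits_made = 0L))
  chars <- strsplit(s, "")[[1]]
  if (operation == "deletion") {
    chars <- chars[-hit]
  } else {
    ins <- sample(BASES, length(hit), replace = TRUE)
    pieces <- character(2L * length(hit) + 1L)
    prev <- 0L
    for (j in seq_along(hit)) {
      pieces[2L * j - 1L] <- paste(chars[(prev + 1L):hit[j]], collapse = "")
      pieces[2L * j] <- ins[j]
      prev <- hit[j]
    }
    pieces[2L * length(hit) + 1L] <-
      if (prev < L) paste(chars[(prev + 1L):L], collapse = "") else ""
    return(list(sequence = paste(pieces, collapse = ""),
                edits_made = length(hit)))
  }
  list(sequence = paste(chars, collapse = ""), edits_made = length(hit))
}

# Deterministic per-iteration seed below 2^31, mixed from the study seed.
iteration_seed <- function(seed, iteration) {
  as.integer((as.double(seed) * 2654435761 + iteration * 40503) %%
               2147483647)
}

#' Run the permutation study
#'
#' For every (probability, operation, rep) triple the UNflipped candidate
#' is perturbed at its ends, flipped, the reads re-aligned, and a
#' [summarize_circularity()] report computed; one baseline entry at
#' probability 0 uses the unmodified candidate. Iterations whose random
#' draw makes zero edits are redrawn (with a fresh derived substream) until
#' at least one edit is made, so every non-baseline entry is an actual
#' perturbation; the baseline alone represents the unmodified sequence.
#' Results are reproducible given `config$seed`.
#'
#' @param circle A [extract_circle()] result, `seq_record`, or DNA text
#'   (the unflipped candidate).
#' @param reads List of [seq_record()]s (the original reads).
#' @param config A [permutation_config()].
#' @param scheme A [scoring_scheme()].
#' @param thresholds A [circ_thresholds()].
#' @param ... Passed to [align_all()] (seeding/band parameters).
#' @return A `permutation_results` data frame: one row per iteration with
#'   `iteration` (0 = baseline), `probability`, `operation`, `edits_made`,
#'   `similarity`, `average_alignment_score`, `min_junction_connectivity`,
#'   `mean_junction_connectivity`, `verdict`, and a list-column `report`.
#' @export
run_permutation_study <- function(circle, reads,
                                  config = permutation_config(),
                                  scheme = scoring_scheme(),
                                  thresholds = circ_thresholds(), ...) {
  seq0 <- if (inherits(circle, "putative_circle")) circle$sequence
          else as_dna_string(circle)
  if (nchar(seq0) < 2L * config$window)
    stop("run_permutation_study: candidate shorter than 2 * window")
  grid <- expand.grid(rep = seq_len(config$reps),
                      operation = config$operations,
                      probability = config$probabilities,
                      stringsAsFactors = FALSE)
  evaluate <- function(sequence) {
    fl <- flip(sequence)
    aln <- align_all(reads, fl$flipped, scheme, ...)
    prof <- position_profile(aln, nchar(fl$flipped))
    summarize_circularity(aln, prof, fl$junction_index, thresholds)
  }
  baseline <- evaluate(seq0)
  n <- nrow(grid)
  rows <- vector("list", n + 1L)
  reports <- vector("list", n + 1L)
  rows[[1L]] <- perm_row(0L, 0, "none", 0L, baseline)
  reports[[1L]] <- baseline
  for (i in seq_len(n)) {
    p <- grid$probability[i]
    op <- grid$operation[i]
    tries <- 0L
    repeat {
      set.seed(iteration_seed(config$seed, i * 1000L + tries))
      pert <- perturb_ends(seq0, config$window, p, op)
      tries <- tries + 1L
      if (pert$edits_made >= 1L || tries >= 1000L) break
    }
    rep_i <- evaluate(pert$sequence)
    rows[[i + 1L]] <- perm_row(i, p, op, pert$edits_made, rep_i)
    reports[[i + 1L]] <- rep_i
  }
  out <- do.call(rbind, rows)
  out$report <- reports
  class(out) <- c("permutation_results", "data.frame")
  attr(out, "baseline") <- baseline
  out
}

perm_row <- function(iteration, probability, operation, edits, report) {
  data.frame(iteration = iteration, probability = probability,
             operation = operation, edits_made = edits,
             similarity = report$similarity,
             average_alignment_score = report$average_alignment_score,
             min_junction_connectivity = report$min_junction_connectivity,
             mean_junction_connectivity = report$mean_junction_connectivity,
             verdict = report$verdict, stringsAsFactors = FALSE)
}

#' Rank permutation results by distance to the baseline
#'
#' Distance is the Euclidean norm of the differences in similarity, mean
#' junction-window connectivity, and average alignment score, each
#' standardised by the baseline's absolute value (or 1 when that is 0).
#' Rank 1 is closest; ties share the smaller rank.
#'
#' @param results A `permutation_results` table.
#' @param baseline The baseline [summarize_circularity()] report (defaults
#'   to the one stored on `results`).
#' @return `results` with columns `distance` and `distance_rank` added.
#' @export
rank_by_distance <- function(results, baseline = attr(results, "baseline")) {
  stopifnot(!is.null(baseline))
  norm_by <- function(x) if (abs(x) > 0) abs(x) else 1
  d_sim <- (results$similarity - baseline$similarity) /
    norm_by(baseline$similarity)
  d_conn <- (results$mean_junction_connectivity -
               baseline$mean_junction_connectivity) /
    norm_by(baseline$mean_junction_connectivity)
  d_score <- (results$average_alignment_score -
                baseline$average_alignment_score) /
    norm_by(baseline$average_alignment_score)
  results$distance <- sqrt(d_sim^2 + d_conn^2 + d_score^2)
  results$distance_rank <- rank(results$distance, ties.method = "min")
  results
}

#' Summarise a permutation study
#'
#' Pass counts per condition and the false-positive rate (PASS verdicts
#' among perturbed entries; the baseline is excluded from all tallies).
#'
#' @param results A `permutation_results` table.
#' @return List with `n_iterations`, `pass_by_condition` (data frame),
#'   `false_positive_rate` (fraction), `baseline_verdict`.
#' @export
summarize_permutations <- function(results) {
  pert <- results[results$iteration > 0L, , drop = FALSE]
  key <- interaction(pert$probability, pert$operation, drop = TRUE)
  tab <- do.call(rbind, lapply(split(pert, key), function(d)
    data.frame(probability = d$probability[1L], operation = d$operation[1L],
               n_pass = sum(d$verdict == "PASS"), total = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  list(n_iterations = nrow(pert),
       pass_by_condition = tab[order(tab$probability, tab$operation), ],
       false_positive_rate = mean(pert$verdict == "PASS"),
       baseline_verdict = results$verdict[results$iteration == 0L])
}
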