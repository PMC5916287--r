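test_that("coverage counts read bases and skips deletion columns", {
  aln <- mk_alns(mk_aln("a", 0, "MMMMMM"), mk_aln("b", 1, "MMM"))
  expect_equal(coverage_profile(aln, 6), c(1, 2, 2, 2, 1, 1))

  expect_equal(coverage_profile(empty_alns(), 4), rep(0L, 4))

  gap <- mk_alns(mk_aln("c", 0, "MMMDMM"))
  expect_equal(coverage_profile(gap, 6), c(1, 1, 1, 0, 1, 1))
})

test_that("connectivity requires gap-free support of both adjacencies", {
  # read a covers [0,6), read b covers [1,4): b starts at 1 and ends at 3,
  # so it supports only position 2
  aln <- mk_alns(mk_aln("a", 0, "MMMMMM"), mk_aln("b", 1, "MMM"))
  expect_equal(connectivity_profile(aln, 6), c(0, 1, 2, 1, 1, 0))

  # a deletion breaks the adjacency chain on both sides of the gap
  gap <- mk_alns(mk_aln("c", 0, "MMMDMM"))
  expect_equal(connectivity_profile(gap, 6), c(0, 1, 0, 0, 0, 0))

  # an insertion between read bases breaks adjacency even though the
  # reference positions are contiguous
  ins <- mk_alns(mk_aln("d", 0, "MMMIMM"))
  expect_equal(connectivity_profile(ins, 5), c(0, 1, 0, 0, 0))
})

test_that("profiles match the direct per-position column scan", {
  set.seed(42)
  for (rep in 1:10) {
    L <- sample(20:50, 1)
    n_reads <- sample(1:20, 1)
    rows <- lapply(seq_len(n_reads), function(i) {
      ops_pool <- c("M", "M", "M", "M", "X", "I", "D")
      len <- sample(4:12, 1)
      ops <- paste(c("M", sample(ops_pool, len, replace = TRUE), "M"),
                   collapse = "")
      nref <- sum(strsplit(ops, "")[[1]] %in% c("M", "X", "D"))
      start <- sample(0:(L - nref), 1)
      mk_aln(paste0("r", i), start, ops)
    })
    aln <- do.call(mk_alns, rows)
    want <- oracle_profiles(aln, L)
    prof <- position_profile(aln, L)
    expect_equal(prof$coverage, want$coverage)
    expect_equal(prof$connectivity, want$connectivity)
    # invariants: connectivity bounded by coverage, ends at zero
    expect_true(all(prof$connectivity <= prof$coverage))
    expect_equal(prof$connectivity[1], 0L)
    expect_equal(prof$connectivity[L], 0L)
    # conservation: total coverage equals total match+mismatch columns
    cols <- sum(vapply(aln$ops, function(o)
      sum(strsplit(o, "")[[1]] %in% c("M", "X")), 0L))
    expect_equal(sum(prof$coverage), cols)
  }
})

test_that("alignments outside the reference raise a consistency error", {
  aln <- mk_alns(mk_aln("a", 10, "MMMM"))
  expect_error(coverage_profile(aln, 12), "outside")
})

test_that("similarity is the match fraction of aligned columns", {
  expect_equal(similarity(mk_alns(mk_aln("a", 0, "MMMM"))), 100)
  expect_equal(similarity(mk_alns(mk_aln("a", 0, "MMMMMMMMMX"))), 90)
  # gaps excluded from the denominator
  expect_equal(similarity(mk_alns(mk_aln("a", 0, "MMIDMX"))), 75)
  expect_error(similarity(empty_alns()), "no mapped reads")
})

test_that("similarity tracks the simulated substitution rate", {
  genome <- simulate_circular_genome(2000, 0.4, seed = 4)
  reads <- simulate_reads(genome, coverage = 15, read_length = 80,
                          insert_mean = 240, insert_sd = 20,
                          sub_rate = 0.02, seed = 5)
  aln <- align_all(reads, flip(genome)$flipped)
  s <- similarity(aln)
  # binomial error on ~24k columns is tiny; allow generous slack
  expect_lt(abs(s - 98), 0.5)
})

test_that("the verdict combines junction connectivity and score", {
  L <- 60
  # ample gap-free coverage across the junction
  rows <- lapply(0:49, function(s) mk_aln(paste0("r", s), s, strrep("M", 10),
                                          score = 0))
  aln <- do.call(mk_alns, rows)
  prof <- position_profile(aln, L)
  rep1 <- summarize_circularity(aln, prof, junction_index = 29,
                                circ_thresholds())
  expect_equal(rep1$verdict, "PASS")
  expect_equal(rep1$similarity, 100)
  expect_lte(rep1$average_alignment_score, 0)

  # a zero-connectivity hole inside the junction window forces FAIL
  rows2 <- rows[!vapply(rows, function(r)
    r$ref_start <= 29 && r$ref_start + 10 > 30, TRUE)]
  aln2 <- do.call(mk_alns, rows2)
  prof2 <- position_profile(aln2, L)
  rep2 <- summarize_circularity(aln2, prof2, junction_index = 29,
                                circ_thresholds())
  expect_equal(rep2$verdict, "FAIL")
  expect_equal(rep2$min_junction_connectivity, 0L)

  # intact connectivity but poor average score: FAIL with review flag
  rows3 <- lapply(rows, function(r) { r$score <- -3.5; r })
  aln3 <- do.call(mk_alns, rows3)
  rep3 <- summarize_circularity(aln3, prof, junction_index = 29,
                                circ_thresholds())
  expect_equal(rep3$verdict, "FAIL")
  expect_true(any(grepl("review", rep3$flags)))

  # no mapped reads at all
  rep4 <- summarize_circularity(empty_alns(), position_profile(empty_alns(),
                                                               L),
                                junction_index = 29)
  expect_equal(rep4$verdict, "FAIL")
  expect_true("no mapped reads" %in% rep4$flags)
})

test_that("error-free wrap-around reads give PASS; a junction indel FAILs", {
  genome <- simulate_circular_genome(3000, 0.4, seed = 14)
  reads <- simulate_reads(genome, coverage = 25, read_length = 80,
                          insert_mean = 240, insert_sd = 20,
                          sub_rate = 0, seed = 15)
  fl <- flip(genome)
  aln <- align_all(reads, fl$flipped)
  prof <- position_profile(aln, nchar(fl$flipped))
  rep0 <- summarize_circularity(aln, prof, fl$junction_index)
  expect_equal(rep0$verdict, "PASS")
  # connectivity positive throughout the interior, in particular across the
  # junction (the flipped sequence's own linear ends taper off because
  # overhanging reads are unmapped, as with any end-to-end mapper)
  expect_true(all(prof$connectivity[81:2920] > 0))
  expect_gt(prof$connectivity[fl$junction_index + 1], 0)

  # delete one base at the junction of the circle, re-flip, re-map
  del <- paste0(substr(genome, 1, nchar(genome) - 1), "")
  fl2 <- flip(del)
  aln2 <- align_all(reads, fl2$flipped)
  prof2 <- position_profile(aln2, nchar(fl2$flipped))
  rep2 <- summarize_circularity(aln2, prof2, fl2$junction_index)
  expect_equal(rep2$verdict, "FAIL")
  # junction adjacency support collapses below the pass threshold (it can
  # stay marginally above zero when the junction abuts a homopolymer, where
  # a read ending exactly at the run boundary still fits gap-free)
  expect_lt(rep2$min_junction_connectivity, 2L)
})
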