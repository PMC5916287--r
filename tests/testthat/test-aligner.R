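q40 <- function(s) seq_record("r", s, rep(40L, nchar(s)))

test_that("spec'd placements score as the penalty formula dictates", {
  # a permissive floor so that tiny example reads stay mapped (the default
  # length-scaled floor -(0.6 + 0.6 L) unmaps a 4-mer with one mismatch)
  deep <- scoring_scheme(min_score = -1000L)

  # exact substring: perfect score at the leftmost placement
  a <- align_end_to_end(q40("ACGT"), "TTACGTTT")
  expect_equal(a$score, 0)
  expect_equal(a$ref_start, 2L)
  expect_equal(a$ops, "MMMM")

  # one Q40 mismatch: penalty 2 + floor(4 * 40/40) = 6
  b <- align_end_to_end(q40("ACGT"), "TTACCTTT", deep)
  expect_equal(b$score, -6)

  # same mismatch at Q0: penalty 2 + floor(4 * 0/40) = 2
  b0 <- align_end_to_end(seq_record("r", "ACGT", rep(0L, 4)), "TTACCTTT",
                         deep)
  expect_equal(b0$score, -2)

  # one inserted read base: gap_open 5 + gap_extend 3 (reference chosen so
  # that no single-mismatch placement can do better)
  i1 <- align_end_to_end(q40("ACGGT"), "CCACGTCC", deep)
  expect_equal(i1$score, -8)
  expect_equal(sum(strsplit(i1$ops, "")[[1]] == "I"), 1L)

  # one deleted read base: same affine cost
  d1 <- align_end_to_end(q40("ACTTTA"), "CCACGTTTACC", deep)
  expect_equal(d1$score, -8)
  expect_equal(sum(strsplit(d1$ops, "")[[1]] == "D"), 1L)
})

test_that("scores match the brute-force placement enumeration", {
  set.seed(42)
  scheme <- scoring_scheme()
  for (rep in 1:40) {
    ref <- random_dna(sample(10:20, 1), with_n = rep %% 5 == 0)
    n <- sample(3:8, 1)
    if (rep %% 2 == 0) {
      read <- random_dna(n)
    } else {
      # plant a (possibly mutated/indeled) substring so placements exist
      st <- sample(nchar(ref) - n + 1, 1)
      read <- substr(ref, st, st + n - 1)
      if (rep %% 3 == 0 && n > 3) {
        cut <- sample(2:(n - 1), 1)
        read <- paste0(substr(read, 1, cut), "A", substr(read, cut + 1, n))
      }
    }
    qual <- sample(c(0L, 11L, 25L, 40L), nchar(read), replace = TRUE)
    want <- oracle_align_score2(read, ref, qual, scheme, max_gaps = 6L)
    got <- align_end_to_end(seq_record("r", read, qual), ref, scheme,
                            full_dp_max_ref = 100L)
    floor_n <- floor(-(0.6 + 0.6 * nchar(read)))
    if (is.na(want) || want < floor_n) {
      expect_false(got$mapped, info = sprintf("read=%s ref=%s", read, ref))
    } else {
      expect_equal(got$score, want,
                   info = sprintf("read=%s ref=%s", read, ref))
    }
  }
})

test_that("score is never positive and exact substrings score zero", {
  set.seed(13)
  for (rep in 1:10) {
    ref <- random_dna(60)
    st <- sample(40, 1)
    read <- substr(ref, st, st + 19)
    a <- align_end_to_end(q40(read), ref)
    expect_equal(a$score, 0)
    expect_true(a$mapped)
    r2 <- random_dna(20)
    a2 <- align_end_to_end(q40(r2), ref)
    if (a2$mapped) expect_lte(a2$score, 0)
  }
})

test_that("a single Q40 mismatch costs exactly mismatch_max", {
  set.seed(21)
  ref <- random_dna(3000)  # exercises the seeded/banded path
  st <- 1200
  read <- substr(ref, st + 1, st + 100)
  chars <- strsplit(read, "")[[1]]
  chars[50] <- setdiff(c("A", "C", "G", "T"), chars[50])[1]
  mm <- paste(chars, collapse = "")
  a0 <- align_end_to_end(q40(read), ref)
  a1 <- align_end_to_end(q40(mm), ref)
  expect_equal(a0$score, 0)
  expect_equal(a0$ref_start, st)
  expect_equal(a1$score, a0$score - 6)
})

test_that("alignment start shifts with reference rotation when the read
           avoids the cut point", {
  set.seed(33)
  ref <- random_dna(400)
  read <- substr(ref, 301, 340)
  rot <- 100L  # cut at position 100 moves [300,340) to [200,240)
  ref_rot <- paste0(substr(ref, rot + 1, 400), substr(ref, 1, rot))
  a <- align_end_to_end(q40(read), ref, full_dp_max_ref = 1000L)
  b <- align_end_to_end(q40(read), ref_rot, full_dp_max_ref = 1000L)
  expect_equal(a$score, b$score)
  expect_equal(b$ref_start, a$ref_start - rot)
})

test_that("degenerate inputs behave as defined", {
  # read longer than reference: unmapped
  a <- align_end_to_end(q40("ACGTACGTA"), "ACGT")
  expect_false(a$mapped)
  expect_error(align_end_to_end(q40("ACGT"), ""), "empty reference")
  # score floor: a hopeless read is unmapped
  bad <- align_end_to_end(q40(strrep("A", 30)), strrep("C", 60))
  expect_false(bad$mapped)
})

test_that("batch alignment is deterministic and maps error-free reads
           perfectly", {
  set.seed(55)
  genome <- simulate_circular_genome(800, 0.45, seed = 8)
  reads <- simulate_reads(genome, coverage = 3, read_length = 60,
                          insert_mean = 180, insert_sd = 10,
                          sub_rate = 0, seed = 9)
  expect_gt(length(reads), 10)
  a1 <- align_all(reads, genome)
  a2 <- align_all(reads, genome)
  expect_identical(a1, a2)
  # reads away from the linearisation cut align perfectly; cut-spanning
  # reads either go unmapped or map imperfectly, never with positive score
  mapped <- a1[a1$mapped, ]
  expect_gt(mean(mapped$score == 0), 0.9)
  expect_true(all(mapped$score <= 0))
  expect_true(all(mapped$ref_start >= 0 & mapped$ref_end <= 800))
  expect_equal(nrow(align_all(list(), genome)), 0L)
})

test_that("ends of alignments always consume reference (no terminal gaps)", {
  set.seed(77)
  deep <- scoring_scheme(min_score = -1000L)
  for (rep in 1:20) {
    ref <- random_dna(60)
    st <- sample(40, 1)
    read <- substr(ref, st, st + 11)
    # mutate or indel the read so gaps and mismatches appear
    chars <- strsplit(read, "")[[1]]
    if (rep %% 3 == 0) chars <- chars[-sample(2:11, 1)]
    if (rep %% 3 == 1) chars <- append(chars, "A", after = sample(2:10, 1))
    if (rep %% 3 == 2) chars[6] <- setdiff(c("A", "C", "G", "T"),
                                           chars[6])[1]
    read <- paste(chars, collapse = "")
    a <- align_end_to_end(q40(read), ref, deep)
    expect_true(a$mapped)
    ops <- strsplit(a$ops, "")[[1]]
    expect_true(ops[1] %in% c("M", "X"))
    expect_true(ops[length(ops)] %in% c("M", "X"))
    # read-consuming columns equal read length (end-to-end, no clipping)
    expect_equal(sum(ops != "D"), nchar(read))
    expect_equal(sum(ops != "I"), a$ref_end - a$ref_start)
  }
})
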