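---
title: "Inferring assembly circularity from junction-spanning reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring assembly circularity from junction-spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocirc)
```

## The model

A circular molecule of length $L$ sequenced with short reads and
assembled de novo yields a linear scaffold. If the assembly is truly a
full circular traversal, the assembler typically walks past the origin,
so the scaffold contains the circle plus a duplicated origin-adjacent
stretch and, often, spurious flanks. Two questions follow:

1. *Where does one traversal of the circle start and end?*
   Answered combinatorially: any k-mer near the scaffold start reappears
   one circle-length downstream. `find_duplicate_kmers()` enumerates all
   same-strand duplicated k-mer pairs at span $\ge$ `min_span`;
   `extract_circle()` keeps the longest-spanning pair (ties: smallest
   left start) and extracts `scaffold[left, right)`. The second k-mer
   copy is excluded so the candidate carries exactly one copy of every
   base and the implied junction is seamless. Only direct-strand
   duplicates are considered: the duplication produced by walking past
   the origin is on the same strand, whereas reverse-complement hits
   indicate inverted repeats, a different phenomenon. k-mers containing
   `N` never match (absence of evidence is not identity).

2. *Are the two ends really adjacent on the molecule?*
   Answered empirically, by the reads. The candidate is *flipped* —
   rotated by $\lfloor L/2 \rfloor$ so the original ends sit adjacent in
   the middle — and the original reads are re-mapped end-to-end. If the
   molecule is circular, reads that straddled the origin now align
   cleanly across the junction; if the ends do not belong together,
   no read supports the junction and the metrics collapse there.

## Alignment scoring

Reads are aligned globally in the read, locally in the reference
(no clipping), on both strands, with the conventions of end-to-end
short-read mappers:

| parameter | default | meaning |
|---|---|---|
| `mismatch_min` / `mismatch_max` | 2 / 6 | mismatch penalty scales with base quality: $2 + \lfloor 4 \cdot \min(Q,40)/40 \rfloor$ |
| `n_penalty` | 1 | any column involving `N` |
| `gap_open` / `gap_extend` | 5 / 3 | a length-$g$ gap costs $5 + 3g$ |
| `min_score` | $\lfloor -(0.6 + 0.6L_r) \rfloor$ | reads scoring below this floor are unmapped |

Scores are $\le 0$ with 0 a perfect alignment. Two semantic choices
matter:

- **No terminal gaps.** The first and last alignment columns must
  consume reference. Reads overhanging the reference ends (for a flipped
  candidate, reads spanning the *linear* ends, i.e. the mid-circle cut)
  go unmapped rather than being aligned with dangling gap penalties;
  this mirrors how end-to-end mappers treat contig boundaries and keeps
  the average score interpretable.
- **Deterministic tie-breaking.** Equal-scoring placements resolve to
  the smallest reference start, then fewest gap columns, then the
  forward strand, making every run byte-reproducible.

Candidate placements are anchored by 20-base exact seeds into a hashed
reference index and resolved by affine-gap dynamic programming over a
window of 15 extra columns around the anchored diagonal; references of
at most 2,000 bases skip seeding and use full dynamic programming. The
test suite validates the seeded/banded path against an exhaustive
enumeration of gapped placements on small cases, where the two must (and
do) agree exactly.

The pipeline equally accepts externally produced SAM (header required,
`AS:i` consumed, `MD` used to recompute scores when `AS:i` is absent and
to classify mismatch columns); metrics are computed identically from
either source.

## Coverage, connectivity and the verdict

For each reference position $i$:

- **coverage** counts mapped reads placing a read base on $i$ (deletion
  columns do not count);
- **connectivity** counts reads placing bases on $i-1$, $i$, $i+1$ with
  those three columns *consecutive in the read*. Reads starting or
  ending at $i$ are thereby excluded, as are reads gapped across it.

The gap-free requirement is deliberately stricter than merely excluding
reads that start or end at the position: it is what makes a single
spurious indel at the junction detectable. A read forced to carry a gap
at the junction supports neither flanking adjacency; for gapless
alignments the rule reduces to the start/end-exclusion phrasing. The
first and last reference positions have connectivity 0 by definition.

`summarize_circularity()` renders the verdict from a junction window
$[j - w + 1,\; j + w]$ (clipped to the interior), where $j$ is the
junction index and $w$ defaults to read length − 1 — every adjacency a
junction-spanning read could attest:

- **PASS** iff minimum junction-window connectivity $\ge$ `min_conn`
  (default 2, guarding against a single chimeric read) *and* average
  alignment score $>$ `score_floor` (default $-3.0$, the conventional
  review threshold for end-to-end scores).
- Advisory flags mark averages $\le -3$ and junction connectivity below
  25% of the profile-wide median.

Each mate of a pair is an independent read for all metrics, and the
average score is over mapped reads only.

## The permutation study

`run_permutation_study()` perturbs the *unflipped* candidate's two
50-bp end windows with per-base insertion or deletion chances (defaults
1% and 5%, 100 repetitions per condition plus one unmodified baseline),
re-flips, re-maps and re-judges each perturbed sequence, then ranks all
entries by Euclidean distance to the baseline in (similarity, mean
junction connectivity, average score), each axis standardised by the
baseline's absolute value.

One design point deserves emphasis: with independent per-base edits at
1% over 100 window positions, roughly 37% of draws would make *zero*
edits and be bit-identical to the baseline — trivially passing entries
that say nothing about sensitivity. Each iteration therefore redraws
(with a deterministically derived sub-seed) until at least one edit is
made, so every non-baseline entry is an actual perturbation;
`perturb_ends()` itself remains purely binomial. Per-iteration sub-seeds
are mixed from the study seed, so any subset of iterations is
reproducible in isolation.

## What the simulator emulates — and what it does not

`simulate_circular_genome()` draws i.i.d. bases at a target GC;
`simulate_reads()` draws fragment starts uniformly on the circle (reads
wrap the origin), reverse-complements mate 2, and applies i.i.d.
substitution errors; `build_artifact_scaffold()` reconstructs the
canonical assembler artifact: rotation, duplicated origin-adjacent
stretch, random flanks.

Base qualities are constant Q40 except at simulated errors, which
default to Q5. This down-weighting is deliberate and load-bearing: real
base callers flag most miscalls with low confidence, and quality-scaled
mismatch penalties are designed around exactly that property. If every
error carried Q40, a 0.5–1% substitution rate would push the average
alignment score to −3 … −6 and the score criterion would reject even a
perfect assembly — a regime no real library at these error rates
exhibits. Setting `error_quality = NULL` restores flat Q40 for
sensitivity analyses.

Not modelled: indel sequencing errors (an option exists but defaults to
0 to keep junction-indel signals sharp), GC/coverage bias, platform
error profiles, chimeric fragments, NUMT contamination, heteroplasmy.
Passing tests on simulated data therefore demonstrate the method's
behaviour under clean, uniform conditions; real libraries add nuisance
structure the verdict thresholds must absorb.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally; SAM's
  1-based `POS` is converted at the boundary.
- `flip()` uses offset $\lfloor L/2 \rfloor$ exactly; rotating back by
  $L - \lfloor L/2 \rfloor$ restores the input, a tested identity.
- Empty candidate sets raise a typed `NoCircularityCandidate` condition
  carrying the largest span actually found.
- Sequences shorter than 2 (flip), empty/all-`N` sequences
  (composition), reads longer than the reference (alignment) and empty
  alignment sets (summary: FAIL, "no mapped reads") are rejected or
  resolved explicitly rather than silently.
- FASTQ quality encoding is fixed at Phred+33; no autodetection, no
  silent misparse.

## Known limitations

- **Homopolymer-adjacent junctions blunt the sharp zero.** A single
  indel at the junction normally drives junction connectivity to
  exactly 0. If the junction abuts a homopolymer run, reads whose
  alignment ends exactly at the run boundary still fit gap-free and can
  keep connectivity at 1–2; the verdict still fails (below `min_conn`)
  but the collapse is not always to zero. The same mechanism lets a
  rare permutation that merely extends a homopolymer slip past the
  connectivity gate — such false positives carry measurably worse
  average scores than the baseline, which is exactly the signature the
  permutation report surfaces.
- A scaffold containing two distinct circular molecules, or unresolved
  heteroplasmy, is outside the model: one candidate per k is reported.
- Mates are aligned independently; no insert-size constraint is
  enforced, so a chimeric pair counts as two independent reads.

## Problem sizes used by the shipped tests

The acceptance-style tests run the full pipeline on a 16-kb simulated
circle (GC 0.40, 300-bp duplicated end, 200-bp flanks) with 2×100-bp
pairs at 40× and a 0.5% substitution rate, a 30× error-free re-test
after a single junction deletion, and a permutation study of 25
repetitions per condition; unit fixtures use 0.5–5-kb circles. These
sizes were chosen so the whole suite exercises every code path, seeded
and reproducible, at desk scale.
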