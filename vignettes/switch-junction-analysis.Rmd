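---
title: "Calling and analyzing class-switch recombination junctions"
author: "switchJunctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analyzing class-switch recombination junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchJunctions)
```

## The problem

Class switch recombination (CSR) replaces the immunoglobulin heavy-chain
constant region expressed by a B cell: the locus is cleaved inside two
repetitive switch (S) regions — the donor Sµ and a downstream acceptor such
as Sγ1 — and the intervening DNA is deleted. Amplicon deep sequencing of the
recombined locus yields short reads that each straddle one Sµ→Sγ joint.
Three questions are asked of such reads:

1. **Where did the locus break?** Each read implies a donor-side and an
   acceptor-side breakpoint.
2. **How was the break repaired?** The joint is *blunt* (the two ends were
   ligated flush), shows a *microhomology* (a short block of sequence
   present at both ends, the signature of alternative end joining), or
   carries an *untemplated insertion* attributable to neither reference.
3. **Do the breakpoints track AID hotspots?** Activation-induced deaminase
   (AID) initiates CSR lesions preferentially at degenerate WRCY motifs
   (W = A/T, R = A/G, Y = C/T). Whether observed breaks sit closer to WRCY
   motifs than random positions would is a test of AID involvement.

`switchJunctions` implements the full path from reads to inference, plus a
synthetic read generator with known truth so that every stage can be
verified without sequencing data.

## The junction-calling procedure

Each read is aligned locally (exact Smith–Waterman, affine gaps; match +1,
mismatch −2, gap open −4, gap extend −1) against the donor region, in both
orientations. A donor segment is *accepted* only if its identity exceeds
90% and its aligned length exceeds 40 nt — both strictly, and with gap
columns counted in the identity denominator. The read portion beyond the
accepted donor segment is then aligned against every acceptor region under
the same thresholds; the best-scoring accepted acceptor wins, with ties
broken by acceptor order in the reference file (5′→3′ locus order). Reads
with a donor segment only are germline (unrecombined or control) material
and yield no call; so do reads matching an acceptor only. This sequential
donor-then-acceptor logic means a junction is only ever reported when both
sides of a joint are independently well supported, which is what makes
non-lymphoid control samples come out empty.

### Breakpoint resolution and the donor-maximal convention

When the two ends of a joint share a k-nt block (microhomology), the
breakpoint pair is intrinsically ambiguous: k + 1 decompositions of the
read are equally consistent. The package resolves this with a declared
convention rather than a hidden one: the shared block is assigned to the
donor (*donor-maximal*), `donor_break` is the donor position of the last
donor-assigned base, `acceptor_break` the acceptor position of the first
acceptor-assigned base, and every call carries the half-open ambiguity
interval `[donor_break - mh_length, donor_break)` listing the alternative
placements. `convertBreakConvention()` re-expresses calls under the
mirror (acceptor-maximal) convention; the two differ by exactly
`mh_length` on both coordinates.

Microhomology is defined by *exact* simultaneous matching: the block must
be identical in the read, the donor continuation, and the acceptor prefix.
A mismatch anywhere breaks the block, so sequencing errors shorten
microhomologies rather than invent them. A gap of g > 0 read bases between
the two segments is an insertion; its bases are reported verbatim.

### Joint refinement under sequencing error

Raw alignment endpoints wobble when substitutions fall near the joint. The
caller therefore refines both endpoints on the alignment's majority
diagonal with a ±1/−2 running-score walk anchored on exact matches: the
donor end is the furthest position that is itself a match and attains the
running maximum, and symmetrically for the acceptor start. A substitution
inside a segment is crossed as soon as enough matches follow it; chance
homology beyond a clean joint keeps a strictly negative score and never
moves the anchor. Some error placements remain irreducibly ambiguous —
a substitution on the last donor base of a blunt joint is observationally
identical to a genuine 1-nt untemplated insertion — which is why
recovery under error is assessed against the ambiguity interval, not as
exact equality.

### Clustering

Reads sharing `(donor_break, acceptor_name, acceptor_break,
insertion_seq)` are assembled into one *cluster*, counted as a single
recombination event. All distance statistics are computed per cluster, not
per read, so PCR duplicates cannot dominate the inference.

## Motif scanning and distance statistics

`scanMotif()` indexes every occurrence of a degenerate IUPAC pattern
(default WRCY) in a reference. By default both strands are scanned — AID
attacks both strands, and a minus-strand hit means the plus strand reads
the reverse-complement motif (RGYW) — but plus-only scanning is available
since the strand convention genuinely matters for the distance scale.
Reference `N` bases never match any motif code, so degenerate reference
positions cannot create phantom hotspots (they are flagged at load time).

`nearestMotifDistance()` measures from the break base to the nearest
*motif-covered base* (not the motif start), so a break inside a motif is at
distance 0 exactly. The anchor choice is a declared convention: published
mean distances depend on it, and no single convention can be inferred from
a mean alone. Distances are 1-Lipschitz in the break position, which the
test suite exploits as a property check.

The inferential layer compares distance profiles with an approximate
permutation test: statistic `|mean(A) − mean(B)|`, labels shuffled over the
pooled values preserving group sizes (100,000 permutations by default), and
the add-one p-value estimator `(1 + #{permuted ≥ observed}) /
(1 + n_permutations)`, whose floor `1/(n_permutations+1)` is reported
rather than a misleading zero. The reference distribution for "no motif
tracking" is 4,000 breaks drawn uniformly over the donor region
(`simulateRandomBreaks()`). Structure composition between groups is
compared with Pearson's χ² (no continuity correction); all-zero categories
are dropped with a warning and the degrees of freedom reduced accordingly.
Pairwise p-values are reported raw with a Holm-adjusted column alongside —
adjustment is provided, not silently imposed.

The difference-of-means statistic is a choice: a permutation framework
admits any statistic, and a rank or full-distribution statistic would be
more sensitive to shape changes. Means match the quantity the distance
profiles summarize, and the statistic is isolated in one function should a
different one be preferred.

## The synthetic junction generator

`simulateJunctionReads()` emits 200-nt reads (the read length of the
amplicon libraries this pipeline targets), each composed of a donor
suffix-context ending at the donor break, an optional untemplated insert,
and acceptor context from the acceptor break, under a configurable
structure mix (default 0.3 blunt / 0.5 microhomology / 0.2 insertion, with
truncated-geometric 1–10 nt length distributions giving the short, few-nt
microhomologies and insertions seen at CSR joints). Donor breaks are placed
either uniformly over the eligible range or anchored on WRCY occurrences
with a Gaussian offset (`decay_sd`), emulating hotspot-focused cleavage.
Junction-free germline reads model non-lymphoid control material.
Substitution errors are applied per base at a configurable rate (default
0.5%, a plausible figure for the targeted platform; there is no public
per-run error profile to calibrate against, so this is an artifact choice).
Only substitutions are modeled: quality strings are constant placeholders
(the analysis never uses quality) and indels are out of scope by default,
so the platform's homopolymer indel behavior is one of the things passing
tests do *not* establish.

### Why emitted joints are normalized and guarded

The generator's contract is that the truth table records exactly what a
correct caller should report, under the same donor-maximal convention.
Three consequences:

* **Blunt joints do not extend**: an acceptor position whose first base
  continues the donor (or vice versa) would silently turn a "blunt" joint
  into a 1-nt microhomology; such positions are resampled.
* **Microhomology joints are realizable and maximal**: the acceptor is
  searched for genuine occurrences of the donor's junction k-mer, and
  positions where the shared block extends further on either side are
  rejected (if no position exists for a sampled k, k is resampled).
* **Insertions are untemplated in the strict sense**: every inserted base
  differs from both references at its position on their local diagonals,
  which is what "attributable to neither reference" means locally.

Additionally, a short-window score guard rejects candidate joints where
chance near-joint homology between the two references would accumulate a
non-negative ±1/−2 score just beyond the recorded breakpoint. Without this
guard, a fraction of emitted reads would admit several equally valid
decompositions and *no* caller could recover the recorded truth exactly —
the ambiguity would live in the data, not the algorithm. The guard trades a
small distortion of acceptor-side placement (donor-break placement, the
quantity the break-model statistics are computed on, is untouched) for a
well-posed truth table. Real S regions are far more repetitive than the
synthetic references, so real junction calls carry more ambiguity than
these tests exhibit; that is a property of the assay, not of the
implementation, and it is why the ambiguity interval is recorded on every
call.

Synthetic references from `simulateSwitchRegions()` reproduce the G-rich
base composition of switch regions (and hence a realistic WRCY density of
roughly one occurrence per 12 nt of sequence) but are non-repetitive random
sequences, not biological annotations; real analyses should supply the
annotated switch-region FASTA for the organism under study.

## Worked example

```{r example, eval = FALSE}
regions <- simulateSwitchRegions(seed = 1)   # or readSwitchRegions("SM1.fa", "Smu")
midx <- scanMotif(regions)                   # WRCY, both strands

cfg <- simConfig(n_reads = 500, break_model = "motif_anchored", decay_sd = 1,
                 error_rate = 0.005, seed = 1)
sim <- simulateJunctionReads(regions, cfg, motif_index = midx)

calls <- callJunctions(sim$reads, regions)
clusters <- clusterJunctions(calls)
summarizeStructures(calls)

report <- compareGroupsReport(list(WT = calls), regions, midx,
                              n_random = 4000, seed = 1)
report
```

The pipeline layer (`runSimulate()`, `runCall()`, `runAnalyze()`, and the
`inst/scripts/switchjunctions` command-line wrapper) drives the same
functions from a YAML configuration, writes TSV/JSON outputs whose headers
embed the configuration hash and seeds, and reproduces outputs
byte-identically under a fixed configuration.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; displays and TSV
  headers state the convention and 1-based inclusive positions are a `+1`
  away. This keeps interval arithmetic unambiguous while staying readable
  to molecular biologists.
* **Thresholds are strict inequalities** (identity > 0.90, length > 40 nt),
  taken literally; a 40-nt exact match is rejected. Identity counts gap
  columns in the denominator — a definition had to be pinned for
  reproducibility.
* **Threshold checking applies to the optimal alignment**: the
  highest-scoring local alignment is computed exactly and then tested
  against the floors. A sub-optimal alignment that would pass while the
  optimum fails is not searched for; with the scoring above the two
  disagree only in contrived cases.
* **Acceptor ties** go to the first acceptor in reference order, a
  deterministic and biologically sensible (5′→3′) rule.
* **Permutation p-values** use the canonical smaller-group subset size in
  every draw, making the p-value exactly invariant to label swap under a
  fixed seed; the statistic makes it exactly invariant to location shifts.
* **Random-break eligibility** is the whole donor region, the simplest
  reading of an in-silico uniform control; when primers are configured the
  amplified window can be used instead.
* **Degenerate inputs** fail loudly: an empty motif index raises an error
  from distance queries (never a silent 0 or infinity), empty groups are
  rejected by the permutation test, all-zero χ² rows are errors, and
  zero-cluster groups are excluded from report tests with an explicit note.
* **Problem sizes** used by the test-suite and acceptance checks —
  1,000-read simulations, a 4,000-break random reference, 100,000
  permutations for single tests and 999 for the repeated-run calibrations
  (1,000 null pairs; 200 discrimination runs) — were chosen to keep
  Monte-Carlo error well inside the tolerances being asserted while
  remaining desk-scale.

## Known limitations

* Single donor→acceptor joints only: no inversions, no sequential
  Sµ–Sx–Sγ multi-segment junctions, no off-locus translocations.
* No indel error model and no flow-space platform model by default.
* The caller's exactness guarantees are stated for locally unambiguous
  joints; highly repetitive references reduce every caller to interval
  answers, which is precisely what the ambiguity field communicates.
* `--threads` style parallelism is deliberately absent: the pipeline is
  single-threaded and byte-reproducible; read-level parallelism would have
  to preserve output order to keep that guarantee.
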