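# switchJunctions

Calling and statistical analysis of immunoglobulin **class-switch
recombination (CSR) junctions** from amplicon sequencing reads.

CSR deletes the DNA between two repetitive switch (S) regions of the IgH
locus — the donor Sµ and a downstream acceptor (Sγ, Sα, ...) — and ligates
the broken ends. Amplicon deep sequencing across the recombined locus yields
short reads that each straddle one Sµ→Sγ joint. This package answers, for
B-cell biologists and immunogenetics labs working with such data:

* **Where are the breakpoints?** Each read is aligned locally against the
  donor region (segments accepted at identity > 90% over > 40 nt, both
  strict), and the remainder of the read against the acceptor regions under
  the same thresholds; reads matching only one side (germline material,
  non-lymphoid controls) yield no call.
* **How was the joint repaired?** Each call is classified as *blunt*
  (flush ligation), *microhomology* (a k-nt block identical at both broken
  ends — for a joint with read `R`, donor break `b` and acceptor break `a`,
  the largest k with `R[b-k+1..b] = D[b-k+1..b] = A[a-k..a-1]`), or
  *untemplated insertion*. Breakpoints follow a declared donor-maximal
  convention and every call carries its ambiguity interval. Identical
  junctions are assembled into clusters (one cluster = one recombination
  event).
* **Do breaks track AID hotspots?** Distances from each cluster's donor
  break to the nearest WRCY motif (W = A/T, R = A/G, Y = C/T) are compared
  between groups, and against a 4,000-break uniform random reference, with
  an approximate permutation test on `|mean(A) − mean(B)|`
  (100,000 permutations, add-one p-value). Junction-structure composition
  is compared with Pearson's χ².

A synthetic junction-read generator (`simulateJunctionReads()`) emits
200-nt reads with a ground-truth table under configurable structure mixes,
break placement models (uniform or WRCY-anchored), sequencing error rates
and germline fractions, so the whole pipeline is verifiable without
sequencing data.

## Worked example

```r
library(switchJunctions)

regions <- simulateSwitchRegions(seed = 1)  # or readSwitchRegions("SM1.fa", donor = "Smu")
midx    <- scanMotif(regions)               # WRCY, both strands

cfg <- simConfig(n_reads = 500, break_model = "motif_anchored", decay_sd = 1,
                 error_rate = 0.005, seed = 1)
sim   <- simulateJunctionReads(regions, cfg, motif_index = midx)
calls <- callJunctions(sim$reads, regions)

summarizeStructures(calls)
#> StructureSummary of 500 junctions
#>   blunt            143  (28.6%)
#>   microhomology    248  (49.6%)
#>   insertion        109  (21.8%)
#>   mean microhomology length: 1.84 nt
#>   mean insertion length:     2.47 nt

compareGroupsReport(list(WT = calls), regions, midx,
                    n_random = 4000, n_permutations = 100000, seed = 1)
#> CSR junction group report
#>   WT             500 junction reads,   493 clusters, mean motif distance 0.19 nt
#>   distance permutation tests:
#>     WT vs random: |d-mean| = 4.978, p = 1e-05 (holm 1e-05)
```

Reading the output: the 500 junction-positive reads collapse into 493
unique breakpoint/insertion clusters; half the joints show short
microhomologies (mean 1.8 nt), the signature of alternative end-joining.
Because this simulation anchored breaks on WRCY motifs (Gaussian sd 1 nt),
the mean break-to-motif distance (0.19 nt) is far below that of uniformly
random breaks in the same region, and the permutation test rejects at its
add-one floor (p = 1/(100,000+1)). A uniform-break simulation is not
distinguishable from the random reference — the package's mirror of an
AID-independent break pattern.

The same analysis runs from the shell via YAML configs:

```sh
inst/scripts/switchjunctions simulate --config run.yaml
inst/scripts/switchjunctions call     --config run.yaml
inst/scripts/switchjunctions analyze  --config run.yaml
```

producing junction/cluster TSVs (0-based coordinates, convention stated in
the header, config hash and seeds embedded) and a JSON analysis report.
See `vignettes/switch-junction-analysis.Rmd` for the model, conventions and
design choices.

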