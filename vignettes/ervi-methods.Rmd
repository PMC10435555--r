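---
title: "Methods: detecting and genotyping invading endogenous retroviruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and genotyping invading endogenous retroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervi)
```

## The problem

Endogenous retroviruses (ERVs) are germline-integrated retroviral copies
inherited as host alleles. Almost all of them are evolutionary fossils, but a
small class is *actively invading* its host population right now. Such an
invader leaves three signatures that this package operationalizes:

1. **Identical LTRs.** Integration creates two identical long terminal
   repeats; they diverge independently afterwards, so 100% LTR identity marks
   a very recent insertion.
2. **Replication intactness.** An element that still produces virions keeps
   intact *gag*, *pro*, *pol* and *env* open reading frames in that order,
   an RT–RH–IN domain architecture in Pol, a transmembrane stretch in Env,
   and no premature stop codons.
3. **Insertional polymorphism.** An ongoing invasion segregates: some
   individuals carry the insertion at a locus (genotypes i/i, i/−), others
   do not (−/−).

`ervi` implements the full chain — identical-LTR scanning, intactness
filtering, junction-read genotyping, clustering of elements into viral
operational taxonomic units (vOTUs), and the downstream statistics used in
such surveys — together with a synthetic-data generator that builds complete
test worlds with known truth.

## Identical-LTR scanning

`find_identical_ltr_pairs()` is a from-scratch scanner (the module replaces a
general-purpose LTR miner for desk-scale work): shared exact k-mers
(default 20-mers) seed candidate repeat pairs, each seed is extended base by
base in both directions for as long as the two copies remain identical, and
the maximal repeat pair is kept when its length (default 100–2000 bp) and the
enclosing element span (default 1–15 kb) are in bounds. Only the similarity
threshold of 100% is supported; detecting degenerate LTR pairs is out of
scope. N never matches anything, so assembly gaps cannot fabricate identity.
Overlapping candidates from nested repeats resolve deterministically to the
longest element, ties to the leftmost.

Two consequences of exact-repeat semantics are worth stating plainly:

* **Orientation is undecidable at scan time.** Two identical direct repeats
  carry no strand information, so candidates are reported on `+` and the
  orientation is refined from the reverse-transcriptase reading frame during
  annotation.
* **A single LTR substitution only hides a pair whose flanking exact
  sub-repeats drop below the minimum LTR length.** A 400-bp LTR pair with
  one central mismatch still contains two ~200-bp identical sub-repeats,
  which a 100-bp floor will report. The synthetic divergent-LTR decoy
  therefore uses a 160-bp LTR with a mid-point substitution, whose ~80-bp
  sub-repeats fall below the floor. For real data the practical reading is:
  the scanner guarantees *no identical pair in bounds is missed*, not that
  every reported pair belongs to a fully identical LTR.

Coordinates are 1-based inclusive everywhere (the R/Bioconductor
convention), in memory and in reports; written GFF3/TSV output follows the
same convention.

`detect_tsd()` looks for the target-site duplication as the longest exact
match (default 4–20 bp) between the bases immediately flanking the element.
The search window is adjacent to the element on both sides, so a sub-window
of a longer shared duplication is itself detectable only for periodic
repeats — the brute-force enumeration in the tests makes that explicit.

`ltr_identity()` reports percent identity position-by-position for
equal-length inputs and over a global alignment (match +1, mismatch −1,
gap −2) otherwise, counted over alignment columns.

## Intactness annotation

The filter cascade asks, in order: is the element retroviral, and is it
replication-intact?

* **RT homology** (`rt_homology_search()`): every panel RT protein is
  aligned locally (BLOSUM62, affine gaps 11/1) against all six translated
  frames of the candidate interior. E-values follow the Karlin–Altschul
  formulation with the standard gapped parameters for that scoring scheme
  over the combined six-frame search space. A hit must reach e ≤ 1e-5,
  exceed 100 aa, and contain no stop codon inside the aligned block.
* **Retrovirus vs retrotransposon** (`classify_rt()`): the paper-scale
  approach (phylogenetic placement among reference RTs) is replaced by
  nearest-reference classification with a 10% ambiguity margin. This is a
  deliberate design deviation: the contract — separating the two RT
  classes — is preserved and directly testable, and the result is
  deterministic on one CPU.
* **ORF annotation** (`annotate_orfs()`): ORFs of ≥ 25 codons (first ATG
  after a stop, through the stop) in all six frames, labeled
  gag/pro/pol/env by best protein alignment against the panel gene
  references. ORFs under 60 aa are reported unlabeled without alignment —
  far below any core-gene cutoff, this only skips spurious micro-ORFs.
  Labeled assignments never overlap; conflicts resolve by alignment score.
* **Length rule**: a labeled gene passes only at ≥ 80% of the shortest
  corresponding ORF in the reference panel — the cutoff table ships with the
  panel and is user-replaceable.
* **Premature stop vs truncation**: a short gene ORF is re-diagnosed by
  in-frame read-through translation past its stop (stops rendered `X`). If
  the read-through still *matches* the gene reference over at least the
  intact minimum (matched residues, not alignment columns — a gap-bridged
  alignment of a genuinely deleted segment must not masquerade as an
  interruption), the gene body is present but interrupted:
  `premature_stop:<gene>`; otherwise `short_orf:<gene>`.
* **Domain architecture** (`check_domain_architecture()`): RT, RH and IN
  presence by ordered motif-profile matches in Pol (patterns are editable
  fixtures; `X` is a wildcard; the sequential search makes an out-of-order
  domain count as absent), and TM presence in Env by a hydrophobic-stretch
  rule: any 19-residue window with mean Kyte–Doolittle hydropathy ≥ 1.6.
  Profile matching replaces profile-HMM domain databases by design; the
  architecture *order* constraint is preserved.

Each violated rule appends a machine-readable reason code, and the verdict
is a pure function of the annotated evidence — re-running `check_intactness()`
reproduces it bit for bit.

## Junction-read genotyping

For each locus, `build_junction_queries()` extends the element by 200 bp on
each side and builds three queries: the *initial state* (the two flanks
joined with one TSD copy removed — the reconstructed pre-insertion locus) and
the 5'/3' *insertion states* (flank joined to the adjacent element end). The
junction window is `[flank_len − 10, flank_len + 10]`, i.e. positions 190–210
at the default flank; the window is kept at that published constant while the
flank length stays configurable.

A read supports a state only via a *meaningful* mapping: full-length, at
≥ 99% identity (matches over aligned columns, gaps count as mismatches),
e ≤ 1e-5, with the mapped span fully covering the junction window. Reads
shorter than the 21-bp window are skipped before alignment — they can never
be meaningful. One meaningful read suffices for presence, but raw counts are
always reported so stricter thresholds can be applied downstream. A read
meaningful on both an insertion-state and the initial-state query (possible
only under pathological query overlap) is discarded and logged; the choice is
this package's own, as the counting rule for that corner case is not
otherwise fixed.

Two mapping engines share these semantics: `map_read()` runs a full local
alignment (reporting partial mappings too), while presence counting uses a
C-level mismatch matcher for full-length hits only — at 99% identity a
full-length mapping admits at most `floor(L/100)` substitutions, and gapped
full-length mappings are not considered there (the simulator's error model
is substitution-only; an indel-bearing read would simply not count, which is
conservative).

Diploid calls follow directly: insertion evidence only → i/i, empty only →
−/−, both → i/−, neither → no call. Pools yield calls only under single-state
evidence (every pooled individual then inferred homozygous); mixed-evidence
pools are recorded as pool-level heterozygosity and excluded from
individual-based frequency math, while still counted in the total-data
tally. Group frequencies use called individuals plus homozygous pools of
known size; frequencies are withheld for groups of 4 or fewer individuals
(the "IN > 4" reporting rule). Frequency tables report both the
individual-based denominator and the total-data sample count, since the two
aggregation conventions answer different questions.

## vOTU clustering

`pairwise_similarity()` emits an edge between two elements only when the
best local alignment reaches ≥ 80% coverage, ≥ 95% identity and e ≤ 1e-5.
Coverage is computed over the *shorter* sequence: a query-relative coverage
is asymmetric and can make edges depend on direction; symmetrizing is this
package's documented answer to that ambiguity.

`mcl_cluster()` is a from-scratch dense-matrix Markov clustering: weighted
adjacency (default weight identity × coverage / 10⁴; binary weights
available, and the choice is recorded in the output object) with unit
self-loops, column normalization, then alternating expansion (matrix
squaring) and inflation (entrywise power 1.4, renormalization), pruning
entries below 1e-8, until the largest entry change falls below 1e-6 or 200
iterations (then the current matrix is interpreted and flagged). Clusters
are the connected components of the limit matrix's support; nodes are
canonically ordered first, so the partition is invariant to input order and
relabeling. Only MCL is implemented; a second community-detection algorithm
is a non-goal.

`find_ortho_para()` searches each LTR with 500-bp flanks against whole
assemblies (exact 30-mer seeds, then a full-query alignment in the seeded
window; a hit needs 100% query coverage at ≥ 95% identity) and labels hits
self / paralog / ortholog by locus and assembly.

## Statistics

* **Richness extrapolation** (`estimate_total_votus()`): the point estimate
  is closed-form rate scaling — mean vOTU count per surveyed species
  (zeros included) times the species-pool size — bootstrapped over species
  (default 10,000 replicates) with a 95% BCa interval. The exact resampling
  design behind the corresponding published estimate is under-specified, so
  this estimator is validated against enumeration oracles and coverage
  simulations rather than against the published point value.
* **BCa** (`bca_interval()`): bias correction z₀ from the bootstrap CDF at
  the observed value (ties counted half), acceleration *a* from the
  jackknife skewness, endpoints at the adjusted quantile levels
  Φ(z₀ + (z₀ + z)/(1 − a(z₀ + z))) with type-7 quantile interpolation.
  With z₀ = a = 0 it collapses to the percentile interval, which the tests
  assert numerically. A degenerate bootstrap distribution yields a
  zero-width interval; an observed value outside the bootstrap range is an
  error (z₀ infinite).
* **Phylogenetic signal D** (`d_statistic()`): the observed sum of edgewise
  changes in nodal values (reconstructed by the contrasts-style two-pass
  weighted average, branch lengths prolonged as in standard independent-
  contrasts machinery) is standardized between two simulated nulls —
  tip-state permutation (phylogenetic randomness) and unit-rate Brownian
  motion thresholded to the observed prevalence (Brownian clumping).
  `p_gt0` is the Brownian-null upper tail at the observed sum; `p_lt1` the
  permutation-null lower tail. The published analysis delegates D to an
  external implementation; re-implementing it is a documented design
  decision, and fidelity is pinned by calibration (mean D within 0.1 of 1
  under permutation and of 0 under thresholded Brownian motion across 100
  simulated 200-tip trees), not by numeric equality with external code.
  Trees must be rooted, bifurcating, with strictly positive branch lengths
  (zero-length branches are a hard error, mirroring how such surveys
  re-sample species to avoid them); fewer than 50 tips triggers a warning
  because D then depends on prevalence and tree shape.
* **G-test** (`g_test()`): G = 2 Σ O ln(O/E) against the chi-square tail
  with (r−1)(c−1) df; Williams correction available but off by default;
  zero margins are an error.
* **Prevalence** (`prevalence_summary()`): percent to two decimals alongside
  the exact fraction.

All resampling is seed-reproducible: same seed and input, bit-identical
output; seeds are carried in every result object.

## The synthetic-data generator

The generator defines the conditions every test runs under; it emulates the
*structure* of real surveys, not their scale or noise.

* **Reference panel** (`make_reference_panel()`): six synthetic proviral
  genomes (a stand-in with the structure of a curated reference set, not
  derived from real sequence) with identical terminal LTRs of 160–400 bp and
  intact gag-pro-pol-env ORFs; every Pol embeds the bundled RT/RH/IN motifs
  in order, every Env a 19-residue hydrophobic stretch. Genomes are mutually
  unrelated random sequences, so pairwise identity stays far below 95% and
  the panel clusters into singleton vOTUs — the toy-scale analogue of the
  published observation that the criteria separate every classified
  replication-competent retrovirus. Per-gene intact-ORF cutoffs are 80% of
  the shortest panel ORF. Decoy "retrotransposon" RTs are 45%-mutated copies
  of one retroviral query: still alignable, but unambiguously nearer to
  themselves.
* **Backgrounds** (`make_background()`): uniform random DNA,
  rejection-sampled until no 20-mer repeats, so decoy LTR pairs cannot arise
  by chance. Toy scale (tens of kb, elements 5–7 kb) keeps the full
  end-to-end battery within minutes on one CPU.
* **Implants** (`implant_provirus()`): TSD duplicated to both flanks, LTR
  divergence applied as evenly spaced substitutions, disruptions
  (premature stop at 70% of a gene, 1-bp frameshift at 30%, gene deletion,
  RT-segment swap) as decoy classes for each filter rule. The element bases
  adjacent to each junction are forced to differ from the corresponding TSD
  base so that maximal exact extension recovers the true spans *exactly* —
  without this, a 1-in-4 chance per boundary of cosmetic off-by-one
  extension would make exact truth comparison flaky.
* **Populations and reads** (`simulate_population()`, `simulate_reads()`):
  Hardy–Weinberg genotypes at a chosen allele frequency; uniform-coverage
  reads per haplotype (`coverage` is per haplotype; a diploid individual
  is sequenced at twice that depth at any position) with substitution
  errors only. No indels, no quality-score model, no demography — real
  data contain all three, so passing tests demonstrate correctness of the
  calling logic, not robustness to every real-world artifact.

## Problem sizes used by the tests

The shipped suite runs scan/annotate truth recovery on three worlds,
genotyping concordance on 20 seeds × 6 individuals at 10× error-free
coverage, MCL-vs-oracle agreement on 20 random 30-node graphs, BCa against
a full 5⁵ enumeration, D calibration on 100 simulated 200-tip trees with
200 + 200 null simulations each, and bootstrap CI coverage on 100
survey-scale worlds (2004 species, ~6% invaded, reps = 2000). These sizes
are the package's chosen test conditions; the defaults of the corresponding
functions (e.g. 10,000 bootstrap replicates, 1000 null simulations) are the
analysis-scale settings.

## Known limitations

* Non-reference insertions — elements absent from the scanned assembly —
  are invisible by construction; the genotyper only interrogates loci the
  scanner found.
* The bundled search backend is a desk-scale stand-in for a production
  aligner; pre-computed tabular hits from an external engine can be
  substituted where interfaces accept them.
* Nearest-reference RT classification is only as good as the reference
  panel; sparse panels push borderline elements into `unclassified`.
* Exact-repeat scanning reports identical sub-repeats of nearly identical
  LTR pairs when those sub-repeats clear the minimum LTR length (see above).
* The D statistic treats a binary trait as continuous during nodal
  reconstruction, as the published estimator does; its p-values inherit the
  resolution of the null-simulation sizes.
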