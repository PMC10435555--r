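# ervi — discovery and population genotyping of invading endogenous retroviruses

Most endogenous retroviruses (ERVs) in vertebrate genomes are inactive
fossils. A small class is invading its host population *right now*, and such
invaders are recognizable by three signatures: the two long terminal repeats
(LTRs) flanking the provirus are still **identical** (they were created equal
at integration and diverge afterwards), the element is **replication-intact**
(*gag*-*pro*-*pol*-*env* in order, RT–RH–IN domain architecture in Pol, a
transmembrane stretch in Env, no premature stop codons), and the insertion is
**polymorphic** among individuals (genotypes i/i, i/−, −/− at the locus).

`ervi` is an R package for people who mine genome assemblies and population
sequencing data for such elements. It provides:

* **Identical-LTR scanning** — exact k-mer-seeded, maximally extended repeat
  pairs with target-site duplication (TSD) detection
  (`find_identical_ltr_pairs()`, `detect_tsd()`).
* **Intactness annotation** — six-frame RT homology search with
  Karlin–Altschul e-values, retrovirus-vs-retrotransposon classification,
  ORF labeling, the 80%-of-shortest ORF length rule, domain-architecture
  checks, and machine-readable failure codes
  (`annotate_element()`, `check_intactness()`).
* **Insertional-polymorphism genotyping** — the three junction queries per
  locus (initial state and 5'/3' insertion states; a read counts only when
  full-length mapped at ≥ 99% identity covering query positions 190–210),
  diploid and pooled genotype calls, and per-group allele/genotype
  frequencies with the IN > 4 reporting rule
  (`build_junction_queries()`, `genotype_locus()`,
  `population_frequencies()`).
* **vOTU clustering** — similarity edges at ≥ 80% coverage / ≥ 95% identity
  / e ≤ 1e-5 and a from-scratch dense-matrix Markov clustering (MCL,
  inflation 1.4), plus ortholog/paralog locus search
  (`cluster_votus()`, `find_ortho_para()`).
* **Survey statistics** — BCa bootstrap richness extrapolation
  (θ = mean per-species vOTU count × species-pool size), the
  phylogenetic-signal D statistic for binary traits
  (D = (d_obs − mean d_Brownian)/(mean d_random − mean d_Brownian), with
  permutation and Brownian-threshold nulls), the G-test of independence and
  prevalence summaries (`estimate_total_votus()`, `bca_interval()`,
  `d_statistic()`, `g_test()`, `prevalence_summary()`).
* **Synthetic test worlds** — reference panels, repeat-free backgrounds,
  provirus implants (intact or decoy), Hardy–Weinberg populations and
  sequencing reads, all pure functions of a seed with machine-readable
  truth (`make_world()`, `make_population_world()`).

See the methods vignette (`vignettes/ervi-methods.Rmd`) for the model,
parameter meanings, numerical choices and known limitations.

## Worked example

Build a synthetic world with one intact invader and a decoy set, then run
the pipeline:

```r
library(ervi)

w <- make_world(seed = 1)                       # genome + implant truth
genome <- c(chr1 = w$genome)
cand <- detect_tsd(genome, find_identical_ltr_pairs(genome))
cand[, c("contig", "start", "end", "ltr_len", "tsd_seq")]
#>   contig start   end ltr_len tsd_seq
#> 1   chr1  4005  9028     220   CCCAT
#> 2   chr1 29868 35086     280   CCCAG
#> 3   chr1 43092 48466     320   AAAGG
#> 4   chr1 56472 62000     360   GCCTC
#> 5   chr1 70006 74562     400   CTTCA
```

Five of the six implanted elements are recovered at their exact truth
coordinates; the sixth carries a single LTR substitution and is correctly
invisible to a 100%-identity scanner. Annotation passes the intact element:

```r
annotate_element(genome, cand[1, ], w$panel)
#> Element record: chr1 4005 - 9028 ( + )
#>   classification: retrovirus (RT hit panelvirus02_RT, 301 aa, e=2.3e-190)
#>   labeled ORFs: gag 294 aa; pro 148 aa; pol 658 aa; env 360 aa
#>   domains: RT+ RH+ IN+ TM+
#>   verdict: pass
```

(the decoys fail with codes such as `premature_stop:pol`, `short_orf:pol`,
`not_retroviral`, `missing_gene:env`). Genotyping a polymorphic locus in a
simulated cohort of six individuals at 10× coverage:

```r
pw <- make_population_world(seed = 2, allele_freq = 0.5, n_individuals = 6)
res <- genotype_locus(c(locus_region = pw$genome_with), pw$candidate,
                      pw$sample_reads)
res$calls[, c("sample_id", "n_ins_reads", "n_empty_reads", "genotype")]
#>   sample_id n_ins_reads n_empty_reads genotype
#> 1    ind001           0            15       --
#> 2    ind002          43             0       ii
#> 3    ind003          37             0       ii
#> 4    ind004          22            10       i-
#> 5    ind005          15             9       i-
#> 6    ind006          26             0       ii
```

Every call matches the simulated truth: `n_ins_reads` / `n_empty_reads`
count junction-spanning reads supporting the insertion and the empty locus,
and both being positive is exactly the heterozygote signature. Group
frequencies (withheld automatically for groups of ≤ 4 individuals):

```r
population_frequencies(res$calls,
                       setNames(rep("grid1", 6), res$calls$sample_id))
#>   group_id n_individuals    freq_i freq_ii  freq_het   freq_mm reported
#> 1    grid1             6 0.6666667     0.5 0.3333333 0.1666667     TRUE
```

so the estimated insertion allele frequency at this locus is 0.67
(8 of 12 sampled alleles). Finally, the toy reference panel separates into
one vOTU per genome under the clustering criteria:

```r
cluster_votus(w$panel$genomes)
#> vOTU partition (MCL, inflation 1.4): 6 clusters over 6 elements
#>   sizes: 1 1 1 1 1 1
```

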