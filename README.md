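# barcodegap

Evaluation toolkit for DNA barcoding markers, built for taxa where the
standard mitochondrial COI protocol struggles — the motivating cases being
monogenean and rhabdocoel flatworms, where universal primers amplify food
and host DNA more readily than the target and where nuclear ribosomal
markers (ITS, 18S/28S) are the practical alternative. The package answers
two questions a barcoding study has to settle:

1. **Does a candidate marker separate species?** Pairwise distances are
   split into intraspecific and interspecific sets, the *barcode gap* is
   assessed, a distance threshold is optimized, and identification success
   is scored per specimen.
2. **Are my sequences even the right organism?** Cloned amplicons are
   screened against a labeled reference panel of possible contaminants
   (host, food items, lab DNA) using a neighbour-joining tree.

## Methods in brief

**K2P distances.** Divergences are computed under the Kimura two-parameter
model with pairwise deletion of gap/ambiguous columns. With transition and
transversion proportions *P* and *Q* among compared sites,

    d = -1/2 * ln[ (1 - 2P - Q) * sqrt(1 - 2Q) ]

in substitutions/site. Saturated pairs (where the logarithm is undefined)
are carried as explicit missing values, never imputed.

**Barcode gap and best compromise threshold (BCTh).** The gap exists when
the smallest interspecific distance exceeds the largest intraspecific one.
For identification, the BCTh minimizes the total misclassification
`e_intra(t) + e_inter(t)`, where `e_intra(t)` is the fraction of
intraspecific distances above `t` and `e_inter(t)` the fraction of
interspecific distances at or below `t` — the intersection point of the two
cumulative frequency curves. The scan runs over the midpoints of the pooled
sorted distances, so the optimum of the step function is exact.

**BM / BCM identification.** Every sequence is queried against the rest in
leave-one-out fashion. *Best match* (BM) assigns the species of the nearest
sequence(s); exact ties spanning several species are *ambiguous* (the
shared-haplotype case), a nearest set excluding the truth is *incorrect*.
*Best close-match* (BCM) additionally rejects queries whose nearest match
lies beyond the threshold (*no match closer than threshold*). Singleton
species are removed first, since they cannot have a conspecific match.

**Contamination screen.** Query clones and references are placed in one K2P
neighbour-joining tree; each clone is assigned a group by (a) its nearest
reference and (b) the purity of the smallest reference-bearing clade around
it. Disagreements between the rules are flagged rather than resolved.

**Simulator.** A K2P sequence generator with a star phylogeny within and
among species (controllable intra/interspecific branch lengths,
transition/transversion ratio, singletons, shared haplotypes, deeply
diverged contaminant groups) provides data with known truth for every
analysis above.

## Worked example

```r
library(barcodegap)

aln <- simulate_alignment(n_species = 20, n_per_species = 5, seq_length = 600,
                          d_intra = 0.005, d_inter = 0.10, kappa = 2, seed = 42)
m    <- k2p_matrix(aln)
part <- partition_distances(m, species_labels(aln))
part
#> distance partition: 200 intraspecific, 4750 interspecific pairs (0 undefined excluded)

barcode_gap(part)
#> barcode gap: yes, (0.02545, 0.1553) [2.54% - 15.53%]

bcth <- best_compromise_threshold(error_curves(part))
bcth
#> BCTh = 0.0903912 (9.039%), min total error = 0
#>   zero-error plateau: (0.0254462, 0.155336)

identification_summary(m, species_labels(aln), threshold = bcth$bcth)
#> identification success over 100 queries (BCM threshold 9.039%)
#>  criterion                       category count percent
#>         BM                        correct   100     100
#>         BM                      ambiguous     0       0
#>         BM                      incorrect     0       0
#>        BCM                        correct   100     100
#>        BCM                      ambiguous     0       0
#>        BCM                      incorrect     0       0
#>        BCM no_match_closer_than_threshold     0       0
```

Every intraspecific distance (mean ≈ 2 × 0.005) sits below every
interspecific one (mean ≈ 2 × 0.105), so the gap is detected, the total
error at the BCTh is zero, and all 100 leave-one-out queries identify
correctly under both criteria. Real markers are rarely this clean: with
overlapping distributions the BCTh lands at the compromise point and the
table fills with ambiguous/incorrect/no-match counts instead.

The contamination workflow runs the same way:

```r
cs  <- simulate_contaminated_set(groups = c("Platyhelminthes", "Arthropoda",
                                            "Nematoda"),
                                 n_queries_per_group = 4, seed = 7)
scr <- run_contamination_screen(cs$alignment, "Platyhelminthes", "screen_out")
scr$report
#> contamination screen: 12 queries, 4 on-target (Platyhelminthes), ...
#>            group count
#>       Arthropoda     4
#>         Nematoda     4
#>  Platyhelminthes     4
```

`run_marker_evaluation()` bundles the whole first workflow (distance
matrix, partition, histograms, gap, threshold scan, BCTh, per-query and
summary tables) into TSV/JSON files plus a manifest.

## Documentation

The methods vignette (`vignettes/barcoding-evaluation.Rmd`) describes the
models, the tunable parameters and their defaults, the numerical choices
and the known limitations in detail.
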