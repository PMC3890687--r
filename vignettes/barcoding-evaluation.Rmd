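---
title: "Evaluating DNA barcoding markers with barcodegap"
author: "barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcoding markers with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

DNA barcoding identifies specimens by comparing a short marker sequence
against a reference library. Its core assumption is that intraspecific
divergence is small relative to interspecific divergence; when the two
distributions separate cleanly there is a *barcode gap* and any threshold
inside it identifies perfectly. In many taxa — flatworms such as
monogeneans and rhabdocoels are the motivating case — that assumption is
strained: universal COI primers underperform or amplify contaminants
(host tissue, food organisms, lab reagents), so studies fall back on
nuclear ribosomal markers and must quantify how well each candidate marker
actually separates species. This package implements that evaluation, plus
the clone-triage step needed when amplicons may not even come from the
target organism.

## Distances

All divergences are Kimura two-parameter (K2P) distances. For a sequence
pair, columns where either sequence carries a gap or an IUPAC ambiguity
code are excluded (*pairwise deletion*); among the remaining pure-base
columns, `P` is the proportion of transitions (A↔G, C↔T) and `Q` the
proportion of transversions, and

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].$$

Pairwise deletion is the default (and switchable to complete deletion)
because spacer alignments such as ITS are indel-rich; deleting every
gapped column once, for all pairs, would discard most of the signal.
Ambiguity codes are treated as missing rather than fractionally matched —
the simplest defensible contract. When `1 - 2P - Q <= 0` or
`1 - 2Q <= 0` the estimator is undefined (saturation); such pairs are
carried as explicit `NA` with a reason code, excluded from partitions and
summaries (but counted), and refused by the tree module. Explicit failure
beats silent imputation. Internally everything is substitutions/site;
human-facing tables render percent, with the unit stated in each header.

## Barcode gap and the best compromise threshold

Species labels are taken as ground truth, and every defined pair is
either intraspecific or interspecific. The gap report compares the largest
intraspecific to the smallest interspecific distance, requiring a strict
inequality. For threshold-based identification the package scans
candidate thresholds $t$ against two cumulative error curves:

* $e_{intra}(t)$, the fraction of intraspecific distances **above** $t$
  (conspecific matches that would be rejected), non-increasing;
* $e_{inter}(t)$, the fraction of interspecific distances **at or below**
  $t$ (heterospecific matches that would be admitted), non-decreasing.

The *best compromise threshold* (BCTh) minimizes
$e_{intra}(t) + e_{inter}(t)$ — graphically, the crossing point of the two
cumulative frequency curves. Both curves are step functions that change
only at observed distances, so the default candidate grid is the set of
midpoints between consecutive pooled sorted unique distances, plus one
candidate below the minimum and one above the maximum: the scan is exact
and needs no resolution parameter. The two outer candidates sit half the
pooled range beyond the extremes, which keeps the whole grid — and hence
the BCTh — equivariant under rescaling of the distances. A fixed-step grid
can be passed explicitly when replicating a published figure. At tied
optima the smallest threshold is returned (most conservative toward
flagging divergent queries) with all ties reported; when the minimum total
error is zero the full zero-error plateau is reported as well, so the
single number is never mistaken for a unique optimum.

Boundary conventions are deliberately complementary: a distance exactly
equal to the threshold still *matches* under BCM (rejection requires
strictly greater), while $e_{inter}$ counts distances $\le t$ as errors.
The sources that introduced these criteria do not pin the boundary; this
pairing makes the two BCM failure modes exhaustive and is documented here
as the package's contract.

## BM and BCM identification

Identification success is scored in leave-one-out fashion over the
reference set itself: each sequence in turn is the query, matched against
all others. *Best match* (BM) takes the species of the sequence(s) at the
minimum distance; the outcome is **correct** (nearest set is exactly the
true species), **ambiguous** (tied nearest sequences span the true species
and at least one other) or **incorrect**. *Best close-match* (BCM) first
rejects queries whose best distance exceeds the threshold — **no match
closer than threshold** — and otherwise applies BM logic; with an infinite
threshold BCM reduces to BM exactly, which the tests assert.

Ties are exact equalities of full-precision distances (an optional
tolerance exists for sensitivity analysis, default 0): the operative case
is identical haplotypes at distance zero, which is precisely how a marker
shared between two species turns all their queries ambiguous. Species
represented by one sequence are removed first — a singleton query can only
be scored against heterospecifics and would count as incorrect by
construction; when *every* species is a singleton the analysis is refused
with that explanation, and the pipeline records the rationale instead of
producing a meaningless table. Percentages are reported on the number of
queries, to two decimals.

## Neighbour-joining and the contamination screen

Tree construction is standard neighbour-joining (the `ape`
implementation), behind a wrapper that enforces this package's contracts:
matrices with undefined entries are refused with instructions to exclude
saturated pairs upstream, and negative branch-length estimates are clamped
to zero with the total deficit logged (clamping, not redistribution — the
simplest transparent rule, and clade structure is unaffected). No
bootstrap is computed. Newick output quotes labels containing reserved
characters instead of mangling them.

Clone triage formalizes what a practitioner does by eye on a reference
tree. Two rules are computed independently:

* **nearest reference**: the query takes the group of its closest panel
  sequence; exact ties across groups are `unassigned`;
* **clade membership**: every edge of the unrooted tree bipartitions the
  leaves, and the side containing the query is a "subtree around the
  query". The smallest such subtree containing at least one reference
  decides: one group among its references (and among equally small
  subtrees) assigns the query; a mixture leaves it `unassigned`. This
  smallest-subtree reading is the deterministic core of "walking outward
  from the leaf until references appear": any larger pure subtree around
  the query necessarily yields the same group, and complement-side
  bipartitions cannot outvote the local clade.

The screen report tallies groups, counts on-target clones and (when
species labels are available) distinct on-target species, and flags
queries where the two rules disagree — disagreement is evidence worth
inspecting, not noise to resolve silently. No distance or support cutoff
is imposed on top of clade membership; raw assignments are reported.
BLAST-style database search is out of scope by design: the screen works
against a user-supplied reference panel, which is also what makes it
testable.

## The simulator

`simulate_alignment()` generates data under the same K2P model the
estimator assumes: a uniform-random root, species ancestors at branch
length `d_inter` from the root, individuals at `d_intra` from their
ancestor, sites independent, base composition uniform (the K2P stationary
distribution, keeping simulator and estimator mutually consistent). For a
branch of length $d$ with transition/transversion rate ratio $\kappa$,
setting $\beta t = d/(\kappa+2)$ and $\alpha t = d\kappa/(\kappa+2)$ gives
the closed-form site-change probabilities

$$p_{tv} = \tfrac12\big(1 - e^{-4\beta t}\big), \qquad
  p_{ts} = \tfrac14 + \tfrac14 e^{-4\beta t}
           - \tfrac12 e^{-2(\alpha+\beta)t},$$

with $p_{same}$ the remainder. Feeding these expected proportions back
through the distance formula returns $d$ exactly, which both the tests and
the acceptance script verify to high precision — the estimator and the
generator are two views of one model.

Design choices, made once and kept:

* **Star phylogeny** within and among species: no coalescent variance, so
  expected distances are exactly `2*d_intra` within and
  `2*(d_inter + d_intra)` between species, and every recovery test has a
  closed-form target. The cost is realism — real gene trees have depth
  variance that erodes barcode gaps — so a clean simulated gap
  demonstrates correctness of the machinery, not that any real marker has
  a gap.
* **Shared haplotypes** come in two constructions. `"species"` (default
  for the ambiguity scenario) collapses *all* members of a species pair
  onto one haplotype, emulating a slow marker with no variation within or
  between the pair — every affected query then ties across both species
  and scores ambiguous, never incorrect. `"individual"` copies a single
  sequence into the second species, creating exactly one zero
  interspecific distance; note that under leave-one-out the two copied
  individuals then have *only* the heterospecific twin at distance zero
  and score incorrect — useful as a stress case, but not the biological
  shared-marker scenario.
* **No indel model**: gaps can be injected column-wise at a configurable
  rate purely to exercise pairwise deletion. Alignment difficulty itself
  (the practical cost of indel-rich spacers) is outside the model.
* **Contaminant groups** diverge from the root along offsets (default 0.5
  substitutions/site) chosen to be large against the within-group
  structure (`d_inter = 0.05`, `d_intra = 0.005`), the regime where a
  reference tree separates target from contaminant clades at a glance; an
  offset of zero is allowed but warned, as recovery then degenerates to
  chance.

Fixed seeds make output bit-identical, including written FASTA.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bin_width` | 0.005 subst/site | histogram bin width (0.5%); half-open bins `[kw, (k+1)w)` |
| `pairwise_deletion` | `TRUE` | per-pair exclusion of gap/ambiguous columns |
| `tie_tol` | 0 | distance tie tolerance in BM/BCM |
| `kappa` | 2 | transition/transversion rate ratio in the simulator |
| `d_intra`, `d_inter` | 0.005, 0.10 | simulator branch lengths (subst/site) |
| `threshold` (BCM) | computed BCTh | override to replicate published thresholds |

The reference simulation used by the tests and the acceptance script is
20 species × 5 sequences of 600 sites at these defaults — around the scale
of a single-marker barcoding test case, and large enough that the
intra/interspecific separation is unambiguous while the whole suite runs
in well under a minute.

## Worked run

```{r example}
aln <- simulate_alignment(n_species = 20, n_per_species = 5,
                          seq_length = 600, d_intra = 0.005, d_inter = 0.10,
                          kappa = 2, seed = 42)
m <- k2p_matrix(aln)
part <- partition_distances(m, species_labels(aln))
barcode_gap(part)
bcth <- best_compromise_threshold(error_curves(part))
bcth
identification_summary(m, species_labels(aln), threshold = bcth$bcth)
```

## Limitations

* Species labels are taken as ground truth; label error propagates
  directly into the partition and the success table.
* Only the K2P model is implemented — no other distance corrections, no
  rate heterogeneity — because the evaluation framework is defined in
  terms of K2P distances. The simulator shares the model's assumptions
  (uniform base frequencies, site independence), so simulation-based tests
  validate the machinery, not model adequacy on real data.
* No per-species ("local") barcode-gap analysis; the gap and BCTh are
  global properties of the marker.
* Multiple sequence alignment is consumed, not produced; the quality of
  upstream alignment, especially for indel-rich spacers, bounds the
  quality of everything downstream.
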