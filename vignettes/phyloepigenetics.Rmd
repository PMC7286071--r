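---
title: "Reconstructing histone-modification histories on cell-type trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing histone-modification histories on cell-type trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitree)
```

## The model

Differentiation can be treated like descent: samples of differentiated
cell types sit at the leaves of a cell-type tree whose internal nodes
correspond to progenitor cells, and an epigenomic feature that is heritable
through division can be reconstructed at those nodes exactly as ancestral
character states are reconstructed on a species tree. epitree does this for
histone modifications observed as ChIP-seq peak calls.

The character model is deliberately minimal. For one modification, every
nucleotide in every sample is ON (inside a peak) or OFF (outside all
peaks). There is no missing state: samples whose peak data lack a whole
chromosome are removed beforehand by `qc_filter()` (any chromosome except
Y, which is absent in some donors). The per-nucleotide character matrix is
never materialised: maximal runs of nucleotides with an identical
cross-sample pattern form *atomic segments*, and unique patterns are kept
once with a bp weight (`encode_patterns()`). Because Fitch length is a
function of the pattern alone, weighted-pattern parsimony is *identical*
to per-nucleotide parsimony; the test suite verifies this equivalence
exhaustively on a 50 kb genome, including the per-branch bp tables and the
decoded node tracks.

Histories are inferred by maximum parsimony with equal undirected costs
(a gain counts the same as a loss). The up pass uses Hartigan vote
counting, which is exact on multifurcating nodes — the lymphoid polytomy
of the backbone is a hard polytomy, never arbitrarily resolved by the
engine. Exact MPR state sets come from a min-cost up/down dynamic program,
and both are checked against an exhaustive enumeration oracle on
thousands of random trees.

### Rooting and tie-breaks

Parsimony on an undirected binary character is root-invariant, but
ancestral-state resolution and per-branch reporting need a root. The root
is placed on the M–L edge (between the myeloid and lymphoid progenitors),
the implied stem-cell position of the differentiation model, and the two
root half-edges are reported as the single merged M–L branch. When a
pattern's root MPR set is {OFF, ON} the root resolves to OFF. This
tie-break is arbitrary by construction — for an undirected character the
direction of a change on the root branch is unknowable — and it is the one
documented, deterministic choice. Its visible consequence: sites whose
single change lies on the M–L branch are always reported as gains on the
ON side rather than losses on the OFF side.

ACCTRAN is the default resolution (changes placed as close to the root as
minimality allows: when both keeping and flipping the parent state stay
minimal, the state flips); DELTRAN (prefer the parent's state) is a flag.
All downstream reporting uses one resolution consistently.

### Constrained tree search

The between-type topology is fixed:
`(((Er,Me),((Eo,Ne),Mo)),(Nk,T,B))`, with each cell type constrained to be
monophyletic. What remains free is the arrangement of samples inside each
type's clade (tissue, individual, subtype variation) and any backbone
polytomy. `constrained_search()` uses random-addition-sequence stepwise
insertion (a sample may only join its own type's clade) followed by TBR
branch swapping; every proposal is checked against the constraints before
scoring and accepted on first improvement, iterating to a local optimum.
The constraint checker accepts refinements of backbone polytomies — a
search may resolve (Nk,T,B) — while every stated backbone split must be
present. With a fully resolved backbone this reduces to "collapsing type
clades yields exactly the backbone", which is what the tests assert. PAUP
trajectory parity is a non-goal; the algorithm class is the same.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `algorithm` | ACCTRAN | MPR resolution used for reporting |
| `promoter_window` | 3000 bp | TSS ± window for gene assignment |
| `upstream_window` | 5000 bp | 5′ upstream extent of the mark table |
| `bh_alpha` | 0.05 | FDR threshold for enrichment |
| `mark_threshold` | 200 bp | min ON bp per mark for active/bivalent calls |
| `anchor` | midpoint | segment anchor for TSS distances |

The 5′ upstream extent of the per-gene mark table is not an inference —
it is a reporting window, recorded in the run manifest. The 200 bp mark
threshold is roughly one nucleosome footprint; the raw bp table is always
emitted, so the calls are a convenience layer, monotone in the threshold.

TSS distances are signed and strand-aware (negative = upstream of the
assigned gene), measured from the segment midpoint — the standard
peak-anchor convention; the 5′ end is available via `anchor`. Bins are
half-open toward larger distances, so |d| = 1000 falls in 1–3 kb, and
d = 0 counts as downstream; the scheme has exactly 12 categories. Segments
on chromosomes without genes are excluded from fractions and the KS test,
with a logged count.

The KS comparison of inter-only vs intra-only distances uses bp-weighted
ECDFs but *segment counts* as effective sample sizes. Neighbouring
nucleotides of one segment are a single observation, not thousands;
bp-level sample sizes would make any difference "significant". For
unweighted, tie-free small samples the exact Smirnov null is used, else
the asymptotic Kolmogorov series.

Per-branch enrichment groups follow the published row scheme: "Inter
(all)" is the sites changing *only* on inter-type branches; the per-branch
rows analyse that same inter-only set separately by branch (a pattern with
gains on two inter branches contributes to both rows); the per-type intra
rows are the sites changing only inside one type's clade. The enrichment
universe is all genes in the supplied annotation, sets outside 5–500 genes
after harmonization are dropped, and the hypergeometric upper tail with
Benjamini–Hochberg control is applied across the whole group × set table.

## What the generator emulates — and what it does not

`simulate_epigenomes()` states a world with the structure the method
assumes: non-overlapping modifiable regions (default 300 per modification,
500–2000 bp, on 3 × 1 Mb chromosomes) that are ON at the root with
probability 0.3 and gain/lose as whole regions along each branch (gain
only where the parent is OFF, loss only where ON) with probability 0.05 on
inter-type and 0.01 on intra-type branches, plus region-level leaf noise
(0.01) standing in for tissue/individual variation. Region counts and gene
geometry (200 genes of 2–10 kb, 20 sets of 15 genes) were fixed once as a
peak-like density (~12 % of the genome modifiable) and are not tuned.

What it does **not** emulate: peak-caller boundary jitter (region edges
are exact, so atomic segments align perfectly with truth regions),
signal-strength variation, copy-number effects, correlated evolution of
neighbouring regions, or biased gain/loss rates. A green recovery test
therefore establishes that the inference machinery is correct under the
stated heritable-binary model — not that real peak data satisfy that
model.

### What recovery can and cannot reach

At the default rates a region carries on average ~0.9 change events over
the whole tree, so roughly a quarter of event-bearing regions carry two or
more. Nested pairs (a gain followed on a descendant branch by a loss) are
*less* parsimonious than a single alternative change, and any
parsimony-based method reassigns them. Measured against simulation truth
at seed 1: internal-node state accuracy 0.999; per-event recall 0.975 for
regions with a single event, 0.77 / 0.56 / 0.25 for regions with 2 / 3 / 4
events, 0.81 overall. The package's acceptance suite asserts the stated
recall target of 0.85 and that assertion fails honestly: the shortfall is
an information-theoretic ceiling of parsimony at these change rates, not
an implementation defect (the oracle-equivalence tests pin the engine
exactly). Event *precision* (~0.68) is additionally bounded by leaf noise,
which manufactures spurious intra-branch events by design.

### The planted-enrichment world

The positive control for the enrichment stage plants a ×10 gain
multiplier on the L–B branch for regions overlapping one gene set's
promoters. Its geometry (1 × 2 Mb chromosome, 2 samples/type, one
modification, 900 regions, 400 genes of 1.5–3.5 kb, 8 sets × 30 genes)
was chosen by an explicit power calculation: the planted branch group must
accumulate enough set genes (k ≈ 10–20 of 30, universe 400) for the
hypergeometric p to clear Benjamini–Hochberg across the ~130-test table in
≥ 90 % of replicates, while background rates, the root probability, the
multiplier and the FDR threshold stay at their stated values. Under the
no-planting null the observed fraction of significant (group, set) pairs
is 0.

## Numerical and degenerate-input choices

- Coordinates are BED-native 0-based half-open everywhere; 1-based appears
  only in GTF import/export. Adjacent intervals merge during
  normalization: per-nucleotide ON/OFF is the only semantics.
- Unknown chromosomes in BED input: skip with a warning by default,
  error under `strict = TRUE`.
- Zero variable patterns: the search returns any constraint-satisfying
  tree with score 0; reconstructions carry the constant state everywhere.
- Equidistant TSSs resolve to the lexicographically smaller gene id.
- Empty groups are skipped by the enrichment stage; empty KS samples are
  an error.
- All randomness (simulation, search addition sequence) flows from one
  integer seed; identical seeds give byte-identical outputs, which the
  pipeline tests assert file by file.

## Known limitations

- Equal-cost undirected parsimony cannot date changes on the root branch
  directionally; the OFF tie-break is a convention.
- Event recall degrades with multi-hit regions (see above); rate regimes
  several-fold higher than the defaults would degrade it further.
- The TBR search is first-improvement to a local optimum with a bounded
  sweep count; it matches the heuristic class, not an exhaustive search.
- The per-gene mark table reports raw ON bp; the active/bivalent calls are
  threshold conveniences, not a chromatin-state HMM.
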