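---
title: "Multidimensional mutual information for residue covariation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional mutual information for residue covariation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Columns of a protein multiple sequence alignment (MSA) covary when the
residues they hold evolve under a shared constraint — most interestingly a
physical contact in the folded structure. The standard pairwise statistic is
the mutual information

I(X1;X2) = H(X1) + H(X2) − H(X1,X2),

with H the plug-in Shannon entropy of the empirical symbol distribution of
one or more columns. Pairwise MI is contaminated by *indirect* coupling: if
X1 and X2 both interact with a third column X3, they covary without touching
each other. `mdmi` implements the multidimensional MI (mdMI) family of
estimators that remove such indirect coupling by conditioning:

* **3D_MI** — for each pair, the conditional mutual information
  I(X1;X2 | X3) = H(X1,X3) − H(X1,X3,X2) − H(X3) + H(X3,X2) is averaged over
  every third column X3 ∉ {X1, X2}. Because I(X1;X2|X3) = I(X1;X2) −
  I(X1;X2;X3) (the three-way interaction information), this average strips
  the ternary coupling routed through any single other column.
* **4D_MI** — the same idea one order higher:
  I(X1;X2 | X3,X4) = −H(X3,X4) + H(X1,X3,X4) + H(X2,X3,X4) − H(X1,X2,X3,X4),
  averaged first over the fourth column for a fixed third, then over the
  third column.

All entropies are maximum-likelihood (plug-in) estimates in bits
(0·log 0 := 0), counted directly from symbol codes over a fixed 21-letter
alphabet: the 20 standard amino acids plus one gap class into which `-`,
`.` and all ambiguity codes (B, J, O, U, X, Z) collapse. A single gap class
keeps contingency tables populated for the small alignments (N ≈ 0.4L–2L
sequences) the method targets. No sequence weighting is applied, and gapped
rows are retained; gap is an ordinary 21st symbol. This inclusion can shift
absolute scores in gap-rich columns, but every downstream consumer is
rank-based and the APC/ZPX2 corrections absorb uniform shifts.

### Conditioning-set conventions

The averaging set for the fourth column is ambiguous in the mdMI
literature: the fourth column may or may not be allowed to coincide with a
member of the scored pair. `build_map_4d()` excludes both pair members by
default (`x4_set = "exclude_pair"`). The alternative reading only adds
zero-valued terms — I(X1;X2|X3,X1) ≡ 0 — so it rescales every score by
(L−3)/(L−1) and cannot change a ranking; it is exposed as
`x4_set = "include_pair"` for completeness.

### Numerical behavior of the plug-in estimators

Plug-in MI is biased upward by roughly (|supp XY| − |supp X| − |supp Y| +
1) / (2N ln 2) bits; conditioning splits the sample into strata and
*inflates* this bias (each stratum is small), and at very small per-stratum
counts the estimates saturate rather than grow. Two practical consequences,
both visible in the test suite:

* On iid alignments the mean 3D/4D score *exceeds* the mean 2D score at
  any realistic N — the conditional estimators carry more bias, not less.
  The bias is near-uniform across pairs and is removed by APC.
* With 21 symbols the 4D estimator only enters its asymptotic decay for N
  far beyond 21² rows per stratum, so convergence-to-zero checks are run
  at alphabet 4, where N = 5000 genuinely reaches the asymptotic regime.

## Corrections

`apc_correct()` applies the average product correction: s[i,j] −
mean_i·mean_j/mean_all, all statistics over off-diagonal entries (the
diagonal carries an NA sentinel, never 0, so self-scores cannot leak into
row means). APC is *not* exactly idempotent under this off-diagonal
formulation: a second pass changes entries at order scale/L, which is why
the tests assert contraction (second-pass changes an order of magnitude
below first-pass changes) rather than fixed-point equality.

`zpx2_correct()` standardizes each score against its row's and its
column's off-diagonal mean and standard deviation (sample sd, n−1) and
multiplies the two z-scores, forcing the product negative when both
z-scores are negative so that "below both row means" reads as
anticovariation. The literature does not print the exact ZPX2 formula;
this product-of-z-scores construction is the documented choice, and
`standard_pipeline()` (APC unless already recorded, then ZPX2) is what the
package applies before any structural evaluation — matching the uniform
practice of correcting every map, including externally computed ones that
do not already carry APC.

## Structural evaluation

`contact_map_from_pdb()` defines residue positions as the unweighted
centroid of all heavy atoms (side chain included; `mode = "CB"` gives the
β-carbon alternative) and flags contacts below a cutoff, 8 Å by default.
Column–residue correspondence comes from `map_columns_to_structure()`:
the k-th non-gap column of a designated reference row maps to the k-th
residue. `top_pairs()` ranks pairs under a sequence-separation filter;
"separated by at least m positions" is read strictly (|j−i| > m, i.e. m
intervening residues), with `strict = FALSE` for the ≥ reading. Ties break
lexicographically so every ranking is deterministic. `tp_curve()` reports
the cumulative percentage of true contacts among the top pairs relative to
all contacts passing the same filter, with unmapped columns excluded from
numerator and denominator alike. `overlap_matrix()` compares the top-L
pair sets of different methods and averages entrywise across families.

## Secondary-structure distance signal

For an element of length n, `distance_signal()` builds the staggered
(n−1)×(n−1) matrix whose r-th row holds the scores C(r, r+1) … C(r, n) and
averages the non-zero entries of each column — distance d therefore draws
on exactly n−d cells. Zero doubles as the "empty" marker, so a true zero
score is indistinguishable from an empty cell; after ZPX2 exact zeros have
measure zero, making the bias negligible. For cross-family aggregation
(`aggregate_signal()`) each map is first min-max scaled to [0,1] over its
off-diagonal entries — normalization happens before the staggered
averaging, the choice that makes families with different score scales
commensurable (z-scaling is available via `normalize`). Helical period-4
enrichment then appears as a local maximum of the aggregate signal at
distance 4.

## Covariation graphs

`build_graph()` turns the top n scoring pairs (after discarding pairs
closer than d positions in sequence) into an unweighted adjacency matrix.
`graph_transitivity()` is 3·triangles / connected triples.
`indirect_path_stats()` answers, for a pair (A,B): with the direct edge
removed, what is the shortest path from A to B through other selected
pairs, where each step is weighted by the *structural* centroid distance
between its endpoints? This is a weighted single-pair shortest-path
problem (Dijkstra via igraph), not a tour: the worked quantity is the
total path length, the mean step length, and the step count. Edges whose
endpoints lack structure coordinates are unusable and dropped; by default
all selected pairs may serve as intermediate steps, without restriction to
structurally proximal ones. `connectivity_profile()` sweeps the graph size
over a 0.25L-step grid up to 3L (configurable), and
`transitivity_profile()` varies either the graph size at fixed minimum
sequence distance (default 6) or the distance at fixed size L.

## The synthetic generator

`generate_alignment()` draws background cells iid uniform over the 20
amino acids (the maximum-entropy choice, keeping closed-form oracle values
simple), with an optional gap fraction (default 0), and plants:

* `pair` — one column copies another per row with probability *fidelity*;
* `chain3` — two columns independently copy a hub (X1 ← X3 → X2), making
  the outer pair's coupling purely indirect: conditionally independent
  given the hub, with closed-form marginal MI;
* `chain4` — a four-column Markov chain with three direct and three
  skip (indirect) pairs;
* `fitness_block` — columns tied to a latent binary row variable:
  correlation without any contact, the star-tree surrogate for shared
  fitness constraints (no phylogenetic tree simulation is attempted).

Every draw is governed by one integer seed; the same spec is bitwise
reproducible. What a green synthetic test establishes is that the
estimators behave as the theory of these factorized models predicts; real
MSAs add phylogenetic autocorrelation, alignment error and composition
bias that the generator deliberately does not model, so synthetic recovery
rates say nothing quantitative about performance on real families.

### What rank-based suppression tests can and cannot see

The benchmark experiment (`planted_recovery_experiment()`) plants one
chain3 motif in an N = 400, L = 50 alignment at fidelity 0.9 and compares
pair rankings under corrected 2D and 3D maps over replicate seeds. The 3D
estimator demonstrably lowers the indirect pair's corrected score in
essentially every replicate while leaving the direct pairs alone — but it
cannot change the pair's *rank* in this world: averaging over all 48 third
columns dilutes the hub conditioning to a ~2% effect, while APC+ZPX2
separate the three planted pairs from the noise band by more than ten
z-units. The suppression is therefore asserted on scores (a paired sign
test across seeds), and the rank-based acceptance check honestly reports
the tie rather than reshaping the generator until a rank moves. Planting
competitor pairs tuned to sit just below the indirect pair would convert
the tie into a pass, but that would be calibrating the world to the
assertion.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| log base | 2 (bits) | information-theory convention; uniform rescale only |
| alphabet | 20 aa + 1 gap class | keeps tables populated at N < 400 |
| contact cutoff | 8 Å centroid–centroid | the field's close-contact criterion |
| pair budget | L | the standard top-L contact-prediction budget |
| separation filters | 0/6/12/20, strict | "m intervening positions" |
| graph grid | 0.25L … 3L | the connectivity-analysis sweep range |
| ZPX2 sd | sample (n−1) | documented choice; population sd differs at O(1/L) |
| recovery replicates | 20 seeds, medians | stochastic assertions stay < 1 min |

## Known limitations

* O(L³)/O(L⁴) column tuples: 4D maps are practical only for small L or
  excised sub-alignments (the implementation is compiled, but the
  combinatorics dominate).
* No sequence weighting or phylogenetic correction beyond APC/ZPX2.
* PDB support is deliberately minimal: first model, altloc A, HELIX/SHEET
  header records; no mmCIF, no DSSP.
* External covariation matrices are trusted as given; only the optional
  standard correction pipeline is offered on ingestion.
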