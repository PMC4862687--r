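---
title: "Methods: receptor mining, classification, and expression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor mining, classification, and expression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrmine)
```

gpcrmine re-implements, as a tested workflow, the computational arc of a
genome-wide G protein-coupled receptor (GPCR) study in a flatworm with two
reproductive strains (a sexual and an asexual biotype): mine a transcriptome
for seven-transmembrane (7TM) receptors, classify them on a
force-directed similarity network, resolve families by neighbor-joining
phylogeny, screen them for sexually enriched expression with a bias-corrected
fold change, and quantify receptor activation (EC50) and transcript levels
(ΔΔCt). This vignette explains each model, the tunable parameters, the
numerical choices, and what the synthetic data do and do not establish.

## Receptor mining

`mine_receptors()` iterates four steps to a fixpoint, mirroring the recursive
discovery workflow: six-frame ORF discovery, end curation, similarity-seeded
candidate admission with a non-GPCR exclusion rule, and a 7TM topology
filter. Each round adds the receptors retained so far to the seed database,
so receptors detectable only through previously found relatives enter in
later rounds; decisions are monotone (exclusion is never revisited within a
pass), and convergence is declared when the retained set stops growing.

**ORFs and curation flags.** `find_orfs()` reports, per reading frame,
maximal ORFs from an ATG to the closing stop (or contig edge), plus the
5'-most segment as an edge-anchored ORF when it is closed by a stop — a
5'-truncated gene model. An open stretch with neither a start nor a stop is
a window, not an ORF, and is not reported. `flag_orf_ends()` encodes the
curation convention: the amino end is trusted when an in-frame stop sits
closely upstream of the ATG (the gap is capped at 90 nt by default — the
source protocol gives no number, so the window is configurable and surfaced
in `mining_params()`), the carboxyl end when the ORF ends at a stop inside
the transcript, and `orf_confident` is their conjunction. The minimum ORF
length (200 residues) is likewise a surfaced convention: full-length GPCRs
are rarely shorter, and shorter fragments cannot carry seven helices.

**Similarity search.** `search_seeds()` scores Smith–Waterman local
alignments (BLOSUM62, gap 11/1) and converts raw scores to bit scores and
E-values with the Karlin–Altschul formula, using the product of query and
database lengths as the search space. No finite-size (effective length)
correction is applied, so E-values at short lengths are mildly optimistic —
roughly a factor of a few at 200 residues; the mining admission threshold
(E ≤ 1e-4) is set with that margin in mind, and an empirical-null test in
the suite pins the observed floor. A candidate enters the pool when any
`gpcr_seed`-class hit reaches the admission threshold.

**Exclusion rule.** `exclusion_filter()` removes a candidate when at least
half of its top-50 hits are non-GPCR transmembrane proteins (ion-channel or
transporter class) at E < 1e-10 — the published rule, with the boundary
tested exactly at 25/50 versus 24/50. Ties at the top-k truncation break by
`(e_value, target_id)`.

**Topology.** `predict_topology()` is a documented hydropathy stand-in for
an HMM topology predictor: Kyte–Doolittle means in a 19-residue window
above 1.6 define TM runs, runs closer than 4 residues merge, segments are
nudged toward the canonical 21-residue helix, and orientation follows the
positive-inside rule (the loop side richer in K+R is intracellular; ties
fall inside). `topology_filter()` excludes only candidates with a
*confident* ORF that fail the 7TM / N-out / C-in architecture — incomplete
models are never rejected for missing helices they may not contain.
Manual rescue of borderline helices is out of scope by design: such
curations are provenance, not computation.

## Similarity network and convex clusters

`build_graph()` stores edges strictly more significant than the threshold
(1e-9 within-species, 1e-6 cross-species) with attraction
`-log10(p) + log10(threshold)`. `force_layout()` is a CLANS-style
force-directed scheme — the published analyses cite the tool, not its
equations, so the functional form here is the package's own: attraction
along edges proportional to weight times distance, inverse-distance
repulsion between all pairs, and a linearly cooling per-step displacement
cap, from uniform unit-cube coordinates under a fixed seed. The layout is
deterministic given `(graph, dims, iterations, seed)`, and its energy
(attraction-weighted squared edge lengths minus the log-distance repulsion
potential) relaxes over the schedule.

`extract_clusters()` applies the "attraction limit at 0.5 standard
deviation": the limit is interpreted as `sd_limit × SD` of the stored
attraction values, used as an absolute minimum attraction — the reading
consistent with a numeric attraction cutoff expressed in SD units. The
alternative reading (mean + 0.5 SD) would discard most within-family edges
whenever no weak between-family edges are stored and cannot reproduce
clean family recovery on block-structured inputs, so it was rejected; this
was a genuinely open point, as the source describes the limit only by that
phrase. Clusters are connected components of the kept-edge subgraph with at
least four members; everything else is unclustered. Convexity — the
fraction of nodes inside a cluster's 2-D convex hull that are members — is
reported, never enforced, because the published clusters were also adjusted
by hand; `apply_curation()` accepts explicit merge/split directives and
logs them. `co_cluster_label()` transfers majority family labels from
reference (e.g. human) receptors sharing a cluster, labels reference-free
clusters "phylum-specific", and records ties as "ambiguous".

## Phylogeny

`progressive_align()` is a minimal deterministic progressive aligner
(pairwise identity distances → average-linkage guide tree → sum-of-pairs
Needleman–Wunsch profile merges with a linear gap penalty); it exists to
make the pipeline self-contained at family scale, not to compete with
production aligners. `jc_distance()` applies the generalized k-state
Jukes–Cantor transform (k = 20 for protein) to mismatch fractions over
pairwise-ungapped columns (pairwise deletion — standard, and stated nowhere
in the source); saturated pairs (p ≥ (k−1)/k) take a configurable cap of 10
with a warning. `neighbor_joining()` is classic NJ with the standard
Q-matrix and branch-length formulas; a negative branch is clamped to zero
with the deficit moved to its sister so the joined pair's path length is
preserved, and Q-ties break lexicographically, making the topology
deterministic. `bootstrap_support()` resamples columns, rebuilds NJ, and
reports the percentage of replicates containing each internal bipartition
of the full-data tree. `root_with_outgroup()` verifies the outgroup is one
side of a bipartition and places the root at the midpoint of the separating
edge. Bayesian tree inference is out of scope; the phylogeny stage exports
the alignment with a run-parameter sidecar recording the settings an
external run would use.

## Expression screen

`map_reads()` counts a read toward a gene when ungapped k-mer-anchored
comparison reaches similarity ≥ 0.9 and coverage ≥ 0.9 — both inclusive,
since a stated "minimum" is attainable; multi-mapping reads go to the
best-similarity gene, with exact ties split fractionally. `rpkm()` is the
usual reads-per-kilobase-per-million scale. `fold_change()` is the log2
sexual/asexual ratio of group mean RPKM with the division-by-zero sentinel:
a zero denominator maps to log2(10,000) = 13.29, the symmetric case to its
negative, and a 0/0 ratio to `NA` (excluded downstream).

`de_test()` is a Baggerly-style weighted two-sample t-test on per-replicate
mapped proportions: replicates weigh by library size, each group's variance
is the weighted replicate variance floored by the binomial variance of the
pooled proportion, and the statistic refers to a t distribution with
Satterthwaite degrees of freedom. The upstream study used an unnamed
commercial test from the same family; the choice here is validated in the
suite against an exact label-permutation oracle. `bh_fdr()` is
Benjamini–Hochberg (via `p.adjust`), with q < 0.05 defining significance.

`fit_trend()` sorts points by log10 abundance, discards `(1−f)/2` per side
(rounded down per side, so 376 points at f = 0.75 retain exactly the middle
282), and fits ordinary least squares. Trimming is by the abscissa, not by
fold change: trimming the regressor leaves the slope estimate unbiased,
whereas trimming on the response attenuates it — this was the open
trimming-order question, decided on statistical grounds.
`normalize_fc()` applies
`log2FC − slope·log10(RPKM) + intercept`, with the published coefficients
(0.411, 2.29) as a preset and `trend_coefficients()` converting a fresh fit
into the same sign convention. In `analyze_expression()` the trend is
fitted on the significant genes (as in the source protocol) against the
maximum control RPKM, with sentinel-valued fold changes excluded from the
fit — they are placeholders, not measurements — though still normalized and
selectable. `select_enriched()` takes q < 0.05 (strict) and normalized
log2FC ≥ 2 (inclusive, i.e. ≥ 4-fold).

Two behaviours of the fitted trend are worth knowing. First, fitting only
significant genes amplifies the slope (a winner's-curse effect: at low
abundance only extreme fold changes reach significance, and the planted
bias tilts which sign survives). Second, the maximum-control-RPKM abscissa
is itself inflated by positive fold changes, adding covariance between x
and y. Both effects shrink as abundance spread and depth grow; at the
panel sizes used here they leave the fitted slope above the planted one,
which the screen tolerates — selection power and false-discovery control
are the tested guarantees, not slope recovery through the full screen.
Slope recovery is verified separately on the generator's full point set.

## Assays

`normalize_response()` is the fraction of the total calcium response
(`peptide / (peptide + Triton)`), `percent_of_max()` rescales a
concentration series so its maximum is exactly 100, and `fit_4pl()` fits
the four-parameter logistic with variable Hill slope on log10 concentration
by Levenberg–Marquardt — the exact sigmoid used by the cited fitting
software is unstated, so 4PL with variable slope is the documented default.
Initialization takes the asymptotes from the data extremes and the EC50
start from the concentration nearest half-range, with three Hill starts
(1, −1, 3) and the best-RSS convergent fit kept; the top is bounded by 1.5×
the observed maximum while the bottom floats (baselines drift).
Non-convergence returns a flagged object, never an exception, and a
`reliable` flag falls when the fitted span or slope is too small to
identify an EC50 (flat series). All replicate points are fitted jointly;
`ec50_bootstrap_ci()` adds a seeded nonparametric bootstrap over replicates
(default 1000 resamples). `delta_delta_ct()` implements relative
quantification with the asymmetric error convention: the SEM is taken over
the test-condition ΔCt replicates only, and the reported range is
`[2^−(ΔΔCt+SEM), 2^−(ΔΔCt−SEM)]`, which brackets the point estimate.

## What the generators emulate

Each generator is byte-deterministic under its seed and returns ground
truth alongside the data.

`make_transcriptome()` plants receptors built on a common 7TM scaffold
(hydrophilic tail, seven 21-residue helices from a leucine-rich pool,
K/R-charged cytoplasmic loops), multi-TM decoys (ten helices from a
disjoint hydrophobic pool with proline-rich loops, carrying a short mutated
copy of the receptor family's N-tail anchor so naive similarity searches
pick them up at moderate significance while full-length similarity points
at the non-GPCR seed class), and ORF-free background transcripts. The
completeness mix truncates 5' or 3' ends to exercise the curation flags.
Realism is motif-level, sufficient for filter-rule testing: real
transcriptomes carry paralogy gradients, chimeras, and sequencing error
that these constructions do not, so perfect mining accuracy here
demonstrates the rules fire as specified, not field performance.

`make_similarity_blocks()` draws within-family p-values log-uniform on
[1e-40, 1e-15] and between-family on [1e-8, 1], so families are planted
cleanly below the 1e-9 threshold. `make_dose_response()` evaluates the 4PL
at the published nanomolar scale (EC50 36.7 nM by default) over eight
half-log steps with additive Gaussian noise (SD 0.02 of the normalized
response, four replicates), clipped to the unit interval.

`make_counts()` emulates the 6-versus-6 biotype design: per-sample library
sizes around 33,000 reads (about 400,000 across the twelve samples),
lognormal baseline abundances spanning several decades (sdlog 2.0),
negative-binomial counts at dispersion 0.01 (clonal laboratory strains,
modest overdispersion), an abundance-correlated log2 fold-change bias with
slope 0.411 (centred on log10 expression, giving the trend normalization
structure to remove), background biological strain differences of SD 0.5
log2 on the null genes — pervasive small true differences, which is what
makes roughly two-thirds of genes significant in such comparisons — and
ten planted enrichments at exactly 8-fold. Problem sizes throughout (200
genes, 20 layout seeds, 50 screen replicates, 100 additive matrices, 20
dose-response seeds) are the package's chosen desk scale: large enough for
the statistical claims they support, small enough to run interactively.

## Known limitations

The alignment E-values lack BLAST's finite-size correction; the hydropathy
topology stand-in has no evolutionary information and misses helices an HMM
would call from weak signals (the source handled those by manual curation,
which is out of scope); the progressive aligner has no iterative
refinement; the layout is a plain force scheme without the original tool's
optimizations; and the screen's fitted trend slope is a biased estimate of
the planted bias under significance selection, as discussed above. The
qPCR error range follows the source's SEM convention and is therefore not
a confidence interval.
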