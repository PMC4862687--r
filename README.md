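# gpcrmine

Planarians (flatworms such as *Schmidtea mediterranea*) exist as a sexual
and an asexual biotype, and peptide signalling through G protein-coupled
receptors (GPCRs) governs their reproductive development. gpcrmine
re-implements, as a tested R workflow, the computational analyses such a
study runs end to end:

- **Mining** — six-frame ORF discovery with end-curation flags
  (`N-term OK` / `C-term OK` / `ORF confident`), similarity-seeded candidate
  admission, the non-GPCR exclusion rule (exclude when ≥ half of the top-50
  hits are non-GPCR transmembrane proteins at E < 1e-10), and a
  seven-transmembrane topology filter (7 helices, extracellular N-terminus,
  intracellular C-terminus, by Kyte–Doolittle hydropathy with the
  positive-inside rule), iterated to a fixpoint.
- **Classification** — an all-against-all similarity network thresholded at
  p < 1e-9 (1e-6 cross-species), a CLANS-style force-directed layout
  (~20,000 cycles), convex clusters of ≥ 4 members at an attraction limit of
  0.5 SD, and cross-species co-clustering for family labels.
- **Phylogeny** — progressive alignment, generalized Jukes–Cantor distances,
  neighbor joining with bootstrap supports, and outgroup rooting.
- **Expression screen** — read mapping at 0.9/0.9 similarity/coverage, RPKM,
  a weighted proportions test with Benjamini–Hochberg FDR, the
  division-by-zero sentinel (log2(10,000) = 13.29), the middle-75% trend-line
  normalization
  `normalized log2FC = log2FC − 0.411·log10(RPKM) + 2.29`
  (published preset; freshly fitted coefficients by default), and selection
  of sexually enriched genes (≥ 4-fold, q < 0.05).
- **Assays** — receptor-activation quantification (total-response
  normalization, percent-of-max, four-parameter logistic fit, EC50 with a
  bootstrap interval) and qPCR ΔΔCt with the asymmetric SEM error range.
- **Generators** — seeded synthetic inputs with planted ground truth for
  every stage: transcriptomes with receptor/decoy/background transcripts,
  block-structured similarity matrices, 6-vs-6 replicate count tables with
  planted 8-fold enrichment and an abundance-correlated fold-change bias,
  and sigmoidal dose-response series.

## Worked example

The `analysis/` scripts run the whole workflow over synthetic data, each
stage reading the previous stage's files under `results/`:

```sh
Rscript analysis/01_simulate.R        # inputs + ground truth
Rscript analysis/02_mine_receptors.R  # recursive receptor mining
Rscript analysis/03_cluster.R         # similarity network + convex clusters
Rscript analysis/04_phylogeny.R       # NJ tree with bootstrap supports
Rscript analysis/05_expression.R      # biotype expression screen
Rscript analysis/06_assays.R          # EC50 fit + qPCR ddCt
```

Output from a run:

```
transcriptome: 70 transcripts (12 receptors, 8 decoys)
retained 12 candidates; sensitivity 1.00, specificity 1.00
3 clusters of sizes 6, 5, 4; ARI vs planted truth: 1
168 of 200 genes significant (q < 0.05)
7 genes called sexually enriched (>= 4-fold, q < 0.05); 7 of 10 planted
  recovered, 0 false positives
EC50 34.3 nM (bootstrap 95% CI 30.6-41.3), hill 1.06
npy-8 sexual vs asexual: RQ 53.8 (range 52.1-55.6)
```

Reading: mining recovered exactly the 12 planted receptors while excluding
all 8 ion-channel-like decoys; cluster extraction reproduced the three
planted families perfectly (adjusted Rand index 1); the expression screen
called 7 of the 10 planted 8-fold genes (the misses sit at low read
counts) with no false positives; the dose-response refit recovered the
generating EC50 of 36.7 nM within the noise of a single 2%-noise series;
and the ΔΔCt example shows a ~50-fold sexual enrichment with its
asymmetric error range.

A direct call looks like:

```r
library(gpcrmine)
sim <- make_transcriptome(12, 8, 50, seed = 7)
res <- mine_receptors(sim$transcripts, sim$seeds, sim$seed_classes)
table(res$candidates$status)
#> excluded_similarity            retained
#>                   8                  12
```

## Layout

```
R/                  package code: io, orf, alignment, topology, mining,
                    network, msa, phylo, expression, assays, simulate
analysis/           numbered workflow drivers (thin, narrative)
scripts/acceptance.R
tests/testthat/     unit, property, and end-to-end acceptance tests
vignettes/          methods vignette (models, parameters, design choices)
```
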