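---
title: "Building a consensus regulatory annotation from multi-cell-type segmentations"
author: "regbuildr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a consensus regulatory annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(regbuildr))
```

## The problem

Genome segmentation algorithms (Segway, ChromHMM) reduce a battery of
epigenomic assays in one cell type to a per-base state assignment, but their
states are arbitrary, unlabeled, and different in every cell type. To present
a single genome-wide regulatory annotation, one must (i) give each state a
functional meaning, (ii) combine the per-cell-type segmentations into
consensus regions, and (iii) restore cell-type specificity as a per-region
activity call. `regbuildr` implements that consensus build: its inputs are
per-cell-type segmentation BED files, peak calls for transcription factors
(TFs) and open chromatin, and a gene annotation; its output is a set of
classified regulatory features — promoters, proximal and distal enhancers,
CTCF binding sites, unannotated TF binding sites and open chromatin — each
with a stable identifier and a binary activity call in every cell type.

## Signal model

Everything is built on genome-wide piecewise-constant functions, represented
as run-length encoded vectors (`RleList`), the natural Bioconductor container
for coverage-like signals. Unlisted bases have value exactly 0; an optional
exclusion mask marks bases removed from every numerator *and* from the genome
size $G$ used in enrichment denominators.

Two families of summary functions drive the build:

* **TF binding probability.** For TF $t$ observed in $n_t$ assays, $p_t(x)$
  is the fraction of assays with a peak covering base $x$ — an approximate
  binomial estimator of binding. Factors are combined assuming approximate
  independence,
  $$p_{TF}(x) = 1 - \prod_t \bigl(1 - p_t(x)\bigr),$$
  which dominates each $p_t$ and is bounded by their sum (Bonferroni
  bounds). Every assay supplied for a factor counts in its denominator, even
  assays from cell types where the factor never binds, and replicate assays
  are counted independently.

* **State summaries.** For segmentation state $s$, $f_s(x)$ counts the cell
  types whose segmentation puts $x$ in state $s$. Over unmasked bases the
  $f_s$ partition the cell-type count.

## Labeling states

Each state is summarized by four statistics computed over the contiguous
regions where $f_s > 0$: fold enrichment of $p_{TF}$ mass, of TSS positions
and of exonic bases (each relative to the unmasked genome mean density), and
the Pearson correlation of $f_s$ with the CTCF binding density, computed on
200 bp bin means (the segmentation resolution; partial terminal bins are
dropped). A configurable ordered decision tree maps the statistics to one of
eight labels. The shipped default is

1. CTCF correlation ≥ 0.25 → `ctcf`
2. TSS enrichment ≥ 5 → `promoter_tss`
3. TF enrichment ≥ 2 and TSS enrichment ≥ 2 → `promoter_flank`
4. TF enrichment ≥ 2 → `enhancer`
5. exon enrichment ≥ 2 → `transcribed`
6. otherwise `low_activity`

`repressed` and `heterochromatin` are reachable only through user-configured
rules: without histone-mark inputs there is no mark-free criterion that
distinguishes them, and the label assignment deliberately minimizes reliance
on specific epigenetic marks. An undefined correlation (a state constant
across bins) is treated as 0 with a warning. Labeling is a pure function of
the statistics — input order can never change a label.

## From labels to consensus regions

Only TF-binding-correlated labels produce regions (default: `promoter_tss`,
`promoter_flank`, `enhancer`, `ctcf`). Two thresholding decisions are made
against $p_{TF}$:

* **Retention.** State $s$ is kept iff some integer cutoff $k$ makes the
  regions $\{f_s > k\}$ strictly more than 2-fold enriched for $p_{TF}$.
  Since $f_s$ is integer-valued, the grid $k = 0, \dots, \max f_s - 1$ is
  exhaustive ($k = \max f_s$ gives an empty set).

* **Cutoff optimization.** For each label $l$, the retained states' summaries
  are summed, $f_l = \sum_{s \in S_l} f_s$, and with $\delta_{l,k}$ the
  indicator of $\{f_l > k\}$:
  $$Se = \frac{\int p_{TF}\,\delta_{l,k}}{\int p_{TF}}, \qquad
    Sp = \frac{\int p_{TF}\,\delta_{l,k}}{\int \delta_{l,k}}, \qquad
    F_{l,k} = \frac{2\,Se\,Sp}{Se + Sp}.$$
  The label's cutoff $k_l$ maximizes $F$ over the same integer grid by
  exhaustive search; the consensus regions of $l$ are the contiguous runs of
  $f_l > k_l$.

Numerical choices worth stating: thresholding uses exact strict comparison
(summary functions are integers, so no epsilon is needed); an empty
$\delta$ makes $Sp$ a 0/0, which we define as $(Se, Sp, F) = (0, 0, 0)$ so
the objective is total — any real region set beats it; equal $F$ ties break
toward the smallest $k$, favoring sensitivity; the retention scan and the
optimization reuse one $k$ grid.

## Merging, classification, augmentation

Label regions are merged into classified features by structural rules:
enhancer regions overlapping a promoter flank are unioned into the flank;
flank regions overlapping a promoter are unioned into the promoter, with the
absorbed bases recorded as `attached_flank_bp`; surviving flanks become
proximal enhancers, surviving enhancer regions distal enhancers. CTCF
regions are never merged into anything and may overlap any class. One case
the rules above leave open is an enhancer region overlapping a promoter with
no flank in between; we absorb it into the promoter, in the same spirit as
the stated rules, so that the non-CTCF classes are pairwise disjoint on any
input — a property the package asserts as a class invariant. Applied
repeatedly until stable, the absorptions neither create nor destroy covered
bases.

The build is then augmented: every contiguous region of $p_{TF} > 0$ sharing
no base with any feature becomes a `tf_binding_site` feature, and afterwards
every open-chromatin peak region (unioned across cell types, to keep the
output disjoint) sharing no base with any feature becomes an
`open_chromatin` feature. Overlap always means at least one shared base, and
a candidate that touches an existing feature by even 1 bp is dropped — after
augmentation every TF-binding and open-chromatin region therefore overlaps
some feature, though not necessarily base-by-base. Finally features are
sorted canonically and numbered with zero-padded 11-digit stable
identifiers; numbering restarts each run (cross-release identifier
reconciliation is out of scope).

## Cell-type activity

Each feature gets a binary activity call per cell type. Segmentation-derived
classes are active where the cell type's segmentation overlaps the feature
with a state carrying the feature's source label; promoter features accept
both `promoter_tss` and `promoter_flank` states because flanks were merged
into them. TF-binding-site features are active where any TF peak of the cell
type overlaps; open-chromatin features where an open-chromatin peak
overlaps. A cell type with missing data is reported inactive (with a
warning), matching the strictly binary vocabulary; distinguishing poised,
repressed or closed states would need richer inputs and is out of scope.

## The synthetic epigenome

Because the build has no closed-form ground truth on real data, the package
ships a deterministic generator that plants a regulatory landscape and emits
exactly the files the pipeline reads. The reference conditions, fixed once:

* 2 chromosomes × 500 kb, 8 cell types — large enough for stable
  enrichments, small enough for sub-minute tests;
* 30 promoter units (two flanks around a core, a transcribed gene body
  downstream, a TSS 150 bp into the core), 50 enhancers, 30 CTCF sites,
  placed with ≥ 500 bp separation;
* each element active in each cell type with probability 0.8 (at least one
  active cell type enforced);
* per-cell-type segment boundaries jittered uniformly ±100 bp, emulating
  boundary uncertainty at the 200 bp segmentation resolution — this is what
  makes label regions from different states overlap at unit boundaries and
  exercises the merge rules end to end;
* per-interval mislabel probability 0.01, peak miss rate 0.1, and 2
  false-positive 200 bp peaks per Mb per assay;
* 6 TFs × 2 assays (half binding promoter units including flanks, half
  binding enhancers), 2 CTCF assays, one open-chromatin assay per cell type.

The TSS offset of 150 bp exceeds the boundary jitter, so flank-state
footprints cleanly exclude TSSs: under the default tree thresholds flank
states classify by their TF enrichment (rule 4) rather than by TSS content.
Their regions then enter the build through the enhancer label and are
absorbed into promoters wherever jitter makes them overlap — the behavior
the merge rules are designed for. Each logical output (truth, each
segmentation, each assay) draws from its own seed-derived stream, so
regenerating one file never perturbs the others, and identical seeds give
byte-identical bundles.

What the generator does *not* emulate: read-level noise, peak-score
distributions, assembly gaps, correlated mislabeling, strand-asymmetric
promoters, or states that are genuine mixtures of two labels. Passing the
recovery tests therefore demonstrates the machinery is correct under the
stated noise model, not that the default thresholds are optimal on real
segmentations.

## A small worked run

```{r example}
cfg <- simulationConfig(seed = 7, nCellTypes = 4L, nChromosomes = 1L,
                        chromLength = 200000L, nPromoters = 10L,
                        nEnhancers = 15L, nCtcfSites = 10L)
bundle <- simulateBundle(cfg)
build <- suppressWarnings(runBuild(bundle$segmentations, bundle$peaks,
                                   bundle$tss, bundle$exons, bundle$layout,
                                   manifest = bundle$manifest))
build
stateLabelTable(build)[, c("state", "label", "retained")]
cutoffTable(build)
truthRecall(bundle$truth, regulatoryFeatures(build))
```

## Testing strategy and problem sizes

The unit and property tests validate every signal operation, the F-score
machinery and the cutoff search against a brute-force per-base array oracle
on hundreds of random instances with genomes of a few kb; merging
invariants (disjointness, base conservation) on randomized region sets;
region-level coverage completeness of the augmentation on random instances;
and parameter recovery plus activity accuracy on full bundles at the
reference conditions above. `scripts/acceptance.R` re-runs the worked 10 bp
cutoff-optimization instance and one full reference build from scratch and
writes the resulting recalls, activity accuracy, coverage and feature count
as JSON.

## Known limitations

* Correlations and integrals are exact at base resolution; the bin width
  only affects the Pearson statistic. Whether the original statistics were
  computed at base or 200 bp resolution is not asserted — the resolution is
  a parameter.
* The default decision-tree thresholds are declared, not fitted; real
  segmentations will usually need tuned rules via the YAML configuration.
* Feature identifiers are stable within a run, not across releases.
* No bigWig or streaming support: correctness over throughput, whole-genome
  tracks are held in memory as run-length vectors.
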