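---
title: "Methods: stratifying injured liver organoid models with liverbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying injured liver organoid models with liverbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverbench)
```

# Scope and design

`liverbench` implements the computational stages used to stratify injury
models in human liver organoids (HLOs) — steatosis and fibrosis induced by
fatty acids or TGF-β1 — across four complementary readouts:

1. single-cell RNA-seq processing: QC, normalization, highly-variable-gene
   selection, scaling, cluster-robustness metrics, marker ranking, and
   marker over-representation annotation;
2. gene-signature scoring with expression-matched control genes, including
   fibrosis/inflammation score batteries and severity ratios for disease
   signatures;
3. post-processing of receptor–ligand interaction tables (CellPhoneDB v2
   layout): counts, fractions, treatment deltas, UpSet identifier sets,
   and induced receptor–ligand pairs;
4. Sirius red histology quantification and ΔΔCt qPCR statistics.

Everything is glued together by a self-contained nonparametric statistics
module and driven end to end by seeded synthetic-data generators that emit
every input format the pipeline consumes along with per-item ground truth,
so all stages are testable offline at desk scale.

The package is a function library, not a shell tool: `run_pipeline()`
executes the demo pipeline over the synthetic fixture and
`pipeline_report()` renders its outputs; each stage is equally usable on
user data through the exported readers (`read_counts_10x()`,
`read_cpdb_tables()`, `read_rgb_image()`, `read_ct_table()`,
`read_marker_db()`, `read_signatures()`).

# Nonparametric statistics

All group comparisons are rank-based, matching standard practice for
non-normal, small-n organoid readouts.

**Mann–Whitney U** (`mann_whitney_u()`): the U statistic is reported for
the first sample. The p-value is computed by exhaustive enumeration of all
`choose(n + m, n)` assignments of the pooled midranks whenever that count
does not exceed 10^5 — this keeps small-sample p-values exact even under
ties — and otherwise by the normal approximation with tie correction and
(by default) a continuity correction. Complete ties across both samples
give p = 1.

**Kruskal–Wallis** (`kruskal_wallis()`): H with tie correction, p from the
chi-square distribution with k − 1 degrees of freedom; an all-identical
input returns H = 0, p = 1 by convention.

**Conover–Iman post hoc** (`conover_posthoc()`): pairwise t statistics on
mean ranks with pooled rank variance and the (N − 1 − H)/(N − k)
correction, two-sided p from the t distribution with N − k degrees of
freedom, optionally Bonferroni-multiplied by the number of pairs and
capped at 1. Zero rank variance (all observations identical) returns p = 1
rather than dividing by zero. The t reference is an approximation to the
permutation null; it is accurate in the moderate-p regime and, like any
asymptotic reference, relatively less accurate in the far tail.

**Per-gene marker ranking** (`wilcoxon_rank_genes()`): a tie-corrected
rank-sum z per gene (no continuity correction, the standard choice for
marker screens), two-sided p, Benjamini–Hochberg adjustment within each
group, genes sorted by z. An `exact = TRUE` mode routes p-values through
`mann_whitney_u()` for small contrasts. The log-fold-change column is
log2 of the ratio of mean `expm1` normalized expression with a 1e-9
pseudocount; the log base is a package choice (the quantity is used for
ranking and sign only).

**Enrichment** (`hypergeom_overrep()`): upper-tail hypergeometric
probability, evaluated on the log scale via `phyper`; `p.adjust(method =
"BH")` backs `benjamini_hochberg()`. Tests verify both against explicit
combinatorial sums and the literal step-up definition.

A deliberate documentation point: pairwise treatment-vs-control
differential expression is computed here on normalized log values (after
removing mitochondrial/ribosomal genes), the representation the rest of
the pipeline uses; rank tests are invariant to monotone per-cell
transformations only when size factors are equal, so this choice is stated
rather than hidden.

# Single-cell core

`count_matrix` holds cells × genes integer counts plus cell metadata
(sample, condition, replicate, doublet score) and gene flags.
Mitochondrial genes are recognized by the `MT-` prefix and ribosomal genes
by `RPS`/`RPL` (mitochondrial-ribosomal `MRP*` symbols intentionally
excluded); both rules are overridable by supplying `gene_meta`.

QC (`filter_cells_genes()`) applies the cell filters first — doublet score
below 0.5, at least 500 detected genes, mitochondrial fraction at most
20%, ribosomal fraction at most 40%, 500–30,000 total counts — and then
keeps genes detected in at least 10 *surviving* cells. The boundary is
strict where the rule says "at least": a gene seen in exactly 10 cells
stays, in 9 it does not. The `qc_report` reconciles exactly with the
output shapes, and filtering is idempotent.

Normalization (`normalize_log()`) ranks genes by total counts over the
joint dataset, flags the top 10% as highly expressed, excludes them from
every cell's size-factor sum, scales each cell so its included-gene sum
equals the median of included-gene sums (the conventional target when none
is given), and applies the natural log1p to all genes — the highly
expressed genes are excluded from size factors only, not from the output.

HVG selection (`select_hvg()`, default `n_top = 5000`) computes dispersion
(variance/mean of `expm1` values) and z-scores it within 20
equal-occupancy mean-expression bins. Rank-based bins are used rather than
equal-width value bins so that no bin degenerates to a single gene (a
singleton bin has no within-bin spread and would silently zero its gene's
normalized dispersion). Ties at the cutoff break by gene index, making the
mask deterministic. Scaling (`scale_clip()`) mean-centers each gene,
divides by its standard deviation, maps zero-variance genes to 0, and
clips values above 5.

Clustering itself is not implemented — community detection is an external
algorithm; labels come from the synthetic truth or from the user — but
`cluster_robustness()` scores candidate labelings with the mean silhouette
width and the Davies–Bouldin index (euclidean), selecting the labeling
with the best silhouette and breaking ties toward the lower
Davies–Bouldin.

# Cluster annotation

`annotate_clusters()` automates marker-list annotation: the top 200 ranked
genes of a cluster are tested against every candidate cell type with the
hypergeometric over-representation test (candidate markers intersected
with the dataset's genes; the dataset gene count is the background), and
p-values are BH-adjusted across candidates within the cluster. Among
significant candidates (adjusted p < 0.05) the label with the most
overlapping markers wins; ties break by lower adjusted p, then
lexicographically. With no significant candidate, the lowest adjusted p
wins (ties by overlap) and the decision is flagged as a fallback.
"Number of matching genes" is interpreted as the overlap between the
cluster's top-200 list and the candidate's markers — the enrichment
overlap itself — which is the only overlap the test actually measures.

The pluripotency gate: the label "Embryonic stem cells" is accepted only
if at least one of *SOX2*, *NANOG*, *POU5F1*, *KLF1* has nonzero
expression in at least one cell of the cluster; otherwise that candidate
is skipped for the next-ranked one, and the skip is recorded. The gate is
evaluated on raw nonzero expression (threshold > 0) and is configurable.

`derive_marker_sets_from_pairwise_dge()` builds marker databases from a
stage-vs-precursor fold-change table: positive-lfc genes mark each stage,
and the earliest hepatoblast stage (HB1), which has no precursor
comparison, takes the negative-lfc genes of the HB2-vs-HB1 contrast.
Zonation reference sets are truncated to the top 100 genes by fold change.
`zonation_score()` maps the six adult hepatocyte reference clusters to the
integers 0–5 along the periportal→pericentral axis.

`enforce_control_representation()` drops clusters missing any control
replicate. `merge_nonsignificant_cluster()` automates the manual merge of
unannotatable clusters with a stated criterion — nearest significantly
annotated centroid by euclidean distance over HVGs, ties to the lower
cluster index — and records provenance so users can override.
`select_early_cell()` seeds trajectory analysis with the cell maximizing
one gene among cells expressing a gate gene (e.g. highest *AFP* among
*CEBPA*+ cells), ties to the lowest cell index.

# Gene-signature scoring and severity

`score_gene_set()` is the control-matched signature score: genes are
binned by the rank of their mean expression into 25 equal-occupancy bins;
for each bin containing signature genes, `n_ctrl` control genes (default:
the signature size, following the convention of setting the control count
to the input list size) are sampled uniformly without replacement,
signature genes excluded; the per-cell score is mean signature expression
minus mean control expression. Sampling is seeded; scores with different
seeds correlate above 0.95 on the fixtures. Duplicates and absent genes
are dropped before scoring.

`cell_cycle_phase()` assigns G1 when neither the S nor the G2M score is
positive and otherwise the phase of the larger score; an exact positive
tie resolves to G1 (no convention exists; the rule is stated and tested).

`severity_ratios()` reports, per signature and treatment, the ratio of
mean scores (treatment over matched control) with a two-sided
Mann–Whitney p over all cells — overall and optionally per cell type —
with significance stars at 0.05/0.01/0.001. Raw p-values are reported by
default; an optional Bonferroni flag multiplies by the number of emitted
comparisons, since no correction convention is standard for this readout.
A zero control mean leaves the ratio flagged undefined: the ratio of means
is only a meaningful effect size when the control mean is bounded away
from zero, which for control-matched scores means the signature must be
at least moderately active in control cells.

# Interactome post-processing

Interaction tables follow the CellPhoneDB v2 text layout: paired
means/pvalues matrices over receptor–ligand pairs × all ordered
"source|target" cluster columns, self-pairs included — ten annotated
cell types address a 10 × 10 = 100 cell grid. Significance is strict
(p < 0.05; the boundary value is excluded). `count_significant()` yields
count and fraction matrices (fractions sum to 1 whenever any interaction
is significant); `fraction_delta()` subtracts control fractions from
treatment fractions, so deltas sum to zero, with positive entries labeled
"enforced" and negative "reduced". Identifiers take the form
`PAIR_CellA|CellB`; cluster names may contain spaces, `|` is the only
reserved separator, and parsing splits at the last `_` before the cluster
pair — the CellPhoneDB dialect. `interaction_id_sets()` enumerates every
exclusive region of the condition Venn for UpSet summaries, and
`induced_pairs()` returns receptor–ligand pairs gaining at least two
significant cluster-pair columns in treatment versus control (the
boundary is inclusive: a gain of exactly two qualifies, a gain of one does
not). Heatmap ordering uses average-linkage hierarchical clustering on
euclidean distances; a constant matrix keeps input order with a warning.

# Sirius red quantification

Images are 8-bit RGB with a µm-per-pixel scale. The stages mirror the
ImageJ-macro-style batch recipe:

1. `clear_artifacts()` replaces pixels dark in all three channels (below
   30/255 by default) with background white, so cleared areas fall into
   the extreme histogram bin that the auto-threshold ignores.
2. `isodata_threshold()` implements iterative intermeans on the 256-bin
   histogram, returning the first (lowest) fixed point — the ImageJ
   "Default" behavior — with the extreme bins 0 and 255 zeroed out first.
3. `tissue_mask()` thresholds the blue channel; tissue is darker than the
   near-white background, so tissue = blue ≤ threshold. `stain_mask()`
   thresholds the green channel (Sirius red absorbs green) and divides the
   threshold by the experiment-specific brightness factor (0.95 or 1.3 in
   practice; 1.0 default), making the stained area monotone non-increasing
   in the factor. The polarity of both masks is invertible by flag since
   stain optics, not the recipe text, dictate the defaults. "Divided by a
   brightness factor" is read as dividing the threshold value (the reading
   the macro's wording attaches the division to), not the pixel values.
4. `quantify()` reports, per region (whole image or 200 × 200 µm ROI
   squares, clipped at borders with the region size adjusted): stained
   pixels within tissue, percent stained per total area, percent stained
   per tissue (flagged undefined without tissue), and the stain-free share
   of the region — the non-tissue fraction, which reads out vacuolization;
   an alternative stain-free-within-tissue definition is available by
   flag. Pixel counts are conserved exactly across tilings.
5. `normalize_to_control()` expresses values as (percent of) the control
   mean, for both stain percentages and contraction-assay areas.

The synthetic image generator renders elliptical organoids with an exact
planted stain fraction, hematoxylin-like nuclei (low green, tissue-like
blue — the dark-green anchor every counterstained section has, which the
first-fixed-point threshold latches onto so that unstained sections
measure near-zero stain), vacuole holes, and near-black artifacts outside
tissue, with per-pixel truth masks.

# ΔΔCt qPCR

`collapse_and_gate()` averages technical triplicates (fewer replicates are
tolerated with a warning) and rejects any sample whose housekeeping mean
Ct is not strictly below 35 — a mean of exactly 35.0 rejects.
`ddct_fold()` computes ΔCt = target − housekeeping per sample, ΔΔCt
against the mean control ΔCt (three control biological replicates
required by default, overridable with a warning), and emits both
`fold = 2^−ΔΔCt` and `log2_fold = −ΔΔCt` under unambiguous names. By
construction the geometric mean of control folds is exactly 1, and adding
any constant to every Ct leaves folds unchanged. `group_compare()` routes
two groups to the Mann–Whitney test and three or more to Kruskal–Wallis
with Conover/Bonferroni post hoc, on fold values by default (the plotted
quantity) with a ΔCt option.

# Synthetic data: what it emulates, and what it does not

`make_count_matrix()` draws negative-binomial counts (gene means
log-normal around `base_mean`, dispersion 0.8, log-normal library-size
factors) for a panel of cell types with planted marker programs
(`marker_fold` = 4 by default), condition-dependent cell-type proportions,
count-level signature shifts, a small high-mitochondrial subpopulation,
and doublets formed by summing two random cells (simulated doublet scores
≥ 0.6 versus < 0.4 for singlets — scores are simulated, not computed,
because doublet detection is an external tool whose downstream contract is
only the score and the 0.5 cutoff). The default fixture — five samples
(three control, two treated replicates), 300 cells each, 1,200 genes with
a base mean of 2 — is sized so that simulated cells satisfy the
500-genes/500-counts QC floor the way real post-QC cells do, and generates
in about a second.

`make_signature_shift_matrix()` constructs normalized log-scale expression
directly: signature genes are co-elevated by `baseline = 1.0` in both arms
and by an additional `delta` in treated cells. The baseline emulates
injury programs being moderately active in control organoids; without it
the control-arm mean of a control-matched score sits at ~0 with arbitrary
sign and the ratio-of-means readout is undefined in practice. The additive
construction makes the expected treated-minus-control score difference
exactly `delta`.

`make_cpdb_tables()`, `make_histology_image()` and `make_ct_table()` plant
significance patterns, stain fractions and fold changes exactly (planted
p < 0.05 versus ≥ 0.05; stain pixels sampled without replacement to the
exact count; fold f realized as a −log2(f) Ct offset), so downstream
summaries can be checked against truth by construction.

None of the generators attempt transcriptome-wide realism: no ambient RNA,
batch chemistry, amplification-efficiency variation, slide-scanner optics,
or spatial autocorrelation of stain. Passing the planted-truth tests
demonstrates that the implementations compute their stated quantities
correctly, not that the thresholds would be optimal on any particular real
dataset.

# Numerical choices and problem sizes

- Exact/approximate Mann–Whitney switch at 10^5 enumerable assignments;
  continuity correction on by default.
- The isodata scan returns the first fixed point from the dark end and
  ignores bins 0 and 255; the brute-force 256-candidate scan is an oracle
  in the tests.
- All tie-breaks are total (gene index, cluster index, lexicographic
  label), so every stage is deterministic given its seed; the end-to-end
  demo is hash-identical across reruns.
- Test and acceptance problem sizes — 750–1,500 simulated cells with
  800–1,200 genes, 20 annotation seeds, 2,000 cells per scoring arm,
  twenty 256 × 256 px images, 10^5-resample permutation oracles — were
  chosen as the smallest scales at which the checked guarantees (≥ 95%
  annotation recovery, score shift within ±0.05, stain error within 2
  points) are stable, keeping the full suite under a minute.

# Known limitations

- The annotation procedure assumes marker databases with reasonably
  disjoint, expressed marker sets; heavily overlapping candidate types are
  resolved by overlap count and adjusted p only.
- Conover p-values inherit the t-reference's far-tail optimism; treat
  p-values below ~10^-3 as "very small" rather than precise.
- The stain threshold is global per image; within-slide illumination
  gradients are out of scope (the brightness factor models between-
  experiment, not within-image, variation).
- Severity ratios require a nonzero (in practice, clearly positive)
  control-arm mean; the undefined flag should be respected downstream.
- The pairwise DGE representation question (raw versus normalized input)
  is resolved in favor of normalized values and documented above.
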