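---
title: "Methods: methylation-sensed alternative splicing with methsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-sensed alternative splicing with methsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsplice)
```

methsplice implements the downstream arm of a methylation–splicing
analysis: junction-based quantification of cassette-exon inclusion,
differential-methylation calling on regions of interest, and a
cross-system direction-concordance classifier, together with a coupled
simulator that generates every input format the pipeline reads. This
vignette explains the models, the defaults, and the decisions taken
where the design was genuinely open. Nothing stated here goes beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## Gene models and coordinates

All coordinates are **0-based half-open** internally. GFF3 input
(1-based inclusive) is converted on read; BED passes through; the
SJ-tab junction dialect stores the 1-based first/last intron bases, so
a junction record `(f, l)` becomes the intron `[f − 1, l)`. Normalizing
at the boundary of the package removes the classic off-by-one drift
between formats, and a BED write/read round-trip is tested to be exact.

Exon ordinals follow **transcription order**, so "the constant exon on
the far side of the variant block" is well-defined on either strand. A
valid model has one contiguous block of variant exons with at least one
constant exon on each flank — the minimal architecture under which a
skipping junction (flank to flank) exists.

The built-in CD44-like fixture (`cd44_gene_model()`) uses compressed
coordinates: 100 bp exons, 300 bp introns. Every downstream operation
depends only on the topology (which exon abuts which junction), not on
real genomic positions, so the fixture is topological rather than
positional.

## The anchor-exon inclusion statistic

For an anchor exon *a*, a junction **abuts** an exon iff its intron
start equals the exon end (donor) or its intron end equals the exon
start (acceptor); junctions of unknown strand are matched by
coordinates alone. Junctions abutting *a* are classified by the exon at
the other boundary: variant → *inclusion*; constant on the far side of
the variant block → *skipping*; anything else (intronic far boundary,
same-side constant exon, or no anchor involvement) → *other* and is
excluded from the statistic. Junctions between two variant exons are
therefore generated by the simulator but never contribute to the
anchor percentage — the denominator is deliberately "inclusion or
skipping junctions" only.

The percentage is **read-weighted** by default: each junction
contributes its unique-read count. The alternative reading — each
detected junction contributing once — is exposed as
`inclusion_percentage(..., weight = "junctions")`, because legend-style
descriptions of "percentage of junctions" support either
interpretation; read weighting was chosen as the default since
downstream sample-level comparisons are phrased as counting *reads* of
the junctions.

The detection filter (`min_reads`, default **2**) is applied **per
sample**: a junction below the threshold in one sample is treated as
undetected in that sample only. Samples with an empty denominator are
reported `NA`, never 0 — a sample without usable junctions carries no
evidence of complete skipping.

Group comparisons use Student's *t* (paired or unpaired) or the paired
Wilcoxon signed-rank test. Signed-rank conventions: zero differences
dropped; exact null distribution up to 25 informative pairs (and only
when |differences| are tie-free, where the exact distribution is
defined); normal approximation with continuity correction otherwise.
The exact branch is verified in the tests against full enumeration of
all 2^n sign assignments. Degenerate cases are explicit: all-zero
differences give p = 1 with a warning; a zero-variance *t* gives
p = NA with a warning rather than a fabricated p-value.

## Expression-level statistics

CPM columns are scaled to 10^6 over the genes supplied; log transforms
use **pseudocount 1** (standard; avoids −∞ at zero counts).
Differential expression between matched pairs is an ordinary paired
two-tailed *t*-test on log2(CPM + 1), with a gene called up/down only
when **both** |log2FC| > 1 **and** p < 0.05. A regularized count model
(DESeq2-style) is deliberately not re-implemented here: the pipeline's
consumers of this stage are threshold calls on log-scale normalized
counts, and the paired *t* on log2-CPM is tested to be calibrated
(type-I error within [0.03, 0.07] on null negative-binomial
simulations with 6 pairs and 2000 genes).

QC filtering uses strict inequalities — a sample is excluded iff
uniquely-mapped % **< 60** or assigned % **< 10** — so samples exactly
at a threshold are kept, matching the "below threshold" phrasing the
defaults come from. Samples missing a metric are flagged
`unevaluable`, never silently kept. Expression-range selection keeps
test samples inside the closed range `[min(ref), max(ref)]` of the
control group.

## Methylation and DMR calling

MeDIP enrichment is expressed as percent of input, with zero-input
loci flagged missing. Binned coverage is normalized with **TMM** scale
factors (edgeR's implementation; 30% trim on M-values, 5% on
A-values, reference = sample whose upper-quartile count is closest to
the mean upper quartile), which the tests cross-check against an
independent implementation written from the published trimmed-mean
definition.

Per region of interest, group comparison runs on log2-CPM (TMM-scaled
effective library sizes, pseudocount 1). The default test is
**limma's moderated *t* with a mean-variance trend**. The design was
open between a plain per-ROI Welch *t* and a moderated one; at the
study conditions this package simulates (6 vs 6 samples, mean coverage
50, negative-binomial dispersion 0.1, Bonferroni over 200 regions),
the plain *t* recovers well under half of planted 4-fold depletions —
its per-ROI variance estimates at n = 6 are too noisy — while the
moderated *t* recovers ~95% at an unchanged null false-positive rate
(~0.05, inside the calibration band). Variance moderation across
regions is the field-standard answer to exactly this small-n setting,
so it is the default; `method = "t"` retains the unmoderated test.
Multiplicity uses **Bonferroni** (not BH) over the number of tested
ROIs, because the downstream concordance logic consumes family-wise
significant DMRs; significance is strict (`p_adj < alpha`). The
correction family is *all* tested ROIs in the panel — when several
genes are analyzed together, the correct family is the pooled panel,
not each gene separately.

Direction follows the project-wide sign convention: **condition A is
the perturbed/tumor group**; `log2fc = mean(A) − mean(B)`, `hypo`
means `log2fc < 0`. ROIs normally come from an external BED (peak
calls); `tile_rois()` provides fixed-width tiling (default 500 bp) for
synthetic runs, and the simulator's gene-scale bins use 100 bp so that
each variant exon occupies exactly one bin.

Locus-group comparisons (`compare_locus_groups()`) are paired
two-tailed *t*-tests across loci (pairing = locus identity) for each
cell line against a baseline, over the panel groups: all loci,
constant exons, variant region including the i10/i11/i15 introns,
variant exons only, introns only.

## Concordance classification

Events from two systems are matched within genes by shared splice-site
coordinates (`site_tolerance` default 0 — callers anchored on the same
annotation produce identical coordinates); a gene contributes at most
one pair (most shared sites, then smallest combined span). Pairs are
`same_local` (both sites match, both cassette/other), `alt_promoter`
(either side), or `different_event` (one shared site, different far
site).

For a same-local pair, DMRs within **`window` = 5000 bp** of the
splice-site span are matched per system. The window default reflects
that regulatory methylation changes sit near but not always on the
affected exon; it is configurable and the tests exercise 0 and large
windows. Category logic, with s = sign(dPSI) and m = direction of the
**nearest significant** matched DMR per system:

* no matched DMR in either system → `meDNA_absent`;
* s = m in both systems → `concordant`; s = −m in both → `opposite`;
* everything else → `uncertain`: mixed signs between systems,
  conflicting significant DMRs within one system, no significant DMR
  among the matches, or dPSI = 0.

Requiring agreement in **both** systems is the default (`require =
"both"`); an `"either"` mode assesses agreement over the systems that
have a usable DMR direction, for comparisons where one system's
methylation assay is much shallower. The conflict rule (opposite-sign
significant DMRs within one system → `uncertain`) is intentionally
conservative; the nearest-DMR rule alone would silently resolve real
ambiguity.

`tally_categories()` reports counts, the DMR-proximal fraction of
same-local events, the concordant and uncorrelated fractions of
DMR-proximal events, and additionally the concordant fraction of
*direction-decided* events (concordant + opposite). The last quantity
is the right null diagnostic: when splicing is uncoupled from
methylation but planted DMRs exist in both systems, two independent
systems produce concordant/opposite/uncertain in ratio ≈ 1:1:2 (the
mixed-sign outcomes land in `uncertain`), so the decided events — not
all proximal events — split evenly around 50%. Percentages are kept
exact, with rounded companions for report formatting.

## The simulator: what it emulates, and what it does not

`sim_config()` fixes the study conditions; the important defaults:

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 6 | samples per group |
| `depth` | 10^4 | mean anchor-junction reads/sample; percentage estimates stable to ~±1 |
| `beta` | 2 | methylation→inclusion coupling, log-odds per unit methylation |
| `baseline_logit` | 0 | inclusion log-odds at methylation 0 |
| `meth_a`, `meth_b` | 0.2, 0.8 | variant-region methylation, perturbed vs control: the 4-fold planted effect |
| `const_meth`, `intron_meth` | 0.5, 0.3 | group-invariant background levels |
| `nb_dispersion` | 0.1 | NB dispersion of depths/coverage |
| `meth_depth` | 60 | mean bin coverage at methylation 1 |
| `bin_width` | 100 bp | one bin per (compressed) exon |

The **logistic link** from methylation to inclusion is the simulator's
model, not an empirical claim: the biology it stands in for asserts a
direction (more intragenic methylation, more variant-exon inclusion),
and the logistic is the minimal monotone link with a controllable
strength β. Reads are allocated by a single multinomial per sample —
each read picks a variant exon uniformly, then includes (anchor→exon
junction) with probability π or skips (anchor→far-flank junction) —
so the expected read-weighted inclusion percentage is exactly
100·mean(π), which the convergence tests use as the analytic target.

What the simulator does **not** emulate: positional effects within
real genomic coordinates, mappability and GC bias, correlated
dispersion between neighboring bins, isoform structure beyond one
cassette block (no intron retention, no alternative 5'/3' sites), or
transcriptome-wide expression changes that confound splicing in real
tumors. Passing tests therefore demonstrate that the *statistics and
bookkeeping* behave as specified under the assumed generative model —
not that the pipeline is robust to every artifact of real sequencing
data.

`simulate_event_tables()` is bookkeeping-level: it plants one shared
event per gene with DMRs constructed to force a chosen category, and
its default composition (24/12/5/8 same-local plus 9 alternative
promoters and 5 different events, 63 genes) mirrors the curated
two-system comparison this package models, so the classifier's tally
can be checked against known totals. `run_coupled_simulation()` is
mechanism-level: two independent systems are simulated from the same
coupling and pushed through quantification, DMR calling (pooled
Bonferroni family), and classification.

## Numerical choices and degenerate inputs

* Pseudocount 1 for every log2-CPM transform.
* Exact signed-rank limited to ≤ 25 tie-free pairs; beyond that,
  normal approximation with continuity correction.
* Zero-denominator inclusion percentages, zero-input MeDIP loci and
  both-zero splicing indices are `NA` (flagged), never 0.
* Bonferroni is `min(1, m·p)`; significance strict (`<`).
* TMM errors out on all-zero samples rather than returning factors.
* Event-pair ties break on smallest combined span, making matching
  deterministic; all generators are bit-reproducible given
  `(seed, config)`, and `run_pipeline()` writes byte-identical
  artifacts for identical configs (verified via MD5 in the manifest).

## Problem sizes

The validation suite and acceptance script use sizes chosen to make
Monte-Carlo bands tight while keeping a laptop-scale footprint: null
DMR calibration averages ten replicate 200-ROI panels (2000 null
tests); planted-recovery averages five panels of 20 planted ROIs;
the end-to-end run uses 50 planted cassette genes per coupling
setting, 6 vs 6 samples, depth 10^4. The full suite runs in well
under a minute of compute.

## Known limitations

* dPSI and its confidence are consumed from external callers, never
  recomputed; the package has no LSV/posterior model of its own.
* The DMR stage tests mean shifts of normalized log-counts; it is not
  an exact count model, and very low coverage (< ~10 mean counts) will
  blunt both calibration and power.
* The concordance classifier is rule-based; it reproduces curation
  logic, not curation judgment — borderline structural calls
  (`different_event` vs `same_local` under nonzero tolerance) follow
  the site-matching rules mechanically.
* Real-coordinate workflows (peak BEDs, aligner junction tables) are
  supported through the readers, but whole-genome scale (millions of
  junctions) has not been a design target.
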