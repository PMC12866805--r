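---
title: "Methods: single-cell target profiling from competitive chemoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell target profiling from competitive chemoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepprofiler)
```

This vignette is the package's own account of its models and the design
choices behind them.  It states no empirical result that the test suite
does not itself compute.

## 1. The two-assay model

**Competitive chemoproteomics.**  A clickable drug probe enriches its
protein partners; a competition arm pre-incubated with excess free drug
suppresses enrichment of genuine targets.  Both arms are quantified on one
TMT plex, giving a protein × channel intensity table with a
probe/competition group label per channel.  We model reporter intensities
as multiplicative: a per-protein baseline times log-normal noise, with a
target-specific engagement factor acting on the probe channels.  Under
this model log-intensities are Gaussian with equal variance across
channels, which motivates two decisions made throughout:

* the per-protein test is a pooled-variance Student's t-test on **log2**
  intensities (the multiplicative model makes the log scale the
  variance-stabilizing one, and "Student's" rather than Welch matches the
  equal-variance model; `gate_params(welch = TRUE)` switches to Welch);
* the fold change is the ratio of arithmetic **group means of linear,
  median-normalized intensities**, the convention for TMT ratio reporting.

The default gate is `|FC| > 1.2` with raw `p < 0.05`.  The raw-p choice is
deliberate: a competition experiment is a screen, and the gate's other arm
(the fold-change threshold) already suppresses the small-effect calls that
dominate false positives; BH-adjusted gating is available via
`gate_params(use_adjusted_p = TRUE)` and adjusted p-values are always
reported.  The fold-change gate is two-sided by default with the direction
(`probe_enriched`) reported separately, so downstream analyses can restrict
to probe-enriched calls without re-testing.

**Cell-type integration (the STEP step).**  Counts are library-size
normalized per cell to `scale_total` (default 10^4) and `log1p`
transformed; expression is averaged per cell type (arithmetic mean over
cells); each target row is z-scored across cell types using the sample SD;
the target is assigned to the type holding the **strict** maximum.  The
"raw-scaled" row z-score is the standard scaling for cross-cell-type
heatmaps, and it is the only reading under which "highest scaled value"
can differ from a raw argmax solely in degenerate rows — which is exactly
how we treat degeneracy: exact ties (within `1e-12`) and zero-variance
rows are reported `AMBIGUOUS` rather than broken arbitrarily, because a
strict "highest" value does not exist there.

## 2. Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `fc_thresh` | 1.2 | linear FC | competition screens accept modest suppression; 20% is the conventional floor |
| `p_thresh` | 0.05 | probability | screening-stage error rate |
| `scale_total` | 10^4 | counts/cell | standard single-cell library-size target |
| `lfc_thresh` (DEG) | 0.25 | log2 | conventional single-cell DEG floor |
| `padj_thresh` (DEG) | 0.05 | probability | BH-adjusted, unlike the chemoproteomics gate — each follows its own field's convention |
| DEG pseudocount | 1 | normalized expr. | keeps `log2` finite on sparse means; configurable |
| `min_set`/`max_set` | 5 / 500 | genes | guards against trivial and uninformative terms in ORA |
| `tol` (argmax tie) | 1e-12 | scaled expr. | distinguishes numerical noise from genuine ties |

The asymmetry between the two gates (raw p for target calling, adjusted p
for DEGs) is intentional and mirrors how the two analyses are used: the
target screen is validated downstream, the DEG lists are terminal claims.

## 3. What the simulators emulate — and what they do not

`simulate_chemoproteomics` draws per-protein baselines log-uniformly over
`baseline_log10_intensity_range` (default 10^4.5–10^7.5, a realistic TMT
reporter dynamic range), multiplies by mean-one log-normal noise with
coefficient of variation `intensity_cv`, and multiplies probe channels of
planted targets by `2^planted_log2fc`.  The default CV of 0.2 is a stated
choice, not a literature-derived constant: no noise magnitude is published
for the assay this emulates, and 10–30% is the range practitioners report
for TMT reporter CVs.  The simulator does **not** model peptide-to-protein
rollup, isotope impurity, co-isolation interference, or missing channels —
so a green recovery test establishes that the *statistics* recover planted
effects under the stated noise model, not that the pipeline is robust to
MS artifacts.

`simulate_scrna` draws negative-binomial counts parameterized by
`(mean, dispersion)` with `variance = mean + mean^2/dispersion` — the
conventional scRNA-seq count model — with planted genes' means multiplied
by `fold` in their home type.  Defaults (8 kidney-like cell types, 200
cells/type, 2000 genes, mean 1, dispersion 2, fold 4) are the conditions
the recovery criteria state.  Not modeled: per-cell library-size variation
beyond NB sampling, doublets, ambient RNA, batch effects, or gene-gene
correlation.  Uniform assignment under `fold = 1` and collapse-to-chance
under label permutation are the corresponding null checks.

`simulate_gene_sets` plants exactly one term overlapping a designated
query by a configured count, all other sets drawn uniformly.  One nuance:
set sizes are drawn randomly, so the planted set's size is raised to at
least the planted overlap instead of erroring on an unlucky draw; the
overlap is validated against the *maximum* of the size range and the query
size up front.

All generators take one seed and are bit-reproducible; the pipeline
derives per-stage sub-seeds deterministically from its single seed
(`derive_seed`), so a run config plus seed fully determines every output
byte (reports contain no timestamps for the same reason).

## 4. Numerical choices

* **Hypergeometric tail** is summed in log space
  (`lchoose` + log-sum-exp), exact to enumeration at double precision.
* **Wilcoxon**: midranks; exact enumeration of all rank splits when either
  group has fewer than 8 observations *and* the enumeration is affordable
  (`choose(n, min) <= 2e5` — a budget so one tiny group paired with a huge
  one cannot explode); otherwise normal approximation with tie-corrected
  variance and continuity correction.  The exact path handles ties, which
  `stats::wilcox.test` refuses to do exactly; on tie-free data the two
  agree exactly, which is how the oracle test is framed.
* **Degenerate t-tests**: zero pooled variance with equal means returns
  `t = 0, p = 1` (an uninformative protein, not an error); with unequal
  means it returns `p = 0` with a warning, since the observed separation
  is infinitely many within-group SDs.
* **Median normalization** rescales each channel's median to the grand
  median of the input.  It is idempotent; scale invariance to a single
  channel's rescaling holds exactly only when the grand median is robust
  to that channel's values, which is the practical regime (few channels
  carry a minority of all intensities).
* **BH** is the standard step-up with `cummin` monotonicity enforcement;
  `NA` p-values pass through without counting toward the number of tests.
* Proteins with missing or non-positive intensities are dropped at table
  construction/reading with a reported count — no imputation, because any
  imputation scheme would leak into the planted-truth recovery tests.

## 5. Open design points, resolved

* *Averages on raw or normalized data?*  Not stated by the source
  analysis; default is log-normalized (averaging raw counts would let
  library size masquerade as cell-type specificity), and
  `average_by_celltype` accepts any matrix, so raw averaging is one
  argument away.
* *Targets absent from the expression matrix?*  Counted (`n_unmapped`) and
  reported, never dropped silently; the report enforces
  `assigned + ambiguous + unmapped = called`.
* *Injury score provenance?*  The underlying per-cell score is defined
  here as the mean z-score over the program's genes — an interpretation,
  since no algorithm is published for it; only the group-difference
  property is testable, and that is what the tests assert.  The
  control-bin module score used by some toolkits is out of scope.
* *Protein-to-gene identifiers* are a user problem by design: a
  two-column map table, with unmapped targets counted.  Simulated runs use
  the built-in index-pairing map.

## 6. Known limitations

* The t-test trusts the log-normal noise model; heavy-tailed channel
  outliers would inflate the null rate (no robust variant is provided).
* Cell types with very few cells give unstable means; the package warns
  below 10 cells per type but does not exclude them.
* The enrichment universe defaults to all genes of the expression matrix
  (or all quantified proteins in the chemoproteomics context).  Published
  term lists are not reproducible without the original annotation version
  and background, so enrichment output is compared only against planted
  truth.
* Assignment is winner-take-all; a target genuinely expressed in two
  types is still assigned to one (or `AMBIGUOUS` on an exact tie).  The
  scaled profile matrix is written out precisely so that such calls can be
  inspected on the heatmap rather than trusted blindly.
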