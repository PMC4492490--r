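---
title: "Methods: the copy-number dosage cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the copy-number dosage cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdosage)
```

## The scientific question

Recurrent chromosomal gains in tumours — the 13q-arm gain present in
40–60% of colorectal cancers is the motivating case — can raise the
expression of genes and miRNAs they cover through a simple dosage effect.
A dosage-driven miRNA is only biologically interesting if its
overexpression propagates: if the expression of its target genes shifts
with it. `mirdosage` implements a two-level inference that asks exactly
these two questions for every miRNA in a region of interest, and then
prioritizes the individual target genes behind a positive second-level
answer.

## The model

### The covariate-set score test

Both levels use the same statistic, a covariate-set score test in the
global-test family. For a response vector $y$ (one miRNA's expression in
$n$ samples) and a covariate matrix $X$ ($n \times m$):

$$S \;=\; \frac{\tilde y^\top X X^\top \tilde y}{m\,\hat\sigma^2},
\qquad \tilde y = y - \bar y,\quad \hat\sigma^2 = \tilde y^\top\tilde y / n .$$

Columns of $X$ are centred and, by default, scaled to unit variance so
every covariate contributes on a comparable scale
(`scale_covariates = TRUE` in `analysis_config()`). $S$ is invariant to
adding a constant to $y$, to the order of the covariate columns, and to a
joint permutation of the rows of $(y, X)$. The test asks whether the set
of covariates is jointly associated with the response — it does not fit
or report per-covariate coefficients.

The reference null is a permutation null: the entries of $y$ are permuted
$B$ times with a seeded generator and
$p = (1 + \#\{S_{perm} \ge S_{obs}\})/(B+1)$, which can never reach zero
and is bounded below by $1/(B+1)$. When $n! \le 5040$ (i.e. $n \le 7$)
all $n!$ permutations are enumerated instead and the p-value is the exact
tail fraction. A moment-matched scaled chi-square (Satterthwaite fit on
the eigenvalues of the centred covariate kernel $XX^\top/m$) is available
as `method = "asymptotic"` for speed; the permutation null remains the
default and the reference in all validation.

One deliberate seeding choice: within one run, the same seed is re-applied
for each feature's permutation draw. This makes the p-value a
deterministic function of the data for each feature — two features with
identical data receive identical p-values — at the cost of sharing one
set of permutations across features. Because features are tested
marginally and the FDR adjustment only consumes the marginal p-values,
this sharing does not bias the per-feature inference.

### Level 1 — copy number → miRNA

Segmented copy-number profiles are resampled onto a genome-wide grid of
`grid_points` (default 30,000) equally spaced positions. The grid is laid
out at constant spacing $\left(\sum_c L_c\right)/n_{points}$ along the
concatenated genome and mapped back to chromosome coordinates, which
keeps spacing uniform to within 1 bp and allocates points to chromosomes
proportionally to length. A grid cell takes the value of the segment
covering it; a cell in a gap between segments takes the nearest segment's
value on that chromosome (segmentation output should tile a chromosome,
so gaps are treated as platform artifacts, not as missing biology); a
chromosome with no segments in a sample stays missing, and samples with
missing values in a tested window are excluded from that one test.

For each miRNA, the level-1 covariate set is the grid copy-number values
inside a window of `window_bp` (default 2 Mb) **centred** on the miRNA's
genomic start, clipped to the chromosome. "A 2 Mb window around the
start" admits two readings — total width or half-width; the centred ±1 Mb
reading is the more literal one and is the default, with the half-width
alternative available by doubling `window_bp`. Clustered miRNAs with the
same start receive identical covariate sets by construction. P-values
are Benjamini–Hochberg adjusted across all tested miRNAs; the published
procedure this follows describes its adjustment as the
"Benjamini & Hochberg step-down" FDR, and the conventional step-up BH
is implemented (`stats::p.adjust`), the wording notwithstanding.

### Level 2 — consensus targets → miRNA

Each miRNA's candidate targets are the genes predicted by at least
`consensus_min_tools` (default 3) of the 4 supplied prediction catalogs.
The level-2 covariate set is the expression of those consensus genes
present in the mRNA matrix. A miRNA with no usable consensus gene is
reported *not determined* (`NA`), excluded from the level-2 FDR
denominator, and can never be selected — mirroring the "n.d." entries of
published result tables. Whether the original analysis computed this FDR
over all region miRNAs or only the determined ones is not stated in the
source material; determined-only is implemented, which is the
conservative reading of "n.d. = not tested".

### Selection and per-target prioritization

A miRNA is a candidate when both FDRs fall below `fdr_alpha` (default
0.05). For each candidate, every consensus gene is re-tested individually
(single-covariate score test) and retained when its raw p-value is
strictly below `target_p_cut` (default 0.01), with the sign of the
miRNA–target Pearson correlation attached. The threshold is applied to
raw p-values, not FDRs, because the prioritization is explicitly a
ranking within an already-selected miRNA. Published tables print
p-values rounded to three decimals, so a *printed* value of 0.010 is
indistinguishable from values just below 0.01; `filter_printed_targets()`
therefore cuts printed tables at `p_cut + 0.0005`, while the pipeline
applies a strict `<` to exact computed p-values. A correlation of exactly
zero is reported as positive by convention (and logged); it occurs with
probability zero for continuous data.

## qPCR quantification and group contrasts

`relative_expression()` implements 2^(−ΔΔCt): technical replicates are
averaged on the Ct scale (the conventional choice), ΔCt is taken against
the designated reference assay, and ΔΔCt against the arithmetic mean ΔCt
of a calibrator group (median available for outlier robustness). The
calibrator choice shifts all folds by a constant factor and cancels out
of any rank-based group comparison, which is what the package reports;
the tumour-panel default is the adenoma group. `contrast()` compares a
per-sample measurement between phenotype groups with the Mann–Whitney U
test — exact enumeration when $n_A + n_B \le 12$ with no ties, otherwise
the tie-corrected normal approximation with continuity correction —
for three designs: adenoma vs carcinoma, 13q no-gain vs gain, and the
progression contrast adenoma-without-gain vs carcinoma-with-gain.
Samples with the relevant status unknown are excluded and counted.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with the statistical structure the
cascade assumes, so that every stage is testable without external data.
Defaults mirror the motivating study setting: 125 samples; a whole-arm
13q gain in 50% of them (the middle of the reported 40–60% range) at a
log2 level of ~0.4 (the expectation for a single-copy gain in an
impure tumour sample); 14 expressed miRNAs on the 13q arm of which 3 are
planted dosage miRNAs (expression = base + 1.0 × local log2 copy number +
N(0, 0.5)); 2000 genes of which each planted miRNA represses 25% of its
20 catalog-listed targets with slope −0.7 (and 5% positively); four
prediction catalogs that each list a true listed target with sensitivity
0.8 plus 30 random decoys per miRNA; Ct values generated as
30 − expression + N(0, 0.1) against a constant reference assay; and
carcinoma histology enriched 4:1 (odds) among gained samples, mirroring
the progression narrative without claiming published estimates.
Expression is generated on a log-like additive scale so the linear
dosage and repression couplings are exact — deliberately matched to the
linear score test so that recovery failures indicate pipeline defects,
not model mismatch.

What the generator does *not* emulate: platform-specific noise and
marginal distributions of real array or sequencing data, focal or partial
gains, miRNA–miRNA co-regulation, or sequence-level target structure.
Passing recovery tests therefore demonstrates that the inference machinery
is correct under its own assumptions, not that those assumptions hold on
any particular real dataset.

## Numerical and validation choices

* Coordinates are 0-based half-open throughout (BED convention).
* Permutation tie-breaks use the "≥ observed" convention with a relative
  tolerance of $10^{-12}$, so floating-point jitter cannot flip a count.
* The gain call is inclusive at the threshold (mean log2 ≥ 0.2 → gain).
* All randomness flows from the seed in `analysis_config()` /
  `scenario_config()`; the same seed reproduces cohorts and result tables
  byte-identically.
* Validation problem sizes: the test suite checks the score statistic
  against a literal double-loop oracle ($n \le 7$, 50 instances at
  $10^{-10}$), Monte-Carlo p-values against exhaustive $n!$ enumeration,
  BH against the literal min-over-tail definition on 1000 random vectors,
  and null calibration on 1000 datasets ($n = 30$, $m = 10$, $B = 499$).
  The Monte-Carlo-vs-exact comparison uses a 3-standard-error band per
  instance; since a correct sampler leaves ~0.3% of instances outside
  that band by chance, the suite requires at least 48 of 50 instances
  inside it rather than all 50.
* The 20-seed planted-recovery benchmark runs the full cascade on the
  default 125-sample scenario with $B = 1999$ permutations — a p-value
  floor of $5 \times 10^{-4}$, two orders of magnitude below the
  selection thresholds, so the reduced permutation count cannot change a
  selection decision.

## Known limitations

* The score test assumes an exchangeable null under permutation; strong
  sample structure (batches, subtypes) would need stratified permutation,
  which is not implemented.
* No covariate adjustment (age, stage) and no mixed models.
* The grid fill policy interpolates over segment gaps; true homozygous
  regions absent from the segmentation are filled from neighbours.
* Catalog handling consumes prediction outputs as given; no seed-match or
  conservation scoring is performed.

## A minimal run

```{r example, eval = FALSE}
cfg <- analysis_config(seed = 1)
sc  <- scenario_config(seed = 1)
manifest <- run_pipeline("run1", config = cfg, scenario = sc)
report(manifest)
```
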