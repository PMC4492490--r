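# mirdosage

Copy-number dosage effects on miRNA expression and their propagation to
target genes.

## The problem

Recurrent chromosomal gains — the 13q-arm gain found in 40–60% of
colorectal cancers is the motivating case — can raise the expression of
the miRNAs they cover through simple DNA dosage. A dosage-driven miRNA
matters biologically only if its overexpression reaches its targets.
`mirdosage` is for analysts integrating three data layers over one tumour
cohort (segmented DNA copy number, miRNA expression, mRNA expression,
optionally qPCR validation panels) who want a reproducible answer to two
questions per miRNA:

1. **Is the miRNA's expression associated with its local copy number?**
2. **Is the miRNA's expression associated with the expression of its
   predicted target genes?**

## The method

Both questions are answered with a covariate-set score test (global
test). For response $y$ (one miRNA's expression, $n$ samples) and
covariates $X$ ($n \times m$):

$$S = \frac{\tilde y^\top X X^\top \tilde y}{m\,\hat\sigma^2},\qquad
\tilde y = y-\bar y,\quad \hat\sigma^2 = \tilde y^\top \tilde y/n,$$

with a seeded permutation null, $p = (1+\#\{S_{perm}\ge S_{obs}\})/(B+1)$
(exhaustive enumeration for $n \le 7$, a Satterthwaite scaled-chi-square
option for speed). At level 1 the covariates are the copy-number values
at grid positions (30,000 equally spaced genome-wide by default) within a
2 Mb window centred on the miRNA start. At level 2 they are the
expression of the miRNA's *consensus targets* — genes predicted by at
least 3 of 4 prediction catalogs. Each level is Benjamini–Hochberg
adjusted; miRNAs significant at both FDRs (< 0.05) are selected, and
their consensus genes are individually re-tested (raw p < 0.01) and
signed by the miRNA–target correlation. Companion tools cover 13q gain
calling, 2^(−ΔΔCt) qPCR quantification, and Mann–Whitney group contrasts
(adenoma vs carcinoma, gain vs no-gain, adenoma-without-gain vs
carcinoma-with-gain). A seeded synthetic-cohort generator
(`generate_cohort()`) emulates the whole setting — arm gain, dosage
miRNAs, repressed targets, prediction catalogs with decoys — so every
stage is testable offline.

## Worked example

```r
library(mirdosage)
manifest <- run_pipeline("run1",
                         config   = analysis_config(seed = 1),
                         scenario = scenario_config(seed = 1))
report(manifest)
```

which prints (abridged):

```
# Dosage-effect pipeline run

- miRNAs tested: 14
- candidate miRNAs selected (both FDR levels): 3 (mir-13q-09, mir-13q-14, mir-13q-03)
- prioritized targets: 17

Top targets:
  - mir-13q-03 -> GENE0111 (p = 0.0001, negative)
  - mir-13q-03 -> GENE0913 (p = 0.0001, negative)
  ...

Group contrasts:
  - mir-13q-09 / gain13q: p = 2.57e-07 (medians 0.833 vs 1.26)
  - mir-13q-09 / adenoma_nogain_vs_carcinoma_gain: p = 0.00167 (medians 0.887 vs 1.21)
  ...
```

The 14 simulated 13q miRNAs were tested at both levels and exactly the 3
planted dosage miRNAs were selected; their prioritized targets carry the
planted (mostly negative) association signs, and the qPCR-style relative
expression of each selected miRNA is higher in samples carrying the 13q
gain (medians 1.2–1.3 vs ≈0.9, Mann–Whitney p ≪ 0.05). Result tables
(`mirna_association.tsv`, `target_priority.tsv`, `gain_calls.tsv`,
`contrasts.tsv`, …) and a manifest with file digests are written to the
output directory; the same seed reproduces them byte-identically.

The package also bundles, as plain-text reference tables
(`reference_mirna_associations()`, `reference_mir15a_targets()`), the
published per-miRNA association summary of a 125-sample colorectal
cohort for the 14 expressed 13q miRNAs and the prioritized target list of
miR-15a, used as worked-example inputs for the selection filters: 6
miRNAs pass the copy-number FDR alone, 3 (miR-15a, miR-17, miR-20a) pass
both levels, and the miR-15a table retains 5 genes (4 negatively, 1
positively associated).

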