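# circascreen

Mammalian tissues run on essentially the same core circadian clock, yet
the share of the transcriptome that cycles with a ~24-h period ranges
from over 10% (liver) to a few percent (brainstem). `circascreen` is an R
package for the screen that asks *why*: it detects rhythmic genes in
multi-tissue expression time courses, computes each tissue's cycling
percentage, and identifies genes whose **relative oscillation amplitude**
(rAMP = amplitude / baseline) or **mean expression level** tracks that
percentage across tissues — candidate amplitude regulators of circadian
transcriptome output. It is aimed at computational chronobiologists
working with tissue-panel time courses (microarray- or RNA-seq-style
designs) and at anyone who wants exact, tested primitives for
rhythmicity statistics and motif scanning.

## What is in the box

- **Rhythm detection** (`detect_all`): per gene per tissue, harmonic
  (cosinor) regression with an F-test, a Lomb–Scargle periodogram with
  the classical Gaussian-null tail, and a JTK-style Kendall-tau test
  with an *exact* null for Kendall's S (convolution recurrence; exact
  permutation counts for n ≤ 18). Component p-values are each corrected
  for their own period/phase grid search, integrated by Fisher's method,
  and Benjamini–Hochberg adjusted within tissue; a gene is rhythmic at
  q < 0.05. Outputs: p's, q, period, phase, baseline, AMP, rAMP.
- **The screen** (`pct_cycling`, `ramp_screen`, `mean_screen`,
  `fisher_rank`, `robust_intersection`): Pearson + Spearman correlation
  of per-gene features against per-tissue cycling percentages, Fisher
  Z = atanh(r) averaged across platforms for ranking, and a
  cross-platform significant-with-matching-sign intersection as the
  robust set.
- **Motif analysis** (`read_jaspar`, `scan_pwm`, `motif_fraction`):
  promoter windows −1000..+100 bp around the TSS, JASPAR PFM parsing
  with pseudocounts, and PWM scanning whose p-values come from an exact
  dynamic-programming null (1/1000-bit discretisation), hits at
  p < 1e-4.
- **SVD** (`svd_project`, `outlier_gene`): eigengene/eigentissue
  decomposition of a gene × tissue feature matrix with a deterministic
  sign convention, plus a centroid-distance outlier ranking.
- **Synthetic study generator** (`synth_config`, `generate_dataset`,
  `plant_regulator`, `generate_promoters`): 12 mouse-like tissues, dense
  (24 × 2 h) and sparse (8 × 6 h) sampling of one shared truth,
  log-normal baselines, multiplicative noise, planted rhythmic sets and
  planted regulators whose feature is linear in the tissue cycling
  fraction — the ground truth all tests are scored against.
- **Pipeline** (`run_pipeline`, `inst/scripts/circascreen.R`): simulate →
  preprocess → detect → screen → motif → svd with TSV outputs and a JSON
  manifest.

## Worked example

Plant a mean-level regulator (mean expression `5 + 40 * f_t` in a tissue
with cycling fraction `f_t`) into a 12-tissue, 1000-gene study sampled on
both designs, then run the screen:

```r
library(circascreen)
cfg <- synth_config(
  n_genes = 1000,
  cycling_fraction = seq(0.15, 0.02, length.out = 12),
  regulators = list(regulator_spec("g0500", "mean_level", 5, 40)),
  seed = 1)
ds <- generate_dataset(cfg)
filt <- lapply(ds$matrices, filter_low_expressed)
det  <- lapply(filt, function(f) detect_all(f$tissues))
summaries <- lapply(det, pct_cycling)
head(summaries$microarray, 4)
#>           tissue n_expressed n_cycling pct_cycling
#> 9          liver         991       159    16.04440
#> 8         kidney         992       145    14.61694
#> 10          lung         992       130    13.10484
#> 4  brown_adipose         993       125    12.58812
```

Detected cycling percentages track the planted fractions (15%, 13.8%,
12.6%, ... down to 2%), slightly inflated by the ~5% FDR budget. Now
correlate every gene's per-tissue mean level with the cycling percentage
on each platform and rank by averaged Fisher Z:

```r
recs <- lapply(names(det), function(nm)
  mean_screen(filt[[nm]]$tissues, summaries[[nm]]))
names(recs) <- names(det)
ranked <- fisher_rank(recs)
head(ranked[, c("gene", "avg_z_pearson", "rank_pearson", "rank_spearman")], 3)
#>      gene avg_z_pearson rank_pearson rank_spearman
#> 494 g0500     2.9792116            1             1
#> 202 g0202     1.1671816            2             2
#> 310 g0313     0.9963024            3             3
```

The planted regulator `g0500` is ranked first in both test families; on
the dense platform alone its correlation record reads
`pearson_r = 0.998 (p = 2.2e-13), spearman_rho = 1.000`. Genes behind it
are the best-correlated of the ~950 null genes (avg z ≈ 1, i.e. r ≈ 0.76
— the expected extreme order statistics under the null).

The same analysis in one call, with all per-stage TSVs and a manifest:

```r
run_pipeline(cfg, outdir = "out")
```

## Notes

- The methods vignette
  (`vignettes/circadian-amplitude-screen.Rmd`) documents the model,
  every tunable threshold, the multiplicity conventions, what the
  synthetic generator does and does not emulate, and known limitations
  (in particular, Fisher integration of dependent detector p-values is
  mildly liberal in the extreme tail).
- A thin CLI over the package functions lives at
  `inst/scripts/circascreen.R`
  (`Rscript circascreen.R {simulate|detect|screen|motif-scan|svd|run-all} ...`).
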