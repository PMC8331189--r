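# mitoquant

Quantitation of **mitophagy** and **macroautophagy** from tandem
mCherry-GFP fluorescence reporter micrographs (the *mito*-QC and
*auto*-QC mouse reporter designs), for cell biologists analysing
reporter images and for method developers who need a fully synthetic,
ground-truthed benchmark of the red-only-puncta counting workflow.

## The science in one paragraph

A tandem mCherry-GFP tag targeted to mitochondria (or to autophagosomes)
emits in both channels at neutral pH, but the acidic lysosomal lumen
quenches GFP while mCherry persists. Structures delivered to lysosomes
therefore appear as **mCherry-only puncta**. The pipeline detects them by
despeckling both channels (median *fine filter*), forming the ratio image

```
R(p) = (red(p) + 1) / (green(p) + 1),   capped at 100,
```

and applying a **double threshold**: mitolysosomes are connected
components with `R >= ratio_thr_high` **and** `red >= red_thr` (the second
threshold suppresses spurious high-ratio pixels where the reporter is
weakly expressed). In the auto-QC design, high-red objects are classified
by their mean ratio into autophagosomes (low `R`) vs autolysosomes (high
`R`). Counts are normalized per µm² of an immunolabelled cell-type stain
or per cell body; a cell is *mitophagic* when its mitolysosome count
exceeds a trimmed-mean threshold derived from untreated wild-type cells;
group comparisons use one-/two-way ANOVA with Tukey HSD on per-subject
means; cohort sizing uses the two-sample equality design
`n = 2σ²(z₁₋α/₂ + z₁₋β)² / δ²`.

Because the original microscopy data are not deposited, the package
includes a synthetic scene generator (mitochondrial networks, quenched
puncta, immunolabel masks, PSF blur, Poisson + Gaussian noise) with
per-object ground truth; all acceptance tests run against that oracle.
See `vignettes/mitoquant-methods.Rmd` for models, parameters and
limitations.

## Worked example

Six simulated mice (3 wild type, 3 LRRK2 G2019S with fewer mitolysosomes
per cell), three fields each, full pipeline:

```r
library(mitoquant)

design <- data.frame(subject_id = sprintf("m%02d", 1:6),
                     genotype  = rep(c("WT", "G2019S"), each = 3),
                     treatment = "none")
scenes <- list()
for (s in seq_len(nrow(design))) {
  mu <- if (design$genotype[s] == "WT") 5 else 2
  base <- scene_spec(n_mitolysosomes_per_cell = count_dist(mu, Inf))
  scenes <- c(scenes, simulate_scenes(base, design[s, , drop = FALSE],
                                      images_per_subject = 3, seed = 100 + s))
}
cfg <- pipeline_config(seed = 1L, out_dir = tempfile())
res <- run_pipeline(cfg, scenes, mode = "mito")
```

`res$records` holds one row per field (detected mitolysosome counts);
`res$summaries` one mean per mouse; `res$stats` the ANOVA + Tukey table.
Output printed by the code above:

```
  subject_id genotype mean_outcome n_images
1        m01       WT    21.666667        3
2        m02       WT    22.666667        3
3        m03       WT    16.666667        3
4        m04   G2019S     7.666667        3
5        m05   G2019S     7.333333        3
6        m06   G2019S    10.666667        3

       term df    sum_sq  F_value    p_value
1  genotype  1 208.07407 30.36757 0.00529096
2 Residuals  4  27.40741       NA         NA

  comparison     diff      lwr     upr       p_adj stars
1  WT-G2019S 11.77778 5.843753 17.7118 0.005292219    **
```

The G2019S deficit designed into the scenes is recovered (≈22 vs ≈9
mitolysosomes per field, Tukey adjusted p = 0.0053, `**`). The cohort
power calculation that sized the original animal study:

```r
sample_size_two_means(mu = 60.6, sd = 19.8, effect_fraction = 0.4)
#> $n_unrounded  10.47376
#> $n_per_group  10
```

i.e. a mean of 60.6 mitolysosomes per section (SD 19.8) needs ~10 animals
per group to detect a 40% change at two-sided α = 0.05 and power 0.8.

## Command line

```sh
Rscript inst/cli/mitoquant simulate      --out scenes/ --n-scenes 5 --seed 3
Rscript inst/cli/mitoquant quantify-mito --images scenes/ --out results/
Rscript inst/cli/mitoquant quantify-auto --images scenes/ --out results/
Rscript inst/cli/mitoquant coloc         --images scenes/ --out results/
Rscript inst/cli/mitoquant stats         --in results/records.csv --out results/
Rscript inst/cli/mitoquant run           --images scenes/ --out results/ --mode mito
```

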