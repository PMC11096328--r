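# rbpimpact

Position-dependent motif activity on pre-mRNA processing, inferred from
RNA-Seq-derived event quantifications.

RNA-binding proteins (RBPs) shape the maturation of pre-mRNAs by binding
short sequence motifs near splice sites and poly(A) sites, activating or
repressing the use of those sites. For most of the >1500 human RBPs the
binding motif, the direction of the effect, and the positions from which
the effect is exerted are unknown. `rbpimpact` addresses this for two
event classes quantified from standard RNA-Seq data: cassette-exon
inclusion and relative tandem poly(A)-site usage. It is aimed at
computational biologists analyzing RBP perturbation experiments (e.g.
knock-downs) or tissue cohorts (e.g. tumor versus normal), who want to
know *which motif*, *acting where*, and *in which direction* explains the
observed processing changes — without CLIP data.

## Models

**Splicing arm.** For cassette exon *e* with inclusion evidence
*i*<sub>e,s</sub> out of *n*<sub>e,s</sub> junction reads in sample *s*,
inclusion follows a binomial logistic model

&nbsp;&nbsp;&nbsp;&nbsp;*i*<sub>e,s</sub> ~ Binomial(*n*<sub>e,s</sub>, Θ<sub>e,s</sub>),&nbsp;&nbsp;
Θ<sub>e,s</sub> = logistic(*b*<sub>s</sub> + *c*<sub>e</sub> + *Ñ*<sub>e,m</sub> · *A*<sub>m,s</sub>)

where *b*<sub>s</sub> is a per-sample baseline, *c*<sub>e</sub> a
per-exon baseline, *Ñ*<sub>e,m</sub> the (event-centered) binding
evidence of motif *m* in a sequence window near the 3′ or 5′ splice
site, and *A*<sub>m,s</sub> the **activity** of motif *m* in sample *s*
(positive = activating, negative = repressive). The MAP fit under
Gaussian priors (Newton–Raphson, sum-to-zero constraints on *A* and *c*)
yields activities with Laplace errors σ<sub>m,s</sub> and z-scores
*Z*<sub>m,s</sub> = *A*<sub>m,s</sub>/σ<sub>m,s</sub>.

**Polyadenylation arm.** For tandem poly(A) site *p* in terminal exon
*e*, the log2 relative usage follows a linear model

&nbsp;&nbsp;&nbsp;&nbsp;log₂ *u*<sub>p,s</sub> = *Ñ*<sub>p,k</sub> · *A*<sub>k,s</sub> + *c*<sub>p</sub> + *c*<sub>s,e</sub> + ε

solved by double centering (across samples per site, then across sites
within each exon per sample) followed by a per-sample OLS slope — exactly
the normal-equations solution with explicit indicator covariates.

Both arms are applied to 50-nt windows sliding by 25 nt across the
regions around the 3′SS, 5′SS, and PAS. Per (site, window, sample)
context the z-scores across all motifs (curated PWMs or all 3–5-nt
k-mers) are renormalized against an empirical-null Gaussian component
(two-component mixture with BIC selection), converted to two-sided
p-values, Bonferroni-corrected over all annotated cells, and assembled
into **impact maps**. Motifs are ranked by a combined z-score — the mean
over site types of the strongest absolute renormalized z-score.

Binding evidence is either the exact overlapping k-mer count or, for a
PWM with site prior ρ (default 0.01), the summed per-position posterior
ρ·P<sub>pwm</sub>/(ρ·P<sub>pwm</sub> + (1−ρ)·4<sup>−L</sup>).

## Worked example

A fully synthetic knock-down experiment: a penta-U-binding repressor is
active upstream of 3′ splice sites in three control samples and depleted
in three knock-down samples. The generator plants `UUUUU` into the
(−50, 0) window of half the exons and draws inclusion counts from the
logistic model; the pipeline then has to rediscover motif, position, and
sign from the sequence and the junction counts alone.

```r
library(rbpimpact)

sim <- simulate_splicing_dataset(
  sim_preset("pentaU_repressor", seed = 42, n_exons = 500))

cfg <- run_config(
  genome = sim$genome, annotation = sim$annotation,
  junction_counts = sim$junction_counts,
  motifs = "kmer", kmer_range = c(5L, 5L),
  scheme = region_scheme(ss3 = c(100, 50), window_width = 50, slide = 25),
  site_types = "SS3", out_dir = file.path(tempdir(), "demo"))
res <- run_impact_pipeline(cfg, quiet = TRUE)

head(res$ranked[, c("motif_id", "combined_z", "rank", "n_significant",
                    "best_window", "best_sample")], 5)
#>   motif_id combined_z rank n_significant best_window best_sample
#> 1    UUUUU  16.916156    1            18      -50_+0      CTRL_2
#> 2    UUUUG   8.837802    2            17      -50_+0      CTRL_3
#> 3    AUUUU   7.857917    3            11      -50_+0      CTRL_1
#> 4    GUUUU   7.569077    4            18      -50_+0      CTRL_3
#> 5    UUUUC   7.048832    5            10      -50_+0      CTRL_2
```

The planted motif ranks first; the runners-up are its partial overlaps.
`combined_z = 16.9` is the strongest absolute renormalized activity
z-score of `UUUUU` across windows and samples, and 18 of its impact-map
cells stay significant after Bonferroni correction. The impact map shows
where and in which direction it acts — repressive (negative z) in
control, released (positive) on knock-down, localized to the windows
overlapping the planted region:

```r
head(impact_map(res$sig, "UUUUU")[, c("window_start", "window_end",
     "sample", "Z", "z_renorm", "p_bonf", "significant")], 8)
#>   window_start window_end sample           Z    z_renorm       p_bonf significant
#> 1         -100        -50 CTRL_1   1.2677205  0.24313438 1.000000e+00       FALSE
#> 2         -100        -50 CTRL_2  -2.9908903 -0.59499325 1.000000e+00       FALSE
#> 3         -100        -50 CTRL_3  -1.1539531 -0.23236460 1.000000e+00       FALSE
#> 4         -100        -50   KD_1   1.3771758  0.28316733 1.000000e+00       FALSE
#> 5         -100        -50   KD_2   1.3324519  0.27259390 1.000000e+00       FALSE
#> 6         -100        -50   KD_3   0.2001866  0.04945505 1.000000e+00       FALSE
#> 7          -75        -25 CTRL_1 -55.2518735 -11.02285993 9.108070e-24        TRUE
#> 8          -75        -25 CTRL_2 -56.8555257 -11.33901925 2.582982e-25        TRUE
```

The (−100, −50) window, which does not overlap the planted region, is
null; the (−75, −25) window, which does, carries strongly negative
(repressive) activity in control samples.

A command-line wrapper over the same functions ships in
`inst/cli/rbpimpact-cli.R` (subcommands for motif curation, k-mer
enumeration, QC gating, event quantification, simulation, the full
pipeline, and coverage metaprofiles).

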