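---
title: "Inferring position-dependent motif activity on pre-mRNA processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring position-dependent motif activity on pre-mRNA processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `rbpimpact`, the
assumptions behind them, the parameters a user may want to change, the
numerical choices made where the mathematics leaves freedom, and what the
synthetic validation does and does not establish.

## The inference problem

RNA-binding proteins (RBPs) act on pre-mRNAs through short sequence
motifs, and their effect depends strongly on *where* the motif sits
relative to the processing site: the same protein can repress a splice
site from one window and have no effect from another. `rbpimpact` turns
this into a regression problem: across many processing events, does the
amount of binding evidence for a motif in a fixed window around the site
explain the between-sample variation in how the site is used? The fitted
coefficient — the motif's *activity* in a sample — is signed (positive =
activating, negative = repressive), and scanning a grid of windows turns
per-window activities into a position-dependent *impact map*.

Two event classes are modeled.

### Cassette-exon inclusion

For exon $e$ and sample $s$, inclusion evidence is
$i_{e,s} = (\text{incl}_\text{up} + \text{incl}_\text{down})/2$ from the
two inclusion junctions, with total support $n_{e,s} = i_{e,s} +
\text{skip}_{e,s}$; the inclusion fraction is $f_{e,s} = i/(i +
\text{skip})$ and is undefined (treated as missing, never imputed) when
no junction read supports the event. The model is

$$ i_{e,s} \sim \mathrm{Binomial}(n_{e,s},\ \Theta_{e,s}), \qquad
\Theta_{e,s} = \frac{e^{X_{e,s}}}{1 + e^{X_{e,s}}}, \qquad
X_{e,s} = b_s + c_e + \tilde N_{e,m} A_{m,s}, $$

with per-sample baseline $b_s$, per-exon baseline $c_e$, and the motif
evidence $\tilde N$ centered across events. One motif is fitted at a time
(no joint multi-motif model), one window at a time.

**Estimation.** The posterior mode is found under Gaussian priors
$A_{m,s} \sim \mathcal N(0, \tau^2)$ (default $\tau = 1$, on the
log-odds-per-binding-site scale) and weak $\mathcal N(0, 10^2)$ priors on
$b$ and $c$, with exact identifiability constraints $\sum_s A_{m,s} = 0$
and $\sum_e c_e = 0$ imposed by reparameterization (the model has two
flat directions: a common shift of $A$ absorbable into $c$, and a shift
between $b$ and $c$). Newton–Raphson with step-halving starts from all
parameters at zero — deterministic, no RNG anywhere in fitting — and
stops when the largest parameter change falls below $10^{-8}$ or after
200 iterations. The per-exon block of the observed information is
diagonal, so each Newton step is solved exactly by a Schur complement
with a Sherman–Morrison correction for the sum-to-zero contrast; cost per
iteration is linear in the number of events. Fitting errors
$\sigma_{m,s}$ come from the diagonal of the inverse observed information
(Laplace approximation), propagated through the constraint contrast, and
$Z_{m,s} = A_{m,s} / \sigma_{m,s}$.

Effective totals $n_{e,s}$ are capped at 100 (counts rescaled
proportionally): junction counts in deep libraries would otherwise
shrink $\sigma$ far below what biological replicate variation supports.
With flat priors the fit reproduces an unpenalized logistic regression
(tested against `glm` to $10^{-4}$); with the defaults and thousands of
events the prior's influence on recovered activities is negligible.

### Tandem poly(A)-site usage

Relative usage of site $p$ in sample $s$ is $u_{p,s} = (x_{p,s} + 1) /
\sum_q (x_{q,s} + 1)$ over the tandem sites of one terminal exon
(pseudocount 1, configurable, keeps $\log_2 u$ finite). The model is

$$ \log_2 u_{p,s} = \tilde N_{p,k} A_{k,s} + c_p + c_{s,e} +
\varepsilon_{p,s}. $$

Both nuisance terms are removed exactly by double centering: subtract the
per-site mean across samples (removes $c_p$), then the per-(exon, sample)
mean across that exon's sites (removes $c_{s,e}$); center $N$ within
exons the same way, and the activity is the per-sample OLS slope
$A_{k,s} = \sum_p \tilde N_p \tilde y_{p,s} / \sum_p \tilde N_p^2$. For
complete site-by-sample tables this equals the full normal-equations OLS
solution with explicit indicator covariates; since a common shift of the
per-sample activities is absorbable into $c_p$, activities are only
identified *relative to the sample mean*, and the double-centered
solution is automatically sum-to-zero across samples (the property the
test suite checks against a pseudoinverse oracle to $10^{-8}$).

The error estimate is $\sigma^2_{k,s} = \mathrm{RSS}_s / ((P - E - 1)
\sum \tilde N^2)$ with $P$ sites and $E$ exons. Double centering deflates
the residual variance by a factor $(S-1)/S$ and the sampling variance of
the slope by the same factor, so this simple degrees-of-freedom count is
exactly calibrated — confirmed by the null z-score calibration test
(sd within [0.8, 1.2]).

## Windows, sequences, and binding evidence

Windows are half-open offset intervals $[a, b)$ in sense orientation,
offset 0 at the site anchor: first exonic base (3′SS), last exonic base
(5′SS), or cleavage position (PAS); negative offsets are upstream. The
default grid tiles −300…+100 around the 3′SS, −100…+300 around the 5′SS
and ±300 around the PAS with 50-nt windows sliding by 25 nt, plus the
central (−25, +25) window; a 20/10 high-resolution grid is available for
narrowly positioned regulators. Defaults were chosen to cover the
regulatory ranges reported for well-studied RBPs (roughly −200…+100 for
poly-U-binding repressors around poly(A) sites, −25…+75 for
pyrimidine-tract-binding proteins); the published figures show the grids
only graphically, so the extents are configurable.

Windows are *masked* — recorded as missing, never zero — when the exonic
side would extend beyond the cassette exon or the intronic side beyond
the flanking intron, preventing sites from the wrong genomic context from
entering the counts. Together with the default minimum exon length of
50 nt this guarantees the central windows of both splice sites are
usable; setting `min_exon_length = 0` admits micro-exons at the cost of
masking their exonic windows. Minus-strand windows are extracted by
reverse complementation, and all matching happens on the RNA alphabet
(genomic T is transcribed to U on read), since the motifs act on the
pre-mRNA.

k-mer evidence is the exact overlapping occurrence count (delegated to
`Biostrings::oligonucleotideFrequency`, verified against a naive scan).
PWM evidence is the sum over start positions of the binding posterior
$\rho P_\mathrm{pwm} / (\rho P_\mathrm{pwm} + (1-\rho) 4^{-L})$ with a
uniform background and site prior $\rho = 0.01$ — about one spurious
"site" per 100 positions a priori; evidence is monotone in $\rho$, and
the value is echoed into output metadata.

## Significance: empirical null, Bonferroni, ranking

Raw z-scores are compared across all motifs within one (site type,
window, sample) context. Because motifs are correlated (overlapping
k-mers, shared composition), the bulk of this distribution is wider or
narrower than $\mathcal N(0,1)$; significance is therefore assessed
against an *empirical null*: a two-component Gaussian mixture is fitted
by EM (deterministic initialization: means at the 25th/75th percentiles,
equal weights, pooled sd; at most 500 iterations or $\Delta\log L <
10^{-10}$), the dominant component is the null, and
$z' = (z - \mu_0)/\sigma_0$.

One subtlety matters: on *unimodal* input a two-component mixture is
unidentifiable, and EM drifts to a symmetric split of the bulk with
$\mu_0 \approx \pm 0.3$ — which would both bias the renormalized scores
and destroy null calibration. The package therefore selects between the
single-Gaussian and two-component fits by BIC and separates a null
component only when the data support it. With fewer than 50 finite
z-scores the mixture is not fit at all and raw z-scores are treated as
standard normal (with a warning).

Two-sided normal p-values of $z'$ are Bonferroni-corrected with
$m = (\text{motifs}) \times (\text{site/window combinations}) \times
(\text{samples})$ — every annotated impact-map cell is a test, so the
sample dimension belongs in the count; a smaller universe omitting it
makes the family-wise error rate approximately $S \cdot \alpha$ and
fails a 20-seed null calibration about half the time. Cells with
$p_\mathrm{bonf} < \alpha$ (default 0.05) are the asterisked cells of the
impact map.

Motifs are ranked by the **combined z-score**: the mean over analyzed
site types of the maximum $|z'|$ across that site type's windows and
samples; ties break lexicographically by motif id, and all-missing maps
rank last with combined z 0. For perturbation experiments,
`rank_for_perturbed_rbp()` reports the best rank among the PWMs mapped
to the perturbed protein that are significant somewhere — the gate
prevents an accidentally high rank without any significant cell from
counting as a recovery.

## The synthetic-data generator

`simulate_splicing_dataset()` draws three-exon genes (200-nt flanking
exons, 400-nt introns, 80-nt cassette exon by default, alternating
strands) with i.i.d. uniform ACGU sequence, plants the configured motif
by overwriting a uniformly chosen position inside the planting window in
a configurable fraction of events, and then generates inclusion counts
from exactly the logistic model above, using the *realized* motif count
in the planted window (including chance occurrences and run extensions)
as the causal covariate. The emitted annotation (inclusion + skipping
isoforms) and junction tables round-trip through the package's own event
selection. `simulate_pas_dataset()` does the analogous thing for the
linear usage model, converting planted log2 usage back to read counts
through a per-exon multinomial. `simulate_coverage()` plants fold
enrichment into Poisson coverage for the metaprofile module. All
generators are pure functions of their `sim_config` (every stream seed is
derived from the mandatory master seed; the global RNG state is saved and
restored).

The reference scenario (`sim_preset("pentaU_repressor")`) encodes a
penta-U-binding repressor depleted by knock-down: 2000 exons, six samples
(3 control, 3 knock-down), binomial depth 50, planting rate 0.5 in the
(−50, 0) window upstream of the 3′SS, activity −2 in control and +2 in
knock-down. The magnitude 2 (log-odds per binding site) was chosen once
as a strong-but-plausible knock-down effect — a planted site shifts an
exon's inclusion odds about $e^2 \approx 7$-fold between conditions; the
rate 0.5 makes planted and unplanted events equally informative. The
null preset (500 exons, 4 samples, nothing planted) is analyzed at the
single (−50, 0) window — a focused calibration context that keeps the
20-seed loop cheap.

**What passing these scenarios shows — and what it does not.** The
generator draws data from the same model family the fits assume, so
parameter recovery demonstrates correctness of the estimation machinery,
not robustness to real data. Real RNA-Seq violates the simulation in
known ways: sequence composition is not i.i.d. uniform (splice-site
consensus, polypyrimidine tracts), junction counts are overdispersed
relative to binomial, motif evidence is a proxy for occupancy, and many
motifs act simultaneously. One consequence shows up even in simulation:
k-mers that are substrings of the planted motif (UUUU inside UUUUU) are
near-collinear proxies and can match or exceed the planted motif's
z-score when the planted effect is strong, because the model-based
standard errors do not penalize misspecification and the exact covariate
saturates its events' inclusion probabilities. The mixed 3–5-mer ranking
therefore asserts only that the top motif is the planted penta-U or a
4-mer substring of it, while the exact rank-1 recovery is checked within
the 5-mer universe, where the planted motif wins by a wide margin.

## Degenerate inputs and edge cases

* Constant motif evidence (after masking) is inseparable from the
  baselines: the fit is flagged `uninformative`, activities are 0, and
  the z-score table emits `NA` (never 0) so the cells drop out of the
  mixture fit instead of inflating its bulk.
* Non-converged Newton fits are flagged and excluded from ranking.
* Events with no junction support in a sample contribute nothing for
  that sample; events masked in a window are dropped from that window's
  fit; exon groups left with fewer than two poly(A) sites are dropped.
* Fewer than 10 usable events/sites (configurable) aborts that motif ×
  window fit with a recorded failure rather than returning an unstable
  estimate.
* Zero-variance z-score contexts yield $p = 1$, flagged degenerate.
* Welch tests on zero-variance-in-both-groups events return $p = 1$ at
  equal means.

## Coverage metaprofiles

CLIP-style validation compares per-position foreground (RBP pulldown)
and background (control) coverage around the processing sites that
change most (default: top 200 in the expected direction) versus those
that change least (default: 1000). Per site and offset the
library-size-normalized ratio uses an $\varepsilon = 10^{-9}$ guard so
zero-background positions remain defined (configurable; the alternative
of dropping such positions biases profiles in low-coverage data). The
mean ratio per offset is smoothed with a ±5-nt running mean, and the
non-target band is the per-offset mean and standard deviation over 100
resamples (with replacement) of 200 non-targets — the only stochastic
step in the analysis path, driven by an explicit seed. Profiles are
reported in sense orientation; minus-strand site windows are reversed.

## Problem sizes used by the test suite

The suite validates at the reference conditions: the penta-U scenario at
2000 exons × 6 samples (recovery and 5-mer ranking), 20 null datasets of
500 exons × 4 samples against all 256 4-mers, 300 terminal exons for the
poly(A) arm, 1000 random 200-nt sequences × 50 k-mers for the counting
oracle, and 80 sites for the metaprofile checks. These sizes give the
stochastic checks comfortable margins (the recovery correlations sit
near 0.999 against a 0.9 threshold) while keeping the full suite at a
few minutes on one CPU.

## Known limitations

* One motif per fit: joint effects and motif-motif redundancy are
  resolved only indirectly through the ranking.
* Model-based errors: no robustification against misspecification; see
  the substring discussion above.
* The event definitions are junction-based; coverage-based poly(A)
  quantification and alignment are upstream of this package and consumed
  as tables.
* PWM scanning assumes independence across motif positions and a uniform
  background; no secondary-structure awareness, no gapped motifs.
* The empirical-null renormalization assumes most motifs in a context
  are inactive; in a run restricted to a handful of strong regulators
  the standard-normal fallback applies instead.
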