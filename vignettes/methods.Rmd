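---
title: "Models and methods behind popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

`popgenscan` chains three analysis blocks — multi-caller variant
filtering, neutral diversity/structure statistics, and a
composite-likelihood sweep scan — behind a synthetic-data generator that
provides known truth.  This vignette explains the models, the parameters
that matter, the numerical choices, and what the tests do and do not
demonstrate.

## The synthetic-data generator

### Genotypes

The generator is Balding–Nichols with founder mosaics.  Per site, an
ancestral frequency $p$ is drawn from a Beta($\alpha$, 1) law
($\alpha$ = `sfs_shape`, default 0.2); each population $k$ perturbs it as

$$p_k \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right),$$

with $F$ = `f_div` (default 0.0025, the weak-differentiation regime of
closely related local populations).  $K$ = `n_founders` founder
haplotypes per population are drawn i.i.d. from $p_k$, and each
individual haplotype is a founder mosaic whose switch probability between
adjacent sites is $1-e^{-r d}$ ($r$ = `recomb_rate`, default
3×10⁻⁴/bp, giving an LD decay scale of a few kb).  Diploids pair
consecutive haplotypes.

Two properties of this model deserve emphasis:

* **The founder pool adds drift.**  Each population's realized allele
  frequency is the mean of $K$ Bernoulli($p_k$) draws, so realized
  differentiation has a floor of roughly $1/K$ on top of $F$.  With the
  default $K = 24$ the genome-wide Weir–Cockerham estimate on simulated
  data sits near 0.04–0.05 even when `f_div` is 0.0025.  When exact
  $F_{ST}$ control matters more than linkage (estimator-calibration
  checks), `n_founders = Inf` gives the pure Balding–Nichols limit:
  haplotypes i.i.d. from $p_k$, no LD, and $\hat\theta_w$ recovering
  `f_div` within a few percent.  Both corners are exercised in the test
  suite; no single finite-$K$ configuration can produce simultaneously
  the study-scale $F_{ST}\sim 10^{-3}$ and strong short-range LD, and the
  package treats that as a documented property of the model rather than
  hiding it.
* **LD strength scales like $1/K$.**  Close-pair $r^2$ on simulated data
  is modest (first-bin means around 0.06–0.09 at $K=6$); the decay
  *shape* across the seven distance bins and the rare-variant contrast
  (filtering MAF < 0.05 raises the first-bin mean) are the properties the
  analyses rely on, and those are reproduced.

SNP alternate alleles take the transition partner of the reference with
probability `ts_fraction` (0.71, reproducing a ts/tv ratio near 2.44);
6.8 % of sites are labelled indels.  Defaults sample 22/14/8 individuals
from three populations — the sampling design the pipeline is meant for.

### Sweeps

`inject_sweep()` emulates hitchhiking without a forward simulation: a
template haplotype carrying the beneficial allele rises to `final_freq`
in the target population, and each carrier haplotype keeps its own allele
at map distance $d$ with escape probability $c(d) = 1-e^{-d/\sigma_s}$
(`sigma_s` in bp, default 100 kb in the scan tests), otherwise copying
the template.  At $d=0$ with `final_freq = 1` the site fixes exactly;
non-target populations are untouched bit for bit.  This is a test
harness for scan localization, not a population-genetic claim: it
produces the right first-order signal (a valley of diversity and a block
of extreme frequency differentiation whose width is set by
$\sigma_s$) but no sojourn-time variance, no soft sweeps, and no
time-depth.

### Caller error model

`emit_caller_vcfs()` emits three call sets.  True sites are dropped per
caller at the false-negative rates (3 %/3 %/6 %); artifact sites are a
shared pool (10 % of true sites) that each caller emits with probability
0.85.  Site qualities are Normal(300, 120) for true sites — deep-coverage
variants carry qualities far above the consensus threshold — and
Normal(28, 12) for artifacts, centred *below* the stage-1 threshold:
being low-confidence is what makes them catchable by consensus, and the
minority that passes is what stage 2 exists for.  The seven annotations
are Gaussian per class: artifact means are shifted ~2 SD overall
(Mahalanobis, spread evenly across annotations) and artifact spreads are
4× the true-class spreads.  The wide-artifact geometry matters: the
VQSLOD of a true site is a quadratic form whose spectrum is set by
$\Sigma_B^{-1}-\Sigma_T^{-1}$; variance-dominated contamination makes
that spectrum full-rank ($\chi^2_7$-like left tail, so the
median − 3·MAD cutoff keeps > 90 % of true sites), whereas a purely
mean-shifted artifact class concentrates it in one direction
($\chi^2_1$-like tail that the same cutoff would clip at ~15–19 %
regardless of separation strength).  Mapping and calling artifacts on
real data are indeed dispersed, not merely shifted.

### mtDNA

`simulate_mtdna()` mutates a random reference independently per sequence
and position, with a hypervariable window at `multiplier` (default 13)
times the background rate (default 2.6×10⁻⁴ per site per sequence,
41 sequences, 16,651 bp, 481 bp window).  These defaults were calibrated
analytically so the expected number of distinct segregating positions is
≈ 230–240 with ≈ 27 % of them inside the window — the regime the
control-region statistics are designed for; the calibration accounts for
position collisions ($1-(1-rm)^{n}$ per window position).

## Two-stage filtering

Stage 1 and the training rules are exact set operations and are tested
against independent enumerations.  Boundary semantics are strict
throughout: quality 30 fails "> 30", quality 100 fails "> 100",
VQSLOD equal to the cutoff is retained (only "< cutoff" fails), GP equal
to 0.95 is kept.  Failing sites are flagged, never deleted.

The recalibration model is a single Gaussian fit to the training
annotations versus a Gaussian fit to all stage-1-passing sites.  Missing
annotation values are imputed with the training median — including sites
the primary caller missed entirely, which score at the centre rather
than being silently discarded.  Numerical choices:

* **Per-annotation ridge.**  Each covariance gets `ridge` (default 0.05)
  times its *own* diagonal added.  The annotations span four orders of
  magnitude (DP variance ~5600 vs InbreedingCoefficient ~0.04); a pooled
  mean-diagonal ridge would swamp the small-scale annotations and erase
  their contribution to the log odds.  If a covariance is still singular
  the ridge escalates tenfold up to a hard stop that names the most
  collinear annotation pair.
* **Unscaled MAD.**  The cutoff is median − 3 × median(|x − median|),
  with no 1.4826 consistency factor; the multiplier is a parameter
  (`mad_multiplier`, default 3).
* Per-population cutoffs are available by running the model per
  population subset; the default computes one cutoff over all samples.
* The minor-allele count and all downstream genotypes come from a
  designated primary caller (default the first file); indel
  left-normalization is not performed — the generator guarantees
  position consistency, and real inputs are assumed pre-normalized.

## Diversity statistics

π is averaged over qualifying variant sites (biallelic, fully genotyped),
not per bp — values near 0.18 on such data are per-variant means.  Ho
and F use listwise deletion; IBS uses pairwise deletion; F is the
method-of-moments homozygosity-excess estimator with the $n/(n-1)$
small-sample correction on expected heterozygosity.  IBS is exposed as
both similarity and 1 − similarity, since "distance" is the common name
for the shared proportion's complement.  The Weir–Cockerham components
use the genotype-based (heterozygosity-aware) 1984 formulas; sites where
any population has fewer than two called genotypes are skipped and
counted, and the genome-wide value is the ratio of component sums, never
the mean of ratios.

## LD and PCA

r² is the squared Pearson correlation of allele dosages over
pairwise-complete samples — the unphased-genotype estimator, chosen
because inputs are not guaranteed phased; a haplotype-EM option is
deliberately out of scope.  Decay-crossing distances interpolate linearly
between bin mean distances, since a continuous crossing is reported from
binned data.  Pruning slides non-overlapping 50-marker windows (the
window semantics are configurable; non-overlapping blocks are the
documented default) and removes the later-positioned member of each
offending pair — a deterministic tie-break.  PCA centres dosages,
scales by $\sqrt{p(1-p)}$, mean-imputes missing calls and
eigendecomposes the sample covariance.

## The XP-CLR scan

The scan models the test-population frequency $p_1$ given the pooled
reference frequency $p_2$.  Neutrally,
$p_1 \sim N(p_2, \omega\, p_2(1-p_2))$ truncated to $[0,1]$, with the
binomial sampling layer folded in as an additional Gaussian variance
term $p(1-p)/n$ — a closed-form approximation that avoids numeric
integration at every grid point.  Under a sweep of strength $s$ at map
distance $d$, a lineage escapes with probability
$c(d,s) = 1-e^{-d/s}$ ($d$ in Morgans); with probability $1-c$ it
hitchhikes, pulling the frequency to $1-c+cp_2$ (if the allele rode the
sweeping haplotype, probability $p_2$) or to $cp_2$ otherwise, with the
drift variance compressed by $c^2$.  The score is twice the maximum over
a logarithmic $s$ grid (10 points per decade over $10^{-4}$–$10^{-1}$)
of the down-weighted sum of per-SNP log-likelihood ratios, floored at 0.
As $s \to 0$, $c \to 1$ and the sweep model collapses onto the neutral
one, so undifferentiated windows score ≈ 0 by construction.

$\omega$ is estimated genome-wide before scanning by method of moments
on a thinned SNP set,
$\hat\omega = \overline{[(\hat p_1-\hat p_2)^2 - \hat p_2(1-\hat p_2)(1/n_1+1/n_2)]/[\hat p_2(1-\hat p_2)]}$,
floored at $10^{-4}$ and overridable.

Windowing follows fixed rules: grid every 2500 bp; ≤ 250 SNPs per 0.5 cM
window with deterministic even-spaced thinning; reference-group
correlation clusters (single linkage on $r^2>0.95$, computed once per
segment in overlapping chunks) down-weight each SNP by its cluster size;
segments of ≤ 27 cM step by 25 cM, and each segment's kept span drops
1 cM at every overlapped edge — left-trim unless first, right-trim
unless last — which tiles every chromosome length exactly (verified for
20, 50, 52 and 100 cM).  The 52 cM case pins the generation rule: starts
at 0, 25, 50, … while the start is inside the chromosome, so 52 cM gets
three segments with the middle one trimmed on both edges.  Physical
positions convert at 1 cM/Mb by default.

Region calling is not fully specified by the windowing rules, so the
defaults are documented here: the threshold is the
$\lceil 0.001\,n\rceil$-th highest defined grid score, ties included;
regions are maximal runs of above-threshold points tolerating one-step
gaps.  Gene mapping intersects regions with gene intervals extended by
1500 bp flanks.  Per-population scans pool the two other populations as
the reference, after the larger population is randomly subsampled to
equalize sizes.

This likelihood pair is a behavioural reimplementation of the published
method: the original's exact boundary-mass treatment is not recoverable
from parameter lists alone, so correctness is established by properties
— null scores near zero, localization of injected sweeps (the
genome-wide peak lands within 0.5 cM of the truth in 10/10 seeded
replicates on a 10 Mb chromosome), score monotonicity in sweep strength,
and exact segment tiling — rather than numeric identity to a binary.

## mtDNA statistics

Segregating sites require two distinct plain nucleotides; gaps and
ambiguity codes are not states.  Haplotype collapsing lets an `N` match
either state (greedy assignment to the first compatible haplotype in
input order — ambiguity-tolerant matching is not transitive, so an order
convention is required and documented).  Region shares compare the
density of segregating sites inside a window with the whole alignment;
the hypervariable window coordinates are a required user parameter since
they depend on the reference annotation.

## Problem sizes and runtime

The test suite and acceptance script use deliberately scaled problem
sizes chosen to exercise every code path on one CPU in minutes: 5000
sites on a 10 Mb chromosome for filtering and scan checks (ten sweep
replicates plus two neutral scans), 5×10⁴ sites × 2×20 samples for
F<sub>ST</sub> recovery, 5000 sites in 1 Mb for LD curves, and the full
16,651 bp × 41-sequence alignment for mtDNA.  These sizes are the
package's validation choices; the estimators themselves are vectorized
and handle larger inputs linearly in sites.

## Known limitations

* The generator is not a coalescent: no recombination hotspots, no
  demography, no background selection; mosaic LD is an exponential-decay
  caricature.  Passing tests show the estimators are correct and the
  scan localizes strong hard sweeps under these conditions — not that
  the pipeline is calibrated for every demographic scenario.
* The recalibration model is a single-Gaussian discriminant, not a
  mixture; multi-modal annotation structure would be mishandled.
* Dosage r² understates haplotype LD when phase matters.
* The sweep likelihood is an approximation pair (truncated normal +
  boundary-pull mixture); scores are comparable within a scan, not
  across tools.
* Beagle-style genotype-probability computation, read mapping, the
  callers themselves, admixture clustering and GO enrichment are out of
  scope; their outputs are consumed, not produced.
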