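# popgenscan

Whole-genome population genomics for small collections of deeply sequenced
individuals: `popgenscan` re-implements, as a tested and reusable R
pipeline, the analysis chain used to characterize weakly structured
livestock populations from WGS data — multi-caller variant consensus
filtering with a robust recalibration cutoff, neutral diversity and
structure statistics, linkage-disequilibrium decay, a Weir–Cockerham
F<sub>ST</sub> scan, a cross-population composite-likelihood (XP-CLR)
selective-sweep scan with segment-wise score assembly, and mitochondrial
control-region haplotype statistics.  A Balding–Nichols founder-mosaic
simulator generates inputs with known truth, so every stage is testable
end to end without access to archived sequencing data.

It is written tidyverse-style: user-facing functions take a data frame
(usually a genotype table: one row per variant site, a dosage
matrix-column `dos`) and return tibbles or small S3 objects with
`tidy()` / `glance()` / `autoplot()` methods.

## The statistics at the core

**Two-stage filtering.**  Stage 1 merges per-caller call sets: a site
passes if called by ≥ 2 callers with site quality > 30; an alternate
allele passes if any caller reports a carrier genotype.  Stage 2 fits a
multivariate Gaussian to the annotation vectors (QD, HaplotypeScore,
MQRankSum, ReadPosRankSum, FS, DP, InbreedingCoefficient) of a
highest-confidence training set (all callers > 100, biallelic, minor
allele count ≥ 3 among GQ > 30 genotypes) and a second Gaussian to the
background; each site gets

> VQSLOD = ln N(x; μ_T, Σ_T) − ln N(x; μ_B, Σ_B),

and is removed iff VQSLOD < median − 3·MAD of the training scores (MAD
unscaled).  Genotypes with posterior probability < 0.95 are masked.

**Diversity.**  Per-site π = 2j(n−j)/(n(n−1)) averaged over fully
genotyped biallelic variants; per-individual observed heterozygosity Ho
and inbreeding F = (O_hom − E_hom)/(S − E_hom); pairwise identity-by-state;
ts/tv; the MAF spectrum with rare = MAF < 0.05; Weir–Cockerham variance
components a, b, c with the weighted genome-wide estimate
θ̂_w = Σa / Σ(a+b+c).

**LD.**  Genotype-dosage r² between biallelic sites, averaged in the
seven distance classes 0–0.2, 0.2–1, 1–2, 2–10, 10–30, 30–60, 60–120 kb;
interpolated decay-crossing distances; 50-marker window pruning at
r² > 0.95; PCA of the pruned matrix.

**Sweep scan.**  XP-CLR scores on a 2500 bp grid with ≤ 250 variants per
0.5 cM window, correlated reference variants (r² > 0.95) down-weighted by
cluster size, computed on overlapped 27 cM segments with 1 cM trimmed
from each overlapped edge (1 Mb ≈ 1 cM), the top 0.1 % of grid scores
condensed into candidate regions, and genes mapped with 1500 bp flanks.

## Worked example

```r
library(popgenscan)

cfg <- sim_config(
  samples     = c(Black = 22, Draa = 14, Northern = 8),
  chromosomes = c(chr1 = 5e6), f_div = 0.0025, seed = 42,
  sweeps = list(list(chrom = "chr1", pos = 2.5e6, pop = "Black",
                     sigma_s = 1e5, final_freq = 1)))
sim <- simulate_genotypes(cfg)
em  <- emit_caller_vcfs(sim)                       # three noisy call sets
fr  <- filter_variants(em$calls, primary = "ug", truth = em$truth)
#> Two-stage variant filter
#>   sites in: 2749 | stage1 pass: 2549 | training: 945
#>   VQSLOD cutoff (median - 3*MAD): -0.520 | retained: 2210 | ts/tv: 2.58

wc_fst(fr$geno, sim$pop_map)
#> Weir-Cockerham FST over 1379 sites (Black, Draa, Northern): theta_w = 0.051

scan <- xpclr_scan(fr$geno, equalize_samples(sim$pop_map, 14, seed = 42),
                   "Black")
#> XP-CLR scan: Black vs pooled {Draa, Northern}; 1999 grid points;
#> omega = 0.218; max score 133.5
call_regions(scan)
#>   region chrom   start     end n_points peak_score peak_pos
#> 1      1  chr1 2497500 2500000        2    133.546  2497500
```

The filter keeps 2210 of 2749 merged sites with a ts/tv of 2.58 close to
the simulated 2.44 class balance; the sweep injected at 2.5 Mb in the
Black population is recovered as the single top-0.1 % region, peaking
2.5 kb from the true position.  (The genome-wide θ̂_w of 0.051 reflects
founder-pool drift on top of the nominal F = 0.0025 at the default 24
founders per population; see the methods vignette.)

The mitochondrial side works on plain alignments:

```r
mt <- simulate_mtdna(seed = 42)    # 41 sequences, 16,651 bp, HVI window
collapse_haplotypes(mt$alignment)
#> 41 haplotypes over 41 sequences; 229 segregating sites
region_share(mt$alignment, 15001, 15481)
#>   n_region n_total variant_share length_share
#> 1       71     229     0.310        0.0289
```

`run_pipeline(default_pipeline_config(seed = 1), "run1/")` chains all
stages into a run directory of TSV reports plus a hash manifest.

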