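#' Per-site and mean nucleotide diversity
#'
#' For a biallelic site with `j` copies of the alternate allele among `n`
#' called chromosomes, `pi = 2 j (n - j) / (n (n - 1))` — the probability
#' that two chromosomes drawn without replacement differ.  The mean is taken
#' over qualifying variant sites only (biallelic, fully genotyped in the
#' chosen sample subset), not per bp.
#'
#' @param j Alternate-allele count(s).
#' @param n Called chromosome count(s).
#' @return `site_pi()`: numeric vector of per-site diversity.
#' @examples
#' site_pi(1, 88)   # a singleton among 44 diploids
#' @export
site_pi <- function(j, n) {
  stopifnot(all(n >= 2), all(j >= 0), all(j <= n))
  2 * j * (n - j) / (n * (n - 1))
}

#' @rdname site_pi
#' @param geno Genotype table.
#' @param samples Optional sample subset (default: all).
#' @return `mean_pi()`: mean per-variant diversity over sites that are
#'   biallelic, fully genotyped in the subset, and polymorphic overall.
#' @export
mean_pi <- function(geno, samples = NULL) {
  if (is.null(samples)) samples <- geno_samples(geno)
  d <- geno$dos[is_biallelic(geno), samples, drop = FALSE]
  full <- rowSums(is.na(d)) == 0
  d <- d[full, , drop = FALSE]
  if (!nrow(d)) stop("undefined mean: no fully genotyped biallelic sites")
  n <- 2 * ncol(d)
  j <- rowSums(d)
  mean(site_pi(j, n))
}

#' Observed per-individual heterozygosity
#'
#' Fraction of heterozygous genotypes per individual, over biallelic sites
#' with no missing genotype call in any sample (listwise exclusion).
#'
#' @param geno Genotype table.
#' @return Tibble `sample, n_sites, ho`.
#' @export
het_observed <- function(geno) {
  d <- geno$dos[is_biallelic(geno) & geno$type == "snp", , drop = FALSE]
  d <- d[rowSums(is.na(d)) == 0, , drop = FALSE]
  if (!nrow(d)) stop("no fully genotyped biallelic SNPs")
  tibble::tibble(sample = colnames(d), n_sites = nrow(d),
                 ho = unname(colMeans(d == 1)))
}

#' Per-individual inbreeding coefficient
#'
#' Method-of-moments homozygosity excess:
#' `F = (O_hom - E_hom) / (S - E_hom)` where `O_hom` is the individual's
#' observed homozygous-site count over `S` qualifying sites and
#' `E_hom = sum_s [1 - 2 p_s (1 - p_s) * n_s / (n_s - 1)]` from allele
#' frequencies computed over all samples (small-sample corrected).
#'
#' @param geno Genotype table.
#' @return Tibble `sample, n_sites, o_hom, e_hom, f`.
#' @export
inbreeding_f <- function(geno) {
  d <- geno$dos[is_biallelic(geno) & geno$type == "snp", , drop = FALSE]
  d <- d[rowSums(is.na(d)) == 0, , drop = FALSE]
  if (!nrow(d)) stop("no fully genotyped biallelic SNPs")
  n_chr <- 2 * ncol(d)
  p <- rowMeans(d) / 2
  e_het_site <- 2 * p * (1 - p) * n_chr / (n_chr - 1)
  e_hom <- sum(1 - e_het_site)
  S <- nrow(d)
  if (abs(S - e_hom) < .Machine$double.eps^0.5)
    stop("undefined F: expected homozygosity equals site count")
  o_hom <- unname(colSums(d != 1))
  tibble::tibble(sample = colnames(d), n_sites = S, o_hom = o_hom,
                 e_hom = e_hom, f = (o_hom - e_hom) / (S - e_hom))
}

#' Pairwise identity-by-state
#'
#' Average proportion of alleles shared between two individuals across
#' sites: 1 for identical genotypes, 0.5 when one allele is shared, 0
#' otherwise; sites missing in either member of a pair are excluded
#' (pairwise deletion).
#'
#' @param geno Genotype table.
#' @return Object of class `ibs_result`: `similarity` and
#'   `distance = 1 - similarity` matrices.  `tidy()` returns the pairs as a
#'   long tibble.
#' @export
ibs_matrix <- function(geno) {
  d <- geno$dos[is_biallelic(geno), , drop = FALSE]
  ns <- ncol(d)
  sim <- matrix(1, ns, ns, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(ns - 1)) {
    di <- d[, i]
    for (j in (i + 1):ns) {
      ok <- !is.na(di) & !is.na(d[, j])
      sim[i, j] <- sim[j, i] <-
        if (any(ok)) mean(1 - abs(di[ok] - d[, j][ok]) / 2) else NA_real_
    }
  }
  structure(list(similarity = sim, distance = 1 - sim), class = "ibs_result")
}

#' @export
tidy.ibs_result <- function(x, ...) {
  s <- x$similarity
  idx <- which(upper.tri(s), arr.ind = TRUE)
  tibble::tibble(sample1 = rownames(s)[idx[, 1]],
                 sample2 = colnames(s)[idx[, 2]],
                 similarity = s[idx], distance = 1 - s[idx])
}

#' Transition/transversion counts and ratio
#'
#' A\eqn{\leftrightarrow}G and C\eqn{\leftrightarrow}T substitutions are
#' transitions; every other single-base substitution is a transversion.
#' Multi-allelic SNPs contribute each alternate allele separately; indels
#' are ignored.  A zero transversion count yields an infinite-ratio
#' sentinel, not an error.
#'
#' @param geno Genotype table (only `ref`/`alt` metadata are used).
#' @return One-row tibble `ts, tv, ratio`.
#' @examples
#' # the arithmetic on externally reported genome-wide counts:
#' tstv_ratio(15948529, 6540478)
#' @export
tstv <- function(geno) {
  alts <- strsplit(geno$alt, ",", fixed = TRUE)
  ref <- rep(geno$ref, lengths(alts))
  alt <- unlist(alts)
  snp <- nchar(ref) == 1 & nchar(alt) == 1
  pair <- paste0(pmin(ref[snp], alt[snp]), pmax(ref[snp], alt[snp]))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- sum(!pair %in% c("AG", "CT"))
  tibble::tibble(ts = ts, tv = tv, ratio = tstv_ratio(ts, tv)$ratio)
}

#' @rdname tstv
#' @param ts,tv Transition and transversion counts.
#' @export
tstv_ratio <- function(ts, tv) {
  tibble::tibble(ts = ts, tv = tv, ratio = if (tv == 0) Inf else ts / tv)
}

#' Minor-allele-frequency spectrum and rare-variant fraction
#'
#' MAF is computed over all called genotypes of all samples; a variant is
#' rare iff its MAF is strictly below `rare_below`.
#'
#' @param geno Genotype table.
#' @param rare_below Rare threshold (strict), default 0.05.
#' @param breaks Histogram bin edges on \[0, 0.5\].
#' @return Object of class `maf_spectrum`: histogram tibble `bin, lo, hi, n`
#'   plus fields `maf`, `n_rare`, `rare_fraction`.
#' @export
maf_spectrum <- function(geno, rare_below = 0.05,
                         breaks = seq(0, 0.5, by = 0.05)) {
  d <- geno$dos[is_biallelic(geno), , drop = FALSE]
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * called)
  maf <- pmin(p, 1 - p)
  h <- hist(maf, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  structure(list(
    histogram = tibble::tibble(lo = utils::head(breaks, -1),
                               hi = breaks[-1], n = h$counts),
    maf = maf,
    n_rare = sum(maf < rare_below),
    rare_fraction = mean(maf < rare_below)),
    class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  cat(sprintf("MAF spectrum over %d biallelic sites; rare (MAF < 0.05): %d (%.1f%%)\n",
              length(x$maf), x$n_rare, 100 * x$rare_fraction))
  invisible(x)
}

#' Rare-variant fraction from externally reported counts
#'
#' @param n_rare,n_total Counts.
#' @return Percentage `100 * n_rare / n_total`.
#' @export
rare_fraction_pct <- function(n_rare, n_total) 100 * n_rare / n_total

#' Partition polymorphic sites by the populations they segregate in
#'
#' A site is polymorphic within a population iff at least two alleles
#' segregate among that population's called genotypes.  Each overall
#' polymorphic site is assigned to the subset of populations in which it is
#' polymorphic; overall-monomorphic sites are excluded, so the subset counts
#' sum exactly to the polymorphic-site total.
#'
#' @param geno Genotype table.
#' @param pop_map Tibble `sample, population`.
#' @return Tibble `subset, n` (subset is a `+`-joined label set), with the
#'   total as attribute `"n_polymorphic"`.
#' @export
polymorphism_partition <- function(geno, pop_map) {
  pm <- match_population_map(geno, pop_map)
  pops <- unique(pm$population)
  seg <- vapply(pops, function(k) {
    d <- geno$dos[, pm$sample[pm$population == k], drop = FALSE]
    alt <- rowSums(d, na.rm = TRUE)
    called <- rowSums(!is.na(d))
    alt > 0 & alt < 2 * called
  }, logical(nrow(geno)))
  any_seg <- rowSums(seg) > 0
  lab <- apply(seg[any_seg, , drop = FALSE], 1, function(z)
    paste(pops[z], collapse = "+"))
  out <- dplyr::count(tibble::tibble(subset = lab), .data$subset, name = "n")
  attr(out, "n_polymorphic") <- sum(any_seg)
  out
}

#' Weir-Cockerham FST
#'
#' Genotype-based variance components of Weir & Cockerham (1984) per
#' polymorphic biallelic site: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals), per-site
#' `theta = a / (a + b + c)`, and the genome-wide weighted estimate
#' `theta_w = sum(a) / sum(a + b + c)` over sites with a positive
#' denominator.  Sites where any included population has fewer than two
#' called genotypes are skipped and counted.
#'
#' @param geno Genotype table.
#' @param pop_map Tibble `sample, population`.
#' @param pops Optional subset of population labels (default: all).
#' @return Object of class `wc_fst` with `by_site` tibble
#'   (`chrom, pos, a, b, c, theta`), `theta_w`, `n_sites_used`,
#'   `n_sites_skipped`.  `tidy()`/`glance()` methods provided.
#' @export
wc_fst <- function(geno, pop_map, pops = NULL) {
  pm <- match_population_map(geno, pop_map)
  if (is.null(pops)) pops <- unique(pm$population)
  if (length(pops) < 2) stop("need at least two populations")
  bi <- is_biallelic(geno)
  d <- geno$dos[bi, pm$sample[pm$population %in% pops], drop = FALSE]
  grp <- pm$population[pm$population %in% pops]
  r <- length(pops)

  n_i <- vapply(pops, function(k)
    rowSums(!is.na(d[, grp == k, drop = FALSE])), numeric(nrow(d)))
  sum_i <- vapply(pops, function(k)
    rowSums(d[, grp == k, drop = FALSE], na.rm = TRUE), numeric(nrow(d)))
  het_i <- vapply(pops, function(k)
    rowSums(d[, grp == k, drop = FALSE] == 1, na.rm = TRUE), numeric(nrow(d)))
  ok <- rowSums(n_i >= 2) == r
  p_i <- sum_i / (2 * n_i)

  nbar <- rowMeans(n_i)
  nsum <- rowSums(n_i)
  nc <- (nsum - rowSums(n_i^2) / nsum) / (r - 1)
  pbar <- rowSums(n_i * p_i) / nsum
  s2 <- rowSums(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(het_i) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  poly <- pbar > 0 & pbar < 1
  use <- ok & poly
  by_site <- tibble::tibble(chrom = geno$chrom[bi][use],
                            pos = geno$pos[bi][use],
                            a = a[use], b = b[use], c = cc[use])
  denom <- by_site$a + by_site$b + by_site$c
  by_site$theta <- ifelse(denom > 0, by_site$a / denom, NA_real_)
  theta_w <- sum(by_site$a[denom > 0]) / sum(denom[denom > 0])
  structure(list(by_site = by_site, theta_w = theta_w,
                 pops = pops, n_sites_used = sum(use),
                 n_sites_skipped = sum(poly & !ok)),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST over %d sites (%s): theta_w = %.4g\n",
              x$n_sites_used, paste(x$pops, collapse = ", "), x$theta_w))
  invisible(x)
}

#' @export
tidy.wc_fst <- function(x, ...) x$by_site

#' @export
glance.wc_fst <- function(x, ...) {
  tibble::tibble(theta_w = x$theta_w, n_sites = x$n_sites_used,
                 n_skipped = x$n_sites_skipped, n_pops = length(x$pops))
}

#' Pairwise population FST
#'
#' @param geno Genotype table.
#' @param pop_map Tibble `sample, population`.
#' @return Tibble `pop1, pop2, theta_w`.
#' @export
wc_fst_pairwise <- function(geno, pop_map) {
  pops <- unique(pop_map$population[pop_map$sample %in% geno_samples(geno)])
  prs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    f <- wc_fst(geno, pop_map, pops = prs[, i])
    tibble::tibble(pop1 = prs[1, i], pop2 = prs[2, i], theta_w = f$theta_w)
  })
}
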