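#' Pairwise linkage disequilibrium within a segment
#'
#' r-squared is the squared Pearson correlation of allele-dosage vectors
#' over samples with both genotypes called (pairwise-complete).  Only
#' biallelic sites enter; sites monomorphic among the used samples are
#' skipped.  Inputs may be unphased: this is the genotype-dosage estimator,
#' not the phased-haplotype EM estimator.
#'
#' @param geno Genotype table.
#' @param chrom Chromosome of the segment (default: first present).
#' @param start,end Segment bounds in bp (1-based inclusive; default: whole
#'   chromosome).
#' @param min_maf Optional MAF filter: sites with MAF strictly below it are
#'   removed before pairing (`NULL` = no filter).
#' @param max_dist Only emit pairs closer than this (bp), default 120 kb —
#'   the upper edge of the standard decay bins.
#' @return Tibble `pos1, pos2, dist, r2` (dist in bp).  A segment with
#'   fewer than two usable sites returns an empty tibble with a warning.
#' @export
pairwise_r2 <- function(geno, chrom = NULL, start = NULL, end = NULL,
                        min_maf = NULL, max_dist = 120e3) {
  if (is.null(chrom)) chrom <- geno$chrom[1]
  g <- geno[geno$chrom == chrom & is_biallelic(geno), ]
  if (!is.null(start)) g <- g[g$pos >= start, ]
  if (!is.null(end)) g <- g[g$pos <= end, ]
  d <- g$dos
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(called, 1))
  keep <- called >= 2 & p > 0 & p < 1
  if (!is.null(min_maf)) keep <- keep & pmin(p, 1 - p) >= min_maf
  g <- g[keep, ]
  if (nrow(g) < 2) {
    warning("segment with fewer than 2 usable sites")
    return(tibble::tibble(pos1 = integer(), pos2 = integer(),
                          dist = integer(), r2 = numeric()))
  }
  r <- suppressWarnings(stats::cor(t(g$dos), use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble::tibble(pos1 = g$pos[idx[, 1]], pos2 = g$pos[idx[, 2]],
                        dist = abs(g$pos[idx[, 2]] - g$pos[idx[, 1]]),
                        r2 = r[idx]^2)
  out <- out[!is.na(out$r2) & out$dist <= max_dist, ]
  dplyr::arrange(out, .data$dist)
}

#' The standard seven LD distance bins (kb)
#'
#' 0-0.2, 0.2-1, 1-2, 2-10, 10-30, 30-60, 60-120 kb.
#' @return Numeric vector of bin edges in kb.
#' @export
ld_bins <- function() c(0, 0.2, 1, 2, 10, 30, 60, 120)

#' Binned LD decay curve
#'
#' Averages pairwise r-squared within inter-site distance classes.
#'
#' @param pairs Pair tibble from [pairwise_r2()] (possibly several segments
#'   row-bound together).
#' @param bins Bin edges in kb (default [ld_bins()]); bins are
#'   left-open/right-closed except the first, which includes 0.
#' @return Object of class `ld_decay`: tibble `bin, lo_kb, hi_kb, mean_r2,
#'   mean_dist_kb, n_pairs`.
#' @export
ld_decay <- function(pairs, bins = ld_bins()) {
  kb <- pairs$dist / 1000
  cut_idx <- cut(kb, breaks = bins, include.lowest = TRUE, right = TRUE)
  curve <- tibble::tibble(kb = kb, r2 = pairs$r2, bin = cut_idx) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(mean_r2 = mean(.data$r2),
                     mean_dist_kb = mean(.data$kb),
                     n_pairs = dplyr::n(), .groups = "drop")
  curve$lo_kb <- utils::head(bins, -1)
  curve$hi_kb <- bins[-1]
  out <- curve[, c("bin", "lo_kb", "hi_kb", "mean_r2", "mean_dist_kb", "n_pairs")]
  class(out) <- c("ld_decay", class(out))
  out
}

#' Distance at which mean LD first decays below a level
#'
#' Linear interpolation of the binned mean r-squared between consecutive bin
#' mean distances; returns the first crossing below `level`.  If the curve
#' starts below `level`, the first bin's mean distance is returned; if it
#' never crosses, `NA` with the sentinel attribute `"not_reached"`.
#'
#' @param curve An `ld_decay` tibble.
#' @param level r-squared level, default 0.20.
#' @return Distance in kb (possibly `NA`).
#' @export
decay_distance <- function(curve, level = 0.20) {
  cv <- curve[curve$n_pairs > 0, ]
  x <- cv$mean_dist_kb
  y <- cv$mean_r2
  if (!length(y)) return(NA_real_)
  if (y[1] < level) return(x[1])
  below <- which(y < level)
  if (!length(below)) {
    out <- NA_real_
    attr(out, "not_reached") <- TRUE
    return(out)
  }
  i <- below[1]
  x[i - 1] + (y[i - 1] - level) / (y[i - 1] - y[i]) * (x[i] - x[i - 1])
}

#' LD pruning in marker windows
#'
#' Slides over each chromosome in non-overlapping windows of `window`
#' consecutive markers; within a window, every pair with r-squared above
#' `r2_threshold` loses its later-positioned member (deterministic
#' tie-break).  Monomorphic or missing-heavy sites never force removals of
#' others (their correlations are `NA`).
#'
#' @param geno Genotype table.
#' @param window Markers per window, default 50.
#' @param r2_threshold Removal threshold (strict), default 0.95.
#' @return Integer vector of retained row indices into `geno`.
#' @export
ld_prune <- function(geno, window = 50, r2_threshold = 0.95) {
  keep <- rep(TRUE, nrow(geno))
  for (ch in unique(geno$chrom)) {
    rows <- which(geno$chrom == ch & is_biallelic(geno))
    rows <- rows[order(geno$pos[rows])]
    starts <- seq(1, length(rows), by = window)
    for (s in starts) {
      w <- rows[s:min(s + window - 1, length(rows))]
      if (length(w) < 2) next
      r2 <- suppressWarnings(stats::cor(t(geno$dos[w, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))^2
      alive <- rep(TRUE, length(w))
      for (i in seq_len(length(w) - 1)) {
        if (!alive[i]) next
        for (j in (i + 1):length(w)) {
          if (alive[j] && !is.na(r2[i, j]) && r2[i, j] > r2_threshold)
            alive[j] <- FALSE
        }
      }
      keep[w[!alive]] <- FALSE
    }
  }
  which(keep)
}

#' PCA of a (pruned) genotype matrix
#'
#' Dosages are centered per site and scaled by `sqrt(p(1-p))`; missing
#' values are replaced by the site mean; components come from the
#' eigendecomposition of the sample covariance, ordered by decreasing
#' variance.
#'
#' @param geno Genotype table.
#' @param markers Optional retained row indices (e.g. from [ld_prune()]).
#' @param n_comp Components to keep, default 10.
#' @return Object of class `geno_pca`: `scores` tibble (`sample`, `PC1`..),
#'   `var_frac`, `n_markers`.
#' @export
pca_genotypes <- function(geno, markers = NULL, n_comp = 10) {
  g <- if (is.null(markers)) geno else geno[markers, ]
  d <- g$dos[is_biallelic(g), , drop = FALSE]
  called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(called, 1))
  use <- called >= 2 & p > 0 & p < 1
  d <- d[use, , drop = FALSE]
  p <- p[use]
  mu <- 2 * p
  Z <- (d - mu) / sqrt(p * (1 - p))
  Z[is.na(Z)] <- 0
  n_comp <- min(n_comp, ncol(Z) - 1, nrow(Z))
  sv <- svd(t(Z) / sqrt(nrow(Z)), nu = n_comp, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_comp)], n_comp)
  colnames(scores) <- paste0("PC", seq_len(n_comp))
  out <- structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = colnames(d)),
                              tibble::as_tibble(scores)),
    var_frac = sv$d[seq_len(n_comp)]^2 / sum(sv$d^2),
    n_markers = nrow(d)), class = "geno_pca")
  out
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA on %d markers; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_markers, 100 * x$var_frac[1],
              100 * ifelse(length(x$var_frac) > 1, x$var_frac[2], NA)))
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @export
glance.geno_pca <- function(x, ...)
  tibble::tibble(n_markers = x$n_markers, var_pc1 = x$var_frac[1],
                 var_pc2 = x$var_frac[2])
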