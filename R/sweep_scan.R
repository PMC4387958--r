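#' Physical-to-map position conversion
#'
#' In the absence of a genetic map, physical positions are converted at a
#' constant rate (default 1 cM per Mb).
#'
#' @param bp Position(s) in bp.
#' @param rate_cm_per_mb Map rate, cM/Mb.
#' @return Map position(s) in cM.
#' @examples
#' physical_to_map(1e6)    # 1 cM
#' physical_to_map(2500)   # 0.0025 cM
#' @export
physical_to_map <- function(bp, rate_cm_per_mb = 1) bp * rate_cm_per_mb / 1e6

#' XP-CLR scan configuration
#'
#' Defaults are the canonical scan settings: grid points every 2500 bp, at
#' most 250 variants per 0.5 cM window (0.25 cM each side), down-weighting
#' of reference-group variants correlated above r-squared 0.95, score
#' estimation on overlapped segments of at most 27 cM with 2 cM overlaps and
#' 1 cM trimmed from each overlapped edge, 1 cM per Mb, and the top 0.1% of
#' grid scores defining candidate regions.
#'
#' @param grid_spacing Grid spacing, bp.
#' @param window_cm Total window size, cM (half each side of the grid
#'   point).
#' @param max_snps Maximum variants per window (deterministic even-spaced
#'   thinning beyond it).
#' @param r2_downweight Reference-group correlation threshold for
#'   down-weighting.
#' @param seg_cm,overlap_cm,trim_cm Segment assembly rules (cM).
#' @param rate_cm_per_mb Map rate.
#' @param s_grid Selection-strength search grid (dimensionless scale of the
#'   escape curve, in Morgans); logarithmic, 10 points per decade.
#' @param omega Drift parameter of the neutral frequency model; `NULL` =
#'   estimate genome-wide by method of moments before scanning.
#' @param omega_thin Thinning step (in SNPs) for the omega estimate.
#' @param top_frac Fraction of grid points called as candidate regions.
#' @return List of class `xpclr_config`.
#' @export
xpclr_config <- function(grid_spacing = 2500, window_cm = 0.5, max_snps = 250,
                         r2_downweight = 0.95, seg_cm = 27, overlap_cm = 2,
                         trim_cm = 1, rate_cm_per_mb = 1,
                         s_grid = 10^seq(-4, -1, by = 0.1),
                         omega = NULL, omega_thin = 10, top_frac = 0.001) {
  stopifnot(grid_spacing > 0, window_cm > 0, max_snps >= 1,
            overlap_cm < seg_cm, trim_cm >= 0, all(s_grid > 0))
  structure(list(grid_spacing = grid_spacing, window_cm = window_cm,
                 max_snps = max_snps, r2_downweight = r2_downweight,
                 seg_cm = seg_cm, overlap_cm = overlap_cm, trim_cm = trim_cm,
                 rate_cm_per_mb = rate_cm_per_mb, s_grid = s_grid,
                 omega = omega, omega_thin = omega_thin,
                 top_frac = top_frac),
            class = "xpclr_config")
}

#' Chromosome segmentation for segment-wise score assembly
#'
#' Segments of at most `seg_cm` step by `seg_cm - overlap_cm`; each
#' segment's kept span excludes `trim_cm` at every *overlapped* edge
#' (chromosome start and end edges are never trimmed).  The kept spans tile
#' the chromosome exactly.
#'
#' @param chrom_length_cm Chromosome length in cM.
#' @param seg_cm,overlap_cm,trim_cm Rules (defaults 27, 2, 1).
#' @return Tibble `segment, lo, hi, keep_lo, keep_hi` (cM); kept spans are
#'   half-open `[keep_lo, keep_hi)` except the last, which is closed.
#' @export
make_segments <- function(chrom_length_cm, seg_cm = 27, overlap_cm = 2,
                          trim_cm = 1) {
  L <- chrom_length_cm
  step <- seg_cm - overlap_cm
  starts <- 0
  while (utils::tail(starts, 1) + step < L) starts <- c(starts, utils::tail(starts, 1) + step)
  n <- length(starts)
  lo <- starts
  hi <- pmin(starts + seg_cm, L)
  keep_lo <- lo + ifelse(seq_len(n) > 1, trim_cm, 0)
  keep_hi <- hi - ifelse(seq_len(n) < n, trim_cm, 0)
  tibble::tibble(segment = seq_len(n), lo = lo, hi = hi,
                 keep_lo = keep_lo, keep_hi = keep_hi)
}

#' Select and thin window SNPs around a grid point
#'
#' SNPs within half the window of the grid point; if more than `max_snps`,
#' a deterministic evenly spaced (by map order) subset is kept.
#'
#' @param map_cm SNP map positions (cM, sorted).
#' @param center_cm Grid-point map position.
#' @param window_cm Total window size (cM).
#' @param max_snps Cap.
#' @return Integer indices into `map_cm`.
#' @export
select_window_snps <- function(map_cm, center_cm, window_cm = 0.5,
                               max_snps = 250) {
  idx <- which(abs(map_cm - center_cm) <= window_cm / 2)
  if (length(idx) > max_snps)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_snps)))]
  idx
}

#' Correlation-cluster down-weights
#'
#' Single-linkage clusters of window SNPs whose reference-group dosage
#' r-squared exceeds the threshold; each SNP's weight is the reciprocal of
#' its cluster size, so a block of k near-duplicate SNPs contributes like
#' one.
#'
#' @param dos_ref Reference-group dosage matrix, SNPs x samples.
#' @param r2_threshold Clustering threshold, default 0.95.
#' @return Numeric weights (1/cluster size) per SNP.
#' @export
snp_weights <- function(dos_ref, r2_threshold = 0.95) {
  m <- nrow(dos_ref)
  if (m == 1) return(1)
  r2 <- suppressWarnings(stats::cor(t(dos_ref),
                                    use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  edges <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(m), find, 0L)
  1 / as.numeric(table(root)[as.character(root)])
}

# Truncated-normal likelihood of an observed frequency in [0,1].
.tn_lik <- function(x, mu, v) {
  v <- pmax(v, 1e-6)
  s <- sqrt(v)
  z <- pmax(stats::pnorm(1, mu, s) - stats::pnorm(0, mu, s), 1e-12)
  stats::dnorm(x, mu, s) / z
}

#' XP-CLR composite likelihood score for one window
#'
#' Models the test-population allele frequency around the reference
#' frequency `p2`.  Neutrally, `p1 ~ N(p2, omega p2 (1 - p2))` truncated to
#' \[0,1\], with binomial sampling noise folded in as an additional normal
#' variance term.  Under a sweep of strength `s` at map distance `d`, a
#' linked lineage escapes with probability `c(d, s) = 1 - exp(-d/s)` (d in
#' Morgans); with probability `1 - c` it hitchhikes: the frequency is pulled
#' to `1 - c + c p2` if the allele rode the sweeping haplotype (probability
#' `p2`) or to `c p2` otherwise, with the drift variance compressed by
#' `c^2`.  The score is twice the maximum over the `s` grid of the
#' weighted sum of per-SNP log-likelihood ratios, floored at 0.
#'
#' @param m Alternate-allele counts in the test population (per SNP).
#' @param n_chr Called chromosome counts in the test population.
#' @param p2 Reference-population allele frequencies (clamped internally).
#' @param w Per-SNP down-weights.
#' @param d_cm Map distance of each SNP from the grid point (cM).
#' @param omega Drift parameter.
#' @param s_grid Selection-strength grid (Morgans).
#' @return List `score`, `s_hat`, `n_snps`.
#' @export
xpclr_score <- function(m, n_chr, p2, w, d_cm, omega,
                        s_grid = xpclr_config()$s_grid) {
  ns <- length(m)
  if (ns == 0) return(list(score = NA_real_, s_hat = NA_real_, n_snps = 0L))
  p2c <- pmin(pmax(p2, 1 / (2 * max(n_chr) + 2)), 1 - 1 / (2 * max(n_chr) + 2))
  phat <- m / n_chr
  base_drift <- omega * p2c * (1 - p2c)
  v_neut <- base_drift + p2c * (1 - p2c) / n_chr
  lnL0 <- log(pmax(.tn_lik(phat, p2c, v_neut), 1e-300))

  d_m <- pmax(d_cm, 0) / 100   # cM -> Morgans
  cs <- 1 - exp(-outer(d_m, 1 / s_grid))        # snps x s
  mu1 <- 1 - cs + cs * p2c
  mu2 <- cs * p2c
  mu1v <- pmin(pmax(mu1, 1 / (2 * n_chr)), 1 - 1 / (2 * n_chr))
  mu2v <- pmin(pmax(mu2, 1 / (2 * n_chr)), 1 - 1 / (2 * n_chr))
  v1 <- cs^2 * base_drift + mu1v * (1 - mu1v) / n_chr
  v2 <- cs^2 * base_drift + mu2v * (1 - mu2v) / n_chr
  Ls <- p2c * .tn_lik(phat, mu1, v1) + (1 - p2c) * .tn_lik(phat, mu2, v2)
  lnLR <- log(pmax(Ls, 1e-300)) - lnL0
  per_s <- colSums(w * lnLR)
  best <- which.max(per_s)
  list(score = max(0, 2 * per_s[best]), s_hat = s_grid[best],
       n_snps = as.integer(ns))
}

# r2 > threshold edges among segment SNPs within window reach, computed in
# overlapping chunks so only near pairs are visited.
.segment_edges <- function(dos_ref, map_cm, window_cm, r2_threshold,
                           chunk = 400) {
  m <- nrow(dos_ref)
  if (m < 2) return(matrix(integer(), 0, 2))
  step <- chunk %/% 2
  out <- list()
  starts <- unique(pmin(seq(1, max(1, m - 1), by = step), m))
  for (s in starts) {
    e <- min(s + chunk - 1, m)
    if (e - s < 1) next
    r2 <- suppressWarnings(stats::cor(t(dos_ref[s:e, , drop = FALSE]),
                                      use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    idx <- which(upper.tri(r2) & r2 > r2_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      gi <- idx + s - 1L
      near <- abs(map_cm[gi[, 2]] - map_cm[gi[, 1]]) <= window_cm
      out[[length(out) + 1L]] <- gi[near, , drop = FALSE]
    }
    if (e == m) break
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  ed <- do.call(rbind, out)
  ed[!duplicated(paste(ed[, 1], ed[, 2])), , drop = FALSE]
}

# cluster down-weights for a window given precomputed edges (global indices)
.weights_from_edges <- function(idx, edges) {
  k <- length(idx)
  if (k == 1 || nrow(edges) == 0) return(rep(1, k))
  inw <- edges[, 1] %in% idx & edges[, 2] %in% idx
  if (!any(inw)) return(rep(1, k))
  lookup <- integer(max(idx)); lookup[idx] <- seq_len(k)
  e <- cbind(lookup[edges[inw, 1]], lookup[edges[inw, 2]])
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(e))) {
    ri <- find(e[r, 1]); rj <- find(e[r, 2])
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(k), find, 0L)
  1 / as.numeric(table(root)[as.character(root)])
}

#' Genome-wide XP-CLR scan
#'
#' Runs the composite-likelihood sweep scan of one test population against
#' the pooled remaining populations: biallelic stage-filtered sites supply
#' allele counts; the drift parameter is estimated genome-wide before
#' scanning; scores are computed per 27 cM segment and assembled from the
#' trimmed kept spans.
#'
#' @param geno Genotype table.
#' @param pop_map Tibble `sample, population`.
#' @param test_pop Test population label.
#' @param config An [xpclr_config()].
#' @param ref_pops Reference population labels (default: all others,
#'   pooled).
#' @param chrom_lengths Named bp lengths (default: max site position per
#'   chromosome).
#' @return Object of class `xpclr_scan`: `track` tibble (`chrom, pos, cm,
#'   score, s_hat, n_snps, segment`), `omega`, `config`, `test_pop`.
#' @export
xpclr_scan <- function(geno, pop_map, test_pop, config = xpclr_config(),
                       ref_pops = NULL, chrom_lengths = NULL) {
  pm <- match_population_map(geno, pop_map, allow_subset = TRUE)
  if (!test_pop %in% pm$population) stop("unknown test population: ", test_pop)
  if (is.null(ref_pops)) ref_pops <- setdiff(unique(pm$population), test_pop)
  bi <- is_biallelic(geno)
  g <- geno[bi, ]
  test_s <- pm$sample[pm$population == test_pop]
  ref_s <- pm$sample[pm$population %in% ref_pops]
  d_test <- g$dos[, test_s, drop = FALSE]
  d_ref <- g$dos[, ref_s, drop = FALSE]

  n1 <- 2 * rowSums(!is.na(d_test))
  m1 <- rowSums(d_test, na.rm = TRUE)
  n2 <- 2 * rowSums(!is.na(d_ref))
  p2 <- rowSums(d_ref, na.rm = TRUE) / pmax(n2, 1)
  usable <- n1 >= 4 & n2 >= 4 & p2 > 0 & p2 < 1
  g <- g[usable, ]
  d_ref <- d_ref[usable, , drop = FALSE]
  m1 <- m1[usable]; n1 <- n1[usable]; n2 <- n2[usable]; p2 <- p2[usable]

  omega <- config$omega
  if (is.null(omega)) {
    th <- seq(1, nrow(g), by = config$omega_thin)
    p1h <- m1[th] / n1[th]
    num <- (p1h - p2[th])^2 -
      p2[th] * (1 - p2[th]) * (1 / n1[th] + 1 / n2[th])
    omega <- max(mean(num / (p2[th] * (1 - p2[th]))), 1e-4)
  }

  rate <- config$rate_cm_per_mb
  radius_cm <- config$window_cm / 2
  tracks <- list()
  for (ch in unique(g$chrom)) {
    rows <- which(g$chrom == ch)
    len_bp <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(g$pos[rows])
    len_cm <- physical_to_map(len_bp, rate)
    segs <- make_segments(len_cm, config$seg_cm, config$overlap_cm, config$trim_cm)
    map_cm_all <- physical_to_map(g$pos[rows], rate)

    seg_scores <- vector("list", nrow(segs))
    for (si in seq_len(nrow(segs))) {
      in_seg <- map_cm_all >= segs$lo[si] & map_cm_all <= segs$hi[si]
      sr <- rows[in_seg]
      map_cm <- map_cm_all[in_seg]
      grid_bp <- seq(config$grid_spacing,
                     floor(segs$hi[si] / rate * 1e6),
                     by = config$grid_spacing)
      grid_bp <- grid_bp[physical_to_map(grid_bp, rate) >= segs$lo[si]]
      grid_cm <- physical_to_map(grid_bp, rate)
      if (!length(grid_bp)) { seg_scores[[si]] <- NULL; next }
      edges <- .segment_edges(g$dos[sr, ref_s, drop = FALSE], map_cm,
                              config$window_cm, config$r2_downweight)
      sc <- sh <- rep(NA_real_, length(grid_bp))
      nsn <- integer(length(grid_bp))
      for (gi in seq_along(grid_bp)) {
        idx <- select_window_snps(map_cm, grid_cm[gi], config$window_cm,
                                  config$max_snps)
        nsn[gi] <- length(idx)
        if (!length(idx)) next
        w <- .weights_from_edges(idx, edges)
        res <- xpclr_score(m1[sr[idx]], n1[sr[idx]], p2[sr[idx]],
                           w, abs(map_cm[idx] - grid_cm[gi]), omega,
                           config$s_grid)
        sc[gi] <- res$score; sh[gi] <- res$s_hat
      }
      seg_scores[[si]] <- tibble::tibble(chrom = ch, pos = as.integer(grid_bp),
                                         cm = grid_cm, score = sc, s_hat = sh,
                                         n_snps = nsn, segment = segs$segment[si])
    }
    tracks[[ch]] <- assemble_scan(seg_scores, segs)
  }
  track <- dplyr::bind_rows(tracks)
  structure(list(track = track, omega = omega, config = config,
                 test_pop = test_pop, ref_pops = ref_pops),
            class = "xpclr_scan")
}

#' Assemble per-segment score tracks into one chromosome track
#'
#' Keeps, from each segment, only grid points inside its kept span
#' (half-open, closed for the last segment), concatenates them, and checks
#' that every grid point appears exactly once.
#'
#' @param seg_scores List of per-segment grid tibbles (`pos, cm, score,
#'   ...`), in segment order.
#' @param segments Segment table from [make_segments()].
#' @return One tibble per chromosome with segment provenance.
#' @export
assemble_scan <- function(seg_scores, segments) {
  n <- nrow(segments)
  kept <- purrr::map_dfr(seq_len(n), function(si) {
    ss <- seg_scores[[si]]
    if (is.null(ss) || !nrow(ss)) return(NULL)
    inside <- ss$cm >= segments$keep_lo[si] &
      (if (si < n) ss$cm < segments$keep_hi[si] else ss$cm <= segments$keep_hi[si])
    ss[inside, ]
  })
  if (anyDuplicated(kept$pos))
    stop("assembly error: grid point covered by more than one kept span")
  dplyr::arrange(kept, .data$pos)
}

#' Call candidate sweep regions from a scan track
#'
#' The threshold is the score of the `ceiling(top_frac * n)`-th highest
#' defined grid point; ties at the threshold are included.  Regions are
#' maximal runs of above-threshold grid points, tolerating gaps of up to
#' `gap` grid steps.
#'
#' @param scan An `xpclr_scan` (or its `track` tibble).
#' @param top_frac Fraction of grid points above threshold, default 0.001.
#' @param gap Gap tolerance in grid steps, default 1.
#' @return Tibble `region, chrom, start, end, n_points, peak_score,
#'   peak_pos`; threshold in attribute `"threshold"`.
#' @export
call_regions <- function(scan, top_frac = 0.001, gap = 1) {
  track <- if (inherits(scan, "xpclr_scan")) scan$track else scan
  def <- track[!is.na(track$score), ]
  if (!nrow(def)) stop("no defined grid scores")
  if (length(unique(def$score)) == 1)
    stop("degenerate track: all grid scores are equal")
  k <- max(1L, ceiling(top_frac * nrow(def)))
  thr <- sort(def$score, decreasing = TRUE)[k]
  above <- def[def$score >= thr, ]
  spacing <- min(diff(sort(unique(track$pos))))
  out <- above |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(new_run = c(TRUE, diff(.data$pos) > (gap + 1) * spacing),
                  run = cumsum(.data$new_run)) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     n_points = dplyr::n(), peak_score = max(.data$score),
                     peak_pos = .data$pos[which.max(.data$score)],
                     .groups = "drop") |>
    dplyr::select(-"run")
  out$region <- seq_len(nrow(out))
  attr(out, "threshold") <- thr
  out[, c("region", "chrom", "start", "end", "n_points", "peak_score", "peak_pos")]
}

#' Map candidate regions onto genes
#'
#' A gene is hit iff its interval extended by `flank` bp on both sides
#' intersects a region; the overlap length of the flanked interval with the
#' region is reported.
#'
#' @param regions Region tibble from [call_regions()].
#' @param genes Gene table (`gene_id, chrom, start, end`, 1-based
#'   inclusive), e.g. from [read_gene_table()].
#' @param flank Flank size, default 1500 bp.
#' @return Tibble `gene_id, region, chrom, overlap_bp`.
#' @export
map_genes <- function(regions, genes, flank = 1500) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    gs <- genes[genes$chrom == r$chrom &
                  genes$start - flank <= r$end &
                  genes$end + flank >= r$start, ]
    if (!nrow(gs)) return(NULL)
    tibble::tibble(gene_id = gs$gene_id, region = r$region, chrom = r$chrom,
                   overlap_bp = pmin(gs$end + flank, r$end) -
                     pmax(gs$start - flank, r$start) + 1L)
  })
}

#' Equalize population sample sizes by random subsampling
#'
#' Populations larger than `target` are subsampled uniformly without
#' replacement; smaller ones are untouched.
#'
#' @param pop_map Tibble `sample, population`.
#' @param target Target size per population.
#' @param seed Optional RNG seed for a reproducible subset.
#' @return Subsampled population map.
#' @export
equalize_samples <- function(pop_map, target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop_map |>
    dplyr::group_by(.data$population) |>
    dplyr::slice_sample(n = target) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$sample, pop_map$sample))
}

#' @export
print.xpclr_scan <- function(x, ...) {
  cat(sprintf("XP-CLR scan: %s vs pooled {%s}; %d grid points; omega = %.3g; max score %.1f\n",
              x$test_pop, paste(x$ref_pops, collapse = ", "),
              nrow(x$track), x$omega, max(x$track$score, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.xpclr_scan <- function(x, ...) x$track

#' @export
glance.xpclr_scan <- function(x, ...) {
  tibble::tibble(test_pop = x$test_pop, n_grid = nrow(x$track),
                 omega = x$omega,
                 max_score = max(x$track$score, na.rm = TRUE),
                 peak_pos = x$track$pos[which.max(x$track$score)])
}
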