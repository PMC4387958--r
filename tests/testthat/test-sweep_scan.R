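test_that("physical positions convert to map positions at 1 cM/Mb", {
  expect_equal(physical_to_map(1e6), 1)
  expect_equal(physical_to_map(0), 0)
  expect_equal(physical_to_map(2500), 0.0025)
  expect_equal(physical_to_map(1e6, rate_cm_per_mb = 2), 2)
})

test_that("segment assembly follows the 27/2/1 cM rules and tiles exactly", {
  s50 <- make_segments(50)
  expect_equal(s50$lo, c(0, 25))
  expect_equal(s50$hi, c(27, 50))
  expect_equal(s50$keep_lo, c(0, 26))
  expect_equal(s50$keep_hi, c(26, 50))

  s20 <- make_segments(20)            # shorter than one segment: untrimmed
  expect_equal(nrow(s20), 1L)
  expect_equal(c(s20$keep_lo, s20$keep_hi), c(0, 20))

  s52 <- make_segments(52)            # three segments, middle trimmed twice
  expect_equal(nrow(s52), 3L)
  expect_equal(s52$keep_lo, c(0, 26, 51))
  expect_equal(s52$keep_hi, c(26, 51, 52))

  for (L in c(20, 50, 52, 100)) {
    s <- make_segments(L)
    expect_equal(s$keep_lo[1], 0)
    expect_equal(s$keep_hi[nrow(s)], L)
    if (nrow(s) > 1)
      expect_equal(s$keep_lo[-1], s$keep_hi[-nrow(s)])   # no gap, no overlap
  }
})

test_that("window SNP selection caps at 250 with even thinning", {
  map <- seq(0, 1, length.out = 500)
  idx <- select_window_snps(map, 0.5, window_cm = 0.5, max_snps = 250)
  expect_length(idx, 250)
  expect_true(all(abs(map[idx] - 0.5) <= 0.25))
  few <- select_window_snps(map, 0.5, window_cm = 0.02, max_snps = 250)
  expect_true(all(abs(map[few] - 0.5) <= 0.01))
  expect_equal(few, which(abs(map - 0.5) <= 0.01))
})

test_that("correlation clusters down-weight to one over cluster size", {
  set.seed(2)
  a <- rbinom(40, 2, 0.5)
  b <- rbinom(40, 2, 0.5)
  dos <- rbind(a, a, a, b)         # three duplicates plus one independent
  w <- snp_weights(dos)
  expect_equal(w, c(1 / 3, 1 / 3, 1 / 3, 1))
  ind <- rbind(a, b, rbinom(40, 2, 0.5))
  expect_equal(snp_weights(ind), rep(1, 3))
})

test_that("the XP-CLR score is near zero without differentiation", {
  set.seed(21)
  scores <- vapply(1:100, function(i) {
    p2 <- runif(40, 0.1, 0.9)
    m <- rbinom(40, 28, p2)
    xpclr_score(m, rep(28, 40), p2, rep(1, 40),
                d_cm = runif(40, 0, 0.25), omega = 0.05)$score
  }, numeric(1))
  expect_lt(median(scores), 0.5)
  expect_true(all(scores >= 0))
})

test_that("the composite score is linear in the weights before maximizing", {
  set.seed(4)
  p2 <- runif(30, 0.4, 0.6)
  m <- rep(28L, 30)                # test population fixed: strong signal
  w <- runif(30, 0.5, 1)
  d <- runif(30, 0, 0.005)         # tight around the grid point
  s_one <- 0.003                   # single-point s grid: no max involved
  a <- xpclr_score(m, rep(28, 30), p2, w, d, omega = 0.05, s_grid = s_one)
  b <- xpclr_score(m, rep(28, 30), p2, 2 * w, d, omega = 0.05, s_grid = s_one)
  expect_gt(a$score, 0)
  expect_equal(b$score, 2 * a$score, tolerance = 1e-10)
  # and against a direct sum over two halves of the window
  h1 <- xpclr_score(m[1:15], rep(28, 15), p2[1:15], w[1:15], d[1:15],
                    omega = 0.05, s_grid = s_one)
  h2 <- xpclr_score(m[16:30], rep(28, 15), p2[16:30], w[16:30], d[16:30],
                    omega = 0.05, s_grid = s_one)
  expect_equal(a$score, h1$score + h2$score, tolerance = 1e-10)
})

test_that("assembled tracks take each grid point from its kept span", {
  segs <- make_segments(50)
  mk <- function(lo, hi, seg, score) {
    bp <- seq(max(2500, ceiling(lo * 1e6 / 2500) * 2500), hi * 1e6, by = 2500)
    tibble::tibble(chrom = "c", pos = as.integer(bp), cm = bp / 1e6,
                   score = score, s_hat = 0.01, n_snps = 5L, segment = seg)
  }
  seg_scores <- list(mk(0, 27, 1L, 1), mk(25, 50, 2L, 2))
  track <- assemble_scan(seg_scores, segs)
  expect_equal(nrow(track), length(seq(2500, 50e6, by = 2500)))
  expect_false(anyDuplicated(track$pos) > 0)
  # in the overlap, scores before 26 cM come from segment 1, after from 2
  expect_true(all(track$score[track$cm >= 25 & track$cm < 26] == 1))
  expect_true(all(track$score[track$cm >= 26 & track$cm <= 27] == 2))
  # single segment: identity
  s1 <- make_segments(20)
  t1 <- assemble_scan(list(mk(0, 20, 1L, 3)), s1)
  expect_equal(nrow(t1), length(seq(2500, 20e6, by = 2500)))
})

test_that("region calling takes the top fraction with gap tolerance", {
  set.seed(8)
  n <- 10000
  track <- tibble::tibble(chrom = "c", pos = seq_len(n) * 2500L,
                          cm = seq_len(n) * 0.0025,
                          score = abs(rnorm(n)), s_hat = 0.01,
                          n_snps = 10L, segment = 1L)
  # two well-separated planted peaks
  track$score[3001:3005] <- 50
  track$score[7001:7005] <- 60
  reg <- call_regions(track)
  expect_equal(nrow(reg), 2L)
  expect_equal(sum(reg$n_points), 10L)          # ceiling(0.001 * 10000)
  expect_equal(reg$peak_score, c(50, 60))

  flat <- dplyr::mutate(track, score = 1)
  expect_error(call_regions(flat), "degenerate")
})

test_that("gene mapping honours the 1500 bp flanks", {
  regions <- tibble::tibble(region = 1:2, chrom = "c",
                            start = c(7400L, 100000L), end = c(9000L, 101000L),
                            n_points = 2L, peak_score = 10, peak_pos = 7400L)
  genes <- tibble::tibble(gene_id = c("near", "far", "inside"),
                          chrom = "c",
                          start = c(5000L, 40000L, 100100L),
                          end = c(6000L, 41000L, 100200L))
  hits <- map_genes(regions, genes)
  expect_setequal(hits$gene_id, c("near", "inside"))
  # flanked end of "near" is 7500, overlapping the region start 7400
  expect_equal(hits$overlap_bp[hits$gene_id == "near"], 101L)
  # flanked gene spans past both region edges; overlap is the whole region
  expect_equal(hits$overlap_bp[hits$gene_id == "inside"], 1001L)
  none <- map_genes(regions[1, ], genes[2, ])
  expect_equal(nrow(none), 0L)
})

test_that("sample equalization subsamples reproducibly", {
  pm <- tibble::tibble(sample = sprintf("s%02d", 1:44),
                       population = rep(c("Black", "Draa", "Northern"),
                                        c(22, 14, 8)))
  eq <- equalize_samples(pm, 14, seed = 5)
  expect_equal(as.integer(table(eq$population)[c("Black", "Draa", "Northern")]),
               c(14L, 14L, 8L))
  expect_identical(equalize_samples(pm, 14, seed = 5), eq)
  expect_equal(nrow(equalize_samples(pm, 22, seed = 1)), 44L)
})

test_that("the scan localizes an injected sweep on a small chromosome", {
  cfg <- sim_config(samples = c(Black = 14, Draa = 14, Northern = 8),
                    chromosomes = c(chr1 = 4e6), n_sites = 2500,
                    f_div = 0.0025, n_founders = 24, recomb_rate = 1e-4,
                    seed = 301,
                    sweeps = list(list(chrom = "chr1", pos = 2e6,
                                       pop = "Black", sigma_s = 1e5,
                                       final_freq = 1)))
  sim <- simulate_genotypes(cfg)
  scan <- xpclr_scan(sim$geno, sim$pop_map, "Black")
  pk <- scan$track$pos[which.max(scan$track$score)]
  expect_lt(abs(pk - sim$sweeps[[1]]$pos), 5e5)    # within 0.5 cM
  expect_true(all(scan$track$score >= 0, na.rm = TRUE))
  # score monotonicity in the sweep's final frequency (median over grid
  # points near the sweep)
  near <- abs(scan$track$pos - sim$sweeps[[1]]$pos) < 2e5
  strong <- median(scan$track$score[near], na.rm = TRUE)
  cfg_w <- cfg
  cfg_w$sweeps[[1]]$final_freq <- 0.5
  sim_w <- simulate_genotypes(cfg_w)
  scan_w <- xpclr_scan(sim_w$geno, sim_w$pop_map, "Black")
  weak <- median(scan_w$track$score[near], na.rm = TRUE)
  expect_gte(strong, weak)
})
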