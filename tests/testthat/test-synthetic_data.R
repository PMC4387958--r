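test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(samples = c(A = 5, B = 5), chromosomes = c(chr1 = 2e5),
                    n_sites = 100, f_div = 0.05, seed = 11)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$geno$dos, s2$geno$dos)
  expect_identical(s1$haplotypes, s2$haplotypes)
  e1 <- emit_caller_vcfs(s1)
  e2 <- emit_caller_vcfs(s2)
  expect_identical(e1$calls[["ug"]], e2$calls[["ug"]])
  m1 <- simulate_mtdna(ref_length = 500, n_seq = 5, hv_window = c(101, 150), seed = 3)
  m2 <- simulate_mtdna(ref_length = 500, n_seq = 5, hv_window = c(101, 150), seed = 3)
  expect_identical(m1$alignment, m2$alignment)
})

test_that("degenerate configurations behave as documented", {
  expect_error(sim_config(seed = 1, f_div = 0), "degenerate")
  expect_error(sim_config(samples = c(A = 2), seed = NULL), "seed")
  expect_error(sim_config(seed = 1, sweeps = list(
    list(chrom = "chr1", pos = 1e9, pop = "Black", sigma_s = 1e4,
         final_freq = 1))), "outside")
  # one founder, no recombination: every individual in a population identical
  cfg <- sim_config(samples = c(A = 6, B = 6), chromosomes = c(chr1 = 1e5),
                    n_sites = 50, f_div = 0.3, n_founders = 1,
                    recomb_rate = 0, seed = 4)
  sim <- simulate_genotypes(cfg)
  dA <- sim$geno$dos[, sim$pop_map$sample[sim$pop_map$population == "A"]]
  expect_true(all(dA == dA[, 1]))
})

test_that("realized FST tracks the Balding-Nichols divergence parameter", {
  cfg <- sim_config(samples = c(A = 20, B = 20), chromosomes = c(chr1 = 5e6),
                    n_sites = 5000, f_div = 0.5, n_founders = 60, seed = 8)
  sim <- simulate_genotypes(cfg)
  est <- wc_fst(sim$geno, sim$pop_map)$theta_w
  # oracle: the same estimator evaluated site by site with the scalar
  # textbook implementation on the drawn genotype matrix
  bi <- is_biallelic(sim$geno)
  grp <- sim$pop_map$population
  comp <- vapply(which(bi), function(i)
    wc_site_oracle(sim$geno$dos[i, ], grp), numeric(3))
  keep <- colSums(comp) > 0 & is.finite(colSums(comp))
  oracle <- sum(comp[1, keep]) / sum(colSums(comp)[keep])
  expect_equal(est, oracle, tolerance = 0.05)
  expect_lt(abs(est - 0.5), 0.05)
})

test_that("the SFS shifts toward rare variants as the shape is skewed", {
  rare <- vapply(c(0.15, 0.4, 0.9), function(sh) {
    cfg <- sim_config(samples = c(A = 20, B = 20), chromosomes = c(chr1 = 2e6),
                      n_sites = 4000, f_div = 0.01, n_founders = Inf,
                      sfs_shape = sh, seed = 21)
    maf_spectrum(simulate_genotypes(cfg)$geno)$rare_fraction
  }, numeric(1))
  expect_true(all(diff(rare) < 0))
})

test_that("mean r2 is non-increasing across distance bins", {
  cfg <- sim_config(samples = c(A = 22, B = 14, C = 8),
                    chromosomes = c(chr1 = 1e6), n_sites = 5000,
                    f_div = 0.0025, n_founders = 6, recomb_rate = 5e-4,
                    seed = 5)
  sim <- simulate_genotypes(cfg)
  cv <- ld_decay(pairwise_r2(sim$geno))
  ok <- cv$n_pairs > 100
  se <- 2 / sqrt(cv$n_pairs[ok])   # generous sampling-error allowance
  expect_true(all(diff(cv$mean_r2[ok]) <= utils::head(se, -1)))
})

test_that("sweep injection fixes the site in the target population only", {
  cfg <- sim_config(samples = c(A = 10, B = 10), chromosomes = c(chr1 = 1e6),
                    n_sites = 400, f_div = 0.01, n_founders = 12, seed = 14)
  sim0 <- simulate_genotypes(cfg)
  sim <- inject_sweep(sim0, "chr1", 5e5, "A", sigma_s = 5e4, final_freq = 1)
  site <- sim$sweeps[[1]]$site
  dA <- sim$geno$dos[site, sim$pop_map$sample[sim$pop_map$population == "A"]]
  expect_true(all(dA == 2))                       # fixed at d = 0
  other <- sim$pop_map$sample[sim$pop_map$population == "B"]
  expect_identical(sim$geno$dos[, other], sim0$geno$dos[, other])  # bit-level
})

test_that("the frequency shift at one sweep scale matches a Monte-Carlo mean", {
  cfg <- sim_config(samples = c(A = 12, B = 6), chromosomes = c(chr1 = 2e5),
                    n_sites = 120, f_div = 0.02, n_founders = 10, seed = 33)
  sim0 <- simulate_genotypes(cfg)
  a_smp <- sim0$pop_map$sample[sim0$pop_map$population == "A"]
  target <- 1e5
  sigma <- 3e4
  site0 <- which.min(abs(sim0$geno$pos - target))
  d <- abs(sim0$geno$pos - sim0$geno$pos[site0])
  near <- which(abs(d - sigma) < sigma / 4 & seq_along(d) != site0)
  # Monte-Carlo oracle: expectation of the post-sweep allele frequency at
  # distance d is (1-c)*template + c*original, averaged over replicates
  set.seed(99)
  reps <- 300
  mc <- matrix(NA_real_, reps, length(near))
  for (r in seq_len(reps)) {
    s <- inject_sweep(sim0, "chr1", target, "A", sigma_s = sigma,
                      final_freq = 1)
    mc[r, ] <- rowMeans(s$geno$dos[near, a_smp, drop = FALSE]) / 2
  }
  # closed-form expectation from the escape curve
  tpl_freq <- 1   # all carriers copy the template allele state (0 or 1)
  set.seed(99)
  s1 <- inject_sweep(sim0, "chr1", target, "A", sigma_s = sigma,
                     final_freq = 1)
  tpl <- s1$sweeps[[1]]$template
  hA <- which(sim0$hap_sample %in% a_smp)
  p0 <- rowMeans(sim0$haplotypes[near, hA, drop = FALSE])
  cesc <- 1 - exp(-d[near] / sigma)
  expected <- cesc * p0 + (1 - cesc) * sim0$haplotypes[near, tpl]
  expect_equal(colMeans(mc), expected, tolerance = 0.06)
})

test_that("caller emission reduces to the truth when error-free", {
  cfg <- sim_config(samples = c(A = 6, B = 6), chromosomes = c(chr1 = 2e5),
                    n_sites = 150, f_div = 0.05, seed = 6)
  sim <- simulate_genotypes(cfg)
  prof <- caller_profile(fn_rates = c(0, 0, 0), fp_rate = 0,
                         qual_true = c(500, 1), geno_error = 0,
                         gp_low_frac = 0)
  em <- emit_caller_vcfs(sim, profile = prof)
  s1 <- stage1_consensus(em$calls)
  expect_true(all(s1$pass_stage1))
  expect_equal(nrow(s1), nrow(sim$geno))
  expect_setequal(paste(s1$chrom, s1$pos), paste(sim$geno$chrom, sim$geno$pos))
})

test_that("stage-1 survival of noisy call sets matches rule enumeration", {
  cfg <- sim_config(samples = c(A = 8, B = 8), chromosomes = c(chr1 = 5e5),
                    n_sites = 400, f_div = 0.02, seed = 10)
  sim <- simulate_genotypes(cfg)
  prof <- caller_profile(fp_rate = 0.1, qual_artifact = c(25, 10))
  em <- emit_caller_vcfs(sim, profile = prof)
  s1 <- stage1_consensus(em$calls)
  got <- sort(paste(s1$chrom, s1$pos)[s1$pass_stage1])
  expect_identical(got, stage1_oracle(em$calls))
})

test_that("mtDNA simulation matches its stated mutation model", {
  # zero rate: identical sequences, no segregating sites
  m0 <- simulate_mtdna(ref_length = 300, n_seq = 2, rate = 0, seed = 1,
                       hv_window = c(100, 150))
  expect_length(segregating_sites(m0$alignment), 0)
  # multiplier 1: uniform expected density, segregating count within 3 SD
  # of the binomial expectation for distinct mutated positions
  L <- 4000; n <- 12; r <- 5e-4
  m1 <- simulate_mtdna(ref_length = L, n_seq = n, rate = r, multiplier = 1,
                       hv_window = c(1, 100), seed = 42)
  p_site <- 1 - (1 - r)^n          # P(position hit at least once)
  expected <- L * p_site
  sdev <- sqrt(L * p_site * (1 - p_site))
  observed <- nrow(m1$truth)
  expect_lt(abs(observed - expected), 3 * sdev)
  # detected segregating sites are exactly the truth positions at low rate
  ss <- segregating_sites(m1$alignment)
  expect_true(all(ss %in% m1$truth$position))
})
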