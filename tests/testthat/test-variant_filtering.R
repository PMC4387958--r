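two_caller_site <- function(q1, q2, gt = "0/1") {
  list(make_calls("chr1", 100L, "A", "G", q1, "c1", matrix(gt, 1, 2)),
       make_calls("chr1", 100L, "A", "G", q2, "c2", matrix(gt, 1, 2)))
}

test_that("stage-1 consensus applies the two-caller strict-quality rule", {
  s <- stage1_consensus(two_caller_site(31, 40))
  expect_true(s$pass_stage1)                       # 31 and 40 both > 30
  s <- stage1_consensus(list(make_calls("chr1", 100L, "A", "G", 500, "c1",
                                        matrix("0/1", 1, 2))))
  expect_false(s$pass_stage1)                      # one caller, however good
  s <- stage1_consensus(two_caller_site(30, 30))
  expect_false(s$pass_stage1)                      # strictly greater than 30
  s <- stage1_consensus(two_caller_site(30, 31))
  expect_false(s$pass_stage1)
})

test_that("an alternate allele needs a carrier genotype somewhere", {
  calls <- list(
    make_calls("chr1", 100L, "A", "G", 50, "c1", matrix("0/1", 1, 2)),
    make_calls("chr1", 100L, "A", "G", 60, "c2", matrix("0/1", 1, 2)),
    make_calls("chr1", 100L, "A", "G,T", 70, "c3", matrix("0/1", 1, 2)))
  s <- stage1_consensus(calls)
  expect_true(s$pass_stage1)
  expect_equal(s$alt_all, "G,T")
  expect_equal(s$alt_pass, "G")        # T never carried by any genotype
})

test_that("callers disagreeing on the reference allele is an error", {
  calls <- list(make_calls("chr1", 100L, "A", "G", 50, "c1", matrix("0/1", 1, 1)),
                make_calls("chr1", 100L, "T", "G", 60, "c2", matrix("0/1", 1, 1)))
  expect_error(stage1_consensus(calls), "ref-mismatch")
})

test_that("stage 1 is monotone in site quality", {
  set.seed(42)
  for (r in 1:25) {
    q <- runif(3, 0, 60)
    base <- lapply(1:3, function(i)
      make_calls("chr1", 100L, "A", "G", q[i], paste0("c", i),
                 matrix("0/1", 1, 2)))
    before <- stage1_consensus(base)$pass_stage1
    i <- sample(3, 1)
    base[[i]]$qual <- base[[i]]$qual + runif(1, 0, 100)
    after <- stage1_consensus(base)$pass_stage1
    expect_true(after >= before)
  }
})

test_that("the training set demands all callers above 100, biallelic, MAC >= 3", {
  # 20 candidate sites, all qualifying except the planted exceptions
  n <- 20
  mk <- function(caller, quals) {
    gt <- matrix(rep(c("0/1", "0/1", "0/1", "0/0"), each = n), n)
    gq <- matrix(60, n, 4)
    gq[12, ] <- 20                   # site 12: nobody passes GQ > 30
    alt <- rep("G", n)
    alt[9] <- "G,T"                  # site 9: triallelic
    calls <- make_calls("chr1", seq_len(n) * 10L, "A", alt[1], quals,
                        caller, gt, gq = gq)
    calls$alt <- alt
    calls
  }
  q1 <- rep(150, n); q1[5] <- 100    # site 5: one caller exactly at 100
  calls <- list(mk("c1", q1), mk("c2", rep(180, n)), mk("c3", rep(220, n)))
  s <- stage1_consensus(calls)
  tr <- build_training_set(s, calls, primary = "c1")
  expect_equal(nrow(tr), 17L)
  expect_true(all(tr$mac == 3L))
  excluded <- c(50L, 90L, 120L)      # the three planted exceptions
  expect_false(any(tr$pos %in% excluded))
  # with only a handful of qualifying sites the explicit error fires
  few <- lapply(calls, function(x) x[1:6, ])
  expect_error(build_training_set(stage1_consensus(few), few,
                                  primary = "c1"), "insufficient")
})

test_that("build_training_set errors only counterbalance real sites", {
  # with many qualifying sites the set comes back intact
  cfg <- sim_config(samples = c(A = 8, B = 8), chromosomes = c(chr1 = 5e5),
                    n_sites = 600, f_div = 0.02, seed = 19)
  em <- emit_caller_vcfs(simulate_genotypes(cfg))
  s1 <- stage1_consensus(em$calls)
  tr <- build_training_set(s1, em$calls, primary = "ug")
  expect_gt(nrow(tr), 2 * length(recal_annotations()))
  # training sites are a subset of stage-1 passers
  expect_true(all(paste(tr$chrom, tr$pos) %in%
                    paste(s1$chrom, s1$pos)[s1$pass_stage1]))
})

test_that("VQSLOD matches a direct two-annotation density computation", {
  set.seed(7)
  n <- 400
  ann <- tibble::tibble(chrom = "chr1", pos = seq_len(n),
                        QD = rnorm(n, 10, 2), FS = rnorm(n, 4, 1))
  train <- c(rep(TRUE, 150), rep(FALSE, n - 150))
  m <- fit_recal_model(ann, train, annotations = c("QD", "FS"), ridge = 1e-9)
  # independent oracle: quadratic-form Gaussian log densities
  ld <- function(x, mu, S) {
    -0.5 * log(det(2 * pi * S)) -
      0.5 * mahalanobis(x, mu, S)
  }
  X <- as.matrix(ann[, c("QD", "FS")])
  want <- ld(X, m$mu_train, m$sigma_train) - ld(X, m$mu_background, m$sigma_background)
  expect_equal(m$scores$vqslod, unname(want), tolerance = 1e-10)
})

test_that("identical training and background populations score near zero", {
  set.seed(3)
  n <- 1000
  ann <- tibble::tibble(chrom = "c", pos = seq_len(n))
  for (k in recal_annotations()) ann[[k]] <- rnorm(n)
  m <- fit_recal_model(ann, seq_len(n) <= 400)
  expect_lt(abs(median(m$scores$vqslod)), 0.1)
  # a site at the training mean scores positive when classes separate
  ann2 <- ann
  art <- (n - 99):n
  for (k in recal_annotations()) ann2[[k]][art] <- ann2[[k]][art] + 4
  m2 <- fit_recal_model(ann2, seq_len(n) <= 400)
  centre <- which.min(rowSums(abs(as.matrix(ann2[, recal_annotations()]))))
  expect_gt(m2$scores$vqslod[centre], 0)
})

test_that("the cutoff is median minus three unscaled MADs", {
  expect_equal(vqslod_cutoff(c(1, 2, 3, 4, 5)), 0)       # median 3, MAD 1
  expect_equal(vqslod_cutoff(rep(7.5, 10)), 7.5)         # MAD 0
  expect_equal(vqslod_cutoff(c(0, 0, 0, 10)), 0)         # median 0, MAD 0
  expect_equal(vqslod_cutoff(c(1, 2, 3, 4, 5), multiplier = 1), 2)
  expect_error(vqslod_cutoff(c(1, 2)), "insufficient")
})

test_that("stage 2 keeps the boundary and masks only below-threshold GP", {
  set.seed(5)
  n <- 60
  ann <- tibble::tibble(chrom = "c", pos = seq_len(n))
  for (k in recal_annotations()) ann[[k]] <- rnorm(n)
  m <- fit_recal_model(ann, rep(c(TRUE, FALSE), c(30, 30)))
  sites <- tibble::tibble(chrom = "c", pos = seq_len(n))
  cut <- m$scores$vqslod[17]
  out <- apply_stage2(sites, m, cutoff = cut)
  expect_true(out$pass_stage2[17])                 # VQSLOD == cutoff retained
  out2 <- apply_stage2(sites, m, cutoff = cut + 1e-9)
  expect_false(out2$pass_stage2[17])               # epsilon below removed

  calls <- make_calls("chr1", 1:3, "A", "G", 50, "c1",
                      matrix("0/1", 3, 2),
                      gp = matrix(c(0.95, 0.949, 1, 1, 1, 1), 3, 2))
  masked <- gp_mask(calls)
  expect_equal(unname(masked$gt[, 1]), c("0/1", NA, "0/1"))  # 0.95 kept
  all_one <- gp_mask(make_calls("chr1", 1:2, "A", "G", 50, "c1",
                                matrix("0/1", 2, 2)))
  expect_false(anyNA(all_one$gt))                  # identity when GP = 0.99
})

test_that("the full filter separates labelled true and artifact sites", {
  cfg <- sim_config(samples = c(A = 15, B = 15, C = 14),
                    chromosomes = c(chr1 = 2e6), n_sites = 1200,
                    f_div = 0.0025, n_founders = Inf, seed = 29)
  sim <- simulate_genotypes(cfg)
  em <- emit_caller_vcfs(sim)
  fr <- filter_variants(em$calls, primary = "ug", truth = em$truth)
  cr <- fr$class_report
  ret <- sum(cr$n[cr$class == "true" & cr$pass_stage2]) /
    sum(cr$n[cr$class == "true"])
  rem <- sum(cr$n[cr$class == "artifact" & !cr$pass_stage2]) /
    sum(cr$n[cr$class == "artifact"])
  expect_gt(ret, 0.85)             # true sites mostly kept
  expect_gt(rem, 0.5)              # artifacts mostly dropped
  # determinism: the filter is a pure function of its inputs
  fr2 <- filter_variants(em$calls, primary = "ug", truth = em$truth)
  expect_equal(fr$sites$vqslod, fr2$sites$vqslod)
  expect_identical(fr$geno$dos, fr2$geno$dos)
})
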