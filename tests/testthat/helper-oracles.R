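# Independent oracles and small fixture builders shared across tests.
# These deliberately use plain scalar loops, separate from the vectorized
# package implementations they check.

# Weir & Cockerham (1984) variance components, one site at a time.
# dos: numeric vector of dosages for one site; grp: population labels.
wc_site_oracle <- function(dos, grp) {
  pops <- unique(grp)
  r <- length(pops)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    d <- dos[grp == pops[k]]
    d <- d[!is.na(d)]
    n_i[k] <- length(d)
    p_i[k] <- sum(d) / (2 * length(d))
    h_i[k] <- mean(d == 1)
  }
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Brute-force per-site enumeration of the stage-1 consensus rules.
stage1_oracle <- function(calls_list, qual_min = 30) {
  recs <- do.call(rbind, lapply(calls_list, function(x)
    data.frame(chrom = x$chrom, pos = x$pos, qual = x$qual)))
  by_site <- split(recs$qual, paste(recs$chrom, recs$pos))
  passed <- character(0)
  for (k in names(by_site)) {
    if (sum(by_site[[k]] > qual_min) >= 2) passed <- c(passed, k)
  }
  sort(passed)
}

# Minimal caller-call tibble builder for hand-crafted filtering cases.
# gt is a matrix of genotype strings (sites x samples).
make_calls <- function(chrom, pos, ref, alt, qual, caller, gt,
                       gq = NULL, gp = NULL, ann = NULL) {
  n <- length(pos)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
  if (is.null(gq)) gq <- matrix(60, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(gp)) gp <- matrix(0.99, n, ncol(gt), dimnames = dimnames(gt))
  out <- tibble::tibble(chrom = rep_len(chrom, n), pos = as.integer(pos),
                        ref = rep_len(ref, n), alt = rep_len(alt, n),
                        qual = rep_len(qual, n), caller = caller)
  for (k in recal_annotations())
    out[[k]] <- if (is.null(ann)) rnorm(n) else rep_len(ann[[k]], n)
  out$gt <- gt
  out$gq <- gq
  out$gp <- gp
  out
}

# Small genotype table straight from a dosage matrix (one chromosome,
# evenly spaced SNPs, A->G so everything is biallelic SNP).
toy_geno <- function(dos, pos = NULL, chrom = "chr1") {
  if (is.null(colnames(dos)))
    colnames(dos) <- sprintf("s%02d", seq_len(ncol(dos)))
  n <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  geno_table(chrom, pos, rep("A", n), rep("G", n), dos)
}
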