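#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults are the
#' study conditions the downstream analyses assume: three weakly
#' differentiated populations sampled 22/14/8, a rare-variant-rich site
#' frequency spectrum, and linkage disequilibrium decaying over a few kb.
#'
#' The genotype model is Balding-Nichols with founder mosaics: each site has
#' an ancestral frequency `p` drawn from a Beta(`sfs_shape`, 1) law (smaller
#' shape = more rare variants); each population perturbs it as
#' `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = f_div`; `n_founders`
#' haplotypes per population are drawn i.i.d. from `p_k`; individual
#' haplotypes are founder mosaics whose switch probability between adjacent
#' sites is `1 - exp(-recomb_rate * distance)`, so r-squared decays with
#' distance.  `n_founders = Inf` is the pure Balding-Nichols limit:
#' haplotypes drawn i.i.d. from `p_k`, no linkage.  Note that finite founder
#' pools add within-population drift of order `1/n_founders` on top of
#' `f_div`, which sets a floor on realized differentiation; use `Inf` when
#' exact FST control matters more than LD.
#'
#' @param samples Named integer vector: samples per population.
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param site_density Variant sites per bp (default 1 per 2 kb).
#' @param n_sites Optional explicit site count per chromosome (overrides
#'   density).
#' @param f_div Balding-Nichols divergence parameter in (0,1).  Zero is a
#'   degenerate configuration (use a tiny positive floor instead).
#' @param n_founders Founder haplotypes per population; `Inf` disables
#'   linkage.
#' @param recomb_rate Founder-switch rate per bp; controls LD decay scale
#'   (~1/recomb_rate bp).
#' @param sfs_shape Beta shape of the ancestral-frequency law.
#' @param indel_frac Fraction of sites labelled indels.
#' @param ts_fraction Probability a SNP's alternate allele is the
#'   transition partner of the reference (0.71 reproduces a ts/tv ratio of
#'   about 2.44).
#' @param sweeps List of sweep specs, each a list
#'   `(chrom, pos, pop, sigma_s, final_freq)`; see [inject_sweep()].
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(samples = c(Black = 22, Draa = 14, Northern = 8),
                       chromosomes = c(chr1 = 5e6),
                       site_density = 5e-4,
                       n_sites = NULL,
                       f_div = 0.0025,
                       n_founders = 24,
                       recomb_rate = 3e-4,
                       sfs_shape = 0.2,
                       indel_frac = 0.068,
                       ts_fraction = 0.71,
                       sweeps = list(),
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: a seed is mandatory")
  if (is.null(names(samples)) || is.null(names(chromosomes)))
    stop("samples and chromosomes must be named")
  if (f_div <= 0 || f_div >= 1)
    stop("degenerate config: f_div must be in (0,1); use a tiny positive floor instead of 0")
  stopifnot(site_density > 0, recomb_rate >= 0, sfs_shape > 0,
            indel_frac >= 0, indel_frac <= 1, n_founders >= 1,
            ts_fraction >= 0, ts_fraction <= 1)
  for (sw in sweeps) {
    if (!sw$chrom %in% names(chromosomes))
      stop("sweep on unknown chromosome: ", sw$chrom)
    if (sw$pos < 1 || sw$pos > chromosomes[[sw$chrom]])
      stop("sweep position outside its chromosome")
    if (!sw$pop %in% names(samples))
      stop("sweep target population unknown: ", sw$pop)
    if (sw$final_freq < 0 || sw$final_freq > 1) stop("final_freq must be in [0,1]")
  }
  structure(list(samples = samples, chromosomes = chromosomes,
                 site_density = site_density, n_sites = n_sites,
                 f_div = f_div, n_founders = n_founders,
                 recomb_rate = recomb_rate, sfs_shape = sfs_shape,
                 indel_frac = indel_frac, ts_fraction = ts_fraction,
                 sweeps = sweeps, seed = seed),
            class = "sim_config")
}

#' Simulate genotypes under the Balding-Nichols founder-mosaic model
#'
#' @param config A [sim_config()].
#' @return A list of class `pop_sim`:
#'   * `geno` — genotype table (see [geno_table()]);
#'   * `pop_map` — tibble `sample`, `population`;
#'   * `haplotypes` — 0/1 matrix, sites x (2 x samples);
#'   * `hap_sample` — sample id of each haplotype column;
#'   * `truth` — per-site tibble with ancestral frequency `p_anc`, one
#'     `p_<pop>` column per population, and the founder-identity matrices in
#'     attribute `founders`;
#'   * `sweeps` — truth records appended by [inject_sweep()].
#' Deterministic for a fixed `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- names(config$samples)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%02d", p, seq_len(config$samples[[p]]))), use.names = FALSE)
  pop_map <- tibble::tibble(
    sample = sample_ids,
    population = rep(pops, times = config$samples))

  per_chrom <- lapply(names(config$chromosomes), function(ch) {
    len <- config$chromosomes[[ch]]
    n <- if (!is.null(config$n_sites)) config$n_sites else max(2L, round(len * config$site_density))
    pos <- sort(sample.int(len, n))
    p <- pmin(pmax(stats::rbeta(n, config$sfs_shape, 1), 1e-4), 1 - 1e-4)
    F <- config$f_div
    p_k <- vapply(pops, function(k)
      stats::rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F), numeric(n))
    p_k <- pmin(pmax(p_k, 0), 1)

    hap_cols <- rep(sample_ids, each = 2)
    haps <- matrix(0L, n, length(hap_cols))
    founder_id <- NULL
    K <- config$n_founders
    if (is.finite(K)) {
      founder_id <- matrix(NA_integer_, n, length(hap_cols))
      gaps <- diff(pos)
      p_switch <- 1 - exp(-config$recomb_rate * gaps)
      col0 <- 0L
      for (k in pops) {
        nk <- config$samples[[k]]
        founders <- matrix(stats::rbinom(n * K, 1L, p_k[, k]), n, K)
        for (h in seq_len(2L * nk)) {
          sw <- c(TRUE, stats::runif(n - 1) < p_switch)
          seg <- cumsum(sw)
          f_per_seg <- sample.int(K, max(seg), replace = TRUE)
          f <- f_per_seg[seg]
          haps[, col0 + h] <- founders[cbind(seq_len(n), f)]
          founder_id[, col0 + h] <- f
        }
        col0 <- col0 + 2L * nk
      }
    } else {
      col0 <- 0L
      for (k in pops) {
        nk <- config$samples[[k]]
        haps[, col0 + seq_len(2L * nk)] <-
          stats::rbinom(n * 2L * nk, 1L, p_k[, k])
        col0 <- col0 + 2L * nk
      }
    }
    list(chrom = ch, pos = pos, p = p, p_k = p_k, haps = haps,
         founder_id = founder_id)
  })

  pos_all <- unlist(lapply(per_chrom, `[[`, "pos"))
  chrom_all <- rep(vapply(per_chrom, `[[`, "", "chrom"),
                   vapply(per_chrom, function(x) length(x$pos), 0L))
  haps <- do.call(rbind, lapply(per_chrom, `[[`, "haps"))
  n_tot <- length(pos_all)

  # allele labels: SNP ref/alt pairs with a transition bias matching the
  # ts/tv ratio typical of mammalian WGS (~2.44), a fraction tagged indel
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- sample(bases, n_tot, replace = TRUE)
  is_ts <- stats::runif(n_tot) < config$ts_fraction
  alt <- ifelse(is_ts, transition[ref],
                vapply(ref, function(r)
                  sample(setdiff(bases, c(r, transition[[r]])), 1), ""))
  type <- ifelse(stats::runif(n_tot) < config$indel_frac, "indel", "snp")
  alt[type == "indel"] <- paste0(alt[type == "indel"], "A")

  dos <- haps[, seq(1, ncol(haps), 2), drop = FALSE] +
    haps[, seq(2, ncol(haps), 2), drop = FALSE]
  colnames(dos) <- sample_ids
  geno <- geno_table(chrom_all, pos_all, ref, alt, dos, type = type)

  truth <- tibble::tibble(chrom = chrom_all, pos = pos_all,
                          p_anc = unlist(lapply(per_chrom, `[[`, "p")))
  pk <- do.call(rbind, lapply(per_chrom, `[[`, "p_k"))
  for (k in pops) truth[[paste0("p_", k)]] <- pk[, k]
  attr(truth, "founders") <- lapply(per_chrom, `[[`, "founder_id")

  sim <- list(geno = geno, pop_map = pop_map, haplotypes = haps,
              hap_sample = rep(sample_ids, each = 2), truth = truth,
              sweeps = list(), config = config)
  class(sim) <- "pop_sim"
  for (sw in config$sweeps)
    sim <- inject_sweep(sim, sw$chrom, sw$pos, sw$pop,
                        sigma_s = sw$sigma_s, final_freq = sw$final_freq)
  sim
}

#' Inject a selective sweep into one population
#'
#' Emulates hitchhiking: a "beneficial" haplotype at the sweep site rises to
#' `final_freq` in the target population, dragging linked sites with it.
#' A carrier haplotype keeps its own allele at distance `d` from the sweep
#' position with escape probability `c(d) = 1 - exp(-d / sigma_s)`, and
#' otherwise copies the sweeping template.  Other populations are untouched
#' bit for bit.
#'
#' @param sim A `pop_sim` from [simulate_genotypes()].
#' @param chrom,pos Sweep location (bp); the nearest simulated site is the
#'   sweep site.
#' @param pop Target population label.
#' @param sigma_s Sweep scale in bp.
#' @param final_freq Frequency the beneficial haplotype reaches at the sweep
#'   site (1.0 = fixation).
#' @return The modified `pop_sim`; a truth record is appended to
#'   `sim$sweeps`.
#' @export
inject_sweep <- function(sim, chrom, pos, pop, sigma_s, final_freq = 1.0) {
  stopifnot(inherits(sim, "pop_sim"))
  if (!pop %in% sim$pop_map$population) stop("unknown target population: ", pop)
  on_chrom <- which(sim$geno$chrom == chrom)
  if (!length(on_chrom)) stop("no sites on chromosome ", chrom)
  site <- on_chrom[which.min(abs(sim$geno$pos[on_chrom] - pos))]
  d <- abs(sim$geno$pos[on_chrom] - sim$geno$pos[site])
  escape <- 1 - exp(-d / sigma_s)

  target_samples <- sim$pop_map$sample[sim$pop_map$population == pop]
  hcols <- which(sim$hap_sample %in% target_samples)
  # template: a target haplotype carrying the alternate allele at the sweep
  # site (forced onto the first one if absent)
  carrier_alt <- hcols[sim$haplotypes[site, hcols] == 1L]
  tpl <- if (length(carrier_alt)) carrier_alt[1] else hcols[1]
  template <- sim$haplotypes[on_chrom, tpl]
  template[d == 0] <- 1L

  carriers <- hcols[stats::runif(length(hcols)) < final_freq]
  for (h in carriers) {
    keep_own <- stats::runif(length(on_chrom)) < escape
    hap <- sim$haplotypes[on_chrom, h]
    hap[!keep_own] <- template[!keep_own]
    sim$haplotypes[on_chrom, h] <- hap
  }

  # rebuild dosages for the target population only
  for (s in target_samples) {
    hc <- which(sim$hap_sample == s)
    sim$geno$dos[on_chrom, s] <-
      sim$haplotypes[on_chrom, hc[1]] + sim$haplotypes[on_chrom, hc[2]]
  }
  sim$sweeps <- c(sim$sweeps, list(list(
    chrom = chrom, pos = sim$geno$pos[site], site = site, pop = pop,
    sigma_s = sigma_s, final_freq = final_freq,
    n_carriers = length(carriers), template = tpl)))
  sim
}

#' Caller error profile
#'
#' Describes how each of the emulated variant callers corrupts the truth:
#' per-caller false-negative rates, a shared pool of artifact (false
#' positive) sites, quality/GQ/GP noise laws, and Gaussian annotation laws
#' whose true/artifact means are separated by about two standard deviations
#' per annotation, so the recalibration model has signal to learn.
#'
#' @param caller_ids Labels of the emulated callers.
#' @param fn_rates Per-caller probability of missing a true site.
#' @param fp_rate Artifact sites as a fraction of true sites.
#' @param artifact_emit Probability that a given caller emits a given
#'   artifact site.
#' @param qual_true,qual_artifact `c(mean, sd)` of site quality (phred).
#'   True sites centre far above the consensus threshold (deep-coverage
#'   variants typically carry qualities in the hundreds); artifact
#'   qualities centre below it, with a tail that sneaks through.
#' @param gq `c(mean, sd)` of genotype quality.
#' @param gp_low_frac Fraction of genotypes with a degraded posterior
#'   (uniform on \[0.5, 1\]); the rest sit near 1.
#' @param geno_error Probability of a miscalled genotype.
#' @param ann_missing Probability an annotation value is absent.
#' @param ann_separation Overall (Mahalanobis) separation between the true
#'   and artifact annotation means, in SD units, spread evenly over the
#'   seven annotations.
#' @param ann_spread Ratio of artifact to true annotation SD; artifacts are
#'   not just shifted but markedly noisier, as mapping/calling artifacts
#'   are on real data.
#' @return List of class `caller_profile`, including the annotation law
#'   table `ann` (`key, mu_true, mu_artifact, sd, sd_artifact`).
#' @export
caller_profile <- function(caller_ids = c("mpileup", "ug", "freebayes"),
                           fn_rates = c(0.03, 0.03, 0.06),
                           fp_rate = 0.10,
                           artifact_emit = 0.85,
                           qual_true = c(300, 120),
                           qual_artifact = c(28, 12),
                           gq = c(65, 15),
                           gp_low_frac = 0.05,
                           geno_error = 0.005,
                           ann_missing = 0.03,
                           ann_separation = 2,
                           ann_spread = 4) {
  stopifnot(length(caller_ids) == length(fn_rates),
            all(fn_rates >= 0 & fn_rates <= 1),
            fp_rate >= 0, artifact_emit >= 0, artifact_emit <= 1,
            ann_separation >= 0, ann_spread > 0)
  sd <- c(4, 4, 2, 2, 10, 75, 0.2)
  mu_true <- c(18, 2, 0, 0, 5, 300, 0.05)
  sgn <- c(-1, 1, -1, -1, 1, -1, 1)   # direction artifacts shift in
  shift <- ann_separation / sqrt(7)
  ann <- tibble::tibble(
    key = recal_annotations(),
    mu_true = mu_true,
    mu_artifact = mu_true + sgn * shift * sd,
    sd = sd,
    sd_artifact = ann_spread * sd)
  structure(list(caller_ids = caller_ids, fn_rates = fn_rates,
                 fp_rate = fp_rate, artifact_emit = artifact_emit,
                 qual_true = qual_true, qual_artifact = qual_artifact,
                 gq = gq, gp_low_frac = gp_low_frac,
                 geno_error = geno_error, ann_missing = ann_missing,
                 ann = ann),
            class = "caller_profile")
}

#' Emit noisy per-caller call sets from simulated genotypes
#'
#' Each true site is emitted by each caller with probability one minus its
#' false-negative rate; artifact sites (absent from the genotype matrix, at
#' positions resampled on collision) are shared across callers and emitted
#' with probability `artifact_emit`.  Site qualities, annotations, GQ and GP
#' are drawn from the class-specific laws of the [caller_profile()].
#'
#' @param sim A `pop_sim`.
#' @param profile A [caller_profile()].
#' @param dir Optional directory; when given, one VCF per caller plus a
#'   `truth.tsv` site table are written there.
#' @param seed RNG seed (defaults to the simulation seed + 1).
#' @return List with `calls` (list of caller-call tibbles, one per caller)
#'   and `truth` (tibble `chrom, pos, class` with class `"true"` /
#'   `"artifact"`).
#' @export
emit_caller_vcfs <- function(sim, profile = caller_profile(), dir = NULL,
                             seed = NULL) {
  stopifnot(inherits(sim, "pop_sim"), inherits(profile, "caller_profile"))
  set.seed(if (is.null(seed)) sim$config$seed + 1L else seed)
  g <- sim$geno
  n_true <- nrow(g)
  samples <- geno_samples(g)
  ns <- length(samples)

  # shared artifact pool
  n_art <- round(profile$fp_rate * n_true)
  art <- NULL
  if (n_art > 0) {
    chroms <- sim$config$chromosomes
    a_chrom <- sample(names(chroms), n_art, replace = TRUE,
                      prob = chroms / sum(chroms))
    a_pos <- vapply(a_chrom, function(ch) sample.int(chroms[[ch]], 1), 0L)
    taken <- paste(g$chrom, g$pos)
    for (i in seq_len(n_art)) {  # resample collisions with true or other artifacts
      while (paste(a_chrom[i], a_pos[i]) %in% taken)
        a_pos[i] <- sample.int(chroms[[a_chrom[i]]], 1)
      taken <- c(taken, paste(a_chrom[i], a_pos[i]))
    }
    bases <- c("A", "C", "G", "T")
    a_ref <- sample(bases, n_art, replace = TRUE)
    a_alt <- vapply(a_ref, function(r) sample(setdiff(bases, r), 1), "")
    art <- tibble::tibble(chrom = a_chrom, pos = as.integer(a_pos),
                          ref = a_ref, alt = a_alt)
  }

  truth <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(chrom = g$chrom, pos = g$pos, class = "true"),
    if (!is.null(art)) tibble::tibble(chrom = art$chrom, pos = art$pos,
                                      class = "artifact")),
    .data$chrom, .data$pos)

  rnorm_ann <- function(n, mu, sd) stats::rnorm(n, mu, sd)
  draw_gp <- function(n) {
    gp <- 1 - stats::rexp(n, rate = 100)
    low <- stats::runif(n) < profile$gp_low_frac
    gp[low] <- stats::runif(sum(low), 0.5, 1)
    pmin(pmax(gp, 0), 1)
  }
  gt_codes <- c("0/0", "0/1", "1/1")

  calls <- vector("list", length(profile$caller_ids))
  names(calls) <- profile$caller_ids
  for (ci in seq_along(profile$caller_ids)) {
    keep_true <- stats::runif(n_true) >= profile$fn_rates[ci]
    tt <- g[keep_true, c("chrom", "pos", "ref", "alt")]
    tt$qual <- pmax(0, stats::rnorm(nrow(tt), profile$qual_true[1],
                                    profile$qual_true[2]))
    dos_t <- g$dos[keep_true, , drop = FALSE]
    gt_t <- matrix(gt_codes[dos_t + 1L], nrow(tt), ns)
    err <- matrix(stats::runif(length(gt_t)) < profile$geno_error, nrow(tt), ns)
    gt_t[err] <- sample(gt_codes, sum(err), replace = TRUE)
    gt_t[is.na(dos_t)] <- NA_character_

    n_a_emit <- 0L
    if (!is.null(art)) {
      emit <- stats::runif(n_art) < profile$artifact_emit
      aa <- art[emit, ]
      n_a_emit <- nrow(aa)
      aa$qual <- pmax(0, stats::rnorm(n_a_emit, profile$qual_artifact[1],
                                      profile$qual_artifact[2]))
      dos_a <- matrix(stats::rbinom(n_a_emit * ns, 2, 0.12), n_a_emit, ns)
      gt_a <- matrix(gt_codes[dos_a + 1L], n_a_emit, ns)
      rec <- dplyr::bind_rows(tt, aa)
      gt <- rbind(gt_t, gt_a)
    } else {
      rec <- tt
      gt <- gt_t
    }
    n_rec <- nrow(rec)
    is_true <- rep(c(TRUE, FALSE), c(nrow(tt), n_a_emit))
    for (k in seq_len(nrow(profile$ann))) {
      key <- profile$ann$key[k]
      sd_art <- if ("sd_artifact" %in% names(profile$ann))
        profile$ann$sd_artifact[k] else profile$ann$sd[k]
      val <- ifelse(is_true,
                    rnorm_ann(n_rec, profile$ann$mu_true[k], profile$ann$sd[k]),
                    rnorm_ann(n_rec, profile$ann$mu_artifact[k], sd_art))
      val[stats::runif(n_rec) < profile$ann_missing] <- NA_real_
      rec[[key]] <- val
    }
    gq <- matrix(pmax(0, round(stats::rnorm(n_rec * ns, profile$gq[1],
                                            profile$gq[2]))), n_rec, ns)
    gp <- matrix(draw_gp(n_rec * ns), n_rec, ns)
    gq[is.na(gt)] <- NA_real_
    gp[is.na(gt)] <- NA_real_
    colnames(gt) <- colnames(gq) <- colnames(gp) <- samples
    rec$caller <- profile$caller_ids[ci]
    rec$gt <- gt
    rec$gq <- gq
    rec$gp <- gp
    rec <- dplyr::arrange(rec, .data$chrom, .data$pos)
    calls[[ci]] <- rec[, c("chrom", "pos", "ref", "alt", "qual", "caller",
                           recal_annotations(), "gt", "gq", "gp")]
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in names(calls))
      write_vcf(calls[[id]], file.path(dir, paste0(id, ".vcf")))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  list(calls = calls, truth = truth)
}

#' Simulate an mtDNA alignment with a hypervariable window
#'
#' Sequences derive from one random reference by independent substitutions;
#' positions inside the hypervariable window mutate at `rate * multiplier`.
#'
#' @param ref_length Alignment length (bp).
#' @param n_seq Number of sequences.
#' @param rate Per-site, per-sequence substitution probability.
#' @param hv_window Integer `c(start, end)`, 1-based inclusive.
#' @param multiplier Rate multiplier inside the window.
#' @param seed RNG seed.
#' @return List with `alignment` (named character vector) and `truth`
#'   (tibble of mutated positions with per-position mutation counts).
#' @export
simulate_mtdna <- function(ref_length = 16651, n_seq = 41, rate = 2.6e-4,
                           hv_window = c(15001, 15481), multiplier = 13,
                           seed = 1) {
  stopifnot(hv_window[1] >= 1, hv_window[2] <= ref_length,
            hv_window[1] <= hv_window[2], rate >= 0, multiplier >= 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ref_length, replace = TRUE)
  site_rate <- rep(rate, ref_length)
  site_rate[hv_window[1]:hv_window[2]] <- rate * multiplier
  site_rate <- pmin(site_rate, 1)
  aln <- character(n_seq)
  hits <- integer(ref_length)
  for (i in seq_len(n_seq)) {
    s <- ref
    mut <- which(stats::runif(ref_length) < site_rate)
    if (length(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1), "")
      hits[mut] <- hits[mut] + 1L
    }
    aln[i] <- paste(s, collapse = "")
  }
  names(aln) <- sprintf("seq_%02d", seq_len(n_seq))
  list(alignment = aln,
       reference = paste(ref, collapse = ""),
       truth = tibble::tibble(position = which(hits > 0),
                              n_mutations = hits[hits > 0]))
}
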