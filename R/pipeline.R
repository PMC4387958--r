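#' Default pipeline configuration
#'
#' A bare run uses the canonical thresholds throughout: site quality 30,
#' training quality 100, 3-MAD cutoff, genotype-probability 0.95, MAF 0.05,
#' 50-marker pruning at r-squared 0.95, XP-CLR grid 2500 bp / 250 SNPs /
#' 0.5 cM windows, 27/2/1 cM segments, 1 cM per Mb, top 0.1% regions, and
#' 1500 bp gene flanks — on a small synthetic genome so the whole chain
#' runs in minutes.
#'
#' @param seed Global seed; every stochastic stage receives a seed derived
#'   deterministically from it.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    stages = list(simulate = TRUE, filter = TRUE, stats = TRUE, ld = TRUE,
                  pca = TRUE, fst = TRUE, xpclr = TRUE, mtdna = TRUE),
    sim = list(samples = c(Black = 10, Draa = 8, Northern = 6),
               chromosomes = c(chr1 = 2e6), site_density = 5e-4,
               f_div = 0.0025, n_founders = 24, recomb_rate = 1e-4,
               sfs_shape = 0.2,
               sweeps = list(list(chrom = "chr1", pos = 1e6, pop = "Black",
                                  sigma_s = 5e4, final_freq = 1.0))),
    filter = list(qual_min = 30, qual_train = 100, gq_min = 30, mac_min = 3,
                  gp_min = 0.95, mad_multiplier = 3, primary = "ug"),
    ld = list(min_maf = 0.05, prune_window = 50, prune_r2 = 0.95),
    xpclr = list(test_pop = "Black", top_frac = 0.001, flank = 1500,
                 equalize = NULL),
    mtdna = list(ref_length = 4000, n_seq = 20, rate = 2.6e-4,
                 hv_window = c(2001, 2481), multiplier = 12),
    inputs = list(caller_vcfs = NULL, pop_map = NULL, fasta = NULL,
                  genes = NULL)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain list, or the path of a YAML file;
#' unknown fields are rejected, missing ones filled from
#' [default_pipeline_config()], and invalid values reported together as a
#' named error list.
#'
#' @param config List, `pipeline_config`, or YAML path.
#' @return A normalized `pipeline_config`; errors if anything is invalid.
#' @export
validate_config <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config field(s): ",
                           paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(unclass(def), config[setdiff(names(config), unknown)])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errs <- c(errs, "seed: must be a single number")
  if (!is.null(cfg$sim$f_div) && (cfg$sim$f_div <= 0 || cfg$sim$f_div >= 1))
    errs <- c(errs, "sim$f_div: must be in (0,1)")
  if (cfg$filter$gp_min < 0 || cfg$filter$gp_min > 1)
    errs <- c(errs, "filter$gp_min: must be in [0,1]")
  if (cfg$xpclr$top_frac <= 0 || cfg$xpclr$top_frac >= 1)
    errs <- c(errs, "xpclr$top_frac: must be in (0,1)")
  if (isTRUE(cfg$stages$simulate)) {
    pops <- names(cfg$sim$samples)
    if (!cfg$xpclr$test_pop %in% pops)
      errs <- c(errs, paste0("xpclr$test_pop: unknown population label '",
                             cfg$xpclr$test_pop, "'"))
  }
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Chains simulate, filter, diversity statistics, LD, PCA, FST, the XP-CLR
#' scan and mtDNA statistics into a run directory of TSV reports plus a
#' JSON manifest listing every output with its MD5 hash and the effective
#' configuration.  Reruns with the same configuration are bit-identical.
#'
#' @param config A [validate_config()]-acceptable configuration.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  log <- function(...) message(sprintf(...))
  stage_seed <- function(k) as.integer((cfg$seed * 1000L + k) %% .Machine$integer.max)

  if (isTRUE(cfg$stages$simulate)) {
    log("simulate: %d samples, %s sites/bp",
        sum(cfg$sim$samples), format(cfg$sim$site_density))
    sim_cfg <- do.call(sim_config, c(cfg$sim, list(seed = stage_seed(1))))
    sim <- simulate_genotypes(sim_cfg)
    emitted <- emit_caller_vcfs(sim, dir = file.path(out_dir, "calls"),
                                seed = stage_seed(2))
    readr::write_tsv(sim$pop_map, file.path(out_dir, "pop_map.tsv"),
                     progress = FALSE)
    res$sim <- sim
    res$calls <- emitted$calls
    res$truth <- emitted$truth
    pop_map <- sim$pop_map
  } else if (!is.null(cfg$inputs$caller_vcfs)) {
    res$calls <- purrr::imap(cfg$inputs$caller_vcfs, read_vcf)
    pop_map <- read_population_map(cfg$inputs$pop_map)
    res$truth <- NULL
  } else if (any(unlist(cfg$stages[c("filter", "stats", "ld", "pca", "fst", "xpclr")]))) {
    stop("dependency error: stage 'filter' enabled but neither simulate nor caller_vcfs inputs provide calls")
  }

  if (isTRUE(cfg$stages$filter)) {
    if (is.null(res$calls)) stop("dependency error: stage 'filter' has no caller calls")
    f <- cfg$filter
    log("filter: qual>%g consensus, training qual>%g, %g-MAD cutoff, GP>=%g",
        f$qual_min, f$qual_train, f$mad_multiplier, f$gp_min)
    primary <- if (f$primary %in% names(res$calls)) f$primary else names(res$calls)[1]
    res$filter <- filter_variants(res$calls, primary = primary,
                                  qual_min = f$qual_min, qual_train = f$qual_train,
                                  gq_min = f$gq_min, mac_min = f$mac_min,
                                  gp_min = f$gp_min,
                                  mad_multiplier = f$mad_multiplier,
                                  truth = res$truth)
    readr::write_tsv(res$filter$report, file.path(out_dir, "filter_report.tsv"),
                     progress = FALSE)
    geno <- res$filter$geno
  } else if (!is.null(res$sim)) {
    geno <- res$sim$geno
  } else geno <- NULL

  need_geno <- function(stage) {
    if (is.null(geno))
      stop("dependency error: stage '", stage, "' has no genotype input")
  }

  if (isTRUE(cfg$stages$stats)) {
    need_geno("stats")
    pm <- match_population_map(geno, pop_map)
    per_pop <- purrr::map_dfr(unique(pm$population), function(k)
      tibble::tibble(population = k,
                     pi = mean_pi(geno, pm$sample[pm$population == k])))
    tt <- tstv(geno)
    mafs <- maf_spectrum(geno)
    res$stats <- list(
      pi = dplyr::bind_rows(per_pop,
                            tibble::tibble(population = "all", pi = mean_pi(geno))),
      ho = het_observed(geno), f = inbreeding_f(geno),
      tstv = tt, maf = mafs,
      partition = polymorphism_partition(geno, pop_map))
    readr::write_tsv(res$stats$pi, file.path(out_dir, "pi.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::left_join(res$stats$ho, res$stats$f[, c("sample", "f")],
                                      by = "sample"),
                     file.path(out_dir, "individual_stats.tsv"), progress = FALSE)
    log("stats: pi(all) = %.3f, ts/tv = %.2f, rare fraction = %.1f%%",
        res$stats$pi$pi[res$stats$pi$population == "all"], tt$ratio,
        100 * mafs$rare_fraction)
  }

  if (isTRUE(cfg$stages$ld)) {
    need_geno("ld")
    log("ld: %d bins to %g kb, MAF filter %s", length(ld_bins()) - 1,
        max(ld_bins()), format(cfg$ld$min_maf))
    prs <- purrr::map_dfr(unique(geno$chrom), function(ch)
      pairwise_r2(geno, chrom = ch, min_maf = cfg$ld$min_maf))
    res$ld <- ld_decay(prs)
    readr::write_tsv(res$ld, file.path(out_dir, "ld_decay.tsv"), progress = FALSE)
  }

  if (isTRUE(cfg$stages$pca)) {
    need_geno("pca")
    kept <- ld_prune(geno, window = cfg$ld$prune_window,
                     r2_threshold = cfg$ld$prune_r2)
    log("pca: %d of %d markers after pruning", length(kept), nrow(geno))
    res$pca <- pca_genotypes(geno, markers = kept)
    readr::write_tsv(res$pca$scores, file.path(out_dir, "pca_scores.tsv"),
                     progress = FALSE)
  }

  if (isTRUE(cfg$stages$fst)) {
    need_geno("fst")
    res$fst <- wc_fst(geno, pop_map)
    res$fst_pairwise <- wc_fst_pairwise(geno, pop_map)
    readr::write_tsv(dplyr::bind_rows(
      tibble::tibble(pop1 = "all", pop2 = "all", theta_w = res$fst$theta_w),
      res$fst_pairwise),
      file.path(out_dir, "fst.tsv"), progress = FALSE)
    log("fst: weighted theta = %.4g", res$fst$theta_w)
  }

  if (isTRUE(cfg$stages$xpclr)) {
    need_geno("xpclr")
    pm_scan <- pop_map
    if (!is.null(cfg$xpclr$equalize))
      pm_scan <- equalize_samples(pop_map, cfg$xpclr$equalize,
                                  seed = stage_seed(3))
    log("xpclr: test %s, grid %g bp, window %g cM, top %.3g%%",
        cfg$xpclr$test_pop, xpclr_config()$grid_spacing,
        xpclr_config()$window_cm, 100 * cfg$xpclr$top_frac)
    res$xpclr <- xpclr_scan(geno, pm_scan, cfg$xpclr$test_pop)
    res$regions <- call_regions(res$xpclr, top_frac = cfg$xpclr$top_frac)
    readr::write_tsv(res$xpclr$track, file.path(out_dir, "xpclr_scan.tsv"),
                     progress = FALSE)
    readr::write_tsv(res$regions, file.path(out_dir, "xpclr_regions.tsv"),
                     progress = FALSE)
    if (!is.null(cfg$inputs$genes)) {
      genes <- read_gene_table(cfg$inputs$genes)
      res$gene_hits <- map_genes(res$regions, genes, flank = cfg$xpclr$flank)
      readr::write_tsv(res$gene_hits, file.path(out_dir, "gene_hits.tsv"),
                       progress = FALSE)
    }
  }

  if (isTRUE(cfg$stages$mtdna)) {
    m <- cfg$mtdna
    if (!is.null(cfg$inputs$fasta)) {
      aln <- read_fasta_alignment(cfg$inputs$fasta)
    } else {
      mt <- simulate_mtdna(ref_length = m$ref_length, n_seq = m$n_seq,
                           rate = m$rate, hv_window = m$hv_window,
                           multiplier = m$multiplier, seed = stage_seed(4))
      aln <- mt$alignment
    }
    hs <- collapse_haplotypes(aln)
    share <- region_share(aln, m$hv_window[1], m$hv_window[2])
    res$mtdna <- list(haplotypes = hs, share = share)
    readr::write_tsv(dplyr::bind_cols(
      tibble::tibble(n_sequences = length(aln),
                     n_haplotypes = hs$n_haplotypes,
                     n_segregating = length(hs$segregating_sites)), share),
      file.path(out_dir, "mtdna.tsv"), progress = FALSE)
    log("mtdna: %d haplotypes, %.1f%% of variants in %.1f%% of length",
        hs$n_haplotypes, 100 * share$variant_share, 100 * share$length_share)
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    config = rapply(unclass(cfg), function(x) x, how = "replace"),
    outputs = purrr::map(outputs, function(f)
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
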