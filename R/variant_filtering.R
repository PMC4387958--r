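#' Stage-1 multi-caller consensus filtering
#'
#' Merges per-caller call sets by `(chrom, pos, ref)` and applies the
#' consensus rule: a site passes if at least two different callers report it,
#' each with site quality strictly above `qual_min`; among passing sites an
#' alternate allele is retained iff some caller calls it with at least one
#' non-reference genotype carrying it.  Failing sites are flagged, never
#' deleted.
#'
#' @param calls_list List of caller-call tibbles (one per caller, distinct
#'   `caller` labels), as from [read_vcf()] or [emit_caller_vcfs()].
#' @param qual_min Site-quality threshold (strict inequality), default 30.
#' @return Tibble with one row per merged site: `chrom, pos, ref`,
#'   `n_callers` (callers reporting), `n_support` (callers with
#'   qual > `qual_min`), `min_qual`, `max_qual` over reporting callers,
#'   `alt_all` (comma-joined union of alternate alleles), `alt_pass`
#'   (alleles meeting the genotype-count rule), and `pass_stage1`.
#' @export
stage1_consensus <- function(calls_list, qual_min = 30) {
  stopifnot(length(calls_list) >= 1)
  ids <- vapply(calls_list, function(x) x$caller[1], "")
  if (anyDuplicated(ids)) stop("caller ids must be distinct")
  recs <- dplyr::bind_rows(calls_list)
  key <- paste(recs$chrom, recs$pos)

  ref_by_site <- tapply(recs$ref, key, function(r) length(unique(r)))
  bad <- names(ref_by_site)[ref_by_site > 1]
  if (length(bad))
    stop("ref-mismatch between callers at site(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  # per-record allele carrier counts, by allele index
  a1 <- substr(recs$gt, 1, 1); dim(a1) <- dim(recs$gt)
  a2 <- substr(recs$gt, 3, 3); dim(a2) <- dim(recs$gt)
  alts <- strsplit(recs$alt, ",", fixed = TRUE)
  max_k <- max(lengths(alts))
  carried <- matrix(FALSE, nrow(recs), max_k)
  for (k in seq_len(max_k)) {
    ck <- as.character(k)
    carried[, k] <- rowSums(a1 == ck | a2 == ck, na.rm = TRUE) > 0
  }

  allele_tbl <- tibble::tibble(
    key = rep(key, lengths(alts)),
    allele = unlist(alts),
    carried = carried[cbind(rep(seq_len(nrow(recs)), lengths(alts)),
                            unlist(lapply(lengths(alts), seq_len)))])
  allele_sum <- allele_tbl |>
    dplyr::group_by(.data$key, .data$allele) |>
    dplyr::summarise(carried = any(.data$carried), .groups = "drop_last") |>
    dplyr::summarise(
      alt_all = paste(sort(unique(.data$allele)), collapse = ","),
      alt_pass = paste(sort(unique(.data$allele[.data$carried])), collapse = ","),
      .groups = "drop")

  sites <- tibble::tibble(key = key, chrom = recs$chrom, pos = recs$pos,
                          ref = recs$ref, qual = recs$qual) |>
    dplyr::group_by(.data$key, .data$chrom, .data$pos, .data$ref) |>
    dplyr::summarise(
      n_callers = dplyr::n(),
      n_support = sum(.data$qual > qual_min),
      min_qual = min(.data$qual),
      max_qual = max(.data$qual),
      .groups = "drop") |>
    dplyr::left_join(allele_sum, by = "key") |>
    dplyr::mutate(pass_stage1 = .data$n_support >= 2) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::select(-"key")
  sites
}

#' Build the highest-confidence training set
#'
#' A stage-1 site enters the recalibration training set iff (i) it is
#' reported by all callers, each with site quality strictly above
#' `qual_train`; (ii) the merged allele set is biallelic; and (iii) the minor
#' allele count is at least `mac_min`, counting only samples of the primary
#' caller whose genotype quality exceeds `gq_min`.
#'
#' @param sites Stage-1 merged table from [stage1_consensus()].
#' @param calls_list The caller-call tibbles passed to stage 1.
#' @param primary Caller id whose genotypes seed the counts (default: first
#'   caller).
#' @param qual_train,gq_min,mac_min Thresholds (defaults 100, 30, 3).
#' @return The training subset of `sites`, with a `mac` column.  Errors if
#'   fewer training sites remain than twice the number of recalibration
#'   annotations.
#' @export
build_training_set <- function(sites, calls_list, primary = NULL,
                               qual_train = 100, gq_min = 30, mac_min = 3) {
  ids <- vapply(calls_list, function(x) x$caller[1], "")
  if (is.null(primary)) primary <- ids[1]
  if (!primary %in% ids) stop("unknown primary caller: ", primary)
  prim <- calls_list[[match(primary, ids)]]

  cand <- sites[sites$n_callers == length(calls_list) &
                  sites$min_qual > qual_train &
                  !grepl(",", sites$alt_all, fixed = TRUE) &
                  sites$alt_all != "", ]
  pk <- paste(prim$chrom, prim$pos)
  idx <- match(paste(cand$chrom, cand$pos), pk)
  mac <- vapply(seq_len(nrow(cand)), function(i) {
    j <- idx[i]
    if (is.na(j)) return(0L)
    ok <- !is.na(prim$gq[j, ]) & prim$gq[j, ] > gq_min & !is.na(prim$gt[j, ])
    if (!any(ok)) return(0L)
    d <- gt_to_dosage(prim$gt[j, ok, drop = FALSE])
    alt_cnt <- sum(d)
    as.integer(min(alt_cnt, 2 * sum(ok) - alt_cnt))
  }, integer(1))
  train <- cand[mac >= mac_min, ]
  train$mac <- mac[mac >= mac_min]
  if (nrow(train) < 2 * length(recal_annotations()))
    stop("insufficient training set: ", nrow(train), " sites (< ",
         2 * length(recal_annotations()), ")")
  train
}

# log multivariate normal density, cholesky-based
ldmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * length(mu) * log(2 * pi)
}

#' Fit the Gaussian recalibration model
#'
#' Fits one multivariate Gaussian to the annotation vectors of the training
#' sites and another to all candidate sites (the background); each scored
#' site gets `VQSLOD = ln N(x; mu_T, Sigma_T) - ln N(x; mu_B, Sigma_B)`, the
#' log odds of being a true variant.  Missing annotation values are imputed
#' with the training median of that annotation.  Covariances are ridge
#' regularized; a covariance still singular after escalating the ridge is a
#' numeric error naming the most collinear annotation pair.
#'
#' @param site_ann Tibble with `chrom, pos` and the annotation columns
#'   (typically the primary caller's records restricted to stage-1 passing
#'   sites).
#' @param train Logical vector along `site_ann`, or a tibble with
#'   `chrom, pos` keys of training sites.
#' @param annotations Annotation names (default [recal_annotations()]).
#' @param ridge Ridge factor: each covariance gets `ridge` times its own
#'   diagonal added (annotation scales differ by orders of magnitude, so
#'   the ridge is per-annotation, never a pooled constant).
#' @return Object of class `recal_model`: annotation list, training and
#'   background moments, and a `scores` tibble (`chrom, pos, vqslod`).
#' @export
fit_recal_model <- function(site_ann, train, annotations = recal_annotations(),
                            ridge = 0.05) {
  annotations <- intersect(annotations, names(site_ann))
  if (!length(annotations)) stop("no annotation columns present")
  if (!is.logical(train))
    train <- paste(site_ann$chrom, site_ann$pos) %in% paste(train$chrom, train$pos)
  if (sum(train) < 2 * length(annotations))
    stop("insufficient training set: ", sum(train), " sites")
  X <- as.matrix(site_ann[, annotations])
  med <- apply(X[train, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  for (j in seq_along(annotations)) X[is.na(X[, j]), j] <- med[j]

  moments <- function(M) {
    mu <- colMeans(M)
    S <- stats::cov(M)
    lam <- ridge
    repeat {
      # ridge scaled per annotation: scales differ by orders of magnitude
      Sr <- S + diag(pmax(lam * diag(S), 1e-10), ncol(S))
      ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
      if (ok) return(list(mu = mu, sigma = Sr))
      lam <- lam * 10
      if (lam > 1) {
        cc <- stats::cov2cor(S); diag(cc) <- 0
        ij <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
        stop("singular covariance: annotations '", annotations[ij[1]],
             "' and '", annotations[ij[2]], "' are collinear")
      }
    }
  }
  mb <- moments(X)
  mt <- moments(X[train, , drop = FALSE])
  vq <- ldmvnorm(X, mt$mu, mt$sigma) - ldmvnorm(X, mb$mu, mb$sigma)
  if (any(!is.finite(vq))) stop("non-finite VQSLOD produced")
  structure(list(annotations = annotations,
                 mu_train = mt$mu, sigma_train = mt$sigma,
                 mu_background = mb$mu, sigma_background = mb$sigma,
                 imputed_medians = med,
                 train = train,
                 scores = tibble::tibble(chrom = site_ann$chrom,
                                         pos = site_ann$pos, vqslod = vq)),
            class = "recal_model")
}

#' Robust VQSLOD cutoff: median minus a multiple of the MAD
#'
#' `cutoff = median(x) - multiplier * MAD(x)` with the *unscaled* median
#' absolute deviation `MAD = median(|x - median(x)|)` (no 1.4826 consistency
#' factor).
#'
#' @param x Training-set VQSLOD values (needs at least 3).
#' @param multiplier MAD multiplier, default 3.
#' @return The cutoff value.
#' @examples
#' vqslod_cutoff(c(1, 2, 3, 4, 5))  # median 3, MAD 1 -> 0
#' @export
vqslod_cutoff <- function(x, multiplier = 3) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("insufficient data: need >= 3 VQSLOD values")
  m <- stats::median(x)
  m - multiplier * stats::median(abs(x - m))
}

#' Apply the stage-2 recalibration filter
#'
#' A site is retained iff its VQSLOD is greater than or equal to the cutoff
#' (sites exactly at the boundary are kept; only `VQSLOD < cutoff` fails).
#'
#' @param sites Site tibble with `chrom, pos` (e.g. the stage-1 table).
#' @param model A fitted [fit_recal_model()].
#' @param cutoff Cutoff value; default computes [vqslod_cutoff()] on the
#'   model's training scores.
#' @param truth Optional truth tibble (`chrom, pos, class`) for per-class
#'   retention counts, attached as attribute `"class_report"`.
#' @return `sites` with `vqslod` and `pass_stage2` columns.
#' @export
apply_stage2 <- function(sites, model, cutoff = NULL, truth = NULL) {
  stopifnot(inherits(model, "recal_model"))
  if (is.null(cutoff))
    cutoff <- vqslod_cutoff(model$scores$vqslod[model$train])
  out <- dplyr::left_join(sites, model$scores, by = c("chrom", "pos"))
  out$pass_stage2 <- !is.na(out$vqslod) & out$vqslod >= cutoff
  attr(out, "cutoff") <- cutoff
  if (!is.null(truth)) {
    rep_tbl <- dplyr::left_join(out, truth, by = c("chrom", "pos")) |>
      dplyr::count(.data$class, .data$pass_stage2)
    attr(out, "class_report") <- rep_tbl
  }
  out
}

#' Mask low-confidence genotypes
#'
#' Sets genotypes with posterior probability strictly below `threshold` to
#' missing (never to reference).  Genotypes whose GP is absent are left
#' untouched.
#'
#' @param calls Caller-call tibble with `gt` and `gp` matrix-columns.
#' @param threshold Minimum genotype probability kept, default 0.95.
#' @return `calls` with masked `gt` (and `gq`, `gp` set `NA` alongside).
#' @export
gp_mask <- function(calls, threshold = 0.95) {
  mask <- !is.na(calls$gp) & calls$gp < threshold
  calls$gt[mask] <- NA_character_
  calls$gq[mask] <- NA_real_
  calls$gp[mask] <- NA_real_
  calls
}

#' Run the full two-stage variant filter
#'
#' Chains [stage1_consensus()], [build_training_set()],
#' [fit_recal_model()], [vqslod_cutoff()], [apply_stage2()] and
#' [gp_mask()], and materializes the retained sites as a genotype table
#' built from the primary caller's (masked) genotypes.
#'
#' @param calls_list List of caller-call tibbles.
#' @param primary Primary caller id (default: first).
#' @param qual_min,qual_train,gq_min,mac_min,gp_min Thresholds as in the
#'   stage functions.
#' @param mad_multiplier MAD multiplier of the cutoff.
#' @param truth Optional truth table for per-class reporting.
#' @return Object of class `filter_result`: `sites` (flags and VQSLOD for
#'   every merged site), `geno` (retained sites), `model`, `cutoff`, and a
#'   one-row `report` tibble (per-stage counts and retained ts/tv).
#' @export
filter_variants <- function(calls_list, primary = NULL,
                            qual_min = 30, qual_train = 100, gq_min = 30,
                            mac_min = 3, gp_min = 0.95, mad_multiplier = 3,
                            truth = NULL) {
  ids <- vapply(calls_list, function(x) x$caller[1], "")
  if (is.null(primary)) primary <- ids[1]
  sites <- stage1_consensus(calls_list, qual_min = qual_min)
  train <- build_training_set(sites, calls_list, primary = primary,
                              qual_train = qual_train, gq_min = gq_min,
                              mac_min = mac_min)
  prim <- calls_list[[match(primary, ids)]]
  s1 <- sites[sites$pass_stage1, ]
  pk <- paste(prim$chrom, prim$pos)
  j_ann <- match(paste(s1$chrom, s1$pos), pk)
  # stage-1 passers the primary caller missed keep an all-NA annotation row:
  # the model imputes training medians rather than dropping the site
  site_ann <- tibble::tibble(chrom = s1$chrom, pos = s1$pos)
  for (k in recal_annotations()) site_ann[[k]] <- prim[[k]][j_ann]
  model <- fit_recal_model(site_ann, train)
  cutoff <- vqslod_cutoff(model$scores$vqslod[model$train],
                          multiplier = mad_multiplier)
  sites2 <- apply_stage2(sites[sites$pass_stage1, ], model, cutoff = cutoff,
                         truth = truth)
  sites <- dplyr::left_join(
    sites, sites2[, c("chrom", "pos", "vqslod", "pass_stage2")],
    by = c("chrom", "pos"))
  sites$pass_stage2[is.na(sites$pass_stage2)] <- FALSE
  sites$in_training <- paste(sites$chrom, sites$pos) %in%
    paste(train$chrom, train$pos)

  keep <- sites[sites$pass_stage1 & sites$pass_stage2, ]
  prim_masked <- gp_mask(prim, threshold = gp_min)
  j <- match(paste(keep$chrom, keep$pos), paste(prim_masked$chrom, prim_masked$pos))
  keep <- keep[!is.na(j), ]
  j <- j[!is.na(j)]
  geno <- geno_table(keep$chrom, keep$pos, keep$ref,
                     ifelse(keep$alt_pass == "", keep$alt_all, keep$alt_pass),
                     gt_to_dosage(prim_masked$gt[j, , drop = FALSE]))

  tt <- tstv(geno)
  report <- tibble::tibble(
    n_input_sites = nrow(sites),
    n_stage1 = sum(sites$pass_stage1),
    n_training = nrow(train),
    cutoff = cutoff,
    n_retained = nrow(geno),
    ts = tt$ts, tv = tt$tv, tstv = tt$ratio)
  structure(list(sites = sites, geno = geno, model = model, cutoff = cutoff,
                 report = report,
                 class_report = attr(sites2, "class_report")),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Two-stage variant filter\n")
  cat(sprintf("  sites in: %d | stage1 pass: %d | training: %d\n",
              x$report$n_input_sites, x$report$n_stage1, x$report$n_training))
  cat(sprintf("  VQSLOD cutoff (median - 3*MAD): %.3f | retained: %d | ts/tv: %.2f\n",
              x$cutoff, x$report$n_retained, x$report$tstv))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.recal_model <- function(x, ...) x$scores

#' @export
glance.recal_model <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$scores), n_train = sum(x$train),
                 n_annotations = length(x$annotations),
                 vqslod_median_train = stats::median(x$scores$vqslod[x$train]))
}

#' @export
tidy.filter_result <- function(x, ...) x$sites

#' @export
glance.filter_result <- function(x, ...) x$report
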