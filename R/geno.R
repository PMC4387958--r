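#' Genotype tables
#'
#' The central container of the package is a plain tibble with one row per
#' variant site and a matrix-column `dos` holding diploid allele dosages
#' (0/1/2 copies of the first alternate allele; `NA` = missing call), one
#' column per sample.  Keeping sites as rows means the usual dplyr verbs
#' (filter on position, arrange, join against interval tables) work directly,
#' while the dosage block stays a numeric matrix for linear-algebra work.
#'
#' Required columns: `chrom` (character), `pos` (1-based bp, integer),
#' `ref`, `alt` (comma-separated if multi-allelic), `type` ("snp"/"indel"),
#' and the matrix-column `dos`.
#'
#' @param chrom,pos,ref,alt Per-site vectors.
#' @param dos Numeric matrix, sites x samples; column names are sample ids.
#' @param type Optional per-site class; inferred from allele lengths when
#'   missing (single-base ref and all alts single-base -> "snp").
#' @return A tibble of class `tbl_df` with the columns above.
#' @examples
#' g <- geno_table("chr1", c(100L, 200L), c("A", "T"), c("G", "TA"),
#'                 dos = matrix(c(0, 1, 2, 0), 2, 2,
#'                              dimnames = list(NULL, c("s1", "s2"))))
#' geno_samples(g)
#' @export
geno_table <- function(chrom, pos, ref, alt, dos, type = NULL) {
  n <- length(pos)
  stopifnot(is.matrix(dos), nrow(dos) == n, !is.null(colnames(dos)))
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (is.null(type)) {
    alt_single <- !vapply(strsplit(alt, ",", fixed = TRUE),
                          function(a) any(nchar(a) != 1L), logical(1))
    type <- ifelse(nchar(ref) == 1L & alt_single, "snp", "indel")
  }
  out <- tibble::tibble(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    type = rep_len(type, n)
  )
  out$dos <- dos
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' @rdname geno_table
#' @param geno A genotype table.
#' @export
geno_samples <- function(geno) colnames(geno$dos)

#' @rdname geno_table
#' @export
is_biallelic <- function(geno) !grepl(",", geno$alt, fixed = TRUE)

#' Read a two-column population map
#'
#' A population map assigns every sample to exactly one population label.
#' The file is a headerless two-column TSV: sample id, population label.
#'
#' @param path TSV path.
#' @return Tibble with columns `sample`, `population`.
#' @export
read_population_map <- function(path) {
  pm <- readr::read_tsv(path, col_names = c("sample", "population"),
                        col_types = "cc", progress = FALSE)
  if (anyDuplicated(pm$sample))
    stop("duplicated sample id(s) in population map: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  pm
}

#' Check a population map against a genotype table
#'
#' @param geno Genotype table.
#' @param pop_map Tibble `sample`, `population`.
#' @param allow_subset If `TRUE`, the map may cover only part of the
#'   genotype samples (e.g. after [equalize_samples()]) and the analysis is
#'   restricted to the mapped ones; otherwise unmapped samples are an error.
#' @return Invisibly, the map restricted and ordered to the genotype samples.
#' @export
match_population_map <- function(geno, pop_map, allow_subset = FALSE) {
  smp <- geno_samples(geno)
  miss <- setdiff(smp, pop_map$sample)
  if (length(miss) && !allow_subset)
    stop("samples missing from population map: ", paste(miss, collapse = ", "))
  pop_map[stats::na.omit(match(smp, pop_map$sample)), ]
}

# Dosage submatrix for the samples of one population.
pop_dosage <- function(geno, pop_map, population) {
  smp <- pop_map$sample[pop_map$population == population]
  geno$dos[, intersect(geno_samples(geno), smp), drop = FALSE]
}
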