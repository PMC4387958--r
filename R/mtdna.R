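#' Segregating sites of an alignment
#'
#' Positions where at least two distinct unambiguous nucleotide states
#' (A/C/G/T) occur; variation involving only gaps or ambiguity codes does
#' not count.
#'
#' @param alignment Named character vector of equal-length sequences (as
#'   from [read_fasta_alignment()] or [simulate_mtdna()]).
#' @return Integer vector of 1-based positions.
#' @export
segregating_sites <- function(alignment) {
  mat <- .aln_matrix(alignment)
  states <- apply(mat, 2, function(col) length(unique(col[col %in% c("A", "C", "G", "T")])))
  which(states >= 2)
}

.aln_matrix <- function(alignment) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  mat
}

#' Collapse sequences into haplotypes
#'
#' Sequences identical over their mutually unambiguous positions merge into
#' one haplotype: an `N` (or gap) matches either state, so a sequence only
#' founds a new haplotype if it conflicts with every existing one at some
#' position where both carry a plain nucleotide.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Object of class `haplotype_set`: `n_haplotypes`,
#'   `segregating_sites`, and a `haplotypes` tibble (`haplotype, n_members,
#'   members`).
#' @export
collapse_haplotypes <- function(alignment) {
  mat <- .aln_matrix(alignment)
  plain <- mat %in% c("A", "C", "G", "T")
  dim(plain) <- dim(mat)
  reps <- integer(0)          # row index of each haplotype's representative
  assign <- integer(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    hit <- 0L
    for (h in seq_along(reps)) {
      r <- reps[h]
      both <- plain[i, ] & plain[r, ]
      if (!any(mat[i, both] != mat[r, both])) { hit <- h; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    assign[i] <- hit
  }
  members <- split(rownames(mat), assign)
  structure(list(
    n_haplotypes = length(reps),
    segregating_sites = segregating_sites(alignment),
    haplotypes = tibble::tibble(
      haplotype = sprintf("H%02d", seq_along(members)),
      n_members = unname(lengths(members)),
      members = unname(members))),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("%d haplotypes over %d sequences; %d segregating sites\n",
              x$n_haplotypes, sum(x$haplotypes$n_members),
              length(x$segregating_sites)))
  invisible(x)
}

#' @export
tidy.haplotype_set <- function(x, ...) x$haplotypes

#' Extract an alignment sub-region
#'
#' @param alignment Named character vector.
#' @param start,end 1-based inclusive column range.
#' @return The sub-alignment (named character vector of length
#'   `end - start + 1` columns).
#' @export
extract_region <- function(alignment, start, end) {
  len <- unique(nchar(alignment))
  if (length(len) != 1) stop("ragged alignment")
  stopifnot(start >= 1, end <= len, start <= end)
  substr(alignment, start, end)
}

#' Share of variation carried by a sub-region
#'
#' Compares the density of segregating sites inside a region (e.g. the
#' hypervariable control-region segment) with the whole alignment:
#' `variant_share` = region segregating sites / total segregating sites;
#' `length_share` = region length / alignment length.
#'
#' @param alignment Named character vector.
#' @param start,end Region bounds, 1-based inclusive.
#' @return One-row tibble `n_region, n_total, variant_share, length_share`.
#' @examples
#' region_share_pct(64, 239)  # share from externally reported counts
#' @export
region_share <- function(alignment, start, end) {
  ss <- segregating_sites(alignment)
  n_total <- length(ss)
  n_region <- sum(ss >= start & ss <= end)
  len <- unique(nchar(alignment))
  tibble::tibble(n_region = n_region, n_total = n_total,
                 variant_share = if (n_total) n_region / n_total else 0,
                 length_share = (end - start + 1) / len)
}

#' @rdname region_share
#' @param n_region,n_total Segregating-site counts.
#' @return `region_share_pct()`: percentage `100 * n_region / n_total`.
#' @export
region_share_pct <- function(n_region, n_total) 100 * n_region / n_total
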