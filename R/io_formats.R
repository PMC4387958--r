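#' Read a VCF file into a caller-call table
#'
#' Reads the VCF v4.2 subset the pipeline uses: `CHROM POS REF ALT QUAL`,
#' INFO keys among the seven recalibration annotations
#' (`QD, HaplotypeScore, MQRankSum, ReadPosRankSum, FS, DP,
#' InbreedingCoefficient`) and per-sample `GT:GQ:GP`.  `GP` is the posterior
#' probability of the called genotype, a single number in \[0,1\]; if a file
#' carries the usual genotype-probability triplet, its maximum is taken.
#' Parsing is delegated to \pkg{vcfR}.
#'
#' Missing INFO annotations stay `NA` (absent, never zero); a missing
#' genotype stays `NA` in all three genotype matrices.
#'
#' @param path VCF path (plain text).
#' @param caller_id Label recorded in the `caller` column.  Multi-caller
#'   inputs arrive as one file per caller; the label is supplied here, not
#'   guessed from headers.
#' @return A tibble with one row per site: `chrom, pos, ref, alt, qual,
#'   caller`, one numeric column per annotation, and matrix-columns
#'   `gt` (genotype strings, e.g. `"0/1"`), `gq`, `gp`.
#' @export
read_vcf <- function(path, caller_id = "caller1") {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  # sorted order within each chromosome block, blocks must not interleave
  if (anyDuplicated(rle(chrom)$values))
    stop("unsorted VCF: chromosome blocks interleave in '", path, "'")
  bad <- which(diff(pos) < 0 & chrom[-1] == chrom[-length(chrom)])
  if (length(bad))
    stop("unsorted VCF: record ", chrom[bad[1] + 1], ":", pos[bad[1] + 1],
         " out of order in '", path, "'")

  out <- tibble::tibble(
    chrom = chrom, pos = pos,
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    caller = caller_id
  )
  for (k in recal_annotations()) {
    out[[k]] <- suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  gp_raw <- vcfR::extract.gt(v, element = "GP")
  if (any(grepl(",", gp_raw, fixed = TRUE), na.rm = TRUE)) {
    gp <- vapply(strsplit(gp_raw, ",", fixed = TRUE), function(x)
      if (length(x) == 0 || all(is.na(x))) NA_real_
      else max(suppressWarnings(as.numeric(x))), numeric(1))
    dim(gp) <- dim(gp_raw)
    dimnames(gp) <- dimnames(gp_raw)
  } else {
    gp <- suppressWarnings(array(as.numeric(gp_raw), dim = dim(gp_raw),
                                 dimnames = dimnames(gp_raw)))
  }
  rownames(gt) <- rownames(gq) <- rownames(gp) <- NULL
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out$gt <- gt
  out$gq <- gq
  out$gp <- gp
  out
}

#' The seven recalibration annotations
#'
#' @return Character vector of INFO keys used by the Gaussian recalibration
#'   model.
#' @export
recal_annotations <- function() {
  c("QD", "HaplotypeScore", "MQRankSum", "ReadPosRankSum", "FS", "DP",
    "InbreedingCoefficient")
}

#' Write a caller-call table back to VCF
#'
#' Inverse of [read_vcf()] on the supported fields; the written file
#' round-trips through [read_vcf()] to identical records.
#'
#' @param calls Tibble as produced by [read_vcf()] or
#'   [emit_caller_vcfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (any(o != seq_len(nrow(calls)))) stop("records must be sorted by (chrom, pos)")
  }
  samples <- colnames(calls$gt)
  if (is.null(samples) && nrow(calls)) stop("calls carry no genotype matrix")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            recal_annotations(), recal_annotations()),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=GP,Number=1,Type=Float,Description=\"Posterior probability of called genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", if (length(samples)) samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(calls)) {
    ann <- as.matrix(calls[, recal_annotations()])
    info <- vapply(seq_len(nrow(calls)), function(i) {
      keep <- !is.na(ann[i, ])
      if (!any(keep)) return(".")
      paste(colnames(ann)[keep], formatC(ann[i, keep], format = "g", digits = 8),
            sep = "=", collapse = ";")
    }, character(1))
    gt <- calls$gt; gq <- calls$gq; gp <- calls$gp
    fmt <- matrix(paste(ifelse(is.na(gt), "./.", gt),
                        ifelse(is.na(gq), ".", formatC(gq, format = "g", digits = 8)),
                        ifelse(is.na(gp), ".", formatC(gp, format = "g", digits = 8)),
                        sep = ":"),
                  nrow = nrow(gt))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  formatC(calls$qual, format = "g", digits = 8), "PASS", info,
                  "GT:GQ:GP",
                  apply(fmt, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene-interval table
#'
#' Internal coordinates are 1-based inclusive everywhere in the package
#' (the VCF convention); BED input (0-based half-open) is converted at this
#' boundary.
#'
#' @param path Path to a headerless BED3+1 file (`chrom start end gene_id`)
#'   or a 1-based TSV (`gene_id chrom start end`).
#' @param format `"bed"` or `"tsv"`; the coordinate convention is declared,
#'   never guessed.
#' @return Tibble `gene_id, chrom, start, end` (1-based inclusive).
#' @export
read_gene_table <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "gene_id"),
                          col_types = "ciic", progress = FALSE)
    if (any(df$start0 >= df$end))
      stop("gene table format error: start >= end (BED half-open)")
    out <- tibble::tibble(gene_id = df$gene_id, chrom = df$chrom,
                          start = df$start0 + 1L, end = df$end)
  } else {
    out <- readr::read_tsv(path, col_names = c("gene_id", "chrom", "start", "end"),
                           col_types = "ccii", progress = FALSE)
    if (any(out$start > out$end))
      stop("gene table format error: start > end")
  }
  if (anyDuplicated(out$gene_id))
    stop("gene table format error: duplicated gene_id")
  out
}

#' Convert gene intervals between internal and BED coordinates
#'
#' Self-inverse pair: `genes_to_bed()` then [read_gene_table()] (or
#' `bed_to_genes()`) reproduces the input.
#'
#' @param genes Tibble `gene_id, chrom, start, end`, 1-based inclusive.
#' @return Tibble in BED column order with 0-based half-open coordinates.
#' @export
genes_to_bed <- function(genes) {
  tibble::tibble(chrom = genes$chrom, start = genes$start - 1L,
                 end = genes$end, name = genes$gene_id)
}

#' @rdname genes_to_bed
#' @param bed Tibble `chrom, start, end, name` in BED convention.
#' @export
bed_to_genes <- function(bed) {
  tibble::tibble(gene_id = bed$name, chrom = bed$chrom,
                 start = bed$start + 1L, end = bed$end)
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over \pkg{Biostrings} returning plain named character
#' vectors (upper case), the alignment representation used by the mtDNA
#' statistics.
#'
#' @param path FASTA path.
#' @return `read_fasta_alignment()`: named character vector of sequences.
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta_alignment
#' @param seqs Named character vector of sequences.
#' @export
write_fasta_alignment <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Turn a caller-call table into a genotype table
#'
#' Takes one caller's genotype strings and produces the dosage-matrix
#' genotype table used by all downstream statistics.  The dosage counts
#' copies of the *first* alternate allele; for multi-allelic sites other
#' alternate alleles contribute to dosage as non-reference copies of their
#' own index and are tracked through `alt`.
#'
#' @param calls Caller-call tibble (one caller).
#' @return Genotype table (see [geno_table()]).
#' @export
calls_to_geno <- function(calls) {
  dos <- gt_to_dosage(calls$gt)
  geno_table(calls$chrom, calls$pos, calls$ref, calls$alt, dos)
}

# "0/1" strings -> dosage of any non-reference allele (0,1,2; NA missing).
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 != "0") + (a2 != "0")
  d[is.na(gt)] <- NA_real_
  dim(d) <- dim(gt)
  colnames(d) <- colnames(gt)
  d
}
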