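# Plain-text I/O: repeat-pair tables, block orders, depth summaries,
# population maps, and a minimal haploid GT-only VCF dialect. TSV tables
# keep the package's 0-based half-open coordinates; VCF positions are
# 1-based as the format requires.

#' Write repeat pairs to TSV
#' @param pairs `repeat_pairs` data.frame
#' @param path output file
#' @export
write_repeats_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read repeat pairs from TSV
#' @param path file written by [write_repeats_tsv()]
#' @export
read_repeats_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

#' Write repeat pairs as BED (both loci, 0-based half-open)
#' @param pairs `repeat_pairs` data.frame
#' @param path output file
#' @param chrom chromosome/molecule name
#' @export
write_repeats_bed <- function(pairs, path, chrom = "mito") {
  n <- nrow(pairs)
  bed <- data.frame(
    chrom = chrom,
    start = c(pairs$startA, pairs$startB),
    end = c(pairs$endA, pairs$endB),
    name = rep(sprintf("repeat_%d", seq_len(n)), 2L),
    score = 0L,
    strand = c(pairs$strandA, pairs$strandB)
  )
  bed <- bed[order(bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write signed block orders (one genome per row, comma-separated)
#' @param orders named list of `signed_perm` or signed integer vectors
#' @param path output file
#' @export
write_block_orders <- function(orders, path) {
  lines <- vapply(names(orders), function(id) {
    paste0(id, "\t", paste(perm_blocks(orders[[id]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read signed block orders
#' @param path file written by [write_block_orders()]
#' @return named list of `signed_perm`
#' @export
read_block_orders <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1L]]
    signed_perm(as.integer(strsplit(parts[2L], ",")[[1L]]), genome_id = parts[1L])
  })
  names(out) <- vapply(out, function(p) p$genome_id, character(1))
  out
}

#' Write a population map (sample, group)
#' @param pops named character vector sample -> group
#' @param path output file
#' @export
write_pop_map <- function(pops, path) {
  utils::write.table(data.frame(sample = names(pops), group = unname(pops)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population map
#' @param path TSV with columns sample, group
#' @return named character vector sample -> group
#' @export
read_pop_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' Write a haploid GT-only VCF
#'
#' Minimal VCF 4.2: integer allele codes are written as haploid GT values
#' (`.` for missing); REF/ALT bases are placeholders encoding the allele
#' codes (the matrix carries no nucleotide states).
#'
#' @param vm `variant_matrix`
#' @param path output file
#' @param chrom molecule name
#' @export
write_vcf_haploid <- function(vm, path, chrom = "mito") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, vm$ref_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vm$gt)), collapse = "\t")
  ), con)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(vm$gt))) {
    g <- vm$gt[i, ]
    nalt <- max(c(g, 1L), na.rm = TRUE)
    alt <- paste(bases[seq_len(min(nalt, 3L)) + 1L], collapse = ",")
    gs <- ifelse(is.na(g), ".", as.character(g))
    writeLines(paste(c(chrom, vm$pos[i], ".", "A", alt, ".", "PASS", ".",
                       "GT", gs), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a haploid GT-only VCF into a variant matrix
#'
#' @param path VCF file (haploid GT field)
#' @param pops named character vector sample -> population
#' @param ref_len circle length; taken from the contig header if absent
#' @return `variant_matrix`
#' @export
read_vcf_haploid <- function(path, pops, ref_len = NULL) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt_chr <- vcfR::extract.gt(v, element = "GT")
    pos <- as.integer(vcfR::getPOS(v))
    if (is.null(ref_len)) {
      m <- regmatches(v@meta, regexpr("length=\\d+", v@meta))
      if (length(m)) ref_len <- as.integer(sub("length=", "", m[[1L]]))
    }
  } else {
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "##")]
    hdr <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1L]]
    body <- lines[!startsWith(lines, "#")]
    fields <- strsplit(body, "\t")
    pos <- as.integer(vapply(fields, `[`, character(1), 2L))
    gt_chr <- t(vapply(fields, function(f) f[10:length(f)],
                       character(length(hdr) - 9L)))
    colnames(gt_chr) <- hdr[10:length(hdr)]
    if (is.null(ref_len)) {
      m <- regmatches(meta, regexpr("length=\\d+", meta))
      if (length(m)) ref_len <- as.integer(sub("length=", "", m[[1L]]))
    }
  }
  # haploid GT: single allele code, "." missing
  gt <- suppressWarnings(matrix(as.integer(gt_chr), nrow = nrow(gt_chr),
                                dimnames = dimnames(gt_chr)))
  if (is.null(ref_len)) ref_len <- max(pos)
  variant_matrix(gt, pos, pops[colnames(gt)], ref_len)
}

#' Write a per-sample depth summary (sample, Idep, Wdep)
#' @param df data.frame with at least sample, Idep, Wdep
#' @param path output file
#' @export
write_depth_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample depth summary
#' @param path TSV with columns sample, Idep, Wdep
#' @export
read_depth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
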