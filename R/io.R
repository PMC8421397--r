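#' Read and write the tabular interchange files of the pipeline
#'
#' Plain TSV readers/writers for the barcode manifest, count tables,
#' BEDPE interaction files and BED peak files, plus a VCF-backed
#' genotype-panel reader. All interval files use 0-based half-open
#' coordinates; variants are 1-based (VCF convention).
#'
#' @param x Object to write (data frame, or matrix for counts).
#' @param path File path.
#' @name emvarkit-io
NULL

#' @rdname emvarkit-io
#' @export
write_manifest <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname emvarkit-io
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname emvarkit-io
#' @export
write_counts <- function(x, path) {
  df <- data.frame(barcode = rownames(x), as.data.frame(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname emvarkit-io
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname emvarkit-io
#' @export
write_bedpe <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname emvarkit-io
#' @export
read_bedpe <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname emvarkit-io
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname emvarkit-io
#' @export
read_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated genotype panel as VCF
#'
#' Minimal unphased diploid VCF (GT field only) for panels from
#' [simulate_genotypes()].
#'
#' @param panel List with `variants` and `dosages` as produced by
#'   [simulate_genotypes()].
#' @param path Output path.
#' @export
write_vcf_panel <- function(panel, path) {
  v <- panel$variants
  dos <- panel$dosages
  gt <- c("0/0", "0/1", "1/1")
  samples <- paste0("S", seq_len(nrow(dos)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(v))) {
    line <- c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
              ".", "GT", gt[dos[, v$id[i]] + 1L])
    writeLines(paste(line, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses a diploid VCF into the `variants` + `dosages` panel structure
#' used by [select_candidates()]. Multiallelic records are kept (with
#' comma-separated `alt`) so that candidate selection can exclude them
#' by rule; their dosage column counts any non-reference allele.
#'
#' @param path VCF path.
#' @return List with `variants` and `dosages`.
#' @export
read_vcf_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosages <- apply(gt, c(1L, 2L), function(g) {
    if (is.na(g)) return(NA_real_)
    a <- strsplit(g, "[/|]")[[1L]]
    sum(a != "0" & a != ".")
  })
  dosages <- t(dosages)
  colnames(dosages) <- variants$id
  list(variants = variants, dosages = dosages)
}
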