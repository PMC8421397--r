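#' Count exact barcode matches in sequenced reads
#'
#' Sequencing reads cover the barcode on the opposite strand, so each
#' read's barcode slice is reverse-complemented before matching. Only
#' exact matches against the manifest are counted; anything else is
#' tallied as unmatched, never rescued.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (optionally gzipped).
#' @param manifest Barcode manifest data frame with a `barcode` column;
#'   duplicate barcodes are a hard error.
#' @param offset 1-based position of the barcode within each read.
#' @param width Barcode length in nt.
#' @return List with `counts` (integer vector named by manifest barcode,
#'   one increment per matched read) and `unmatched` (count of reads
#'   matching no manifest barcode).
#' @export
match_barcodes <- function(reads, manifest, offset = 1L, width = 10L) {
  if (anyDuplicated(manifest$barcode)) {
    stop("manifest contains duplicate barcodes; refusing ambiguous counting")
  }
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  slice <- substring(reads, offset, offset + width - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(slice)))
  tab <- table(factor(rc, levels = manifest$barcode))
  counts <- as.integer(tab)
  names(counts) <- manifest$barcode
  list(counts = counts, unmatched = length(reads) - sum(counts))
}

#' Drop barcodes with insufficient DNA representation
#'
#' Barcodes poorly represented in the plasmid input give unstable
#' activity ratios and are removed before quantification.
#'
#' @param counts Count matrix, barcodes x samples; the DNA input column
#'   is named by `dna_col`.
#' @param min_dna Minimum raw DNA count for a barcode to be retained.
#' @param dna_col Name of the DNA input column (default `"dna"`).
#' @return The filtered matrix, with attribute `removed_fraction`.
#' @export
filter_low_barcodes <- function(counts, min_dna = 10L, dna_col = "dna") {
  if (!dna_col %in% colnames(counts)) {
    stop("DNA column '", dna_col, "' not found in count table")
  }
  keep <- counts[, dna_col] >= min_dna
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed_fraction") <- 1 - sum(keep) / nrow(counts)
  message(sprintf("filter_low_barcodes: removed %d/%d barcodes (%.1f%%) with DNA < %d",
                  sum(!keep), nrow(counts), 100 * attr(out, "removed_fraction"),
                  min_dna))
  out
}

#' Counts per million
#'
#' Column-wise library-size normalization: `count / column_sum * 1e6`.
#'
#' @param counts Non-negative count matrix (features x samples).
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size in column(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Per-barcode enhancer activity
#'
#' Activity contrasts each barcode's RNA output against its DNA input on
#' the log2 scale: `log2(rna_cpm + pc) - log2(dna_cpm + pc)`. A positive
#' value means the element drives transcription above its plasmid
#' representation. With `pseudocount = 0`, barcodes with a zero CPM on
#' either side become `NA` (undefined, flagged rather than fabricated).
#'
#' The construct is also available in a literal difference form,
#' `log2(rna_cpm - dna_cpm)` (`eq4_literal = TRUE`), for auditing: that
#' reading is undefined whenever input meets or exceeds output and is
#' not used by the pipeline.
#'
#' @param rna_cpm,dna_cpm Numeric vectors over the same barcodes.
#' @param pseudocount Non-negative stabilizer added inside each log
#'   (default 1 CPM unit).
#' @param eq4_literal Use the literal log-of-difference form.
#' @return Numeric vector of activities (log2 units), `NA` where
#'   undefined.
#' @export
activity <- function(rna_cpm, dna_cpm, pseudocount = 1, eq4_literal = FALSE) {
  stopifnot(length(rna_cpm) == length(dna_cpm), pseudocount >= 0)
  if (eq4_literal) {
    d <- rna_cpm - dna_cpm
    out <- ifelse(d > 0, log2(d), NA_real_)
  } else {
    r <- rna_cpm + pseudocount
    d <- dna_cpm + pseudocount
    out <- ifelse(r > 0 & d > 0, log2(r) - log2(d), NA_real_)
  }
  names(out) <- names(rna_cpm)
  out
}

#' Quantile normalization across replicate columns
#'
#' Classic quantile normalization: values are ranked within each column
#' and replaced by the cross-column mean of the order statistics at that
#' rank; tied values receive the mean of the reference values over their
#' tied rank positions, so the transform is well defined and idempotent.
#' After normalization every column has the same sorted value vector.
#'
#' @param x Numeric matrix with at least two columns (e.g. an activity
#'   table, barcodes x replicates). `NA`s are not supported.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (anyNA(x)) stop("quantile_normalize does not accept NA values; filter first")
  const <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    warning("column(s) with all-identical values passed through: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  ref <- rowMeans(apply(x, 2L, sort))
  cs0 <- c(0, cumsum(ref))
  out <- apply(x, 2L, function(col) {
    # a tie occupies sorted positions rank_min..rank_max; assign the mean
    # of the reference order statistics over that whole span
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Build a per-barcode activity table from counts
#'
#' Convenience wrapper running CPM, the activity contrast for every RNA
#' replicate column against the DNA input, and (optionally) quantile
#' normalization across replicates.
#'
#' @param counts Filtered count matrix with a DNA column and one column
#'   per RNA replicate.
#' @param dna_col Name of the DNA input column.
#' @param pseudocount Passed to [activity()].
#' @param quantile_norm Apply [quantile_normalize()] across replicate
#'   columns (default `TRUE`).
#' @return Numeric matrix, barcodes x RNA replicates, of activities.
#' @export
activity_table <- function(counts, dna_col = "dna", pseudocount = 1,
                           quantile_norm = TRUE) {
  cp <- cpm(counts)
  rna_cols <- setdiff(colnames(cp), dna_col)
  act <- vapply(rna_cols, function(cc) {
    activity(cp[, cc], cp[, dna_col], pseudocount = pseudocount)
  }, numeric(nrow(cp)))
  rownames(act) <- rownames(counts)
  if (quantile_norm && length(rna_cols) >= 2L) act <- quantile_normalize(act)
  act
}
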