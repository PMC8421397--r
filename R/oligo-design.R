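#' Constant segments of the reporter oligo
#'
#' The 230-nt reporter fragment is assembled as
#' `FLANK5 + enh + LINKER + barcode + FLANK3`, where `enh` is a 175-nt
#' genomic context centred on the variant and `barcode` a 10-nt tag.
#' The linker carries the KpnI (`GGTACC`) and XbaI (`TCTAGA`) sites used
#' to open the construct for promoter/GFP insertion, so those sites must
#' not occur anywhere else in the assembled fragment.
#'
#' @format A named character vector with elements `flank5` (16 nt),
#'   `linker` (12 nt) and `flank3` (17 nt).
#' @export
oligo_segments <- c(
  flank5 = "ACTGGCCGCTTCACTG",
  linker = "GGTACCTCTAGA",
  flank3 = "AGATCGGAAGAGCGTCG"
)

.KPNI <- "GGTACC"
.XBAI <- "TCTAGA"

.check_acgt <- function(seq) {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop("non-ACGT character in sequence(s): ",
         paste(utils::head(seq[bad], 3L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Validate candidate barcodes
#'
#' A barcode is valid when it has the expected length, contains no
#' homopolymer run of three or more identical bases, does not end in
#' `TCT` (which recreates an XbaI site against the downstream constant
#' region), and introduces no KpnI (`GGTACC`) or XbaI (`TCTAGA`) site
#' anywhere in its assembled context - the scan covers the junctions
#' with the linker and the 3' constant region, so sites formed across a
#' boundary are caught as well.
#'
#' @param seq Character vector of candidate barcodes (A/C/G/T only).
#' @param width Expected barcode length in nt (default 10).
#' @return Logical vector, `TRUE` for barcodes passing every rule.
#' @examples
#' is_valid_barcode(c("ACGTACGTCA", "ACGTAAAGTC", "ACGTACGTCT"))
#' @export
is_valid_barcode <- function(seq, width = 10L) {
  .check_acgt(seq)
  ok <- nchar(seq) == width
  ok <- ok & !grepl("AAA|CCC|GGG|TTT", seq)
  ok <- ok & !endsWith(seq, "TCT")
  # any restriction site overlapping the barcode lies within 5 nt of a
  # junction, so scanning linker-tail + barcode + flank3-head is exhaustive
  ctx <- paste0(substring(oligo_segments[["linker"]], 8L, 12L), seq,
                substring(oligo_segments[["flank3"]], 1L, 5L))
  ok & !grepl(.KPNI, ctx, fixed = TRUE) & !grepl(.XBAI, ctx, fixed = TRUE)
}

#' Generate distinct valid barcodes
#'
#' Draws random A/C/G/T strings and keeps those passing
#' [is_valid_barcode()] until `n` distinct barcodes are collected.
#' Deterministic for a given seed.
#'
#' @param n Number of barcodes required.
#' @param width Barcode length in nt.
#' @param seed Integer RNG seed.
#' @param max_tries Sampling batches before giving up (safety valve for
#'   near-exhausted pools).
#' @return Character vector of `n` distinct valid barcodes.
#' @export
generate_barcodes <- function(n, width = 10L, seed = 1L, max_tries = 1000L) {
  stopifnot(n >= 0, width >= 1)
  if (n == 0L) return(character(0L))
  set.seed(seed)
  pool <- character(0L)
  bases <- c("A", "C", "G", "T")
  batch <- max(1000L, 2L * n)
  for (i in seq_len(max_tries)) {
    draw <- matrix(sample(bases, batch * width, replace = TRUE), ncol = width)
    cand <- do.call(paste0, as.data.frame(draw, stringsAsFactors = FALSE))
    pool <- unique(c(pool, cand[is_valid_barcode(cand, width)]))
    if (length(pool) >= n) return(pool[seq_len(n)])
  }
  stop("barcode pool exhausted: only ", length(pool),
       " distinct valid ", width, "-mers found, ", n, " requested")
}

#' Extract the genomic enhancer context for a variant allele
#'
#' Returns the 175-nt reference sequence centred on the variant (87 nt of
#' flank on each side), with the centre base substituted by the requested
#' allele. Only single-nucleotide substitutions are supported.
#'
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome name
#'   (e.g. from [Biostrings::readDNAStringSet()]).
#' @param chrom,pos Variant location (1-based).
#' @param allele Single base to place at the centre.
#' @param width Context width in nt; must be odd (default 175).
#' @return Character string of length `width` with the allele at the
#'   centre (0-based index `(width - 1) / 2`).
#' @export
extract_context <- function(genome, chrom, pos, allele, width = 175L) {
  stopifnot(width %% 2L == 1L)
  if (nchar(allele) != 1L || !allele %in% c("A", "C", "G", "T")) {
    stop("only single-nucleotide alleles are supported, got '", allele, "'")
  }
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  half <- (width - 1L) %/% 2L
  start <- pos - half
  end <- pos + half
  if (start < 1L || end > length(genome[[chrom]])) {
    stop("variant at ", chrom, ":", pos, " is within ", half,
         " nt of a contig edge; full context unavailable")
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  substr(s, half + 1L, half + 1L) <- allele
  s
}

#' Assemble a reporter oligo from enhancer context and barcode
#'
#' Concatenates the constant 5' flank, the 175-nt enhancer fragment, the
#' KpnI/XbaI linker, the 10-nt barcode and the constant 3' flank into the
#' 230-nt synthesis sequence.
#'
#' @param enh 175-nt enhancer context string.
#' @param barcode 10-nt barcode string; must pass [is_valid_barcode()].
#' @return Character string of length 230.
#' @seealso [parse_oligo()] for the inverse.
#' @export
build_oligo <- function(enh, barcode) {
  .check_acgt(c(enh, barcode))
  if (nchar(enh) != 175L) stop("enh must be 175 nt, got ", nchar(enh))
  if (nchar(barcode) != 10L) stop("barcode must be 10 nt, got ", nchar(barcode))
  if (!is_valid_barcode(barcode)) stop("barcode '", barcode, "' fails validity rules")
  paste0(oligo_segments[["flank5"]], enh, oligo_segments[["linker"]],
         barcode, oligo_segments[["flank3"]])
}

#' Parse a reporter oligo back into its variable parts
#'
#' @param sequence 230-nt assembled oligo.
#' @return List with elements `enh` (175 nt) and `barcode` (10 nt).
#' @export
parse_oligo <- function(sequence) {
  if (nchar(sequence) != 230L) {
    stop("oligo must be 230 nt, got ", nchar(sequence))
  }
  seg <- oligo_segments
  if (substring(sequence, 1L, 16L) != seg[["flank5"]] ||
      substring(sequence, 192L, 203L) != seg[["linker"]] ||
      substring(sequence, 214L, 230L) != seg[["flank3"]]) {
    stop("constant segments not found at their designed positions")
  }
  list(enh = substring(sequence, 17L, 191L),
       barcode = substring(sequence, 204L, 213L))
}

#' Build the full oligo library for a candidate variant table
#'
#' For each variant allele, extracts the centred genomic context and
#' attaches `barcodes_per_allele` distinct barcodes, yielding one
#' manifest row (and one 230-nt fragment) per barcode.
#'
#' @param candidates Data frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt` (as from [select_candidates()]).
#' @param genome [Biostrings::DNAStringSet] of reference contigs.
#' @param barcodes_per_allele Barcodes attached to each allele
#'   (default 18, the lower end of the designed 18-19 range).
#' @param seed RNG seed for barcode generation.
#' @return Data frame (the barcode manifest) with columns `element_id`,
#'   `allele` (`"ref"`/`"alt"`), `barcode`, `enh`, `sequence`.
#' @export
build_library <- function(candidates, genome, barcodes_per_allele = 18L,
                          seed = 1L) {
  stopifnot(barcodes_per_allele >= 1)
  n_bc <- 2L * nrow(candidates) * barcodes_per_allele
  bcs <- generate_barcodes(n_bc, seed = seed)
  rows <- vector("list", 2L * nrow(candidates))
  k <- 0L
  for (i in seq_len(nrow(candidates))) {
    v <- candidates[i, ]
    for (al in c("ref", "alt")) {
      k <- k + 1L
      base <- if (al == "ref") v$ref else v$alt
      enh <- extract_context(genome, v$chrom, v$pos, base)
      idx <- ((k - 1L) * barcodes_per_allele + 1L):(k * barcodes_per_allele)
      rows[[k]] <- data.frame(
        element_id = v$id, allele = al, barcode = bcs[idx],
        enh = enh, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$sequence <- vapply(seq_len(nrow(manifest)), function(i) {
    build_oligo(manifest$enh[i], manifest$barcode[i])
  }, character(1L))
  rownames(manifest) <- NULL
  manifest
}
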