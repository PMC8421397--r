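#' Filter promoter-capture Hi-C interactions
#'
#' Keeps interactions whose score exceeds 5 at any timepoint, that join
#' two fragments on the same chromosome (no trans contacts), and whose
#' anchors lie within 1 Mb of each other. Distance is measured between
#' anchor midpoints by default; edge-to-edge is available.
#'
#' @param interactions BEDPE-style data frame with columns `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2` (0-based half-open)
#'   plus one or more score columns and optional annotation columns
#'   (`gene`, `cell_type`, ...).
#' @param score_cols Names of the per-timepoint score columns; defaults
#'   to every column starting with `"score"`.
#' @param min_score Score threshold, strictly greater-than (default 5).
#' @param max_dist Maximum cis distance in bp (default 1e6).
#' @param distance `"midpoint"` (default) or `"edge"`.
#' @return The surviving rows, same columns. Idempotent.
#' @export
filter_interactions <- function(interactions,
                                score_cols = grep("^score", names(interactions),
                                                  value = TRUE),
                                min_score = 5, max_dist = 1e6,
                                distance = c("midpoint", "edge")) {
  distance <- match.arg(distance)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(req %in% names(interactions))) {
    stop("interactions must carry BEDPE columns: ",
         paste(setdiff(req, names(interactions)), collapse = ", "))
  }
  bad <- which(interactions$start1 >= interactions$end1 |
                 interactions$start2 >= interactions$end2)
  if (length(bad)) stop("malformed interval(s) at row(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  if (length(score_cols) == 0L) stop("no score columns found")
  smax <- do.call(pmax, c(interactions[score_cols], na.rm = TRUE))
  cis <- interactions$chrom1 == interactions$chrom2
  if (distance == "midpoint") {
    d <- abs((interactions$start1 + interactions$end1) / 2 -
               (interactions$start2 + interactions$end2) / 2)
  } else {
    d <- pmax(interactions$start2 - interactions$end1,
              interactions$start1 - interactions$end2, 0)
  }
  interactions[smax > min_score & cis & d <= max_dist, , drop = FALSE]
}

.distal_granges <- function(interactions) {
  GenomicRanges::GRanges(
    seqnames = interactions$chrom2,
    ranges = IRanges::IRanges(start = interactions$start2 + 1L,
                              end = interactions$end2)
  )
}

#' Link EMVars to promoters through cHi-C interactions
#'
#' An EMVar is linked to a baited promoter gene when the distal end of
#' one of that gene's interactions comes within `window` bp of the SNP
#' position (distance 0 when the SNP falls inside the distal fragment;
#' boundary inclusive, so a SNP exactly `window` bp from the fragment
#' edge is linked). Links are unioned over all interaction libraries
#' present in the table.
#'
#' @param emvars Data frame with `variant_id`, `chrom`, `pos` (1-based
#'   SNP position).
#' @param interactions Filtered BEDPE data frame (see
#'   [filter_interactions()]) with a `gene` column naming the baited
#'   promoter; an optional `cell_type` column is carried through.
#' @param window Linking distance in bp (default 1000).
#' @return Data frame of links: `variant_id`, `gene`, `distance`, plus
#'   `cell_type` when present. Empty output is allowed.
#' @export
link_emvar_promoters <- function(emvars, interactions, window = 1000L) {
  empty <- data.frame(variant_id = character(0L), gene = character(0L),
                      distance = integer(0L), stringsAsFactors = FALSE)
  if (nrow(emvars) == 0L || nrow(interactions) == 0L) return(empty)
  snp <- GenomicRanges::GRanges(
    seqnames = emvars$chrom,
    ranges = IRanges::IRanges(start = emvars$pos - window,
                              end = emvars$pos + window)
  )
  distal <- .distal_granges(interactions)
  ov <- GenomicRanges::findOverlaps(snp, distal)
  if (length(ov) == 0L) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  pos <- emvars$pos[qi]
  b <- interactions$start2[si] + 1L
  e <- interactions$end2[si]
  dist <- ifelse(pos < b, b - pos, ifelse(pos > e, pos - e, 0L))
  out <- data.frame(variant_id = emvars$variant_id[qi],
                    gene = interactions$gene[si],
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  if ("cell_type" %in% names(interactions)) out$cell_type <- interactions$cell_type[si]
  unique(out)
}

#' Count distinct ATAC peaks reachable from each promoter
#'
#' For each baited promoter gene, counts the distinct harmonized ATAC
#' peaks overlapping the distal end of any of its interactions, across
#' all timepoint libraries (interactions and peaks need not be
#' significant at the same timepoint). A peak reachable through several
#' interactions is counted once.
#'
#' @param interactions Filtered BEDPE data frame with a `gene` column.
#' @param peaks Data frame of harmonized peaks: `chrom`, `start`, `end`
#'   (0-based half-open) and a unique `peak_id` column (created from
#'   coordinates when absent).
#' @return Data frame: `gene`, `n_peaks` (genes with zero overlapping
#'   peaks included with 0).
#' @export
link_promoter_atac <- function(interactions, peaks) {
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  }
  distal <- .distal_granges(interactions)
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  ov <- GenomicRanges::findOverlaps(distal, pk)
  hits <- data.frame(gene = interactions$gene[S4Vectors::queryHits(ov)],
                     peak_id = peaks$peak_id[S4Vectors::subjectHits(ov)],
                     stringsAsFactors = FALSE)
  hits <- unique(hits)
  n <- table(factor(hits$gene, levels = sort(unique(interactions$gene))))
  data.frame(gene = names(n), n_peaks = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Bin EMVars into their GWAS loci
#'
#' Each EMVar inherits every locus (lead-SNP tag) its variant qualified
#' for during candidate selection; variants in LD with two leads appear
#' under both loci.
#'
#' @param emvar_ids Character vector of EMVar variant ids.
#' @param candidate_table Output of [select_candidates()] (columns `id`,
#'   `locus_ids` with comma-separated lead tags).
#' @return Data frame: `variant_id`, `locus_id`, one row per membership.
#' @export
bin_emvars_to_loci <- function(emvar_ids, candidate_table) {
  miss <- setdiff(emvar_ids, candidate_table$id)
  if (length(miss)) {
    stop("EMVar(s) absent from candidate table: ",
         paste(miss, collapse = ", "))
  }
  idx <- match(emvar_ids, candidate_table$id)
  loci <- strsplit(candidate_table$locus_ids[idx], ",", fixed = TRUE)
  data.frame(
    variant_id = rep(emvar_ids, lengths(loci)),
    locus_id = unlist(loci),
    stringsAsFactors = FALSE
  )
}

#' Classify one gene's evidence flags into a support class
#'
#' The four-tier scheme combines physical contact (an EMVar of the locus
#' interacts with the gene's promoter) with eQTL support in the matched
#' or in other tissue classes, gated on expression:
#' \describe{
#'   \item{I}{contact AND matched-tissue eQTL}
#'   \item{II}{contact AND other-tissue eQTL (no matched eQTL)}
#'   \item{III}{exactly one of contact / matched-tissue eQTL}
#'   \item{IV}{other-tissue eQTL only}
#'   \item{unclassified}{no evidence, or not expressed}
#' }
#' Classes are assigned by strict precedence I > II > III > IV; genes
#' failing the expression gate (> 1 TPM in at least one timepoint) are
#' always `"unclassified"`.
#'
#' @param interacts,eqtl_matched,eqtl_other,expressed Logical vectors
#'   (recycled to common length).
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`,
#'   `"unclassified"`.
#' @export
classify_evidence <- function(interacts, eqtl_matched, eqtl_other, expressed) {
  n <- max(length(interacts), length(eqtl_matched), length(eqtl_other),
           length(expressed))
  interacts <- rep_len(interacts, n)
  eqtl_matched <- rep_len(eqtl_matched, n)
  eqtl_other <- rep_len(eqtl_other, n)
  expressed <- rep_len(expressed, n)
  cls <- rep("unclassified", n)
  cls[interacts & eqtl_matched] <- "I"
  cls[cls == "unclassified" & interacts & eqtl_other] <- "II"
  cls[cls == "unclassified" & xor(interacts, eqtl_matched)] <- "III"
  cls[cls == "unclassified" & eqtl_other] <- "IV"
  cls[!expressed] <- "unclassified"
  cls
}

#' Assign gene-support classes per locus and cell type
#'
#' Combines EMVar-promoter links, eQTL records and expression into the
#' Class I-IV scheme of [classify_evidence()], per (gene, locus) pair
#' and for a fixed cell type. Candidate genes are those linked to or
#' eQTL-associated with any EMVar of a locus.
#'
#' @param emvar_loci Data frame from [bin_emvars_to_loci()]
#'   (`variant_id`, `locus_id`).
#' @param links EMVar-promoter links from [link_emvar_promoters()]
#'   (`variant_id`, `gene`).
#' @param eqtls Data frame with `variant_id`, `gene`, `tissue_class`
#'   (values such as `"adipose"`, `"brain"`, `"other"`, derived from an
#'   explicit tissue-to-class map).
#' @param expression Numeric matrix or data frame of TPM, genes x
#'   timepoints, rownames = gene.
#' @param cell_type The matched tissue class for this analysis (e.g.
#'   `"adipose"` or `"brain"`).
#' @param tpm_gate Expression threshold; a gene must exceed it in at
#'   least one timepoint (default 1).
#' @return Data frame: `gene`, `locus_id`, `cell_type`, `class`, plus
#'   the evidence flags `interacts`, `eqtl_matched`, `eqtl_other`,
#'   `expressed`. Genes absent from the expression table are dropped
#'   with a warning.
#' @export
assign_gene_classes <- function(emvar_loci, links, eqtls, expression,
                                cell_type, tpm_gate = 1) {
  expression <- as.matrix(expression)
  pairs <- unique(rbind(
    merge(emvar_loci, links[c("variant_id", "gene")])[c("gene", "locus_id")],
    merge(emvar_loci, eqtls[c("variant_id", "gene")])[c("gene", "locus_id")]
  ))
  if (nrow(pairs) == 0L) {
    return(data.frame(gene = character(0L), locus_id = character(0L),
                      cell_type = character(0L), class = character(0L),
                      interacts = logical(0L), eqtl_matched = logical(0L),
                      eqtl_other = logical(0L), expressed = logical(0L),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(unique(pairs$gene), rownames(expression))
  if (length(miss)) {
    warning("gene(s) missing from expression table, excluded: ",
            paste(miss, collapse = ", "))
    pairs <- pairs[!pairs$gene %in% miss, , drop = FALSE]
  }
  flags <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene[i]
    emv <- emvar_loci$variant_id[emvar_loci$locus_id == pairs$locus_id[i]]
    eq <- eqtls[eqtls$gene == g & eqtls$variant_id %in% emv, , drop = FALSE]
    c(interacts = any(links$gene == g & links$variant_id %in% emv),
      eqtl_matched = any(eq$tissue_class == cell_type),
      eqtl_other = any(eq$tissue_class != cell_type),
      expressed = max(expression[g, ]) > tpm_gate)
  })
  fl <- do.call(rbind, flags)
  out <- data.frame(
    gene = pairs$gene, locus_id = pairs$locus_id, cell_type = cell_type,
    class = classify_evidence(fl[, "interacts"], fl[, "eqtl_matched"],
                              fl[, "eqtl_other"], fl[, "expressed"]),
    interacts = fl[, "interacts"], eqtl_matched = fl[, "eqtl_matched"],
    eqtl_other = fl[, "eqtl_other"], expressed = fl[, "expressed"],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$locus_id, out$gene), ]
  rownames(out) <- NULL
  out
}
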