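#' Mann-Whitney U test p-value
#'
#' Thin, contract-pinned wrapper around [stats::wilcox.test()]: exact
#' rank-split enumeration when both groups have fewer than 50 values and
#' there are no ties; otherwise the tie-corrected normal approximation
#' with continuity correction (the exact path refuses ties, and the
#' fallback is logged by the underlying engine).
#'
#' @param x,y Numeric vectors (each non-empty). `alternative = "greater"`
#'   tests whether `x` is stochastically greater than `y`.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
mwu <- function(x, y, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("both groups must be non-empty")
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = NULL, correct = TRUE)
  )$p.value
}

# Rank-sum test of each barcode group against all remaining barcodes in
# the same replicate, vectorized over groups. Reproduces wilcox.test's
# tie-corrected, continuity-corrected normal approximation (the regime
# wilcox.test itself uses at these group sizes).
.pooled_rank_p <- function(values, group, alternative = "greater") {
  ok <- !is.na(values)
  values <- values[ok]
  group <- group[ok]
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  Rsum <- tapply(r, group, sum)
  n <- tapply(r, group, length)
  keys <- names(Rsum)
  n <- as.numeric(n[keys])
  m <- N - n
  U <- as.numeric(Rsum[keys]) - n * (n + 1) / 2
  sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
  z <- U - n * m / 2
  if (alternative == "greater") {
    p <- stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE)
  } else {
    p <- 2 * stats::pnorm((abs(z) - 0.5) / sigma, lower.tail = FALSE)
    p <- pmin(p, 1)
  }
  names(p) <- keys
  p
}

# column-wise BH adjustment preserving matrix shape
.adjust_cols <- function(p) {
  q <- p
  for (j in seq_len(ncol(p))) q[, j] <- stats::p.adjust(p[, j], method = "fdr")
  q
}

#' Replicate-concordance rule
#'
#' A call replicates when it is significant in at least half of all
#' technical replicates (rounding up for odd counts) or in at least one
#' technical replicate of every biological replicate group.
#'
#' @param significant Logical vector, one entry per technical replicate
#'   (`NA` treated as not significant).
#' @param groups Vector of biological-group labels, same length as
#'   `significant`; required.
#' @return Single logical.
#' @export
concordance <- function(significant, groups) {
  if (missing(groups) || is.null(groups)) {
    stop("replicate design (biological groups) must be declared")
  }
  if (length(groups) != length(significant)) {
    stop("groups and significant must align one-to-one over technical replicates")
  }
  sig <- !is.na(significant) & significant
  half_rule <- sum(sig) >= ceiling(length(sig) / 2)
  bio_rule <- all(tapply(sig, groups, any))
  half_rule || bio_rule
}

#' Call enhancer alleles from an activity table
#'
#' Per replicate, each allele's barcode activities are tested one-sided
#' (greater) against a null distribution: by default the pooled activity
#' of every other tested barcode in that replicate (self-normalizing
#' empirical null; the allele's own barcodes are excluded so the two
#' groups are disjoint), or a designated negative-control barcode set.
#' p-values are Benjamini-Hochberg adjusted across tested alleles within
#' each replicate; the consensus flag applies the replicate-concordance
#' rule to the per-replicate `q < alpha` calls.
#'
#' @param act Activity matrix, barcodes x replicates (see
#'   [activity_table()]).
#' @param manifest Manifest data frame with `element_id`, `allele`,
#'   `barcode`; only barcodes present in `act` are used.
#' @param groups Biological-group label per replicate column.
#' @param alpha FDR threshold for significance (default 0.05).
#' @param min_barcodes Alleles with fewer barcodes after filtering are
#'   reported untested, not failed (default 5).
#' @param null `"pooled"` (default) or `"negctrl"`.
#' @param null_barcodes Barcode ids of the negative-control set
#'   (required when `null = "negctrl"`).
#' @return Object of class `enhancer_calls`: list with `calls` (data
#'   frame: `element_id`, `allele`, `n_barcodes`, `tested`,
#'   `is_enhancer`), `p` and `q` matrices (tested alleles x replicates),
#'   `alpha`, `groups`, `null`.
#' @export
call_enhancers <- function(act, manifest, groups, alpha = 0.05,
                           min_barcodes = 5L,
                           null = c("pooled", "negctrl"),
                           null_barcodes = NULL) {
  null <- match.arg(null)
  if (null == "negctrl" && is.null(null_barcodes)) {
    stop("null_barcodes must be supplied when null = 'negctrl'")
  }
  if (length(groups) != ncol(act)) {
    stop("groups must declare one biological group per replicate column")
  }
  mf <- manifest[manifest$barcode %in% rownames(act), , drop = FALSE]
  act <- act[mf$barcode, , drop = FALSE]
  key <- paste(mf$element_id, mf$allele, sep = "\r")
  nbc <- table(key)
  tested_keys <- names(nbc)[nbc >= min_barcodes]
  if (null == "negctrl") {
    tested_keys <- setdiff(tested_keys,
                           unique(key[mf$barcode %in% null_barcodes]))
  }
  nrep <- ncol(act)
  p <- matrix(NA_real_, length(tested_keys), nrep,
              dimnames = list(tested_keys, colnames(act)))
  for (j in seq_len(nrep)) {
    if (null == "pooled") {
      pj <- .pooled_rank_p(act[, j], key, alternative = "greater")
      p[, j] <- pj[tested_keys]
    } else {
      y <- act[mf$barcode %in% null_barcodes, j]
      y <- y[!is.na(y)]
      for (k in tested_keys) {
        x <- act[key == k, j]
        p[k, j] <- mwu(x[!is.na(x)], y, alternative = "greater")
      }
    }
  }
  q <- .adjust_cols(p)
  sig <- q < alpha
  all_keys <- sort(unique(key))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  calls <- data.frame(
    element_id = parts[, 1L], allele = parts[, 2L],
    n_barcodes = as.integer(nbc[all_keys]),
    tested = all_keys %in% tested_keys,
    is_enhancer = NA, stringsAsFactors = FALSE
  )
  calls$is_enhancer <- vapply(all_keys, function(k) {
    if (!k %in% tested_keys) return(NA)
    concordance(sig[k, ], groups)
  }, logical(1L))
  structure(list(calls = calls, p = p, q = q, alpha = alpha,
                 groups = groups, null = null),
            class = "enhancer_calls")
}

#' Call enhancer-modulating variants (EMVars)
#'
#' Only elements with at least one consensus-significant enhancer allele
#' are tested: per replicate, reference-allele barcode activities versus
#' alternate-allele activities, two-sided, BH-adjusted across tested
#' elements within the replicate. A variant is an EMVar when the allelic
#' test satisfies the replicate-concordance rule. Elements missing one
#' allele in the activity table are skipped with a message.
#'
#' @inheritParams call_enhancers
#' @param enhancer_calls Result of [call_enhancers()] on the same
#'   activity table.
#' @return Object of class `emvar_calls`: list with `calls` (data frame:
#'   `element_id`, `direction` - sign of alt minus ref median activity -
#'   `concordant`, `is_emvar`), and `p`, `q` matrices over tested
#'   elements.
#' @export
call_emvars <- function(act, manifest, enhancer_calls, groups,
                        alpha = 0.05) {
  stopifnot(inherits(enhancer_calls, "enhancer_calls"))
  if (length(groups) != ncol(act)) {
    stop("groups must declare one biological group per replicate column")
  }
  ec <- enhancer_calls$calls
  enh_elements <- unique(ec$element_id[!is.na(ec$is_enhancer) & ec$is_enhancer])
  mf <- manifest[manifest$barcode %in% rownames(act), , drop = FALSE]
  act <- act[mf$barcode, , drop = FALSE]
  tested <- character(0L)
  for (el in enh_elements) {
    al <- unique(mf$allele[mf$element_id == el])
    if (all(c("ref", "alt") %in% al)) {
      tested <- c(tested, el)
    } else {
      message("call_emvars: element '", el, "' missing one allele; skipped")
    }
  }
  nrep <- ncol(act)
  p <- matrix(NA_real_, length(tested), nrep,
              dimnames = list(tested, colnames(act)))
  direction <- stats::setNames(integer(length(tested)), tested)
  for (el in tested) {
    ref_v <- act[mf$barcode[mf$element_id == el & mf$allele == "ref"], ,
                 drop = FALSE]
    alt_v <- act[mf$barcode[mf$element_id == el & mf$allele == "alt"], ,
                 drop = FALSE]
    for (j in seq_len(nrep)) {
      x <- ref_v[, j]
      y <- alt_v[, j]
      p[el, j] <- mwu(x[!is.na(x)], y[!is.na(y)], alternative = "two_sided")
    }
    direction[el] <- sign(stats::median(alt_v, na.rm = TRUE) -
                            stats::median(ref_v, na.rm = TRUE))
  }
  q <- .adjust_cols(p)
  conc <- vapply(tested, function(el) concordance(q[el, ] < alpha, groups),
                 logical(1L))
  calls <- data.frame(
    element_id = tested,
    direction = as.integer(direction),
    concordant = conc,
    is_emvar = conc,
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  structure(list(calls = calls, p = p, q = q, alpha = alpha, groups = groups),
            class = "emvar_calls")
}
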