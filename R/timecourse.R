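#' TMM library-size scale factors
#'
#' Trimmed-mean-of-M-values normalization factors for a count matrix:
#' per non-reference sample, log-ratios (M) and log-abundances (A)
#' against the reference are computed over genes expressed in both, the
#' most extreme 30% of M and 5% of A are trimmed, and the
#' precision-weighted mean of the remaining M gives the log2 factor.
#' Factors are centred so their product is 1. The reference sample is
#' the column whose upper quartile is closest to the mean upper
#' quartile, unless given.
#'
#' @param counts Non-negative count matrix, features x samples (at
#'   least two samples).
#' @param logratio_trim Fraction of M values trimmed (default 0.30).
#' @param sum_trim Fraction of A values trimmed (default 0.05).
#' @param ref_col Optional reference column (index or name).
#' @return Named numeric vector of scale factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                        ref_col = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L)
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              refColumn = ref_col,
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  names(f) <- colnames(counts)
  f
}

#' Expression filter ahead of time-course clustering
#'
#' Removes genes with CPM below `cpm_min` in more than `max_low`
#' samples across the whole course (a gene failing in exactly
#' `max_low` samples is kept).
#'
#' @param counts Count matrix, genes x samples.
#' @param cpm_min CPM floor (default 1).
#' @param max_low Tolerated number of below-floor samples (default 3).
#' @return Filtered count matrix.
#' @export
filter_for_clustering <- function(counts, cpm_min = 1, max_low = 3L) {
  low <- rowSums(cpm(counts) < cpm_min)
  counts[low <= max_low, , drop = FALSE]
}

#' Expression filter ahead of the HSV transformation
#'
#' Per timepoint, replicate TPM values are averaged and the gene is
#' dropped when `log2(mean TPM)` falls below `threshold` at any
#' timepoint (a gene sitting exactly at the threshold everywhere is
#' kept).
#'
#' @param tpm TPM matrix, genes x samples.
#' @param timepoints Vector assigning each column to a timepoint.
#' @param threshold Minimum `log2(mean TPM)` (default 1).
#' @return Filtered TPM matrix.
#' @export
filter_for_hsv <- function(tpm, timepoints, threshold = 1) {
  stopifnot(length(timepoints) == ncol(tpm))
  tps <- unique(timepoints)
  mean_tpm <- vapply(tps, function(tt) {
    rowMeans(tpm[, timepoints == tt, drop = FALSE])
  }, numeric(nrow(tpm)))
  keep <- rowSums(log2(mean_tpm) < threshold) == 0L
  tpm[keep, , drop = FALSE]
}

#' HSV transformation of temporal profiles
#'
#' Maps each feature's ordered profile \eqn{C_t} (non-negative,
#' log2-normalized expression or accessibility) to a colour triple for
#' circular time-course visualization:
#' \deqn{V = \max_t C_t}
#' \deqn{S = 1 - \min_t C_t / V}
#' \deqn{H = 60 \left(2 + \frac{C_{first} + C_{second} - C_{last} - V}{V S}\right)
#'       \, \mathrm{sign}(C_{second} - C_{first})}
#' wrapped into `[0, 360)`. Value is the peak level, saturation the
#' maximal fold change, hue the pattern of change. Degenerate profiles
#' are flagged instead of producing numbers: all-zero features are
#' `"undefined"`, flat profiles (`S = 0`) are `"static"`, and profiles
#' with `C_second = C_first` (sign term singular) are `"static-onset"`;
#' in all three cases `H` is `NA`. Rank-scaled copies of V and S
#' (`(rank - 1) / (n - 1)`, order-preserving into `[0, 1]`) are emitted
#' alongside the raw values.
#'
#' @param C Numeric matrix, features x ordered timepoints (at least 3
#'   columns), non-negative; or a single profile vector.
#' @return Data frame: `feature`, `H`, `S`, `V`, `S_rank`, `V_rank`,
#'   `pattern` (`"ok"`, `"static"`, `"static-onset"`, `"undefined"`).
#' @export
hsv_transform <- function(C) {
  if (is.null(dim(C))) C <- matrix(C, nrow = 1L, dimnames = list("feature1"))
  C <- as.matrix(C)
  if (ncol(C) < 3L) stop("at least 3 timepoints required (hue undefined otherwise)")
  if (any(C < 0)) stop("profiles must be non-negative; offset or clamp first")
  if (is.null(rownames(C))) rownames(C) <- paste0("feature", seq_len(nrow(C)))
  V <- apply(C, 1L, max)
  Cmin <- apply(C, 1L, min)
  S <- ifelse(V > 0, 1 - Cmin / V, NA_real_)
  c1 <- C[, 1L]
  c2 <- C[, 2L]
  cl <- C[, ncol(C)]
  sgn <- sign(c2 - c1)
  H <- ifelse(V > 0 & S > 0 & sgn != 0,
              (60 * (2 + (c1 + c2 - cl - V) / (V * S)) * sgn) %% 360,
              NA_real_)
  pattern <- rep("ok", nrow(C))
  pattern[sgn == 0] <- "static-onset"
  pattern[!is.na(S) & S == 0] <- "static"
  pattern[V == 0] <- "undefined"
  n <- nrow(C)
  rank01 <- function(x) if (n == 1L) rep(1, n) else (rank(x) - 1) / (n - 1)
  data.frame(feature = rownames(C), H = H, S = S, V = V,
             S_rank = rank01(S), V_rank = rank01(V),
             pattern = pattern, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bin hue values into temporal-pattern sectors
#'
#' Features flagged static/undefined get their flag as the bin; the
#' rest are assigned to equal hue sectors of width `360 / n_bins`.
#'
#' @param hsv Data frame from [hsv_transform()].
#' @param n_bins Number of hue sectors (default 6, i.e. 60-degree
#'   guide patterns; configurable).
#' @return Character vector of bin labels (e.g. `"[60,120)"`).
#' @export
bin_patterns <- function(hsv, n_bins = 6L) {
  width <- 360 / n_bins
  sector <- floor(hsv$H / width)
  sector[sector == n_bins] <- n_bins - 1L  # guards H == 360 after rounding
  lab <- sprintf("[%g,%g)", sector * width, (sector + 1) * width)
  ifelse(hsv$pattern == "ok", lab, hsv$pattern)
}

# standard fuzzy c-means membership of profiles x against fixed centers
.fcm_membership <- function(x, centers, m = 2) {
  d2 <- outer(seq_len(nrow(x)), seq_len(nrow(centers)),
              Vectorize(function(i, j) sum((x[i, ] - centers[j, ])^2)))
  pw <- 1 / (m - 1)
  u <- t(apply(d2, 1L, function(di) {
    zero <- di == 0
    if (any(zero)) return(as.numeric(zero) / sum(zero))
    w <- (1 / di)^pw
    w / sum(w)
  }))
  dimnames(u) <- list(rownames(x), rownames(centers))
  u
}

#' Fuzzy c-means clustering of time-course profiles
#'
#' Clusters replicate-averaged temporal profiles with fuzzy c-means
#' (fuzzifier `m = 2`, seeded initialization), then scores every
#' individual replicate's profile against the fitted centres so the
#' per-replicate membership rule of [assign_clusters()] can be applied.
#'
#' @param mat Matrix, genes x samples (normalized, e.g. log2 CPM).
#' @param timepoints,replicates Vectors assigning each column to a
#'   timepoint and a replicate.
#' @param centers Number of clusters.
#' @param m Fuzzifier (default 2).
#' @param seed RNG seed for centre initialization.
#' @param scale Row-standardize profiles before clustering (default
#'   `TRUE`, so shape rather than level drives the clusters).
#' @return List with `membership_avg` (genes x clusters),
#'   `membership_rep` (list per replicate), `centers`, and the
#'   [assign_clusters()] result as `assignment`.
#' @export
cluster_timecourse <- function(mat, timepoints, replicates, centers,
                               m = 2, seed = 1L, scale = TRUE) {
  stopifnot(length(timepoints) == ncol(mat),
            length(replicates) == ncol(mat))
  tps <- unique(timepoints)
  avg <- vapply(tps, function(tt) {
    rowMeans(mat[, timepoints == tt, drop = FALSE])
  }, numeric(nrow(mat)))
  norm_rows <- function(x) {
    if (!scale) return(x)
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    sd[sd == 0] <- 1
    (x - mu) / sd
  }
  avg_n <- norm_rows(avg)
  set.seed(seed)
  fit <- e1071::cmeans(avg_n, centers = centers, m = m, iter.max = 200L)
  u_avg <- fit$membership
  rownames(u_avg) <- rownames(mat)
  reps <- unique(replicates)
  u_rep <- lapply(reps, function(rr) {
    sub <- mat[, replicates == rr, drop = FALSE]
    sub <- sub[, match(tps, timepoints[replicates == rr]), drop = FALSE]
    .fcm_membership(norm_rows(sub), fit$centers, m = m)
  })
  names(u_rep) <- reps
  list(membership_avg = u_avg, membership_rep = u_rep,
       centers = fit$centers,
       assignment = assign_clusters(u_avg, u_rep))
}

#' Apply the cluster-assignment membership rules
#'
#' A gene is assigned to its highest-membership cluster only when the
#' replicate-averaged membership exceeds 0.3 (strict) and the
#' membership for that cluster exceeds 0.2 (strict) in every individual
#' replicate; otherwise it stays unassigned.
#'
#' @param membership_avg Matrix, genes x clusters, of memberships from
#'   replicate-averaged profiles.
#' @param membership_rep List of genes x clusters membership matrices,
#'   one per replicate.
#' @param avg_min,rep_min Thresholds (defaults 0.3 and 0.2).
#' @return Data frame: `gene`, `cluster` (`NA` when unassigned),
#'   `membership_avg`, `min_rep_membership`.
#' @export
assign_clusters <- function(membership_avg, membership_rep,
                            avg_min = 0.3, rep_min = 0.2) {
  rs <- rowSums(membership_avg)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("membership rows do not sum to 1 (max deviation ",
            format(max(abs(rs - 1))), ")")
  }
  best <- max.col(membership_avg, ties.method = "first")
  n <- nrow(membership_avg)
  u_best <- membership_avg[cbind(seq_len(n), best)]
  rep_best <- vapply(membership_rep, function(u) u[cbind(seq_len(n), best)],
                     numeric(n))
  if (n == 1L) rep_best <- matrix(rep_best, nrow = 1L)
  min_rep <- apply(rep_best, 1L, min)
  ok <- u_best > avg_min & min_rep > rep_min
  data.frame(
    gene = rownames(membership_avg),
    cluster = ifelse(ok, best, NA_integer_),
    membership_avg = u_best,
    min_rep_membership = min_rep,
    stringsAsFactors = FALSE
  )
}

#' Harmonize ATAC peaks to uniform 1-kb intervals
#'
#' Peaks from all timepoints are merged into union loci (overlap in
#' half-open coordinates); within each locus the summit of the
#' highest-scoring peak defines the centre, and a fixed-width interval
#' `[summit - width/2, summit + width/2)` is emitted per locus.
#'
#' @param peaks Data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `summit` (absolute 0-based position; missing summits
#'   fall back to the interval midpoint with a warning), `score`
#'   (peak height).
#' @param width Output interval width in bp (default 1000).
#' @return Data frame of harmonized peaks: `chrom`, `start`, `end`,
#'   `summit`, `score`, `peak_id`; one row per union locus.
#' @export
harmonize_peaks <- function(peaks, width = 1000L) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(peaks)))
  if (!"summit" %in% names(peaks)) peaks$summit <- NA_real_
  if (anyNA(peaks$summit)) {
    warning("missing summit(s); falling back to interval midpoint")
    mid <- as.integer((peaks$start + peaks$end) %/% 2)
    peaks$summit <- ifelse(is.na(peaks$summit), mid, peaks$summit)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  loci <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, loci)
  locus_of <- rep(NA_integer_, nrow(peaks))
  locus_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  half <- width %/% 2L
  out <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), locus_of), function(ix) {
    top <- ix[which.max(peaks$score[ix])]
    s <- peaks$summit[top]
    data.frame(chrom = peaks$chrom[top],
               start = s - half, end = s + (width - half),
               summit = s, score = peaks$score[top],
               stringsAsFactors = FALSE)
  }))
  out$peak_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  rownames(out) <- NULL
  out
}
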