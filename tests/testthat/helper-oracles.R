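# Independent brute-force oracles used across the suite. These follow
# the written definitions step by step and deliberately share no code
# with the package implementation.

# barcode validity by counting restriction-site occurrences in the full
# assembled downstream context (the designed linker carries exactly one
# KpnI and one XbaI site; any extra occurrence must involve the barcode)
oracle_valid_barcode <- function(bc, width = nchar(bc)) {
  if (nchar(bc) != width) return(FALSE)
  chars <- strsplit(bc, "")[[1]]
  run <- 1L
  for (i in seq_along(chars)[-1]) {
    run <- if (chars[i] == chars[i - 1]) run + 1L else 1L
    if (run >= 3L) return(FALSE)
  }
  if (substring(bc, nchar(bc) - 2L) == "TCT") return(FALSE)
  ctx <- paste0("GGTACCTCTAGA", bc, "AGATCGGAAGAGCGTCG")
  count_site <- function(site) {
    n <- 0L
    for (i in seq_len(nchar(ctx) - nchar(site) + 1L)) {
      if (substring(ctx, i, i + nchar(site) - 1L) == site) n <- n + 1L
    }
    n
  }
  count_site("GGTACC") == 1L && count_site("TCTAGA") == 1L
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# exact Mann-Whitney p by exhaustive enumeration of rank splits
oracle_mwu <- function(x, y, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  if (alternative == "greater") {
    mean(u_all >= u_obs)
  } else {
    min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  }
}

# step-by-step TMM following the published definition: 30% two-sided
# trim on M, 5% on A, precision-weighted mean of remaining M, factors
# centred to product 1; reference column by upper quartile
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) {
      f[j] <- 1
      next
    }
    o <- counts[, j]
    r <- counts[, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    v <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) {
      f[j] <- 1
      next
    }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f / exp(mean(log(f)))
}

# quantile normalization spelled out per cell on a small matrix
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    for (i in seq_len(nrow(x))) {
      tied <- which(x[, j] == x[i, j])
      pos <- which(order(x[, j]) %in% tied)
      out[i, j] <- mean(ref[pos])
    }
  }
  out
}

# shared small MPRA run: simulate, filter, quantify, call
run_mpra_pipeline <- function(params, min_dna = 10) {
  sim <- simulate_mpra_counts(params)
  filt <- suppressMessages(filter_low_barcodes(sim$counts, min_dna))
  act <- activity_table(filt)
  enh <- call_enhancers(act, sim$manifest, groups = sim$groups)
  emv <- suppressMessages(
    call_emvars(act, sim$manifest, enh, groups = sim$groups)
  )
  list(sim = sim, act = act, enh = enh, emv = emv)
}
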