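test_that("TMM factors are 1 on identical libraries and recover scaling", {
  set.seed(41)
  base <- matrix(rnbinom(600, mu = 200, size = 10), ncol = 3)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)
  # a column that is exactly 2x the reference has no composition bias:
  # TMM must not mistake depth for expression change
  doubled <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  f <- tmm_factors(doubled)
  expect_equal(unname(f[2] / f[1]), 1, tolerance = 1e-12)
})

test_that("TMM matches a step-by-step reimplementation", {
  set.seed(42)
  m <- matrix(rnbinom(200 * 4, mu = exp(runif(200 * 4, 2, 7)), size = 5),
              ncol = 4)
  m[sample(length(m), 40)] <- 0
  expect_equal(unname(tmm_factors(m)), oracle_tmm(m), tolerance = 1e-8)
})

test_that("clustering filter drops genes low in more than three samples", {
  set.seed(43)
  counts <- matrix(rpois(12 * 8, 300), nrow = 12,
                   dimnames = list(paste0("g", 1:12), NULL))
  lib <- colSums(counts)
  # plant: g1 below 1 CPM in exactly 3 samples (kept), g2 in 4 (dropped)
  low_val <- 0L
  counts["g1", 1:3] <- low_val
  counts["g2", 1:4] <- low_val
  filt <- filter_for_clustering(counts)
  expect_true("g1" %in% rownames(filt))
  expect_false("g2" %in% rownames(filt))
})

test_that("hsv expression filter uses mean TPM per timepoint at any timepoint", {
  tpm <- rbind(
    at_boundary = c(2, 2, 2, 2, 2, 2),   # log2(mean TPM) = 1 everywhere
    dips = c(4, 4, 1.4, 1.4, 4, 4),      # log2(1.4) < 1 at timepoint 2
    high = c(8, 8, 8, 8, 8, 8)
  )
  tps <- c(1, 1, 2, 2, 3, 3)
  filt <- filter_for_hsv(tpm, tps)
  expect_setequal(rownames(filt), c("at_boundary", "high"))
})

test_that("hsv transform matches direct evaluation and flags degeneracies", {
  h <- hsv_transform(matrix(c(1, 2, 4), nrow = 1))
  expect_equal(h$V, 4)
  expect_equal(h$S, 0.75)
  expect_equal(h$H, 20)
  expect_identical(h$pattern, "ok")

  flat <- hsv_transform(matrix(c(3, 3, 3), nrow = 1))
  expect_equal(flat$S, 0)
  expect_true(is.na(flat$H))
  expect_identical(flat$pattern, "static")

  onset <- hsv_transform(matrix(c(2, 2, 5), nrow = 1))
  expect_true(is.na(onset$H))
  expect_identical(onset$pattern, "static-onset")

  zero <- hsv_transform(matrix(c(0, 0, 0), nrow = 1))
  expect_identical(zero$pattern, "undefined")
  expect_true(is.na(zero$H))

  expect_error(hsv_transform(matrix(c(1, 2), nrow = 1)), "3 timepoints")
  expect_error(hsv_transform(matrix(c(-1, 2, 3), nrow = 1)), "non-negative")
})

test_that("hue and saturation are invariant to positive scaling", {
  set.seed(44)
  for (i in 1:20) {
    C <- matrix(runif(4, 0.5, 8), nrow = 1)
    k <- runif(1, 0.1, 10)
    a <- hsv_transform(C)
    b <- hsv_transform(k * C)
    expect_equal(b$S, a$S, tolerance = 1e-10)
    if (a$pattern == "ok") expect_equal(b$H, a$H, tolerance = 1e-9)
    expect_equal(b$V, k * a$V, tolerance = 1e-9)
    expect_true(a$S >= 0 && a$S <= 1)
    expect_true(is.na(a$H) || (a$H >= 0 && a$H < 360))
  }
})

test_that("rank scaling preserves order and attains both extremes", {
  set.seed(45)
  C <- matrix(runif(50 * 4, 0.5, 9), ncol = 4)
  h <- hsv_transform(C)
  expect_equal(order(h$V), order(h$V_rank))
  expect_equal(range(h$V_rank), c(0, 1))
  expect_equal(range(h$S_rank), c(0, 1))
})

test_that("pattern binning sectors hue and passes flags through", {
  hs <- data.frame(H = c(20, 359.9, NA, NA),
                   pattern = c("ok", "ok", "static", "undefined"))
  bins <- bin_patterns(hs, n_bins = 6)
  expect_identical(bins, c("[0,60)", "[300,360)", "static", "undefined"))
})

test_that("cluster assignment enforces avg and per-replicate membership rules", {
  # g1: avg 0.35 on its best cluster, replicates (0.25, 0.30, 0.40) -> assigned
  # g2: avg 0.35 but one replicate at 0.10 -> unassigned
  # g3: comfortable memberships everywhere -> assigned
  u_avg <- rbind(g1 = c(0.35, 0.325, 0.325),
                 g2 = c(0.35, 0.325, 0.325),
                 g3 = c(0.10, 0.80, 0.10))
  mk_rep <- function(b1, b2, b3) {
    rbind(g1 = c(b1, (1 - b1) / 2, (1 - b1) / 2),
          g2 = c(b2, (1 - b2) / 2, (1 - b2) / 2),
          g3 = c((1 - b3) / 2, b3, (1 - b3) / 2))
  }
  reps <- list(mk_rep(0.25, 0.10, 0.7),
               mk_rep(0.30, 0.60, 0.8),
               mk_rep(0.40, 0.60, 0.9))
  res <- assign_clusters(u_avg, reps)
  expect_identical(res$cluster[res$gene == "g1"], 1L)
  expect_true(is.na(res$cluster[res$gene == "g2"]))
  expect_identical(res$cluster[res$gene == "g3"], 2L)
})

test_that("membership thresholds are strict inequalities", {
  # avg exactly 0.30 on the best cluster: unassigned
  res_b <- suppressWarnings(
    assign_clusters(rbind(g1 = c(0.30, 0.25, 0.25)),
                    list(rbind(g1 = c(0.90, 0.05, 0.05))))
  )
  expect_true(is.na(res_b$cluster))
  # replicate membership exactly 0.20 on the best cluster: unassigned
  res_c <- assign_clusters(rbind(g1 = c(0.40, 0.30, 0.30)),
                           list(rbind(g1 = c(0.20, 0.40, 0.40))))
  expect_true(is.na(res_c$cluster))
  # just above both thresholds: assigned
  res_d <- assign_clusters(rbind(g1 = c(0.31, 0.35, 0.34)),
                           list(rbind(g1 = c(0.30, 0.35, 0.35))))
  expect_identical(res_d$cluster, 2L)
})

test_that("peak harmonization emits 1-kb summit-centred union loci", {
  single <- data.frame(chrom = "chr1", start = 10200L, end = 10900L,
                       summit = 10500L, score = 7, stringsAsFactors = FALSE)
  h <- harmonize_peaks(single)
  expect_identical(h$start, 10000L)
  expect_identical(h$end, 11000L)

  overlapping <- data.frame(
    chrom = "chr1", start = c(1000L, 1400L), end = c(1600L, 2200L),
    summit = c(1300L, 1800L), score = c(5, 9), stringsAsFactors = FALSE
  )
  h2 <- harmonize_peaks(overlapping)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$summit, 1800L)  # summit of the height-9 peak

  disjoint <- data.frame(
    chrom = "chr1", start = c(1000L, 9000L, 50000L),
    end = c(1500L, 9500L, 50500L),
    summit = c(1200L, 9100L, 50200L), score = c(1, 2, 3),
    stringsAsFactors = FALSE
  )
  h3 <- harmonize_peaks(disjoint)
  expect_identical(nrow(h3), 3L)  # count conserved
  expect_true(all(h3$end - h3$start == 1000L))

  nosummit <- single
  nosummit$summit <- NA
  expect_warning(h4 <- harmonize_peaks(nosummit), "midpoint")
  expect_identical(h4$summit, 10550L)

  # touching-but-not-overlapping half-open intervals stay separate loci
  touching <- data.frame(
    chrom = "chr1", start = c(1000L, 1500L), end = c(1500L, 2000L),
    summit = c(1200L, 1700L), score = c(4, 6), stringsAsFactors = FALSE
  )
  expect_identical(nrow(harmonize_peaks(touching)), 2L)
})

test_that("fuzzy memberships against fixed centres sum to one", {
  set.seed(46)
  x <- matrix(rnorm(30), 10, 3)
  centers <- matrix(rnorm(9), 3, 3)
  u <- emvarkit:::.fcm_membership(x, centers)
  expect_equal(unname(rowSums(u)), rep(1, 10), tolerance = 1e-12)
  # profile sitting exactly on a centre gets full membership there
  x2 <- rbind(centers[2, ], x)
  u2 <- emvarkit:::.fcm_membership(x2, centers)
  expect_equal(unname(u2[1, ]), c(0, 1, 0))
})
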