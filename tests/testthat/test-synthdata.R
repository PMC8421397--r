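test_that("generators are bit-identical across runs with the same seed", {
  pp <- sim_params(n_loci = 1, proxies_per_locus = 4, seed = 99)
  expect_identical(simulate_mpra_counts(pp), simulate_mpra_counts(pp))
  g1 <- simulate_genotypes(50, c(1e5, 2e5), c(0.9, 0.85), seed = 9)
  g2 <- simulate_genotypes(50, c(1e5, 2e5), c(0.9, 0.85), seed = 9)
  expect_identical(g1, g2)
  genes <- data.frame(gene = "G1", chrom = "chr1", tss = 5e5)
  expect_identical(simulate_chic(genes, seed = 9), simulate_chic(genes, seed = 9))
  expect_identical(simulate_timecourse(20, seed = 9),
                   simulate_timecourse(20, seed = 9))
})

test_that("sim_params validates its invariants", {
  expect_error(sim_params(frac_enhancers = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(nb_dispersion = 0), "> 0")
  expect_error(sim_params(n_loci = 0), ">= 1")
  expect_error(sim_params(dna_mean = -5), "positive")
})

test_that("manifest size is elements x alleles x barcodes", {
  # 5 variants, 2 alleles, 18 barcodes each
  m <- emvarkit:::.synthetic_manifest(5L, 18L, seed = 1)
  expect_identical(nrow(m), 180L)
  expect_identical(anyDuplicated(m$barcode), 0L)
  expect_true(all(table(m$element_id, m$allele) == 18L))
})

test_that("simulated counts have the declared NB moments", {
  pp <- sim_params(n_loci = 10, proxies_per_locus = 16, seed = 30,
                   frac_enhancers = 0, dna_mean = 100, nb_dispersion = 0.1)
  sim <- simulate_mpra_counts(pp)
  dna <- sim$counts[, "dna"]  # 5760 draws
  expect_equal(mean(dna), 100, tolerance = 0.05)
  # variance = mu + phi mu^2 = 100 + 0.1 * 1e4 = 1100
  expect_equal(var(dna), 1100, tolerance = 0.15)
})

test_that("null allelic effect gives balanced ref/alt activities", {
  pp <- sim_params(n_loci = 5, proxies_per_locus = 10, seed = 31,
                   frac_enhancers = 0.5, frac_emvars = 0)
  sim <- simulate_mpra_counts(pp)
  act <- activity_table(suppressMessages(filter_low_barcodes(sim$counts, 10)),
                        quantile_norm = FALSE)
  mf <- sim$manifest[sim$manifest$barcode %in% rownames(act), ]
  a <- rowMeans(act[mf$barcode, ])
  d <- tapply(a, mf$allele, mean)
  expect_lt(abs(d[["ref"]] - d[["alt"]]), 0.05)
})

test_that("planted enhancer shift is recovered in mean activity", {
  # ~10^4 barcodes split between enhancer and null elements, several seeds
  shifts <- vapply(1:10, function(s) {
    pp <- sim_params(n_loci = 10, proxies_per_locus = 15, seed = 100 + s,
                     frac_enhancers = 0.5, enhancer_log2fc = 1,
                     frac_emvars = 0)
    sim <- simulate_mpra_counts(pp)
    act <- activity_table(suppressMessages(filter_low_barcodes(sim$counts, 10)),
                          quantile_norm = FALSE)
    mf <- sim$manifest[sim$manifest$barcode %in% rownames(act), ]
    enh <- sim$truth$is_enhancer_ref[match(mf$element_id,
                                           sim$truth$element_id)]
    a <- rowMeans(act[mf$barcode, ])
    mean(a[enh]) - mean(a[!enh])
  }, numeric(1))
  expect_equal(mean(shifts), 1, tolerance = 0.05)
})

test_that("truth-table proportions match requested fractions", {
  pp <- sim_params(n_loci = 20, proxies_per_locus = 25, seed = 32,
                   frac_enhancers = 0.3, frac_emvars = 0.5)
  truth <- simulate_mpra_counts(pp)$truth
  n <- nrow(truth)
  p_enh <- mean(truth$is_enhancer_ref)
  expect_lt(abs(p_enh - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # emvar implies enhancer on at least one allele
  expect_true(all(truth$is_enhancer_ref[truth$is_emvar]))
})

test_that("genotype simulation hits its LD targets", {
  g <- simulate_genotypes(500, 1e5, c(1, 0.9, 0), seed = 33)
  v <- g$variants
  expect_equal(v$realized_r2[v$id == "proxy1_1"], 1)  # exact copy
  expect_lt(v$realized_r2[v$id == "proxy1_3"], 0.05)  # independent flips
  r2s <- vapply(1:20, function(s) {
    gg <- simulate_genotypes(500, 1e5, 0.9, seed = 200 + s)
    gg$variants$realized_r2[2]
  }, numeric(1))
  expect_gt(mean(r2s), 0.85)
  expect_lt(mean(r2s), 0.95)
  expect_error(simulate_genotypes(5, 1e5, 0.9), ">= 10")
  expect_error(simulate_genotypes(50, 1e5, 1.5), "\\[0, 1\\]")
})

test_that("selection on a simulated panel recovers planted proxies", {
  g <- simulate_genotypes(800, c(1e5, 5e5), c(0.95, 0.9, 0.2), seed = 34)
  panel <- list(variants = g$variants, dosages = g$dosages)
  res <- select_candidates(g$leads, panel)
  # high-r2 proxies of each lead qualify; the r2=0.2 proxies do not
  expect_true(all(c("proxy1_1", "proxy1_2", "proxy2_1", "proxy2_2")
                  %in% res$id))
  expect_false(any(c("proxy1_3", "proxy2_3") %in% res$id))
  expect_setequal(res$locus_ids[res$id == "proxy1_1"], "lead1")
})

test_that("chic simulation plants exactly the interactions the filter keeps", {
  genes <- data.frame(gene = paste0("G", 1:4), chrom = "chr1",
                      tss = c(3e6, 4e6, 5e6, 6e6), stringsAsFactors = FALSE)
  chic <- simulate_chic(genes, n_keep = 10, n_low_score = 4, n_far = 3,
                        n_trans = 3, seed = 35)
  kept <- filter_interactions(chic)
  expect_identical(nrow(kept), 10L)
  expect_true(all(kept$category == "keep"))
  expect_error(simulate_chic(genes[0, ]), "non-empty")
})

test_that("planted emvar links respect the 1-kb window", {
  genes <- data.frame(gene = paste0("G", 1:3), chrom = "chr1",
                      tss = c(3e6, 3.4e6, 3.8e6), stringsAsFactors = FALSE)
  ev <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 3200000L)
  near <- simulate_chic(genes, ev, n_keep = 2, n_emvar_links = 1,
                        emvar_distance = 500L, seed = 36)
  links <- link_emvar_promoters(ev, filter_interactions(near))
  expect_true("rs1" %in% links$variant_id)
  expect_identical(links$distance[links$variant_id == "rs1"], 500L)
  far <- simulate_chic(genes, ev, n_keep = 2, n_emvar_links = 1,
                       emvar_distance = 5000L, seed = 37)
  links_far <- link_emvar_promoters(ev, filter_interactions(far))
  expect_false("rs1" %in% links_far$variant_id)
})

test_that("timecourse archetypes behave as constructed", {
  # zero-noise flat course: every profile is constant, so S = 0
  tc_flat <- simulate_timecourse(10, n_timepoints = 4, n_reps = 2, seed = 38,
                                 pattern_mix = c(up = 0, down = 0,
                                                 transient = 0, flat = 1),
                                 noise = "none")
  lcpm <- log2(cpm(tc_flat$counts) + 1)
  h <- hsv_transform(lcpm[, order(tc_flat$timepoints)][,
                          !duplicated(sort(tc_flat$timepoints))])
  expect_true(all(h$S < 1e-9))
  expect_true(all(h$pattern %in% c("static", "static-onset")))

  # zero-noise mixed course, on the per-gene log2 count scale
  tc0 <- simulate_timecourse(40, n_timepoints = 4, n_reps = 1, seed = 39,
                             noise = "none")
  lc <- log2(tc0$counts + 1)[, order(tc0$timepoints)]
  up <- tc0$truth$archetype == "up"
  down <- tc0$truth$archetype == "down"
  # the hue sign term (C2 - C1)/|C2 - C1| is +1 for up, -1 for down
  expect_true(all(sign(lc[up, 2] - lc[up, 1]) == 1))
  expect_true(all(sign(lc[down, 2] - lc[down, 1]) == -1))
  # up- and down-archetypes land in disjoint hue sectors
  hm <- hsv_transform(lc[up | down, ])
  bins <- bin_patterns(hm, n_bins = 6)
  expect_length(intersect(bins[tc0$truth$archetype[up | down] == "up"],
                          bins[tc0$truth$archetype[up | down] == "down"]), 0L)
  expect_error(simulate_timecourse(10, n_timepoints = 2), ">= 3")
})

test_that("fuzzy clustering recovers archetypes above chance", {
  aris <- vapply(1:5, function(s) {
    tc <- simulate_timecourse(120, n_timepoints = 5, n_reps = 3,
                              seed = 300 + s)
    keep <- filter_for_clustering(tc$counts)
    lcpm <- log2(cpm(keep) + 1)
    cl <- cluster_timecourse(lcpm, tc$timepoints, tc$replicates,
                             centers = 4, seed = s)
    truth <- tc$truth$archetype[match(rownames(keep), tc$truth$gene)]
    ok <- !is.na(cl$assignment$cluster)
    expect_gt(mean(ok), 0.5)  # most genes pass the membership rules
    mclust::adjustedRandIndex(cl$assignment$cluster[ok], truth[ok])
  }, numeric(1))
  expect_gt(mean(aris), 0.5)  # well above chance (ARI ~ 0)
})
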