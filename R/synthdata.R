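#' Simulation parameters for synthetic MPRA experiments
#'
#' Bundles and validates the knobs of [simulate_mpra_counts()]. The
#' defaults describe the assay the pipeline targets: elements tagged by
#' 18 barcodes per allele, two biological replicate groups spanning the
#' technical replicates, negative-binomial barcode counts
#' (variance \eqn{\mu + \phi \mu^2}), and a subset of elements carrying
#' planted enhancer and allelic effects on the log2 activity scale.
#'
#' @param n_loci Number of GWAS loci simulated.
#' @param proxies_per_locus Candidate elements per locus.
#' @param barcodes_per_allele Barcodes tagging each allele (default 18;
#'   19 is the upper end of the designed range).
#' @param n_tech_reps Total technical RNA replicates.
#' @param n_bio_reps Biological replicate groups the technical
#'   replicates are split over.
#' @param dna_mean Expected DNA (plasmid input) count per barcode.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi}.
#' @param frac_enhancers Proportion of elements that are enhancers.
#' @param enhancer_log2fc Planted log2 activity shift of enhancers.
#' @param frac_emvars Proportion of enhancers with an allelic effect.
#' @param allelic_log2fc Planted allelic log2 shift (applied to the
#'   alternate allele of EMVar elements).
#' @param seed RNG seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_loci = 5L, proxies_per_locus = 10L,
                       barcodes_per_allele = 18L, n_tech_reps = 5L,
                       n_bio_reps = 2L, dna_mean = 100,
                       nb_dispersion = 0.1, frac_enhancers = 0.2,
                       enhancer_log2fc = 1, frac_emvars = 0.3,
                       allelic_log2fc = 1, seed = 1L) {
  p <- list(n_loci = n_loci, proxies_per_locus = proxies_per_locus,
            barcodes_per_allele = barcodes_per_allele,
            n_tech_reps = n_tech_reps, n_bio_reps = n_bio_reps,
            dna_mean = dna_mean, nb_dispersion = nb_dispersion,
            frac_enhancers = frac_enhancers,
            enhancer_log2fc = enhancer_log2fc, frac_emvars = frac_emvars,
            allelic_log2fc = allelic_log2fc, seed = seed)
  counts <- c("n_loci", "proxies_per_locus", "barcodes_per_allele",
              "n_tech_reps", "n_bio_reps")
  for (nm in counts) {
    if (p[[nm]] < 1) stop(nm, " must be >= 1")
  }
  for (nm in c("frac_enhancers", "frac_emvars")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  }
  if (p$dna_mean <= 0) stop("dna_mean must be positive")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (p$n_bio_reps > p$n_tech_reps) {
    stop("n_bio_reps cannot exceed n_tech_reps")
  }
  class(p) <- "sim_params"
  p
}

# synthetic manifest without sequences: element x allele x barcode rows
.synthetic_manifest <- function(n_elements, barcodes_per_allele, seed) {
  bcs <- generate_barcodes(2L * n_elements * barcodes_per_allele,
                           seed = seed)
  ids <- sprintf("el%04d", seq_len(n_elements))
  data.frame(
    element_id = rep(ids, each = 2L * barcodes_per_allele),
    allele = rep(rep(c("ref", "alt"), each = barcodes_per_allele),
                 times = n_elements),
    barcode = bcs,
    stringsAsFactors = FALSE
  )
}

#' Simulate MPRA barcode counts with planted effects
#'
#' Draws DNA counts per barcode from NB(`dna_mean`, `nb_dispersion`)
#' and, for every technical replicate, RNA counts from a negative
#' binomial whose mean is the barcode's realized DNA count scaled by
#' `2^(enhancer_log2fc)` for enhancer elements and additionally by
#' `2^(allelic_log2fc)` for the alternate allele of EMVar elements
#' (non-enhancers are centred at activity 0). Conditioning the RNA mean
#' on the realized DNA count mirrors transcription from the transfected
#' plasmid pool. Ground-truth labels are returned alongside.
#'
#' @param params A [sim_params()] object.
#' @param manifest Optional barcode manifest (`element_id`, `allele`,
#'   `barcode`); autogenerated from `params` when `NULL`.
#' @return List: `counts` (barcodes x samples integer matrix with a
#'   `"dna"` column and `"rna1"..` replicate columns), `manifest`,
#'   `groups` (biological group per RNA column), `truth` (data frame:
#'   `element_id`, `is_enhancer_ref`, `is_enhancer_alt`, `is_emvar`,
#'   `planted_effect`).
#' @export
simulate_mpra_counts <- function(params, manifest = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  if (is.null(manifest)) {
    n_el <- params$n_loci * params$proxies_per_locus
    manifest <- .synthetic_manifest(n_el, params$barcodes_per_allele,
                                    seed = params$seed)
  }
  if (min(table(manifest$element_id, manifest$allele)) < 1) {
    stop("manifest must have >= 1 barcode per allele")
  }
  elements <- unique(manifest$element_id)
  n_el <- length(elements)
  is_enh <- stats::runif(n_el) < params$frac_enhancers
  is_emv <- is_enh & stats::runif(n_el) < params$frac_emvars
  truth <- data.frame(
    element_id = elements,
    is_enhancer_ref = is_enh, is_enhancer_alt = is_enh,
    is_emvar = is_emv,
    planted_effect = ifelse(is_emv, params$allelic_log2fc, 0),
    stringsAsFactors = FALSE
  )
  size <- 1 / params$nb_dispersion
  nb <- nrow(manifest)
  dna <- stats::rnbinom(nb, mu = params$dna_mean, size = size)
  shift <- ifelse(is_enh[match(manifest$element_id, elements)],
                  params$enhancer_log2fc, 0) +
    ifelse(is_emv[match(manifest$element_id, elements)] &
             manifest$allele == "alt", params$allelic_log2fc, 0)
  mu_rna <- dna * 2^shift
  counts <- matrix(0L, nb, params$n_tech_reps + 1L,
                   dimnames = list(manifest$barcode,
                                   c("dna", paste0("rna", seq_len(params$n_tech_reps)))))
  counts[, "dna"] <- dna
  for (j in seq_len(params$n_tech_reps)) {
    counts[, j + 1L] <- stats::rnbinom(nb, mu = mu_rna, size = size)
  }
  groups <- paste0("bio", rep_len(seq_len(params$n_bio_reps),
                                  params$n_tech_reps))
  list(counts = counts, manifest = manifest, groups = groups, truth = truth)
}

#' Simulate LD-structured genotype panels
#'
#' Leads are drawn as Bernoulli haplotypes at frequency `maf`; each
#' proxy copies the lead's haplotypes and flips each allele with
#' probability `(1 - sqrt(r2)) / 2`, so the haplotype correlation is
#' approximately `sqrt(r2)` and the dosage r-squared approximately the
#' target. The realized r-squared is reported per proxy (computed with
#' [compute_r2()]), never assumed.
#'
#' @param n_samples Number of diploid samples (at least 10; below that,
#'   r-squared estimates are too unstable to be meaningful).
#' @param lead_positions Integer vector of lead SNP positions (all on
#'   `chrom`).
#' @param proxy_r2 Target r-squared values; each lead receives one
#'   proxy per value, spaced `spacing` bp downstream.
#' @param seed RNG seed.
#' @param maf Allele frequency used for every lead (default 0.3).
#' @param chrom Chromosome label.
#' @param spacing Distance between consecutive proxies (default 5000).
#' @return List: `variants` (data frame: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `lead_id`, `target_r2`, `realized_r2`, `maf`), `dosages`
#'   (samples x variants), `leads` (lead ids).
#' @export
simulate_genotypes <- function(n_samples, lead_positions, proxy_r2,
                               seed = 1L, maf = 0.3, chrom = "chr1",
                               spacing = 5000L) {
  if (n_samples < 10L) stop("n_samples must be >= 10 (r2 unstable below)")
  if (any(proxy_r2 < 0 | proxy_r2 > 1)) stop("proxy_r2 values must be in [0, 1]")
  set.seed(seed)
  vars <- list()
  dos <- list()
  for (i in seq_along(lead_positions)) {
    lead_id <- paste0("lead", i)
    hap <- matrix(stats::rbinom(2L * n_samples, 1L, maf), ncol = 2L)
    dos[[lead_id]] <- rowSums(hap)
    vars[[length(vars) + 1L]] <- data.frame(
      id = lead_id, chrom = chrom, pos = lead_positions[i],
      ref = "A", alt = "G", lead_id = lead_id,
      target_r2 = 1, realized_r2 = 1, stringsAsFactors = FALSE
    )
    for (j in seq_along(proxy_r2)) {
      eps <- (1 - sqrt(proxy_r2[j])) / 2
      flip <- matrix(stats::rbinom(2L * n_samples, 1L, eps), ncol = 2L)
      phap <- (hap + flip) %% 2L
      pid <- paste0("proxy", i, "_", j)
      dos[[pid]] <- rowSums(phap)
      vars[[length(vars) + 1L]] <- data.frame(
        id = pid, chrom = chrom, pos = lead_positions[i] + j * spacing,
        ref = "A", alt = "G", lead_id = lead_id,
        target_r2 = proxy_r2[j],
        realized_r2 = compute_r2(dos[[lead_id]], dos[[pid]]),
        stringsAsFactors = FALSE
      )
    }
  }
  variants <- do.call(rbind, vars)
  dosages <- do.call(cbind, dos)
  variants$maf <- .panel_maf(dosages)
  list(variants = variants, dosages = dosages,
       leads = paste0("lead", seq_along(lead_positions)))
}

#' Simulate promoter-capture Hi-C interactions with truth labels
#'
#' Emits a labelled mix of interactions: cis pairs within 1 Mb scoring
#' above 5 at one timepoint (`keep`), cis pairs within 1 Mb scoring
#' below 5 everywhere (`low_score`), cis pairs beyond 1 Mb (`far_cis`)
#' and trans-chromosomal pairs (`trans`) - only the first category
#' should survive [filter_interactions()]. Optionally plants `keep`
#' interactions whose distal end sits at a controlled distance from an
#' EMVar position, recorded in `planted_variant`.
#'
#' @param genes Data frame: `gene`, `chrom`, `tss` (1-based TSS).
#' @param emvar_positions Optional data frame `variant_id`, `chrom`,
#'   `pos` used for planted links.
#' @param n_keep,n_low_score,n_far,n_trans Rows per category.
#' @param n_emvar_links Number of additional `keep` interactions whose
#'   distal end is planted near an EMVar.
#' @param emvar_distance Distance (bp) from the planted SNP to the
#'   nearest distal-fragment edge; 0 places the SNP inside.
#' @param n_timepoints Number of score columns (`score_t1`, ...).
#' @param cell_type Label carried on every row.
#' @param seed RNG seed.
#' @return BEDPE-style data frame (see [filter_interactions()]) with
#'   truth columns `category` and `planted_variant`.
#' @export
simulate_chic <- function(genes, emvar_positions = NULL, n_keep = 10L,
                          n_low_score = 3L, n_far = 3L, n_trans = 3L,
                          n_emvar_links = 0L, emvar_distance = 0L,
                          n_timepoints = 2L, cell_type = "adipose",
                          seed = 1L) {
  if (is.null(genes) || nrow(genes) == 0L) stop("gene list must be non-empty")
  set.seed(seed)
  bait_half <- 2500L
  distal_w <- 4000L
  mk_scores <- function(high) {
    s <- stats::runif(n_timepoints, 0, 4.5)
    if (high) s[sample.int(n_timepoints, 1L)] <- stats::runif(1, 5.5, 15)
    stats::setNames(as.list(round(s, 3)), paste0("score_t", seq_len(n_timepoints)))
  }
  row_for <- function(g, offset, trans_chrom = NULL, high = TRUE,
                      category, planted = NA_character_, distal_start = NULL) {
    b1 <- g$tss - bait_half
    chrom2 <- if (is.null(trans_chrom)) g$chrom else trans_chrom
    s2 <- if (is.null(distal_start)) g$tss + offset else distal_start
    cbind(data.frame(chrom1 = g$chrom, start1 = b1, end1 = b1 + 2L * bait_half,
                     chrom2 = chrom2, start2 = s2, end2 = s2 + distal_w,
                     gene = g$gene, cell_type = cell_type,
                     stringsAsFactors = FALSE),
          as.data.frame(mk_scores(high)),
          data.frame(category = category, planted_variant = planted,
                     stringsAsFactors = FALSE))
  }
  rows <- list()
  pick <- function() genes[sample.int(nrow(genes), 1L), , drop = FALSE]
  for (i in seq_len(n_keep)) {
    rows[[length(rows) + 1L]] <- row_for(pick(), sample(10000:800000, 1L),
                                         category = "keep")
  }
  for (i in seq_len(n_low_score)) {
    rows[[length(rows) + 1L]] <- row_for(pick(), sample(10000:800000, 1L),
                                         high = FALSE, category = "low_score")
  }
  for (i in seq_len(n_far)) {
    rows[[length(rows) + 1L]] <- row_for(pick(), sample(1200000:2000000, 1L),
                                         category = "far_cis")
  }
  for (i in seq_len(n_trans)) {
    g <- pick()
    other <- paste0(g$chrom, "_alt")
    rows[[length(rows) + 1L]] <- row_for(g, NULL, trans_chrom = other,
                                         category = "trans",
                                         distal_start = sample(1e5:2e5, 1L))
  }
  if (n_emvar_links > 0L) {
    if (is.null(emvar_positions) || nrow(emvar_positions) == 0L) {
      stop("emvar_positions required when n_emvar_links > 0")
    }
    for (i in seq_len(n_emvar_links)) {
      ev <- emvar_positions[((i - 1L) %% nrow(emvar_positions)) + 1L, ]
      cand <- genes[genes$chrom == ev$chrom &
                      abs(genes$tss - ev$pos) <= 900000L, , drop = FALSE]
      if (nrow(cand) == 0L) {
        stop("no gene within 0.9 Mb of EMVar ", ev$variant_id,
             " on ", ev$chrom, "; cannot plant a cis link")
      }
      g <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      # SNP at `emvar_distance` bp left of the distal fragment start
      # (inside the fragment when 0)
      ds <- if (emvar_distance == 0L) ev$pos - distal_w %/% 2L
            else ev$pos + emvar_distance - 1L
      rows[[length(rows) + 1L]] <- row_for(g, NULL, category = "keep",
                                           planted = ev$variant_id,
                                           distal_start = ds)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate clusterable multi-timepoint count matrices
#'
#' Genes are drawn from four temporal archetypes - monotone up,
#' monotone down, transient (mid-course peak) and flat - on the log2
#' mean scale, then counts are sampled per (timepoint, replicate) from
#' a negative binomial around those means (`noise = "nb"`), or emitted
#' deterministically (`noise = "none"`) for exact checks of the HSV
#' formulas. Truth labels are returned.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Ordered timepoints (at least 3; the hue formula
#'   is undefined below that).
#' @param n_reps Replicates per timepoint.
#' @param pattern_mix Named proportions over
#'   `c("up", "down", "transient", "flat")`.
#' @param seed RNG seed.
#' @param base_log2 Baseline log2 expression (default 5).
#' @param amplitude Log2 swing of the dynamic archetypes (default 2).
#' @param nb_dispersion NB dispersion for `noise = "nb"` (default 0.05).
#' @param noise `"nb"` or `"none"`.
#' @return List: `counts` (genes x samples), `timepoints`, `replicates`
#'   (per-column labels), `truth` (data frame: `gene`, `archetype`).
#' @export
simulate_timecourse <- function(n_genes, n_timepoints = 4L, n_reps = 3L,
                                pattern_mix = c(up = 0.25, down = 0.25,
                                                transient = 0.25, flat = 0.25),
                                seed = 1L, base_log2 = 5, amplitude = 2,
                                nb_dispersion = 0.05,
                                noise = c("nb", "none")) {
  noise <- match.arg(noise)
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3 (hue undefined)")
  stopifnot(abs(sum(pattern_mix) - 1) < 1e-8)
  set.seed(seed)
  archetypes <- sample(names(pattern_mix), n_genes, replace = TRUE,
                       prob = pattern_mix)
  tgrid <- (seq_len(n_timepoints) - 1) / (n_timepoints - 1)
  profile <- function(a) {
    switch(a,
           up = base_log2 + amplitude * tgrid,
           down = base_log2 + amplitude * (1 - tgrid),
           transient = base_log2 + amplitude * (1 - abs(2 * tgrid - 1)),
           flat = rep(base_log2, n_timepoints))
  }
  mu_log2 <- t(vapply(archetypes, profile, numeric(n_timepoints)))
  samples <- expand.grid(rep = seq_len(n_reps), tp = seq_len(n_timepoints))
  counts <- matrix(0L, n_genes, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mu <- 2^mu_log2[, samples$tp[j]]
    counts[, j] <- if (noise == "nb") {
      stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    } else {
      as.integer(round(mu))
    }
  }
  rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("t%d_r%d", samples$tp, samples$rep)
  list(counts = counts,
       timepoints = samples$tp, replicates = samples$rep,
       truth = data.frame(gene = rownames(counts), archetype = archetypes,
                          stringsAsFactors = FALSE))
}
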