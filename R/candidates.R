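#' Squared dosage correlation between two variants
#'
#' Linkage disequilibrium r-squared computed as the squared Pearson
#' correlation of genotype dosages (0/1/2), pairwise-complete over
#' missing entries. Returns `NA` (an "undefined" flag, never an error or
#' a fabricated number) when fewer than two complete pairs remain or
#' when either variant is monomorphic across the complete pairs.
#'
#' @param dosages_a,dosages_b Numeric vectors of equal length with
#'   values in `{0, 1, 2}`; `NA` allowed.
#' @return A value in `[0, 1]`, or `NA` when undefined.
#' @export
compute_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b), length(dosages_a) >= 2)
  ok <- stats::complete.cases(dosages_a, dosages_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- dosages_a[ok]
  b <- dosages_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

.panel_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Select LD-proxy candidate variants around GWAS lead SNPs
#'
#' For each lead SNP, retains the lead itself plus every biallelic panel
#' variant on the same chromosome within `window` bp whose dosage
#' r-squared with the lead exceeds `r2_min` and whose minor-allele
#' frequency is at least `maf_min`. A variant qualifying for several
#' loci is emitted once, carrying every locus it belongs to.
#'
#' @param leads Character vector of lead variant ids (must appear in the
#'   panel; absent leads raise a warning and are still emitted with the
#'   panel-independent fields `NA`).
#' @param panel List with `variants` (data frame: `id`, `chrom`, `pos`,
#'   `ref`, `alt`; multiallelic records carry comma-separated `alt`) and
#'   `dosages` (samples x variants matrix, columns named by `id`), as
#'   produced by [simulate_genotypes()] or [read_vcf_panel()].
#' @param window Maximum distance from the lead in bp, boundary
#'   inclusive (default 50,000).
#' @param r2_min LD threshold; strictly greater-than (default 0.8).
#' @param maf_min Minor-allele-frequency floor, inclusive (default 0.05).
#' @return Data frame with the panel variant columns plus `maf`, `r2`
#'   (with the first qualifying lead), `locus_ids` (comma-separated lead
#'   ids) and `is_lead`.
#' @export
select_candidates <- function(leads, panel, window = 50000L, r2_min = 0.8,
                              maf_min = 0.05) {
  vars <- panel$variants
  dos <- panel$dosages
  stopifnot(is.matrix(dos), !is.null(colnames(dos)))
  maf <- .panel_maf(dos)
  biallelic <- !grepl(",", vars$alt, fixed = TRUE)
  hits <- list()
  for (lead in leads) {
    if (!lead %in% vars$id) {
      warning("lead '", lead, "' absent from panel; emitted without proxies")
      hits[[length(hits) + 1L]] <- data.frame(
        id = lead, chrom = NA_character_, pos = NA_integer_,
        ref = NA_character_, alt = NA_character_, maf = NA_real_,
        r2 = 1, locus_id = lead, is_lead = TRUE, stringsAsFactors = FALSE
      )
      next
    }
    li <- match(lead, vars$id)
    near <- which(vars$chrom == vars$chrom[li] &
                    abs(vars$pos - vars$pos[li]) <= window)
    for (j in near) {
      if (j == li) {
        r2 <- 1
      } else {
        if (!biallelic[j] || maf[j] < maf_min) next
        r2 <- compute_r2(dos[, li], dos[, j])
        if (is.na(r2) || r2 <= r2_min) next
      }
      hits[[length(hits) + 1L]] <- data.frame(
        id = vars$id[j], chrom = vars$chrom[j], pos = vars$pos[j],
        ref = vars$ref[j], alt = vars$alt[j], maf = maf[j], r2 = r2,
        locus_id = lead, is_lead = j == li, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(NULL)
  # collapse to one row per variant, keeping every qualifying locus
  agg <- split(out, out$id)
  res <- do.call(rbind, lapply(agg, function(d) {
    d1 <- d[1L, , drop = FALSE]
    d1$locus_ids <- paste(sort(unique(d$locus_id)), collapse = ",")
    d1$is_lead <- any(d$is_lead)
    d1$r2 <- max(d$r2)
    d1
  }))
  res$locus_id <- NULL
  res <- res[order(res$chrom, res$pos, res$id), ]
  rownames(res) <- NULL
  res
}
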