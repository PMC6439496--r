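# Site- and sample-level filters that turn a raw genotype matrix into the
# analysis datasets. Boundary semantics are deliberate and asymmetric:
# excess-heterozygosity removes at >= 0.6, the sample filter drops at > 80%
# missing (strict), the site filter keeps < 30% missing (strict), and the
# MAF filter keeps >= 0.05 (inclusive). Every filter is monotone (output
# sites/samples are a subset of input) and idempotent.

new_filter_report <- function(step, g_in, g_out, dropped_ids = character(0)) {
  data.frame(step = step,
             sites_in = n_sites(g_in), sites_out = n_sites(g_out),
             samples_in = n_samples(g_in), samples_out = n_samples(g_out),
             dropped_ids = paste(dropped_ids, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Keep only biallelic SNP sites
#'
#' Drops rows flagged as indels or multiallelic at parse time. The sample
#' set is unchanged.
#' @param g a [genotype_matrix()]
#' @export
filter_biallelic_snps <- function(g) {
  keep <- if (is.null(g$sites$is_biallelic_snp)) rep(TRUE, n_sites(g))
          else g$sites$is_biallelic_snp %in% TRUE
  subset_genotypes(g, sites = keep)
}

#' Remove sites with excess observed heterozygosity
#'
#' Sites where the heterozygote fraction among non-missing genotypes is
#' `max_het` or greater are removed — such sites are characteristic of
#' collapsed paralogues rather than allelic variation. All-missing sites
#' are removed here too (no statistic is computable).
#'
#' @param g a [genotype_matrix()]
#' @param max_het removal threshold, inclusive (default 0.6)
#' @export
filter_excess_heterozygosity <- function(g, max_het = 0.6) {
  n_obs <- colSums(!is.na(g$dosage))
  n_het <- colSums(g$dosage == 1L, na.rm = TRUE)
  het <- ifelse(n_obs > 0, n_het / n_obs, 1)  # all-missing -> removed
  subset_genotypes(g, sites = het < max_het)
}

#' Mask low-quality genotypes
#'
#' Genotypes with quality below `min_gq` are set to missing; a quality of
#' exactly `min_gq` is retained. Dimensions are unchanged. When the matrix
#' carries no qualities nothing is masked and a warning is raised.
#'
#' @param g a [genotype_matrix()]
#' @param min_gq minimum genotype quality kept (default 10)
#' @export
mask_low_quality <- function(g, min_gq = 10) {
  if (is.null(g$quality)) {
    warning("no genotype qualities present; nothing masked")
    return(g)
  }
  d <- g$dosage
  q <- g$quality
  mask <- !is.na(q) & q < min_gq
  d[mask] <- NA_integer_
  q[mask] <- NA_real_
  genotype_matrix(d, g$sites, g$samples, quality = q)
}

#' Drop samples with excessive missing data
#'
#' Samples whose missing fraction exceeds `max_missing` (strictly) are
#' removed; a sample at exactly the threshold is retained.
#'
#' @param g a [genotype_matrix()]
#' @param max_missing per-sample missing-fraction bound (default 0.80)
#' @return list with the filtered `genotypes` and a `report` row
#' @export
filter_sample_missingness <- function(g, max_missing = 0.80) {
  miss <- rowMeans(is.na(g$dosage))
  keep <- miss <= max_missing
  out <- subset_genotypes(g, samples = keep)
  list(genotypes = out,
       report = new_filter_report("sample_missingness", g, out,
                                  g$samples$sample_id[!keep]))
}

#' Drop sites with too many missing genotypes
#'
#' Keeps sites with strictly less than `max_missing` missing genotypes.
#' Apply after [mask_low_quality()] so quality-masked calls count as
#' missing.
#'
#' @param g a [genotype_matrix()]
#' @param max_missing per-site missing-fraction bound (default 0.30)
#' @export
filter_site_missingness <- function(g, max_missing = 0.30) {
  miss <- colMeans(is.na(g$dosage))
  subset_genotypes(g, sites = miss < max_missing)
}

#' Remove rare alleles by singleton dropping or a MAF threshold
#'
#' `drop_singletons` removes sites whose minor allele is observed exactly
#' once (a single heterozygote and no other carriers); `maf_threshold`
#' keeps sites with minor allele frequency of `maf` or higher, computed on
#' non-missing genotypes. Monomorphic sites are removed in both modes.
#'
#' @param g a [genotype_matrix()]
#' @param mode `"drop_singletons"` or `"maf_threshold"`
#' @param maf threshold for `maf_threshold` mode, inclusive (default 0.05)
#' @export
filter_rare_alleles <- function(g, mode = c("drop_singletons",
                                            "maf_threshold"), maf = 0.05) {
  mode <- match.arg(mode)
  d <- g$dosage
  n_obs <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  minor_count <- pmin(alt, 2 * n_obs - alt)
  if (mode == "drop_singletons") {
    keep <- n_obs > 0 & minor_count != 1 & minor_count != 0
  } else {
    p_minor <- ifelse(n_obs > 0, minor_count / (2 * n_obs), 0)
    keep <- p_minor >= maf & minor_count > 0
  }
  subset_genotypes(g, sites = keep)
}

#' Greedy LD pruning within physical windows
#'
#' Scans sites in `(scaffold, position)` order; a site is dropped when its
#' squared genotype correlation with any already-retained site within
#' `window_bp` upstream on the same scaffold exceeds `r2_max`. Deterministic
#' for a given input order, and idempotent.
#'
#' @param g a [genotype_matrix()], sites sorted by `(scaffold, position)`
#' @param r2_max maximum allowed squared correlation (default 0.2)
#' @param window_bp physical window (default 500000)
#' @param seed unused placeholder kept for interface stability
#' @export
ld_prune <- function(g, r2_max = 0.2, window_bp = 5e5, seed = NULL) {
  ord <- order(g$sites$scaffold, g$sites$position)
  if (!identical(ord, seq_len(n_sites(g)))) g <- subset_genotypes(g, sites = ord)
  d <- g$dosage
  scaf <- g$sites$scaffold
  pos <- g$sites$position
  keep <- logical(n_sites(g))
  kept_idx <- integer(0)
  for (j in seq_len(n_sites(g))) {
    in_win <- kept_idx[scaf[kept_idx] == scaf[j] &
                       pos[j] - pos[kept_idx] <= window_bp]
    ok <- TRUE
    for (k in rev(in_win)) {
      r <- suppressWarnings(stats::cor(d[, j], d[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
    }
    if (ok) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  subset_genotypes(g, sites = keep)
}

#' Flag putatively sex-linked loci from known-sex heterozygosity contrast
#'
#' In birds, Z-linked loci appear heterozygous only in males (ZZ); females
#' (ZW) are hemizygous and called homozygous. Each site is tested for a
#' difference in heterozygote counts between known-sex groups with Fisher's
#' exact test; sites with `p < alpha` and male-biased heterozygosity are
#' flagged. This is a principled stand-in for an external sex-linkage
#' screen; the exact published procedure is not specified in accessible
#' form.
#'
#' @param g a [genotype_matrix()]
#' @param alpha per-site test level (default 1e-3)
#' @param min_per_sex minimum known-sex samples per sex (default 3)
#' @return logical vector of flags, one per site (with attribute `pvalue`)
#' @export
detect_sex_linked_loci <- function(g, alpha = 1e-3, min_per_sex = 3) {
  sex <- g$samples$sex
  males <- which(sex == "M"); females <- which(sex == "F")
  flags <- logical(n_sites(g))
  if (length(males) < min_per_sex || length(females) < min_per_sex) {
    warning("too few known-sex samples; no sex-linkage flags")
    return(flags)
  }
  pv <- rep(NA_real_, n_sites(g))
  for (j in seq_len(n_sites(g))) {
    dm <- g$dosage[males, j]; df <- g$dosage[females, j]
    hm <- sum(dm == 1L, na.rm = TRUE); nm <- sum(!is.na(dm))
    hf <- sum(df == 1L, na.rm = TRUE); nf <- sum(!is.na(df))
    if (nm == 0 || nf == 0) next
    tab <- matrix(c(hm, nm - hm, hf, nf - hf), nrow = 2)
    pv[j] <- stats::fisher.test(tab)$p.value
    flags[j] <- pv[j] < alpha && hm / nm > hf / nf
  }
  attr(flags, "pvalue") <- pv
  flags
}

#' Detect close-kin sample pairs by robust moment kinship
#'
#' Pairwise kinship via the robust between-family moment estimator on
#' shared non-missing dosages:
#' `phi = (N_AaAa - 2 N_opp) / (2 min(Ni_Aa, Nj_Aa)) + 1/2 -
#'  (Ni_Aa + Nj_Aa) / (4 min(Ni_Aa, Nj_Aa))`,
#' where `N_AaAa` counts doubly heterozygous sites, `N_opp` opposite
#' homozygotes, and `Ni_Aa` each sample's heterozygous sites over the shared
#' set. Duplicates score ~0.5, parent-offspring and full sibs ~0.25. The
#' default threshold 0.177 is the usual midpoint separating first- from
#' second-degree relatives.
#'
#' @param g a [genotype_matrix()]
#' @param threshold kinship above which a pair is flagged (default 0.177)
#' @return data.frame of flagged pairs: `id1`, `id2`, `kinship`, `n_sites`,
#'   and `drop` — the member of the pair with more missing data, the
#'   deterministic removal suggestion
#' @export
detect_close_kin <- function(g, threshold = 0.177) {
  d <- g$dosage
  n <- nrow(d)
  ids <- g$samples$sample_id
  miss <- rowMeans(is.na(d))
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- which(!is.na(d[i, ]) & !is.na(d[j, ]))
    if (length(sh) < 2) next
    di <- d[i, sh]; dj <- d[j, sh]
    n_aa <- sum(di == 1L & dj == 1L)
    n_opp <- sum(abs(di - dj) == 2L)
    ni <- sum(di == 1L); nj <- sum(dj == 1L)
    if (min(ni, nj) == 0) next
    phi <- (n_aa - 2 * n_opp) / (2 * min(ni, nj)) + 0.5 -
      (ni + nj) / (4 * min(ni, nj))
    if (phi > threshold) {
      drop <- if (miss[i] >= miss[j]) ids[i] else ids[j]
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[j], kinship = phi,
        n_sites = length(sh), drop = drop, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0), n_sites = integer(0),
                      drop = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the standard filter chain
#'
#' Fixed order: biallelic -> excess-heterozygosity -> sample missingness ->
#' GQ masking -> site missingness -> rare alleles -> LD pruning, with a
#' composable report of the attrition at every step.
#'
#' @param g a raw [genotype_matrix()]
#' @param mode rare-allele mode, see [filter_rare_alleles()]
#' @param maf MAF threshold for `maf_threshold` mode
#' @param min_gq,max_het,max_sample_missing,max_site_missing,r2_max,window_bp
#'   per-filter thresholds (see the individual filters)
#' @param prune logical: run LD pruning (default TRUE)
#' @return list with filtered `genotypes` and the `report` data.frame chain
#' @export
filter_chain <- function(g, mode = "maf_threshold", maf = 0.05,
                         min_gq = 10, max_het = 0.6,
                         max_sample_missing = 0.80, max_site_missing = 0.30,
                         r2_max = 0.2, window_bp = 5e5, prune = TRUE) {
  rep_rows <- list()
  step <- function(name, before, after) {
    rep_rows[[length(rep_rows) + 1L]] <<- new_filter_report(
      name, before, after,
      setdiff(before$samples$sample_id, after$samples$sample_id))
    after
  }
  g1 <- step("biallelic", g, filter_biallelic_snps(g))
  g2 <- step("excess_het", g1, filter_excess_heterozygosity(g1, max_het))
  sm <- filter_sample_missingness(g2, max_sample_missing)
  rep_rows[[length(rep_rows) + 1L]] <- sm$report
  g3 <- sm$genotypes
  g4 <- step("gq_mask", g3,
             if (is.null(g3$quality)) g3 else mask_low_quality(g3, min_gq))
  g5 <- step("site_missingness", g4,
             filter_site_missingness(g4, max_site_missing))
  g6 <- step("rare_alleles", g5, filter_rare_alleles(g5, mode, maf))
  g7 <- if (prune) step("ld_prune", g6, ld_prune(g6, r2_max, window_bp))
        else g6
  list(genotypes = g7, report = do.call(rbind, rep_rows))
}

#' Attrition summary by tissue source
#'
#' From a sample-level filter report and the original metadata, computes
#' the percentage of dropped samples coming from each source and the source
#' composition of the retained set — the bookkeeping behind statements such
#' as "feathers were 22 of the 25 (88.0%) eliminated samples and 12 of the
#' 135 (8.9%) remaining". Percentages are rounded half-up to one decimal.
#'
#' @param report a report data.frame containing a `sample_missingness` row
#'   (or any row with dropped ids)
#' @param samples the pre-filter sample metadata
#' @param source the tissue source summarised (default `"feather"`)
#' @return list: `n_dropped`, `n_dropped_source`, `pct_dropped_source`,
#'   `n_remaining`, `n_remaining_source`, `pct_remaining_source`
#' @export
attrition_by_source <- function(report, samples, source = "feather") {
  dropped <- unlist(strsplit(report$dropped_ids[report$dropped_ids != ""],
                             ","))
  dropped <- unique(dropped)
  remaining <- setdiff(samples$sample_id, dropped)
  src <- stats::setNames(samples$source, samples$sample_id)
  nd <- length(dropped); nds <- sum(src[dropped] == source)
  nr <- length(remaining); nrs <- sum(src[remaining] == source)
  list(n_dropped = nd, n_dropped_source = nds,
       pct_dropped_source = round_half_up(100 * nds / nd, 1),
       n_remaining = nr, n_remaining_source = nrs,
       pct_remaining_source = round_half_up(100 * nrs / nr, 1))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead.
#' @param x numeric
#' @param digits decimal places (default 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
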