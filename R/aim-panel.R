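# Ancestry-informative marker (AIM) panel design: rank sites by per-site
# F_ST between the focal group and everything else, then accept top sites
# that satisfy assayability filters (clean flanks, one site per scaffold),
# and attach reference-group allele frequencies for downstream (S, H)
# estimation. Also the cross-platform genotype concordance report.

#' Rank AIM candidates by per-site F_ST
#'
#' Sites with pooled minor allele frequency below `maf_min` are removed;
#' the remainder is sorted by descending per-site F_ST ratio, ties broken
#' by `(scaffold, position)`.
#'
#' @param fst_per_site per-site data.frame from [wc_fst()] (`$per_site`),
#'   aligned with the sites of `g`
#' @param g the [genotype_matrix()] the ratios were computed on
#' @param maf_min pooled MAF threshold (default 0.05, sites below are
#'   dropped)
#' @return data.frame of candidate sites (site metadata + `ratio` +
#'   `rank`), best first
#' @export
rank_candidates <- function(fst_per_site, g, maf_min = 0.05) {
  maf <- minor_allele_freq(g)
  ok <- !is.na(fst_per_site$ratio) & !is.nan(maf) & maf >= maf_min
  if (!any(ok)) stop("no candidates remain after the MAF filter")
  cand <- cbind(g$sites[ok, , drop = FALSE],
                site = fst_per_site$site[ok],
                ratio = fst_per_site$ratio[ok])
  ord <- order(-cand$ratio, cand$scaffold, cand$position)
  cand <- cand[ord, ]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Apply assay-design filters and build the AIM panel
#'
#' Greedy top-down acceptance of ranked candidates that have (i) at least
#' `flank_bp` of flanking sequence on both sides, (ii) no non-rare variant
#' (pooled MAF >= `rare_maf` anywhere in the dataset) within `flank_bp` of
#' the target position, and (iii) a scaffold not already used by an
#' accepted site. Stops at `panel_size` accepted sites; a smaller panel is
#' returned with a warning when the candidates run out.
#'
#' @param ranked ranked candidate data.frame from [rank_candidates()]
#' @param g the full [genotype_matrix()] (flanking-variant lookup)
#' @param flank_bp required clean flank length (default 30)
#' @param panel_size target number of markers (default 11)
#' @param rare_maf pooled MAF at which a flanking variant disqualifies a
#'   candidate (default 0.05)
#' @return an `aim_panel`: data.frame of accepted sites in rank order
#' @export
apply_design_filters <- function(ranked, g, flank_bp = 30, panel_size = 11,
                                 rare_maf = 0.05) {
  maf_all <- minor_allele_freq(g)
  pos_all <- g$sites$position
  scaf_all <- g$sites$scaffold
  common <- !is.nan(maf_all) & maf_all >= rare_maf
  used_scaf <- character(0)
  acc <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    if (length(acc) >= panel_size) break
    fl <- ranked$flank_left[i]; fr <- ranked$flank_right[i]
    if (is.na(fl) || is.na(fr) || nchar(fl) < flank_bp ||
        nchar(fr) < flank_bp) next
    if (ranked$scaffold[i] %in% used_scaf) next
    near <- which(scaf_all == ranked$scaffold[i] &
                  abs(pos_all - ranked$position[i]) <= flank_bp &
                  pos_all != ranked$position[i])
    if (any(common[near])) next
    acc <- c(acc, i)
    used_scaf <- c(used_scaf, ranked$scaffold[i])
  }
  if (length(acc) < panel_size)
    warning("only ", length(acc), " of the requested ", panel_size,
            " panel sites passed the design filters")
  panel <- ranked[acc, , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("aim_panel", class(panel))
  panel
}

#' Attach reference-group allele frequencies to a panel
#'
#' ALT-allele frequencies from non-missing genotypes of the two disjoint
#' reference groups; an error names any panel site unobserved in a
#' reference group.
#'
#' @param panel an `aim_panel` from [apply_design_filters()]
#' @param g the [genotype_matrix()] holding the reference samples
#' @param ref_group1,ref_group2 sample ids or region codes
#' @return the panel with `p_ref1`, `p_ref2` columns added
#' @export
panel_frequencies <- function(panel, g, ref_group1, ref_group2) {
  i1 <- group_indices(g, ref_group1)
  i2 <- group_indices(g, ref_group2)
  if (length(intersect(i1, i2))) stop("reference groups must be disjoint")
  f1 <- allele_freqs(g, i1); f2 <- allele_freqs(g, i2)
  j <- panel$site
  bad <- which(f1$n[j] == 0 | f2$n[j] == 0)
  if (length(bad))
    stop("panel site(s) unobserved in a reference group: ",
         paste(panel$scaffold[bad], panel$position[bad], sep = ":",
               collapse = ", "))
  panel$p_ref1 <- f1$p[j]
  panel$p_ref2 <- f2$p[j]
  panel
}

#' Cross-platform genotype concordance
#'
#' Compares two genotype matrices over their shared samples and shared
#' `(scaffold, position)` sites, counting only calls non-missing in both.
#' Discrepancies are classified as heterozygote-vs-homozygote or
#' opposite-homozygote. The rate is also reported as a percentage rounded
#' half-up to one decimal.
#'
#' @param gA,gB two [genotype_matrix()] objects (e.g. sequencing vs assay)
#' @return list: `n_compared`, `n_discrepant`, `rate`, `rate_pct`,
#'   `n_het_hom`, `n_opposite_hom`
#' @export
genotype_concordance <- function(gA, gB) {
  ids <- intersect(gA$samples$sample_id, gB$samples$sample_id)
  keyA <- paste(gA$sites$scaffold, gA$sites$position)
  keyB <- paste(gB$sites$scaffold, gB$sites$position)
  shared <- intersect(keyA, keyB)
  if (!length(ids) || !length(shared)) stop("no shared samples/sites")
  a <- gA$dosage[match(ids, gA$samples$sample_id),
                 match(shared, keyA), drop = FALSE]
  b <- gB$dosage[match(ids, gB$samples$sample_id),
                 match(shared, keyB), drop = FALSE]
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop("zero comparable genotype calls")
  av <- a[both]; bv <- b[both]
  disc <- av != bv
  het_hom <- disc & (av == 1L | bv == 1L)
  opp_hom <- disc & abs(av - bv) == 2L
  n_comp <- sum(both); n_disc <- sum(disc)
  list(n_compared = n_comp, n_discrepant = n_disc,
       rate = n_disc / n_comp,
       rate_pct = round_half_up(100 * n_disc / n_comp, 2),
       n_het_hom = sum(het_hom), n_opposite_hom = sum(opp_hom))
}
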