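# Differentiation and divergence statistics: Weir-Cockerham variance-
# component F_ST from genotypes, Hudson's sequence-based F_ST from
# alignments, windowed D_XY / D_X / D_Y over callsets with invariant sites,
# net divergence D_A, the D = 2*mu*t divergence-time approximation, and
# per-individual inbreeding coefficients.

#' Weir-Cockerham F_ST between two groups
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) from the
#' diploid two-level estimator using observed heterozygosity. The weighted
#' estimate is `sum(a) / sum(a + b + c)` over contributing sites — a ratio
#' of sums, never a mean of ratios. Per-site ratios are returned for
#' outlier analyses; sites with `a + b + c <= 0` have an undefined ratio.
#' The estimator is not clamped and may legitimately go negative when
#' between-group variance is below its sampling expectation.
#'
#' @param g a [genotype_matrix()]
#' @param group1,group2 sample ids or region codes (see [group_indices()])
#' @return list: `per_site` data.frame (`site`, `a`, `b`, `c`, `ratio`),
#'   `weighted` F_ST
#' @export
wc_fst <- function(g, group1, group2) {
  i1 <- group_indices(g, group1)
  i2 <- group_indices(g, group2)
  if (!length(i1) || !length(i2)) stop("empty group")
  comp <- wc_components(g$dosage[i1, , drop = FALSE],
                        g$dosage[i2, , drop = FALSE])
  denom <- comp$a + comp$b + comp$c
  ratio <- ifelse(denom > 0, comp$a / denom, NA_real_)
  ok <- comp$contrib
  weighted <- sum(comp$a[ok]) / sum(denom[ok])
  list(per_site = data.frame(site = seq_along(ratio), a = comp$a,
                             b = comp$b, c = comp$c, ratio = ratio),
       weighted = weighted)
}

# vectorised W-C (1984) two-population components; a site contributes when
# both groups have >= 2 non-missing genotypes
wc_components <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(d2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  contrib <- n1 >= 2 & n2 >= 2
  a[!contrib] <- NA_real_; b[!contrib] <- NA_real_; cc[!contrib] <- NA_real_
  list(a = a, b = b, c = cc, contrib = contrib)
}

#' Empirical outlier threshold for per-site F_ST ratios
#'
#' The q-quantile (default top 1%) of the defined per-site ratios, by
#' linear interpolation between order statistics (`stats::quantile`
#' type 7); sites at or above the threshold are flagged.
#'
#' @param ratios per-site F_ST ratios (NAs ignored)
#' @param q quantile (default 0.99)
#' @return list: `threshold`, `flagged` (logical over the input vector)
#' @export
fst_outlier_threshold <- function(ratios, q = 0.99) {
  ok <- !is.na(ratios)
  if (!any(ok)) stop("no defined per-site ratios")
  thr <- unname(stats::quantile(ratios[ok], q, type = 7))
  list(threshold = thr, flagged = !is.na(ratios) & ratios >= thr)
}

#' Hudson's sequence-based F_ST
#'
#' `F_ST = 1 - Hw / Hb` with `Hw` the unweighted mean of the two
#' within-group mean pairwise difference rates and `Hb` the between-group
#' mean pairwise difference rate; sites with N or gap in either sequence of
#' a pair are dropped for that pair (pairwise deletion). May be negative
#' when within-group diversity exceeds between-group divergence.
#'
#' @param aln a [haplotype_alignment()]
#' @param group1,group2 sample ids or (when `aln$regions` is set) region
#'   codes
#' @return Hudson F_ST (scalar)
#' @export
hudson_fst <- function(aln, group1, group2) {
  i1 <- aln_indices(aln, group1)
  i2 <- aln_indices(aln, group2)
  if (length(i1) < 2 || length(i2) < 2)
    stop("need >= 2 sequences per group")
  M <- aln_matrix(aln)
  hw1 <- mean_pairwise_rate(M, i1, i1)
  hw2 <- mean_pairwise_rate(M, i2, i2)
  hb <- mean_pairwise_rate(M, i1, i2)
  if (hb == 0) stop("between-group diversity is zero; Hudson F_ST undefined")
  1 - mean(c(hw1, hw2)) / hb
}

aln_indices <- function(aln, group) {
  if (all(group %in% aln$sample_ids)) return(match(group, aln$sample_ids))
  hit <- which(aln$regions %in% group)
  if (!length(hit)) stop("group matches no sequences")
  hit
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequences, ""))
}

# mean pairwise difference rate between two index sets (within-group when
# identical: all unordered pairs), pairwise deletion of N/- columns
mean_pairwise_rate <- function(M, ia, ib) {
  within <- identical(ia, ib)
  rates <- numeric(0)
  for (x in seq_along(ia)) {
    ys <- if (within) seq_along(ib)[-seq_len(x)] else seq_along(ib)
    for (y in ys) {
      s1 <- M[ia[x], ]; s2 <- M[ib[y], ]
      ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
      if (!any(ok)) next
      rates <- c(rates, mean(s1[ok] != s2[ok]))
    }
  }
  mean(rates)
}

#' Windowed D_XY / D_X / D_Y from a callset with invariant sites
#'
#' Sites with more than `max_missing` missing genotypes (over both groups)
#' are excluded; windows accumulate the next `window_bp_sequenced` retained
#' ("sequenced") positions per scaffold. Per window, `D_XY` is the mean
#' over sites of the between-group average pairwise difference probability
#' `pX (1 - pY) + pY (1 - pX)`; `D_X` and `D_Y` use the sample-size
#' unbiased within-group form `2 p (1 - p) * 2n / (2n - 1)`. The genome
#' estimate is the unweighted mean over windows. A terminal window with at
#' least half the target sites is kept; smaller remainders are discarded.
#'
#' @param g a [genotype_matrix()] including invariant positions
#' @param groupX,groupY sample ids or region codes
#' @param window_bp_sequenced retained positions per window (default 5000)
#' @param max_missing per-site missing-fraction bound (default 0.60,
#'   exclusive: sites above it are dropped)
#' @return list: `windows` data.frame (`scaffold`, `start`, `end` half-open,
#'   `n_sequenced_bp`, `DXY`, `DX`, `DY`), and overall `DXY`, `DX`, `DY`
#'   (means over windows)
#' @export
windowed_divergence <- function(g, groupX, groupY,
                                window_bp_sequenced = 5000,
                                max_missing = 0.60) {
  ix <- group_indices(g, groupX); iy <- group_indices(g, groupY)
  both <- c(ix, iy)
  miss <- colMeans(is.na(g$dosage[both, , drop = FALSE]))
  keep <- which(miss <= max_missing)
  if (!length(keep))
    return(list(windows = data.frame(), DXY = NA_real_, DX = NA_real_,
                DY = NA_real_))
  fx <- allele_freqs(g, ix); fy <- allele_freqs(g, iy)
  ok <- keep[fx$n[keep] >= 1 & fy$n[keep] >= 1]
  px <- fx$p[ok]; py <- fy$p[ok]
  dxy <- px * (1 - py) + py * (1 - px)
  dx <- unbiased_pi(px, fx$nchr[ok])
  dy <- unbiased_pi(py, fy$nchr[ok])
  scaf <- g$sites$scaffold[ok]; pos <- g$sites$position[ok]
  rows <- list()
  for (sc in unique(scaf)) {
    i_sc <- which(scaf == sc)
    nw <- length(i_sc) %/% window_bp_sequenced
    rem <- length(i_sc) %% window_bp_sequenced
    bounds <- rep(seq_len(nw + 1), c(rep(window_bp_sequenced, nw), rem))
    if (rem > 0 && rem < window_bp_sequenced / 2)
      bounds[bounds == nw + 1] <- NA  # discard small remainder
    for (w in unique(stats::na.omit(bounds))) {
      ii <- i_sc[which(bounds == w)]
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, start = min(pos[ii]), end = max(pos[ii]) + 1L,
        n_sequenced_bp = length(ii),
        DXY = mean(dxy[ii]), DX = mean(dx[ii]), DY = mean(dy[ii]))
    }
  }
  if (!length(rows))
    return(list(windows = data.frame(), DXY = NA_real_, DX = NA_real_,
                DY = NA_real_))
  win <- do.call(rbind, rows)
  list(windows = win, DXY = mean(win$DXY), DX = mean(win$DX),
       DY = mean(win$DY))
}

# unbiased per-site nucleotide diversity from allele frequency and
# chromosome count
unbiased_pi <- function(p, nchr) {
  ifelse(nchr > 1, 2 * p * (1 - p) * nchr / (nchr - 1), NA_real_)
}

#' Net divergence D_A
#'
#' `D_A = D_XY - 0.5 (D_X + D_Y)`: between-group divergence net of shared
#' ancestral diversity. May be negative when groups are effectively
#' undifferentiated.
#' @param DXY,DX,DY finite divergence estimates
#' @export
net_divergence <- function(DXY, DX, DY) {
  stopifnot(is.finite(DXY), is.finite(DX), is.finite(DY))
  DXY - 0.5 * (DX + DY)
}

#' TN93 distances with gamma rate variation
#'
#' Tamura-Nei (1993) pairwise distances with among-site rate variation
#' modelled by a gamma distribution (default shape 0.05), pairwise deletion
#' of ambiguous columns. Saturated pairs come back as `NaN` with a warning.
#'
#' @param aln a [haplotype_alignment()]
#' @param gamma_shape gamma shape parameter (default 0.05)
#' @return symmetric distance matrix with zero diagonal
#' @export
tn93_gamma_distance <- function(aln, gamma_shape = 0.05) {
  dna <- as_DNAbin(aln)
  dm <- as.matrix(ape::dist.dna(dna, model = "TN93", gamma = gamma_shape,
                                pairwise.deletion = TRUE))
  if (any(!is.finite(dm)))
    warning("saturated sequence pair(s): distance undefined")
  dm
}

#' Mean within/between TN93 distances and mtDNA D_A
#'
#' Convenience for the mtDNA divergence-time route: D_XY, D_X, D_Y as mean
#' pairwise TN93+Gamma distances and the resulting D_A.
#' @param aln a [haplotype_alignment()]
#' @param group1,group2 sample ids or region codes
#' @param gamma_shape gamma shape (default 0.05)
#' @export
mtdna_divergence <- function(aln, group1, group2, gamma_shape = 0.05) {
  dm <- tn93_gamma_distance(aln, gamma_shape)
  i1 <- aln_indices(aln, group1); i2 <- aln_indices(aln, group2)
  DXY <- mean(dm[i1, i2])
  DX <- mean(dm[i1, i1][upper.tri(dm[i1, i1])])
  DY <- mean(dm[i2, i2][upper.tri(dm[i2, i2])])
  list(DXY = DXY, DX = DX, DY = DY, DA = net_divergence(DXY, DX, DY))
}

#' Divergence time from net divergence
#'
#' The neutral-theory approximation `D = 2 mu t` inverted: `t = D_A / (2
#' mu)` years. Negative `D_A` is flagged non-estimable (`NA` with
#' `estimable = FALSE`). Point estimates only; rate calibration and
#' saturation make these rough.
#'
#' @param DA net divergence (per bp)
#' @param mu substitution rate per year per bp (> 0)
#' @return list: `t_years`, `estimable`
#' @export
divergence_time <- function(DA, mu) {
  if (mu <= 0) stop("mu must be > 0")
  if (DA < 0) return(list(t_years = NA_real_, estimable = FALSE))
  list(t_years = DA / (2 * mu), estimable = TRUE)
}

#' Per-individual inbreeding coefficient (method of moments)
#'
#' For each sample, `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the
#' observed homozygote count over the sample's non-missing sites, `E_hom =
#' sum_sites [1 - 2 p (1 - p) * 2n / (2n - 1)]` uses group allele
#' frequencies `p` and allele counts `2n`, and `L` is the number of
#' contributing sites. Negative values indicate less homozygosity than the
#' group-frequency expectation.
#'
#' @param g a [genotype_matrix()]
#' @param group sample ids or region codes defining both the samples scored
#'   and the frequency reference
#' @return data.frame: `sample_id`, `F`, `n_sites`
#' @export
inbreeding_F <- function(g, group) {
  idx <- group_indices(g, group)
  f <- allele_freqs(g, idx)
  res <- data.frame(sample_id = g$samples$sample_id[idx], F = NA_real_,
                    n_sites = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[k]
    obs <- which(!is.na(g$dosage[i, ]) & f$nchr > 1 & !is.nan(f$p))
    if (!length(obs)) next
    o_hom <- sum(g$dosage[i, obs] != 1L)
    e_hom <- sum(1 - 2 * f$p[obs] * (1 - f$p[obs]) *
                   f$nchr[obs] / (f$nchr[obs] - 1))
    L <- length(obs)
    res$n_sites[k] <- L
    if (abs(L - e_hom) > 1e-12) res$F[k] <- (o_hom - e_hom) / (L - e_hom)
  }
  res
}
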