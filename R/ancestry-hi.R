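# Maximum-likelihood joint estimation of the ancestry index S (proportion
# of the genome from reference population 1) and interclass heterozygosity
# H (proportion of loci with one allele copy from each source) for an
# individual genotyped at a small marker panel with known reference allele
# frequencies. (S, H) lives in the triangle H <= 2 min(S, 1 - S): S = 1,
# H = 0 is a pure reference-1 individual, S = 0.5, H = 1 an F1.

#' Log-likelihood of (S, H) given panel genotypes
#'
#' Per-locus genotype probabilities mix the three ancestry classes with
#' weights `pi11 = S - H/2`, `pi12 = H`, `pi22 = 1 - S - H/2` and the
#' reference frequencies `p1`, `p2` of the panel: dosage 2 has probability
#' `pi11 p1^2 + pi12 p1 p2 + pi22 p2^2`, dosage 1
#' `pi11 2 p1 q1 + pi12 (p1 q2 + q1 p2) + pi22 2 p2 q2`, dosage 0 the
#' complement squares. Zero-probability genotypes (possible with fixed
#' reference frequencies and a genotyping error) are floored at
#' `log(1e-300)` rather than `-Inf` so single incompatible calls do not
#' destroy estimation.
#'
#' @param dosages dosage vector over the panel (NA = missing, skipped)
#' @param panel an `aim_panel` with `p_ref1`, `p_ref2`
#' @param S,H feasible ancestry parameters
#' @return log-likelihood (<= 0)
#' @export
hi_loglik <- function(dosages, panel, S, H) {
  check_feasible(S, H)
  probs <- hi_class_probs(dosages, panel)
  if (!nrow(probs)) stop("no non-missing panel genotypes")
  pis <- c(S - H / 2, H, 1 - S - H / 2)
  sum(log(pmax(as.vector(probs %*% pis), 1e-300)))
}

check_feasible <- function(S, H) {
  if (S < -1e-12 || S > 1 + 1e-12 || H < -1e-12 ||
      H > 2 * min(S, 1 - S) + 1e-9)
    stop("infeasible (S, H) = (", S, ", ", H, ")")
  invisible(TRUE)
}

# per-locus probabilities of the observed dosage under each ancestry class
# (columns: both-from-1, one-each, both-from-2); rows = non-missing loci
hi_class_probs <- function(dosages, panel) {
  ok <- which(!is.na(dosages))
  p1 <- panel$p_ref1[ok]; p2 <- panel$p_ref2[ok]
  q1 <- 1 - p1; q2 <- 1 - p2
  d <- dosages[ok]
  cbind(
    ifelse(d == 2, p1^2, ifelse(d == 1, 2 * p1 * q1, q1^2)),
    ifelse(d == 2, p1 * p2, ifelse(d == 1, p1 * q2 + q1 * p2, q1 * q2)),
    ifelse(d == 2, p2^2, ifelse(d == 1, 2 * p2 * q2, q2^2))
  )
}

#' Maximum-likelihood (S, H) for one individual
#'
#' Exhaustive grid search over the feasible triangle at `grid_step`
#' resolution, followed by Nelder-Mead refinement in a reparameterisation
#' that keeps iterates inside the triangle (`H = h 2 min(S, 1 - S)`,
#' `h in [0, 1]`). Individuals with fewer than `min_loci` non-missing panel
#' genotypes are not estimated.
#'
#' @param dosages dosage vector over the panel
#' @param panel an `aim_panel` with reference frequencies
#' @param grid_step grid resolution (default 0.005)
#' @param min_loci minimum non-missing panel genotypes (default 7)
#' @return list: `S`, `H`, `logL`, `n_loci_used` (or `NULL` with a warning
#'   when below `min_loci`)
#' @export
estimate_SH <- function(dosages, panel, grid_step = 0.005, min_loci = 7) {
  n_used <- sum(!is.na(dosages))
  if (n_used < min_loci) {
    warning("only ", n_used, " panel genotypes (< ", min_loci,
            "); sample skipped")
    return(NULL)
  }
  probs <- hi_class_probs(dosages, panel)
  ll_of <- function(S, H) {
    pis <- c(S - H / 2, H, 1 - S - H / 2)
    sum(log(pmax(as.vector(probs %*% pis), 1e-300)))
  }
  S_grid <- seq(0, 1, by = grid_step)
  best <- c(S = 0.5, H = 0, ll = -Inf)
  for (S in S_grid) {
    hmax <- 2 * min(S, 1 - S)
    H_grid <- seq(0, hmax, by = grid_step)
    if (hmax - H_grid[length(H_grid)] > grid_step / 2)
      H_grid <- c(H_grid, hmax)
    ll <- vapply(H_grid, function(H) ll_of(S, H), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best[["ll"]]) best <- c(S = S, H = H_grid[i], ll = ll[i])
  }
  # refine inside the triangle: theta = (S, h) with H = h * 2 min(S, 1-S)
  h0 <- {
    hm <- 2 * min(best[["S"]], 1 - best[["S"]])
    if (hm > 0) best[["H"]] / hm else 0
  }
  obj <- function(th) {
    S <- min(max(th[1], 0), 1)
    h <- min(max(th[2], 0), 1)
    -ll_of(S, h * 2 * min(S, 1 - S))
  }
  opt <- stats::optim(c(best[["S"]], h0), obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
  S_hat <- min(max(opt$par[1], 0), 1)
  h_hat <- min(max(opt$par[2], 0), 1)
  H_hat <- h_hat * 2 * min(S_hat, 1 - S_hat)
  if (-opt$value < best[["ll"]]) {  # keep the grid optimum if refinement lost
    S_hat <- best[["S"]]; H_hat <- best[["H"]]
    opt$value <- -best[["ll"]]
  }
  list(S = S_hat, H = H_hat, logL = -opt$value, n_loci_used = n_used)
}

#' Estimate (S, H) for every sample of a panel genotype matrix
#'
#' @param g a [genotype_matrix()] restricted to (or containing) the panel
#'   sites; sites are matched to the panel by `(scaffold, position)`
#' @param panel an `aim_panel` with reference frequencies
#' @param grid_step,min_loci see [estimate_SH()]
#' @return data.frame: `sample_id`, `S`, `H`, `logL`, `n_loci` (skipped
#'   samples have NA estimates)
#' @export
estimate_SH_all <- function(g, panel, grid_step = 0.005, min_loci = 7) {
  key_g <- paste(g$sites$scaffold, g$sites$position)
  key_p <- paste(panel$scaffold, panel$position)
  j <- match(key_p, key_g)
  if (anyNA(j)) stop("panel sites missing from the genotype matrix")
  out <- data.frame(sample_id = g$samples$sample_id, S = NA_real_,
                    H = NA_real_, logL = NA_real_, n_loci = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_samples(g))) {
    d <- g$dosage[i, j]
    out$n_loci[i] <- sum(!is.na(d))
    est <- suppressWarnings(estimate_SH(d, panel, grid_step, min_loci))
    if (is.null(est)) next
    out$S[i] <- est$S; out$H[i] <- est$H; out$logL[i] <- est$logL
  }
  out
}

#' Classify hybrids by interclass heterozygosity
#'
#' `high` for `H >= high_H` (first/second-generation hybrids), `intermediate`
#' for `mid_H <= H < high_H`, `low` below. Also flags cluster membership by
#' `S > 0.5`.
#'
#' @param estimates data.frame with `S` and `H` columns (as from
#'   [estimate_SH_all()])
#' @param high_H,mid_H class boundaries (defaults 0.5 and 0.25, both
#'   inclusive at their lower edge)
#' @return the input with `class` and `cluster1` columns plus a `counts`
#'   attribute
#' @export
classify_hybrids <- function(estimates, high_H = 0.5, mid_H = 0.25) {
  H <- estimates$H
  cls <- ifelse(is.na(H), NA_character_,
                ifelse(H >= high_H, "high",
                       ifelse(H >= mid_H, "intermediate", "low")))
  estimates$class <- cls
  estimates$cluster1 <- estimates$S > 0.5
  attr(estimates, "counts") <- table(factor(cls, levels = c("high",
                                                            "intermediate",
                                                            "low")))
  estimates
}

#' Admixture fit restricted to the panel loci
#'
#' Re-uses [fit_admixture()] on the panel-only matrix so panel-based Q can
#' be compared with genome-wide Q; the panel estimate is expectedly
#' noisier.
#'
#' @param g a [genotype_matrix()] containing the panel sites
#' @param panel an `aim_panel`
#' @param K clusters (default 2)
#' @param seed,tol,max_iter passed to [fit_admixture()]
#' @export
admixture_on_panel <- function(g, panel, K = 2, seed = 1L, tol = 1e-9,
                               max_iter = 10000) {
  key_g <- paste(g$sites$scaffold, g$sites$position)
  key_p <- paste(panel$scaffold, panel$position)
  j <- match(key_p, key_g)
  if (anyNA(j)) stop("panel sites missing from the genotype matrix")
  fit_admixture(subset_genotypes(g, sites = j), K, seed = seed, tol = tol,
                max_iter = max_iter)
}
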