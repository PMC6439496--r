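# f3 admixture statistic with block jackknife. A significantly negative
# f3(X; Y, Z) indicates X is admixed between sources related to Y and Z;
# significantly positive values indicate no admixture.

#' f3 admixture statistic with block-jackknife standard error
#'
#' Per site j, `f3_j = (x - y)(x - z) - x (1 - x) / (n_X - 1)` with `x`,
#' `y`, `z` the sample ALT-allele frequencies of the target and the two
#' sources, and `n_X` the number of non-missing chromosomes in X (the
#' correction removes the sampling bias of the target frequency). The
#' statistic is the mean over contributing sites; the standard error comes
#' from a delete-one-block jackknife over consecutive blocks of
#' `block_size` SNPs in `(scaffold, position)` order (a short terminal
#' block is kept with equal weight).
#'
#' @param g a [genotype_matrix()], sites ordered by position
#' @param X,Y,Z sample ids or region codes: target and the two sources
#' @param block_size SNPs per jackknife block (default 50)
#' @return list of class `f3_result`: `X`, `Y`, `Z`, `f3`, `se`, `z`,
#'   `n_blocks`, `n_sites`
#' @export
f3_statistic <- function(g, X, Y, Z, block_size = 50) {
  ix <- group_indices(g, X); iy <- group_indices(g, Y)
  iz <- group_indices(g, Z)
  fx <- allele_freqs(g, ix); fy <- allele_freqs(g, iy)
  fz <- allele_freqs(g, iz)
  ok <- which(fx$nchr >= 2 & fy$nchr >= 1 & fz$nchr >= 1)
  if (!length(ok)) stop("no contributing sites for f3")
  x <- fx$p[ok]; y <- fy$p[ok]; z <- fz$p[ok]
  f3_j <- (x - y) * (x - z) - x * (1 - x) / (fx$nchr[ok] - 1)
  m <- length(f3_j)
  f3 <- mean(f3_j)
  block <- ceiling(seq_len(m) / block_size)
  B <- max(block)
  se <- NA_real_; zscore <- NA_real_
  if (B >= 2) {
    tot <- sum(f3_j)
    jk <- vapply(seq_len(B), function(b) {
      inb <- block == b
      (tot - sum(f3_j[inb])) / (m - sum(inb))
    }, numeric(1))
    se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
    if (se > 0) zscore <- f3 / se
  }
  structure(list(X = label_of(X), Y = label_of(Y), Z = label_of(Z),
                 f3 = f3, se = se, z = zscore, n_blocks = B, n_sites = m),
            class = "f3_result")
}

label_of <- function(group) paste(group, collapse = "+")

#' Enumerate f3 test triples over a region set
#'
#' All ordered triples (X; Y, Z) of distinct regions — `n (n-1) (n-2)` of
#' them, e.g. 336 for eight regions. Since the statistic is symmetric in
#' (Y, Z), `dedup = TRUE` keeps one of each (Y, Z) order, halving the
#' count.
#'
#' @param regions character vector of >= 3 region codes
#' @param dedup collapse (Y, Z) with (Z, Y) (default FALSE)
#' @return data.frame with columns `X`, `Y`, `Z`
#' @export
enumerate_f3_tests <- function(regions, dedup = FALSE) {
  regions <- unique(regions)
  n <- length(regions)
  if (n < 3) stop("need >= 3 regions")
  out <- expand.grid(Z = regions, Y = regions, X = regions,
                     stringsAsFactors = FALSE)[, c("X", "Y", "Z")]
  out <- out[out$X != out$Y & out$X != out$Z & out$Y != out$Z, ]
  if (dedup) out <- out[match(out$Y, regions) < match(out$Z, regions), ]
  rownames(out) <- NULL
  out
}

#' Run f3 for every triple of a region set
#'
#' @param g a [genotype_matrix()]
#' @param regions region codes (default: all regions present)
#' @param block_size SNPs per jackknife block
#' @param dedup see [enumerate_f3_tests()]
#' @return data.frame: `X`, `Y`, `Z`, `f3`, `se`, `z`, `n_blocks`
#' @export
f3_all_triples <- function(g, regions = NULL, block_size = 50,
                           dedup = FALSE) {
  if (is.null(regions))
    regions <- unique(stats::na.omit(g$samples$region))
  tests <- enumerate_f3_tests(regions, dedup = dedup)
  res <- lapply(seq_len(nrow(tests)), function(i) {
    r <- f3_statistic(g, tests$X[i], tests$Y[i], tests$Z[i], block_size)
    data.frame(X = r$X, Y = r$Y, Z = r$Z, f3 = r$f3, se = r$se, z = r$z,
               n_blocks = r$n_blocks, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
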