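# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as direct, scalar transcriptions of the
# defining formulas, independent of the package's vectorised paths.

# quick genotype_matrix from a dosage matrix (samples x sites)
make_gm <- function(dosage, regions = NULL, quality = NULL,
                    scaffold = NULL, positions = NULL, sources = NULL,
                    sex = NULL, flanks = FALSE) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(regions)) regions <- rep("East", n)
  sites <- data.frame(
    scaffold = if (is.null(scaffold)) rep("s1", m) else scaffold,
    position = if (is.null(positions)) seq_len(m) * 1000L else positions,
    ref = rep("A", m), alt = rep("G", m),
    is_biallelic_snp = rep(TRUE, m), stringsAsFactors = FALSE)
  if (flanks) {
    sites$flank_left <- strrep("A", 35)
    sites$flank_right <- strrep("C", 35)
  }
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    region = regions,
    source = if (is.null(sources)) rep("tissue", n) else sources,
    sex = if (is.null(sex)) rep("unknown", n) else sex,
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, sites, samples, quality = quality)
}

# scalar transcription of the Weir-Cockerham (1984) two-population
# variance components for one site
oracle_wc_site <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2)
  p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
  h1 <- mean(d1 == 1); h2 <- mean(d2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# brute-force mean pairwise difference rate between two sequence sets,
# enumerating every pair and every site
oracle_pairwise_rate <- function(seqs, ia, ib) {
  chars <- strsplit(seqs, "")
  acgt <- c("A", "C", "G", "T")
  rates <- c()
  within <- identical(ia, ib)
  for (x in seq_along(ia)) {
    ys <- if (within) seq_along(ib)[-seq_len(x)] else seq_along(ib)
    for (y in ys) {
      s1 <- chars[[ia[x]]]; s2 <- chars[[ib[y]]]
      num <- 0; den <- 0
      for (k in seq_along(s1)) {
        if (s1[k] %in% acgt && s2[k] %in% acgt) {
          den <- den + 1
          if (s1[k] != s2[k]) num <- num + 1
        }
      }
      if (den > 0) rates <- c(rates, num / den)
    }
  }
  mean(rates)
}

# brute-force between/within average pairwise difference per site from
# genotype allele counts, enumerating chromosome pairs
oracle_dxy_site <- function(dx, dy) {
  dx <- dx[!is.na(dx)]; dy <- dy[!is.na(dy)]
  ax <- sum(dx); nx <- 2 * length(dx)
  ay <- sum(dy); ny <- 2 * length(dy)
  (ax * (ny - ay) + (nx - ax) * ay) / (nx * ny)
}
oracle_pi_site <- function(d) {
  d <- d[!is.na(d)]
  a <- sum(d); n <- 2 * length(d)
  a * (n - a) / choose(n, 2)
}

# direct transcription of the three-class (S, H) mixture likelihood
oracle_hi_loglik <- function(dosages, p1, p2, S, H) {
  pi11 <- S - H / 2; pi12 <- H; pi22 <- 1 - S - H / 2
  ll <- 0
  for (i in seq_along(dosages)) {
    g <- dosages[i]
    if (is.na(g)) next
    q1 <- 1 - p1[i]; q2 <- 1 - p2[i]
    pr <- if (g == 2) pi11 * p1[i]^2 + pi12 * p1[i] * p2[i] + pi22 * p2[i]^2
    else if (g == 1) pi11 * 2 * p1[i] * q1 +
      pi12 * (p1[i] * q2 + q1 * p2[i]) + pi22 * 2 * p2[i] * q2
    else pi11 * q1^2 + pi12 * q1 * q2 + pi22 * q2^2
    ll <- ll + log(max(pr, 1e-300))
  }
  ll
}

# minimum spanning-tree weight by exhaustive enumeration: try every
# (k-1)-subset of edges and keep the lightest connected one (k <= 6)
oracle_mst_weight <- function(D) {
  k <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  combos <- utils::combn(nrow(pairs), k - 1)
  best <- Inf
  for (ci in seq_len(ncol(combos))) {
    es <- pairs[combos[, ci], , drop = FALSE]
    # connectivity via union-find
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in seq_len(nrow(es))) {
      a <- find(es[e, 1]); b <- find(es[e, 2])
      parent[a] <- b
    }
    if (length(unique(vapply(seq_len(k), find, integer(1)))) == 1) {
      w <- sum(D[es])
      best <- min(best, w)
    }
  }
  best
}

# random additive (tree-metric) distance matrix from a random binary tree
# with positive branch lengths; returns the patristic distances
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# tiny deterministic diagnostic panel: p_ref1 = 1, p_ref2 = 0
diagnostic_panel <- function(n_loci) {
  data.frame(scaffold = sprintf("s%d", seq_len(n_loci)),
             position = rep(100L, n_loci),
             ref = "A", alt = "G", site = seq_len(n_loci),
             ratio = 1, rank = seq_len(n_loci),
             p_ref1 = rep(1, n_loci), p_ref2 = rep(0, n_loci),
             stringsAsFactors = FALSE)
}
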