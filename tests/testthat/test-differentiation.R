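test_that("fixed difference gives weighted F_ST = 1; identical groups <= 0", {
  d <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  g <- make_gm(d, regions = rep(c("HG", "East"), each = 10))
  fst <- wc_fst(g, "HG", "East")
  expect_equal(fst$weighted, 1)
  # identical genotype multisets in both groups
  set.seed(3)
  block <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30)
  g2 <- make_gm(rbind(block, block), regions = rep(c("HG", "East"), each = 8))
  fst2 <- wc_fst(g2, "HG", "East")
  expect_lte(fst2$weighted, 0)   # estimator may go negative; not clamped
  expect_error(wc_fst(g, character(0), "East"))
})

test_that("W-C components match the scalar oracle transcription", {
  set.seed(44)
  for (rep in 1:3) {
    d <- matrix(sample(c(0:2, NA), 6 * 4, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 6, 4)
    # ensure >= 2 non-missing per group per site
    d[1:2, ] <- sample(0:2, 8, replace = TRUE)
    d[4:5, ] <- sample(0:2, 8, replace = TRUE)
    g <- make_gm(d, regions = c(rep("HG", 3), rep("East", 3)))
    fst <- wc_fst(g, "HG", "East")
    for (j in 1:4) {
      o <- oracle_wc_site(d[1:3, j], d[4:6, j])
      expect_equal(fst$per_site$a[j], unname(o["a"]), tolerance = 1e-12)
      expect_equal(fst$per_site$b[j], unname(o["b"]), tolerance = 1e-12)
      expect_equal(fst$per_site$c[j], unname(o["c"]), tolerance = 1e-12)
    }
    ok <- !is.na(fst$per_site$a)
    expect_equal(fst$weighted,
                 sum(fst$per_site$a[ok]) /
                   sum(fst$per_site$a[ok] + fst$per_site$b[ok] +
                         fst$per_site$c[ok]), tolerance = 1e-12)
  }
})

test_that("outlier threshold is the interpolated quantile and monotone in q", {
  ratios <- seq(0, 0.99, by = 0.01)
  thr <- fst_outlier_threshold(ratios, 0.99)
  expect_equal(thr$threshold, unname(quantile(ratios, 0.99, type = 7)))
  expect_true(thr$threshold >= 0.98 && thr$threshold <= 0.99)
  same <- fst_outlier_threshold(rep(0.4, 200))
  expect_equal(same$threshold, 0.4)
  expect_true(all(same$flagged))
  f95 <- fst_outlier_threshold(ratios, 0.95)$flagged
  expect_true(all(thr$flagged[f95 == FALSE] == FALSE |
                    sum(thr$flagged) <= sum(f95)))
  expect_error(fst_outlier_threshold(rep(NA_real_, 5)), "no defined")
})

test_that("Hudson F_ST: fixed difference = 1; pooled haplotypes ~ 0; oracle", {
  a1 <- haplotype_alignment(
    c("x1", "x2", "y1", "y2"),
    c("AAAA", "AAAA", "TTTT", "TTTT"),
    regions = c("HG", "HG", "East", "East"))
  expect_equal(hudson_fst(a1, "HG", "East"), 1)
  # both groups drawn from one haplotype pool: near zero, may be negative
  set.seed(61)
  pool <- c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAC", "ACGTACCTAC")
  seqs <- sample(pool, 16, replace = TRUE)
  a2 <- haplotype_alignment(sprintf("s%02d", 1:16), seqs,
                            regions = rep(c("HG", "East"), 8))
  expect_lt(abs(hudson_fst(a2, "HG", "East")), 0.15)
  # 4-sequence worked fixture vs brute force over all pairs
  a3 <- haplotype_alignment(
    c("p1", "p2", "q1", "q2"),
    c("ACGTAC", "ACGTAT", "TCGAAC", "TCGANC"),
    regions = c("HG", "HG", "East", "East"))
  hw <- mean(c(oracle_pairwise_rate(a3$sequences, 1:2, 1:2),
               oracle_pairwise_rate(a3$sequences, 3:4, 3:4)))
  hb <- oracle_pairwise_rate(a3$sequences, 1:2, 3:4)
  expect_equal(hudson_fst(a3, "HG", "East"), 1 - hw / hb, tolerance = 1e-10)
  a4 <- haplotype_alignment(c("a", "b", "c", "d"), rep("ACGT", 4),
                            regions = c("HG", "HG", "East", "East"))
  expect_error(hudson_fst(a4, "HG", "East"), "undefined")
})

test_that("windowed divergence matches the pair-enumeration oracle", {
  set.seed(71)
  nx <- 5; ny <- 4; m <- 40
  d <- rbind(matrix(sample(c(0:2, NA), nx * m, replace = TRUE,
                           prob = c(.4, .2, .3, .1)), nx, m),
             matrix(sample(c(0:2, NA), ny * m, replace = TRUE,
                           prob = c(.2, .2, .5, .1)), ny, m))
  d[1, ] <- 0L; d[nx + 1, ] <- 2L  # anchor both groups observed everywhere
  g <- make_gm(d, regions = c(rep("HG", nx), rep("East", ny)))
  res <- windowed_divergence(g, "HG", "East", window_bp_sequenced = 40,
                             max_missing = 0.60)
  keep <- which(colMeans(is.na(d)) <= 0.60)
  dxy_o <- sapply(keep, function(j) oracle_dxy_site(d[1:nx, j],
                                                    d[nx + 1:ny, j]))
  dx_o <- sapply(keep, function(j) oracle_pi_site(d[1:nx, j]))
  dy_o <- sapply(keep, function(j) oracle_pi_site(d[nx + 1:ny, j]))
  expect_equal(res$DXY, mean(dxy_o), tolerance = 1e-10)
  expect_equal(res$DX, mean(dx_o), tolerance = 1e-10)
  expect_equal(res$DY, mean(dy_o), tolerance = 1e-10)
})

test_that("windowed divergence degenerate patterns and window sizes", {
  # identical monomorphic groups
  g0 <- make_gm(matrix(0L, 6, 10), regions = rep(c("HG", "East"), each = 3))
  r0 <- windowed_divergence(g0, "HG", "East", window_bp_sequenced = 10)
  expect_equal(c(r0$DXY, r0$DX, r0$DY), c(0, 0, 0))
  # X fixed ref, Y fixed alt
  g1 <- make_gm(rbind(matrix(0L, 3, 10), matrix(2L, 3, 10)),
                regions = rep(c("HG", "East"), each = 3))
  r1 <- windowed_divergence(g1, "HG", "East", window_bp_sequenced = 5)
  expect_true(all(r1$windows$DXY == 1))
  expect_true(all(r1$windows$DX == 0 & r1$windows$DY == 0))
  expect_equal(nrow(r1$windows), 2)
  expect_true(all(r1$windows$n_sequenced_bp == 5))
  # terminal window below half the target is discarded
  g2 <- make_gm(matrix(1L, 4, 12), regions = rep(c("HG", "East"), each = 2))
  r2 <- windowed_divergence(g2, "HG", "East", window_bp_sequenced = 10)
  expect_equal(nrow(r2$windows), 1)   # 12 = 10 + 2; remainder 2 < 5 dropped
})

test_that("net divergence is the defining arithmetic and symmetric", {
  expect_equal(net_divergence(0, 0, 0), 0)
  expect_equal(net_divergence(0.01, 0.01, 0.01), 0)
  expect_equal(net_divergence(0.012, 0.008, 0.006), 0.005)
  expect_equal(net_divergence(0.012, 0.006, 0.008), 0.005)  # group exchange
})

test_that("TN93+Gamma distances: zero diagonal, symmetry, small-distance limit", {
  aln <- haplotype_alignment(
    c("a", "b", "c"),
    c(strrep("ACGT", 100),
      paste0("T", substr(strrep("ACGT", 100), 2, 400)),
      strrep("ACGT", 100)))
  dm <- tn93_gamma_distance(aln)
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))
  expect_equal(dm, t(dm))
  expect_equal(dm["a", "c"], 0)
  # one difference in 400 bp: correction nearly vanishes
  p <- 1 / 400
  expect_lt(abs(dm["a", "b"] - p) / p, 0.05)
})

test_that("divergence time inverts D = 2 mu t and flags negatives", {
  expect_equal(divergence_time(0, 1e-9)$t_years, 0)
  expect_equal(divergence_time(1.104e-4, 2.30e-9)$t_years, 24000)
  expect_equal(divergence_time(7.54e-3, 2.9e-7)$t_years, 13000)
  neg <- divergence_time(-0.001, 1e-9)
  expect_false(neg$estimable)
  expect_true(is.na(neg$t_years))
  expect_error(divergence_time(0.01, 0), "mu")
})

test_that("inbreeding F: fully homozygous = 1, HWE ~ 0, F = 0.25 recovered", {
  set.seed(81)
  m <- 600; n <- 40
  p <- runif(m, 0.2, 0.8)
  d_hwe <- t(replicate(n, rbinom(m, 2, p)))
  d_hwe[1, ] <- ifelse(d_hwe[1, ] == 1L, 2L, d_hwe[1, ])  # force sample 1 homozygous
  g <- make_gm(d_hwe, regions = rep("East", n))
  res <- inbreeding_F(g, "East")
  expect_equal(res$F[1], 1, tolerance = 1e-12)
  expect_lt(abs(mean(res$F[-1])), 0.03)
  expect_true(any(res$F[-1] < 0))   # individual values may be negative
  # inbred simulation: with probability F the two alleles are identical
  Fin <- 0.25
  d_inb <- t(replicate(n, {
    ibd <- runif(m) < Fin
    ifelse(ibd, 2L * rbinom(m, 1, p), rbinom(m, 2, p))
  }))
  gi <- make_gm(d_inb, regions = rep("East", n))
  ri <- inbreeding_F(gi, "East")
  expect_lt(abs(mean(ri$F) - Fin), 0.03)
})
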