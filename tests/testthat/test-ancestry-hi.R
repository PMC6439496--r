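random_panel <- function(m, seed, contrast = NULL) {
  set.seed(seed)
  p1 <- runif(m, 0, 1); p2 <- runif(m, 0, 1)
  if (!is.null(contrast)) {      # enforce |p1 - p2| = contrast
    p1 <- runif(m, contrast, 1)
    p2 <- p1 - contrast
  }
  pan <- diagnostic_panel(m)
  pan$p_ref1 <- p1; pan$p_ref2 <- p2
  pan
}

sample_admixed <- function(pan, S, H, seed) {
  set.seed(seed)
  m <- nrow(pan)
  cls <- sample.int(3, m, replace = TRUE, prob = c(S - H / 2, H,
                                                   1 - S - H / 2))
  c1 <- rbinom(m, 1, ifelse(cls == 3, pan$p_ref2, pan$p_ref1))
  c2 <- rbinom(m, 1, ifelse(cls == 1, pan$p_ref1, pan$p_ref2))
  c1 + c2
}

test_that("per-locus genotype probabilities sum to one over dosages", {
  pan <- random_panel(25, 7)
  for (SH in list(c(1, 0), c(0.5, 1), c(0.3, 0.4), c(0.75, 0.5))) {
    p_sum <- sapply(seq_len(25), function(i) {
      sum(sapply(0:2, function(d) {
        dd <- rep(NA_integer_, 25); dd[i] <- d
        exp(hi_loglik(dd, pan, SH[1], SH[2]))
      }))
    })
    expect_equal(p_sum, rep(1, 25), tolerance = 1e-10)
  }
})

test_that("hi_loglik matches the direct mixture-formula transcription", {
  pan <- random_panel(30, 11)
  set.seed(12)
  d <- sample(c(0:2, NA), 30, replace = TRUE)
  for (SH in list(c(0.9, 0.1), c(0.5, 0.8), c(0.2, 0.35))) {
    expect_equal(hi_loglik(d, pan, SH[1], SH[2]),
                 oracle_hi_loglik(d, pan$p_ref1, pan$p_ref2, SH[1], SH[2]),
                 tolerance = 1e-12)
  }
  expect_error(hi_loglik(d, pan, 0.9, 0.9), "infeasible")
})

test_that("diagnostic-panel closed forms: F1 and pure individuals", {
  pan <- diagnostic_panel(12)
  all_het <- rep(1L, 12)
  expect_equal(hi_loglik(all_het, pan, 0.5, 1), 0)
  expect_lt(hi_loglik(all_het, pan, 0.5, 0.9), 0)
  est <- estimate_SH(all_het, pan)
  expect_equal(est$S, 0.5, tolerance = 1e-6)
  expect_equal(est$H, 1, tolerance = 1e-6)
  pure <- estimate_SH(rep(2L, 12), pan)
  expect_equal(pure$S, 1, tolerance = 1e-6)
  expect_equal(pure$H, 0, tolerance = 1e-6)
  # with diagnostic markers, S-hat = reference-1 allele fraction and
  # H-hat = heterozygous fraction
  mixed <- c(rep(2L, 6), rep(1L, 4), rep(0L, 2))
  em <- estimate_SH(mixed, pan)
  expect_equal(em$S, mean(mixed) / 2, tolerance = 0.006)
  expect_equal(em$H, mean(mixed == 1L), tolerance = 0.006)
})

test_that("estimates always satisfy the ancestry-triangle constraint", {
  pan <- random_panel(10, 23)
  set.seed(5)
  for (k in 1:12) {
    d <- sample(0:2, 10, replace = TRUE)
    est <- estimate_SH(d, pan)
    expect_lte(est$H, 2 * min(est$S, 1 - est$S) + 1e-9)
    expect_lte(est$logL, 0)
  }
})

test_that("grid + refinement matches a dense 0.001 grid within 0.005", {
  pan <- random_panel(40, 29, contrast = 0.6)
  set.seed(6)
  for (k in 1:3) {
    d <- sample_admixed(pan, 0.6, 0.4, seed = 100 + k)
    est <- estimate_SH(d, pan)
    # dense-grid oracle: per-locus class probabilities from the direct
    # formula transcription, scanned over a 0.001 grid
    ok <- !is.na(d)
    probs <- t(sapply(which(ok), function(i) {
      p1 <- pan$p_ref1[i]; p2 <- pan$p_ref2[i]
      q1 <- 1 - p1; q2 <- 1 - p2
      if (d[i] == 2) c(p1^2, p1 * p2, p2^2)
      else if (d[i] == 1) c(2 * p1 * q1, p1 * q2 + q1 * p2, 2 * p2 * q2)
      else c(q1^2, q1 * q2, q2^2)
    }))
    best <- c(-Inf, NA, NA)
    for (S in seq(0, 1, by = 0.001)) {
      Hs <- seq(0, 2 * min(S, 1 - S), by = 0.001)
      pis <- cbind(S - Hs / 2, Hs, 1 - S - Hs / 2)
      ll <- rowSums(log(pmax(pis %*% t(probs), 1e-300)))
      i <- which.max(ll)
      if (ll[i] > best[1]) best <- c(ll[i], S, Hs[i])
    }
    expect_lt(abs(est$S - best[2]), 0.005)
    expect_lt(abs(est$H - best[3]), 0.005)
  }
})

test_that("planted (S, H) recovered at the stated tolerances", {
  pan_big <- random_panel(500, 31, contrast = 0.8)
  ests <- t(sapply(1:8, function(k)
    unlist(estimate_SH(sample_admixed(pan_big, 0.75, 0.5, seed = 200 + k),
                       pan_big)[c("S", "H")])))
  expect_lt(abs(mean(ests[, "S"]) - 0.75), 0.03)
  expect_lt(abs(mean(ests[, "H"]) - 0.5), 0.06)
  # small panel: tolerances widen
  pan_small <- random_panel(10, 37, contrast = 0.8)
  ests_s <- t(sapply(1:10, function(k)
    unlist(estimate_SH(sample_admixed(pan_small, 0.75, 0.5, seed = 300 + k),
                       pan_small)[c("S", "H")])))
  expect_lt(abs(mean(ests_s[, "S"]) - 0.75), 0.15)
  expect_lt(abs(mean(ests_s[, "H"]) - 0.5), 0.25)
})

test_that("samples below the minimum panel-genotype count are skipped", {
  pan <- random_panel(10, 41)
  d <- c(rep(1L, 6), rep(NA_integer_, 4))
  expect_warning(out <- estimate_SH(d, pan, min_loci = 7), "skipped")
  expect_null(out)
})

test_that("hybrid classes use inclusive boundaries and flag clusters", {
  est <- data.frame(sample_id = letters[1:6],
                    S = c(0.9, 0.5, 0.2, 0.6, 0.5, NA),
                    H = c(0.5, 0.25, 0.1, 0.49, 0.24, NA))
  cl <- classify_hybrids(est)
  expect_equal(cl$class, c("high", "intermediate", "low", "intermediate",
                           "low", NA))
  expect_equal(cl$cluster1, c(TRUE, FALSE, FALSE, TRUE, FALSE, NA))
  cnt <- attr(cl, "counts")
  expect_equal(unname(cnt[["high"]]), 1)
})

test_that("an F1 cohort is classified high", {
  pan <- random_panel(60, 43, contrast = 0.8)
  ests <- lapply(1:6, function(k)
    estimate_SH(sample_admixed(pan, 0.5, 1, seed = 400 + k), pan))
  H <- vapply(ests, `[[`, 0, "H")
  df <- data.frame(sample_id = as.character(1:6),
                   S = vapply(ests, `[[`, 0, "S"), H = H)
  expect_true(all(classify_hybrids(df)$class == "high"))
})

test_that("panel-based admixture Q tracks genome-wide Q but is noisier", {
  cfg <- sim_config(n_sites = 1200, region_sizes = c(HG = 14, East = 16),
                    drift_F = c(HG = 0.3, East = 0.01),
                    admixed_specs = list(list(region = "AA", S = 0.5,
                                              H = 0.6),
                                         list(region = "AA", S = 0.25,
                                              H = 0.3)),
                    seed = 47)
  fr <- simulate_allele_frequencies(cfg)
  g <- simulate_genotypes(fr, cfg)
  fst <- wc_fst(g, "HG", "East")
  panel <- apply_design_filters(rank_candidates(fst$per_site, g), g,
                                panel_size = 10)
  panel <- panel_frequencies(panel, g, "HG", "East")
  fit_gw <- fit_admixture(g, K = 2, seed = 3)
  fit_pn <- admixture_on_panel(g, panel, K = 2, seed = 3)
  # align cluster labelling by correlation sign with the island indicator
  isl <- as.numeric(g$samples$region == "HG")
  pick <- function(fit) {
    q <- fit$Q[, which.max(abs(cor(fit$Q, isl)))]
    if (cor(q, isl) < 0) 1 - q else q
  }
  q_gw <- pick(fit_gw); q_pn <- pick(fit_pn)
  expect_gt(cor(q_gw, q_pn, method = "spearman"), 0.8)
  # K = 1 degenerate case
  one <- admixture_on_panel(g, panel, K = 1, seed = 2)
  expect_true(all(one$Q == 1))
})
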