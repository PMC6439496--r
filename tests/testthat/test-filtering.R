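test_that("excess-heterozygosity boundary is inclusive at 0.6", {
  # site 1: 6/10 hets (= 0.6, removed); site 2: 5/10 hets (kept);
  # site 3: all missing (removed)
  d <- cbind(c(rep(1L, 6), rep(0L, 4)),
             c(rep(1L, 5), rep(0L, 5)),
             rep(NA_integer_, 10))
  g <- filter_excess_heterozygosity(make_gm(d))
  expect_equal(n_sites(g), 1)
  expect_equal(unname(g$dosage[, 1]), c(rep(1L, 5), rep(0L, 5)))
})

test_that("GQ masking keeps calls at exactly the threshold", {
  d <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  q <- matrix(c(10, 9, 9.9, 40), 2, 2)
  g <- mask_low_quality(make_gm(d, quality = q), min_gq = 10)
  expect_equal(unname(g$dosage), matrix(c(0L, NA, NA, 1L), 2, 2))
  # identity when everything passes
  g2 <- mask_low_quality(make_gm(d, quality = matrix(50, 2, 2)))
  expect_equal(unname(g2$dosage), d)
  expect_warning(mask_low_quality(make_gm(d)), "no genotype qualities")
})

test_that("sample filter is strict at >80% missing", {
  m <- 10
  d <- rbind(c(rep(NA_integer_, 8), 0L, 0L),   # exactly 80% -> retained
             c(rep(NA_integer_, 9), 0L),       # 90% -> dropped
             rep(0L, m))
  res <- filter_sample_missingness(make_gm(d))
  expect_equal(n_samples(res$genotypes), 2)
  expect_equal(res$report$dropped_ids, "S002")
  expect_equal(res$report$samples_in, 3)
  expect_equal(res$report$samples_out, 2)
})

test_that("site filter is strict at <30% missing", {
  d29 <- c(rep(NA_integer_, 29), rep(0L, 71))
  d30 <- c(rep(NA_integer_, 30), rep(0L, 70))
  g <- filter_site_missingness(make_gm(cbind(d29, d30)))
  expect_equal(n_sites(g), 1)
  full <- make_gm(matrix(0:1, 4, 3))
  expect_equal(n_sites(filter_site_missingness(full)), 3)
})

test_that("rare-allele modes: singletons, MAF boundary, monomorphic", {
  # site 1: one heterozygote among 50 -> singleton
  # site 2: MAF exactly 0.05 (5 alt alleles / 100) -> kept in maf mode
  # site 3: monomorphic
  s1 <- c(1L, rep(0L, 49))
  s2 <- c(rep(1L, 5), rep(0L, 45))
  s3 <- rep(2L, 50)
  g <- make_gm(cbind(s1, s2, s3))
  out_s <- filter_rare_alleles(g, "drop_singletons")
  expect_equal(n_sites(out_s), 1)            # only site 2 survives
  out_m <- filter_rare_alleles(g, "maf_threshold", maf = 0.05)
  expect_equal(n_sites(out_m), 1)
  expect_equal(unname(out_m$dosage[, 1]), s2)
})

test_that("LD pruning keeps one of a perfectly correlated pair and is idempotent", {
  set.seed(8)
  base <- sample(0:2, 40, replace = TRUE)
  indep <- replicate(6, sample(0:2, 40, replace = TRUE))
  d <- cbind(base, base, indep)
  g <- make_gm(d, positions = as.integer(seq(1000, by = 1000, length.out = 8)))
  pruned <- ld_prune(g, r2_max = 0.2)
  expect_lt(n_sites(pruned), n_sites(g))
  keys <- paste(pruned$sites$scaffold, pruned$sites$position)
  expect_true(all(keys %in% paste(g$sites$scaffold, g$sites$position)))
  expect_true("1000" %in% pruned$sites$position)  # first of the dup pair
  expect_false(all(c(1000, 2000) %in% pruned$sites$position))
  again <- ld_prune(pruned, r2_max = 0.2)
  expect_equal(n_sites(again), n_sites(pruned))
})

test_that("independent simulated sites survive pruning nearly intact", {
  set.seed(12)
  d <- matrix(sample(0:2, 60 * 200, replace = TRUE, prob = c(.25, .5, .25)),
              60, 200)
  g <- make_gm(d, positions = as.integer(seq(500, by = 700, length.out = 200)))
  pruned <- ld_prune(g, r2_max = 0.2)
  expect_gt(n_sites(pruned) / n_sites(g), 0.9)
})

test_that("Z-like loci are flagged, autosomal HWE loci mostly are not", {
  set.seed(31)
  n_m <- 20; n_f <- 20
  sex <- c(rep("M", n_m), rep("F", n_f))
  # 20 Z-like sites: males ~50% het, females all homozygous
  z <- sapply(seq_len(20), function(j)
    c(sample(c(0L, 1L), n_m, replace = TRUE),
      sample(c(0L, 2L), n_f, replace = TRUE, prob = c(.5, .5))))
  # 200 autosomal HWE sites
  p <- runif(200, .2, .8)
  aut <- sapply(p, function(pp) rbinom(n_m + n_f, 2, pp))
  g <- make_gm(cbind(z, aut), sex = sex)
  flags <- detect_sex_linked_loci(g, alpha = 1e-3)
  expect_gt(mean(flags[1:20]), 0.5)
  expect_lt(mean(flags[21:220]), 0.02)
  g_u <- make_gm(cbind(z, aut))
  expect_warning(f0 <- detect_sex_linked_loci(g_u), "known-sex")
  expect_false(any(f0))
})

test_that("kinship flags duplicates (~0.5) and parent-offspring (~0.25)", {
  set.seed(19)
  m <- 400
  p <- runif(m, 0.1, 0.9)
  parent1 <- rbinom(m, 2, p)
  parent2 <- rbinom(m, 2, p)
  # offspring: one allele from each parent
  pick <- function(g) ifelse(g == 1, rbinom(m, 1, 0.5), g / 2)
  child <- pick(parent1) + pick(parent2)
  unrel <- replicate(4, rbinom(m, 2, p))
  d <- rbind(parent1, parent1, parent2, child, t(unrel))
  g <- make_gm(d)
  pairs <- detect_close_kin(g, threshold = 0.177)
  key <- paste(pairs$id1, pairs$id2)
  expect_true("S001 S002" %in% key)  # duplicate
  dup <- pairs$kinship[key == "S001 S002"]
  expect_lt(abs(dup - 0.5), 0.08)
  expect_true("S001 S004" %in% key)  # parent-offspring
  po <- pairs$kinship[key == "S001 S004"]
  expect_lt(abs(po - 0.25), 0.08)
  # no unrelated pairs flagged
  unrel_ids <- sprintf("S%03d", 5:8)
  expect_false(any(pairs$id1 %in% unrel_ids & pairs$id2 %in% unrel_ids))
})

test_that("filter chain composes, reports attrition, and is deterministic", {
  cfg <- sim_config(n_sites = 400, region_sizes = c(HG = 6, East = 12),
                    source_tiers = list(HG = c(tissue = 1),
                                        East = c(tissue = 0.7,
                                                 feather = 0.3)),
                    seed = 33)
  sim <- simulate_dataset(cfg)
  fc1 <- filter_chain(sim$genotypes)
  fc2 <- filter_chain(sim$genotypes)
  expect_identical(fc1$report, fc2$report)
  expect_identical(fc1$genotypes$dosage, fc2$genotypes$dosage)
  r <- fc1$report
  expect_true(all(r$sites_out <= r$sites_in))
  expect_true(all(r$samples_out <= r$samples_in))
  # chain composes: each step's input equals the previous step's output
  expect_equal(r$sites_in[-1], r$sites_out[-nrow(r)])
  expect_equal(r$samples_in[-1], r$samples_out[-nrow(r)])
  # feather-tier samples at rate 0.85 fail the 80% filter, tissue passes
  dropped <- unlist(strsplit(r$dropped_ids[r$step == "sample_missingness"],
                             ","))
  src <- setNames(sim$genotypes$samples$source,
                  sim$genotypes$samples$sample_id)
  expect_true(all(src[dropped] == "feather"))
  kept <- fc1$genotypes$samples$sample_id
  expect_false(any(src[kept] == "feather"))
})

test_that("attrition arithmetic reproduces the source percentages", {
  # 160 samples: 25 dropped of which 22 feathers; 135 remain, 12 feathers
  samples <- data.frame(
    sample_id = sprintf("x%03d", 1:160),
    region = "East",
    source = c(rep("feather", 22), rep("tissue", 3),     # dropped
               rep("feather", 12), rep("tissue", 123)),  # remaining
    sex = "unknown", stringsAsFactors = FALSE)
  report <- data.frame(step = "sample_missingness", sites_in = 1,
                       sites_out = 1, samples_in = 160, samples_out = 135,
                       dropped_ids = paste(samples$sample_id[1:25],
                                           collapse = ","),
                       stringsAsFactors = FALSE)
  att <- attrition_by_source(report, samples, "feather")
  expect_equal(att$n_dropped, 25)
  expect_equal(att$n_dropped_source, 22)
  expect_equal(att$pct_dropped_source, 88.0)
  expect_equal(att$n_remaining, 135)
  expect_equal(att$n_remaining_source, 12)
  expect_equal(att$pct_remaining_source, 8.9)
})
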