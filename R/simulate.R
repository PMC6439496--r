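# Synthetic-data generator. Emulates the study conditions the pipeline was
# designed for: one strongly drifted island population (HG) against a weakly
# structured continental cluster, planted admixed individuals parameterised
# by (S, H), tiered genotype missingness and quality by tissue source, and a
# low-diversity island mtDNA control region.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: eight North American sampling
#' regions at the nuclear-dataset sample sizes (HG = 12, AA = 17, AK = 26,
#' BC = 11, BCc = 5, East = 29, VI = 6, WA = 13), island drift F = 0.15
#' against continental drift F = 0.003 — under Balding-Nichols drift the
#' expected pairwise Weir-Cockerham F_ST is about the mean of the two
#' drift parameters, so these defaults put island-vs-continent F_ST in the
#' 0.06-0.09 band and continental pairs at or below 0.01 — plus feather
#' samples with far higher genotype missingness than tissue, and an island
#' mtDNA pool restricted to two haplotypes one mutational step apart.
#'
#' @param n_sites number of biallelic SNPs to simulate
#' @param region_sizes named integer vector: samples per region (names are
#'   region codes; the first entry is the island population)
#' @param drift_F named numeric vector of per-region Balding-Nichols drift
#'   parameters in `[0, 1)`; recycled names must match `region_sizes`
#' @param admixed_specs list of `list(region=, S=, H=)` planted admixed
#'   individuals; each must satisfy `H <= 2 * min(S, 1 - S)`
#' @param admix_parents length-2 character vector: the two reference regions
#'   whose allele frequencies the admixed genomes are drawn from
#'   (parent 1 contributes the `S` fraction)
#' @param source_tiers named list: per-region probabilities over tissue
#'   sources
#' @param missing_rates named numeric vector: per-source genotype missing
#'   probability in `[0, 1]`
#' @param gq_params named list of `c(shape=, scale=)` gamma parameters for
#'   per-source genotype qualities
#' @param mt_length mtDNA alignment length in bp
#' @param mt_theta expected pairwise mtDNA differences within the
#'   continental group
#' @param mt_island_haps number of distinct island haplotypes
#' @param mt_island_divergence mutational steps between the island and
#'   continental mtDNA ancestors
#' @param n_scaffolds number of scaffolds sites are spread over
#' @param seed integer seed; identical seeds give bit-identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_sites = 5000,
                       region_sizes = c(HG = 12, AA = 17, AK = 26, BC = 11,
                                        BCc = 5, East = 29, VI = 6, WA = 13),
                       drift_F = c(HG = 0.15, AA = 0.003, AK = 0.003,
                                   BC = 0.003, BCc = 0.003, East = 0.003,
                                   VI = 0.003, WA = 0.003),
                       admixed_specs = list(),
                       admix_parents = c("HG", "East"),
                       source_tiers = NULL,
                       missing_rates = c(tissue = 0.10, blood = 0.12,
                                         feather = 0.85, toepad = 0.50),
                       gq_params = list(tissue = c(shape = 8, scale = 5),
                                        blood = c(shape = 8, scale = 5),
                                        feather = c(shape = 2, scale = 6),
                                        toepad = c(shape = 3, scale = 6)),
                       mt_length = 578, mt_theta = 4,
                       mt_island_haps = 2, mt_island_divergence = 5,
                       n_scaffolds = 40, seed = 1L) {
  regions <- names(region_sizes)
  if (is.null(regions)) stop("region_sizes must be named by region code")
  if (is.null(source_tiers))
    source_tiers <- stats::setNames(
      rep(list(c(tissue = 0.85, feather = 0.15)), length(regions)), regions)
  cfg <- list(n_sites = as.integer(n_sites),
              region_sizes = region_sizes, drift_F = drift_F[regions],
              admixed_specs = admixed_specs, admix_parents = admix_parents,
              source_tiers = source_tiers, missing_rates = missing_rates,
              gq_params = gq_params, mt_length = as.integer(mt_length),
              mt_theta = mt_theta, mt_island_haps = as.integer(mt_island_haps),
              mt_island_divergence = as.integer(mt_island_divergence),
              n_scaffolds = as.integer(n_scaffolds), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_sites < 1) stop("n_sites must be >= 1")
  if (any(cfg$region_sizes < 1)) stop("region_sizes must be positive")
  f <- cfg$drift_F
  if (any(is.na(f)) || any(f < 0) || any(f >= 1))
    stop("configuration error: drift_F must lie in [0, 1)")
  if (any(cfg$missing_rates < 0 | cfg$missing_rates > 1))
    stop("missing_rates must lie in [0, 1]")
  for (sp in cfg$admixed_specs) {
    S <- sp$S; H <- sp$H
    if (S < 0 || S > 1 || H < 0 ||
        H > 2 * min(S, 1 - S) + 1e-12)
      stop("infeasible admixed spec: (S, H) = (", S, ", ", H,
           ") violates H <= 2 min(S, 1 - S)")
  }
  invisible(cfg)
}

#' Simulate per-region allele frequencies under Balding-Nichols drift
#'
#' Ancestral frequencies are drawn Uniform(0.05, 0.95) (bounded away from
#' fixation so sites stay informative); region frequencies follow
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` given ancestral `p` and the
#' region's drift parameter `F`. `F = 0` copies the ancestral frequency
#' exactly. Expected Weir-Cockerham F_ST between two regions is their mean
#' `F`. Site coordinates and 35-bp flanking sequences for marker design are
#' attached.
#'
#' @param config a [sim_config()]
#' @return a `sim_freqs` list: `ancestral` vector, `freq` region-by-site
#'   matrix, `sites` data.frame
#' @export
simulate_allele_frequencies <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_sites
  p <- stats::runif(m, 0.05, 0.95)
  regions <- names(config$region_sizes)
  freq <- matrix(NA_real_, nrow = length(regions), ncol = m,
                 dimnames = list(regions, NULL))
  for (r in regions) {
    F <- config$drift_F[[r]]
    if (F == 0) {
      freq[r, ] <- p
    } else {
      k <- (1 - F) / F
      freq[r, ] <- stats::rbeta(m, p * k, (1 - p) * k)
    }
  }
  # spread sites over scaffolds with ~1.5 kb spacing so LD windows and
  # flanking-variant checks are exercised
  scaf <- sort(sample.int(config$n_scaffolds, m, replace = TRUE))
  pos <- integer(m)
  for (sc in unique(scaf)) {
    k <- sum(scaf == sc)
    pos[scaf == sc] <- cumsum(sample(500:2500, k, replace = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  ra <- t(replicate(m, sample(bases, 2)))
  mkflank <- function(n) {
    vapply(seq_len(n), function(i)
      paste(sample(bases, 35, replace = TRUE), collapse = ""), character(1))
  }
  sites <- data.frame(
    scaffold = sprintf("scaffold_%03d", scaf),
    position = pos, ref = ra[, 1], alt = ra[, 2],
    is_biallelic_snp = TRUE,
    flank_left = mkflank(m), flank_right = mkflank(m),
    stringsAsFactors = FALSE
  )
  structure(list(ancestral = p, freq = freq, sites = sites),
            class = "sim_freqs")
}

#' Simulate diploid genotypes from regional allele frequencies
#'
#' Pure individuals draw dosage ~ Binomial(2, p_region). Planted admixed
#' individuals assign each locus independently to one of three ancestry
#' classes — both copies from parent 1, one from each, both from parent 2 —
#' with probabilities `(S - H/2, H, 1 - S - H/2)`, then draw each allele
#' copy from the corresponding parent's frequency.
#'
#' @param freqs a `sim_freqs` object from [simulate_allele_frequencies()]
#'   (or any list with a region-by-site `freq` matrix and a `sites` table)
#' @param config a [sim_config()]
#' @return a [genotype_matrix()] (no quality; see [apply_quality_model()])
#' @export
simulate_genotypes <- function(freqs, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  m <- ncol(freqs$freq)
  regions <- names(config$region_sizes)
  ids <- character(0); reg <- character(0); src <- character(0)
  rows <- list()
  for (r in regions) {
    nr <- config$region_sizes[[r]]
    tier <- config$source_tiers[[r]]
    s_r <- sample(names(tier), nr, replace = TRUE, prob = tier)
    p <- freqs$freq[r, ]
    for (i in seq_len(nr)) {
      rows[[length(rows) + 1L]] <- stats::rbinom(m, 2, p)
    }
    ids <- c(ids, sprintf("%s_%02d", r, seq_len(nr)))
    reg <- c(reg, rep(r, nr)); src <- c(src, s_r)
  }
  pa <- config$admix_parents
  k <- 0
  for (sp in config$admixed_specs) {
    k <- k + 1
    S <- sp$S; H <- sp$H
    cls <- sample.int(3, m, replace = TRUE,
                      prob = c(S - H / 2, H, 1 - S - H / 2))
    p1 <- freqs$freq[pa[1], ]; p2 <- freqs$freq[pa[2], ]
    c1 <- stats::rbinom(m, 1, ifelse(cls == 3, p2, p1))
    c2 <- stats::rbinom(m, 1, ifelse(cls == 1, p1, p2))
    rows[[length(rows) + 1L]] <- c1 + c2
    ids <- c(ids, sprintf("%s_adm%02d", sp$region, k))
    reg <- c(reg, sp$region); src <- c(src, "tissue")
  }
  dosage <- do.call(rbind, rows)
  samples <- data.frame(
    sample_id = ids, region = reg, source = src,
    sex = sample(c("M", "F"), length(ids), replace = TRUE),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, freqs$sites, samples)
}

#' Apply the tiered missingness and genotype-quality model
#'
#' Each genotype is masked to missing independently at its sample's
#' source-tier rate; retained genotypes get qualities drawn from the tier's
#' discretised gamma distribution. Matrix dimensions are unchanged. Feather
#' samples at the default 0.85 rate fail the 80%-missing sample filter while
#' tissue samples pass — the attrition pattern the filtering stage expects.
#'
#' @param g a [genotype_matrix()] with `source` metadata
#' @param config a [sim_config()]
#' @return the masked [genotype_matrix()] with a quality matrix attached
#' @export
apply_quality_model <- function(g, config) {
  set.seed(config$seed + 2L)
  d <- g$dosage
  q <- matrix(NA_real_, nrow = nrow(d), ncol = ncol(d))
  m <- ncol(d)
  for (i in seq_len(nrow(d))) {
    src <- g$samples$source[i]
    rate <- config$missing_rates[[src]]
    if (rate > 0) d[i, stats::runif(m) < rate] <- NA_integer_
    gp <- config$gq_params[[src]]
    obs <- !is.na(d[i, ])
    q[i, obs] <- round(stats::rgamma(sum(obs), shape = gp[["shape"]],
                                     scale = gp[["scale"]]))
  }
  genotype_matrix(d, g$sites, g$samples, quality = q)
}

#' Simulate an mtDNA control-region alignment
#'
#' Uses a per-group star-like coalescent approximation: each continental
#' sequence carries Poisson(`mt_theta`/2) private mutations on a shared
#' group ancestor, so the expected pairwise difference count is `mt_theta`.
#' The island group (first region of the configuration) is constrained to
#' `mt_island_haps` haplotypes one mutational step apart, on an ancestor
#' `mt_island_divergence` steps from the continental one — the
#' low-island-diversity pattern the haplotype analyses expect. Gap-free,
#' fixed length.
#'
#' @param config a [sim_config()]
#' @return a [haplotype_alignment()] with region labels
#' @export
simulate_mtdna <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  L <- config$mt_length
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  mutate <- function(seqv, k) {
    if (k == 0) return(seqv)
    at <- sample.int(L, min(k, L))
    for (j in at) seqv[j] <- sample(setdiff(bases, seqv[j]), 1)
    seqv
  }
  regions <- names(config$region_sizes)
  island <- regions[1]
  isl_anc <- mutate(root, config$mt_island_divergence)
  haps <- list(isl_anc)
  if (config$mt_island_haps > 1) {
    for (h in 2:config$mt_island_haps) haps[[h]] <- mutate(haps[[h - 1]], 1)
  }
  ids <- character(0); reg <- character(0); seqs <- character(0)
  for (r in regions) {
    nr <- config$region_sizes[[r]]
    for (i in seq_len(nr)) {
      if (r == island) {
        s <- haps[[sample.int(length(haps), 1,
                              prob = c(0.7, rep(0.3 / max(1, length(haps) - 1),
                                                length(haps) - 1)))]]
      } else {
        s <- mutate(root, stats::rpois(1, config$mt_theta / 2))
      }
      ids <- c(ids, sprintf("%s_%02d", r, i))
      reg <- c(reg, r)
      seqs <- c(seqs, paste(s, collapse = ""))
    }
  }
  haplotype_alignment(ids, seqs, regions = reg)
}

#' Run the full generator and write its standard files
#'
#' Convenience wrapper: frequencies, genotypes, quality model and mtDNA in
#' one call, optionally written as VCF + FASTA + metadata TSV.
#'
#' @param config a [sim_config()]
#' @param out_prefix if non-NULL, writes `<prefix>.vcf`, `<prefix>_mt.fasta`
#'   and `<prefix>_samples.tsv`
#' @return list with `genotypes` (quality-masked), `raw` (pre-mask),
#'   `freqs`, `mtdna`
#' @export
simulate_dataset <- function(config = sim_config(), out_prefix = NULL) {
  freqs <- simulate_allele_frequencies(config)
  raw <- simulate_genotypes(freqs, config)
  g <- apply_quality_model(raw, config)
  mt <- simulate_mtdna(config)
  if (!is.null(out_prefix)) {
    write_vcf(g, paste0(out_prefix, ".vcf"))
    write_fasta_alignment(mt, paste0(out_prefix, "_mt.fasta"))
    write_metadata(g$samples, paste0(out_prefix, "_samples.tsv"))
  }
  list(genotypes = g, raw = raw, freqs = freqs, mtdna = mt)
}
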