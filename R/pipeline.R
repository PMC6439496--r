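# End-to-end orchestration: one declarative config drives simulate/ingest
# -> filter -> structure -> differentiation -> f3 -> AIM panel -> (S, H),
# writing TSV/VCF/newick outputs plus a run manifest. A single global seed
# is expanded into fixed per-stage seeds so each stage is individually
# reproducible.

PIPELINE_KEYS <- c("simulation", "input", "filters", "stages", "out_dir",
                   "seed", "island", "continental_ref", "panel_size")

#' Default pipeline configuration
#'
#' @param out_dir output directory
#' @param seed global seed (expanded per stage as `seed + stage offset`)
#' @param simulation list of [sim_config()] overrides (used when no input
#'   files are given)
#' @param input optional list with `vcf`, `meta`, `fasta` paths for real
#'   data
#' @param filters list of [filter_chain()] overrides
#' @param stages character vector from
#'   `c("structure", "differentiation", "f3", "panel", "hi", "mtdna")`
#' @param island island region code (default "HG")
#' @param continental_ref continental reference region for panel design
#'   (default "East")
#' @param panel_size AIM panel size (default 11)
#' @export
pipeline_config <- function(out_dir = tempfile("run"), seed = 1L,
                            simulation = list(), input = NULL,
                            filters = list(),
                            stages = c("structure", "differentiation", "f3",
                                       "panel", "hi", "mtdna"),
                            island = "HG", continental_ref = "East",
                            panel_size = 11) {
  cfg <- list(simulation = simulation, input = input, filters = filters,
              stages = stages, out_dir = out_dir, seed = as.integer(seed),
              island = island, continental_ref = continental_ref,
              panel_size = panel_size)
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(cfg$stages, c("structure", "differentiation", "f3",
                               "panel", "hi", "mtdna"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with [pipeline_config()] keys
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in methods order and writes every result
#' table under `out_dir`, together with `manifest.yaml` recording the
#' configuration, per-stage seeds and attrition counts. Re-running with the
#' same config and seed is bit-identical. A stage failure aborts with a
#' stage-tagged message; outputs already written are retained.
#'
#' @param config a [pipeline_config()] list or path to a YAML file
#' @return (invisibly) list of in-memory results per stage
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed

  # --- ingest or simulate -------------------------------------------------
  res$data <- stage("input", {
    if (!is.null(config$input)) {
      g <- read_vcf(config$input$vcf, meta = config$input$meta)
      mt <- if (!is.null(config$input$fasta)) {
        meta <- read_metadata(config$input$meta)
        read_fasta_alignment(config$input$fasta,
                             regions = stats::setNames(meta$region,
                                                       meta$sample_id))
      }
      list(genotypes = g, mtdna = mt)
    } else {
      sim_args <- config$simulation
      sim_args$seed <- seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(cfg)
      write_vcf(sim$genotypes, out("simulated.vcf"))
      write_metadata(sim$genotypes$samples, out("samples.tsv"))
      if (!is.null(sim$mtdna))
        write_fasta_alignment(sim$mtdna, out("simulated_mt.fasta"))
      sim
    }
  })
  g_raw <- res$data$genotypes

  # --- filtering ----------------------------------------------------------
  res$filtered <- stage("filter", {
    fc <- do.call(filter_chain, c(list(g = g_raw), config$filters))
    utils::write.table(fc$report, out("filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_vcf(fc$genotypes, out("filtered.vcf"))
    fc
  })
  g <- res$filtered$genotypes

  # --- structure ----------------------------------------------------------
  if ("structure" %in% config$stages) {
    res$structure <- stage("structure", {
      pca <- run_pca(g, n_axes = min(10, n_samples(g) - 1))
      utils::write.table(
        data.frame(sample_id = rownames(pca$scores), pca$scores),
        out("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      adm <- fit_admixture(g, K = 2, seed = seed + 11L)
      q <- data.frame(sample_id = g$samples$sample_id,
                      region = g$samples$region, adm$Q)
      utils::write.table(q, out("admixture_Q.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(pca = pca, admixture = adm)
    })
  }

  # --- differentiation ----------------------------------------------------
  island <- config$island
  continental <- setdiff(unique(stats::na.omit(g$samples$region)), island)
  if ("differentiation" %in% config$stages) {
    res$differentiation <- stage("differentiation", {
      fst <- wc_fst(g, island, continental)
      utils::write.table(fst$per_site, out("fst_per_site.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      thr <- fst_outlier_threshold(fst$per_site$ratio)
      f_inb <- inbreeding_F(g, island)
      utils::write.table(f_inb, out("inbreeding.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(wc = fst, outlier_threshold = thr$threshold, inbreeding = f_inb)
    })
  }

  # --- f3 -----------------------------------------------------------------
  if ("f3" %in% config$stages) {
    res$f3 <- stage("f3", {
      tab <- f3_all_triples(g, dedup = TRUE)
      utils::write.table(tab, out("f3.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      tab
    })
  }

  # --- AIM panel and (S, H) ----------------------------------------------
  if ("panel" %in% config$stages) {
    res$panel <- stage("panel", {
      fst <- if (!is.null(res$differentiation)) res$differentiation$wc
             else wc_fst(g, island, continental)
      ranked <- rank_candidates(fst$per_site, g)
      panel <- apply_design_filters(ranked, g,
                                    panel_size = config$panel_size)
      panel <- panel_frequencies(panel, g, island, config$continental_ref)
      utils::write.table(
        panel[, c("scaffold", "position", "ref", "alt", "p_ref1", "p_ref2",
                  "rank")],
        out("aim_panel.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      panel
    })
  }
  if ("hi" %in% config$stages && !is.null(res$panel)) {
    res$hi <- stage("hi", {
      est <- estimate_SH_all(g, res$panel)
      est <- classify_hybrids(est)
      utils::write.table(est, out("sh_estimates.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      est
    })
  }

  # --- mtDNA --------------------------------------------------------------
  mt <- res$data$mtdna
  if ("mtdna" %in% config$stages && !is.null(mt)) {
    res$mtdna <- stage("mtdna", {
      tab <- collapse_haplotypes(mt)
      utils::write.table(tab, out("haplotypes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      net <- mst_haplotype_network(tab)
      utils::write.table(net, out("haplotype_network.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      nj <- neighbor_joining(p_distance_matrix(mt))
      writeLines(nj$newick, out("mtdna_nj.nwk"))
      hfst <- tryCatch(hudson_fst(mt, island, continental),
                       error = function(e) NA_real_)
      list(haplotypes = tab, network = net, nj = nj, hudson_fst = hfst)
    })
  }

  manifest <- list(
    seed = seed,
    stages = config$stages,
    island = island,
    n_samples_in = n_samples(g_raw), n_sites_in = n_sites(g_raw),
    n_samples_out = n_samples(g), n_sites_out = n_sites(g)
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(res)
}
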