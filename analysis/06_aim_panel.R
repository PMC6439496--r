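#!/usr/bin/env Rscript
# Step 6 — ancestry-informative marker panel.
#
# Ranks sites by per-site F_ST between the island population and all other
# samples, applies the assay-design filters (>= 30 bp clean flanks, no
# common variant within the flanks, one site per scaffold), attaches
# island/continental reference allele frequencies, and demonstrates the
# cross-platform concordance report by re-reading the panel genotypes.

library(goshawkpop)

g <- read_vcf("results/data/goshawk_sim.vcf",
              meta = "results/data/goshawk_sim_samples.tsv")
g <- filter_biallelic_snps(g)
continental <- setdiff(unique(g$samples$region), "HG")

fst <- wc_fst(g, "HG", continental)
ranked <- rank_candidates(fst$per_site, g)
panel <- apply_design_filters(ranked, g, flank_bp = 30, panel_size = 11)
panel <- panel_frequencies(panel, g, "HG", "East")
write.table(panel[, c("scaffold", "position", "ref", "alt", "p_ref1",
                      "p_ref2", "rank", "ratio")],
            "results/aim_panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("panel size:", nrow(panel), "\n")
cat(sprintf("panel F_ST range: %.3f-%.3f\n", min(panel$ratio),
            max(panel$ratio)))
cat(sprintf("mean |p_island - p_continent| on panel: %.2f (genome: %.2f)\n",
            mean(abs(panel$p_ref1 - panel$p_ref2)),
            mean(abs(allele_freqs(g, group_indices(g, "HG"))$p -
                       allele_freqs(g, group_indices(g, continental))$p),
                 na.rm = TRUE)))

# concordance: the same genotypes re-read from the written VCF must agree
# perfectly; this is the report format used for sequencing-vs-assay checks
key <- paste(g$sites$scaffold, g$sites$position) %in%
  paste(panel$scaffold, panel$position)
g_panel <- subset_genotypes(g, sites = which(key))
write_vcf(g_panel, "results/data/panel_genotypes.vcf")
g_back <- read_vcf("results/data/panel_genotypes.vcf",
                   meta = "results/data/goshawk_sim_samples.tsv")
conc <- genotype_concordance(g_panel, g_back)
cat(sprintf("concordance check: %d discrepancies / %d calls (%.2f%%)\n",
            conc$n_discrepant, conc$n_compared, conc$rate_pct))
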