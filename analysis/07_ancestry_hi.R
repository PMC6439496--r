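#!/usr/bin/env Rscript
# Step 7 — ancestry index and interclass heterozygosity.
#
# Maximum-likelihood (S, H) for every sample with >= 7 non-missing panel
# genotypes, using the island/continental reference frequencies attached
# to the AIM panel, followed by hybrid classification: H >= 0.5 suggests a
# first/second-generation hybrid, 0.25 <= H < 0.5 later-generation
# admixture.

library(goshawkpop)

g <- read_vcf("results/data/goshawk_sim.vcf",
              meta = "results/data/goshawk_sim_samples.tsv")
g <- filter_biallelic_snps(g)
panel <- read.table("results/aim_panel.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
key_g <- paste(g$sites$scaffold, g$sites$position)
panel$site <- match(paste(panel$scaffold, panel$position), key_g)

est <- estimate_SH_all(g, panel, min_loci = 7)
est <- classify_hybrids(est)
write.table(est, "results/sh_estimates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hg <- g$samples$region == "HG"
cat(sprintf("mean S: island %.2f, continent %.2f\n",
            mean(est$S[hg], na.rm = TRUE),
            mean(est$S[!hg & !grepl("_adm", est$sample_id)], na.rm = TRUE)))
cat("hybrid classes:\n"); print(attr(est, "counts"))
adm <- grepl("_adm", est$sample_id)
cat("planted admixed individuals:\n")
print(est[adm, c("sample_id", "S", "H", "class")], row.names = FALSE)

# panel-only admixture for comparison with the genome-wide Q
fit <- admixture_on_panel(g, panel, K = 2, seed = 5)
q <- data.frame(sample_id = g$samples$sample_id, fit$Q)
write.table(q, "results/panel_admixture_Q.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("panel-only admixture written (10-ish loci: expect noisier Q)\n")
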