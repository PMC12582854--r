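#!/usr/bin/env Rscript
# Stage 2: post-genotyping SNP filters.
#
# Removes SNP clusters (>= 3 SNPs in any 10 bp span) and sites with a
# heterozygote-excess exact Hardy-Weinberg p < 0.01, the two bespoke filters
# applied on top of standard genotype quality control before any LD analysis.

suppressPackageStartupMessages(library(ayemaps))

out <- "results/synthetic"
snps <- read_vcf(file.path(out, "snps_raw.vcf"))
message("input: ", length(snps$pos), " biallelic SNPs")

cl <- filter_snp_clusters(snps, k = 3, w = 10)
message("cluster filter removed ", cl$removed)

hw <- filter_hwe(cl$snps, p_threshold = 0.01, side = "excess")
message("heterozygote-excess filter removed ", hw$removed)

write_vcf(hw$snps, file.path(out, "snps_filtered.vcf"))
message("kept ", length(hw$snps$pos), " SNPs -> snps_filtered.vcf")
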