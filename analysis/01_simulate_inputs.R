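#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# A 2 Mb toy scaffold stands in for an aye-aye autosomal scaffold: substitutions
# dropped along a single lineage at a known mutation rate, a phased 5-diploid
# haplotype panel from the SMC' coalescent with a hot/cold crossover landscape,
# exon annotations, and motif placements enriched in the high-recombination
# quarter. Everything is written in standard formats under results/synthetic/.

suppressPackageStartupMessages(library(ayemaps))

seed <- 20260919
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- genome_spec("scaffold_1", 2e6, gc = 0.41)
model <- equilibrium_model()            # N = 11,695 diploids
mu <- 0.4e-8                            # pedigree rate, young parents
branch_gens <- 54.9e6 / 5               # divergence time over generation time

w <- sliding_windows(spec, 5e5)
rec_truth <- rate_track(w$scaffold, w$start, w$end, c(0.5, 2.5, 0.5, 0.5),
                        units = "cM/Mb")
mu_truth <- uniform_rate_track(spec, mu, window = 2e6, units = "mut/bp/gen")

message("simulating sequence, substitutions, haplotypes, annotations, motifs")
seqs <- simulate_sequence(spec, seed = seed + 1)
subs <- simulate_substitutions(spec, mu_truth, branch_gens, seed = seed + 2)
panel <- simulate_haplotypes(model, mu, rec_truth, n_hap = 10, length = 2e6,
                             seed = seed + 3)
ann <- simulate_annotations(spec, exon_density = 0.02, mean_exon_len = 1000,
                            seed = seed + 4)
motifs <- place_motifs(spec, rec_truth, enrichment = 8, n_motifs = 25,
                       seed = seed + 5)

Biostrings::writeXStringSet(seqs, file.path(out, "genome.fasta"))
write_bed(subs, file.path(out, "substitutions.bed"))
write_vcf(panel_to_polymorphisms(panel), file.path(out, "snps_raw.vcf"))
write_gff3(ann, file.path(out, "annotations.gff3"))
write_bed(motifs, file.path(out, "motifs.bed"))
write_bedgraph(rec_truth, file.path(out, "true_recombination.bedGraph"))
write_bedgraph(mu_truth, file.path(out, "true_mutation_rate.bedGraph"))

message(sprintf("wrote inputs: %d substitutions, %d SNPs, %d exons, %d motifs",
                nrow(subs), length(panel$positions), nrow(ann), nrow(motifs)))
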