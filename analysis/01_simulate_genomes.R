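#!/usr/bin/env Rscript
# Simulate the study system: a six-chromosome monocot-like ancestor evolved
# through two independent lineages, each with two WGD rounds, fusions,
# fissions and fractionation. Lineage A follows the palm-like history
# (6 -> WGD -> 12 -> 2 fissions + 5 fusions -> 9 -> WGD -> 18 ->
# 1 fission + 3 fusions -> 16); lineage B ends at n = 20. Writes the
# genomes, homology truth and scenario record used by the later steps.

suppressMessages(library(palmkaryo))
seed <- 20250502L
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ancestor <- make_ancestor(6, 200, seed = seed)
sim <- evolve_lineages(ancestor,
                       palm_scenario(retention = 0.8, seed = seed + 1L),
                       waterweed_scenario(retention = 0.8, seed = seed + 2L))

cat(sprintf("ancestor: %d chromosomes, %d genes\n",
            n_chromosomes(ancestor), n_genes(ancestor)))
cat(sprintf("lineage A: %d chromosomes, %d genes (palm-like history)\n",
            n_chromosomes(sim$genome_a), n_genes(sim$genome_a)))
cat(sprintf("lineage B: %d chromosomes, %d genes\n",
            n_chromosomes(sim$genome_b), n_genes(sim$genome_b)))
cat(sprintf("homology truth: %d cross pairs, %d/%d within pairs\n",
            nrow(sim$truth$cross), nrow(sim$truth$within_a),
            nrow(sim$truth$within_b)))

write_fixtures(list(
  genome_a = sim$genome_a,
  genome_b = sim$genome_b,
  homology = sim$truth$cross[, c("gene_a", "gene_b")],
  truth = list(
    seed = seed,
    n_ancestral_chromosomes = n_chromosomes(ancestor),
    lineage_a = list(n_chromosomes = n_chromosomes(sim$genome_a),
                     wgd = 2, fissions = 3, fusions = 8),
    lineage_b = list(n_chromosomes = n_chromosomes(sim$genome_b),
                     wgd = 2, fissions = 1, fusions = 4),
    copy_count_range_a = range(sim$truth$copy_counts$n_a),
    copy_count_range_b = range(sim$truth$copy_counts$n_b))
), out)

# within-genome paralog truth for the self-synteny step
write.table(sim$truth$within_a, file.path(out, "homology_within_A.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$within_b, file.path(out, "homology_within_B.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
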