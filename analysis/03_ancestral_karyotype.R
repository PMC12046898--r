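#!/usr/bin/env Rscript
# Reconstruct the ancestral karyotype from synteny: infer ancestral
# chromosome groups ("colours") from cross- and self-synteny, paint the
# palm-like genome, recover its fusion/fission history across the two WGD
# rounds, and project the composition onto a triplicated third lineage.

suppressMessages(library(palmkaryo))
seed <- 20250502L
simdir <- "results/simulation"
out <- "results/karyotype"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ga <- read_genome_gff3(file.path(simdir, "genes_A.gff3"), "A")
gb <- read_genome_gff3(file.path(simdir, "genes_B.gff3"), "B")
hom <- read_homology_tsv(file.path(simdir, "homology.tsv"))
wa <- read_homology_tsv(file.path(simdir, "homology_within_A.tsv"))
wb <- read_homology_tsv(file.path(simdir, "homology_within_B.tsv"))

cross <- chain_anchors(build_anchors(ga, gb, hom[, 1:2]))
self_a <- chain_anchors(build_anchors(ga, ga, wa[, 1:2]))
self_b <- chain_anchors(build_anchors(gb, gb, wb[, 1:2]))

groups <- infer_ancestral_groups(list(cross, self_a, self_b),
                                 min_component_genes = 30)
cat(sprintf("ancestral groups: %d (gene counts %s)\n",
            nrow(groups$groups),
            paste(groups$groups$n_genes, collapse = ", ")))

painting <- paint_chromosomes(ga, groups, min_segment = 10)
cat(sprintf("painting of lineage A: %d segments, coverage %.2f\n",
            nrow(painting$segments), painting$coverage))
write.table(painting$segments, file.path(out, "painting.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

scenario <- infer_event_scenario(painting, n_wgd = 2, n_ancestral = 6)
cat(sprintf("inferred history: %d fusions, %d fissions (n %d -> %d)\n",
            scenario$fusions, scenario$fissions,
            scenario$n_expected, scenario$n_observed))
jsonlite::write_json(
  list(n0 = scenario$n0, n_wgd = scenario$n_wgd,
       fusions = scenario$fusions, fissions = scenario$fissions,
       per_epoch = scenario$per_epoch,
       n_expected = scenario$n_expected, n_observed = scenario$n_observed),
  file.path(out, "scenario.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, dataframe = "rows")

# validation against a third lineage that went through a triplication
anc <- make_ancestor(6, 200, seed = seed)
third <- evolve_lineages(anc,
                         palm_scenario(retention = 0.8, seed = seed + 1L),
                         evolution_scenario(list(wgt_event(),
                                                 loss_event(0.85)),
                                            seed = seed + 9L),
                         ids = c("A", "C"))
blocks_ac <- chain_anchors(build_anchors(third$genome_a, third$genome_b,
                                         third$truth$cross[, 1:2]))
proj <- project_composition(painting, blocks_ac)
per_group <- tapply(proj$segments$chrom, proj$segments$group_id,
                    function(x) length(unique(x)))
cat("triplicated-lineage validation, chromosomes per group:\n")
print(per_group)
write.table(proj$fractions, file.path(out, "projection_fractions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
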