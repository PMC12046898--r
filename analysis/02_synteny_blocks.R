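#!/usr/bin/env Rscript
# Chain homolog anchors into collinear synteny blocks (cross-genome and
# self comparisons), profile the syntenic multiplicity (expected 4:4 after
# two WGD rounds in each lineage), and derive one-to-one allelic pairs with
# CDS identity classes on a simulated haplotype pair.

suppressMessages(library(palmkaryo))
seed <- 20250502L
simdir <- "results/simulation"
out <- "results/synteny"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ga <- read_genome_gff3(file.path(simdir, "genes_A.gff3"), "A")
gb <- read_genome_gff3(file.path(simdir, "genes_B.gff3"), "B")
hom <- read_homology_tsv(file.path(simdir, "homology.tsv"))

blocks <- chain_anchors(build_anchors(ga, gb, hom))
cat(sprintf("cross-genome: %d blocks over %d anchors\n",
            nrow(blocks$blocks), nrow(blocks$anchors)))
write.table(blocks$blocks, file.path(out, "blocks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(blocks$anchors, file.path(out, "anchors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

mult <- block_multiplicity(blocks, window = 20)
cat(sprintf("modal syntenic multiplicity: %d:%d\n",
            mult$modal_a, mult$modal_b))
write.table(rbind(mult$windows_a, mult$windows_b),
            file.path(out, "multiplicity_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# haplotype-vs-haplotype allelic pairs: identical gene orders, CDS copies
# with a ~26% planted edit fraction
n_pairs <- 500
h1 <- data.frame(gene_id = sprintf("H1_%04d", seq_len(n_pairs)),
                 chrom = rep(sprintf("chr%d", 1:5), each = n_pairs / 5),
                 start = rep(seq_len(n_pairs / 5) * 4000L, 5))
h2 <- h1
h2$gene_id <- sub("^H1", "H2", h1$gene_id)
cds <- simulate_allelic_cds(n_pairs, n_codons = 100, edit_fraction = 0.26,
                            edits_per_seq = 2, seed = seed)
names(cds$cds_h1) <- h1$gene_id
names(cds$cds_h2) <- h2$gene_id
hap_blocks <- chain_anchors(build_anchors(h1, h2,
                                          data.frame(gene_a = h1$gene_id,
                                                     gene_b = h2$gene_id)))
pairs <- find_allelic_pairs(hap_blocks, cds$cds_h1, cds$cds_h2)
cat(sprintf("allelic pairs: %d; identical %.2f%%, similar %.2f%%, diverged %.2f%%\n",
            nrow(pairs),
            100 * mean(pairs$class == "identical"),
            100 * mean(pairs$class == "similar"),
            100 * mean(pairs$class == "diverged")))
write.table(pairs, file.path(out, "allelic_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
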