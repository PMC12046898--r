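toy_genes <- function(n, chrom = "c1", prefix = "g") {
  data.frame(gene_id = sprintf("%s%02d", prefix, seq_len(n)),
             chrom = chrom, start = seq_len(n) * 1000L,
             stringsAsFactors = FALSE)
}

test_that("anchors carry dense ranks and surface id errors", {
  ga <- toy_genes(5, prefix = "a")
  gb <- toy_genes(5, prefix = "b")
  hom <- data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id)
  anc <- build_anchors(ga, gb, hom)
  expect_equal(anc$rank_a, 0:4)
  expect_equal(anc$rank_b, 0:4)
  expect_equal(nrow(build_anchors(ga, gb, hom[0, ])), 0)
  expect_error(build_anchors(ga, gb, data.frame(gene_a = "zz", gene_b = "b01")),
               "zz")
  dup <- rbind(ga, ga[1, ])
  expect_error(build_anchors(dup, gb, hom), "duplicate")
})

test_that("one WGD bounds the anchor fan-out at two per gene", {
  anc <- make_ancestor(2, 30, seed = 1)
  sim <- evolve_lineages(anc, evolution_scenario(list(), 1),
                         evolution_scenario(list(wgd_event()), 2))
  anchors <- build_anchors(sim$genome_a, sim$genome_b, sim$truth$cross[, 1:2])
  expect_true(all(table(anchors$gene_a) <= 2))
})

test_that("plain diagonals chain into single blocks of either orientation", {
  ga <- toy_genes(5, prefix = "a")
  gb <- toy_genes(5, prefix = "b")
  plus <- build_anchors(ga, gb, data.frame(gene_a = ga$gene_id,
                                           gene_b = gb$gene_id))
  bp <- chain_anchors(plus, max_gap = 25, min_block_anchors = 5)
  expect_equal(nrow(bp$blocks), 1)
  expect_equal(bp$blocks$orientation, "+")
  expect_equal(bp$blocks$n_anchors, 5)
  minus <- build_anchors(ga, gb, data.frame(gene_a = ga$gene_id,
                                            gene_b = rev(gb$gene_id)))
  bm <- chain_anchors(minus, max_gap = 25, min_block_anchors = 5)
  expect_equal(nrow(bm$blocks), 1)
  expect_equal(bm$blocks$orientation, "-")
  expect_equal(bm$blocks$n_anchors, 5)
  expect_error(chain_anchors(plus, max_gap = 0), "max_gap")
  expect_error(chain_anchors(plus, min_block_anchors = 1),
               "min_block_anchors")
})

test_that("gap and minimum-anchor constraints prune chains", {
  ga <- toy_genes(40, prefix = "a")
  gb <- toy_genes(40, prefix = "b")
  # two diagonal runs separated by a 20-rank jump on both axes
  idx <- c(1:6, 27:32)
  hom <- data.frame(gene_a = ga$gene_id[idx], gene_b = gb$gene_id[idx])
  anc <- build_anchors(ga, gb, hom)
  one <- chain_anchors(anc, max_gap = 25, min_block_anchors = 5)
  expect_equal(nrow(one$blocks), 1)   # the jump is within max_gap
  expect_equal(one$blocks$n_anchors, 12)
  two <- chain_anchors(anc, max_gap = 10, min_block_anchors = 5)
  expect_equal(nrow(two$blocks), 2)
  expect_equal(sort(two$blocks$n_anchors), c(6, 6))
  none <- chain_anchors(anc[1:4, ], max_gap = 10, min_block_anchors = 5)
  expect_equal(nrow(none$blocks), 0)
})

test_that("chaining matches the exhaustive packing oracle on small instances", {
  withr::with_seed(99, {
    for (trial in 1:200) {
      n <- sample(4:12, 1)
      mg <- sample(c(3, 6, 25), 1)
      mb <- sample(2:5, 1)
      inst <- random_anchor_instance(n)
      got <- chain_anchors(inst, max_gap = mg, min_block_anchors = mb)
      expect_equal(sum(got$blocks$n_anchors),
                   oracle_chain_score(inst, mg, mb),
                   info = sprintf("trial %d n=%d gap=%d min=%d",
                                  trial, n, mg, mb))
    }
  })
})

test_that("blocks never share anchors and stay rank-monotone", {
  sim <- standard_two_wgd_sim(seed = 7)
  blocks <- chain_anchors(build_anchors(sim$genome_a, sim$genome_b,
                                        sim$truth$cross[, 1:2]))
  a <- blocks$anchors
  expect_false(any(duplicated(paste(a$gene_a, a$gene_b))))
  for (bid in blocks$blocks$block_id) {
    sub <- a[a$block_id == bid, ]
    expect_true(all(diff(sub$rank_a) > 0))
    ori <- blocks$blocks$orientation[blocks$blocks$block_id == bid]
    if (ori == "+") expect_true(all(diff(sub$rank_b) > 0))
    else expect_true(all(diff(sub$rank_b) < 0))
  }
})

test_that("chained anchors are nearly all truth homologs (block purity)", {
  sim <- standard_two_wgd_sim(seed = 8)
  # anchors from a noisy homology table: truth plus 10% random junk pairs
  truth_pairs <- sim$truth$cross[, 1:2]
  withr::with_seed(1, {
    junk <- data.frame(
      gene_a = sample(sim$genome_a$genes$gene_id, nrow(truth_pairs) %/% 10),
      gene_b = sample(sim$genome_b$genes$gene_id, nrow(truth_pairs) %/% 10))
  })
  blocks <- chain_anchors(build_anchors(sim$genome_a, sim$genome_b,
                                        rbind(truth_pairs, junk)))
  key_truth <- paste(truth_pairs$gene_a, truth_pairs$gene_b)
  purity <- mean(paste(blocks$anchors$gene_a, blocks$anchors$gene_b) %in%
                   key_truth)
  expect_gte(purity, 0.95)
})

test_that("modal multiplicity reads 1:1 on self and drops under fractionation", {
  ga <- toy_genes(60, prefix = "s")
  anc <- build_anchors(ga, ga, data.frame(gene_a = ga$gene_id,
                                          gene_b = ga$gene_id))
  blocks <- chain_anchors(anc)
  m <- block_multiplicity(blocks, window = 10)
  expect_equal(m$modal_a, 1)
  expect_equal(m$modal_b, 1)
  expect_equal(unname(m$ratio), c(1, 1))

  sim <- standard_two_wgd_sim(seed = 9, retention = 0.8)
  blocks4 <- chain_anchors(build_anchors(sim$genome_a, sim$genome_b,
                                         sim$truth$cross[, 1:2]))
  m4 <- block_multiplicity(blocks4, window = 20)
  expect_equal(m4$modal_a, 4)
  expect_equal(m4$modal_b, 4)

  # unbiased fractionation recompacts ranks, so window multiplicity cannot
  # increase (and in fact stays at the surviving copy number)
  ga2 <- apply_event(sim$genome_a, loss_event(0.4), seed = 99)
  truth2 <- truth_homology(ga2, sim$genome_b)
  blocks_f <- chain_anchors(build_anchors(ga2, sim$genome_b,
                                          truth2$cross[, 1:2]))
  mf <- suppressWarnings(block_multiplicity(blocks_f, window = 20))
  expect_lte(mf$modal_a, 4)
  expect_lte(mf$modal_b, 4)
  # copy-biased loss removes whole duplicate copies and the multiplicity
  # seen from the other genome drops accordingly
  keep <- !grepl("\\.2$", sim$genome_a$genes$copy_label)
  ga3 <- sim$genome_a$genes[keep, c("gene_id", "chrom", "start")]
  hom3 <- sim$truth$cross[sim$truth$cross$gene_a %in% ga3$gene_id, 1:2]
  gb_tab <- sim$genome_b$genes[, c("gene_id", "chrom", "start")]
  blocks_biased <- chain_anchors(build_anchors(ga3, gb_tab, hom3))
  mb <- block_multiplicity(blocks_biased, window = 20)
  expect_equal(mb$modal_b, 2)
  expect_lt(mb$modal_b, 4)
})

test_that("identical haplotypes give exactly one identical pair per gene", {
  ga <- toy_genes(30, prefix = "h1_")
  gb <- toy_genes(30, prefix = "h2_")
  cds <- simulate_allelic_cds(30, n_codons = 40, edit_fraction = 0,
                              seed = 1)
  names(cds$cds_h1) <- ga$gene_id
  names(cds$cds_h2) <- gb$gene_id
  blocks <- chain_anchors(build_anchors(ga, gb,
                                        data.frame(gene_a = ga$gene_id,
                                                   gene_b = gb$gene_id)))
  pairs <- find_allelic_pairs(blocks, cds$cds_h1, cds$cds_h2)
  expect_equal(nrow(pairs), 30)
  expect_equal(anyDuplicated(pairs$gene_h1), 0)
  expect_true(all(pairs$class == "identical"))
  expect_true(all(pairs$identity_pct == 100))
  expect_error(find_allelic_pairs(blocks, cds$cds_h1[-1], cds$cds_h2),
               "missing CDS")
})

test_that("a single substitution in a 10-bp CDS scores 90 percent identity", {
  ga <- toy_genes(6, prefix = "x")
  gb <- toy_genes(6, prefix = "y")
  cds1 <- setNames(rep("ACGTACGTAC", 6), ga$gene_id)
  cds2 <- setNames(c("ACGTACGTAC", "ACGTTCGTAC", rep("ACGTACGTAC", 4)),
                   gb$gene_id)
  blocks <- chain_anchors(build_anchors(ga, gb,
                                        data.frame(gene_a = ga$gene_id,
                                                   gene_b = gb$gene_id)),
                          min_block_anchors = 5)
  pairs <- find_allelic_pairs(blocks, cds1, cds2)
  expect_equal(pairs$identity_pct[pairs$gene_h1 == "x02"], 90)
  expect_equal(pairs$class[pairs$gene_h1 == "x02"], "similar")
})

test_that("planted CDS edits are recovered as the non-identical fraction", {
  n <- 200
  ga <- toy_genes(n, prefix = "h1_")
  gb <- toy_genes(n, prefix = "h2_")
  cds <- simulate_allelic_cds(n, n_codons = 60, edit_fraction = 0.26,
                              seed = 5)
  names(cds$cds_h1) <- ga$gene_id
  names(cds$cds_h2) <- gb$gene_id
  blocks <- chain_anchors(build_anchors(ga, gb,
                                        data.frame(gene_a = ga$gene_id,
                                                   gene_b = gb$gene_id)))
  pairs <- find_allelic_pairs(blocks, cds$cds_h1, cds$cds_h2)
  frac_non_identical <- mean(pairs$class != "identical")
  expect_equal(frac_non_identical, mean(cds$edited))
  expect_lt(abs(frac_non_identical - 0.26), 0.08)
})
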