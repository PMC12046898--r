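test_that("ancestor construction is shaped and reproducible", {
  anc <- make_ancestor(6, 200, seed = 1)
  expect_equal(n_chromosomes(anc), 6)
  expect_equal(n_genes(anc), 1200)
  expect_identical(anc, make_ancestor(6, 200, seed = 1))
  expect_identical(anc$genes$gene_id, anc$genes$ancestral_id)
  tiny <- make_ancestor(1, 1, seed = 0)
  expect_equal(n_genes(tiny), 1)
  expect_error(make_ancestor(0, 10), "n_chrom")
  expect_error(make_ancestor(3, -1), "genes_per_chrom")
})

test_that("genes stay sorted, dense-ranked and non-overlapping after events", {
  g <- make_ancestor(3, 40, seed = 2)
  g <- apply_event(g, wgd_event())
  g <- apply_event(g, inversion_event("c2.1", 5, 20))
  g <- apply_event(g, fission_event("c1.2", 13))
  g <- apply_event(g, fusion_event("c3.1", "c1.2a", "-"))
  g <- apply_event(g, loss_event(0.7), seed = 9)
  for (ch in g$chrom_order) {
    s <- g$genes[g$genes$chrom == ch, ]
    expect_equal(s$rank, seq_len(nrow(s)) - 1L)
    expect_true(all(s$start < s$end))
    if (nrow(s) > 1) expect_true(all(head(s$end, -1) <= tail(s$start, -1)))
  }
})

test_that("event arithmetic matches the karyotype algebra", {
  anc <- make_ancestor(6, 30, seed = 3)
  expect_equal(n_chromosomes(apply_event(anc, wgd_event())), 12)
  expect_equal(n_chromosomes(apply_event(anc, wgt_event())), 18)
  g12 <- apply_event(anc, wgd_event())
  expect_equal(n_chromosomes(apply_event(g12, fusion_event("c1.1", "c2.2"))),
               11)
  expect_equal(n_chromosomes(apply_event(g12, fission_event("c4.1", 10))), 13)
  # retention 1 leaves the genome untouched
  expect_identical(apply_event(g12, loss_event(1), seed = 1)$genes, g12$genes)
  expect_error(apply_event(anc, fusion_event("c1", "nope")), "not found")
  expect_error(apply_event(anc, fission_event("c1", 99)), "out of range")
})

test_that("inversion reverses gene order and flips strands in the interval", {
  g <- make_ancestor(1, 10, seed = 4)
  inv <- apply_event(g, inversion_event("c1", 2, 5))
  expect_equal(inv$genes$ancestral_id[3:6], rev(g$genes$ancestral_id[3:6]))
  expect_true(all(inv$genes$strand[3:6] ==
                    rev(ifelse(g$genes$strand[3:6] == "+", "-", "+"))))
  expect_identical(inv$genes$ancestral_id[c(1:2, 7:10)],
                   g$genes$ancestral_id[c(1:2, 7:10)])
})

test_that("chromosome counts of random scenarios match event_accounting", {
  for (s in 1:25) {
    anc <- make_ancestor(3, 30, seed = s)
    rs <- random_scenario(anc, n_events = 8, seed = 100 + s)
    epochs <- lapply(rs$events, function(ev) switch(ev$type,
      wgd = "wgd", fission = c(1, 0), fusion = c(0, 1), NULL))
    epochs <- Filter(Negate(is.null), epochs)
    expect_equal(n_chromosomes(rs$genome),
                 event_accounting(3, epochs)$n_final)
  }
})

test_that("loss drops copies but never orphans an ancestral gene", {
  anc <- make_ancestor(4, 50, seed = 5)
  g <- apply_event(anc, wgd_event())
  g <- apply_event(g, loss_event(0.05), seed = 6)
  expect_lt(n_genes(g), n_genes(anc) * 2)
  expect_setequal(unique(g$genes$ancestral_id), anc$genes$ancestral_id)
  # non-loss events preserve the ancestral id multiset entirely
  g2 <- apply_event(apply_event(anc, wgd_event()), fission_event("c2.1", 25))
  expect_equal(sort(g2$genes$ancestral_id),
               sort(rep(anc$genes$ancestral_id, 2)))
})

test_that("two-WGD lineages yield up to 4 copies and a symmetric truth table", {
  sim <- standard_two_wgd_sim(seed = 11)
  cc <- sim$truth$copy_counts
  expect_true(all(cc$n_a >= 1 & cc$n_a <= 4))
  expect_true(all(cc$n_b >= 1 & cc$n_b <= 4))
  expect_true(all(sim$truth$cross$gene_a %in% sim$genome_a$genes$gene_id))
  expect_true(all(sim$truth$cross$gene_b %in% sim$genome_b$genes$gene_id))
  # identity scenarios: homology is the identity pairing up to the id prefix
  anc <- make_ancestor(2, 20, seed = 12)
  ev0 <- evolve_lineages(anc, evolution_scenario(list(), 1),
                         evolution_scenario(list(), 2))
  expect_equal(nrow(ev0$truth$cross), n_genes(anc))
  expect_identical(sub("^A_", "", ev0$truth$cross$gene_a),
                   sub("^B_", "", ev0$truth$cross$gene_b))
})

test_that("codon-pair simulator hits its Ks target and stays stop-free", {
  p0 <- simulate_codon_pair(0, 50, seed = 1)
  expect_identical(p0$cds_a, p0$cds_b)
  expect_equal(p0$ks_truth, 0)
  expect_identical(simulate_codon_pair(0.3, 100, seed = 7),
                   simulate_codon_pair(0.3, 100, seed = 7))
  has_stop <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(Biostrings::GENETIC_CODE[cods] == "*")
  }
  truths <- vapply(1:50, function(s) {
    p <- simulate_codon_pair(0.3, 300, alphabet = "all", seed = s)
    expect_false(has_stop(p$cds_b))
    p$ks_truth
  }, numeric(1))
  se <- sd(truths) / sqrt(length(truths))
  expect_lt(abs(mean(truths) - 0.3), 3 * se + 1e-12)
  expect_error(simulate_codon_pair(-1, 100), "ks_target")
  expect_error(simulate_codon_pair(0.1, 5), "codons")
})

test_that("LTR pair divergence follows 2 * mu * T and scales with age", {
  p0 <- simulate_ltr_element(0, 5.6e-10, 1000, seed = 1)
  expect_identical(p0$ltr5, p0$ltr3)
  expect_equal(p0$d_truth, 0)
  p <- simulate_ltr_element(2.5e6, 5.6e-10, 2e5, seed = 2)
  expect_lt(abs(p$d_truth - 0.0028), 5 * sqrt(2 * 5.6e-10 * 2.5e6 / 2e5))
  d1 <- mean(vapply(1:10, function(s)
    simulate_ltr_element(1e6, 5.6e-10, 5e4, seed = s)$d_truth, numeric(1)))
  d2 <- mean(vapply(1:10, function(s)
    simulate_ltr_element(2e6, 5.6e-10, 5e4, seed = 100 + s)$d_truth,
    numeric(1)))
  expect_lt(abs(d2 / d1 - 2), 0.25)
})

test_that("expression simulator plants the stated allele fold change", {
  ex <- simulate_expression(n_pairs = 100, tissues = c("root", "stem", "leaf"),
                            n_reps = 3, ase_fraction = 0.1, effect = 4,
                            noise_sd = 0.1, seed = 21)
  expect_identical(ex$counts,
                   simulate_expression(n_pairs = 100,
                                       tissues = c("root", "stem", "leaf"),
                                       n_reps = 3, ase_fraction = 0.1,
                                       effect = 4, noise_sd = 0.1,
                                       seed = 21)$counts)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  planted <- ex$truth[ex$truth$is_ase, ]
  ratios <- vapply(seq_len(nrow(planted)), function(i) {
    up <- planted$up_haplotype[i]
    dn <- ifelse(up == "h1", "h2", "h1")
    s_up <- ex$samples$sample[ex$samples$haplotype == up]
    s_dn <- ex$samples$sample[ex$samples$haplotype == dn]
    mean(tpm[paste0(planted$pair_id[i], "_", up), s_up]) /
      mean(tpm[paste0(planted$pair_id[i], "_", dn), s_dn])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.5)
})

test_that("no-effect expression simulation plants nothing", {
  expect_error(simulate_expression(n_pairs = 10, ase_fraction = 0.2,
                                   effect = 1, seed = 1), "effect")
  ex <- simulate_expression(n_pairs = 10, ase_fraction = 0, effect = 1,
                            seed = 1)
  expect_false(any(ex$truth$is_ase))
})

test_that("metabolome simulator plants correlations of the target size", {
  ex <- simulate_expression(n_pairs = 30, tissues = c("root", "stem", "leaf"),
                            n_reps = 3, ase_fraction = 0, seed = 31)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  h1 <- ex$samples$sample[ex$samples$haplotype == "h1"]
  expr <- tpm[paste0(ex$pairs$pair_id, "_h1"), h1]
  tissues <- ex$samples$tissue[match(h1, ex$samples$sample)]

  met1 <- suppressWarnings(
    simulate_metabolome(expr, tissues, n_metabolites = 5,
                        linked_fraction = 0.4, target_r = 1,
                        negative_fraction = 0, seed = 1))
  for (k in seq_len(nrow(met1$truth_links))) {
    r <- cor(log2(met1$intensity[met1$truth_links$metabolite[k], ] + 1),
             log2(expr[met1$truth_links$gene[k], ] + 1))
    expect_equal(unname(r), 1, tolerance = 1e-8)
  }

  hit <- logical(0)
  for (s in 1:5) {
    met <- suppressWarnings(
      simulate_metabolome(expr, tissues, n_metabolites = 20,
                          linked_fraction = 0.5, target_r = 0.9, seed = s))
    hit <- c(hit, vapply(seq_len(nrow(met$truth_links)), function(k) {
      abs(cor(log2(met$intensity[met$truth_links$metabolite[k], ] + 1),
              log2(expr[met$truth_links$gene[k], ] + 1))) > 0.8
    }, logical(1)))
  }
  expect_gte(mean(hit), 0.9)
})

test_that("unlinked metabolomes rarely reach the edge threshold", {
  ex <- simulate_expression(n_pairs = 3, tissues = c("root", "stem", "leaf"),
                            n_reps = 3, ase_fraction = 0, seed = 41)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  h1 <- ex$samples$sample[ex$samples$haplotype == "h1"]
  expr <- tpm[paste0(ex$pairs$pair_id, "_h1"), h1]
  tissues <- ex$samples$tissue[match(h1, ex$samples$sample)]
  clean <- logical(0)
  for (s in 1:5) {
    met <- simulate_metabolome(expr, tissues, n_metabolites = 100,
                               linked_fraction = 0, seed = s)
    rmax <- apply(abs(cor(t(log2(met$intensity + 1)), t(log2(expr + 1)))),
                  1, max)
    clean <- c(clean, rmax <= 0.8)
  }
  expect_gte(mean(clean), 0.95)
})
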