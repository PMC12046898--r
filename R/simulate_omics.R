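# Omics simulators: allele-level expression counts for allelic gene pairs
# across tissues, and metabolite intensity matrices with planted
# gene-metabolite links.

#' Default twelve-tissue design
#'
#' Root, stem, leaf plus nine flower parts, mirroring a typical perennial
#' palm sampling design.
#' @return Character vector of tissue names.
#' @export
default_tissues <- function() {
  c("root", "stem", "leaf", "female_flower", "male_flower", "stamen",
    "pistil", "sepal", "petal", "peduncle", "pericarp", "seed")
}

#' Simulate allele-level expression counts with planted allele-specific effects
#'
#' Each allelic gene pair gets a gamma-distributed baseline abundance and a
#' per-tissue log-normal modulation shared by both alleles. A planted
#' fraction of pairs carries a true allele fold change (`effect`) in the
#' chosen tissues, direction alternating between haplotypes. Counts are
#' log-normal multiplicative noise around the scaled mean, one library per
#' (tissue, replicate, haplotype); a library holds only the genes of its own
#' haplotype (the other haplotype's rows are zero), matching
#' align-to-each-haplotype quantification.
#'
#' @param n_pairs Number of allelic gene pairs.
#' @param tissues Character vector of tissue names.
#' @param n_reps Replicates per tissue (>= 2).
#' @param ase_fraction Fraction of pairs with a planted allele effect.
#' @param effect True allele fold change for planted pairs (> 1).
#' @param noise_sd Log-scale (natural log) standard deviation of count noise.
#' @param ase_tissues Tissues in which the effect is planted (default all).
#' @param seed Optional integer seed.
#' @return List with `counts` (gene x sample integer matrix), `lengths`
#'   (named vector, bp), `samples` (sample sheet data frame with `sample`,
#'   `tissue`, `replicate`, `haplotype`), `pairs` (pair table) and `truth`
#'   (pair_id, is_ase, up_haplotype).
#' @export
simulate_expression <- function(n_pairs = 200, tissues = default_tissues(),
                                n_reps = 3, ase_fraction = 0.1, effect = 4,
                                noise_sd = 0.1, ase_tissues = tissues,
                                seed = NULL) {
  if (ase_fraction < 0 || ase_fraction > 1)
    stop("ase_fraction must be in [0, 1]")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (ase_fraction > 0 && effect <= 1)
    stop("effect must be > 1 when ASE pairs are planted")
  run <- function() {
    pair_id <- sprintf("P%04d", seq_len(n_pairs))
    gene_h1 <- paste0(pair_id, "_h1")
    gene_h2 <- paste0(pair_id, "_h2")
    base <- rgamma(n_pairs, shape = 1.5, scale = 200)
    tis_mod <- matrix(exp(rnorm(n_pairs * length(tissues), 0, 0.5)),
                      n_pairs, dimnames = list(pair_id, tissues))
    n_ase <- round(ase_fraction * n_pairs)
    ase_idx <- if (n_ase > 0) sample.int(n_pairs, n_ase) else integer(0)
    up_hap <- rep(NA_character_, n_pairs)
    up_hap[ase_idx] <- rep_len(c("h1", "h2"), n_ase)
    len <- sample(seq(600L, 3000L, by = 3L), n_pairs, replace = TRUE)
    lengths <- setNames(rep(len, each = 2L),
                        as.vector(rbind(gene_h1, gene_h2)))
    samples <- expand.grid(haplotype = c("h1", "h2"),
                           replicate = seq_len(n_reps), tissue = tissues,
                           stringsAsFactors = FALSE)[, 3:1]
    samples$sample <- sprintf("%s_r%d_%s", samples$tissue, samples$replicate,
                              samples$haplotype)
    samples <- samples[, c("sample", "tissue", "replicate", "haplotype")]
    genes <- c(gene_h1, gene_h2)
    counts <- matrix(0L, length(genes), nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (s in seq_len(nrow(samples))) {
      t <- samples$tissue[s]
      hap <- samples$haplotype[s]
      fac <- rep(1, n_pairs)
      if (t %in% ase_tissues) {
        up <- !is.na(up_hap) & up_hap == hap
        fac[up] <- effect
      }
      mu <- base * tis_mod[, t] * fac
      rows <- if (hap == "h1") gene_h1 else gene_h2
      counts[rows, s] <-
        as.integer(round(mu * exp(rnorm(n_pairs, 0, noise_sd))))
    }
    list(
      counts = counts, lengths = lengths, samples = samples,
      pairs = data.frame(pair_id = pair_id, gene_h1 = gene_h1,
                         gene_h2 = gene_h2, stringsAsFactors = FALSE),
      truth = data.frame(pair_id = pair_id,
                         is_ase = seq_len(n_pairs) %in% ase_idx,
                         up_haplotype = up_hap, stringsAsFactors = FALSE)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Metabolite classes used by the simulator
#' @return Character vector of eight class names.
#' @export
metabolite_classes <- function() {
  c("alkaloid", "flavonoid", "phenolic acid", "terpenoid",
    "amino acid and derivatives", "organic acid", "lipid", "others")
}

#' Simulate a metabolite intensity matrix with planted gene links
#'
#' A planted fraction of metabolites are noisy linear functions (on the log2
#' scale) of a partner gene's abundance; the remaining metabolites are
#' independent log-normal noise with no group structure. The noise of a
#' linked metabolite is residualised against its partner, so the planted
#' in-sample correlation equals `target_r` exactly. A planted link is only
#' meaningful when the partner is identifiable, so partners are preferably
#' drawn from genes whose in-sample correlation (log2 scale) with every
#' other gene stays below `identifiability`; when too few genes qualify the
#' least-entangled ones are used, with a warning.
#'
#' @param expr Gene x sample abundance matrix (e.g. TPM).
#' @param sample_tissues Tissue label per expression sample (recycled names of
#'   `colnames(expr)` order).
#' @param n_metabolites Number of metabolites to simulate.
#' @param linked_fraction Fraction of metabolites linked to a gene.
#' @param target_r Planted correlation magnitude in `[0, 1]`.
#' @param partner_genes Candidate partner genes (default: all rows of `expr`).
#' @param negative_fraction Fraction of planted links with negative sign.
#' @param identifiability Maximum in-sample correlation a partner may have
#'   with any other gene.
#' @param seed Optional integer seed.
#' @return List with `intensity` (metabolite x sample matrix), `classes`,
#'   `truth_links` (metabolite, gene, sign) and `sample_tissues`.
#' @export
simulate_metabolome <- function(expr, sample_tissues, n_metabolites = 25,
                                linked_fraction = 0.2, target_r = 0.9,
                                partner_genes = rownames(expr),
                                negative_fraction = 0.3,
                                identifiability = 0.6, seed = NULL) {
  if (abs(target_r) > 1) stop("target_r must be in [-1, 1]")
  if (linked_fraction < 0 || linked_fraction > 1)
    stop("linked_fraction must be in [0, 1]")
  if (length(sample_tissues) != ncol(expr))
    stop("sample_tissues must match the expression samples")
  run <- function() {
    n_samp <- ncol(expr)
    n_link <- round(linked_fraction * n_metabolites)
    met_id <- sprintf("M%03d", seq_len(n_metabolites))
    zmat <- t(scale(t(log2(as.matrix(expr) + 1))))
    zmat[!is.finite(zmat)] <- 0
    partners <- character(0)
    if (n_link > 0) {
      cand <- intersect(partner_genes, rownames(expr))
      entangled <- vapply(cand, function(g) {
        others <- setdiff(rownames(expr), g)
        if (!length(others)) return(0)
        max(abs(zmat[others, , drop = FALSE] %*% zmat[g, ]) / (n_samp - 1))
      }, numeric(1))
      eligible <- cand[entangled < identifiability]
      if (length(eligible) >= n_link) {
        partners <- sample(eligible, n_link)
      } else {
        warning("fewer than ", n_link, " identifiable partner genes; ",
                "using the least-entangled candidates")
        partners <- cand[order(entangled)][seq_len(n_link)]
      }
    }
    signs <- if (n_link > 0)
      ifelse(runif(n_link) < negative_fraction, -1, 1) else numeric(0)
    logi <- matrix(rnorm(n_metabolites * n_samp), n_metabolites,
                   dimnames = list(met_id, colnames(expr)))
    for (k in seq_len(n_link)) {
      z <- zmat[partners[k], ]
      eps <- rnorm(n_samp)
      if (sd(z) > 0) {
        eps <- eps - z * sum(eps * z) / sum(z^2)   # residualise on partner
        if (sd(eps) > 0) eps <- (eps - mean(eps)) / sd(eps)
        logi[k, ] <- signs[k] * target_r * z +
          sqrt(max(0, 1 - target_r^2)) * eps
      }
    }
    intensity <- 2^(16 + 2 * logi)
    classes <- setNames(sample(metabolite_classes(), n_metabolites,
                               replace = TRUE), met_id)
    truth <- data.frame(
      metabolite = met_id[seq_len(n_link)], gene = partners,
      sign = ifelse(signs > 0, "positive", "negative"),
      stringsAsFactors = FALSE
    )
    list(intensity = intensity, classes = classes, truth_links = truth,
         sample_tissues = sample_tissues)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
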