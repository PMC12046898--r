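# Independent oracles used against the package implementations. These are
# deliberately written from scratch (subset enumeration, explicit pathway
# permutation, eigen decomposition) rather than reusing package internals.

# Optimal total anchor count over disjoint collinear chains, by enumerating
# every subset that forms a valid chain and packing them exactly.
oracle_chain_score <- function(anchors, max_gap, min_block_anchors) {
  n <- nrow(anchors)
  stopifnot(n <= 16)
  ord <- order(anchors$rank_a, anchors$rank_b)
  ra <- anchors$rank_a[ord]
  rb <- anchors$rank_b[ord]
  bits <- bitwShiftL(1L, 0:(n - 1))
  masks <- integer(0)
  sizes <- integer(0)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bits) != 0L)
    if (length(idx) < min_block_anchors) next
    da <- diff(ra[idx])
    db <- diff(rb[idx])
    ok_plus <- all(da >= 1 & da <= max_gap & db >= 1 & db <= max_gap)
    ok_minus <- all(da >= 1 & da <= max_gap & -db >= 1 & -db <= max_gap)
    if (ok_plus || ok_minus) {
      masks <- c(masks, mask)
      sizes <- c(sizes, length(idx))
    }
  }
  if (!length(masks)) return(0L)
  memo <- new.env(parent = emptyenv())
  solve <- function(avail) {
    if (avail == 0L) return(0L)
    key <- as.character(avail)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    low_bit <- bitwAnd(avail, -avail)
    best <- solve(avail - low_bit)   # leave the lowest anchor unchained
    for (k in seq_along(masks)) {
      m <- masks[k]
      if (bitwAnd(m, low_bit) != 0L && bitwAnd(m, avail) == m) {
        v <- sizes[k] + solve(avail - m)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  solve(sum(bits))
}

random_anchor_instance <- function(n, rank_range = 12L) {
  data.frame(
    gene_a = sprintf("a%02d", seq_len(n)),
    gene_b = sprintf("b%02d", seq_len(n)),
    chrom_a = "x", chrom_b = "y",
    rank_a = sample.int(rank_range, n),
    rank_b = sample.int(rank_range, n),
    stringsAsFactors = FALSE)
}

# Nei-Gojobori bookkeeping for one codon pair by explicit enumeration:
# site fractions from the nine single-nucleotide neighbours, difference
# counts averaged over permutations of the differing positions (pathways
# crossing a stop codon dropped).
oracle_ng_codon_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(gc[cod])
  site_count <- function(cod) {
    if (translate1(cod) == "*") return(0)
    s <- 0
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(cod, pos, pos) == b) next
        alt <- cod
        substr(alt, pos, pos) <- b
        if (translate1(alt) == translate1(cod) && translate1(alt) != "*")
          s <- s + 1 / 3
      }
    }
    s
  }
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  sd_acc <- nd_acc <- numeric(0)
  for (path in perms(diffs)) {
    cur <- c1
    sdc <- ndc <- 0
    bad <- FALSE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (translate1(nxt) == "*") { bad <- TRUE; break }
      if (translate1(nxt) == translate1(cur)) sdc <- sdc + 1 else ndc <- ndc + 1
      cur <- nxt
    }
    if (!bad) { sd_acc <- c(sd_acc, sdc); nd_acc <- c(nd_acc, ndc) }
  }
  list(s1 = site_count(c1), s2 = site_count(c2),
       sd = mean(sd_acc), nd = mean(nd_acc))
}

# Per-metabolite top-k / threshold edge set by direct loops.
oracle_network_edges <- function(met, gene, r_threshold, top_k) {
  out <- list()
  for (i in seq_len(nrow(met))) {
    rs <- sapply(seq_len(nrow(gene)), function(j)
      cor(log2(met[i, ] + 1), log2(gene[j, ] + 1)))
    names(rs) <- rownames(gene)
    ord <- names(sort(-abs(rs)))[seq_len(min(top_k, length(rs)))]
    keep <- ord[abs(rs[ord]) > r_threshold]
    if (length(keep))
      out[[length(out) + 1]] <- data.frame(
        metabolite = rownames(met)[i], gene = keep, r = unname(rs[keep]),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(metabolite = character(0), gene = character(0),
               r = numeric(0))
}

# standard two-lineage two-WGD simulation used across karyotype tests
standard_two_wgd_sim <- function(seed, retention = 0.8,
                                 genes_per_chrom = 200) {
  anc <- make_ancestor(6, genes_per_chrom, seed = seed)
  evolve_lineages(anc,
                  palm_scenario(retention, seed = seed + 1000L),
                  waterweed_scenario(retention, seed = seed + 2000L))
}

sim_block_sets <- function(sim, ...) {
  cross <- chain_anchors(build_anchors(sim$genome_a, sim$genome_b,
                                       sim$truth$cross[, 1:2]), ...)
  self_a <- chain_anchors(build_anchors(sim$genome_a, sim$genome_a,
                                        sim$truth$within_a[, 1:2]), ...)
  self_b <- chain_anchors(build_anchors(sim$genome_b, sim$genome_b,
                                        sim$truth$within_b[, 1:2]), ...)
  list(cross = cross, self_a = self_a, self_b = self_b)
}

# ancestral chromosome of a simulated gene, read off the gene id
truth_ancestral_chrom <- function(gene_ids, ancestor) {
  anc_chr <- setNames(ancestor$genes$chrom, ancestor$genes$gene_id)
  aid <- regmatches(gene_ids, regexpr("g[0-9]+", gene_ids))
  unname(anc_chr[aid])
}
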