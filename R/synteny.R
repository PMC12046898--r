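# Synteny-block detection: homolog pairs become rank-space anchors, anchors
# are chained into collinear blocks (MCScanX-style), block multiplicity is
# profiled, and 1:1 blocks between haplotypes yield allelic gene pairs with
# CDS identity classes.

.as_gene_table <- function(x) {
  if (inherits(x, "sim_genome")) {
    tab <- x$genes[, c("gene_id", "chrom", "start", "rank")]
    attr(tab, "genome_id") <- x$genome_id
    return(tab)
  }
  stopifnot(is.data.frame(x), all(c("gene_id", "chrom", "start") %in% names(x)))
  tab <- x[order(x$chrom, x$start), , drop = FALSE]
  tab$rank <- unlist(lapply(split(seq_len(nrow(tab)), tab$chrom),
                            seq_along), use.names = FALSE)[
    order(order(tab$chrom, tab$start))]
  # recompute cleanly: dense 0-based rank per chromosome in start order
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  tab$rank <- unlist(lapply(split(tab$start, tab$chrom),
                            function(s) seq_along(s) - 1L), use.names = FALSE)
  attr(tab, "genome_id") <- attr(x, "genome_id") %||% "genome"
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build rank-space anchors from two gene orders and a homolog-pair table
#'
#' Each homologous gene pair becomes one anchor carrying the per-chromosome
#' gene ranks of its two genes (ranks are the dense ordinal positions of
#' genes sorted by start coordinate). For a within-genome comparison pass the
#' same genome twice and a table of paralog pairs.
#'
#' @param genes_a,genes_b `sim_genome` objects or data frames with `gene_id`,
#'   `chrom`, `start`.
#' @param homology Data frame whose first two columns are gene ids in
#'   `genes_a` and `genes_b` respectively.
#' @return Anchor data frame (`gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`) with `genome_a`/`genome_b` id attributes.
#' @export
build_anchors <- function(genes_a, genes_b, homology) {
  ta <- .as_gene_table(genes_a)
  tb <- .as_gene_table(genes_b)
  if (anyDuplicated(ta$gene_id)) stop("duplicate gene ids in genes_a")
  if (anyDuplicated(tb$gene_id)) stop("duplicate gene ids in genes_b")
  if (nrow(homology) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      rank_a = integer(0), rank_b = integer(0))
  } else {
    ga <- as.character(homology[[1]])
    gb <- as.character(homology[[2]])
    ia <- match(ga, ta$gene_id)
    ib <- match(gb, tb$gene_id)
    if (anyNA(ia))
      stop("homology gene id not found in genes_a: ", ga[which(is.na(ia))[1]])
    if (anyNA(ib))
      stop("homology gene id not found in genes_b: ", gb[which(is.na(ib))[1]])
    out <- data.frame(
      gene_a = ga, gene_b = gb,
      chrom_a = ta$chrom[ia], chrom_b = tb$chrom[ib],
      rank_a = ta$rank[ia], rank_b = tb$rank[ib],
      stringsAsFactors = FALSE
    )
    out <- out[order(out$chrom_a, out$chrom_b, out$rank_a, out$rank_b), ]
    rownames(out) <- NULL
  }
  attr(out, "genome_a") <- attr(ta, "genome_id")
  attr(out, "genome_b") <- attr(tb, "genome_id")
  out
}

# collapse anchors sharing a rank within one chromosome pair: keep the anchor
# with the smallest partner rank (deterministic; prevents degenerate
# vertical/horizontal chains from tandem-like multi-hits)
.collapse_tandem <- function(anc) {
  anc <- anc[order(anc$rank_a, anc$rank_b), , drop = FALSE]
  anc <- anc[!duplicated(anc$rank_a), , drop = FALSE]
  anc <- anc[order(anc$rank_b, anc$rank_a), , drop = FALSE]
  anc <- anc[!duplicated(anc$rank_b), , drop = FALSE]
  anc[order(anc$rank_a), , drop = FALSE]
}

# greedy best-first extraction for one chromosome pair; returns list of
# list(idx (row indices into anc), orientation)
.chain_greedy <- function(anc, max_gap, min_block_anchors) {
  chains <- list()
  avail <- seq_len(nrow(anc))
  repeat {
    if (length(avail) < min_block_anchors) break
    sub <- anc[avail, , drop = FALSE]
    op <- order(sub$rank_a, sub$rank_b)
    cp <- chain_dp_cpp(sub$rank_a[op], sub$rank_b[op], max_gap)
    om <- order(sub$rank_a, -sub$rank_b)
    cm <- chain_dp_cpp(sub$rank_a[om], -sub$rank_b[om], max_gap)
    if (length(cp) >= length(cm)) {
      pick <- avail[op[cp]]; orient <- "+"
    } else {
      pick <- avail[om[cm]]; orient <- "-"
    }
    if (length(pick) < min_block_anchors) break
    chains[[length(chains) + 1L]] <- list(idx = pick, orientation = orient)
    avail <- setdiff(avail, pick)
  }
  chains
}

# exact extraction for small chromosome pairs: enumerate every valid chain,
# then find the disjoint chain set with maximal total anchor count
# (branch-and-bound with memoisation over availability bitmasks)
.chain_exact <- function(anc, max_gap, min_block_anchors) {
  n <- nrow(anc)
  ord <- order(anc$rank_a, anc$rank_b)
  ra <- anc$rank_a[ord]
  rb <- anc$rank_b[ord]
  step_ok <- function(i, j, orient) {
    if (!(ra[j] > ra[i]) || ra[j] - ra[i] > max_gap) return(FALSE)
    if (orient > 0) rb[j] > rb[i] && rb[j] - rb[i] <= max_gap
    else rb[j] < rb[i] && rb[i] - rb[j] <= max_gap
  }
  chains <- list()
  grow <- function(path, orient) {
    if (length(path) >= min_block_anchors)
      chains[[length(chains) + 1L]] <<- list(
        idx = path, orientation = if (orient > 0) "+" else "-")
    last <- path[length(path)]
    for (j in seq_len(n)) {
      if (j > last && step_ok(last, j, orient)) grow(c(path, j), orient)
    }
  }
  for (orient in c(1, -1)) for (i in seq_len(n)) grow(i, orient)
  if (!length(chains)) return(list())
  sizes <- vapply(chains, function(ch) length(ch$idx), integer(1))
  masks <- vapply(chains, function(ch) sum(2^(ch$idx - 1)), numeric(1))
  by_anchor <- lapply(seq_len(n), function(a) {
    cand <- which(vapply(chains, function(ch) a %in% ch$idx, logical(1)))
    cand[order(-sizes[cand], masks[cand])]   # longest first for the bound
  })
  # branch and bound: the first descent tries the longest chain through the
  # lowest uncovered anchor, so a clean diagonal is solved on the first
  # branch and everything else is pruned by the incumbent
  best_val <- 0L
  best_pick <- integer(0)
  search <- function(avail, n_avail, cur_val, cur_pick) {
    if (cur_val + n_avail <= best_val) return()
    if (n_avail == 0) {
      if (cur_val > best_val) {
        best_val <<- cur_val
        best_pick <<- cur_pick
      }
      return()
    }
    a <- which((avail %/% 2^(seq_len(n) - 1)) %% 2 == 1)[1]
    for (ci in by_anchor[[a]]) {
      if (bitwAnd_num(masks[ci], avail) == masks[ci]) {
        search(avail - masks[ci], n_avail - sizes[ci],
               cur_val + sizes[ci], c(cur_pick, ci))
      }
    }
    search(avail - 2^(a - 1), n_avail - 1L, cur_val, cur_pick)
  }
  search(sum(2^(seq_len(n) - 1)), n, 0L, integer(0))
  lapply(best_pick, function(ci) {
    ch <- chains[[ci]]
    list(idx = ord[ch$idx], orientation = ch$orientation)
  })
}

# double-precision bitwise AND for masks up to 2^52
bitwAnd_num <- function(x, y) {
  r <- 0; bit <- 1
  while (any(x >= 1) && any(y >= 1)) {
    r <- r + bit * ((x %% 2 >= 1) & (y %% 2 >= 1))
    x <- x %/% 2; y <- y %/% 2; bit <- bit * 2
  }
  r
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, anchors are chained into strictly collinear
#' runs (both ranks increasing for `+` blocks, rank_b decreasing for `-`),
#' with consecutive rank gaps bounded by `max_gap` in both genomes and block
#' score equal to the anchor count. Multi-hits sharing a rank are collapsed
#' to one anchor first. Small chromosome pairs (at most `exact_limit`
#' anchors) are solved to optimality by exhaustive chain packing; larger
#' ones use best-first greedy extraction with used anchors removed. Chains
#' shorter than `min_block_anchors` are discarded.
#'
#' @param anchors Anchor data frame from [build_anchors()].
#' @param max_gap Maximum rank gap (gene-rank units) between consecutive
#'   anchors of a chain, in both genomes (>= 1).
#' @param min_block_anchors Minimum anchors per reported block (>= 2).
#' @param exact_limit Chromosome pairs with at most this many anchors are
#'   solved exactly (the cost of the exhaustive search grows as 2^n).
#' @return A `synteny_blocks` object: `blocks` (one row per block with rank
#'   intervals `[lo, hi)`, orientation and score) and `anchors` (block
#'   membership of every chained anchor).
#' @export
chain_anchors <- function(anchors, max_gap = 25, min_block_anchors = 5,
                          exact_limit = 12) {
  if (max_gap < 1) stop("max_gap must be >= 1")
  if (min_block_anchors < 2) stop("min_block_anchors must be >= 2")
  genome_a <- attr(anchors, "genome_a") %||% "A"
  genome_b <- attr(anchors, "genome_b") %||% "B"
  keys <- paste(anchors$chrom_a, anchors$chrom_b, sep = "\r")
  out_blocks <- list()
  out_anchors <- list()
  for (key in sort(unique(keys))) {
    anc <- .collapse_tandem(anchors[keys == key, , drop = FALSE])
    if (nrow(anc) < min_block_anchors) next
    chains <- if (nrow(anc) <= exact_limit) {
      .chain_exact(anc, max_gap, min_block_anchors)
    } else {
      .chain_greedy(anc, max_gap, min_block_anchors)
    }
    for (ch in chains) {
      sub <- anc[ch$idx, , drop = FALSE]
      sub <- sub[order(sub$rank_a), , drop = FALSE]
      out_blocks[[length(out_blocks) + 1L]] <- data.frame(
        chrom_a = sub$chrom_a[1], lo_a = min(sub$rank_a),
        hi_a = max(sub$rank_a) + 1L,
        chrom_b = sub$chrom_b[1], lo_b = min(sub$rank_b),
        hi_b = max(sub$rank_b) + 1L,
        orientation = ch$orientation, n_anchors = nrow(sub),
        stringsAsFactors = FALSE
      )
      out_anchors[[length(out_blocks)]] <- sub
    }
  }
  if (!length(out_blocks)) {
    blocks <- data.frame(block_id = character(0), chrom_a = character(0),
                         lo_a = integer(0), hi_a = integer(0),
                         chrom_b = character(0), lo_b = integer(0),
                         hi_b = integer(0), orientation = character(0),
                         n_anchors = integer(0))
    banchors <- cbind(block_id = character(0),
                      anchors[0, , drop = FALSE])
  } else {
    blocks <- do.call(rbind, out_blocks)
    ord <- order(blocks$chrom_a, blocks$lo_a, blocks$chrom_b, blocks$lo_b)
    blocks <- blocks[ord, , drop = FALSE]
    out_anchors <- out_anchors[ord]
    blocks <- cbind(block_id = sprintf("B%04d", seq_len(nrow(blocks))),
                    blocks, stringsAsFactors = FALSE)
    banchors <- do.call(rbind, Map(function(id, sub) {
      cbind(block_id = id, sub, stringsAsFactors = FALSE)
    }, blocks$block_id, out_anchors))
    rownames(blocks) <- rownames(banchors) <- NULL
  }
  structure(
    list(blocks = blocks, anchors = banchors,
         genome_a = genome_a, genome_b = genome_b,
         params = list(max_gap = max_gap,
                       min_block_anchors = min_block_anchors)),
    class = "synteny_blocks"
  )
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks: %d blocks (%s vs %s), %d chained anchors\n",
              nrow(x$blocks), x$genome_a, x$genome_b, nrow(x$anchors)))
  invisible(x)
}

#' Syntenic multiplicity profile of two genomes
#'
#' Slides non-overlapping windows of `window` gene ranks along every
#' chromosome of each genome and counts the distinct blocks covering each
#' window; the modal count over covered windows is the genome's syntenic
#' multiplicity (e.g. 4:4 after two rounds of whole-genome duplication in
#' both lineages).
#'
#' @param blocks A `synteny_blocks` object (cross-genome comparison).
#' @param window Window size in gene ranks.
#' @param extent_a,extent_b Optional named integer vectors of chromosome
#'   lengths in genes; by default inferred from the blocks themselves.
#' @return List with per-window count tables (`windows_a`, `windows_b`),
#'   `modal_a`, `modal_b` and `ratio`.
#' @export
block_multiplicity <- function(blocks, window = 20,
                               extent_a = NULL, extent_b = NULL) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  b <- blocks$blocks
  if (!nrow(b)) stop("block set is empty")
  min_span <- min(b$hi_a - b$lo_a, b$hi_b - b$lo_b)
  if (window > min_span)
    warning("window exceeds the smallest block span; counts may be sparse")
  side <- function(chrom, lo, hi, extent) {
    if (is.null(extent))
      extent <- tapply(hi, chrom, max)
    out <- list()
    for (ch in names(extent)) {
      ws <- seq(0L, max(0L, extent[[ch]] - 1L), by = window)
      sel <- chrom == ch
      cnt <- vapply(ws, function(w) {
        sum(sel & lo < w + window & hi > w)
      }, numeric(1))
      out[[ch]] <- data.frame(chrom = ch, w_lo = ws, w_hi = ws + window,
                              n_blocks = as.integer(cnt))
    }
    do.call(rbind, out)
  }
  wa <- side(b$chrom_a, b$lo_a, b$hi_a, extent_a)
  wb <- side(b$chrom_b, b$lo_b, b$hi_b, extent_b)
  modal <- function(w) {
    cov <- w$n_blocks[w$n_blocks >= 1L]
    if (!length(cov)) return(NA_integer_)
    tab <- table(cov)
    as.integer(names(tab)[which.max(tab)])
  }
  list(windows_a = wa, windows_b = wb,
       modal_a = modal(wa), modal_b = modal(wb),
       ratio = c(a = modal(wa), b = modal(wb)))
}

.as_seq_set <- function(x, arg) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop(arg, " must be a named character vector or DNAStringSet")
}

#' Derive allelic gene pairs from haplotype-vs-haplotype blocks
#'
#' Blocks are visited best-first (by score); anchors whose genes are still
#' unclaimed become allelic pairs, so each gene contributes to at most one
#' pair and only the single best block covers any region. CDS identity is
#' computed from a global Needleman-Wunsch alignment (match +1, mismatch -1,
#' gap -2) as matches over alignment columns, and classified as `identical`
#' (100), `similar` (at least `similar_threshold`) or `diverged`.
#'
#' @param blocks `synteny_blocks` between haplotype 1 and haplotype 2.
#' @param cds_h1,cds_h2 Named character vectors or `DNAStringSet`s of CDS.
#' @param similar_threshold Percent identity separating similar from diverged.
#' @return Data frame: `gene_h1`, `gene_h2`, `block_id`, `identity_pct`,
#'   `class`.
#' @export
find_allelic_pairs <- function(blocks, cds_h1, cds_h2,
                               similar_threshold = 80) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  s1 <- .as_seq_set(cds_h1, "cds_h1")
  s2 <- .as_seq_set(cds_h2, "cds_h2")
  banch <- blocks$anchors
  ord <- order(-blocks$blocks$n_anchors, blocks$blocks$block_id)
  used1 <- character(0)
  used2 <- character(0)
  keep <- logical(nrow(banch))
  for (bid in blocks$blocks$block_id[ord]) {
    rows <- which(banch$block_id == bid)
    for (r in rows) {
      if (banch$gene_a[r] %in% used1 || banch$gene_b[r] %in% used2) next
      keep[r] <- TRUE
      used1 <- c(used1, banch$gene_a[r])
      used2 <- c(used2, banch$gene_b[r])
    }
  }
  sel <- banch[keep, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(gene_h1 = character(0), gene_h2 = character(0),
                      block_id = character(0), identity_pct = numeric(0),
                      class = character(0)))
  }
  miss1 <- setdiff(sel$gene_a, names(s1))
  if (length(miss1)) stop("missing CDS for gene: ", miss1[1])
  miss2 <- setdiff(sel$gene_b, names(s2))
  if (length(miss2)) stop("missing CDS for gene: ", miss2[1])
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ident <- vapply(seq_len(nrow(sel)), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      s1[[sel$gene_a[i]]], s2[[sel$gene_b[i]]], type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    100 * Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::pattern(aln)))
  }, numeric(1))
  cls <- ifelse(ident >= 100 - 1e-9, "identical",
                ifelse(ident >= similar_threshold, "similar", "diverged"))
  out <- data.frame(gene_h1 = sel$gene_a, gene_h2 = sel$gene_b,
                    block_id = sel$block_id, identity_pct = ident,
                    class = cls, stringsAsFactors = FALSE)
  out[order(out$gene_h1), , drop = FALSE]
}
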