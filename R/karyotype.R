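# Ancestral-karyotype reconstruction: block-segment graphs yield ancestral
# chromosome groups, extant chromosomes are painted by group, and the
# fusion/fission history is recovered by event accounting over the painting.

.block_segments <- function(sb) {
  stopifnot(inherits(sb, "synteny_blocks"))
  b <- sb$blocks
  if (!nrow(b)) return(NULL)
  blk <- paste0(sb$genome_a, "-", sb$genome_b, "-", b$block_id)
  rbind(
    data.frame(node = paste0(blk, "/a"), block = blk,
               genome = sb$genome_a, chrom = b$chrom_a,
               lo = b$lo_a, hi = b$hi_a, stringsAsFactors = FALSE),
    data.frame(node = paste0(blk, "/b"), block = blk,
               genome = sb$genome_b, chrom = b$chrom_b,
               lo = b$lo_b, hi = b$hi_b, stringsAsFactors = FALSE)
  )
}

# Merge components separated only by lineage-specific fission/fusion noise.
# Two components are joined when their atoms are immediate neighbours on
# more than half of the chromosome copies carrying them: an ancestral
# continuity broken by one lineage's fission stays adjacent in most copies,
# whereas a fusion junction is adjacent only in the fused copies.
.merge_majority_adjacent <- function(comp, bps, comp_genes,
                                     min_component_genes) {
  atoms <- names(comp)
  parts <- do.call(rbind, strsplit(atoms, "\r", fixed = TRUE))
  at <- data.frame(atom = atoms, key = paste(parts[, 1], parts[, 2],
                                             sep = "\r"),
                   idx = as.integer(parts[, 3]), comp = unname(comp),
                   stringsAsFactors = FALSE)
  # tiny spurious components must not vote or act as bridges
  big <- as.integer(names(comp_genes)[comp_genes >= min_component_genes])
  at <- at[at$comp %in% big, , drop = FALSE]
  if (!nrow(at)) return(comp)
  parent <- seq_len(max(comp))
  find <- function(x) {
    x <- as.integer(x)
    while (parent[x] != x) x <- parent[x]
    x
  }
  repeat {
    runs <- list()   # per chromosome: run-length sequence of components
    adj <- list()
    for (key in unique(at$key)) {
      s <- at[at$key == key, , drop = FALSE]
      s <- s[order(s$idx), , drop = FALSE]
      cc <- vapply(s$comp, find, integer(1))
      cc <- cc[c(TRUE, cc[-1] != cc[-length(cc)])]
      runs[[key]] <- cc
      if (length(cc) > 1) {
        # one junction joins two components at most once per chromosome
        pairs <- unique(vapply(seq_len(length(cc) - 1), function(k)
          paste(sort(c(cc[k], cc[k + 1])), collapse = "-"), character(1)))
        for (pair in pairs)
          adj[[pair]] <- (adj[[pair]] %||% 0L) + 1L
      }
    }
    all_runs <- unlist(runs)
    n_copies <- table(all_runs)   # chromosome copies carrying each component
    merged_any <- FALSE
    for (pair in names(adj)) {
      pq <- as.integer(strsplit(pair, "-", fixed = TRUE)[[1]])
      if (find(pq[1]) == find(pq[2])) next
      m <- min(n_copies[as.character(pq[1])], n_copies[as.character(pq[2])])
      if (adj[[pair]] > m / 2) {
        parent[find(pq[2])] <- find(pq[1])
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  out <- vapply(comp, find, integer(1))
  names(out) <- names(comp)
  out
}

#' Infer ancestral chromosome groups from synteny blocks
#'
#' Formalises the dotplot colour-block reading as a graph problem on a
#' common segmentation. The rank interval of every block side is split at
#' the union of all block boundaries on its chromosome, giving atomic
#' intervals; every chained anchor then joins the atomic interval holding
#' its gene on one side to the one holding its partner on the other side.
#' Connected components of this anchor graph gather all chromosome segments
#' descending from one ancestral chromosome, even when a post-WGD sibling
#' block runs across a fusion junction (the junction is a boundary of some
#' other block, so the spanning block is cut there and its two parts stay in
#' their own components). Components carrying at least
#' `min_component_genes` distinct genes become groups ("colours"), sorted by
#' gene count and labelled `G1`, `G2`, ...
#'
#' @param block_sets A `synteny_blocks` object or a list of them; include the
#'   cross-genome comparison and, if available, the within-genome
#'   self-comparisons.
#' @param min_component_genes Minimum distinct genes for a reported group.
#' @return An `ancestral_groups` object: `groups` (group_id, n_genes),
#'   `segments` (group_id, genome, chrom, lo, hi) and `gene_map`
#'   (genome, gene_id, chrom, rank, group_id).
#' @export
infer_ancestral_groups <- function(block_sets, min_component_genes = 30) {
  if (inherits(block_sets, "synteny_blocks")) block_sets <- list(block_sets)
  segs <- do.call(rbind, lapply(block_sets, .block_segments))
  if (is.null(segs) || !nrow(segs)) stop("block set is empty")
  anch <- do.call(rbind, lapply(block_sets, function(sb) {
    if (!nrow(sb$anchors)) return(NULL)
    a <- sb$anchors
    data.frame(genome_a = sb$genome_a, genome_b = sb$genome_b,
               gene_a = a$gene_a, gene_b = a$gene_b,
               chrom_a = a$chrom_a, chrom_b = a$chrom_b,
               rank_a = a$rank_a, rank_b = a$rank_b,
               stringsAsFactors = FALSE)
  }))
  # common segmentation: breakpoints per (genome, chromosome)
  segs$key <- paste(segs$genome, segs$chrom, sep = "\r")
  bps <- lapply(split(segs, segs$key),
                function(s) sort(unique(c(s$lo, s$hi))))
  atom_id <- function(genome, chrom, rank) {
    key <- paste(genome, chrom, sep = "\r")
    idx <- vapply(seq_along(rank), function(i)
      findInterval(rank[i], bps[[key[i]]]), integer(1))
    paste(key, idx, sep = "\r")
  }
  a_atom <- atom_id(anch$genome_a, anch$chrom_a, anch$rank_a)
  b_atom <- atom_id(anch$genome_b, anch$chrom_b, anch$rank_b)
  edges <- unique(data.frame(from = a_atom, to = b_atom,
                             stringsAsFactors = FALSE))
  verts <- unique(c(a_atom, b_atom))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  comp <- igraph::components(g)$membership
  gene_rows <- unique(rbind(
    data.frame(genome = anch$genome_a, gene = anch$gene_a,
               chrom = anch$chrom_a, rank = anch$rank_a, atom = a_atom,
               stringsAsFactors = FALSE),
    data.frame(genome = anch$genome_b, gene = anch$gene_b,
               chrom = anch$chrom_b, rank = anch$rank_b, atom = b_atom,
               stringsAsFactors = FALSE)))
  pre_sizes <- vapply(
    split(paste(gene_rows$genome, gene_rows$gene), comp[gene_rows$atom]),
    function(x) length(unique(x)), integer(1))
  comp <- .merge_majority_adjacent(comp, bps, pre_sizes,
                                   min_component_genes)
  gene_rows$component <- comp[gene_rows$atom]
  n_genes <- vapply(split(paste(gene_rows$genome, gene_rows$gene),
                          gene_rows$component),
                    function(x) length(unique(x)), integer(1))
  keep <- names(n_genes)[n_genes >= min_component_genes]
  keep <- keep[order(-n_genes[keep], as.integer(keep))]
  if (!length(keep)) stop("no component reaches min_component_genes")
  gid <- setNames(sprintf("G%d", seq_along(keep)), keep)
  gene_rows <- gene_rows[as.character(gene_rows$component) %in% keep, ,
                         drop = FALSE]
  gene_rows$group_id <- gid[as.character(gene_rows$component)]
  # a gene rank lies in exactly one atom, so the gene map is unambiguous
  gm <- unique(gene_rows[, c("genome", "gene", "chrom", "rank", "group_id")])
  names(gm)[names(gm) == "gene"] <- "gene_id"
  # group segments: contiguous runs of same-group atoms per chromosome
  atom_tab <- unique(gene_rows[, c("atom", "genome", "chrom", "group_id")])
  seg_list <- list()
  for (r in seq_len(nrow(atom_tab))) {
    key <- paste(atom_tab$genome[r], atom_tab$chrom[r], sep = "\r")
    idx <- as.integer(strsplit(atom_tab$atom[r], "\r", fixed = TRUE)[[1]][3])
    b <- bps[[key]]
    seg_list[[r]] <- data.frame(
      group_id = atom_tab$group_id[r], genome = atom_tab$genome[r],
      chrom = atom_tab$chrom[r], lo = b[idx], hi = b[idx + 1L],
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[order(segments$genome, segments$chrom, segments$lo), ]
  merged <- list()
  for (key in unique(paste(segments$genome, segments$chrom, sep = "\r"))) {
    s <- segments[paste(segments$genome, segments$chrom, sep = "\r") == key, ]
    cur <- s[1, ]
    for (r in seq_len(nrow(s))[-1]) {
      if (s$group_id[r] == cur$group_id && s$lo[r] <= cur$hi) {
        cur$hi <- max(cur$hi, s$hi[r])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- s[r, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  segments <- do.call(rbind, merged)
  rownames(segments) <- NULL
  groups <- data.frame(group_id = unname(gid),
                       n_genes = as.integer(n_genes[keep]))
  structure(
    list(groups = groups, segments = segments,
         gene_map = gm[order(gm$genome, gm$chrom, gm$rank), ]),
    class = "ancestral_groups"
  )
}

#' @export
print.ancestral_groups <- function(x, ...) {
  cat(sprintf("ancestral_groups: %d groups over %d segments\n",
              nrow(x$groups), nrow(x$segments)))
  print(x$groups)
  invisible(x)
}

#' Paint a genome's chromosomes by ancestral group
#'
#' Assigns each gene its ancestral group through the group gene map, merges
#' consecutive runs of the same group (genes without assignment do not break
#' a run), and keeps runs with at least `min_segment` assigned genes.
#'
#' @param genome A `sim_genome` (or gene table with `gene_id`, `chrom`,
#'   `start`) to paint.
#' @param groups An `ancestral_groups` object.
#' @param min_segment Minimum assigned genes per painted segment.
#' @return A `chromosome_painting` object: `segments` (chrom, lo, hi,
#'   group_id, n_genes; rank interval `[lo, hi)`), `coverage` (fraction of
#'   genes painted) and `genome_id`.
#' @export
paint_chromosomes <- function(genome, groups, min_segment = 10) {
  stopifnot(inherits(groups, "ancestral_groups"))
  tab <- .as_gene_table(genome)
  gm <- groups$gene_map[groups$gene_map$genome ==
                          attr(tab, "genome_id"), , drop = FALSE]
  if (!nrow(gm))
    stop("group gene map carries no genes for genome '",
         attr(tab, "genome_id"), "'")
  tab$group_id <- gm$group_id[match(tab$gene_id, gm$gene_id)]
  seg_list <- list()
  for (ch in unique(tab$chrom)) {
    s <- tab[tab$chrom == ch, , drop = FALSE]
    s <- s[order(s$rank), , drop = FALSE]
    known <- which(!is.na(s$group_id))
    if (!length(known)) next
    grp <- s$group_id[known]
    run_start <- c(1L, which(grp[-1] != grp[-length(grp)]) + 1L)
    run_end <- c(run_start[-1] - 1L, length(grp))
    for (k in seq_along(run_start)) {
      idx <- known[run_start[k]:run_end[k]]
      if (length(idx) < min_segment) next
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        chrom = ch, lo = s$rank[idx[1]], hi = s$rank[idx[length(idx)]] + 1L,
        group_id = grp[run_start[k]], n_genes = length(idx),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(chrom = character(0), lo = integer(0), hi = integer(0),
               group_id = character(0), n_genes = integer(0))
  segments <- segments[order(segments$chrom, segments$lo), , drop = FALSE]
  rownames(segments) <- NULL
  structure(
    list(segments = segments,
         coverage = sum(!is.na(tab$group_id)) / nrow(tab),
         genome_id = attr(tab, "genome_id"),
         n_chromosomes = length(unique(tab$chrom))),
    class = "chromosome_painting"
  )
}

#' @export
print.chromosome_painting <- function(x, ...) {
  cat(sprintf(
    "chromosome_painting of '%s': %d segments on %d chromosomes (coverage %.2f)\n",
    x$genome_id, nrow(x$segments), length(unique(x$segments$chrom)),
    x$coverage))
  invisible(x)
}

#' Chromosome-count accounting over an event scenario
#'
#' Applies, in order, the chromosome-count algebra of a karyotype scenario:
#' a whole-genome duplication doubles the count, each fission adds one, each
#' fusion removes one. A scenario is a list of epochs; each epoch is either
#' `"wgd"` or a `c(fissions, fusions)` pair.
#'
#' @param n0 Starting chromosome count (>= 1).
#' @param scenario List of epochs, e.g.
#'   `list("wgd", c(fissions = 2, fusions = 5))`.
#' @return An `event_accounting` object with the step-by-step trajectory and
#'   `n_final`.
#' @examples
#' event_accounting(6, list("wgd"))$n_final                    # 12
#' event_accounting(6, list("wgd", c(2, 5)))$n_final           # 9
#' event_accounting(9, list("wgd", c(1, 3)))$n_final           # 16
#' @export
event_accounting <- function(n0, scenario) {
  if (!is.numeric(n0) || n0 < 1) stop("n0 must be >= 1")
  n <- as.integer(n0)
  steps <- data.frame(step = "start", n = n, stringsAsFactors = FALSE)
  for (ep in scenario) {
    if (identical(ep, "wgd") || identical(ep, "WGD")) {
      n <- 2L * n
      steps <- rbind(steps, data.frame(step = "wgd", n = n))
    } else {
      fi <- as.integer(ep[[1]])
      fu <- as.integer(ep[[2]])
      if (fi < 0 || fu < 0) stop("fission/fusion counts must be >= 0")
      n <- n + fi - fu
      steps <- rbind(steps,
                     data.frame(step = sprintf("+%dfi-%dfu", fi, fu), n = n))
    }
    if (n < 1) stop("infeasible scenario: chromosome count fell below 1")
  }
  structure(list(n0 = as.integer(n0), steps = steps, n_final = n),
            class = "event_accounting")
}

#' @export
print.event_accounting <- function(x, ...) {
  cat(sprintf("event_accounting: n0 = %d -> n_final = %d\n", x$n0, x$n_final))
  print(x$steps)
  invisible(x)
}

#' Infer the fusion/fission scenario behind a painting
#'
#' Greedy parsimony over a chromosome painting. Every junction between
#' adjacent segments of different groups witnesses a fusion. With two WGD
#' rounds, a fusion that happened before the last WGD leaves two copies of
#' its junction (same unordered group pair, similar flanking segment sizes);
#' such duplicated junctions are paired and counted once as early fusions,
#' unpaired junctions count as late fusions. Fission totals then follow from
#' the chromosome-count algebra, placing fissions as early as possible
#' (early events change the final count twice as much, so this is the
#' minimal-event solution); per-epoch placement is reported but inherently
#' ambiguous.
#'
#' @param painting A `chromosome_painting`.
#' @param n_wgd Number of WGD rounds (1 or 2).
#' @param n_ancestral Ancestral chromosome count.
#' @param size_tol Relative tolerance when matching flanking-segment sizes of
#'   duplicated junctions.
#' @return A `karyotype_scenario` estimate: totals, per-epoch counts, the
#'   junction table, and expected/observed chromosome counts.
#' @export
infer_event_scenario <- function(painting, n_wgd, n_ancestral,
                                 size_tol = 0.3) {
  stopifnot(inherits(painting, "chromosome_painting"), n_wgd %in% c(1L, 2L))
  seg <- painting$segments
  if (nrow(seg) && any(duplicated(paste(seg$chrom, seg$lo))))
    stop("inconsistent painting: duplicated segment starts")
  # junctions between adjacent different-group segments
  jn <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) < 2) next
    for (k in seq_len(nrow(s) - 1)) {
      if (s$group_id[k] == s$group_id[k + 1]) next
      gp <- sort(c(s$group_id[k], s$group_id[k + 1]))
      jn[[length(jn) + 1L]] <- data.frame(
        chrom = ch, group_1 = gp[1], group_2 = gp[2],
        size_1 = s$n_genes[k], size_2 = s$n_genes[k + 1],
        stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(jn)) do.call(rbind, jn) else
    data.frame(chrom = character(0), group_1 = character(0),
               group_2 = character(0), size_1 = integer(0),
               size_2 = integer(0))
  n_obs <- painting$n_chromosomes
  expected <- n_ancestral * 2^n_wgd
  if (n_wgd == 1L) {
    fu <- nrow(junctions)
    fi <- max(0L, n_obs - 2L * n_ancestral + fu)
    per_epoch <- data.frame(epoch = 1L, fissions = fi, fusions = fu)
  } else {
    # pair duplicated junctions (same group pair, similar flank sizes)
    early <- 0L
    if (nrow(junctions)) {
      junctions$pairkey <- paste(junctions$group_1, junctions$group_2)
      junctions$epoch <- 2L
      for (pk in unique(junctions$pairkey)) {
        idx <- which(junctions$pairkey == pk)
        while (length(idx) >= 2) {
          i <- idx[1]
          match_j <- NA_integer_
          for (j in idx[-1]) {
            ok1 <- abs(junctions$size_1[i] - junctions$size_1[j]) <=
              size_tol * pmax(junctions$size_1[i], junctions$size_1[j])
            ok2 <- abs(junctions$size_2[i] - junctions$size_2[j]) <=
              size_tol * pmax(junctions$size_2[i], junctions$size_2[j])
            if (ok1 && ok2) { match_j <- j; break }
          }
          if (is.na(match_j)) { idx <- idx[-1]; next }
          junctions$epoch[c(i, match_j)] <- 1L
          early <- early + 1L
          idx <- setdiff(idx, c(i, match_j))
        }
      }
    }
    fu1 <- early
    fu2 <- nrow(junctions) - 2L * early
    # chromosome-count algebra: n_final = 4 n0 + 2 fi1 - 2 fu1 + fi2 - fu2
    r <- n_obs - 4L * n_ancestral + 2L * fu1 + fu2
    if (r < 0) r <- 0L
    fi1 <- r %/% 2L
    fi2 <- r %% 2L
    fu <- fu1 + fu2
    fi <- fi1 + fi2
    per_epoch <- data.frame(epoch = c(1L, 2L), fissions = c(fi1, fi2),
                            fusions = c(fu1, fu2))
  }
  structure(
    list(n0 = n_ancestral, n_wgd = n_wgd, fusions = fu, fissions = fi,
         per_epoch = per_epoch, junctions = junctions,
         n_expected = expected, n_observed = n_obs,
         note = paste("per-epoch placement is ambiguous; totals are greedy",
                      "parsimony, fissions placed as early as possible")),
    class = "karyotype_scenario"
  )
}

#' @export
print.karyotype_scenario <- function(x, ...) {
  cat(sprintf(
    "karyotype_scenario: n0 = %d, %d WGD; %d fusions, %d fissions (n %d -> %d)\n",
    x$n0, x$n_wgd, x$fusions, x$fissions, x$n_expected, x$n_observed))
  invisible(x)
}

#' Project ancestral-group composition onto a third genome
#'
#' Transfers group labels from a painted reference genome across
#' reference-vs-target synteny blocks: each block takes the group its
#' reference side overlaps most, each target gene rank takes the group of
#' the highest-scoring block covering it, and per-chromosome group fractions
#' are reported. Chromosomes untouched by any block are reported unassigned.
#'
#' @param painting `chromosome_painting` of the reference genome.
#' @param blocks `synteny_blocks` with the reference genome as side A.
#' @param target_extent Optional named vector of target chromosome gene
#'   counts (defaults to the extent seen in blocks).
#' @return List with `segments` (target chrom, lo, hi, group_id),
#'   `fractions` (target chrom, group_id, fraction) and `unassigned`
#'   fraction per chromosome.
#' @export
project_composition <- function(painting, blocks, target_extent = NULL) {
  stopifnot(inherits(painting, "chromosome_painting"),
            inherits(blocks, "synteny_blocks"))
  b <- blocks$blocks
  pseg <- painting$segments
  # majority group of the reference interval of each block
  block_group <- vapply(seq_len(nrow(b)), function(i) {
    s <- pseg[pseg$chrom == b$chrom_a[i], , drop = FALSE]
    if (!nrow(s)) return(NA_character_)
    ov <- pmin(s$hi, b$hi_a[i]) - pmax(s$lo, b$lo_a[i])
    if (all(ov <= 0)) return(NA_character_)
    best <- which(ov == max(ov))
    s$group_id[best[order(as.integer(sub("^G", "", s$group_id[best])))[1]]]
  }, character(1))
  chroms <- unique(b$chrom_b)
  ext <- target_extent %||%
    setNames(vapply(chroms, function(ch) max(b$hi_b[b$chrom_b == ch]),
                    numeric(1)), chroms)
  seg_out <- list()
  frac_out <- list()
  for (ch in names(ext)) {
    len <- as.integer(ext[[ch]])
    lab <- rep(NA_character_, len)
    score <- rep(0L, len)
    rows <- which(b$chrom_b == ch & !is.na(block_group))
    for (i in rows[order(b$n_anchors[rows])]) {
      rr <- (b$lo_b[i] + 1L):b$hi_b[i]
      upd <- b$n_anchors[i] >= score[rr]
      lab[rr[upd]] <- block_group[i]
      score[rr[upd]] <- b$n_anchors[i]
    }
    known <- which(!is.na(lab))
    if (length(known)) {
      grp <- lab[known]
      rs <- c(1L, which(grp[-1] != grp[-length(grp)]) + 1L)
      re <- c(rs[-1] - 1L, length(grp))
      for (k in seq_along(rs)) {
        seg_out[[length(seg_out) + 1L]] <- data.frame(
          chrom = ch, lo = known[rs[k]] - 1L, hi = known[re[k]],
          group_id = grp[rs[k]], stringsAsFactors = FALSE)
      }
    }
    tabg <- table(lab[!is.na(lab)])
    if (length(tabg)) {
      frac_out[[length(frac_out) + 1L]] <- data.frame(
        chrom = ch, group_id = names(tabg),
        fraction = as.numeric(tabg) / len, stringsAsFactors = FALSE)
    }
    frac_out[[length(frac_out) + 1L]] <- data.frame(
      chrom = ch, group_id = "unassigned",
      fraction = sum(is.na(lab)) / len, stringsAsFactors = FALSE)
  }
  segments <- if (length(seg_out)) do.call(rbind, seg_out) else
    data.frame(chrom = character(0), lo = integer(0), hi = integer(0),
               group_id = character(0))
  fractions <- do.call(rbind, frac_out)
  list(segments = segments[order(segments$chrom, segments$lo), , drop = FALSE],
       fractions = fractions,
       unassigned = setNames(
         fractions$fraction[fractions$group_id == "unassigned"],
         fractions$chrom[fractions$group_id == "unassigned"]))
}
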