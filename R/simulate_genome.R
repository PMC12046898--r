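# Genome-evolution simulator: ordered genes on chromosomes, evolved through
# whole-genome duplications, fusions, fissions, inversions and fractionation,
# with ground-truth homology carried along via stable ancestral gene labels.

.GENE_GAP <- 1000L

#' Create an unevolved ancestral genome
#'
#' Builds a genome of `n_chrom` chromosomes carrying `genes_per_chrom` ordered,
#' non-overlapping genes each. Every gene's `ancestral_id` equals its
#' `gene_id`, so homology of all later descendants can be traced exactly.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param genes_per_chrom Genes per chromosome (>= 1).
#' @param seed Optional integer seed; given the same seed the genome is
#'   reproduced exactly.
#' @return A `sim_genome` object: a list with `genome_id`, a `genes`
#'   data frame (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `ancestral_id`, `copy_label`, `rank`; coordinates 0-based half-open)
#'   and `chrom_order`.
#' @examples
#' anc <- make_ancestor(6, 200, seed = 1)
#' n_genes(anc)
#' @export
make_ancestor <- function(n_chrom, genes_per_chrom, seed = NULL) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1 || n_chrom < 1)
    stop("n_chrom must be a single integer >= 1")
  if (!is.numeric(genes_per_chrom) || length(genes_per_chrom) != 1 ||
      genes_per_chrom < 1)
    stop("genes_per_chrom must be a single integer >= 1")
  n_chrom <- as.integer(n_chrom)
  genes_per_chrom <- as.integer(genes_per_chrom)
  build <- function() {
    n <- n_chrom * genes_per_chrom
    ids <- sprintf("g%05d", seq_len(n))
    chrom <- rep(sprintf("c%d", seq_len(n_chrom)), each = genes_per_chrom)
    len <- sample(seq(900L, 6000L, by = 3L), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- data.frame(
      gene_id = ids, chrom = chrom, start = 0L, end = len,
      strand = strand, ancestral_id = ids, copy_label = "0",
      rank = 0L, stringsAsFactors = FALSE
    )
    new_sim_genome("ancestor", genes, sprintf("c%d", seq_len(n_chrom)))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

new_sim_genome <- function(genome_id, genes, chrom_order) {
  g <- structure(
    list(genome_id = genome_id, genes = genes, chrom_order = chrom_order),
    class = "sim_genome"
  )
  relayout_genome(g)
}

# Reassign dense ranks and non-overlapping coordinates, preserving each
# gene's length and the current within-chromosome row order.
relayout_genome <- function(genome) {
  genes <- genome$genes
  genes$chrom <- as.character(genes$chrom)
  keep <- genome$chrom_order[genome$chrom_order %in% genes$chrom]
  genes <- genes[order(match(genes$chrom, keep)), , drop = FALSE]
  len <- genes$end - genes$start
  rank <- unlist(lapply(split(seq_len(nrow(genes)), factor(genes$chrom, keep)),
                        function(i) seq_along(i) - 1L), use.names = FALSE)
  genes$rank <- rank
  start <- unlist(lapply(split(len, factor(genes$chrom, keep)), function(l) {
    cumsum(c(0L, head(l, -1L) + .GENE_GAP))
  }), use.names = FALSE)
  genes$start <- as.integer(start)
  genes$end <- as.integer(start + len)
  rownames(genes) <- NULL
  genome$genes <- genes
  genome$chrom_order <- keep
  genome
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome '%s': %d chromosomes, %d genes\n",
              x$genome_id, length(x$chrom_order), nrow(x$genes)))
  invisible(x)
}

#' Number of genes / chromosomes in a simulated genome
#' @param genome A `sim_genome`.
#' @return Integer count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

#' @rdname n_genes
#' @export
n_chromosomes <- function(genome) length(genome$chrom_order)

# --- event constructors ------------------------------------------------------

#' Karyotype-evolution events
#'
#' Constructors for the events understood by [apply_event()]:
#' whole-genome duplication, chromosome fusion (joining two chromosomes,
#' optionally reversing the second), fission (splitting at a gene-rank
#' breakpoint), inversion of a rank interval, and fractionation (`loss`),
#' which drops gene copies independently at `1 - retention` but never removes
#' the last surviving copy of an ancestral gene.
#'
#' @param chrom_a,chrom_b,chrom Chromosome ids as found in the genome.
#' @param orientation `"+"` appends `chrom_b` as is; `"-"` reverses it first.
#' @param breakpoint Gene rank at which to split: ranks `< breakpoint` stay on
#'   the first product.
#' @param lo,hi Inclusive 0-based gene-rank interval to invert.
#' @param retention Per-gene-copy retention probability in `[0, 1]`.
#' @return A list describing the event, class `sim_event`.
#' @export
wgd_event <- function() structure(list(type = "wgd"), class = "sim_event")

#' @rdname wgd_event
#' @export
wgt_event <- function() structure(list(type = "wgt"), class = "sim_event")

#' @rdname wgd_event
#' @export
fusion_event <- function(chrom_a, chrom_b, orientation = "+") {
  stopifnot(orientation %in% c("+", "-"))
  structure(list(type = "fusion", chrom_a = chrom_a, chrom_b = chrom_b,
                 orientation = orientation), class = "sim_event")
}

#' @rdname wgd_event
#' @export
fission_event <- function(chrom, breakpoint) {
  structure(list(type = "fission", chrom = chrom,
                 breakpoint = as.integer(breakpoint)), class = "sim_event")
}

#' @rdname wgd_event
#' @export
inversion_event <- function(chrom, lo, hi) {
  stopifnot(lo <= hi)
  structure(list(type = "inversion", chrom = chrom, lo = as.integer(lo),
                 hi = as.integer(hi)), class = "sim_event")
}

#' @rdname wgd_event
#' @export
loss_event <- function(retention) {
  if (!is.numeric(retention) || retention < 0 || retention > 1)
    stop("retention must be in [0, 1]")
  structure(list(type = "loss", retention = retention), class = "sim_event")
}

#' Bundle events into an evolution scenario
#' @param events List of `sim_event` objects, applied in order.
#' @param seed Integer seed controlling all randomness while the scenario runs.
#' @return An `evolution_scenario` object.
#' @export
evolution_scenario <- function(events, seed = 20250502L) {
  stopifnot(is.list(events))
  structure(list(events = events, seed = as.integer(seed)),
            class = "evolution_scenario")
}

# --- event application -------------------------------------------------------

.gene_id_for <- function(ancestral_id, copy_label) {
  ifelse(copy_label == "0", ancestral_id,
         paste0(ancestral_id, "_", copy_label))
}

.check_chrom <- function(genome, chrom) {
  if (!chrom %in% genome$chrom_order)
    stop(sprintf("chromosome '%s' not found in genome '%s'",
                 chrom, genome$genome_id))
}

#' Apply one evolutionary event to a genome
#'
#' WGD duplicates every chromosome (gene copies receive extended copy
#' labels and fresh gene ids); fusion concatenates two chromosomes; fission
#' splits one at a gene-rank breakpoint; inversion reverses gene order and
#' flips strands inside a rank interval; loss drops gene copies independently
#' while guaranteeing every ancestral gene keeps at least one copy.
#'
#' @param genome A `sim_genome`.
#' @param event A `sim_event` from one of the event constructors.
#' @param seed Optional seed for the stochastic events (`loss`).
#' @return The evolved `sim_genome`.
#' @export
apply_event <- function(genome, event, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(event, "sim_event"))
  run <- function() switch(event$type,
    wgd = .apply_wgd(genome),
    wgt = .apply_wgd(genome, 3L),
    fusion = .apply_fusion(genome, event),
    fission = .apply_fission(genome, event),
    inversion = .apply_inversion(genome, event),
    loss = .apply_loss(genome, event),
    stop("unknown event type: ", event$type)
  )
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.apply_wgd <- function(genome, k = 2L) {
  genes <- genome$genes
  copies <- lapply(seq_len(k), function(i) {
    g <- genes
    g$copy_label <- paste0(genes$copy_label, ".", i)
    g$chrom <- paste0(genes$chrom, ".", i)
    g$gene_id <- .gene_id_for(g$ancestral_id, g$copy_label)
    g
  })
  genome$genes <- do.call(rbind, copies)
  genome$chrom_order <- unlist(lapply(seq_len(k), function(i)
    paste0(genome$chrom_order, ".", i)))
  relayout_genome(genome)
}

.apply_fusion <- function(genome, event) {
  .check_chrom(genome, event$chrom_a)
  .check_chrom(genome, event$chrom_b)
  if (event$chrom_a == event$chrom_b) stop("cannot fuse a chromosome to itself")
  genes <- genome$genes
  new_id <- paste0(event$chrom_a, "+", event$chrom_b)
  ia <- which(genes$chrom == event$chrom_a)
  ib <- which(genes$chrom == event$chrom_b)
  if (event$orientation == "-") {
    ib <- rev(ib)
    genes$strand[ib] <- ifelse(genes$strand[ib] == "+", "-", "+")
  }
  keep <- setdiff(seq_len(nrow(genes)), c(ia, ib))
  genes <- rbind(genes[keep, , drop = FALSE], genes[c(ia, ib), , drop = FALSE])
  genes$chrom[genes$chrom %in% c(event$chrom_a, event$chrom_b)] <- new_id
  pos <- match(event$chrom_a, genome$chrom_order)
  ord <- setdiff(genome$chrom_order, c(event$chrom_a, event$chrom_b))
  ord <- append(ord, new_id, after = min(pos, length(ord) + 1L) - 1L)
  genome$genes <- genes
  genome$chrom_order <- ord
  relayout_genome(genome)
}

.apply_fission <- function(genome, event) {
  .check_chrom(genome, event$chrom)
  genes <- genome$genes
  k <- sum(genes$chrom == event$chrom)
  if (event$breakpoint < 1L || event$breakpoint > k - 1L)
    stop(sprintf("fission breakpoint %d out of range 1..%d on '%s'",
                 event$breakpoint, k - 1L, event$chrom))
  on_chr <- genes$chrom == event$chrom
  left <- on_chr & genes$rank < event$breakpoint
  right <- on_chr & !left
  id_a <- paste0(event$chrom, "a")
  id_b <- paste0(event$chrom, "b")
  genes$chrom[left] <- id_a
  genes$chrom[right] <- id_b
  pos <- match(event$chrom, genome$chrom_order)
  ord <- append(setdiff(genome$chrom_order, event$chrom), c(id_a, id_b),
                after = pos - 1L)
  genome$genes <- genes
  genome$chrom_order <- ord
  relayout_genome(genome)
}

.apply_inversion <- function(genome, event) {
  .check_chrom(genome, event$chrom)
  genes <- genome$genes
  idx <- which(genes$chrom == event$chrom)
  k <- length(idx)
  if (event$lo < 0L || event$hi > k - 1L)
    stop(sprintf("inversion interval [%d, %d] out of range on '%s' (%d genes)",
                 event$lo, event$hi, event$chrom, k))
  sel <- idx[genes$rank[idx] >= event$lo & genes$rank[idx] <= event$hi]
  ord <- seq_len(nrow(genes))
  ord[sel] <- rev(sel)
  genes <- genes[ord, , drop = FALSE]
  flip <- genes$gene_id %in% genome$genes$gene_id[sel]
  genes$strand[flip] <- ifelse(genes$strand[flip] == "+", "-", "+")
  genome$genes <- genes
  relayout_genome(genome)
}

.apply_loss <- function(genome, event) {
  genes <- genome$genes
  drop <- runif(nrow(genes)) >= event$retention
  # last-copy guard: an ancestral gene losing all copies keeps one at random
  lost_all <- tapply(drop, genes$ancestral_id, all)
  for (aid in names(lost_all)[lost_all]) {
    cand <- which(genes$ancestral_id == aid)
    drop[cand[sample.int(length(cand), 1L)]] <- FALSE
  }
  # a chromosome never disappears by fractionation: keep one gene on each
  chr_lost <- tapply(drop, genes$chrom, all)
  for (ch in names(chr_lost)[chr_lost]) {
    cand <- which(genes$chrom == ch)
    drop[cand[sample.int(length(cand), 1L)]] <- FALSE
  }
  genome$genes <- genes[!drop, , drop = FALSE]
  genome$chrom_order <-
    genome$chrom_order[genome$chrom_order %in% genome$genes$chrom]
  relayout_genome(genome)
}

#' Apply a whole scenario of events
#'
#' Events run in order; event `i` uses seed `scenario$seed + i` so the run is
#' reproducible end to end.
#'
#' @param genome A `sim_genome`.
#' @param scenario An [evolution_scenario()].
#' @return The evolved `sim_genome`.
#' @export
apply_scenario <- function(genome, scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  for (i in seq_along(scenario$events)) {
    genome <- apply_event(genome, scenario$events[[i]],
                          seed = scenario$seed + i)
  }
  genome
}

# --- lineages and truth homology --------------------------------------------

#' Evolve two lineages from one ancestor and record homology truth
#'
#' Runs `scenario_a` and `scenario_b` independently on copies of the ancestor,
#' prefixes gene ids with the genome id (so the two gene universes are
#' disjoint), and tabulates the full homology truth: all cross-genome and
#' within-genome gene pairs sharing an ancestral gene, plus per-ancestral-id
#' copy counts.
#'
#' @param ancestor A `sim_genome`, typically from [make_ancestor()].
#' @param scenario_a,scenario_b [evolution_scenario()] objects.
#' @param ids Character vector of length 2: genome ids (default `c("A","B")`).
#' @return List with `genome_a`, `genome_b` and `truth`
#'   (class `truth_homology`: `cross`, `within_a`, `within_b`, `copy_counts`).
#' @export
evolve_lineages <- function(ancestor, scenario_a, scenario_b,
                            ids = c("A", "B")) {
  ga <- apply_scenario(ancestor, scenario_a)
  gb <- apply_scenario(ancestor, scenario_b)
  ga$genome_id <- ids[1]
  gb$genome_id <- ids[2]
  ga$genes$gene_id <- paste0(ids[1], "_", ga$genes$gene_id)
  gb$genes$gene_id <- paste0(ids[2], "_", gb$genes$gene_id)
  truth <- truth_homology(ga, gb)
  list(genome_a = ga, genome_b = gb, truth = truth)
}

#' Homology ground truth for a pair of simulated genomes
#' @param genome_a,genome_b `sim_genome` objects descended from one ancestor.
#' @return A `truth_homology` object; `cross` lists every between-genome pair
#'   sharing an `ancestral_id`, `within_a`/`within_b` the within-genome
#'   paralog pairs, `copy_counts` the per-ancestral-id copy numbers.
#' @export
truth_homology <- function(genome_a, genome_b) {
  a <- genome_a$genes[, c("gene_id", "ancestral_id")]
  b <- genome_b$genes[, c("gene_id", "ancestral_id")]
  cross <- merge(a, b, by = "ancestral_id", suffixes = c("_a", "_b"))
  cross <- cross[order(cross$gene_id_a, cross$gene_id_b),
                 c("gene_id_a", "gene_id_b", "ancestral_id")]
  names(cross) <- c("gene_a", "gene_b", "ancestral_id")
  within <- function(g) {
    m <- merge(g, g, by = "ancestral_id", suffixes = c("_1", "_2"))
    m <- m[m$gene_id_1 < m$gene_id_2,
           c("gene_id_1", "gene_id_2", "ancestral_id")]
    names(m) <- c("gene_a", "gene_b", "ancestral_id")
    m[order(m$gene_a, m$gene_b), , drop = FALSE]
  }
  counts <- merge(
    as.data.frame(table(ancestral_id = a$ancestral_id),
                  responseName = "n_a"),
    as.data.frame(table(ancestral_id = b$ancestral_id),
                  responseName = "n_b"),
    by = "ancestral_id", all = TRUE
  )
  counts$n_a[is.na(counts$n_a)] <- 0L
  counts$n_b[is.na(counts$n_b)] <- 0L
  counts$ancestral_id <- as.character(counts$ancestral_id)
  structure(list(cross = cross, within_a = within(a), within_b = within(b),
                 copy_counts = counts),
            class = "truth_homology")
}

#' @export
print.truth_homology <- function(x, ...) {
  cat(sprintf(
    "truth_homology: %d cross pairs, %d + %d within pairs, %d ancestral ids\n",
    nrow(x$cross), nrow(x$within_a), nrow(x$within_b), nrow(x$copy_counts)))
  invisible(x)
}

# --- scenario builders -------------------------------------------------------

#' Canonical two-WGD palm-like and duckweed-like scenarios
#'
#' `palm_scenario()` encodes the karyotype history inferred for the betel
#' palm: from a six-chromosome ancestor, a first WGD (n = 12), two fissions
#' and five fusions (n = 9), a second WGD (n = 18), then one fission and three
#' fusions (n = 16). `waterweed_scenario()` is the simulator's free-parameter
#' companion lineage, also with two WGDs, ending at n = 20. Both interleave a
#' fractionation (loss) epoch after each WGD, and both pick fusion partners
#' from different ancestral chromosomes so fusion junctions remain visible to
#' downstream painting. Fission breakpoints sit mid-chromosome.
#'
#' @param retention Per-copy retention probability applied after each WGD.
#' @param seed Scenario seed.
#' @return An [evolution_scenario()].
#' @export
palm_scenario <- function(retention = 0.8, seed = 20250502L) {
  ev <- list(
    wgd_event(),
    loss_event(retention),
    # n = 12; two fissions (mid-chromosome) -> 14 pieces
    fission_event("c1.1", 80L),
    fission_event("c2.1", 80L),
    # five fusions joining different ancestral chromosomes -> n = 9
    fusion_event("c1.1a", "c3.1", "+"),
    fusion_event("c1.1b", "c4.1", "-"),
    fusion_event("c2.1a", "c5.1", "+"),
    fusion_event("c2.1b", "c6.1", "-"),
    fusion_event("c3.2", "c5.2", "+"),
    wgd_event(),
    loss_event(retention),
    # n = 18; one fission, three fusions -> n = 16
    fission_event("c4.2.1", 60L),
    fusion_event("c4.2.1a", "c6.2.1", "+"),
    fusion_event("c4.2.1b", "c1.2.1", "-"),
    fusion_event("c6.2.2", "c2.2.2", "+")
  )
  evolution_scenario(ev, seed = seed)
}

#' @rdname palm_scenario
#' @export
waterweed_scenario <- function(retention = 0.8, seed = 20250502L) {
  ev <- list(
    wgd_event(),
    loss_event(retention),
    # n = 12; one fission, two fusions -> n = 11
    fission_event("c3.1", 80L),
    fusion_event("c1.1", "c5.1", "+"),
    fusion_event("c2.2", "c4.1", "-"),
    wgd_event(),
    loss_event(retention),
    # n = 22; two fusions -> n = 20
    fusion_event("c3.1a.1", "c6.2.1", "+"),
    fusion_event("c5.2.2", "c6.2.2", "+")
  )
  evolution_scenario(ev, seed = seed)
}

#' Random feasible scenario generator
#'
#' Draws a random sequence of events that is guaranteed feasible on the given
#' genome (chromosome ids and breakpoints are sampled from the evolving
#' genome). Used to property-test the chromosome-count algebra.
#'
#' @param genome Starting `sim_genome`.
#' @param n_events Number of events to draw.
#' @param p_wgd,p_fission,p_fusion,p_inversion,p_loss Sampling weights.
#' @param seed Integer seed.
#' @return List with `events` and the evolved `genome`.
#' @export
random_scenario <- function(genome, n_events, p_wgd = 0.1, p_fission = 0.25,
                            p_fusion = 0.25, p_inversion = 0.2, p_loss = 0.2,
                            seed = 1L) {
  withr::with_seed(seed, {
    events <- list()
    for (i in seq_len(n_events)) {
      w <- c(wgd = p_wgd, fission = p_fission, fusion = p_fusion,
             inversion = p_inversion, loss = p_loss)
      if (length(genome$chrom_order) < 2) w["fusion"] <- 0
      if (length(genome$chrom_order) > 40) w["wgd"] <- 0
      splittable <- genome$chrom_order[
        tabulate(factor(genome$genes$chrom, genome$chrom_order)) >= 2]
      if (!length(splittable)) w["fission"] <- 0
      type <- sample(names(w), 1L, prob = w)
      ev <- switch(type,
        wgd = wgd_event(),
        fusion = {
          ch <- sample(genome$chrom_order, 2L)
          fusion_event(ch[1], ch[2], sample(c("+", "-"), 1L))
        },
        fission = {
          ch <- sample(splittable, 1L)
          k <- sum(genome$genes$chrom == ch)
          fission_event(ch, sample.int(k - 1L, 1L))
        },
        inversion = {
          ch <- sample(genome$chrom_order, 1L)
          k <- sum(genome$genes$chrom == ch)
          lo <- sample.int(k, 1L) - 1L
          hi <- min(k - 1L, lo + sample.int(max(1L, k %/% 2L), 1L))
          inversion_event(ch, lo, hi)
        },
        loss = loss_event(runif(1, 0.7, 0.98))
      )
      genome <- apply_event(genome, ev, seed = seed + i)
      events[[i]] <- ev
    }
    list(events = events, genome = genome)
  })
}
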