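# Sequence-pair simulators: codon pairs diverged to a target synonymous
# divergence, and LTR pairs diverged for a known time at a known rate.
# Both return the realized divergence counted directly from the mutation log,
# which downstream estimators are tested against.

.BASES <- c("A", "C", "G", "T")

# Codon bookkeeping shared with the Nei-Gojobori estimator: per-codon
# synonymous site fractions and a codon x position x replacement-base map.
# Changes that create a stop codon are possible but nonsynonymous; stop
# codons themselves carry no sites.
codon_tables <- function() {
  if (!is.null(.pk_cache$codon)) return(.pk_cache$codon)
  codons <- names(Biostrings::GENETIC_CODE)
  aa <- unname(Biostrings::GENETIC_CODE)
  n <- length(codons)
  syn_sites <- numeric(n)
  # new_codon[codon, pos, base]: index of codon after substituting base at pos
  new_codon <- array(NA_integer_, dim = c(n, 3, 4))
  is_syn <- array(FALSE, dim = c(n, 3, 4))
  for (i in seq_len(n)) {
    cod <- strsplit(codons[i], "")[[1]]
    for (p in 1:3) {
      for (b in seq_along(.BASES)) {
        if (.BASES[b] == cod[p]) next
        alt <- cod
        alt[p] <- .BASES[b]
        j <- match(paste(alt, collapse = ""), codons)
        new_codon[i, p, b] <- j
        is_syn[i, p, b] <- aa[j] == aa[i] && aa[j] != "*"
      }
    }
    if (aa[i] != "*")
      syn_sites[i] <- sum(is_syn[i, , ]) / 3
  }
  # codon families whose third position is fully fourfold degenerate and
  # whose first/second positions admit no synonymous change: on these codons
  # synonymous evolution is exactly a Jukes-Cantor process on third
  # positions, so the Nei-Gojobori + Jukes-Cantor estimator is consistent
  fourfold <- which(substr(codons, 1, 2) %in%
                      c("GC", "GT", "GG", "CC", "AC", "TC"))
  # third-position synonymous neighbours of the fourfold codons
  syn3 <- matrix(NA_integer_, n, 3)
  for (i in fourfold) {
    nb <- new_codon[i, 3, ]
    syn3[i, ] <- nb[!is.na(nb)]
  }
  .pk_cache$codon <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                          new_codon = new_codon, is_syn = is_syn,
                          sense = which(aa != "*"), fourfold = fourfold,
                          syn3 = syn3)
  .pk_cache$codon
}

#' Simulate a codon-sequence pair at a target synonymous divergence
#'
#' Draws a random stop-free coding sequence and applies synonymous-only
#' single-nucleotide substitutions to a copy until the number of accepted
#' events reaches a Poisson draw with mean `ks_target` times the sequence's
#' Nei-Gojobori synonymous site count. The realized truth is the accepted
#' event count divided by the synonymous sites, i.e. the quantity a
#' synonymous-distance estimator should recover.
#'
#' @param ks_target Synonymous substitutions per synonymous site (>= 0).
#' @param length Sequence length in codons (>= 10).
#' @param alphabet `"fourfold"` (default) draws codons from fully
#'   fourfold-degenerate families, on which the synonymous process is an
#'   exact Jukes-Cantor chain and the target Ks is identifiable;
#'   `"all"` draws from all sense codons (twofold-degenerate sites then
#'   saturate faster than the Jukes-Cantor model assumes, so estimators are
#'   upward-biased at high Ks).
#' @param seed Optional integer seed.
#' @return List with `cds_a`, `cds_b` (character strings), `ks_truth`,
#'   `n_substitutions`, `syn_sites`, and the `mutation_log` data frame.
#' @export
simulate_codon_pair <- function(ks_target, length,
                                alphabet = c("fourfold", "all"),
                                seed = NULL) {
  if (ks_target < 0) stop("ks_target must be >= 0")
  if (length < 10) stop("length must be at least 10 codons")
  alphabet <- match.arg(alphabet)
  tab <- codon_tables()
  pool <- if (alphabet == "fourfold") tab$fourfold else tab$sense
  run <- function() {
    idx <- sample(pool, length, replace = TRUE)
    S <- sum(tab$syn_sites[idx])
    n_sub <- rpois(1L, ks_target * S)
    cur <- idx
    log_pos <- integer(0); log_from <- integer(0); log_to <- integer(0)
    if (alphabet == "fourfold") {
      # on fourfold codons every codon accepts a proposal with the same
      # probability, so accepted events are uniform over codons: draw hit
      # counts multinomially and walk each hit codon through uniform
      # synonymous third-position steps
      hits <- tabulate(sample.int(length, n_sub, replace = TRUE),
                       nbins = length)
      maxk <- if (n_sub > 0) max(hits) else 0L
      for (step in seq_len(maxk)) {
        sel <- which(hits >= step)
        nxt <- tab$syn3[cbind(cur[sel],
                              sample.int(3L, length(sel), replace = TRUE))]
        log_pos <- c(log_pos, sel)
        log_from <- c(log_from, cur[sel])
        log_to <- c(log_to, nxt)
        cur[sel] <- nxt
      }
    } else {
      # general sense codons: sequential rejection sampling (uniform over
      # all possible synonymous single-nucleotide changes of the current
      # sequence state)
      accepted <- 0L
      while (accepted < n_sub) {
        cc <- sample.int(length, 1L)
        pp <- sample.int(3L, 1L)
        bb <- sample.int(4L, 1L)
        nxt <- tab$new_codon[cur[cc], pp, bb]
        if (!is.na(nxt) && tab$is_syn[cur[cc], pp, bb]) {
          log_pos <- c(log_pos, cc)
          log_from <- c(log_from, cur[cc])
          log_to <- c(log_to, nxt)
          cur[cc] <- nxt
          accepted <- accepted + 1L
        }
      }
    }
    list(
      cds_a = paste(tab$codons[idx], collapse = ""),
      cds_b = paste(tab$codons[cur], collapse = ""),
      ks_truth = n_sub / S,
      n_substitutions = n_sub,
      syn_sites = S,
      mutation_log = data.frame(codon = log_pos,
                                from = tab$codons[log_from],
                                to = tab$codons[log_to])
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a diverged LTR pair of known insertion age
#'
#' The two long terminal repeats of a retrotransposon are identical at
#' insertion; each then accumulates substitutions independently at rate `mu`
#' per site per year for `age_T` years. The expected pairwise divergence is
#' `2 * mu * age_T`; the realized truth divides the logged substitution events
#' by the sequence length.
#'
#' @param age_T Insertion age in years (>= 0).
#' @param mu Substitution rate per site per year (> 0).
#' @param length LTR length in bp.
#' @param seed Optional integer seed.
#' @return List with `ltr5`, `ltr3` (character strings), `d_truth`,
#'   `n_substitutions` (per copy), `age_T` and `mu`.
#' @export
simulate_ltr_element <- function(age_T, mu, length, seed = NULL) {
  if (age_T < 0) stop("age_T must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  if (length < 1) stop("length must be >= 1")
  length <- as.integer(length)
  run <- function() {
    anc <- sample.int(4L, length, replace = TRUE)
    mutate <- function(seq) {
      n <- rpois(1L, mu * age_T * length)
      if (n > 0) {
        pos <- sample.int(length, n, replace = TRUE)
        for (k in seq_len(n)) {
          seq[pos[k]] <- sample(setdiff(1:4, seq[pos[k]]), 1L)
        }
      }
      list(seq = seq, n = n)
    }
    m5 <- mutate(anc)
    m3 <- mutate(anc)
    list(
      ltr5 = paste(.BASES[m5$seq], collapse = ""),
      ltr3 = paste(.BASES[m3$seq], collapse = ""),
      d_truth = (m5$n + m3$n) / length,
      n_substitutions = c(ltr5 = m5$n, ltr3 = m3$n),
      age_T = age_T, mu = mu
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate CDS pairs for two haplotypes with planted edits
#'
#' Generates one random stop-free CDS per gene pair for haplotype 1, copies it
#' to haplotype 2, and gives a chosen fraction of haplotype-2 copies a few
#' random synonymous-or-not single-base substitutions. Used to exercise
#' CDS-identity classification of allelic pairs against known edit labels.
#'
#' @param n_pairs Number of allelic CDS pairs.
#' @param n_codons CDS length in codons.
#' @param edit_fraction Fraction of pairs whose haplotype-2 copy is edited.
#' @param edits_per_seq Substitutions per edited copy.
#' @param seed Optional integer seed.
#' @return List with `cds_h1`, `cds_h2` (named character vectors) and
#'   `edited` (logical vector, the truth labels).
#' @export
simulate_allelic_cds <- function(n_pairs, n_codons = 100,
                                 edit_fraction = 0.25, edits_per_seq = 2,
                                 seed = NULL) {
  tab <- codon_tables()
  run <- function() {
    h1 <- vapply(seq_len(n_pairs), function(i) {
      paste(tab$codons[sample(tab$sense, n_codons, replace = TRUE)],
            collapse = "")
    }, character(1))
    h2 <- h1
    edited <- runif(n_pairs) < edit_fraction
    for (i in which(edited)) {
      s <- strsplit(h2[i], "")[[1]]
      pos <- sample.int(length(s), edits_per_seq)
      for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
      h2[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("P%04d", seq_len(n_pairs))
    list(cds_h1 = setNames(h1, paste0(ids, "_h1")),
         cds_h2 = setNames(h2, paste0(ids, "_h2")),
         edited = setNames(edited, ids))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
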