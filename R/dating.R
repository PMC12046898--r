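# Molecular dating: Nei-Gojobori synonymous/nonsynonymous divergence with
# Jukes-Cantor correction, Ks-distribution peak detection, molecular-clock
# calibration, Kimura two-parameter distance, and LTR insertion ages.

.split_codons <- function(x, arg) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  x <- toupper(x[[1]])
  if (grepl("-", x, fixed = TRUE)) stop(arg, " must be gap-free")
  if (nchar(x) %% 3 != 0) stop(arg, " length must be a multiple of 3")
  if (grepl("[^ACGT]", x)) stop(arg, " must contain only A, C, G, T")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

# average synonymous/nonsynonymous differences over all shortest mutational
# pathways between two codons; pathways through stop codons are excluded
# unless every pathway hits one
.pathway_counts <- function(c1, c2) {
  key <- paste(c1, c2)
  hit <- .pk_cache$path[[key]]
  if (!is.null(hit)) return(hit)
  tab <- codon_tables()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) {
    res <- c(sd = 0, nd = 0)
  } else {
    paths <- if (k == 1) list(diff_pos) else
      lapply(asplit(.permutations(diff_pos), 1), as.integer)
    acc <- matrix(NA_real_, length(paths), 2)
    for (pi in seq_along(paths)) {
      cur <- c1
      sd <- nd <- 0
      ok <- TRUE
      for (p in paths[[pi]]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (tab$aa[match(nxt, tab$codons)] == "*") { ok <- FALSE; break }
        if (tab$aa[match(nxt, tab$codons)] ==
            tab$aa[match(cur, tab$codons)]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc[pi, ] <- c(sd, nd)
    }
    valid <- !is.na(acc[, 1])
    if (!any(valid)) {
      # all pathways pass a stop codon: fall back to counting through stops
      for (pi in seq_along(paths)) {
        cur <- c1
        sd <- nd <- 0
        for (p in paths[[pi]]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (tab$aa[match(nxt, tab$codons)] ==
              tab$aa[match(cur, tab$codons)]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        acc[pi, ] <- c(sd, nd)
      }
      valid <- rep(TRUE, length(paths))
    }
    res <- c(sd = mean(acc[valid, 1]), nd = mean(acc[valid, 2]))
  }
  if (is.null(.pk_cache$path)) .pk_cache$path <- new.env(parent = emptyenv())
  .pk_cache$path[[key]] <- res
  res
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori synonymous and nonsynonymous divergence
#'
#' Classic pathway-counting estimator on a gap-free, in-frame codon
#' alignment. Synonymous (S) and nonsynonymous (N) site counts are averaged
#' over the two sequences; synonymous and nonsynonymous differences are
#' averaged over all shortest mutational pathways per codon pair (pathways
#' through stop codons excluded). Proportions are Jukes-Cantor corrected:
#' `Ks = -3/4 * log(1 - 4/3 * pS)`, and analogously for Ka.
#'
#' @param cds_a,cds_b Aligned coding sequences (character or `DNAString`),
#'   equal length, multiple of 3, no gaps or internal stops.
#' @return A `codon_pair_stats` list: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka` (`Ka` is `NA` when saturated).
#' @export
nei_gojobori_ks <- function(cds_a, cds_b) {
  ca <- .split_codons(cds_a, "cds_a")
  cb <- .split_codons(cds_b, "cds_b")
  if (length(ca) != length(cb))
    stop("sequences must have equal codon length")
  tab <- codon_tables()
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  if (any(tab$aa[ia] == "*") || any(tab$aa[ib] == "*"))
    stop("internal stop codon in input")
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * length(ca) - S
  sd_tot <- nd_tot <- 0
  for (i in which(ca != cb)) {
    pc <- .pathway_counts(ca[i], cb[i])
    sd_tot <- sd_tot + pc[["sd"]]
    nd_tot <- nd_tot + pc[["nd"]]
  }
  pS <- sd_tot / S
  pN <- nd_tot / N
  if (pS >= 3 / 4)
    stop("synonymous sites saturated (pS >= 3/4); Ks undefined")
  Ks <- -3 / 4 * log(1 - 4 / 3 * pS)
  Ka <- if (pN < 3 / 4) -3 / 4 * log(1 - 4 / 3 * pN) else NA_real_
  structure(list(S = S, N = N, Sd = sd_tot, Nd = nd_tot, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka),
            class = "codon_pair_stats")
}

#' @export
print.codon_pair_stats <- function(x, ...) {
  cat(sprintf("codon_pair_stats: S=%.1f N=%.1f Sd=%.2f Nd=%.2f Ks=%.4f Ka=%s\n",
              x$S, x$N, x$Sd, x$Nd, x$Ks,
              ifelse(is.na(x$Ka), "NA", sprintf("%.4f", x$Ka))))
  invisible(x)
}

#' Detect peaks in a Ks distribution
#'
#' Gaussian kernel density on a fixed grid from 0 to 3 (step 0.005); values
#' above 3 are discarded as saturation noise. Peaks are local maxima of the
#' density above 10 percent of the global maximum, reported sorted by
#' location. The default bandwidth is Silverman's rule on the retained
#' sample.
#'
#' @param ks_values Numeric vector of Ks estimates (>= 50 finite values
#'   required after filtering).
#' @param bandwidth Kernel bandwidth; default `bw.nrd0`.
#' @return Data frame with `location`, `height` and `bandwidth`.
#' @export
detect_ks_peaks <- function(ks_values, bandwidth = NULL) {
  x <- ks_values[is.finite(ks_values) & ks_values >= 0 & ks_values <= 3]
  if (length(x) < 50)
    stop("need at least 50 finite Ks values in [0, 3]")
  bw <- bandwidth %||% bw.nrd0(x)
  d <- density(x, bw = bw, from = 0, to = 3, n = 601)
  y <- d$y
  n <- length(y)
  is_peak <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > 0.1 * max(y)
  data.frame(location = d$x[is_peak], height = y[is_peak], bandwidth = bw)
}

#' Calibrate a synonymous substitution rate from a dated Ks peak
#'
#' Inverts the molecular clock `T = Ks / (2 r)` at a calibration point.
#'
#' @param ks_peak Ks peak location (> 0).
#' @param age Age of the event in years (> 0).
#' @return Rate `r` in substitutions per synonymous site per year.
#' @examples
#' r <- calibrate_rate(0.9, 80.34e6)
#' date_event(0.3, r) / 1e6   # ~26.78 Mya
#' @export
calibrate_rate <- function(ks_peak, age) {
  if (ks_peak <= 0 || age <= 0) stop("ks_peak and age must be > 0")
  ks_peak / (2 * age)
}

#' Date a WGD from its Ks peak with a molecular clock
#'
#' @param ks_peak Ks peak location (>= 0).
#' @param rate Synonymous substitution rate per site per year (> 0), e.g.
#'   from [calibrate_rate()].
#' @return Age `T = ks_peak / (2 * rate)` in years.
#' @export
date_event <- function(ks_peak, rate) {
  if (ks_peak < 0) stop("ks_peak must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  ks_peak / (2 * rate)
}

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance
#'
#' Computes transition (P) and transversion (Q) proportions over aligned
#' sites (sites with gaps or ambiguity codes are excluded pairwise) and the
#' K2P distance `D = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`.
#'
#' @param seq_a,seq_b Equal-length sequences (character or `DNAString`).
#' @return List with `P`, `Q`, `D` and `n_sites`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  to_chr <- function(x) {
    if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
      x <- as.character(x)
    strsplit(toupper(x[[1]]), "")[[1]]
  }
  a <- to_chr(seq_a)
  b <- to_chr(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no comparable sites")
  diff <- a != b
  ts <- diff & .TRANSITIONS[a] == b
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated divergence: K2P distance undefined")
  list(P = P, Q = Q, D = -0.5 * log(w1 * sqrt(w2)), n_sites = n)
}

#' LTR insertion age from divergence
#'
#' The two LTRs of a retrotransposon are identical on insertion, so their
#' divergence D dates the insertion: `T = D / (2 * mu)`.
#'
#' @param D Pairwise divergence between the two LTRs (>= 0).
#' @param mu Neutral substitution rate per site per year (default the
#'   published palm value `5.6e-10`; see Details).
#' @details The default rate is the value printed in the source workflow;
#'   rates calibrated from palm Ks peaks are about tenfold higher, so `mu`
#'   is always explicit in reported tables.
#' @return Insertion age in years.
#' @export
ltr_insertion_age <- function(D, mu = 5.6e-10) {
  if (any(D < 0)) stop("D must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  D / (2 * mu)
}

#' Ks table for a set of aligned CDS pairs
#'
#' Convenience wrapper applying [nei_gojobori_ks()] across pairs; saturated
#' pairs yield `NA` Ks with a warning count.
#'
#' @param cds_a,cds_b Named character vectors (or `DNAStringSet`s) of equal
#'   length listing the aligned pair members.
#' @param pair_ids Optional pair identifiers.
#' @return Data frame with per-pair `S`, `N`, `pS`, `pN`, `Ks`, `Ka`.
#' @export
ks_table <- function(cds_a, cds_b, pair_ids = NULL) {
  if (inherits(cds_a, "DNAStringSet")) cds_a <- as.character(cds_a)
  if (inherits(cds_b, "DNAStringSet")) cds_b <- as.character(cds_b)
  stopifnot(length(cds_a) == length(cds_b))
  ids <- pair_ids %||% names(cds_a) %||% sprintf("pair%04d", seq_along(cds_a))
  rows <- lapply(seq_along(cds_a), function(i) {
    st <- tryCatch(nei_gojobori_ks(cds_a[[i]], cds_b[[i]]),
                   error = function(e) NULL)
    if (is.null(st))
      return(data.frame(pair_id = ids[i], S = NA, N = NA, pS = NA, pN = NA,
                        Ks = NA, Ka = NA))
    data.frame(pair_id = ids[i], S = st$S, N = st$N, pS = st$pS, pN = st$pN,
               Ks = st$Ks, Ka = st$Ka)
  })
  out <- do.call(rbind, rows)
  n_bad <- sum(is.na(out$Ks))
  if (n_bad) warning(n_bad, " pair(s) saturated or invalid; Ks set to NA")
  out
}
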