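# Telomere-repeat scanning at chromosome ends. Plant telomeres carry a
# conserved 7-bp unit (TTTAGGG on the 3' strand, CCCTAAA at the 5' end).

#' Scan chromosome ends for telomere repeats
#'
#' Counts exact occurrences of the telomere motif in the two terminal
#' windows of each chromosome: the reverse complement of the motif at the
#' 5' end and the motif itself at the 3' end. An end is telomeric when it
#' carries at least `min_copies` occurrences. Sequences shorter than twice
#' the window use half-length windows so the two ends never overlap.
#'
#' @param chrom_seq A `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param motif Telomere repeat unit (default plant `TTTAGGG`).
#' @param window Terminal window size in bp.
#' @param min_copies Copies required to call an end telomeric.
#' @return Data frame with one row per chromosome end: `chrom`, `end`
#'   (`five_prime`/`three_prime`), `motif`, `copies`, `present`,
#'   `both_ends`.
#' @export
scan_telomeres <- function(chrom_seq, motif = "TTTAGGG", window = 10000,
                           min_copies = 10) {
  if (is.character(chrom_seq)) chrom_seq <- Biostrings::DNAStringSet(chrom_seq)
  if (inherits(chrom_seq, "DNAString"))
    chrom_seq <- Biostrings::DNAStringSet(list(chrom = chrom_seq))
  if (any(Biostrings::width(chrom_seq) == 0)) stop("empty sequence")
  if (is.null(names(chrom_seq)))
    names(chrom_seq) <- sprintf("chr%d", seq_along(chrom_seq))
  motif_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rows <- list()
  for (i in seq_along(chrom_seq)) {
    s <- chrom_seq[[i]]
    len <- length(s)
    w <- min(window, len %/% 2)
    c5 <- if (w > 0) Biostrings::countPattern(
      motif_rc, Biostrings::subseq(s, 1, w)) else 0L
    c3 <- if (w > 0) Biostrings::countPattern(
      motif, Biostrings::subseq(s, len - w + 1, len)) else 0L
    present <- c(c5, c3) >= min_copies
    rows[[i]] <- data.frame(
      chrom = names(chrom_seq)[i], end = c("five_prime", "three_prime"),
      motif = motif, copies = c(c5, c3), present = present,
      both_ends = all(present), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
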