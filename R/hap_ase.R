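# Allele-specific expression: TPM normalisation, per-tissue ASE calls on
# allelic pairs, tissue-specificity classes, and differential-expression
# screening between tissues.

.EPS_FC <- 1e-9

#' Transcripts-per-million normalisation
#'
#' `tpm_g = (c_g / L_g) / sum_h(c_h / L_h) * 1e6` per sample; an all-zero
#' sample stays all-zero.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param gene_lengths Named vector of gene lengths in bp (> 0), covering
#'   every row of `counts`.
#' @return TPM matrix with the same dimensions.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss)) stop("missing gene length for gene: ", miss[1])
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be > 0")
  rate <- counts / len
  denom <- colSums(rate)
  denom[denom == 0] <- 1  # all-zero sample -> all-zero column
  sweep(rate, 2, denom, "/") * 1e6
}

# vectorised two-sided Welch t-test on rows of two matrices;
# zero-variance rows: p = 1 when means equal, 0 otherwise
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  i <- !degen
  tstat <- (m1[i] - m2[i]) / sqrt(se2[i])
  df <- se2[i]^2 / ((v1[i] / n1)^2 / (n1 - 1) + (v2[i] / n2)^2 / (n2 - 1))
  p[i] <- 2 * pt(-abs(tstat), df)
  list(p = p, mean_1 = m1, mean_2 = m2)
}

.require_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "tissue", "replicate") %in% names(samples)))
  samples
}

#' Call allele-specific expression for allelic pairs in one tissue
#'
#' For each pair, replicate TPM values of the two alleles in the tissue are
#' compared: a pair is ASE when (i) the larger allele mean TPM exceeds 1,
#' (ii) |log2 fold change| of the allele means exceeds 1 (fold change > 2),
#' and (iii) a two-sided Welch t-test on log2(TPM + 1) replicate values gives
#' p < 0.05. All inequalities are strict. With `tpm_rule = "both"` both
#' allele means must exceed 1, with `"mean"` their average must.
#'
#' @param pairs Data frame with `gene_h1`, `gene_h2` (and optionally
#'   `pair_id`).
#' @param tpm TPM matrix from [compute_tpm()].
#' @param samples Sample sheet with `sample`, `tissue`, `replicate`,
#'   `haplotype`.
#' @param tissue Tissue to test (default: all tissues in the sheet).
#' @param tpm_rule Which allele mean the TPM > 1 filter applies to.
#' @param alpha P-value threshold.
#' @return Data frame with one row per pair and tissue: allele means,
#'   `log2fc` (h1 over h2), `p_value`, the three filter flags and `is_ase`.
#' @export
call_ase <- function(pairs, tpm, samples, tissue = NULL,
                     tpm_rule = c("either", "both", "mean"), alpha = 0.05) {
  tpm_rule <- match.arg(tpm_rule)
  samples <- .require_samples(samples)
  if (!"haplotype" %in% names(samples))
    stop("sample sheet must carry a 'haplotype' column")
  tissues <- tissue %||% unique(samples$tissue)
  if (!all(tissues %in% samples$tissue))
    stop("tissue not present in sample sheet: ",
         setdiff(tissues, samples$tissue)[1])
  if (is.null(pairs$pair_id))
    pairs$pair_id <- paste(pairs$gene_h1, pairs$gene_h2, sep = "|")
  out <- list()
  for (tis in tissues) {
    s1 <- samples$sample[samples$tissue == tis & samples$haplotype == "h1"]
    s2 <- samples$sample[samples$tissue == tis & samples$haplotype == "h2"]
    if (length(s1) < 2 || length(s2) < 2)
      stop("need >= 2 replicates per allele in tissue '", tis, "'")
    x1 <- tpm[pairs$gene_h1, s1, drop = FALSE]
    x2 <- tpm[pairs$gene_h2, s2, drop = FALSE]
    wt <- welch_rows(log2(x1 + 1), log2(x2 + 1))
    m1 <- rowMeans(x1)
    m2 <- rowMeans(x2)
    log2fc <- log2(m1 + .EPS_FC) - log2(m2 + .EPS_FC)
    passes_tpm <- switch(tpm_rule,
      either = pmax(m1, m2) > 1,
      both = pmin(m1, m2) > 1,
      mean = (m1 + m2) / 2 > 1)
    passes_fc <- abs(log2fc) > 1
    passes_p <- wt$p < alpha
    out[[tis]] <- data.frame(
      pair_id = pairs$pair_id, tissue = tis,
      tpm_h1 = unname(m1), tpm_h2 = unname(m2), log2fc = unname(log2fc),
      p_value = wt$p, passes_tpm = unname(passes_tpm),
      passes_fc = unname(passes_fc), passes_p = passes_p,
      is_ase = unname(passes_tpm & passes_fc & passes_p),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify tissue specificity of ASE calls
#'
#' Counts, per pair, the tissues with `is_ase = TRUE`: exactly one tissue is
#' `one_tissue`, every tested tissue is `all`, two or more (but not all) is
#' `multiple`; pairs never called are excluded.
#'
#' @param ase_calls Output of [call_ase()] across tissues.
#' @return Data frame with `pair_id`, `n_tissues_ase`, `class`.
#' @export
classify_specificity <- function(ase_calls) {
  n_tissues <- length(unique(ase_calls$tissue))
  cnt <- tapply(ase_calls$is_ase, ase_calls$pair_id, sum)
  cnt <- cnt[cnt > 0]
  cls <- ifelse(cnt == 1, "one_tissue",
                ifelse(cnt == n_tissues, "all", "multiple"))
  data.frame(pair_id = names(cnt), n_tissues_ase = as.integer(cnt),
             class = unname(cls), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Screen differentially expressed genes between two tissues
#'
#' Per gene: log2 fold change of tissue mean TPM, two-sided Welch t-test on
#' log2(TPM + 1) replicates, Benjamini-Hochberg adjustment across all tested
#' genes. A gene is a DEG when |log2FC| > 1 and adjusted p < 0.05 (strict).
#'
#' @param tpm TPM matrix.
#' @param samples Sample sheet (`sample`, `tissue`, `replicate`; rows with
#'   other haplotypes should be filtered by the caller via `haplotype`).
#' @param contrast Character vector of two tissue names (tissue1 vs tissue2).
#' @param haplotype Optional haplotype filter applied to the sheet.
#' @param alpha Adjusted p-value threshold.
#' @return Data frame with `gene`, `contrast`, `log2fc`, `p_value`, `padj`,
#'   `is_deg`.
#' @export
screen_degs <- function(tpm, samples, contrast, haplotype = NULL,
                        alpha = 0.05) {
  samples <- .require_samples(samples)
  if (!is.null(haplotype) && "haplotype" %in% names(samples))
    samples <- samples[samples$haplotype == haplotype, , drop = FALSE]
  if (!all(contrast %in% samples$tissue))
    stop("contrast tissue absent from sample sheet: ",
         setdiff(contrast, samples$tissue)[1])
  s1 <- samples$sample[samples$tissue == contrast[1]]
  s2 <- samples$sample[samples$tissue == contrast[2]]
  if (length(s1) < 2 || length(s2) < 2)
    stop("need >= 2 replicates per tissue")
  x1 <- tpm[, s1, drop = FALSE]
  x2 <- tpm[, s2, drop = FALSE]
  wt <- welch_rows(log2(x1 + 1), log2(x2 + 1))
  log2fc <- log2(rowMeans(x1) + .EPS_FC) - log2(rowMeans(x2) + .EPS_FC)
  padj <- p.adjust(wt$p, method = "BH")
  data.frame(
    gene = rownames(tpm), contrast = paste(contrast, collapse = "_vs_"),
    log2fc = unname(log2fc), p_value = wt$p, padj = padj,
    is_deg = unname(abs(log2fc) > 1 & padj < alpha),
    stringsAsFactors = FALSE, row.names = NULL)
}
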