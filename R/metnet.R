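# Metabolomics screening and gene-metabolite networks: PLS-DA VIP scores
# (NIPALS), differentially-accumulated-metabolite calls, and the signed
# top-k / |r| > threshold correlation network.

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS2 model by NIPALS on the autoscaled variable matrix against a
#' centred one-hot group membership matrix and returns per-variable VIP
#' scores: `VIP_j = sqrt(p * sum_a(SSY_a * (w_aj / ||w_a||)^2) /
#' sum_a(SSY_a))` where `SSY_a` is the Y sum of squares explained by
#' component `a`. The squared VIPs average to 1 over variables by
#' construction.
#'
#' @param X Samples x variables numeric matrix.
#' @param y Group label per sample (>= 2 groups).
#' @param n_components Number of PLS components (default 2).
#' @param max_iter,tol NIPALS iteration controls.
#' @return A `vip_result` list: `vip` (named), `weights`, `scores`,
#'   `ssy` (per component), `excluded` (zero-variance variables).
#' @export
plsda_vip <- function(X, y, n_components = 2, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least 2 groups")
  if (length(y) != nrow(X)) stop("y must have one label per row of X")
  sds <- apply(X, 2, sd)
  excluded <- colnames(X)[sds == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " zero-variance variable(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  if (p == 0) stop("no variable with nonzero variance")
  n_components <- min(n_components, p, nrow(X) - 1)
  Xs <- scale(X)
  Y <- stats::model.matrix(~ y - 1)
  Ys <- scale(Y, center = TRUE, scale = FALSE)
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  ssy <- numeric(n_components)
  Xc <- Xs
  Yc <- Ys
  n_used <- 0L
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w_old <- rep(Inf, p)
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      wn <- sqrt(sum(w^2))
      if (!is.finite(wn) || wn < 1e-12) { degenerate <- TRUE; break }
      w <- w / wn
      tt <- drop(Xc %*% w)
      if (sum(tt^2) < 1e-24) { degenerate <- TRUE; break }
      q <- drop(crossprod(Yc, tt)) / sum(tt^2)
      if (sum(q^2) < 1e-24) { degenerate <- TRUE; break }
      u <- drop(Yc %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    if (degenerate) break   # X carries no further Y-relevant variation
    pl <- drop(crossprod(Xc, tt)) / sum(tt^2)
    yhat <- tcrossprod(tt, q)
    ssy[a] <- sum(yhat^2)
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - yhat
    W[, a] <- w
    Tm[, a] <- tt
    n_used <- a
  }
  if (n_used == 0L || sum(ssy) == 0) {
    vip <- rep(0, p)   # no group-relevant structure at all
  } else {
    W <- W[, seq_len(n_used), drop = FALSE]
    Tm <- Tm[, seq_len(n_used), drop = FALSE]
    ssy <- ssy[seq_len(n_used)]
    vip <- sqrt(p * colSums(t(W^2) * ssy) / sum(ssy))
  }
  names(vip) <- colnames(X)
  structure(list(vip = vip, weights = W, scores = Tm, ssy = ssy,
                 n_components = n_components, excluded = excluded),
            class = "vip_result")
}

#' Screen differentially accumulated metabolites
#'
#' A metabolite is a DAM between two groups when its group-mean fold change
#' exceeds 2 (or falls below 0.5) and its PLS-DA VIP score exceeds 1, both
#' strict. VIP is computed on autoscaled log2(intensity + 1) of the two
#' groups.
#'
#' @param intensity Metabolite x sample matrix.
#' @param groups Group label per sample.
#' @param contrast Character vector of two group names (group1 vs group2).
#' @param n_components PLS components for the VIP model.
#' @return Data frame with `metabolite`, `contrast`, `fold_change`, `vip`,
#'   `is_dam`.
#' @export
screen_dams <- function(intensity, groups, contrast, n_components = 2) {
  intensity <- as.matrix(intensity)
  if (!all(contrast %in% groups))
    stop("contrast group absent: ", setdiff(contrast, groups)[1])
  i1 <- groups == contrast[1]
  i2 <- groups == contrast[2]
  if (sum(i1) < 3 || sum(i2) < 3)
    stop("need >= 3 samples per group")
  m1 <- rowMeans(intensity[, i1, drop = FALSE])
  m2 <- rowMeans(intensity[, i2, drop = FALSE])
  fc <- (m1 + .EPS_FC) / (m2 + .EPS_FC)
  sub <- intensity[, i1 | i2, drop = FALSE]
  vip <- rep(NA_real_, nrow(intensity))
  names(vip) <- rownames(intensity)
  vr <- suppressWarnings(
    plsda_vip(t(log2(sub + 1)), groups[i1 | i2], n_components))
  vip[names(vr$vip)] <- vr$vip
  vip[is.na(vip)] <- 0  # zero-variance metabolites cannot be important
  data.frame(
    metabolite = rownames(intensity),
    contrast = paste(contrast, collapse = "_vs_"),
    fold_change = unname(fc), vip = unname(vip),
    is_dam = unname((fc > 2 | fc < 0.5) & vip > 1),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the signed gene-metabolite correlation network
#'
#' Pearson (or Spearman) correlation between every metabolite and every gene
#' on log2(x + 1)-transformed values over matched samples. Per metabolite,
#' genes are ranked by |r| descending, truncated to the `top_k` best, then
#' filtered to |r| > `r_threshold` (the `"filter_first"` order applies the
#' threshold before the truncation). Edge sign is the correlation sign.
#'
#' @param met_intensity Metabolite x sample matrix (typically the DAMs).
#' @param gene_abundance Gene x sample matrix (typically the DEGs).
#' @param r_threshold Absolute correlation threshold (strict).
#' @param top_k Maximum edges per metabolite.
#' @param method `"pearson"` or `"spearman"`.
#' @param rule Whether to rank-truncate before or after thresholding.
#' @param log_transform Apply log2(x + 1) before correlating.
#' @return List with `edges` (metabolite, gene, r, sign) and `nodes`
#'   (id, type).
#' @export
build_correlation_network <- function(met_intensity, gene_abundance,
                                      r_threshold = 0.8, top_k = 5,
                                      method = c("pearson", "spearman"),
                                      rule = c("rank_first", "filter_first"),
                                      log_transform = TRUE) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  met_intensity <- as.matrix(met_intensity)
  gene_abundance <- as.matrix(gene_abundance)
  common <- intersect(colnames(met_intensity), colnames(gene_abundance))
  if (length(common) < 3)
    stop("need >= 3 matched samples for correlation")
  m <- met_intensity[, common, drop = FALSE]
  g <- gene_abundance[, common, drop = FALSE]
  if (log_transform) {
    m <- log2(m + 1)
    g <- log2(g + 1)
  }
  r <- suppressWarnings(cor(t(m), t(g), method = method))
  r[is.na(r)] <- 0
  edges <- list()
  gene_names <- colnames(r) %||% rownames(gene_abundance)
  for (i in seq_len(nrow(r))) {
    ri <- as.numeric(r[i, ])
    ord <- order(-abs(ri), gene_names)
    cand <- if (rule == "rank_first") {
      keep <- head(ord, top_k)
      keep[abs(ri[keep]) > r_threshold]
    } else {
      ok <- ord[abs(ri[ord]) > r_threshold]
      head(ok, top_k)
    }
    if (length(cand)) {
      edges[[length(edges) + 1L]] <- data.frame(
        metabolite = rownames(r)[i], gene = gene_names[cand],
        r = ri[cand],
        sign = ifelse(ri[cand] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(metabolite = character(0), gene = character(0),
               r = numeric(0), sign = character(0))
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = c(unique(edges$metabolite), unique(edges$gene)),
    type = rep(c("metabolite", "gene"),
               c(length(unique(edges$metabolite)),
                 length(unique(edges$gene)))),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Export a gene-metabolite network to GraphML and SIF
#'
#' @param network List with `edges` and `nodes` from
#'   [build_correlation_network()].
#' @param graphml,sif Optional output paths; written when non-`NULL`.
#' @return The `igraph` graph, invisibly.
#' @export
export_network <- function(network, graphml = NULL, sif = NULL) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("metabolite", "gene", "r", "sign")],
    directed = FALSE, vertices = network$nodes)
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(sif)) {
    sif_df <- data.frame(a = network$edges$metabolite,
                         rel = network$edges$sign,
                         b = network$edges$gene)
    write.table(sif_df, sif, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(g)
}
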