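#' Interaction-profile correlation matrix
#'
#' The interaction profile of gene i is row i of the interaction matrix —
#' its scores against all other tested genes. `c_ij` is the Spearman
#' (default) or Pearson correlation of the profiles of i and j. By default
#' the two columns indexed by the pair itself are excluded from the
#' computation (the diagonal is undefined and the mutual entry would inject
#' the pair's own interaction into its similarity); set
#' `exclude_mutual = FALSE` to additionally include the mutual entry as a
#' matched position.
#'
#' @param W symmetric interaction matrix with NA diagonal.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param exclude_mutual drop the mutual entry (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal; entries are NA
#'   (with a `"flagged"` attribute listing them) where a profile is constant
#'   or fewer than 3 shared finite positions remain.
#' @export
profile_correlation <- function(W, method = c("spearman", "pearson"),
                                exclude_mutual = TRUE) {
  method <- match.arg(method)
  N <- nrow(W)
  if (N < 4) stop("value error: need at least 4 reagents for profiles")
  C <- matrix(NA_real_, N, N, dimnames = dimnames(W))
  diag(C) <- 1
  flagged <- character(0)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    idx <- setdiff(seq_len(N), c(i, j))
    xi <- W[i, idx]; xj <- W[j, idx]
    if (!exclude_mutual) { xi <- c(xi, W[i, j]); xj <- c(xj, W[j, i]) }
    ok <- is.finite(xi) & is.finite(xj)
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
      flagged <- c(flagged, paste(rownames(W)[i], colnames(W)[j], sep = ":"))
      next
    }
    C[i, j] <- C[j, i] <- stats::cor(xi[ok], xj[ok], method = method)
  }
  attr(C, "method") <- method
  attr(C, "flagged") <- flagged
  C
}

threshold_graph <- function(nodes, edges, thresholds, kind) {
  structure(list(nodes = nodes, edges = edges, thresholds = thresholds,
                 kind = kind),
            class = "threshold_graph")
}

#' @export
print.threshold_graph <- function(x, ...) {
  cat(sprintf("threshold_graph (%s): %d nodes, %d edges\n",
              x$kind, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Interaction threshold graph
#'
#' Draws an edge for every pair whose FDR-adjusted p-value is below `p_cut`
#' AND whose absolute interaction score exceeds `w_cut` (defaults 0.1 and
#' 0.3); the edge sign is the sign of the score.
#'
#' @param W interaction matrix (for node set and weights).
#' @param tests a [pair_tests()] result covering the pairs of `W`.
#' @param p_cut adjusted-p threshold (default 0.1).
#' @param w_cut absolute effect-size threshold, log2 units (default 0.3).
#' @param test which adjusted p to threshold: `"moderated"` (default) or
#'   `"ordinary"`.
#' @param node_class optional named vector of node class labels (e.g. query
#'   vs random set).
#' @return A `threshold_graph`.
#' @export
interaction_graph <- function(W, tests, p_cut = 0.1, w_cut = 0.3,
                              test = c("moderated", "ordinary"),
                              node_class = NULL) {
  test <- match.arg(test)
  if (p_cut <= 0 || w_cut <= 0)
    stop("option error: thresholds must be positive")
  padj <- tests[[paste0("p_", test, "_adj")]]
  keep <- !is.na(padj) & padj < p_cut & !is.na(tests$w) & abs(tests$w) > w_cut
  edges <- data.frame(from = tests$i[keep], to = tests$j[keep],
                      weight = tests$w[keep], sign = sign(tests$w[keep]),
                      stringsAsFactors = FALSE)
  ids <- rownames(W)
  nodes <- data.frame(id = ids,
                      class = if (is.null(node_class)) ""
                              else as.character(node_class[ids]),
                      stringsAsFactors = FALSE)
  threshold_graph(nodes, edges,
                  list(p_cut = p_cut, w_cut = w_cut, test = test),
                  kind = "interaction")
}

#' Interaction-profile correlation graph
#'
#' Edge (i, j) iff `|c_ij| > c_cut` (strict); the edge sign is the sign of
#' the correlation. Genes acting in a shared complex tend to form cliques.
#'
#' @param C a [profile_correlation()] matrix.
#' @param c_cut absolute-correlation threshold (default 0.8).
#' @param node_class optional named class labels.
#' @return A `threshold_graph`.
#' @export
correlation_graph <- function(C, c_cut = 0.8, node_class = NULL) {
  ij <- which(upper.tri(C), arr.ind = TRUE)
  v <- C[ij]
  keep <- !is.na(v) & abs(v) > c_cut
  edges <- data.frame(from = rownames(C)[ij[keep, 1]],
                      to = colnames(C)[ij[keep, 2]],
                      weight = v[keep], sign = sign(v[keep]),
                      stringsAsFactors = FALSE)
  ids <- rownames(C)
  nodes <- data.frame(id = ids,
                      class = if (is.null(node_class)) ""
                              else as.character(node_class[ids]),
                      stringsAsFactors = FALSE)
  threshold_graph(nodes, edges, list(c_cut = c_cut), kind = "correlation")
}

#' Export a threshold graph
#'
#' `"edgelist"` writes a TSV (source, target, weight, sign, kind); an empty
#' graph yields a header-only file. `"graphml"` writes GraphML with the node
#' `class` attribute, losslessly re-readable with igraph.
#'
#' @param g a `threshold_graph`.
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("option error: unknown format"))
  if (format == "edgelist") {
    tab <- data.frame(source = g$edges$from, target = g$edges$to,
                      weight = g$edges$weight, sign = g$edges$sign,
                      kind = rep(g$kind, nrow(g$edges)),
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(
      g$edges, directed = FALSE,
      vertices = data.frame(name = g$nodes$id, class = g$nodes$class,
                            stringsAsFactors = FALSE))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
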