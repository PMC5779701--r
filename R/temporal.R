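#' Correlation of two networks' adjacency (weight) matrices
#'
#' Correlates the lower-triangle edge-weight vectors of two networks over the
#' same nodes, zeros included: in a regularized network an absent edge is an
#' estimate of zero, and excluding absent edges would condition on the
#' selected support. Default is the Spearman rank correlation.
#'
#' @param net_a,net_b `ggm_network` objects or symmetric weight matrices over
#'   the same node set.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return The correlation.
#' @export
adjacency_correlation <- function(net_a, net_b,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  Wa <- net_weight_matrix(net_a)
  Wb <- net_weight_matrix(net_b)
  la <- colnames(Wa); lb <- colnames(Wb)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("node sets differ between the networks")
  if (!all(dim(Wa) == dim(Wb))) stop("networks have different sizes")
  lo <- lower.tri(Wa)
  a <- Wa[lo]; b <- Wb[lo]
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined: constant edge-weight vector")
  cor(a, b, method = method)
}

#' Correlation of centrality estimates across two networks
#'
#' @param tab_a,tab_b [centrality_table()] results over the same nodes.
#' @param metric which centrality to correlate (default strength).
#' @param method `"pearson"` (default, the `r` reported for strength
#'   stability) or `"spearman"`.
#' @return The correlation of the raw per-node values.
#' @export
centrality_correlation <- function(tab_a, tab_b,
                                   metric = c("strength", "betweenness",
                                              "closeness"),
                                   method = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (!identical(tab_a$node, tab_b$node))
    stop("centrality tables cover different nodes")
  a <- tab_a[[metric]]; b <- tab_b[[metric]]
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined: constant centrality vector")
  cor(a, b, method = method)
}

#' Cross-wave similarity report
#'
#' For every pair of waves: Spearman and product-moment correlations of the
#' adjacency matrices and the correlation of strength centralities.
#'
#' @param networks named list of `ggm_network` objects (names are wave
#'   labels).
#' @return Data frame with one row per wave pair: `wave_a`, `wave_b`,
#'   `adjacency_spearman`, `adjacency_pearson`, `strength_pearson`,
#'   `strength_spearman`, `n_entries` (compared edge entries).
#' @export
similarity_report <- function(networks) {
  stopifnot(length(networks) >= 2)
  labs <- names(networks)
  if (is.null(labs)) labs <- paste0("T", seq_along(networks))
  tabs <- lapply(networks, centrality_table)
  pairs <- combn(seq_along(networks), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- length(networks[[i]]$node_labels)
    data.frame(wave_a = labs[i], wave_b = labs[j],
               adjacency_spearman = adjacency_correlation(networks[[i]], networks[[j]], "spearman"),
               adjacency_pearson = adjacency_correlation(networks[[i]], networks[[j]], "pearson"),
               strength_pearson = centrality_correlation(tabs[[i]], tabs[[j]], "strength", "pearson"),
               strength_spearman = centrality_correlation(tabs[[i]], tabs[[j]], "strength", "spearman"),
               n_entries = p * (p - 1) / 2)
  }))
  rownames(out) <- NULL
  out
}
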