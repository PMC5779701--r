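#' Node strength
#'
#' Sum of absolute weights of the edges incident to each node.
#'
#' @param network a `ggm_network` or symmetric weight matrix.
#' @return Named numeric vector.
#' @export
node_strength <- function(network) {
  W <- if (inherits(network, "ggm_network")) network$W else as.matrix(network)
  s <- rowSums(abs(W))
  names(s) <- colnames(W)
  s
}

net_weight_matrix <- function(network) {
  if (inherits(network, "ggm_network")) {
    W <- network$W
    if (is.null(colnames(W)))
      dimnames(W) <- list(network$node_labels, network$node_labels)
    W
  } else {
    as.matrix(network)
  }
}

#' Shortest-path centralities on a weighted network
#'
#' Edge lengths are inverse absolute weights, `1 / |w|`, the standard distance
#' transform for association networks; negative edges therefore contribute
#' through their magnitude. Betweenness counts, for every ordered
#' source-target pair excluding the node itself, the fraction of shortest
#' paths passing through the node. Closeness is the inverse of the summed
#' distance to all other nodes; when the network is disconnected it is
#' computed over the reachable nodes and scaled by `reachable / (p - 1)` so
#' that values stay finite, and isolated nodes get 0.
#'
#' @param network a `ggm_network` or symmetric weight matrix.
#' @return A data frame with columns `node`, `betweenness`, `closeness`.
#' @export
shortest_path_metrics <- function(network) {
  W <- net_weight_matrix(network)
  p <- ncol(W)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("node", seq_len(p))
  A <- abs(W)
  A[A < 1e-12] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  if (igraph::ecount(g) == 0) {
    return(data.frame(node = labels, betweenness = rep(0, p),
                      closeness = rep(0, p)))
  }
  btw <- 2 * igraph::betweenness(g, weights = len)   # ordered pairs
  D <- igraph::distances(g, weights = len)
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    fin <- is.finite(d)
    r <- sum(fin)
    if (r == 0 || sum(d[fin]) == 0) return(0)
    (r / (p - 1)) / sum(d[fin])
  }, numeric(1))
  data.frame(node = labels, betweenness = unname(btw), closeness = clo)
}

#' Centrality table with within-network standardization
#'
#' Computes strength, betweenness and closeness per node and their
#' z-standardized versions (mean 0, SD 1 with denominator `n - 1`, across the
#' nodes of the same network). By default all nodes present in the network,
#' including covariate nodes, enter the standardization; pass `nodes` to
#' restrict it.
#'
#' @param network a `ggm_network` or symmetric weight matrix.
#' @param nodes optional subset of node labels to keep (subsetting happens
#'   before standardization).
#' @return A data frame of class `centrality_table` with columns `node`,
#'   `strength`, `betweenness`, `closeness`, `z_strength`, `z_betweenness`,
#'   `z_closeness`.
#' @export
centrality_table <- function(network, nodes = NULL) {
  s <- node_strength(network)
  sp <- shortest_path_metrics(network)
  tab <- data.frame(node = sp$node, strength = unname(s),
                    betweenness = sp$betweenness, closeness = sp$closeness)
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, tab$node)
    if (length(missing))
      stop("unknown nodes: ", paste(missing, collapse = ", "))
    tab <- tab[match(nodes, tab$node), , drop = FALSE]
    rownames(tab) <- NULL
  }
  standardize_centrality(tab)
}

#' Standardize centrality columns within a network
#'
#' @param tab data frame with columns `strength`, `betweenness`, `closeness`.
#' @return The table with `z_` columns added (z = (x - mean) / SD). A metric
#'   with zero spread gets z = 0 with a warning.
#' @export
standardize_centrality <- function(tab) {
  stopifnot(nrow(tab) >= 2)
  for (m in c("strength", "betweenness", "closeness")) {
    x <- tab[[m]]
    sdx <- sd(x)
    if (sdx == 0) {
      warning("zero spread in ", m, "; standardized values set to 0")
      z <- rep(0, length(x))
    } else {
      z <- (x - mean(x)) / sdx
    }
    tab[[paste0("z_", m)]] <- z
  }
  class(tab) <- c("centrality_table", "data.frame")
  tab
}
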