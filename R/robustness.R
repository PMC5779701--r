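#' Bootstrap specification
#'
#' @param n_boot number of bootstrap replicates (1000 in typical use).
#' @param kind `"nonparametric"` (subjects resampled with replacement, for
#'   edge-weight confidence intervals and difference tests) or
#'   `"case_dropping"` (subsets without replacement, for centrality
#'   stability).
#' @param drop_proportions grid of dropped-case proportions for the
#'   case-dropping routine.
#' @param stability_cor_threshold correlation with the full-sample result a
#'   subset replicate must reach to count as stable.
#' @param stability_prob required fraction of replicates at or above the
#'   threshold.
#' @param seed root seed; replicate `b` uses `seed + b` (plus a fixed offset
#'   per drop proportion), so partial runs are reproducible.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_boot = 1000,
                           kind = c("nonparametric", "case_dropping"),
                           drop_proportions = seq(0.1, 0.75, by = 0.05),
                           stability_cor_threshold = 0.7,
                           stability_prob = 0.95, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_boot >= 1, all(drop_proportions > 0), all(drop_proportions < 1),
            stability_cor_threshold > 0, stability_cor_threshold < 1,
            stability_prob > 0, stability_prob <= 1)
  structure(list(n_boot = as.integer(n_boot), kind = kind,
                 drop_proportions = drop_proportions,
                 stability_cor_threshold = stability_cor_threshold,
                 stability_prob = stability_prob, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

subset_dataset <- function(data, idx, reindex = TRUE) {
  ids <- if (reindex) seq_along(idx) else data$subject_ids[idx]
  ordinal_dataset(data$values[idx, , drop = FALSE],
                  item_codes = data$item_codes, item_kind = data$item_kind,
                  time_label = data$time_label, subject_ids = ids)
}

pair_labels <- function(labels) {
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples subjects with replacement, re-runs the whole estimation pipeline
#' (latent correlations plus EBIC graphical lasso) per replicate, and collects
#' each edge's bootstrap distribution. Confidence limits are the 2.5% and
#' 97.5% quantiles by linear interpolation. Because regularization biases
#' estimates toward zero, a point estimate can fall outside the resampled
#' quantiles; such edges are flagged, not forbidden.
#'
#' @param data an [ordinal_dataset()].
#' @param spec a [bootstrap_spec()].
#' @param config a [ggm_config()] describing the estimation pipeline.
#' @param min_pairwise_n passed to [correlation_matrix()].
#' @return An object of class `edge_ci_table`: `table` (per unordered pair:
#'   estimate, lower, upper, flag), `edge_replicates` and
#'   `strength_replicates` matrices (replicate store for difference tests),
#'   `n_failed`, `network` (the full-sample fit).
#' @export
nonparametric_boot <- function(data, spec = bootstrap_spec(),
                               config = ggm_config(), min_pairwise_n = 10) {
  stopifnot(inherits(data, "ordinal_dataset"), inherits(spec, "bootstrap_spec"))
  full <- estimate_network(data, config, min_pairwise_n = min_pairwise_n)
  labels <- full$node_labels
  up <- upper.tri(full$W)
  est <- full$W[up]
  n <- nrow(data$values)
  B <- spec$n_boot
  edge_rep <- matrix(NA_real_, B, sum(up))
  str_rep <- matrix(NA_real_, B, length(labels),
                    dimnames = list(NULL, labels))
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(spec$seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    net <- tryCatch(
      estimate_network(subset_dataset(data, idx), config,
                       min_pairwise_n = min_pairwise_n),
      error = function(e) NULL)
    if (is.null(net)) { n_failed <- n_failed + 1L; next }
    edge_rep[b, ] <- net$W[up]
    str_rep[b, ] <- node_strength(net)
  }
  if (n_failed > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed (", n_failed, "/", B, ")")
  if (B == 1)
    warning("n_boot = 1: degenerate confidence intervals equal to the single replicate")
  qs <- apply(edge_rep, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  idx2 <- which(up, arr.ind = TRUE)
  tab <- data.frame(node_i = labels[idx2[, 1]], node_j = labels[idx2[, 2]],
                    estimate = est, lower = qs[1, ], upper = qs[2, ],
                    n_replicates = colSums(!is.na(edge_rep)))
  tab$outside <- est < tab$lower | est > tab$upper
  colnames(edge_rep) <- pair_labels(labels)
  structure(list(table = tab, edge_replicates = edge_rep,
                 strength_replicates = str_rep, n_failed = n_failed,
                 network = full, spec = spec),
            class = "edge_ci_table")
}

#' Correlation stability (CS) coefficient
#'
#' The largest drop proportion at which at least `prob` of the subset
#' replicates correlate at least `threshold` with the full-sample centrality;
#' 0 when no proportion qualifies.
#'
#' @param correlations replicates-by-proportions matrix of correlations, or a
#'   `stability_result`.
#' @param proportions drop proportions matching the columns.
#' @param threshold,prob stability criterion (conventionally 0.7 and 0.95).
#' @return The CS coefficient.
#' @export
cs_coefficient <- function(correlations, proportions = NULL, threshold = 0.7,
                           prob = 0.95) {
  if (inherits(correlations, "stability_result")) {
    proportions <- correlations$proportions
    correlations <- correlations$correlations
  }
  stopifnot(ncol(correlations) == length(proportions))
  ok <- vapply(seq_along(proportions), function(j) {
    x <- correlations[, j]
    x <- x[!is.na(x)]
    length(x) > 0 && mean(x >= threshold) >= prob
  }, logical(1))
  if (!any(ok)) 0 else max(proportions[ok])
}

#' Case-dropping subset bootstrap for centrality stability
#'
#' For each drop proportion, draws `n_boot` subject subsets without
#' replacement, re-estimates the network, and correlates the subset centrality
#' with the full-sample centrality across nodes. The CS coefficient summarizes
#' how many cases can be dropped before the chosen centrality becomes
#' unstable.
#'
#' @inheritParams nonparametric_boot
#' @param metric centrality to track: `"strength"`, `"betweenness"` or
#'   `"closeness"`.
#' @param cor_method correlation between subset and full-sample centralities
#'   (product-moment by default; `"spearman"` available).
#' @return An object of class `stability_result`: `proportions`,
#'   `correlations` (replicates x proportions), `cs_coefficient`, `metric`.
#' @export
case_dropping_boot <- function(data, spec = bootstrap_spec(kind = "case_dropping"),
                               metric = c("strength", "betweenness", "closeness"),
                               config = ggm_config(), min_pairwise_n = 10,
                               cor_method = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  cor_method <- match.arg(cor_method)
  stopifnot(inherits(data, "ordinal_dataset"), inherits(spec, "bootstrap_spec"))
  full <- estimate_network(data, config, min_pairwise_n = min_pairwise_n)
  full_cent <- centrality_value(full, metric)
  n <- nrow(data$values)
  p <- length(full$node_labels)
  props <- spec$drop_proportions
  keep <- vapply(props, function(pr) {
    nk <- round(n * (1 - pr))
    if (nk < p + 5) {
      warning(sprintf("drop proportion %.2f skipped: retained subset (%d) below %d subjects",
                      pr, nk, p + 5))
      FALSE
    } else TRUE
  }, logical(1))
  props <- props[keep]
  B <- spec$n_boot
  cors <- matrix(NA_real_, B, length(props),
                 dimnames = list(NULL, sprintf("%.2f", props)))
  n_failed <- 0L
  for (j in seq_along(props)) {
    nk <- round(n * (1 - props[j]))
    for (b in seq_len(B)) {
      set.seed(spec$seed + 1000003L * j + b)
      idx <- sample.int(n, nk, replace = FALSE)
      net <- tryCatch(
        estimate_network(subset_dataset(data, idx), config,
                         min_pairwise_n = min_pairwise_n),
        error = function(e) NULL)
      if (is.null(net)) { n_failed <- n_failed + 1L; next }
      sub_cent <- centrality_value(net, metric)
      cors[b, j] <- suppressWarnings(
        cor(full_cent, sub_cent, method = cor_method))
    }
  }
  if (n_failed > 0.1 * B * length(props))
    stop("more than 10% of case-dropping replicates failed")
  cs <- cs_coefficient(cors, props, spec$stability_cor_threshold,
                       spec$stability_prob)
  structure(list(proportions = props, correlations = cors,
                 cs_coefficient = cs, metric = metric,
                 threshold = spec$stability_cor_threshold,
                 prob = spec$stability_prob, n_failed = n_failed),
            class = "stability_result")
}

centrality_value <- function(network, metric) {
  if (metric == "strength") return(unname(node_strength(network)))
  sp <- shortest_path_metrics(network)
  sp[[metric]]
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("case-dropping stability of %s: CS(cor >= %.2f, prob %.2f) = %.2f\n",
              x$metric, x$threshold, x$prob, x$cs_coefficient))
  invisible(x)
}

#' Bootstrap difference tests for edges and strength centrality
#'
#' For every pair of edges (and every pair of nodes), the bootstrap
#' distribution of the difference is formed from the replicate store of
#' [nonparametric_boot()]; a difference is declared when the central 95%
#' bootstrap quantile interval excludes 0. No multiplicity correction is
#' applied.
#'
#' @param boot an `edge_ci_table` from [nonparametric_boot()].
#' @param level interval coverage (default 0.95).
#' @return A list with symmetric logical matrices `edges` (edge pairs) and
#'   `strength` (node pairs); `TRUE` marks a significant difference.
#' @export
difference_tests <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "edge_ci_table"))
  a <- (1 - level) / 2
  sig_matrix <- function(store) {
    k <- ncol(store)
    out <- matrix(FALSE, k, k, dimnames = list(colnames(store), colnames(store)))
    for (i in seq_len(k - 1)) {
      d <- store[, (i + 1):k, drop = FALSE] - store[, i]
      qs <- apply(d, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE, type = 7)
      sig <- qs[1, ] > 0 | qs[2, ] < 0
      out[i, (i + 1):k] <- sig
      out[(i + 1):k, i] <- sig
    }
    out
  }
  list(edges = sig_matrix(boot$edge_replicates),
       strength = sig_matrix(boot$strength_replicates))
}
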