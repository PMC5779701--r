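#' Item roster
#'
#' Describes the columns of a wave CSV: item code, kind, and for ordinal /
#' binary items the admissible level range.
#'
#' @param codes character vector of item codes.
#' @param kinds per-item kind (`"ordinal"`, `"binary"`, `"continuous"`).
#' @param min_level,max_level per-item admissible level bounds for
#'   ordinal/binary items (recycled; ignored, and may be `NA`, for continuous
#'   items).
#' @return A data frame of class `item_roster`.
#' @export
item_roster <- function(codes, kinds = rep("ordinal", length(codes)),
                        min_level = 0L, max_level = 3L) {
  stopifnot(length(kinds) == length(codes),
            all(kinds %in% c("ordinal", "binary", "continuous")))
  out <- data.frame(code = codes, kind = kinds,
                    min_level = rep_len(min_level, length(codes)),
                    max_level = rep_len(max_level, length(codes)))
  class(out) <- c("item_roster", "data.frame")
  out
}

#' Standard roster for the depression/self-efficacy study layout
#'
#' 20 CES-D items scored 0-3, 10 GSE items scored 1-4, and a binary
#' intervention indicator coded 1 (control) / 2 (intervention).
#'
#' @return An [item_roster()].
#' @export
cesd_gse_roster <- function() {
  item_roster(
    codes = c(paste0("cesd", 1:20), paste0("gse", 1:10), "rx"),
    kinds = c(rep("ordinal", 30), "binary"),
    min_level = c(rep(0L, 20), rep(1L, 10), 1L),
    max_level = c(rep(3L, 20), rep(4L, 10), 2L))
}

#' Read one wave of wide-format CSV data
#'
#' The file must contain `subject_id`, `time`, and every roster column.
#' Ordinal and binary entries are validated against the roster's level range;
#' an out-of-range value is rejected naming the cell.
#'
#' @param path CSV file path.
#' @param roster an [item_roster()].
#' @param time_label expected wave label; defaults to the file's `time` value.
#' @return An [ordinal_dataset()].
#' @export
load_wave <- function(path, roster, time_label = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", roster$code)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject IDs in ", path, ": ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  if (is.null(time_label)) time_label <- as.character(df$time[1])
  V <- as.matrix(df[, roster$code, drop = FALSE])
  for (j in seq_len(nrow(roster))) {
    if (roster$kind[j] == "continuous") next
    x <- V[, j]
    bad <- which(!is.na(x) &
                   (x != round(x) | x < roster$min_level[j] | x > roster$max_level[j]))
    if (length(bad))
      stop(sprintf("out-of-range value %s for item '%s' at row %d of %s",
                   format(x[bad[1]]), roster$code[j], bad[1], path))
  }
  ordinal_dataset(V, item_codes = roster$code, item_kind = roster$kind,
                  time_label = time_label, subject_ids = df$subject_id)
}

#' Write an ordinal dataset as wide CSV
#'
#' @param data an [ordinal_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "ordinal_dataset"))
  df <- data.frame(subject_id = data$subject_ids, time = data$time_label)
  df <- cbind(df, as.data.frame(data$values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' First principal component score of a self-efficacy item block
#'
#' Columns are standardized over the complete rows and the first principal
#' component extracted; the component sign is fixed so that the loading sum is
#' positive. Rows with any missing item get a missing score.
#'
#' @param gse_items numeric matrix, subjects by items (conventionally the 10
#'   GSE items).
#' @return An object of class `component_score`: `scores` (zero mean over the
#'   estimation sample, `NA` for incomplete rows), `variance_explained`
#'   (percent), `loadings`, `n_complete`.
#' @export
gse_component <- function(gse_items) {
  X <- as.matrix(gse_items)
  if (ncol(X) < 2) stop("at least 2 item columns are required")
  cc <- stats::complete.cases(X)
  if (sum(cc) < 2) stop("fewer than 2 complete rows")
  Xc <- X[cc, , drop = FALSE]
  sds <- apply(Xc, 2, sd)
  if (any(sds == 0))
    stop("constant item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(Xc)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (sum(load1) < 0) load1 <- -load1
  scores <- rep(NA_real_, nrow(X))
  scores[cc] <- as.numeric(Xs %*% load1)
  ve <- 100 * pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(list(scores = scores, variance_explained = ve,
                 loadings = load1, n_complete = sum(cc)),
            class = "component_score")
}

#' Complete-case filter across waves
#'
#' Retains subjects with all listed items observed at every wave — the paired
#' subset required by the dependent network comparison test.
#'
#' @param waves list of [ordinal_dataset()] objects with aligned subjects.
#' @param items item codes to require (default: all items of the first wave).
#' @return A list with `waves` (filtered datasets), `n_retained`,
#'   `subject_ids`.
#' @export
complete_case_filter <- function(waves, items = NULL) {
  stopifnot(length(waves) >= 1)
  ids <- waves[[1]]$subject_ids
  for (w in waves) {
    if (!identical(w$subject_ids, ids))
      stop("waves have unaligned subject IDs")
  }
  if (is.null(items)) items <- waves[[1]]$item_codes
  keep <- rep(TRUE, length(ids))
  for (w in waves) {
    miss <- setdiff(items, w$item_codes)
    if (length(miss)) stop("items absent from a wave: ",
                           paste(miss, collapse = ", "))
    keep <- keep & stats::complete.cases(w$values[, items, drop = FALSE])
  }
  if (!any(keep)) stop("no subject is complete at every wave")
  list(waves = lapply(waves, subset_dataset, idx = which(keep),
                      reindex = FALSE),
       n_retained = sum(keep), subject_ids = ids[keep])
}

#' Write a network's weight matrix, edge list, and GraphML
#'
#' @param network a `ggm_network`.
#' @param prefix path prefix; writes `<prefix>_adjacency.csv`,
#'   `<prefix>_edges.csv` and `<prefix>.graphml`.
#' @return The written paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  W <- net_weight_matrix(network)
  adj_path <- paste0(prefix, "_adjacency.csv")
  write.csv(W, adj_path, row.names = TRUE)
  up <- which(upper.tri(W) & abs(W) > 1e-10, arr.ind = TRUE)
  edges <- data.frame(node_i = colnames(W)[up[, 1]],
                      node_j = colnames(W)[up[, 2]],
                      weight = W[up])
  edge_path <- paste0(prefix, "_edges.csv")
  write.csv(edges, edge_path, row.names = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  gml_path <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(adj_path, edge_path, gml_path))
}

#' Study configuration
#'
#' @param waves named list: wave label -> CSV path or [ordinal_dataset()].
#' @param roster an [item_roster()] describing the columns.
#' @param gse_items codes of the items to reduce to a single first-principal-
#'   component node (set `NULL` to skip the reduction).
#' @param gse_node name of the resulting component node.
#' @param ggm a [ggm_config()].
#' @param bootstrap a [bootstrap_spec()] or `NULL` to skip bootstrapping.
#' @param bootstrap_waves wave labels to bootstrap (default: all waves).
#' @param stability_metric centrality tracked by the case-dropping bootstrap.
#' @param n_perm permutations for the paired network comparison tests.
#' @param nct_items items whose completeness defines the paired complete-case
#'   subset (default: all analysed items).
#' @param out_dir output directory (`NULL`: nothing is written).
#' @param seed root seed for every stochastic stage.
#' @param min_pairwise_n minimum pairwise-complete count per correlation.
#' @return An object of class `study_config`.
#' @export
study_config <- function(waves, roster, gse_items = NULL, gse_node = "gse",
                         ggm = ggm_config(), bootstrap = NULL,
                         bootstrap_waves = NULL,
                         stability_metric = "strength", n_perm = 1000,
                         nct_items = NULL, out_dir = NULL, seed = 1L,
                         min_pairwise_n = 10) {
  stopifnot(length(waves) >= 1, inherits(roster, "item_roster"))
  structure(list(waves = waves, roster = roster, gse_items = gse_items,
                 gse_node = gse_node, ggm = ggm, bootstrap = bootstrap,
                 bootstrap_waves = bootstrap_waves,
                 stability_metric = stability_metric, n_perm = n_perm,
                 nct_items = nct_items, out_dir = out_dir,
                 seed = as.integer(seed), min_pairwise_n = min_pairwise_n),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' The file mirrors the arguments of [study_config()]; `roster` is given as a
#' table of `code` / `kind` / `min_level` / `max_level`, `ggm` and `bootstrap`
#' as argument lists.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  roster <- do.call(item_roster, list(
    codes = vapply(cfg$roster, `[[`, "", "code"),
    kinds = vapply(cfg$roster, `[[`, "", "kind"),
    min_level = vapply(cfg$roster, function(r) as.integer(r$min_level %||% NA), 1L),
    max_level = vapply(cfg$roster, function(r) as.integer(r$max_level %||% NA), 1L)))
  ggm <- if (is.null(cfg$ggm)) ggm_config() else do.call(ggm_config, cfg$ggm)
  boot <- if (is.null(cfg$bootstrap)) NULL else do.call(bootstrap_spec, cfg$bootstrap)
  study_config(waves = cfg$waves, roster = roster,
               gse_items = cfg$gse_items, gse_node = cfg$gse_node %||% "gse",
               ggm = ggm, bootstrap = boot,
               stability_metric = cfg$stability_metric %||% "strength",
               n_perm = cfg$n_perm %||% 1000, nct_items = cfg$nct_items,
               out_dir = cfg$out_dir, seed = cfg$seed %||% 1L,
               min_pairwise_n = cfg$min_pairwise_n %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replace the GSE item block of a wave with its first-component score node.
reduce_gse <- function(data, gse_items, gse_node) {
  idx <- match(gse_items, data$item_codes)
  if (anyNA(idx)) stop("gse_items not found in the wave")
  comp <- gse_component(data$values[, idx, drop = FALSE])
  scores <- comp$scores
  s <- sd(scores, na.rm = TRUE)
  if (s > 0) scores <- scores / s   # standardized before entering the network
  keep <- setdiff(seq_along(data$item_codes), idx)
  V <- cbind(data$values[, keep, drop = FALSE], scores)
  codes <- c(data$item_codes[keep], gse_node)
  kinds <- c(data$item_kind[keep], "continuous")
  list(data = ordinal_dataset(V, item_codes = codes, item_kind = kinds,
                              time_label = data$time_label,
                              subject_ids = data$subject_ids),
       component = comp)
}

#' Run the full longitudinal network study
#'
#' Orchestrates the whole analysis: per wave, optional principal-component
#' reduction of the self-efficacy items, latent correlation matrix, EBIC
#' graphical-lasso network, centrality, and (if requested) edge-accuracy and
#' case-dropping bootstraps; across waves, complete-case filtering, all
#' pairwise dependent network comparison tests, and the similarity report.
#' Every stochastic stage derives its seed from `config$seed`, so a re-run
#' with the same configuration is identical.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report` (a list with per-wave results and
#'   cross-wave comparisons); if `config$out_dir` is set, CSV/GraphML/JSON
#'   outputs are written there, including a `summary.json` with provenance
#'   (seed, package version, configuration echo).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  labs <- names(config$waves)
  if (is.null(labs)) labs <- paste0("T", seq_along(config$waves))

  waves <- list()
  components <- list()
  networks <- list()
  centralities <- list()
  boots <- list()
  stabilities <- list()

  for (i in seq_along(config$waves)) {
    w <- config$waves[[i]]
    data <- if (inherits(w, "ordinal_dataset")) w else
      load_wave(w, config$roster, time_label = labs[i])
    message(sprintf("[%s] loaded: %d subjects x %d items", labs[i],
                    nrow(data$values), ncol(data$values)))
    comp <- NULL
    if (!is.null(config$gse_items)) {
      red <- reduce_gse(data, config$gse_items, config$gse_node)
      data <- red$data
      comp <- red$component
      message(sprintf("[%s] first component of %d items explains %.2f%% of variance",
                      labs[i], length(config$gse_items),
                      comp$variance_explained))
    }
    waves[[labs[i]]] <- data
    components[[labs[i]]] <- comp

    net <- estimate_network(data, config$ggm,
                            min_pairwise_n = config$min_pairwise_n)
    message(sprintf("[%s] network: %d edges, lambda = %.4g, global strength = %.3f",
                    labs[i], net$n_edges, net$lambda_selected,
                    net$global_strength))
    networks[[labs[i]]] <- net
    cent <- centrality_table(net)
    centralities[[labs[i]]] <- cent

    if (!is.null(out_dir)) {
      prefix <- file.path(out_dir, paste0("network_", labs[i]))
      write_network(net, prefix)
      write.csv(net$correlations$R,
                file.path(out_dir, paste0("correlations_", labs[i], ".csv")),
                row.names = TRUE)
      long <- do.call(rbind, lapply(c("strength", "betweenness", "closeness"),
        function(m) data.frame(node = cent$node, metric = m, raw = cent[[m]],
                               z = cent[[paste0("z_", m)]])))
      write.csv(long, file.path(out_dir, paste0("centrality_", labs[i], ".csv")),
                row.names = FALSE)
    }

    if (!is.null(config$bootstrap) &&
        (is.null(config$bootstrap_waves) || labs[i] %in% config$bootstrap_waves)) {
      spec <- config$bootstrap
      spec$seed <- config$seed + 100L * i
      spec$kind <- "nonparametric"
      boots[[labs[i]]] <- nonparametric_boot(data, spec, config$ggm,
                                             config$min_pairwise_n)
      spec$kind <- "case_dropping"
      stabilities[[labs[i]]] <- case_dropping_boot(
        data, spec, metric = config$stability_metric, config = config$ggm,
        min_pairwise_n = config$min_pairwise_n)
      message(sprintf("[%s] CS(%s) = %.2f", labs[i], config$stability_metric,
                      stabilities[[labs[i]]]$cs_coefficient))
      if (!is.null(out_dir)) {
        write.csv(boots[[labs[i]]]$table,
                  file.path(out_dir, paste0("edge_ci_", labs[i], ".csv")),
                  row.names = FALSE)
        write.csv(stabilities[[labs[i]]]$correlations,
                  file.path(out_dir, paste0("stability_", labs[i], ".csv")),
                  row.names = FALSE)
      }
    }
  }

  ncts <- NULL
  similarity <- NULL
  cc_n <- NA_integer_
  if (length(waves) >= 2) {
    cc <- complete_case_filter(waves, items = config$nct_items)
    cc_n <- cc$n_retained
    message(sprintf("complete cases across %d waves: %d subjects",
                    length(waves), cc_n))
    pairs <- combn(seq_along(waves), 2)
    ncts <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      res <- nct_dependent(cc$waves[[i]], cc$waves[[j]],
                           n_perm = config$n_perm, config = config$ggm,
                           seed = config$seed + 10000L + k,
                           min_pairwise_n = config$min_pairwise_n)
      message(sprintf("NCT %s vs %s: p_structure = %.3f, p_strength = %.3f",
                      labs[i], labs[j], res$p_structure, res$p_strength))
      res
    })
    names(ncts) <- apply(pairs, 2, function(ij)
      paste(labs[ij[1]], labs[ij[2]], sep = "_"))
    similarity <- similarity_report(networks)
    if (!is.null(out_dir))
      write.csv(similarity, file.path(out_dir, "similarity.csv"),
                row.names = FALSE)
  } else {
    message("single wave: comparison and similarity stages skipped")
  }

  summary <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("longnet")),
    r_version = R.version.string,
    waves = labs,
    n_subjects = vapply(waves, function(w) nrow(w$values), 1L),
    global_strength = vapply(networks, global_strength, 1.0),
    n_edges = vapply(networks, function(n) n$n_edges, 1L),
    lambda_selected = vapply(networks, function(n) n$lambda_selected, 1.0),
    variance_explained = if (length(components) && !is.null(components[[1]]))
      vapply(components, function(c) c$variance_explained, 1.0) else NULL,
    complete_case_n = cc_n,
    cs_coefficient = if (length(stabilities))
      vapply(stabilities, function(s) s$cs_coefficient, 1.0) else NULL,
    nct = if (!is.null(ncts)) lapply(ncts, function(x)
      list(m = x$m_observed, s = x$s_observed,
           p_structure = x$p_structure, p_strength = x$p_strength)) else NULL,
    similarity = similarity)
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)

  structure(list(waves = waves, components = components, networks = networks,
                 centralities = centralities, bootstraps = boots,
                 stabilities = stabilities, ncts = ncts,
                 similarity = similarity, complete_case_n = cc_n,
                 summary = summary, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d waves (%s)\n", length(x$waves),
              paste(names(x$waves), collapse = ", ")))
  cat("global strength:",
      paste(sprintf("%.3f", x$summary$global_strength), collapse = ", "), "\n")
  invisible(x)
}
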