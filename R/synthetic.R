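#' Construct a ground-truth sparse partial-correlation network model
#'
#' Builds a random Gaussian graphical model with known sparse structure, to be
#' used as the generating truth for ordinal symptom data. Edges are sampled
#' independently with probability `edge_prob`; each present edge receives a
#' partial correlation drawn uniformly from `weight_range`. The precision
#' matrix starts as the identity plus the negated edge weights and, if needed,
#' is made positive definite by diagonal loading (adding `delta` to the
#' diagonal until the smallest eigenvalue is at least 0.05) followed by
#' rescaling to unit partial variances, which preserves the edge support.
#'
#' @param p number of nodes (items), at least 2.
#' @param edge_prob probability that any given node pair is connected.
#' @param weight_range length-2 numeric interval inside (-1, 1) from which
#'   edge partial correlations are drawn uniformly. Symptom networks are
#'   predominantly positive, hence the positive default.
#' @param seed integer seed; the model is fully reproducible from it.
#' @param n_levels number of ordinal categories per item (CES-D items have 4).
#' @param thresholds optional per-item cut points on the latent standard
#'   normal scale: a numeric vector of length `n_levels - 1` shared by all
#'   items, or a `p x (n_levels - 1)` matrix. Defaults to equal-probability
#'   categories, `qnorm(k / n_levels)`.
#' @param delta diagonal loading increment.
#' @param max_load maximum number of loading iterations before failing.
#'
#' @return An object of class `true_network_model` with elements `p`, `Omega`
#'   (precision matrix), `Pcor_true` (implied partial correlations, unit
#'   diagonal), `thresholds`, `n_levels`, and `seed`.
#' @export
make_true_network <- function(p, edge_prob, weight_range = c(0.15, 0.4),
                              seed = 1L, n_levels = 4L, thresholds = NULL,
                              delta = 0.05, max_load = 200L) {
  stopifnot(p >= 2, edge_prob > 0 || edge_prob == 0, edge_prob <= 1,
            length(weight_range) == 2,
            all(weight_range > -1), all(weight_range < 1),
            n_levels >= 2)
  set.seed(seed)
  A <- matrix(0, p, p)
  up <- upper.tri(A)
  n_pairs <- sum(up)
  present <- runif(n_pairs) < edge_prob
  w <- ifelse(present,
              runif(n_pairs, min(weight_range), max(weight_range)), 0)
  A[up] <- w
  A <- A + t(A)

  Omega <- diag(p) - A
  loads <- 0L
  while (min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values) < 0.05) {
    Omega <- Omega + delta * diag(p)
    loads <- loads + 1L
    if (loads > max_load)
      stop("precision matrix not positive definite after maximum diagonal-loading iterations")
  }
  d <- sqrt(diag(Omega))
  Omega <- Omega / outer(d, d)          # unit partial variances

  Pcor <- -Omega / sqrt(outer(diag(Omega), diag(Omega)))
  diag(Pcor) <- 1

  if (is.null(thresholds)) {
    thresholds <- qnorm(seq_len(n_levels - 1) / n_levels)
  }
  if (is.vector(thresholds)) {
    stopifnot(length(thresholds) == n_levels - 1)
    thresholds <- matrix(thresholds, nrow = p, ncol = n_levels - 1,
                         byrow = TRUE)
  }
  stopifnot(nrow(thresholds) == p, ncol(thresholds) == n_levels - 1,
            all(apply(thresholds, 1, function(t) all(diff(t) > 0)) |
                  n_levels == 2))

  structure(list(p = p, Omega = Omega, Pcor_true = Pcor,
                 thresholds = thresholds, n_levels = n_levels, seed = seed),
            class = "true_network_model")
}

#' Ordinal dataset container
#'
#' Subjects-by-items matrix of ordinal (or continuous) values with missing
#' entries as `NA`, item metadata, and a wave label.
#'
#' @param values numeric or integer matrix, subjects in rows.
#' @param item_codes character vector of column labels.
#' @param item_kind per-item kind: `"ordinal"`, `"binary"` or `"continuous"`.
#' @param time_label wave identifier such as `"T1"`.
#' @param subject_ids subject identifiers, defaults to row numbers.
#' @return An object of class `ordinal_dataset`.
#' @export
ordinal_dataset <- function(values, item_codes = colnames(values),
                            item_kind = rep("ordinal", ncol(values)),
                            time_label = "T1", subject_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(item_codes))
    item_codes <- paste0("item", seq_len(ncol(values)))
  stopifnot(length(item_codes) == ncol(values),
            length(item_kind) == ncol(values),
            all(item_kind %in% c("ordinal", "binary", "continuous")))
  disc <- item_kind != "continuous"
  if (any(disc)) {
    v <- values[, disc, drop = FALSE]
    obs <- v[!is.na(v)]
    if (length(obs) && any(obs != round(obs)))
      stop("ordinal/binary items must contain integer level codes")
  }
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(values))
  stopifnot(!anyDuplicated(subject_ids))
  colnames(values) <- item_codes
  structure(list(values = values, item_codes = item_codes,
                 item_kind = item_kind, time_label = time_label,
                 subject_ids = subject_ids),
            class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  cat(sprintf("ordinal_dataset: %d subjects x %d items (wave %s), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$time_label,
              100 * mean(is.na(x$values))))
  invisible(x)
}

# Latent correlation matrix implied by a model's precision matrix.
latent_sigma <- function(model) {
  S <- solve(model$Omega)
  d <- sqrt(diag(S))
  S / outer(d, d)
}

discretize_latent <- function(Z, thresholds) {
  X <- matrix(NA_integer_, nrow(Z), ncol(Z))
  for (j in seq_len(ncol(Z))) {
    X[, j] <- findInterval(Z[, j], thresholds[j, ])
  }
  X
}

#' Sample one wave of ordinal data from a ground-truth network model
#'
#' Draws latent vectors from the zero-mean multivariate normal whose
#' covariance is the (unit-variance rescaled) inverse of the model's precision
#' matrix, then discretizes each coordinate at the item's thresholds. Levels
#' are coded `0 ... n_levels - 1`.
#'
#' @param model a [make_true_network()] object.
#' @param n number of subjects.
#' @param seed integer seed.
#' @param time_label wave label for the resulting dataset.
#' @return An [ordinal_dataset()].
#' @export
sample_ordinal_wave <- function(model, n, seed = 1L, time_label = "T1") {
  stopifnot(inherits(model, "true_network_model"), n >= 1)
  set.seed(seed)
  R <- chol(latent_sigma(model))
  Z <- matrix(rnorm(n * model$p), n, model$p) %*% R
  X <- discretize_latent(Z, model$thresholds)
  ordinal_dataset(X, item_codes = paste0("item", seq_len(model$p)),
                  time_label = time_label)
}

#' Longitudinal sampling design
#'
#' @param n_subjects number of subjects.
#' @param n_timepoints number of waves (>= 1).
#' @param subject_corr within-subject latent correlation across waves, in
#'   `[0, 1)`; the shared subject-level latent component enters each wave with
#'   weight `sqrt(subject_corr)`.
#' @param missing_rate probability that a (subject, wave) observation is
#'   missing entirely (missing completely at random).
#' @param seed root integer seed; every dataset drawn under the design is
#'   reproducible from it.
#' @return An object of class `longitudinal_design`.
#' @export
longitudinal_design <- function(n_subjects, n_timepoints, subject_corr = 0,
                                missing_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, n_timepoints >= 1,
            subject_corr >= 0, subject_corr < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_subjects = n_subjects, n_timepoints = n_timepoints,
                 subject_corr = subject_corr, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "longitudinal_design")
}

#' Sample a longitudinal ordinal study with known network structure
#'
#' Generates one [ordinal_dataset()] per wave with aligned subjects. Within a
#' subject, the latent vectors of all waves share a common standard-normal
#' component with weight `sqrt(subject_corr)`, so that when all waves use the
#' same model the across-wave latent correlation of any item equals
#' `subject_corr`. Missingness is applied independently per (subject, wave)
#' by blanking the whole observation, emulating wave non-response.
#'
#' @param models a single [make_true_network()] model (recycled over waves) or
#'   a list with one model per wave; all must share `p` and `n_levels`.
#' @param design a [longitudinal_design()].
#' @return A list with `waves` (list of datasets labelled `T1`, `T2`, ...),
#'   `complete` (logical, subjects observed at every wave), `design`, `models`.
#' @export
sample_longitudinal <- function(models, design) {
  stopifnot(inherits(design, "longitudinal_design"))
  if (inherits(models, "true_network_model"))
    models <- rep(list(models), design$n_timepoints)
  stopifnot(length(models) == design$n_timepoints)
  p <- models[[1]]$p
  n_levels <- models[[1]]$n_levels
  for (m in models) {
    if (m$p != p || m$n_levels != n_levels)
      stop("all wave models must share the node count and number of levels")
  }
  n <- design$n_subjects
  tt <- design$n_timepoints
  c2 <- sqrt(design$subject_corr)
  e2 <- sqrt(1 - design$subject_corr)

  set.seed(design$seed)
  U <- matrix(rnorm(n * p), n, p)
  waves <- vector("list", tt)
  miss <- matrix(runif(n * tt) < design$missing_rate, n, tt)
  for (t in seq_len(tt)) {
    E <- matrix(rnorm(n * p), n, p)
    Z <- (c2 * U + e2 * E) %*% chol(latent_sigma(models[[t]]))
    X <- discretize_latent(Z, models[[t]]$thresholds)
    X[miss[, t], ] <- NA_integer_
    waves[[t]] <- ordinal_dataset(X,
                                  item_codes = paste0("item", seq_len(p)),
                                  time_label = paste0("T", t))
  }
  list(waves = waves, complete = rowSums(miss) == 0,
       design = design, models = models)
}

#' Write / read ground-truth models as JSON
#'
#' @param model a [make_true_network()] object.
#' @param path output file.
#' @return `write_true_network` returns `path` invisibly;
#'   `read_true_network` returns the reconstructed model.
#' @export
write_true_network <- function(model, path) {
  stopifnot(inherits(model, "true_network_model"))
  obj <- list(p = model$p, Omega = model$Omega,
              thresholds = model$thresholds, n_levels = model$n_levels,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_true_network
#' @export
read_true_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Omega <- as.matrix(obj$Omega)
  Pcor <- -Omega / sqrt(outer(diag(Omega), diag(Omega)))
  diag(Pcor) <- 1
  structure(list(p = obj$p, Omega = Omega, Pcor_true = Pcor,
                 thresholds = as.matrix(obj$thresholds),
                 n_levels = obj$n_levels, seed = obj$seed),
            class = "true_network_model")
}
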