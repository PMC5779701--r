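#' Network comparison statistics
#'
#' The structure statistic `M` is the maximum absolute edge-weight difference
#' over unordered node pairs; the global-strength statistic `S` is the
#' absolute difference of the two networks' global strengths.
#'
#' @param net_a,net_b `ggm_network` objects (or weight matrices) over the same
#'   node set in the same order.
#' @return Named numeric vector `c(M = ..., S = ...)`.
#' @export
nct_statistics <- function(net_a, net_b) {
  Wa <- net_weight_matrix(net_a)
  Wb <- net_weight_matrix(net_b)
  la <- colnames(Wa); lb <- colnames(Wb)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    bad <- union(setdiff(la, lb), setdiff(lb, la))
    if (length(bad) == 0) bad <- la[la != lb]
    stop("node sets differ or are ordered differently: ",
         paste(bad, collapse = ", "))
  }
  if (!all(dim(Wa) == dim(Wb))) stop("networks have different sizes")
  up <- upper.tri(Wa)
  c(M = max(abs(Wa[up] - Wb[up])),
    S = abs(sum(abs(Wa[up])) - sum(abs(Wb[up]))))
}

#' Dependent (paired) permutation network comparison test
#'
#' Tests network-structure invariance (maximum edge difference) and global
#' strength invariance between two waves measured on the same subjects. Each
#' permutation independently swaps, per subject with probability 1/2, the
#' subject's observation vectors between the two conditions — the standard
#' paired exchangeability scheme — and re-estimates both networks with the
#' full pipeline (latent correlations plus EBIC graphical lasso, identical
#' settings). P-values use the add-one convention
#' `(1 + #permuted >= observed) / (1 + n_perm)`, so they are never exactly 0.
#'
#' @param data_a,data_b [ordinal_dataset()] objects with identical subjects
#'   (paired design). Subjects with any missing value in either wave are
#'   removed first (complete-case analysis, as required by a paired
#'   permutation test).
#' @param n_perm number of permutations.
#' @param config a [ggm_config()] applied to the observed and every permuted
#'   estimation.
#' @param seed integer seed for the permutation stream.
#' @param min_pairwise_n passed to [correlation_matrix()].
#' @return An object of class `nct_result` with observed statistics
#'   (`m_observed`, `s_observed`), permutation distributions (`m_perm`,
#'   `s_perm`), `p_structure`, `p_strength`, `n_perm`, `n_subjects`,
#'   `n_redraws`, and `paired = TRUE`.
#' @export
nct_dependent <- function(data_a, data_b, n_perm = 1000,
                          config = ggm_config(), seed = 1L,
                          min_pairwise_n = 10) {
  stopifnot(inherits(data_a, "ordinal_dataset"),
            inherits(data_b, "ordinal_dataset"), n_perm >= 1)
  if (!identical(data_a$subject_ids, data_b$subject_ids))
    stop("paired comparison requires identical subjects in both datasets")
  if (!identical(data_a$item_codes, data_b$item_codes))
    stop("item sets differ between the two datasets")
  cc <- stats::complete.cases(data_a$values) &
    stats::complete.cases(data_b$values)
  if (!all(cc)) {
    data_a <- subset_dataset(data_a, which(cc), reindex = FALSE)
    data_b <- subset_dataset(data_b, which(cc), reindex = FALSE)
  }
  n <- nrow(data_a$values)
  if (n < min_pairwise_n) stop("too few complete-case subjects: ", n)

  est <- function(values, template) {
    d <- ordinal_dataset(values, item_codes = template$item_codes,
                         item_kind = template$item_kind,
                         time_label = template$time_label)
    estimate_network(d, config, min_pairwise_n = min_pairwise_n)
  }
  net_a <- est(data_a$values, data_a)
  net_b <- est(data_b$values, data_b)
  obs <- nct_statistics(net_a, net_b)

  m_perm <- numeric(n_perm)
  s_perm <- numeric(n_perm)
  n_redraws <- 0L
  set.seed(seed)
  b <- 1L
  while (b <= n_perm) {
    swap <- runif(n) < 0.5
    Va <- data_a$values
    Vb <- data_b$values
    Va[swap, ] <- data_b$values[swap, , drop = FALSE]
    Vb[swap, ] <- data_a$values[swap, , drop = FALSE]
    stat <- tryCatch({
      pa <- est(Va, data_a)
      pb <- est(Vb, data_b)
      nct_statistics(pa, pb)
    }, error = function(e) NULL)
    if (is.null(stat)) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > 0.1 * n_perm)
        stop("more than 10% of permutations required redrawing")
      next
    }
    m_perm[b] <- stat["M"]
    s_perm[b] <- stat["S"]
    b <- b + 1L
  }
  eps <- 1e-12
  structure(list(m_observed = unname(obs["M"]), s_observed = unname(obs["S"]),
                 m_perm = m_perm, s_perm = s_perm,
                 p_structure = (1 + sum(m_perm >= obs["M"] - eps)) / (1 + n_perm),
                 p_strength = (1 + sum(s_perm >= obs["S"] - eps)) / (1 + n_perm),
                 n_perm = n_perm, n_subjects = n, n_redraws = n_redraws,
                 paired = TRUE,
                 networks = list(a = net_a, b = net_b)),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf("paired network comparison test (n = %d, %d permutations)\n",
              x$n_subjects, x$n_perm))
  cat(sprintf("  structure invariance: M = %.4f, p = %.4f\n",
              x$m_observed, x$p_structure))
  cat(sprintf("  global strength invariance: S = %.4f, p = %.4f\n",
              x$s_observed, x$p_strength))
  invisible(x)
}
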