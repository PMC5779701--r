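#' Estimate latent-normal thresholds from an ordinal margin
#'
#' Cut point k is the standard-normal quantile of the cumulative proportion at
#' or below category k. Zero-mass categories (boundary or interior) contribute
#' no cut point; they are merged with their neighbour.
#'
#' @param x vector of ordinal level codes (integers, `NA` allowed).
#' @param item optional item name used in error messages.
#' @return Strictly increasing numeric vector of cut points.
#' @export
estimate_thresholds <- function(x, item = NULL) {
  x <- x[!is.na(x)]
  lab <- if (is.null(item)) "column" else paste0("item '", item, "'")
  if (length(x) == 0) stop(lab, " has no observed values")
  counts <- table(x)
  if (length(counts) < 2) stop(lab, " is constant; thresholds are undefined")
  cp <- cumsum(as.numeric(counts)) / length(x)
  th <- qnorm(cp[cp > 0 & cp < 1])
  unique(th)
}

#' Two-step maximum likelihood polychoric correlation of two ordinal variables
#'
#' Thresholds are fixed at the standard-normal quantiles of the pairwise
#' cumulative margins; the latent correlation then maximizes the bivariate
#' normal likelihood of the contingency table, constrained to
#' `[-0.999, 0.999]`. Binary variables are the tetrachoric special case of the
#' same likelihood.
#'
#' @param x,y ordinal level vectors of equal length (`NA` allowed; pairwise
#'   complete cases are used).
#' @param min_n minimum number of pairwise-complete cases.
#' @param tol optimizer tolerance.
#' @return The estimated correlation, with attribute `boundary` set to `TRUE`
#'   when the estimate lies at the constraint boundary (flat or monotone
#'   likelihood, e.g. an empty off-diagonal 2 x 2 table).
#' @export
polychoric_pair <- function(x, y, min_n = 10, tol = 1e-6) {
  stopifnot(length(x) == length(y))
  X <- cbind(as.integer(round(x)), as.integer(round(y)))
  res <- cpp_polychoric_pair(X, 1L, 2L, as.integer(min_n), 0.999, tol)
  if (res$flag == 2)
    stop("fewer than ", min_n, " pairwise-complete observations (", res$n, ")")
  if (res$flag == 3)
    stop("a variable is constant on the pairwise-complete subset")
  if (res$flag == 1)
    warning("polychoric estimate at the constraint boundary")
  structure(res$rho, boundary = res$flag == 1)
}

#' Polychoric correlation from a contingency table
#'
#' @param tab matrix of cell counts (rows = categories of the first variable).
#' @param tol optimizer tolerance.
#' @return As [polychoric_pair()], with threshold attributes.
#' @export
polychoric_table <- function(tab, tol = 1e-6) {
  tab <- as.matrix(tab)
  res <- cpp_polychoric_table(tab, 0.999, tol)
  if (res$flag == 3) stop("table has fewer than 2 non-empty rows or columns")
  if (res$flag == 1)
    warning("polychoric estimate at the constraint boundary")
  structure(res$rho, boundary = res$flag == 1,
            thresholds_row = res$thresholds_row,
            thresholds_col = res$thresholds_col)
}

#' Two-step maximum likelihood polyserial correlation
#'
#' Latent bivariate-normal correlation between an observed continuous variable
#' and an ordinal variable. The continuous margin is standardized empirically;
#' the ordinal thresholds come from its pairwise margin; the correlation then
#' maximizes the conditional likelihood of the ordinal categories given the
#' continuous values.
#'
#' @inheritParams polychoric_pair
#' @param x continuous values.
#' @param y ordinal level codes.
#' @return The estimated correlation (attribute `boundary` as in
#'   [polychoric_pair()]).
#' @export
polyserial_pair <- function(x, y, min_n = 10, tol = 1e-6) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n)
    stop("fewer than ", min_n, " pairwise-complete observations")
  if (sd(x) == 0) stop("continuous variable has zero variance")
  if (length(unique(y)) < 2)
    stop("ordinal variable is constant on the pairwise-complete subset")
  z <- (x - mean(x)) / sd(x)
  th <- estimate_thresholds(y)
  cuts <- c(-Inf, th, Inf)
  ylev <- match(y, sort(unique(y)))
  lo <- cuts[ylev]
  hi <- cuts[ylev + 1L]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- pnorm((hi - rho * z) / s) - pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-12)))
  }
  opt <- optimize(nll, c(-0.999, 0.999), tol = tol)
  rho <- opt$minimum
  # optimize() never touches the endpoints; pick them up explicitly
  for (b in c(-0.999, 0.999)) if (nll(b) < opt$objective) rho <- b
  boundary <- abs(abs(rho) - 0.999) < 1e-4
  if (boundary) warning("polyserial estimate at the constraint boundary")
  structure(rho, boundary = boundary)
}

#' Repair an indefinite correlation matrix to positive definiteness
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to it, the matrix
#' is reconstructed and rescaled to unit diagonal. Already positive definite
#' input is returned unchanged, so the operation is idempotent.
#'
#' @param R symmetric matrix.
#' @param floor smallest admissible eigenvalue.
#' @return Symmetric positive definite matrix with unit diagonal.
#' @export
nearest_pd_repair <- function(R, floor = 1e-6) {
  stopifnot(isSymmetric(unname(R), tol = 1e-8))
  out <- R
  # rescaling to unit diagonal can nudge the smallest eigenvalue back under
  # the floor, so clip repeatedly (converges in a couple of passes)
  for (i in 1:20) {
    e <- eigen((out + t(out)) / 2, symmetric = TRUE)
    if (min(e$values) >= floor) return(out)
    v <- pmax(e$values, floor)
    out <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(out))
    out <- out / outer(d, d)
    out <- (out + t(out)) / 2
    diag(out) <- 1
    dimnames(out) <- dimnames(R)
  }
  out
}

#' Mixed-type latent correlation matrix of an ordinal dataset
#'
#' Per-pair dispatch on item kinds: ordinal-ordinal (and binary, treated as a
#' 2-level ordinal, i.e. tetrachoric) pairs get the two-step polychoric
#' estimate; continuous-ordinal pairs the polyserial estimate;
#' continuous-continuous pairs the product-moment correlation. With
#' `pairwise_complete = TRUE` every pair uses all subjects observed on that
#' pair; otherwise listwise deletion is applied first. An indefinite result is
#' passed through [nearest_pd_repair()].
#'
#' @param data an [ordinal_dataset()].
#' @param pairwise_complete use pairwise-complete observations (default) or
#'   listwise deletion.
#' @param min_pairwise_n minimum pairwise-complete count per pair; pairs below
#'   it raise an error naming the offending pairs.
#' @param tol optimizer tolerance for the latent correlations.
#' @return An object of class `correlation_matrix_est`: `R` (the matrix),
#'   `thresholds` (per ordinal item, from its full observed margin),
#'   `n_pairwise`, `pd_repaired`, `boundary` (logical matrix of
#'   boundary-constrained pairs).
#' @export
correlation_matrix <- function(data, pairwise_complete = TRUE,
                               min_pairwise_n = 10, tol = 1e-6) {
  stopifnot(inherits(data, "ordinal_dataset"))
  V <- data$values
  p <- ncol(V)
  if (p < 3) stop("at least 3 items are required")
  if (!pairwise_complete) V <- V[stats::complete.cases(V), , drop = FALSE]
  kind <- data$item_kind
  disc <- kind %in% c("ordinal", "binary")
  codes <- data$item_codes

  R <- diag(p)
  Np <- matrix(NA_integer_, p, p)
  bound <- matrix(FALSE, p, p)
  diag(Np) <- colSums(!is.na(V))

  if (any(disc)) {
    Xo <- V[, disc, drop = FALSE]
    storage.mode(Xo) <- "integer"
    res <- cpp_polychoric_matrix(Xo, as.integer(min_pairwise_n), 0.999, tol)
    bad <- which(res$flag >= 2 & upper.tri(res$flag), arr.ind = TRUE)
    if (nrow(bad)) {
      oc <- codes[disc]
      stop("correlation undefined for pairs: ",
           paste(oc[bad[, 1]], oc[bad[, 2]], sep = "-", collapse = ", "),
           " (too few pairwise-complete cases or constant on subset)")
    }
    idx <- which(disc)
    R[idx, idx] <- res$R
    Np[idx, idx] <- res$n_pairwise
    bound[idx, idx] <- res$flag == 1
  }

  cont <- which(!disc)
  if (length(cont)) {
    for (a in cont) {
      for (b in seq_len(p)) {
        if (b == a || (b %in% cont && b < a)) next
        ok <- !is.na(V[, a]) & !is.na(V[, b])
        Np[a, b] <- Np[b, a] <- sum(ok)
        if (sum(ok) < min_pairwise_n)
          stop("correlation undefined for pair ", codes[a], "-", codes[b],
               ": only ", sum(ok), " pairwise-complete cases")
        if (b %in% cont) {
          r <- cor(V[ok, a], V[ok, b])
        } else {
          r <- suppressWarnings(
            polyserial_pair(V[ok, a], V[ok, b], min_n = min_pairwise_n,
                            tol = tol))
          bound[a, b] <- bound[b, a] <- isTRUE(attr(r, "boundary"))
          r <- as.numeric(r)
        }
        R[a, b] <- R[b, a] <- r
      }
    }
  }

  dimnames(R) <- list(codes, codes)
  thresholds <- lapply(which(disc), function(j)
    estimate_thresholds(V[, j], item = codes[j]))
  names(thresholds) <- codes[disc]

  pd_repaired <- FALSE
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    R <- nearest_pd_repair(R)
    pd_repaired <- TRUE
  }

  structure(list(R = R, thresholds = thresholds, n_pairwise = Np,
                 pd_repaired = pd_repaired, boundary = bound,
                 item_codes = codes),
            class = "correlation_matrix_est")
}

#' @export
print.correlation_matrix_est <- function(x, ...) {
  cat(sprintf("latent correlation matrix: %d items%s\n", ncol(x$R),
              if (x$pd_repaired) " (PD-repaired)" else ""))
  invisible(x)
}

#' Bivariate standard normal distribution function
#'
#' `P(X <= h, Y <= k)` for correlation `rho`, vectorized over its arguments
#' (recycled to a common length). Absolute accuracy is about 1e-8 or better.
#'
#' @param h,k upper limits (may be infinite).
#' @param rho correlation in `[-1, 1]`.
#' @return Numeric vector of probabilities.
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  cpp_pbvnorm(rep_len(as.numeric(h), n), rep_len(as.numeric(k), n),
              rep_len(as.numeric(rho), n))
}
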