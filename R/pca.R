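## Principal-component basis of the docking-score matrix and predictive-axis
## selection.  Columns (probe proteins) are centred but not standardised:
## all scores share a kcal/mol-like unit, and the projection subtracts the
## per-protein mean only.

#' Principal-component basis of a docking-score matrix
#'
#' Column-centres the score matrix and decomposes it by SVD.  Loading columns
#' are orthonormal and ordered by non-increasing explained variance.  Signs
#' are fixed deterministically (the largest-magnitude entry of each loading is
#' made positive) so repeated runs and platforms agree.
#'
#' @param scores numeric matrix, compounds x probe proteins, with compound ids
#'   as rownames and protein ids as colnames.  All entries must be finite.
#' @return object of class `dsq_pca`: `center` (per-protein score means),
#'   `loadings` (proteins x components), `explained_variance` (per-axis
#'   variance of the projected training data), `scores` (training projection,
#'   compounds x components), `protein_ids`, `compound_ids`.
#' @examples
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("c", 1:8), paste0("p", 1:5)))
#' b <- score_pca(m)
#' crossprod(b$loadings)  # identity
#' @export
score_pca <- function(scores) {
  assert_score_matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 compounds for PCA", call. = FALSE)
  ctr <- colMeans(scores)
  xc <- sweep(scores, 2L, ctr)
  sv <- svd(xc)
  k <- length(sv$d)
  loadings <- sv$v
  proj <- sv$u * rep(sv$d, each = n)
  for (j in seq_len(k)) {               # deterministic sign convention
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      proj[, j] <- -proj[, j]
    }
  }
  axis_names <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(colnames(scores), axis_names)
  dimnames(proj) <- list(rownames(scores), axis_names)
  structure(list(center = ctr, loadings = loadings,
                 explained_variance = sv$d^2 / (n - 1),
                 scores = proj,
                 protein_ids = colnames(scores),
                 compound_ids = rownames(scores)),
            class = "dsq_pca")
}

#' @export
print.dsq_pca <- function(x, ...) {
  cat(sprintf("Docking-score PCA basis: %d proteins, %d compounds, %d axes\n",
              length(x$protein_ids), length(x$compound_ids),
              ncol(x$loadings)))
  ev <- x$explained_variance
  cat(sprintf("  explained variance: %.3g (PC1) .. %.3g (PC%d)\n",
              ev[1L], ev[length(ev)], length(ev)))
  invisible(x)
}

#' Project compounds onto a principal-component basis
#'
#' `p_ij = sum_b d_bj (s_ib - mean_b)`: the centred score vector of each
#' compound is projected onto the loading vectors.  Columns are matched to
#' the basis by protein id, not by position.
#'
#' @param scores score matrix whose colnames cover exactly the basis proteins.
#' @param basis a [score_pca()] result.
#' @param axes integer indices of basis axes (default: all).
#' @return matrix of coordinates, compounds x selected axes.
#' @export
project_scores <- function(scores, basis, axes = NULL) {
  if (is.null(dim(scores))) scores <- t(as.matrix(scores))
  assert_score_matrix(scores)
  if (!inherits(basis, "dsq_pca"))
    stop("basis must be a score_pca() result", call. = FALSE)
  missing_ids <- setdiff(basis$protein_ids, colnames(scores))
  extra_ids <- setdiff(colnames(scores), basis$protein_ids)
  if (length(missing_ids) > 0L || length(extra_ids) > 0L)
    stop("protein ids do not match the basis; missing: {",
         paste(missing_ids, collapse = ", "), "}; extra: {",
         paste(extra_ids, collapse = ", "), "}", call. = FALSE)
  axes <- axes %||% seq_len(ncol(basis$loadings))
  xc <- sweep(scores[, basis$protein_ids, drop = FALSE], 2L, basis$center)
  xc %*% basis$loadings[, axes, drop = FALSE]
}

## Exact leave-one-out predictions of the restrained fit (intercept
## unpenalised) via the linear-smoother identity e_i / (1 - h_ii).
## Returns -Inf criterion on degenerate designs.
loo_cor_penalized <- function(P, y, lambda) {
  n <- length(y)
  X <- cbind(P, 1)
  pen <- diag(c(rep(lambda, ncol(P)), 0), ncol(X))
  A <- crossprod(X) + pen
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(-Inf)
  B <- X %*% Ainv
  h <- rowSums(B * X)
  if (any(h >= 1 - 1e-8)) return(-Inf)
  theta <- Ainv %*% crossprod(X, y)
  e <- y - drop(X %*% theta)
  pred <- y - e / (1 - h)
  ct <- suppressWarnings(stats::cor(pred, y))
  if (is.na(ct)) -Inf else ct
}

#' Select predictive principal-component axes
#'
#' Greedy forward selection: starting from the empty set, the axis whose
#' inclusion maximises the leave-one-out cross-validated Pearson correlation
#' of the ridge-restrained fit is added, until no axis improves the criterion
#' or `max_axes` are selected.  Leave-one-out predictions are exact (computed
#' through the penalised-least-squares smoother identity, with a fast
#' additive path when the candidate columns are orthogonal and centred, as
#' training-fold PC scores always are).  Ties break to the lowest axis index.
#'
#' With `exhaustive = TRUE` (at most 12 candidate axes) every non-empty
#' subset is scored instead — a verification mode for the greedy search.
#'
#' @param projection compounds x axes coordinate matrix (e.g. the `scores`
#'   element of [score_pca()]).
#' @param y experimental free energies, one per row of `projection`.
#' @param lambda ridge restraint used inside the selection criterion.
#' @param max_axes upper bound on the number of selected axes.
#' @param exhaustive score all subsets instead of the greedy path.
#' @return list with `axes` (selected column indices, in selection order) and
#'   `trace` (the LOO correlation after each greedy step; non-decreasing).
#' @export
select_axes <- function(projection, y, lambda = 1e-4, max_axes = NULL,
                        exhaustive = FALSE) {
  P <- as.matrix(projection)
  n <- nrow(P); m <- ncol(P)
  if (length(y) != n)
    stop("length(y) must equal nrow(projection)", call. = FALSE)
  if (n < 3L) stop("need at least 3 compounds to select axes", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("y is constant; the correlation criterion is undefined",
         call. = FALSE)
  max_axes <- max_axes %||% m
  cap <- min(max_axes, m)
  if (cap < 1L) stop("max_axes must be at least 1", call. = FALSE)

  if (exhaustive) {
    if (m > 12L)
      stop("exhaustive search supports at most 12 candidate axes",
           call. = FALSE)
    best <- NULL; best_crit <- -Inf
    for (mask in seq_len(2L^m - 1L)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
      if (length(sel) > cap) next
      crit <- loo_cor_penalized(P[, sel, drop = FALSE], y, lambda)
      if (crit > best_crit + 1e-12 ||
          (abs(crit - best_crit) <= 1e-12 && !is.null(best) &&
           length(sel) < length(best))) {
        best <- sel; best_crit <- crit
      }
    }
    return(list(axes = best, trace = best_crit))
  }

  q <- colSums(P^2)
  usable <- q > 1e-12 * max(q, 1)
  if (lambda > 0) usable <- usable | TRUE
  usable <- usable & (q + lambda > 0)
  colm <- colSums(P) / n
  offd <- if (m > 1L) {
    G <- crossprod(P)
    max(abs(G - diag(diag(G), m)))
  } else 0
  orthogonal <- offd <= 1e-8 * max(q, 1) &&
    max(abs(colm)) <= 1e-8 * sqrt(max(q, 1) / n + 1)

  sel <- integer()
  trace <- numeric()
  if (orthogonal) {
    denom <- q + lambda
    cj <- drop(crossprod(P, y)) / denom
    P2 <- P^2
    e <- y - mean(y)
    h <- rep(1 / n, n)
    best_crit <- -Inf
    while (length(sel) < cap) {
      rem <- setdiff(which(usable), sel)
      if (length(rem) == 0L) break
      Ecand <- e - P[, rem, drop = FALSE] *
        rep(cj[rem], each = n)
      Hcand <- h + P2[, rem, drop = FALSE] *
        rep(1 / denom[rem], each = n)
      Pred <- y - Ecand / (1 - Hcand)
      bad <- apply(Hcand, 2L, max) >= 1 - 1e-8
      crit <- suppressWarnings(drop(stats::cor(Pred, y)))
      crit[is.na(crit) | bad] <- -Inf
      jbest <- which.max(crit)           # first max = lowest axis index
      if (crit[jbest] <= best_crit) break
      j <- rem[jbest]
      sel <- c(sel, j)
      trace <- c(trace, unname(crit[jbest]))
      best_crit <- crit[jbest]
      e <- e - cj[j] * P[, j]
      h <- h + P2[, j] / denom[j]
    }
  } else {
    best_crit <- -Inf
    while (length(sel) < cap) {
      rem <- setdiff(which(usable), sel)
      if (length(rem) == 0L) break
      crit <- vapply(rem, function(j)
        loo_cor_penalized(P[, c(sel, j), drop = FALSE], y, lambda),
        numeric(1))
      jbest <- which.max(crit)
      if (crit[jbest] <= best_crit) break
      sel <- c(sel, rem[jbest])
      trace <- c(trace, unname(crit[jbest]))
      best_crit <- crit[jbest]
    }
  }
  if (length(sel) == 0L)
    stop("no usable axis found (degenerate projection)", call. = FALSE)
  list(axes = sel, trace = trace)
}
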