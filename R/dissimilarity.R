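#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' `d(i, j) = sum |y_i - y_j| / sum (y_i + y_j)` between sites, by default
#' after a `log(x + 1)` transform that down-weights the influence of extreme
#' abundances. A pair of all-zero sites has undefined Bray-Curtis
#' dissimilarity; it is reported as 0 with a warning.
#'
#' @param m A [community_matrix()] or non-negative matrix.
#' @param transform `"log1p"` (natural log of x + 1, default) or `"none"`.
#' @return Symmetric n x n matrix in `[0, 1]` with attribute `transform`.
#' @export
bray_curtis <- function(m, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  Y <- if (inherits(m, "community_matrix")) m$counts else as.matrix(m)
  if (any(Y < 0)) stop("abundances must be non-negative")
  Yt <- if (transform == "log1p") log1p(Y) else Y
  D <- as.matrix(suppressWarnings(vegan::vegdist(Yt, method = "bray")))
  if (any(is.nan(D)) || any(rowSums(Yt) == 0)) {
    warning("all-zero site(s): affected dissimilarities set to 0")
    D[is.nan(D)] <- 0
  }
  dimnames(D) <- list(rownames(Y), rownames(Y))
  attr(D, "transform") <- transform
  D
}

#' Non-metric multidimensional scaling
#'
#' Ordination of a dissimilarity matrix minimising Kruskal's stress-1 (the
#' 0-1 ratio form) with monotone regression of configuration distances on
#' dissimilarity ranks, taking the best of `n_starts` random starts plus a
#' metric-scaling start.
#'
#' @param D Dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Number of ordination dimensions (default 2).
#' @param n_starts Random starts (default 20).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed.
#' @return Object of class `nmds_result`: list with `points` (n x k, centred),
#'   `stress` (stress-1 in `[0, 1]`), `converged`, `n_starts`, `seed`.
#' @export
nmds_ordination <- function(D, k = 2, n_starts = 20, max_iter = 300, seed = 1) {
  D <- stats::as.dist(D)
  n <- attr(D, "Size")
  if (n < k + 2) stop("need at least k + 2 sites")
  rs <- .seed_stream(seed)
  fit <- vegan::metaMDS(D, k = k, try = n_starts, trymax = n_starts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  .restore_seed(rs)
  pts <- .center(fit$points)
  structure(list(points = pts, stress = fit$stress,
                 converged = fit$converged > 0, n_starts = n_starts,
                 seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Classical metric scaling keeping the positive-eigenvalue axes (at most
#' `k`). Used to place period-wise community structure in a common Euclidean
#' space before Procrustes comparison.
#'
#' @param D Dissimilarity matrix.
#' @param k Maximum number of axes (default `min(n - 1, 10)`).
#' @return n x k' coordinate matrix (k' <= k positive-eigenvalue axes).
#' @export
pcoa_config <- function(D, k = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(k)) k <- min(n - 1, 10)
  # negative-eigenvalue axes are filtered below; cmdscale's axis-count
  # warning is redundant here
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = min(k, n - 1),
                                          eig = TRUE))
  pos <- which(fit$eig[seq_len(ncol(fit$points))] > 1e-9 * max(fit$eig))
  pts <- fit$points[, pos, drop = FALSE]
  rownames(pts) <- rownames(D)
  pts
}

#' Procrustes comparison of two configurations (PROTEST)
#'
#' Symmetric Procrustes analysis: both configurations are centred and scaled
#' to unit trace, and the optimal rotation (reflections allowed) is found by
#' singular value decomposition. The statistic `m2` is the residual sum of
#' squares; `correlation = sqrt(1 - m2)`. Significance is assessed by
#' permuting the rows of one configuration (PROTEST), with the plus-one
#' p-value estimator.
#'
#' @param conf_a,conf_b Numeric matrices with identical row counts, rows
#'   matched one-to-one (same sites in the same order).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `protest_result`: list with `m2`, `correlation`,
#'   `p`, `n_perm`, `seed`.
#' @export
procrustes_protest <- function(conf_a, conf_b, n_perm = 999, seed = 1) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (nrow(conf_a) != nrow(conf_b)) stop("configurations have different row counts")
  if (!is.null(rownames(conf_a)) && !is.null(rownames(conf_b)) &&
      !identical(rownames(conf_a), rownames(conf_b)))
    stop("row identities differ between configurations")
  rs <- .seed_stream(seed)
  fit <- vegan::protest(conf_a, conf_b, permutations = n_perm, symmetric = TRUE)
  .restore_seed(rs)
  structure(list(m2 = fit$ss, correlation = sqrt(max(0, 1 - fit$ss)),
                 p = fit$signif, n_perm = n_perm, seed = seed),
            class = "protest_result")
}

#' @export
print.protest_result <- function(x, ...) {
  cat(sprintf("PROTEST: correlation = %.3f, m2 = %.3f, p = %.3g (%d permutations)\n",
              x$correlation, x$m2, x$p, x$n_perm))
  invisible(x)
}

#' Concordance of two sampling periods
#'
#' Justifies pooling periods: each period's community matrix is turned into
#' a Bray-Curtis matrix on `log(x + 1)` abundances, embedded by principal
#' coordinates, and the two configurations compared by
#' [procrustes_protest()]. A strong, significant correlation supports
#' analysing the pooled data.
#'
#' @param m_a,m_b `community_matrix` objects for the two periods (same
#'   sites).
#' @param k Maximum PCoA dimensionality (default `min(n - 1, 10)`).
#' @param n_perm,seed Passed to [procrustes_protest()].
#' @return A `protest_result`.
#' @export
period_concordance <- function(m_a, m_b, k = NULL, n_perm = 999, seed = 1) {
  sa <- sites(m_a)
  if (!setequal(sa, sites(m_b))) stop("periods cover different site sets")
  idx <- match(sa, sites(m_b))
  mb <- community_matrix(m_b$counts[idx, , drop = FALSE], period = m_b$period)
  pa <- pcoa_config(bray_curtis(m_a), k = k)
  pb <- pcoa_config(bray_curtis(mb), k = k)
  kk <- min(ncol(pa), ncol(pb))
  procrustes_protest(pa[, seq_len(kk), drop = FALSE],
                     pb[, seq_len(kk), drop = FALSE],
                     n_perm = n_perm, seed = seed)
}
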