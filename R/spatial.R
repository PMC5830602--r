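#' Geographic distance matrix between sites
#'
#' @param coords Data frame with `site_id`, `latitude`, `longitude`
#'   (decimal degrees) for `method = "haversine"`, or `site_id`, `x`, `y`
#'   (already-projected planar coordinates, km) for `method = "euclidean"`.
#' @param method `"haversine"` (great-circle, default) or `"euclidean"`.
#' @return Symmetric n x n matrix of distances in km with site ids as
#'   dimnames and attribute `method`.
#' @export
distance_matrix <- function(coords, method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  if (nrow(coords) < 2) stop("need at least 2 sites")
  ids <- trimws(as.character(coords$site_id))
  if (anyDuplicated(ids)) stop("duplicate site ids in coordinates")
  if (method == "haversine") {
    if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180))
      stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
    D <- geosphere::distm(cbind(coords$longitude, coords$latitude),
                          fun = geosphere::distHaversine) / 1000
  } else {
    D <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  }
  dimnames(D) <- list(ids, ids)
  if (any(D[upper.tri(D)] == 0))
    warning("two distinct sites share identical coordinates (zero distance)")
  attr(D, "method") <- method
  D
}

#' Truncation threshold from the minimum spanning tree
#'
#' The dbMEM truncation distance is the longest distance connecting two
#' neighbouring sites, i.e. the maximum edge weight of the minimum spanning
#' tree of the complete graph on the distance matrix: the smallest distance
#' that keeps all sites connected.
#'
#' @param D Symmetric distance matrix.
#' @return Threshold distance (same units as `D`).
#' @export
truncation_threshold <- function(D) {
  max(mst_edges(D)$weight)
}

# Prim's algorithm; returns the n-1 MST edges (from, to, weight).
mst_edges <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 sites for a spanning tree")
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]; parent <- rep(1L, n)
  from <- to <- integer(n - 1); w <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    from[k] <- parent[j]; to[k] <- j; w[k] <- best[j]
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best
    best[upd] <- D[j, upd]; parent[upd] <- j
  }
  data.frame(from = from, to = to, weight = w)
}

#' Distance-based Moran eigenvector maps
#'
#' Builds spatial eigenfunction predictors from a geographic distance
#' matrix: distances beyond the truncation threshold are replaced by an
#' arbitrarily large value equal to four times the threshold; the modified
#' matrix is Gower-centred (`-d^2/2`, double-centred) and
#' eigen-decomposed. Eigenvectors with positive eigenvalues are retained and
#' ordered by decreasing eigenvalue, so dbMEM 1 models the broadest-scale
#' spatial structure and the last dbMEM the finest. Each retained vector's
#' Moran's I (binary neighbourhood at the threshold) is reported.
#'
#' Column signs are normalised so the first non-zero loading of each vector
#' is positive (eigenvector sign being arbitrary).
#'
#' @param D Symmetric distance matrix (km), e.g. from [distance_matrix()].
#' @param threshold Truncation distance; default the MST longest edge via
#'   [truncation_threshold()].
#' @return Object of class `mem_basis`: list with `vectors` (n x k,
#'   unit-norm zero-mean columns named `dbMEM1..k`), `values` (positive,
#'   descending), `morans_i`, `threshold_km`, `site_ids`.
#' @export
dbmem <- function(D, threshold = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(threshold)) threshold <- truncation_threshold(D)
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be positive")
  Dstar <- ifelse(D > threshold, 4 * threshold, D)
  diag(Dstar) <- 0
  A <- -0.5 * Dstar^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  if (!any(keep)) stop("no positive eigenvalues: degenerate configuration")
  V <- e$vectors[, keep, drop = FALSE]
  lambda <- e$values[keep]
  # fix arbitrary signs: first non-negligible loading positive
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (V[nz, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(rownames(D), paste0("dbMEM", seq_len(ncol(V))))
  mi <- vapply(seq_len(ncol(V)), function(j) morans_i(V[, j], D, threshold), numeric(1))
  structure(list(vectors = V, values = lambda, morans_i = mi,
                 threshold_km = threshold, site_ids = rownames(D)),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("mem_basis: %d dbMEMs over %d sites, truncation = %.3f km\n",
              ncol(x$vectors), nrow(x$vectors), x$threshold_km))
  print(data.frame(eigenvalue = x$values, morans_i = x$morans_i,
                   row.names = colnames(x$vectors)))
  invisible(x)
}

#' Moran's I of a vector under binary threshold connectivity
#'
#' `I = (n / W) * sum_ij w_ij v_i v_j / sum_i v_i^2` with `w_ij = 1` iff
#' `0 < d_ij <= threshold`, using deviations of `v` from its mean.
#'
#' @param v Numeric vector over sites.
#' @param D Distance matrix.
#' @param threshold Neighbourhood distance.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(v, D, threshold) {
  D <- as.matrix(D)
  n <- length(v)
  stopifnot(nrow(D) == n)
  W <- (D <= threshold) * 1
  diag(W) <- 0
  sw <- sum(W)
  if (sw == 0) stop("empty neighbourhood: threshold below all distances")
  z <- v - mean(v)
  (n / sw) * drop(crossprod(z, W %*% z)) / sum(z^2)
}
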