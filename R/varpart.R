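#' Hellinger transformation
#'
#' Square root of relative abundance per site:
#' `y'_ij = sqrt(y_ij / sum_j y_ij)`. Makes abundance data suitable for
#' Euclidean-based linear ordination (RDA) by removing the double-zero
#' problem and down-weighting dominant taxa. Every transformed row has unit
#' sum of squares.
#'
#' @param Y Non-negative abundance matrix (sites x species) or a
#'   [community_matrix()].
#' @return Matrix of the same shape, class `hellinger_matrix`, with
#'   attribute `row_totals` (original row sums).
#' @export
hellinger <- function(Y) {
  if (inherits(Y, "community_matrix")) Y <- Y$counts
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("abundances must be non-negative")
  rs <- rowSums(Y)
  if (any(rs == 0))
    stop("all-zero row(s): ", paste(rownames(Y)[rs == 0], collapse = ", "),
         " (remove empty sites before transforming)")
  if (all(abs(rowSums(Y^2) - 1) < 1e-8))
    warning("rows already have unit sum of squares; input looks already ",
            "Hellinger-transformed (the transformation is not idempotent)")
  out <- sqrt(sweep(Y, 1, rs, "/"))
  attr(out, "row_totals") <- rs
  class(out) <- c("hellinger_matrix", class(out))
  out
}

# Center columns of a matrix.
.center <- function(M) sweep(as.matrix(M), 2, colMeans(as.matrix(M)), "-")

# QR basis of the centered predictor matrix; errors on rank deficiency.
.qr_basis <- function(X, label = "X") {
  Xc <- .center(X)
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrx$pivot[(qrx$rank + 1):ncol(Xc)]]
    stop(sprintf("rank-deficient predictor matrix %s: collinear column(s) %s",
                 label, paste(drop, collapse = ", ")))
  }
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

#' Redundancy analysis R-squared
#'
#' Multivariate least-squares fit of the (column-centred) response matrix on
#' the (column-centred) predictors. `R2` is the proportion of the total sum
#' of squares, summed over all response columns, captured by the fitted
#' values; `adj_r2` applies Ezekiel's correction
#' `1 - (1 - R2) (n - 1)/(n - m - 1)`; `f = (R2/m) / ((1 - R2)/(n - m - 1))`.
#'
#' @param Y Response matrix (typically Hellinger-transformed abundances).
#' @param X Predictor matrix (n x m), full column rank after centring.
#' @return List with `r2`, `adj_r2`, `f`, `df` (m), `df_res` (n - m - 1).
#' @export
rda_r2 <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X row counts differ")
  Q <- .qr_basis(X)
  m <- ncol(Q)
  if (n <= m + 1) stop("too few rows: need n > m + 1")
  Yc <- .center(Y)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response matrix has zero variance")
  ss_fit <- sum(crossprod(Q, Yc)^2)
  r2 <- ss_fit / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  f <- (r2 / m) / ((1 - r2) / (n - m - 1))
  list(r2 = r2, adj_r2 = adj, f = f, df = m, df_res = n - m - 1)
}

# Rank-tolerant adjusted R2: redundant columns are dropped (effective rank
# used as the model df). Needed for the joint E+S model of variation
# partitioning, where the two sets may overlap up to identity.
.rda_adj_rank <- function(Y, X) {
  Yc <- .center(Y)
  qrx <- qr(.center(as.matrix(X)))
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  n <- nrow(Yc); m <- qrx$rank
  if (n <= m + 1) stop("too few rows: need n > rank + 1")
  r2 <- sum(crossprod(Q, Yc)^2) / sum(Yc^2)
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Permutation test of a (partial) RDA component
#'
#' Tests the added effect of predictors `X` given conditioning variables `W`
#' by Freedman-Lane permutation of the reduced-model residuals: the observed
#' statistic is the partial F of `X` after `W`; under each permutation the
#' rows of the reduced-model residuals are shuffled, added back to the
#' reduced-model fit, and the partial F recomputed. The p-value uses the
#' `(count + 1)/(n_perm + 1)` estimator and is never exactly zero.
#'
#' @param Y Response matrix.
#' @param X Predictors of interest.
#' @param W Conditioning matrix, or `NULL` for a simple RDA test.
#' @param n_perm Number of permutations (default 999; a warning is issued
#'   below 99).
#' @param seed Integer seed for the permutation stream.
#' @return List with `adj_r2` (semipartial adjusted R2 of `X`), `r2`
#'   (semipartial R2), `f`, `p`, `df`, `df_res`, `n_perm`.
#' @export
partial_rda_test <- function(Y, X, W = NULL, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value")
  Yc <- .center(Y)
  ss_tot <- sum(Yc^2)
  if (is.null(W) || length(W) == 0 || NCOL(W) == 0) {
    Qw <- NULL; mw <- 0
    Yres <- Yc; Yfit_w <- matrix(0, n, ncol(Yc))
    Qfull <- .qr_basis(X)
  } else {
    W <- as.matrix(W)
    Qw <- .qr_basis(W, "W"); mw <- ncol(Qw)
    XW <- cbind(W, X)
    qful <- qr(.center(XW))
    if (qful$rank <= mw)
      stop("X lies in the span of W: partial F undefined")
    Qfull <- qr.Q(qful)[, seq_len(qful$rank), drop = FALSE]
    Yfit_w <- Qw %*% crossprod(Qw, Yc)
    Yres <- Yc - Yfit_w
  }
  mx <- ncol(Qfull) - mw
  df_res <- n - mw - mx - 1
  if (df_res < 1) stop("no residual degrees of freedom")
  pf_stat <- function(Ym) {
    # partial F of X after W for response Ym (already centred); the residual
    # SS is clamped at 0 against cancellation in (near-)perfect fits
    ss_full <- sum(crossprod(Qfull, Ym)^2)
    ss_w <- if (mw > 0) sum(crossprod(Qw, Ym)^2) else 0
    ss_res <- max(sum(Ym^2) - ss_full, 0)
    if (ss_res == 0) return(Inf)
    ((ss_full - ss_w) / mx) / (ss_res / df_res)
  }
  f_obs <- pf_stat(Yc)
  r2_semi <- {
    ss_full <- sum(crossprod(Qfull, Yc)^2)
    ss_w <- if (mw > 0) sum(crossprod(Qw, Yc)^2) else 0
    (ss_full - ss_w) / ss_tot
  }
  # semipartial adjusted R2: R2adj(full) - R2adj(W)
  adj_full <- 1 - (1 - sum(crossprod(Qfull, Yc)^2) / ss_tot) * (n - 1) / (n - mw - mx - 1)
  adj_w <- if (mw > 0)
    1 - (1 - sum(crossprod(Qw, Yc)^2) / ss_tot) * (n - 1) / (n - mw - 1) else 0
  f_perm <- numeric(n_perm)
  rs <- .seed_stream(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Ym <- Yfit_w + Yres[perm, , drop = FALSE]
    f_perm[b] <- pf_stat(.center(Ym))
  }
  .restore_seed(rs)
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  list(adj_r2 = adj_full - adj_w, r2 = r2_semi, f = f_obs, p = p,
       df = mx, df_res = df_res, n_perm = n_perm)
}

#' Forward selection with the double stopping criterion
#'
#' Greedy forward selection of predictors for an RDA of `Y`: at each step
#' the candidate giving the largest increase in fit is tested by permutation
#' (conditioning on the variables already selected). Selection stops when
#' (i) the best candidate's permutation p-value exceeds `alpha`, or (ii) the
#' cumulative adjusted R2 of the selected set reaches the adjusted R2 of the
#' global model containing every candidate. The double stop guards against
#' the inflated type-I error of alpha-only forward selection.
#'
#' @param Y Response matrix (Hellinger-transformed abundances).
#' @param candidates Predictor matrix or data frame; columns are candidate
#'   variables.
#' @param alpha Significance level for the per-step permutation test.
#' @param n_perm Permutations per step.
#' @param seed Integer seed.
#' @return Object of class `forward_selection`: data frame with one row per
#'   selected variable (`variable`, `cum_r2`, `cum_adj_r2`, `f`, `p`) and
#'   attributes `global_adj_r2` and `stopped_by`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  X <- as.matrix(candidates)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 0) {
    out <- data.frame(variable = character(), cum_r2 = numeric(),
                      cum_adj_r2 = numeric(), f = numeric(), p = numeric())
    attr(out, "global_adj_r2") <- NA_real_
    attr(out, "stopped_by") <- "no candidates"
    class(out) <- c("forward_selection", "data.frame")
    return(out)
  }
  global_adj <- rda_r2(Y, X)$adj_r2
  selected <- character(0)
  rows <- list()
  stopped_by <- "exhausted candidates"
  for (step in seq_len(ncol(X))) {
    remaining <- setdiff(colnames(X), selected)
    if (length(remaining) == 0) break
    r2s <- vapply(remaining, function(v)
      rda_r2(Y, X[, c(selected, v), drop = FALSE])$r2, numeric(1))
    best <- remaining[which.max(r2s)]
    tst <- partial_rda_test(Y, X[, best, drop = FALSE],
                            W = if (length(selected)) X[, selected, drop = FALSE] else NULL,
                            n_perm = n_perm, seed = seed + step)
    if (tst$p > alpha) { stopped_by <- "alpha"; break }
    selected <- c(selected, best)
    cum <- rda_r2(Y, X[, selected, drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      variable = best, cum_r2 = cum$r2, cum_adj_r2 = cum$adj_r2,
      f = tst$f, p = tst$p, stringsAsFactors = FALSE)
    if (cum$adj_r2 >= global_adj - 1e-10) { stopped_by <- "global adj R2"; break }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), cum_r2 = numeric(),
               cum_adj_r2 = numeric(), f = numeric(), p = numeric())
  attr(out, "global_adj_r2") <- global_adj
  attr(out, "stopped_by") <- stopped_by
  class(out) <- c("forward_selection", "data.frame")
  out
}

#' Two-component variation partitioning
#'
#' Partitions the variation of a community matrix between an environmental
#' predictor set `E` and a spatial predictor set `S` using adjusted R2:
#' with `RE = adjR2(Y ~ E)`, `RS = adjR2(Y ~ S)` and
#' `RES = adjR2(Y ~ E + S)`, the fractions are the pure environmental
#' `a = RES - RS`, pure spatial `c = RES - RE`, shared `b = RE + RS - RES`
#' (which may be negative), and residual `d = 1 - RES`. The testable pure
#' fractions `[a]` and `[c]` get partial-RDA permutation tests
#' ([partial_rda_test()]) on independent seeded streams.
#'
#' @param Y Response matrix (Hellinger-transformed abundances).
#' @param E Environmental predictor matrix (may be `NULL`/empty).
#' @param S Spatial predictor matrix, e.g. selected dbMEMs (may be
#'   `NULL`/empty).
#' @param n_perm Permutations for the two tests (default 999).
#' @param seed Integer seed.
#' @return Object of class `varpart_result`: list with `a`, `b`, `c`, `d`,
#'   `test_a`, `test_c` (each a [partial_rda_test()] result or `NULL`),
#'   `adj_r2` (named RE/RS/RES), `n_perm`.
#' @export
variation_partition <- function(Y, E, S, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  has_e <- !is.null(E) && NCOL(E) > 0
  has_s <- !is.null(S) && NCOL(S) > 0
  if (!has_e && !has_s) stop("at least one predictor set required")
  re <- if (has_e) rda_r2(Y, E)$adj_r2 else 0
  rs <- if (has_s) rda_r2(Y, S)$adj_r2 else 0
  res <- if (has_e && has_s) .rda_adj_rank(Y, cbind(as.matrix(E), as.matrix(S)))
         else max(re, rs)
  a <- res - rs; c_ <- res - re; b <- re + rs - res; d <- 1 - res
  degenerate_test <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning("pure-fraction test skipped: ", conditionMessage(e))
      NULL
    })
  }
  test_a <- if (has_e) degenerate_test(
    partial_rda_test(Y, E, W = if (has_s) S else NULL,
                     n_perm = n_perm, seed = seed)) else NULL
  test_c <- if (has_s) degenerate_test(
    partial_rda_test(Y, S, W = if (has_e) E else NULL,
                     n_perm = n_perm, seed = seed + 104729L)) else NULL
  structure(list(a = a, b = b, c = c_, d = d,
                 test_a = test_a, test_c = test_c,
                 adj_r2 = c(E = re, S = rs, ES = res), n_perm = n_perm),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, digits = 2, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  pv <- function(t) if (is.null(t)) "" else sprintf("  F = %.3f, p = %.3g", t$f, t$p)
  cat("  Environmental [a]:", fmt(x$a), pv(x$test_a), "\n")
  cat("  Spatial       [c]:", fmt(x$c), pv(x$test_c), "\n")
  cat("  Shared        [b]:", fmt(x$b), "\n")
  cat("  Residual      [d]:", fmt(x$d), "\n")
  invisible(x)
}
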