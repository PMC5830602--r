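#' Arrange a presence matrix for nestedness scoring
#'
#' Nestedness metrics are order-sensitive, so the arrangement is explicit:
#' empty rows and columns are dropped (and recorded), rows are placed either
#' by a supplied gradient ordering or by decreasing richness, and columns
#' are always placed by decreasing species frequency with ties broken by
#' species id. Gradient mode fixes the row order only; the metric's
#' definition requires the other dimension to be ranked by marginal totals.
#'
#' @param presence A `presence_matrix` (see [to_presence()]) or a 0/1
#'   matrix with dimnames.
#' @param row_order A `gradient_ranking` (see [gradient_rankings()]), a
#'   character vector of site ids, or `NULL` for decreasing richness (ties
#'   by site id).
#' @return Object of class `ranked_matrix`: list with `incidence` (arranged
#'   0/1 matrix), `row_order` tag, `dropped_rows`, `dropped_cols`.
#' @export
ranked_matrix <- function(presence, row_order = NULL) {
  inc <- if (inherits(presence, "presence_matrix")) presence$incidence
         else as.matrix(presence)
  if (is.null(rownames(inc)) || is.null(colnames(inc)))
    stop("incidence matrix needs dimnames")
  if (any(inc != 0L & inc != 1L)) stop("incidence entries must be 0/1")
  storage.mode(inc) <- "integer"
  dropped_rows <- rownames(inc)[rowSums(inc) == 0]
  dropped_cols <- colnames(inc)[colSums(inc) == 0]
  if (length(dropped_rows) || length(dropped_cols))
    message("dropping empty rows [", paste(dropped_rows, collapse = ", "),
            "] and columns [", paste(dropped_cols, collapse = ", "), "]")
  inc <- inc[rowSums(inc) > 0, colSums(inc) > 0, drop = FALSE]
  tag <- "richness_desc"
  if (is.null(row_order)) {
    o <- order(-rowSums(inc), rownames(inc), method = "radix")
    inc <- inc[o, , drop = FALSE]
  } else {
    if (inherits(row_order, "gradient_ranking")) {
      tag <- row_order$name
      row_order <- row_order$site_ids
    } else tag <- "user"
    row_order <- intersect(row_order, rownames(inc))
    if (!setequal(row_order, rownames(inc)))
      stop("row_order does not cover all non-empty sites")
    inc <- inc[row_order, , drop = FALSE]
  }
  oc <- order(-colSums(inc), colnames(inc), method = "radix")
  inc <- inc[, oc, drop = FALSE]
  structure(list(incidence = inc, row_order = tag,
                 dropped_rows = dropped_rows, dropped_cols = dropped_cols),
            class = "ranked_matrix")
}

.incidence_of <- function(x) {
  if (inherits(x, "ranked_matrix")) x$incidence
  else if (inherits(x, "presence_matrix")) x$incidence
  else as.matrix(x)
}

# Sum of pairwise NODF scores over ordered row pairs of M:
# pair (u earlier, v later) contributes 100 * |u n v| / fill(v) when
# fill(u) > fill(v), else 0.
.nodf_pair_sum <- function(M) {
  f <- rowSums(M)
  O <- tcrossprod(M)
  n <- nrow(M)
  contrib <- 100 * O / matrix(f, n, n, byrow = TRUE)
  dec <- outer(f, f, ">")
  sum(contrib[upper.tri(O) & dec])
}

#' NODF: nestedness metric based on overlap and decreasing fill
#'
#' For every ordered pair of rows (u before v in the arranged matrix) with
#' strictly decreasing marginal totals, the paired score is the percentage
#' of v's presences shared with u; pairs with equal or increasing totals
#' score 0. Likewise over column pairs in column order. NODF is the mean
#' paired score over all row and column pairs, from 0 (no nestedness) to
#' 100 (every poorer assemblage a perfect subset of every richer one).
#'
#' @param rm A [ranked_matrix()] (or an already-arranged 0/1 matrix).
#' @return NODF value in `[0, 100]`.
#' @export
nodf <- function(rm) {
  M <- .incidence_of(rm)
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("NODF needs at least 2 rows and 2 columns")
  np <- choose(nrow(M), 2) + choose(ncol(M), 2)
  (.nodf_pair_sum(M) + .nodf_pair_sum(t(M))) / np
}

# Geometry of the matrix-temperature statistic for given shape and fill:
# unit-square row/column positions, the fill-dependent isocline of perfect
# nestedness, and the normalising diagonal lengths. Depends only on
# (nrow, ncol, fill), so it can be computed once and reused across
# fixed-margin null draws.
.temp_geometry <- function(nr, nc, fill) {
  r <- stats::ppoints(nr, a = 0.5)
  cc <- stats::ppoints(nc, a = 0.5)
  fillfun <- function(x, p) 1 - (1 - (1 - x)^p)^(1 / p)
  intfun <- function(p, fill) {
    stats::integrate(fillfun, lower = 0, upper = 1, p = p)$value - fill
  }
  p <- stats::uniroot(intfun, c(0, 20), fill = fill, extendInt = "downX")$root
  iso <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      a <- cc[j] - r[i]
      iso[i, j] <- stats::uniroot(function(x) fillfun(x, p) - a - x, c(0, 1))$root
    }
  }
  list(dis = matrix(r, nr, nc), iso = iso,
       totdis = 1 - abs(outer(r, cc, "-")), p = p)
}

# Score one arranged incidence matrix against precomputed geometry.
.temp_score <- function(M, g) {
  u <- (g$dis - g$iso) / g$totdis
  u[u < 0 & M == 1] <- 0
  u[u > 0 & M == 0] <- 0
  100 * sum(u^2) / length(M) / 0.04145
}

# Deterministic matrix packing for temperature: iterative row/column
# ordering by the s + t unexpectedness scores, with ties broken by current
# position (ties.method = "first") so repeated runs agree.
.temp_pack <- function(M) {
  colpack <- function(x, rr) {
    ind <- matrix(rep(rr, ncol(x)), nrow = nrow(x))
    s <- -colSums((x * ind)^2)
    t <- -colSums((nrow(x) - (1 - x) * ind + 1)^2)
    rank(s + t, ties.method = "first")
  }
  rowpack <- function(x, cr) {
    ind <- matrix(rep(cr, each = nrow(x)), nrow = nrow(x))
    s <- -rowSums((x * ind)^2)
    t <- -rowSums((ncol(x) - (1 - x) * ind + 1)^2)
    rank(s + t, ties.method = "first")
  }
  if (ncol(M) >= nrow(M)) {
    i <- rank(-rowSums(M), ties.method = "average")
  } else {
    j <- rank(-colSums(M), ties.method = "average")
    i <- rowpack(M, j)
  }
  for (k in seq_len(8)) {
    j <- colpack(M, i)
    i <- rowpack(M, j)
  }
  if (ncol(M) < nrow(M)) j <- colpack(M, i)
  M[order(i), order(j), drop = FALSE]
}

#' Matrix temperature
#'
#' Disorder statistic of a presence matrix: each unexpected presence (beyond
#' the fill-dependent isocline of perfect nestedness) and unexpected absence
#' (before it) contributes its squared normalised distance along its
#' diagonal; the total is scaled by the maximal attainable unexpectedness
#' (`Umax = 0.04145`) to a 0-100 degree scale. 0 means perfectly nested,
#' 100 maximally disordered. Uses the isocline parametrisation of
#' Rodriguez-Girones and Santamaria (2006).
#'
#' With `ordering = "pack"` the matrix is re-packed (rows and columns sorted
#' to minimise unexpectedness) before scoring; with `"gradient"` it is
#' scored exactly as arranged, so disorder is measured relative to the
#' supplied gradient ordering.
#'
#' @param rm A [ranked_matrix()] or arranged 0/1 matrix.
#' @param ordering `"pack"` (default) or `"gradient"`.
#' @return Temperature in `[0, 100]` degrees, with attribute `degenerate`
#'   set to `TRUE` when the matrix is completely full or empty (T defined
#'   as 0).
#' @export
matrix_temperature <- function(rm, ordering = c("pack", "gradient")) {
  ordering <- match.arg(ordering)
  M <- .incidence_of(rm)
  if (nrow(M) < 2 || ncol(M) < 2)
    stop("matrix temperature needs at least 2 rows and 2 columns")
  fill <- sum(M) / length(M)
  if (fill == 0 || fill == 1) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (ordering == "pack") M <- .temp_pack(M)
  g <- .temp_geometry(nrow(M), ncol(M), fill)
  out <- .temp_score(M, g)
  attr(out, "degenerate") <- FALSE
  out
}

#' Fixed-fixed null model samples
#'
#' Draws random binary matrices that preserve every row and column total of
#' the input (the FF null model), using the curveball algorithm by default:
#' repeated random trades of species between site pairs, which mix the
#' fixed-margin state space rapidly and sample it uniformly. A classical
#' checkerboard-swap engine is available behind `algorithm = "swap"`.
#'
#' @param rm A [ranked_matrix()], `presence_matrix`, or 0/1 matrix.
#' @param n Number of matrices to draw (default 1000).
#' @param algorithm `"curveball"` (default) or `"swap"`.
#' @param burn_in Mixing steps before the first sample; default `10 * fill`
#'   where fill is the number of presences.
#' @param thin Steps between consecutive samples; default `fill`.
#' @param seed Integer seed.
#' @return List of `n` integer 0/1 matrices with the same dimnames and
#'   margins as the input.
#' @export
ff_null <- function(rm, n = 1000, algorithm = c("curveball", "swap"),
                    burn_in = NULL, thin = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  M <- .incidence_of(rm)
  storage.mode(M) <- "integer"
  fill <- sum(M)
  if (is.null(burn_in)) burn_in <- 10L * fill
  if (is.null(thin)) thin <- max(1L, fill)
  rs <- .seed_stream(seed)
  out <- if (algorithm == "curveball") {
    curveball_samples_cpp(M, as.integer(n), as.integer(burn_in), as.integer(thin))
  } else {
    .swap_samples(M, n, burn_in, thin)
  }
  .restore_seed(rs)
  dn <- dimnames(M)
  lapply(out, function(x) { dimnames(x) <- dn; x })
}

# Checkerboard swap engine: pick random 2x2 submatrices and swap when they
# form a checkerboard; margins invariant.
.swap_samples <- function(M, n, burn_in, thin) {
  nr <- nrow(M); nc <- ncol(M)
  step <- function() {
    i <- sample.int(nr, 2); j <- sample.int(nc, 2)
    sub <- M[i, j]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] && sub[1, 1] != sub[1, 2])
      M[i, j] <<- 1L - sub
  }
  for (s in seq_len(burn_in)) step()
  out <- vector("list", n)
  for (t in seq_len(n)) {
    for (s in seq_len(thin)) step()
    out[[t]] <- M
  }
  out
}

#' Nestedness test against the fixed-fixed null model
#'
#' Scores the arranged matrix with NODF or matrix temperature, draws `n`
#' fixed-fixed null matrices ([ff_null()]), scores each under the same
#' arrangement (valid because fixed margins preserve both the gradient row
#' order and the column frequency order), and standardises the observed
#' value as `z = (obs - null_mean) / null_sd`. For NODF, positive z
#' indicates a tendency towards nestedness and negative z towards
#' anti-nestedness; for temperature the directions are reversed. The
#' one-tailed empirical p counts null values at least as extreme as the
#' observation in the observed direction, with the plus-one estimator.
#'
#' @param rm A [ranked_matrix()].
#' @param metric `"NODF"` or `"T"`.
#' @param n Null draws (default 1000).
#' @param seed Integer seed.
#' @param algorithm Passed to [ff_null()].
#' @return Object of class `nestedness_result`: list with `metric`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p`, `direction`
#'   (`"nested"`/`"anti-nested"`), `n_rand`, `ordering`, `seed`,
#'   `degenerate` (TRUE when the null distribution has zero spread; `z` is
#'   then `NA` and `p` comes from exact tie counting).
#' @export
nestedness_test <- function(rm, metric = c("NODF", "T"), n = 1000, seed = 1,
                            algorithm = "curveball") {
  metric <- match.arg(metric)
  stopifnot(inherits(rm, "ranked_matrix"))
  M <- rm$incidence
  if (metric == "NODF") {
    scorer <- function(x) (.nodf_pair_sum(x) + .nodf_pair_sum(t(x))) /
      (choose(nrow(x), 2) + choose(ncol(x), 2))
  } else {
    g <- .temp_geometry(nrow(M), ncol(M), sum(M) / length(M))
    scorer <- function(x) .temp_score(x, g)
  }
  obs <- scorer(M)
  nulls <- vapply(ff_null(rm, n = n, algorithm = algorithm, seed = seed),
                  scorer, numeric(1))
  mu <- mean(nulls); sg <- stats::sd(nulls)
  degenerate <- !is.finite(sg) || sg < 1e-12
  z <- if (degenerate) NA_real_ else (obs - mu) / sg
  nested_dir <- if (metric == "NODF") obs >= mu else obs <= mu
  direction <- if (nested_dir) "nested" else "anti-nested"
  extreme <- if (obs >= mu) sum(nulls >= obs) else sum(nulls <= obs)
  p <- (extreme + 1) / (n + 1)
  structure(list(metric = metric, observed = obs, null_mean = mu,
                 null_sd = sg, z = z, p = p, direction = direction,
                 n_rand = n, ordering = rm$row_order, seed = seed,
                 degenerate = degenerate),
            class = "nestedness_result")
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("%s under '%s' ordering: obs = %.2f, exp = %.2f (sd %.3f), z = %s, p = %.3f (%s)\n",
              x$metric, x$ordering, x$observed, x$null_mean, x$null_sd,
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p, x$direction))
  invisible(x)
}

#' Gradient-ordered nestedness battery
#'
#' Runs the full nestedness design: for each period (the two sampling
#' periods and their pooled union) x each of the four morphodynamic
#' gradient orderings x each metric (NODF and matrix temperature), tests
#' the gradient-ranked presence matrix against the fixed-fixed null model.
#' With both metrics and all periods this yields 24 result rows.
#'
#' @param m_fall,m_spring `community_matrix` objects for the two periods.
#' @param env An `env_table` covering all sites.
#' @param metrics Subset of `c("NODF", "T")`.
#' @param n Null draws per cell (default 1000).
#' @param seed Master seed; each cell uses a deterministic child seed.
#' @return Data frame of class `nestedness_battery` with columns `period`,
#'   `ordering`, `metric`, `obs`, `exp`, `sd`, `z`, `p`, `direction`.
#' @export
run_gradient_battery <- function(m_fall, m_spring, env,
                                 metrics = c("NODF", "T"), n = 1000, seed = 1) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  pooled <- pool_periods(m_fall, m_spring)
  periods <- list(fall = m_fall, spring = m_spring, pooled = pooled)
  rankings <- gradient_rankings(env)
  rows <- list()
  k <- 0L
  for (pn in names(periods)) {
    pres <- suppressWarnings(to_presence(periods[[pn]]))
    for (rk in rankings) {
      rmx <- suppressMessages(ranked_matrix(pres, row_order = rk))
      for (met in metrics) {
        k <- k + 1L
        res <- nestedness_test(rmx, metric = met, n = n,
                               seed = .child_seed(seed, k))
        rows[[k]] <- data.frame(period = pn, ordering = rk$name, metric = met,
                                obs = res$observed, exp = res$null_mean,
                                sd = res$null_sd, z = res$z, p = res$p,
                                direction = res$direction,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nestedness_battery", "data.frame")
  out
}

#' Minimal site cover
#'
#' The smallest number of sites whose combined species lists include every
#' species in the matrix. A useful anti-nestedness diagnostic: when more
#' than 40% of the sites are required to include all species, datasets tend
#' towards anti-nestedness (species replacement rather than subsetting). A
#' perfectly nested matrix needs only its richest site.
#'
#' Solved exactly by branch and bound for up to 25 sites; larger inputs get
#' the greedy bound with `exact = FALSE`.
#'
#' @param presence A `presence_matrix`, [ranked_matrix()] or 0/1 matrix;
#'   species with no occurrences are dropped with a warning.
#' @return List with `k` (sites needed), `fraction` (k / total sites),
#'   `sites` (ids of one optimal cover), `exact`.
#' @export
min_site_cover <- function(presence) {
  M <- .incidence_of(presence)
  if (length(M) == 0 || sum(M) == 0) stop("empty matrix: nothing to cover")
  if (any(colSums(M) == 0)) {
    warning("dropping species with no occurrences")
    M <- M[, colSums(M) > 0, drop = FALSE]
  }
  n <- nrow(M)
  sets <- lapply(seq_len(n), function(i) which(M[i, ] > 0))
  greedy <- function() {
    covered <- logical(ncol(M)); chosen <- integer(0)
    while (!all(covered)) {
      gain <- vapply(sets, function(s) sum(!covered[s]), integer(1))
      i <- which.max(gain)
      chosen <- c(chosen, i); covered[sets[[i]]] <- TRUE
    }
    chosen
  }
  best <- greedy()
  if (n > 25) {
    return(list(k = length(best), fraction = length(best) / n,
                sites = rownames(M)[best], exact = FALSE))
  }
  # branch and bound: branch on the sites containing the rarest uncovered
  # species; any cover must use one of them
  best_sol <- best
  recurse <- function(chosen, covered) {
    if (all(covered)) {
      if (length(chosen) < length(best_sol)) best_sol <<- chosen
      return()
    }
    if (length(chosen) + 1 >= length(best_sol)) return()
    uncov <- which(!covered)
    counts <- colSums(M[, uncov, drop = FALSE])
    sp <- uncov[which.min(counts)]
    for (i in which(M[, sp] > 0)) {
      cov2 <- covered; cov2[sets[[i]]] <- TRUE
      recurse(c(chosen, i), cov2)
    }
  }
  recurse(integer(0), logical(ncol(M)))
  list(k = length(best_sol), fraction = length(best_sol) / n,
       sites = rownames(M)[sort(best_sol)], exact = TRUE)
}
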