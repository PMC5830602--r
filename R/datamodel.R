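#' Construct a site-by-species community matrix
#'
#' The community matrix is the central object of the package: rows are
#' site-sectors, columns are species, cells are non-negative integer counts.
#' Row and column order is meaningful (gradient orderings downstream are
#' explicit permutations of it), so it is preserved exactly as given.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   row names (site ids) and column names (species ids). Names are trimmed
#'   of surrounding whitespace.
#' @param period Sampling period label, e.g. `"fall"`, `"spring"`, or
#'   `"pooled"`.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` (integer matrix) and `period`.
#' @examples
#' m <- community_matrix(matrix(c(1, 0, 0, 2), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("spA", "spB"))), period = "fall")
#' richness(m)
#' @export
community_matrix <- function(counts, period = "pooled") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("community matrix needs row (site) and column (species) names")
  rownames(counts) <- trimws(rownames(counts))
  colnames(counts) <- trimws(colnames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate site ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate species ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; offending cell (%s, %s) = %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, period = as.character(period)),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species, period = %s, total count = %d\n",
              nrow(x$counts), ncol(x$counts), x$period, sum(x$counts)))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Sites and species of a community matrix
#' @param m A `community_matrix` or `presence_matrix`.
#' @return Character vector of ids in stored order.
#' @export
sites <- function(m) rownames(if (inherits(m, "presence_matrix")) m$incidence else m$counts)

#' @rdname sites
#' @export
species <- function(m) colnames(if (inherits(m, "presence_matrix")) m$incidence else m$counts)

#' Read a community matrix from CSV
#'
#' Two layouts are accepted. The canonical wide layout has a first column of
#' site ids and one column per species. The long layout has columns
#' `site_id, species, count` (and optionally `period`); duplicate
#' (site, species) rows are aggregated by summation and missing cells are 0.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @param period Period label attached to the result; for long layouts with a
#'   `period` column, rows are first filtered to this period unless `NULL`.
#' @return A [community_matrix()].
#' @export
read_community <- function(path, layout = c("wide", "long"), period = "pooled") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (layout == "wide") {
    sites <- trimws(as.character(df[[1]]))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- sites
    return(community_matrix(m, period = period))
  }
  need <- c("site_id", "species", "count")
  if (!all(need %in% names(df)))
    stop("long layout needs columns: ", paste(need, collapse = ", "))
  if (!is.null(period) && "period" %in% names(df) && period %in% df$period)
    df <- df[df$period == period, , drop = FALSE]
  df$site_id <- trimws(as.character(df$site_id))
  df$species <- trimws(as.character(df$species))
  agg <- stats::aggregate(count ~ site_id + species, data = df, FUN = sum)
  m <- matrix(0L, nrow = length(unique(agg$site_id)), ncol = length(unique(agg$species)),
              dimnames = list(unique(agg$site_id), unique(agg$species)))
  m[cbind(agg$site_id, agg$species)] <- agg$count
  community_matrix(m, period = period)
}

#' Write a community matrix to wide CSV
#'
#' Round-trips exactly through [read_community()]: integer cells, header
#' `site_id,<species...>`.
#'
#' @param m A [community_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_community <- function(m, path) {
  stopifnot(inherits(m, "community_matrix"))
  df <- data.frame(site_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pool two sampling periods into one community matrix
#'
#' Counts are summed element-wise over the union of the species sets
#' (species absent from one period contribute zeros). Pooling abundance data
#' across periods increases the number and abundance of species per site
#' before ordination and variation partitioning.
#'
#' @param m_a,m_b `community_matrix` objects over the same site set.
#' @return A `community_matrix` with `period = "pooled"`.
#' @export
pool_periods <- function(m_a, m_b) {
  stopifnot(inherits(m_a, "community_matrix"), inherits(m_b, "community_matrix"))
  sa <- sites(m_a); sb <- sites(m_b)
  if (!setequal(sa, sb)) {
    stop("site sets differ; only in first: [",
         paste(setdiff(sa, sb), collapse = ", "), "]; only in second: [",
         paste(setdiff(sb, sa), collapse = ", "), "]")
  }
  spp <- union(species(m_a), species(m_b))
  out <- matrix(0L, nrow = length(sa), ncol = length(spp),
                dimnames = list(sa, spp))
  out[, species(m_a)] <- out[, species(m_a)] + m_a$counts
  out[, species(m_b)] <- out[, species(m_b)] + m_b$counts[sa, , drop = FALSE]
  community_matrix(out, period = "pooled")
}

#' Convert counts to a presence/absence matrix
#'
#' @param m A [community_matrix()].
#' @return An object of class `presence_matrix`: list with `incidence`
#'   (0/1 integer matrix), `fill` (total presences), `row_fills`,
#'   `col_fills`, `period`, and `empty` flag (`TRUE` when fill is 0).
#' @export
to_presence <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  inc <- ifelse(m$counts > 0L, 1L, 0L)
  dimnames(inc) <- dimnames(m$counts)
  fill <- sum(inc)
  if (fill == 0L) warning("presence matrix is empty (no occurrences)")
  structure(list(incidence = inc, fill = fill,
                 row_fills = rowSums(inc), col_fills = colSums(inc),
                 period = m$period, empty = fill == 0L),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d sites x %d species, fill = %d (%.1f%%)\n",
              nrow(x$incidence), ncol(x$incidence), x$fill,
              100 * x$fill / length(x$incidence)))
  invisible(x)
}

#' Species exclusive to a single group of sites
#'
#' A species is exclusive to a group (by default each site-sector is its own
#' group; sectors of one beach can be mapped to a common group) when every
#' one of its presences falls within that group's sites. Species with no
#' occurrences are exclusive nowhere.
#'
#' @param m A [community_matrix()] or `presence_matrix`.
#' @param grouping Named character vector mapping every site id to a group
#'   label; `NULL` means one group per site.
#' @return List with `species`: named list (per group) of exclusive species
#'   ids, and `counts`: named integer vector of exclusive-species counts
#'   (one entry per group, in first-appearance order).
#' @export
exclusive_species <- function(m, grouping = NULL) {
  inc <- if (inherits(m, "presence_matrix")) m$incidence else to_presence(m)$incidence
  sids <- rownames(inc)
  if (is.null(grouping)) grouping <- stats::setNames(sids, sids)
  missing <- setdiff(sids, names(grouping))
  if (length(missing) > 0)
    stop("sites missing from grouping: ", paste(missing, collapse = ", "))
  groups <- unique(unname(grouping[sids]))
  res <- lapply(groups, function(g) {
    inside <- sids[grouping[sids] == g]
    outside <- setdiff(sids, inside)
    pres_in <- colSums(inc[inside, , drop = FALSE]) > 0
    pres_out <- colSums(inc[outside, , drop = FALSE]) > 0
    colnames(inc)[pres_in & !pres_out]
  })
  names(res) <- groups
  list(species = res, counts = vapply(res, length, integer(1)))
}

#' Per-site species richness
#'
#' @param m A [community_matrix()] or `presence_matrix`.
#' @return List with `by_site`: named integer vector of per-site richness,
#'   and `total`: number of species occurring anywhere.
#' @export
richness <- function(m) {
  inc <- if (inherits(m, "presence_matrix")) m$incidence else to_presence(m)$incidence
  list(by_site = rowSums(inc), total = sum(colSums(inc) > 0))
}
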