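#' Beach Index
#'
#' Composite morphodynamic index `BI = log10((Mz * TR) / S)` where
#' `Mz = mz_phi + 1` is the mean grain size term (phi units plus one),
#' `TR` the maximum spring tide range in metres, and `S` the beach slope
#' expressed as a ratio (rise/run). Higher values denote more dissipative
#' beaches (finer sand, gentler slope); lower values more reflective ones.
#'
#' The slope entering the formula is the ratio itself (e.g. 0.1 for a 1:10
#' beach face), not its reciprocal: only this reading reproduces published
#' index values computed from field tables.
#'
#' @param mz_phi Mean grain diameter in phi units; `mz_phi + 1` must be
#'   positive.
#' @param slope_ratio Beach-face slope as a ratio, strictly positive.
#' @param tide_range_m Maximum spring tide range in metres (default 2.0).
#' @return Numeric vector of Beach Index values (dimensionless, log10 scale).
#' @examples
#' beach_index(mz_phi = 0.94, slope_ratio = 0.1)   # reflective, ~1.59
#' beach_index(mz_phi = 3.20, slope_ratio = 0.013) # dissipative, ~2.81
#' @export
beach_index <- function(mz_phi, slope_ratio, tide_range_m = 2) {
  arg <- (mz_phi + 1) * tide_range_m / slope_ratio
  if (any(!is.finite(arg) | arg <= 0))
    stop("non-positive argument to log10: check that mz_phi + 1, ",
         "tide_range_m and slope_ratio are all positive")
  log10(arg)
}

#' Classify beach morphodynamic state
#'
#' Maps Beach Index values onto the reflective / intermediate / dissipative
#' continuum with configurable cut-offs: reflective when
#' `BI < reflective_max`, dissipative when `BI > dissipative_min`,
#' intermediate otherwise (both boundaries fall into the middle class).
#' Defaults (2.0, 2.55) reproduce published classifications where the index
#' alone is decisive; near the upper boundary the published classes also
#' weigh beach width, which is why the cut-offs are exposed as configuration.
#'
#' @param bi Numeric vector of Beach Index values.
#' @param thresholds Named numeric vector with `reflective_max` and
#'   `dissipative_min`, `reflective_max < dissipative_min`.
#' @return Factor with levels `reflective`, `intermediate`, `dissipative`.
#' @export
classify_state <- function(bi, thresholds = c(reflective_max = 2.0,
                                              dissipative_min = 2.55)) {
  rm_ <- thresholds[["reflective_max"]]; dm_ <- thresholds[["dissipative_min"]]
  if (!is.finite(rm_) || !is.finite(dm_) || rm_ >= dm_)
    stop("inverted thresholds: need reflective_max < dissipative_min")
  out <- ifelse(bi < rm_, "reflective", ifelse(bi > dm_, "dissipative", "intermediate"))
  factor(out, levels = c("reflective", "intermediate", "dissipative"))
}

#' Morphodynamic gradient rankings of sites
#'
#' Builds the four site orderings used to rank a presence matrix before
#' nestedness scoring, each placing the most dissipative-like site first:
#' decreasing Beach Index (`BI_desc`), decreasing mean grain diameter in phi
#' (`grain_phi_desc`, finer sand first), increasing slope ratio
#' (`slope_asc`), and decreasing beach width (`width_desc`). Ties are broken
#' by site id in lexical order (stable).
#'
#' @param env An environment table as returned by [read_env()] or
#'   [generate_env()]: data frame with `site_id`, `beach_index`,
#'   `mean_diameter_phi`, `slope_ratio`, `width_m`.
#' @return Named list of four `gradient_ranking` objects, each a list with
#'   `name`, `site_ids` (the permutation) and `values` (the ranking key).
#' @export
gradient_rankings <- function(env) {
  need <- c("site_id", "beach_index", "mean_diameter_phi", "slope_ratio", "width_m")
  miss <- setdiff(need, names(env))
  if (length(miss) > 0) stop("environment table lacks columns: ",
                             paste(miss, collapse = ", "))
  for (cn in need[-1]) {
    if (any(!is.finite(env[[cn]])))
      stop(sprintf("missing value in column '%s' for site '%s'",
                   cn, env$site_id[which(!is.finite(env[[cn]]))[1]]))
  }
  mk <- function(name, key, decreasing) {
    o <- order(if (decreasing) -key else key, env$site_id, method = "radix")
    structure(list(name = name, site_ids = env$site_id[o], values = key[o]),
              class = "gradient_ranking")
  }
  list(BI_desc        = mk("BI_desc", env$beach_index, TRUE),
       grain_phi_desc = mk("grain_phi_desc", env$mean_diameter_phi, TRUE),
       slope_asc      = mk("slope_asc", env$slope_ratio, FALSE),
       width_desc     = mk("width_desc", env$width_m, TRUE))
}

#' @export
print.gradient_ranking <- function(x, ...) {
  cat("gradient_ranking", x$name, ":", paste(x$site_ids, collapse = " > "), "\n")
  invisible(x)
}

#' Read a site environment table from CSV
#'
#' Expected columns: `site_id, width_m, slope_ratio, mean_diameter_phi,
#' sorting_phi, caco3_pct, om_pct`, optionally a pre-computed `beach_index`.
#' When absent, the Beach Index is computed with [beach_index()] at the
#' given tide range.
#'
#' @param path CSV path.
#' @param tide_range_m Tide range used when `beach_index` must be computed.
#' @return A validated data frame of class `env_table`.
#' @export
read_env <- function(path, tide_range_m = 2) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  as_env_table(df, tide_range_m = tide_range_m)
}

#' @rdname read_env
#' @param df A data frame with the `env.csv` schema.
#' @export
as_env_table <- function(df, tide_range_m = 2) {
  need <- c("site_id", "width_m", "slope_ratio", "mean_diameter_phi",
            "sorting_phi", "caco3_pct", "om_pct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("env table lacks columns: ", paste(miss, collapse = ", "))
  df$site_id <- trimws(as.character(df$site_id))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in env table")
  if (any(df$width_m <= 0) || any(df$slope_ratio <= 0))
    stop("width_m and slope_ratio must be strictly positive")
  if (any(df$caco3_pct < 0 | df$caco3_pct > 100) ||
      any(df$om_pct < 0 | df$om_pct > 100))
    stop("caco3_pct and om_pct must lie in [0, 100]")
  if (is.null(df$beach_index))
    df$beach_index <- beach_index(df$mean_diameter_phi, df$slope_ratio, tide_range_m)
  class(df) <- c("env_table", "data.frame")
  df
}
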