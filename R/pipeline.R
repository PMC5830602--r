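#' Pearson correlation with t test
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @param label Optional label for the variable pair.
#' @return Data frame with `pair`, `n`, `r`, `t`, `p` (two-tailed, t
#'   distribution with n - 2 df).
#' @export
pearson_cor <- function(x, y, label = "x~y") {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(pair = label, n = length(x), r = unname(ct$estimate),
             t = unname(ct$statistic), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Assemble and validate a run configuration
#'
#' A flat key-value configuration (R list or YAML file) for [run_all()].
#' Recognised keys: `community_fall`, `community_spring`, `sites`, `env`
#' (input CSV paths), `tide_range_m` (default 2), `n_perm` (default 10000),
#' `n_rand` (default 1000), `seed` (mandatory), `out_dir`, and per-stage
#' toggles `do_varpart`, `do_nmds`, `do_nestedness`, `do_correlations`
#' (all default `TRUE`).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(tide_range_m = 2, n_perm = 10000, n_rand = 1000,
                   do_varpart = TRUE, do_nmds = TRUE, do_nestedness = TRUE,
                   do_correlations = TRUE, out_dir = ".")
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$seed)) stop("seed is mandatory")
  for (k in c("community_fall", "community_spring", "sites", "env")) {
    if (is.null(config[[k]])) stop("missing input path: ", k)
    if (!file.exists(config[[k]])) stop("input does not exist: ", config[[k]])
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end from the input CSVs: Beach Index and
#' state classification; Procrustes concordance of the two periods (the
#' justification for pooling); pooling; dbMEM construction; forward
#' selection of environmental variables and dbMEMs; variation partitioning
#' with permutation tests; Bray-Curtis NMDS; the gradient-ordered
#' nestedness battery; and richness / exclusive-species correlations with
#' the Beach Index (at site-by-period resolution, n = 2 x sites, for
#' richness). Each stage derives its own child seed from the master seed,
#' and artifacts are written as CSV/JSON into `out_dir`.
#'
#' @param config A [run_config()] (or list/YAML path coercible to one).
#' @return Invisibly, a list with all stage results (`env`, `concordance`,
#'   `mem`, `selection_env`, `selection_mem`, `varpart`, `nmds`,
#'   `nestedness`, `correlations`) plus `artifacts` (paths written).
#' @export
run_all <- function(config) {
  config <- run_config(config)
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  emit <- function(name) {
    path <- file.path(config$out_dir, name)
    art <<- c(art, path)
    path
  }
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  log_stage("reading inputs")
  fall <- read_community(config$community_fall, period = "fall")
  spring <- read_community(config$community_spring, period = "spring")
  sites_df <- utils::read.csv(config$sites, fileEncoding = "UTF-8")
  env <- read_env(config$env, tide_range_m = config$tide_range_m)

  log_stage("beach index and morphodynamic state")
  env$state <- as.character(classify_state(env$beach_index))
  utils::write.csv(as.data.frame(env), emit("env_bi.csv"), row.names = FALSE)

  log_stage("period concordance (Procrustes)")
  conc <- period_concordance(fall, spring, n_perm = min(config$n_perm, 999),
                             seed = .child_seed(seed, 11L))
  jsonlite::write_json(list(correlation = conc$correlation, m2 = conc$m2,
                            p = conc$p, n_perm = conc$n_perm),
                       emit("procrustes.json"), auto_unbox = TRUE, digits = NA)

  pooled <- pool_periods(fall, spring)
  res <- list(env = env, concordance = conc)

  if (isTRUE(config$do_varpart)) {
    log_stage("dbMEM and variation partitioning")
    D <- distance_matrix(sites_df)
    D <- D[env$site_id, env$site_id]
    mem <- dbmem(D)
    Yh <- hellinger(pooled)
    Yh <- Yh[env$site_id, , drop = FALSE]
    Xe <- as.matrix(env[, c("beach_index", "mean_diameter_phi",
                            "slope_ratio", "width_m")])
    rownames(Xe) <- env$site_id
    sel_e <- forward_select(Yh, Xe, n_perm = min(config$n_perm, 999),
                            seed = .child_seed(seed, 21L))
    sel_s <- forward_select(Yh, mem$vectors, n_perm = min(config$n_perm, 999),
                            seed = .child_seed(seed, 22L))
    E <- if (nrow(sel_e)) Xe[, sel_e$variable, drop = FALSE] else NULL
    S <- if (nrow(sel_s)) mem$vectors[, sel_s$variable, drop = FALSE] else NULL
    vp <- if (is.null(E) && is.null(S)) NULL else
      variation_partition(Yh, E, S, n_perm = config$n_perm,
                          seed = .child_seed(seed, 23L))
    sel <- rbind(cbind(component = "environmental", as.data.frame(sel_e)),
                 cbind(component = "spatial", as.data.frame(sel_s)))
    utils::write.csv(sel, emit("selection.csv"), row.names = FALSE)
    if (!is.null(vp))
      jsonlite::write_json(list(
        a = vp$a, b = vp$b, c = vp$c, d = vp$d,
        f_a = if (!is.null(vp$test_a)) vp$test_a$f else NULL,
        p_a = if (!is.null(vp$test_a)) vp$test_a$p else NULL,
        f_c = if (!is.null(vp$test_c)) vp$test_c$f else NULL,
        p_c = if (!is.null(vp$test_c)) vp$test_c$p else NULL,
        n_perm = vp$n_perm), emit("varpart.json"),
        auto_unbox = TRUE, digits = NA)
    res$mem <- mem; res$selection_env <- sel_e; res$selection_mem <- sel_s
    res$varpart <- vp
  }

  if (isTRUE(config$do_nmds)) {
    log_stage("Bray-Curtis NMDS")
    ord <- nmds_ordination(bray_curtis(pooled), k = 2,
                           seed = .child_seed(seed, 31L))
    utils::write.csv(data.frame(site_id = rownames(ord$points), ord$points),
                     emit("nmds_scores.csv"), row.names = FALSE)
    jsonlite::write_json(list(stress = ord$stress, converged = ord$converged),
                         emit("nmds.json"), auto_unbox = TRUE, digits = NA)
    res$nmds <- ord
  }

  if (isTRUE(config$do_nestedness)) {
    log_stage("gradient nestedness battery")
    bat <- run_gradient_battery(fall, spring, env, n = config$n_rand,
                                seed = .child_seed(seed, 41L))
    utils::write.csv(as.data.frame(bat), emit("table_nestedness.csv"),
                     row.names = FALSE)
    pres_pooled <- to_presence(pooled)
    inc <- pres_pooled$incidence[, pres_pooled$col_fills > 0, drop = FALSE]
    cover <- min_site_cover(inc)
    jsonlite::write_json(list(k = cover$k, fraction = cover$fraction,
                              exact = cover$exact),
                         emit("site_cover.json"), auto_unbox = TRUE, digits = NA)
    res$nestedness <- bat; res$site_cover <- cover
  }

  if (isTRUE(config$do_correlations)) {
    log_stage("richness and exclusive-species correlations")
    rich_f <- richness(fall)$by_site[env$site_id]
    rich_s <- richness(spring)$by_site[env$site_id]
    cors <- rbind(
      pearson_cor(rep(env$beach_index, 2), c(rich_f, rich_s),
                  label = "richness~beach_index"),
      pearson_cor(rep(env$slope_ratio, 2), c(rich_f, rich_s),
                  label = "richness~slope_ratio"),
      pearson_cor(rep(env$mean_diameter_phi, 2), c(rich_f, rich_s),
                  label = "richness~mean_diameter_phi"),
      pearson_cor(rep(env$width_m, 2), c(rich_f, rich_s),
                  label = "richness~width_m"))
    excl <- exclusive_species(pooled)
    excl_cor <- tryCatch(
      pearson_cor(env$beach_index, as.numeric(excl$counts[env$site_id]),
                  label = "exclusive_species~beach_index"),
      error = function(e) NULL)  # constant exclusive counts are legitimate
    cors <- rbind(cors, excl_cor)
    utils::write.csv(cors, emit("correlations.csv"), row.names = FALSE)
    res$correlations <- cors; res$exclusive <- excl
  }

  res$artifacts <- art
  invisible(res)
}
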