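#' Scenario configuration for the synthetic metacommunity generator
#'
#' Defines the ground-truth structure of a simulated sandy-beach
#' metacommunity. Scenarios:
#' * `ENV_ONLY`: species sort along the morphodynamic (Beach Index)
#'   gradient, which is spatially shuffled; no spatial signal.
#' * `SPACE_ONLY`: environment constant across sites; occurrence driven by
#'   spatially autocorrelated latent fields (dispersal-like structure).
#' * `MIXED`: both effects.
#' * `NESTED`: ordered species loss along the gradient - each site's
#'   assemblage is (up to Bernoulli noise `epsilon`) a subset of every more
#'   dissipative site's assemblage.
#' * `TURNOVER`: narrow, equally spaced niches, so species replace each
#'   other along the gradient (anti-nested structure).
#'
#' Defaults emulate the motivating field design: 14 site-sectors along
#' ~60 km of coast, 112 species, Beach Index spanning 1.59-2.81, sparse
#' clumped counts whose pooled total over two periods is close to 2800
#' individuals.
#'
#' @param scenario One of `"ENV_ONLY"`, `"SPACE_ONLY"`, `"MIXED"`,
#'   `"NESTED"`, `"TURNOVER"`.
#' @param n_sites Number of site-sectors (>= 3, default 14).
#' @param n_species Species pool size (default 112).
#' @param bi_range Beach Index envelope (default `c(1.59, 2.81)`).
#' @param niche_breadth Gaussian niche breadth in Beach Index units
#'   (default 0.35; `TURNOVER` defaults to 0.25, about two site spacings of
#'   the default gradient, so each species occupies a band of neighbouring
#'   sites rather than an isolated one).
#' @param spatial_range Range `rho` (km) of the exponential spatial
#'   covariance `exp(-d / rho)` (default 15).
#' @param env_effect,space_effect Non-negative weights of the environmental
#'   and spatial terms on the log-intensity; defaults depend on scenario.
#' @param mean_abundance Expected count per cell per period (default 0.9,
#'   giving ~2800 pooled individuals at default dimensions).
#' @param overdispersion Negative-binomial overdispersion (variance
#'   `mu + overdispersion * mu^2`; 0 = Poisson limit, default 1).
#' @param epsilon Bernoulli noise rate for `NESTED` incidence (default 0.05).
#' @param coast_length_km Along-shore extent (default 60).
#' @param tide_range_m Spring tide range used in the Beach Index (fixed
#'   2.0 m in the synthetic environment).
#' @param seed Mandatory integer seed.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("ENV_ONLY", "SPACE_ONLY", "MIXED",
                                         "NESTED", "TURNOVER"),
                            n_sites = 14, n_species = 112,
                            bi_range = c(1.59, 2.81),
                            niche_breadth = NULL, spatial_range = 15,
                            env_effect = NULL, space_effect = NULL,
                            mean_abundance = 0.9, overdispersion = 1,
                            epsilon = 0.05, coast_length_km = 60,
                            tide_range_m = 2, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("seed is mandatory")
  if (n_sites < 3) stop("n_sites must be >= 3")
  if (spatial_range <= 0) stop("spatial_range must be positive")
  if (mean_abundance <= 0) stop("non-positive intensity configuration: mean_abundance must be > 0")
  defaults <- switch(scenario,
    ENV_ONLY  = c(env = 2.0, space = 0.0),
    SPACE_ONLY = c(env = 0.0, space = 2.0),
    MIXED     = c(env = 1.5, space = 1.5),
    NESTED    = c(env = 2.0, space = 0.0),
    TURNOVER  = c(env = 4.0, space = 0.0))
  if (is.null(env_effect)) env_effect <- defaults[["env"]]
  if (is.null(space_effect)) space_effect <- defaults[["space"]]
  if (env_effect < 0 || space_effect < 0) stop("effect weights must be >= 0")
  if (is.null(niche_breadth))
    niche_breadth <- if (scenario == "TURNOVER") 0.25 else 0.35
  structure(list(scenario = scenario, n_sites = n_sites, n_species = n_species,
                 bi_range = sort(bi_range), niche_breadth = niche_breadth,
                 spatial_range = spatial_range, env_effect = env_effect,
                 space_effect = space_effect, mean_abundance = mean_abundance,
                 overdispersion = overdispersion, epsilon = epsilon,
                 coast_length_km = coast_length_km, tide_range_m = tide_range_m,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate site records along a synthetic coastline
#'
#' Places `n_sites` at irregular intervals along a smooth gently curving
#' coastline embedded in geographic space (decimal degrees, subtropical
#' Atlantic coast setting), deterministically under the configuration seed.
#'
#' @param config A [scenario_config()].
#' @return Data frame with `site_id`, `beach`, `latitude`, `longitude` and
#'   `along_km` (along-shore position).
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rs <- .seed_stream(.child_seed(config$seed, 1L))
  on.exit(.restore_seed(rs))
  n <- config$n_sites
  gaps <- stats::rgamma(n - 1, shape = 2, rate = 1)
  s <- c(0, cumsum(gaps)) / sum(gaps) * config$coast_length_km
  # smooth heading along the coast: gentle meander around ENE
  theta <- 0.35 + 0.4 * sin(2 * pi * s / config$coast_length_km * 1.25)
  ds <- diff(c(0, s))
  x <- cumsum(ds * cos(theta))  # km east
  y <- cumsum(ds * sin(theta))  # km north
  lat0 <- -23.7; lon0 <- -45.5
  lat <- lat0 + y / 110.57
  lon <- lon0 + x / (111.32 * cos(lat0 * pi / 180))
  ids <- sprintf("S%02d", seq_len(n))
  data.frame(site_id = ids, beach = ids, latitude = lat, longitude = lon,
             along_km = s, stringsAsFactors = FALSE)
}

#' Generate a synthetic environment table
#'
#' Draws grain size, slope and width jointly so the computed Beach Index
#' spans `config$bi_range` exactly (slope is back-solved from the index at
#' the configured tide range, so the invariant holds by construction).
#' Under `SPACE_ONLY` the environment is constant across sites; under every
#' other scenario the Beach Index values are spatially shuffled, i.e.
#' decorrelated from along-shore position.
#'
#' @param sites Output of [generate_sites()].
#' @param config A [scenario_config()].
#' @return An `env_table` data frame (see [as_env_table()]) with
#'   `beach_index` computed.
#' @export
generate_env <- function(sites, config) {
  stopifnot(inherits(config, "scenario_config"))
  rs <- .seed_stream(.child_seed(config$seed, 2L))
  on.exit(.restore_seed(rs))
  n <- nrow(sites)
  if (config$scenario == "SPACE_ONLY") {
    bi <- rep(mean(config$bi_range), n)
    mz <- rep(2.2, n)
    width <- rep(80, n)
  } else {
    bi <- sample(seq(config$bi_range[1], config$bi_range[2], length.out = n))
    rk <- rank(bi, ties.method = "first")
    mz <- seq(0.9, 3.4, length.out = n)[rk] + stats::rnorm(n, 0, 0.05)
    width <- pmax(10, 25 + 115 * (bi - config$bi_range[1]) /
                    max(diff(config$bi_range), 1e-9) + stats::rnorm(n, 0, 8))
  }
  slope <- (mz + 1) * config$tide_range_m / 10^bi
  df <- data.frame(site_id = sites$site_id, width_m = width,
                   slope_ratio = slope, mean_diameter_phi = mz,
                   sorting_phi = stats::runif(n, 0.3, 1.1),
                   caco3_pct = stats::runif(n, 0.3, 7.5),
                   om_pct = stats::runif(n, 0.1, 1.4),
                   stringsAsFactors = FALSE)
  as_env_table(df, tide_range_m = config$tide_range_m)
}

#' Generate synthetic community matrices with known truth
#'
#' For the continuous scenarios, the log-intensity of species i at site j is
#' `base_i + env_effect * exp(-(BI_j - opt_i)^2 / (2 sigma^2)) +
#' space_effect * W_i(x_j)`, with `W_i` independent zero-mean latent fields
#' with exponential covariance `exp(-d / rho)`; counts are drawn
#' negative-binomially around the intensity, and the two sampling periods
#' are conditionally independent draws from the same intensity. `NESTED`
#' instead builds a deterministic subset structure along the Beach Index
#' order (species i occupies the `depth_i` most dissipative sites), flips
#' cells with probability `epsilon`, and draws strictly positive counts for
#' present cells so the incidence is exactly the constructed one.
#'
#' @param sites Output of [generate_sites()].
#' @param env Output of [generate_env()].
#' @param config A [scenario_config()].
#' @return List with `fall` and `spring` (`community_matrix` objects) and
#'   `truth` (scenario, optima, breadths, latent fields, expected dominant
#'   variance fraction and expected nestedness sign).
#' @export
generate_community <- function(sites, env, config) {
  stopifnot(inherits(config, "scenario_config"))
  rs <- .seed_stream(.child_seed(config$seed, 3L))
  on.exit(.restore_seed(rs))
  n <- nrow(sites); p <- config$n_species
  bi <- env$beach_index
  spp <- sprintf("sp%03d", seq_len(p))
  expected_dominant <- switch(config$scenario,
    ENV_ONLY = "env", SPACE_ONLY = "space", MIXED = "both",
    NESTED = "env", TURNOVER = "env")
  expected_nestedness <- switch(config$scenario,
    NESTED = "nested", TURNOVER = "anti-nested", "none")

  if (config$scenario == "NESTED") {
    q <- rank(-bi, ties.method = "first")          # 1 = most dissipative
    depth <- ceiling(seq_len(p) * n / p)           # sites occupied per species
    inc <- outer(q, depth, "<=") * 1L
    if (config$epsilon > 0) {
      flip <- matrix(stats::runif(n * p) < config$epsilon, n, p)
      inc <- ifelse(flip, 1L - inc, inc)
    }
    draw <- function() {
      cnt <- inc * (1L + stats::rnbinom(n * p, mu = config$mean_abundance,
                                        size = 1 / max(config$overdispersion, 1e-8)))
      matrix(as.integer(cnt), n, p, dimnames = list(sites$site_id, spp))
    }
    fall <- community_matrix(draw(), period = "fall")
    spring <- community_matrix(draw(), period = "spring")
    truth <- list(scenario = config$scenario, depth = depth,
                  site_rank = q, optima = NULL, breadths = NULL,
                  expected_dominant = expected_dominant,
                  expected_nestedness = expected_nestedness,
                  seed = config$seed)
    return(list(fall = fall, spring = spring, truth = truth))
  }

  optima <- if (config$scenario == "TURNOVER")
    seq(config$bi_range[1], config$bi_range[2], length.out = p)
  else stats::runif(p, config$bi_range[1], config$bi_range[2])
  base <- stats::rnorm(p, 0, 1)
  env_term <- config$env_effect *
    exp(-outer(bi, optima, "-")^2 / (2 * config$niche_breadth^2))
  D <- distance_matrix(sites, method = "haversine")
  C <- exp(-D / config$spatial_range)
  L <- chol(C + diag(1e-8, n))
  W <- crossprod(L, matrix(stats::rnorm(n * p), n, p))
  log_lambda <- matrix(base, n, p, byrow = TRUE) + env_term +
    config$space_effect * W
  lambda <- exp(log_lambda)
  lambda <- lambda * (config$mean_abundance / mean(lambda))
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("non-positive intensity configuration")
  draw <- function() {
    cnt <- stats::rnbinom(n * p, mu = lambda,
                          size = 1 / max(config$overdispersion, 1e-8))
    matrix(as.integer(cnt), n, p, dimnames = list(sites$site_id, spp))
  }
  fall <- community_matrix(draw(), period = "fall")
  spring <- community_matrix(draw(), period = "spring")
  truth <- list(scenario = config$scenario, optima = optima,
                breadths = rep(config$niche_breadth, p),
                latent_fields = W, lambda = lambda,
                expected_dominant = expected_dominant,
                expected_nestedness = expected_nestedness,
                seed = config$seed)
  list(fall = fall, spring = spring, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: generates sites, environment and the two period
#' communities under one seed, optionally writing the standard CSV schemas
#' (`sites.csv`, `env.csv`, `community_fall.csv`, `community_spring.csv`)
#' plus `truth.json` to a directory.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return List with `sites`, `env`, `fall`, `spring`, `truth`, `config`.
#' @export
simulate_metacommunity <- function(config, dir = NULL) {
  sites <- generate_sites(config)
  env <- generate_env(sites, config)
  com <- generate_community(sites, env, config)
  out <- list(sites = sites, env = env, fall = com$fall, spring = com$spring,
              truth = com$truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sites[, c("site_id", "beach", "latitude", "longitude")],
                     file.path(dir, "sites.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(env), file.path(dir, "env.csv"),
                     row.names = FALSE)
    write_community(com$fall, file.path(dir, "community_fall.csv"))
    write_community(com$spring, file.path(dir, "community_spring.csv"))
    truth <- com$truth
    truth$latent_fields <- NULL  # matrices are kept in memory only
    truth$lambda <- NULL
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
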