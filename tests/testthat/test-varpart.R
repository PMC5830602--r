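test_that("Hellinger transformation normalises rows and guards misuse", {
  Y <- named_matrix(c(1, 3, 5, 0), 2, 2)
  H <- hellinger(Y)
  expect_equal(unname(H[1, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(H[2, ]), c(1, 0))
  set.seed(2)
  R <- named_matrix(rpois(60, 3) + 1, 6, 10)
  expect_equal(unname(rowSums(hellinger(R)^2)), rep(1, 6))
  # agrees with the standard implementation
  expect_equal(unname(unclass(hellinger(R)))[, ],
               unname(as.matrix(vegan::decostand(R, "hellinger")))[, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  Y0 <- named_matrix(c(1, 1, 0, 0), 2, 2)
  expect_error(hellinger(Y0), "s02")
  expect_warning(hellinger(hellinger(Y)), "idempotent")
})

test_that("RDA R2 matches the hat-matrix oracle and vegan", {
  set.seed(11)
  for (r in 1:10) {
    n <- 12
    Y <- matrix(rnorm(n * 5), n, 5)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
    fit <- rda_r2(Y, X)
    # brute-force projection
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
    r2 <- sum((H %*% Yc)^2) / sum(Yc^2)
    expect_equal(fit$r2, r2, tolerance = 1e-10)
    expect_equal(fit$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 2 - 1), tolerance = 1e-10)
    expect_equal(fit$f, (r2 / 2) / ((1 - r2) / (n - 2 - 1)), tolerance = 1e-10)
    # independent implementation cross-check
    vfit <- vegan::rda(Y ~ X)
    expect_equal(fit$adj_r2, vegan::RsquareAdj(vfit)$adj.r.squared,
                 tolerance = 1e-10)
  }
  # perfect fit and orthogonal predictors
  x <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "x"))
  expect_equal(rda_r2(x, x)$r2, 1, tolerance = 1e-12)
  expect_equal(rda_r2(x, x)$adj_r2, 1, tolerance = 1e-12)
  y <- cbind(v = rep(c(1, -1), 5))
  z <- cbind(w = rep(c(1, 1, -1, -1), length.out = 10))
  expect_lt(abs(rda_r2(y, z)$r2), 0.2)
  expect_lt(rda_r2(matrix(rnorm(10), 10, 1), z)$adj_r2 - 0, 1)
  # collinear predictors are named
  Xd <- cbind(a = rnorm(10), b = 1:10, c = 2 * (1:10))
  expect_error(rda_r2(matrix(rnorm(10)), Xd), "c")
})

test_that("forward selection obeys the double stopping rule", {
  set.seed(21)
  n <- 30
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  # response built from x1 and x2 only
  Y <- cbind(x1 + 0.5 * x2 + rnorm(n, 0, 0.3),
             0.8 * x1 + rnorm(n, 0, 0.3))
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  sel <- forward_select(Y, X, n_perm = 199, seed = 1)
  expect_equal(sel$variable[1], "x1")
  # first pick agrees with exhaustive best single-variable fit
  single <- vapply(colnames(X), function(v)
    rda_r2(Y, X[, v, drop = FALSE])$r2, numeric(1))
  expect_equal(sel$variable[1], names(which.max(single)))
  expect_false("x3" %in% sel$variable)
  expect_true(all(diff(c(0, sel$cum_r2)) > 0))

  # perfect single predictor stops via the global adjusted-R2 criterion
  yx <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "y"))
  sel2 <- forward_select(yx, cbind(x1 = drop(yx), x2 = rnorm(20)),
                         n_perm = 199, seed = 2)
  expect_equal(sel2$variable, "x1")
  expect_equal(attr(sel2, "stopped_by"), "global adj R2")

  # pure-noise candidate is (almost) never selected
  picked <- 0
  for (s in 1:40) {
    set.seed(300 + s)
    Yn <- matrix(rnorm(15 * 4), 15, 4)
    Xn <- cbind(noise = rnorm(15))
    if (nrow(forward_select(Yn, Xn, n_perm = 99, seed = s)) > 0)
      picked <- picked + 1
  }
  expect_lte(picked, 6)  # ~alpha = 0.05 false-selection rate

  empty <- forward_select(Y, X[, 0, drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("partial RDA test reduces correctly and is calibrated under the null", {
  set.seed(31)
  n <- 16
  Y <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(x = rnorm(n))
  # with empty W the F statistic equals the plain RDA F
  t0 <- partial_rda_test(Y, X, NULL, n_perm = 99, seed = 1)
  expect_equal(t0$f, rda_r2(Y, X)$f, tolerance = 1e-12)
  # X duplicated inside W is degenerate
  expect_error(partial_rda_test(Y, X, cbind(X, w = rnorm(n)), n_perm = 99),
               "span")
  expect_warning(partial_rda_test(Y, X, NULL, n_perm = 49, seed = 1), "coarse")

  # null calibration: X noise, W explanatory; p ~ Uniform(0, 1]
  set.seed(32)
  pvals <- numeric(200)
  for (r in 1:200) {
    w <- rnorm(12)
    Yn <- cbind(w + rnorm(12, 0, 0.5), rnorm(12))
    pvals[r] <- partial_rda_test(Yn, cbind(x = rnorm(12)), cbind(w = w),
                                 n_perm = 199, seed = 1000 + r)$p
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variation partitioning satisfies its algebraic identities", {
  set.seed(41)
  for (r in 1:10) {
    n <- 14
    Y <- hellinger(named_matrix(rpois(n * 20, 2) + 1, n, 20))
    E <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("e1", "e2")))
    S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
    vp <- variation_partition(Y, E, S, n_perm = 99, seed = r)
    expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-12)
    expect_equal(vp$a + vp$b, vp$adj_r2[["E"]], tolerance = 1e-12)
    expect_equal(vp$c + vp$b, vp$adj_r2[["S"]], tolerance = 1e-12)
    expect_gt(vp$test_a$p, 0); expect_lte(vp$test_a$p, 1)
  }

  # E explains Y perfectly, S empty
  n <- 12
  E1 <- cbind(e = rnorm(n))
  vp1 <- variation_partition(E1, E1, NULL, n_perm = 99, seed = 1)
  expect_equal(vp1$a, 1, tolerance = 1e-10)
  expect_equal(vp1$b, 0, tolerance = 1e-10)
  expect_equal(vp1$c, 0, tolerance = 1e-10)
  expect_equal(vp1$d, 0, tolerance = 1e-10)

  # identical predictor sets: only shared variance
  set.seed(42)
  Y2 <- matrix(rnorm(n * 3), n, 3)
  X2 <- cbind(q = rnorm(n))
  vp2 <- suppressWarnings(variation_partition(Y2, X2, X2 + 0, n_perm = 99, seed = 2))
  expect_equal(vp2$a, 0, tolerance = 1e-10)
  expect_equal(vp2$c, 0, tolerance = 1e-10)
  expect_equal(vp2$b, rda_r2(Y2, X2)$adj_r2, tolerance = 1e-10)
})
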