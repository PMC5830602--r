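test_that("wide and long CSV layouts read, validate and round-trip", {
  tmp <- withr::local_tempdir()
  # empty community
  p0 <- file.path(tmp, "zero.csv")
  writeLines(c("site_id,a,b,c", "s1,0,0,0", "s2,0,0,0"), p0)
  m0 <- read_community(p0)
  expect_equal(sum(m0$counts), 0)
  expect_warning(to_presence(m0), "empty")

  # long layout aggregates duplicates by summation
  pl <- file.path(tmp, "long.csv")
  writeLines(c("site_id,species,count", "s1,a,2", "s1,a,3", "s2,b,1"), pl)
  ml <- read_community(pl, layout = "long")
  expect_equal(ml$counts["s1", "a"], 2L + 3L)
  expect_equal(ml$counts["s1", "b"], 0L)

  # invalid cells are named
  pb <- file.path(tmp, "bad.csv")
  writeLines(c("site_id,a,b", "s1,-1,0", "s2,0,2"), pb)
  expect_error(read_community(pb), "s1.*a", ignore.case = TRUE)
  pd <- file.path(tmp, "dup.csv")
  writeLines(c("site_id,a,b", "s1,1,0", "s1,0,2"), pd)
  expect_error(read_community(pd), "duplicate")

  # synthetic 14 x 112 fixture round-trips bit-identically
  sim <- simulate_metacommunity(scenario_config("MIXED", seed = 101))
  pr <- file.path(tmp, "round.csv")
  write_community(sim$fall, pr)
  back <- read_community(pr, period = "fall")
  expect_identical(back$counts, sim$fall$counts)
})

test_that("pooling sums counts over the species union and checks sites", {
  a <- community_matrix(named_matrix(c(1, 0, 0, 2), 2, 2), "fall")
  b <- community_matrix(named_matrix(c(0, 3, 1, 0), 2, 2), "spring")
  pooled <- pool_periods(a, b)
  expect_equal(unname(pooled$counts), matrix(c(1, 3, 1, 2), 2, 2, byrow = TRUE))
  expect_equal(pooled$period, "pooled")

  # identity with an all-zero matrix
  z <- community_matrix(named_matrix(0, 2, 2), "spring")
  expect_equal(pool_periods(a, z)$counts, a$counts)

  # species only in one period appear with their counts
  spring_only <- community_matrix(
    matrix(c(4L, 7L), 2, 1, dimnames = list(c("s01", "s02"), "extra")), "spring")
  pooled2 <- pool_periods(a, spring_only)
  expect_equal(unname(pooled2$counts[, "extra"]), c(4, 7))

  # mismatched sites are listed
  c2 <- community_matrix(matrix(1L, 1, 1, dimnames = list("sX", "p01")), "spring")
  expect_error(pool_periods(a, c2), "sX")

  # commutativity and associativity on a shared site set
  set.seed(42)
  ms <- replicate(3, random_community_pair()$fall, simplify = FALSE)
  expect_equal(pool_periods(ms[[1]], ms[[2]])$counts[, sort(species(ms[[1]]))],
               pool_periods(ms[[2]], ms[[1]])$counts[, sort(species(ms[[1]]))])
  lhs <- pool_periods(pool_periods(ms[[1]], ms[[2]]), ms[[3]])
  rhs <- pool_periods(ms[[1]], pool_periods(ms[[2]], ms[[3]]))
  expect_equal(lhs$counts[, sort(colnames(lhs$counts))],
               rhs$counts[, sort(colnames(rhs$counts))])
})

test_that("presence conversion tracks marginals and the OR property", {
  m <- community_matrix(named_matrix(c(0, 5, 2, 0), 2, 2))
  pr <- to_presence(m)
  expect_equal(unname(pr$incidence), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(pr$fill, 2L)
  expect_equal(pr$fill, sum(pr$row_fills))
  expect_equal(pr$fill, sum(pr$col_fills))

  # pooled presence equals element-wise OR of period presences
  set.seed(7)
  for (r in 1:20) {
    pair <- random_community_pair()
    por <- (to_presence(pair$fall)$incidence | to_presence(pair$spring)$incidence) * 1L
    expect_equal(unname(to_presence(pool_periods(pair$fall, pair$spring))$incidence),
                 unname(por))
  }
})

test_that("exclusive species and richness follow set logic", {
  M <- named_matrix(c(1, 1, 0,
                      0, 1, 0,
                      0, 0, 1), 3, 3)
  m <- community_matrix(M)
  ex <- exclusive_species(m)
  expect_equal(ex$species$s01, "p01")   # present at one site only
  expect_equal(ex$species$s03, "p03")
  expect_false("p02" %in% unlist(ex$species))  # present at two sites

  # grouping two sectors into one beach makes the shared species exclusive
  grp <- c(s01 = "A", s02 = "A", s03 = "B")
  exg <- exclusive_species(m, grp)
  expect_setequal(exg$species$A, c("p01", "p02"))
  expect_error(exclusive_species(m, c(s01 = "A")), "missing")

  # sum of exclusives never exceeds the species total
  set.seed(9)
  for (r in 1:10) {
    mm <- random_community_pair()$fall
    expect_lte(sum(exclusive_species(mm)$counts), richness(mm)$total)
  }

  r <- richness(m)
  expect_equal(unname(r$by_site), c(2, 1, 1))
  expect_equal(r$total, 3)
  empty <- community_matrix(named_matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(unname(richness(empty)$by_site), c(0, 1))
})
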