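# Shared fixture builders; everything is generated in code under fixed seeds.

named_matrix <- function(x, nr, nc, byrow = TRUE) {
  matrix(x, nr, nc, byrow = byrow,
         dimnames = list(sprintf("s%02d", seq_len(nr)),
                         sprintf("p%02d", seq_len(nc))))
}

# Random 0/1 matrix with no empty rows or columns (resampled until valid).
random_incidence <- function(nr, nc, fill = 0.4) {
  repeat {
    M <- named_matrix(stats::rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(M) > 0) && all(colSums(M) > 0)) return(M)
  }
}

# Perfectly nested staircase: row i holds species 1..(n - i + 1).
staircase <- function(n) {
  M <- named_matrix(0L, n, n)
  for (i in seq_len(n)) M[i, seq_len(n - i + 1)] <- 1L
  M
}

# Random small community pair on a common site set.
random_community_pair <- function(nr = 6, nc = 10) {
  a <- community_matrix(named_matrix(stats::rpois(nr * nc, 1), nr, nc), "fall")
  b <- community_matrix(named_matrix(stats::rpois(nr * nc, 1), nr, nc), "spring")
  list(fall = a, spring = b)
}

# The bundled 14-sector environment table.
saopaulo_env <- function() {
  read_env(system.file("extdata", "env_saopaulo.csv", package = "nestshore"))
}

saopaulo_sites <- function() {
  utils::read.csv(system.file("extdata", "sites_saopaulo.csv",
                              package = "nestshore"))
}
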