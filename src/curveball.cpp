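#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n), using R's RNG stream.
static inline int unif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One curveball trade: pick two distinct sites, pool the species held by
// exactly one of them, and redistribute that pool at random while keeping
// each site's richness. Row and column sums are invariant by construction.
// `xt` is the incidence matrix stored species-by-site (transposed), so one
// site's list is a contiguous block.
static void curveball_step(int *xt, int n_sites, int n_species,
                           std::vector<int> &diff) {
  if (n_sites < 2) return;
  int i = unif_int(n_sites);
  int j = unif_int(n_sites - 1);
  if (j >= i) ++j;
  int *a = xt + (size_t)i * n_species;
  int *b = xt + (size_t)j * n_species;
  diff.clear();
  int ai = 0;
  for (int k = 0; k < n_species; ++k) {
    if (a[k] != b[k]) {
      diff.push_back(k);
      if (a[k]) ++ai;
    }
  }
  int m = (int)diff.size();
  if (m < 2 || ai == 0 || ai == m) return;
  for (int k = m - 1; k > 0; --k) {
    int l = unif_int(k + 1);
    std::swap(diff[k], diff[l]);
  }
  for (int k = 0; k < m; ++k) {
    int sp = diff[k];
    a[sp] = (k < ai) ? 1 : 0;
    b[sp] = (k < ai) ? 0 : 1;
  }
}

// [[Rcpp::export]]
List curveball_samples_cpp(IntegerMatrix inc, int n_samples, int burn_in,
                           int thin) {
  int nr = inc.nrow(), nc = inc.ncol();
  std::vector<int> xt((size_t)nr * nc);
  for (int i = 0; i < nr; ++i)
    for (int k = 0; k < nc; ++k) xt[(size_t)i * nc + k] = inc(i, k);
  List out(n_samples);
  std::vector<int> diff;
  diff.reserve(nc);
  for (int s = 0; s < burn_in; ++s) curveball_step(xt.data(), nr, nc, diff);
  for (int t = 0; t < n_samples; ++t) {
    for (int s = 0; s < thin; ++s) curveball_step(xt.data(), nr, nc, diff);
    IntegerMatrix m(nr, nc);
    for (int i = 0; i < nr; ++i)
      for (int k = 0; k < nc; ++k) m(i, k) = xt[(size_t)i * nc + k];
    out[t] = m;
  }
  return out;
}
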