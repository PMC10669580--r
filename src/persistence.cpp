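#include <Rcpp.h>
using namespace Rcpp;

// 0-dimensional persistence of the sublevel-set filtration of an integer
// intensity image on the 4-connected pixel grid, by union-find with the
// elder rule (at a merge the component with the earlier birth survives;
// ties broken by creation order, i.e. raster order of the birth pixel).
//
// Pixels are activated in order of (value, linear index). A pixel whose
// activation creates a new component opens a bar; a merge closes the
// younger bar at the current level. Every pixel is assigned to the bar of
// the component it lands in at activation time, which is what the
// contrast-enhancement step consumes. Bars that are born and die at the
// same level (plateau pixels joining an existing component) are recorded
// with zero lifespan; the R wrapper drops them and remaps their pixels to
// the absorbing bar via `merged_into`.

static int uf_find(std::vector<int> &parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

// [[Rcpp::export]]
List h0_persist_cpp(IntegerVector values, int nrow, int ncol) {
  const int n = nrow * ncol;
  if ((int)values.size() != n) stop("values length does not match dimensions");

  // sort pixel indices by (value, index)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return values[a] < values[b];
  });

  std::vector<int> parent(n, -1);       // union-find parent, -1 = inactive
  std::vector<int> comp_size(n, 0);
  std::vector<int> root_bar(n, -1);     // bar id carried by each root
  std::vector<int> bar_birth, bar_birth_pixel, bar_death, bar_merged_into;
  std::vector<int> pixel_bar(n, -1);

  // growth curve of the essential component (the one containing the first
  // activated pixel): component size recorded after each distinct level
  std::vector<int> growth_level, growth_size;
  const int p_first = ord[0];

  int i = 0;
  while (i < n) {
    const int level = values[ord[i]];
    int j = i;
    for (; j < n && values[ord[j]] == level; ++j) {
      const int p = ord[j];
      const int r = p / ncol, c = p % ncol;
      parent[p] = p;
      comp_size[p] = 1;
      const int bid = (int)bar_birth.size();
      bar_birth.push_back(level);
      bar_birth_pixel.push_back(p);
      bar_death.push_back(NA_INTEGER);
      bar_merged_into.push_back(NA_INTEGER);
      root_bar[p] = bid;

      const int nb[4] = { (r > 0) ? p - ncol : -1,
                          (r < nrow - 1) ? p + ncol : -1,
                          (c > 0) ? p - 1 : -1,
                          (c < ncol - 1) ? p + 1 : -1 };
      for (int k = 0; k < 4; ++k) {
        const int q = nb[k];
        if (q < 0 || parent[q] == -1) continue;
        int rp = uf_find(parent, p), rq = uf_find(parent, q);
        if (rp == rq) continue;
        int bp = root_bar[rp], bq = root_bar[rq];
        // elder rule: smaller (birth, bar id) survives
        int surv_root, dead_root;
        if (bar_birth[bp] < bar_birth[bq] ||
            (bar_birth[bp] == bar_birth[bq] && bp < bq)) {
          surv_root = rp; dead_root = rq;
        } else {
          surv_root = rq; dead_root = rp;
        }
        const int dead_bar = root_bar[dead_root];
        const int surv_bar = root_bar[surv_root];
        bar_death[dead_bar] = level;
        bar_merged_into[dead_bar] = surv_bar;
        // union by attaching dead root under surviving root
        parent[dead_root] = surv_root;
        comp_size[surv_root] += comp_size[dead_root];
        root_bar[surv_root] = surv_bar;
      }
      pixel_bar[p] = root_bar[uf_find(parent, p)];
    }
    growth_level.push_back(level);
    growth_size.push_back(comp_size[uf_find(parent, p_first)]);
    i = j;
  }

  const int essential = root_bar[uf_find(parent, p_first)];

  return List::create(
    _["birth"] = wrap(bar_birth),
    _["death"] = wrap(bar_death),
    _["birth_pixel"] = wrap(bar_birth_pixel),
    _["merged_into"] = wrap(bar_merged_into),
    _["pixel_bar"] = wrap(pixel_bar),
    _["essential"] = essential,
    _["growth_level"] = wrap(growth_level),
    _["growth_size"] = wrap(growth_size));
}
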