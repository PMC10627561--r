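// LCA duplication-loss reconciliation of a gene tree against a species (or
// MUL) tree, plus exhaustive/greedy minimisation over ambiguous tip
// assignments for multilabeled trees.
//
// Trees arrive as 1-based parent arrays (0 = root) with a postorder node
// sequence; species nodes additionally carry their root depth.

#include <Rcpp.h>
using namespace Rcpp;

static inline int lca2(int a, int b, const IntegerVector& spar,
                       const IntegerVector& sdep) {
  while (a != b) {
    if (sdep[a - 1] >= sdep[b - 1]) a = spar[a - 1];
    else b = spar[b - 1];
  }
  return a;
}

struct ReconResult {
  int dups;
  int losses;
};

// tipmap: per gene node, 1-based species node for tips, 0 for internals
static ReconResult recon_core(const IntegerVector& gpar,
                              const IntegerVector& gpost,
                              const std::vector<int>& tipmap,
                              const IntegerVector& spar,
                              const IntegerVector& sdep,
                              std::vector<int>* map_out,
                              std::vector<int>* dup_out) {
  int ng = gpar.size();
  std::vector<int> map(ng, 0);
  std::vector<char> isdup(ng, 0);
  std::vector<std::vector<int> > kids(ng);
  for (int v = 0; v < ng; ++v)
    if (gpar[v] > 0) kids[gpar[v] - 1].push_back(v + 1);
  for (int i = 0; i < ng; ++i) {
    int v = gpost[i];
    if (tipmap[v - 1] > 0) { map[v - 1] = tipmap[v - 1]; continue; }
    int m = 0;
    for (size_t j = 0; j < kids[v - 1].size(); ++j) {
      int u = kids[v - 1][j];
      m = (m == 0) ? map[u - 1] : lca2(m, map[u - 1], spar, sdep);
    }
    map[v - 1] = m;
    for (size_t j = 0; j < kids[v - 1].size(); ++j)
      if (map[kids[v - 1][j] - 1] == m) isdup[v - 1] = 1;
  }
  int losses = 0, ndup = 0;
  for (int v = 1; v <= ng; ++v) {
    int p = gpar[v - 1];
    if (p == 0) continue;
    int d = sdep[map[v - 1] - 1] - sdep[map[p - 1] - 1];
    losses += d - 1 + (isdup[p - 1] ? 1 : 0);
  }
  for (int v = 0; v < ng; ++v) ndup += isdup[v];
  if (map_out) *map_out = map;
  if (dup_out) {
    dup_out->assign(ng, 0);
    for (int v = 0; v < ng; ++v) (*dup_out)[v] = isdup[v];
  }
  ReconResult r; r.dups = ndup; r.losses = losses;
  return r;
}

// [[Rcpp::export]]
List cpp_lca_reconcile(IntegerVector gpar, IntegerVector gpost,
                       IntegerVector gtipmap, IntegerVector spar,
                       IntegerVector sdep) {
  std::vector<int> tipmap(gtipmap.begin(), gtipmap.end());
  std::vector<int> map, dup;
  ReconResult r = recon_core(gpar, gpost, tipmap, spar, sdep, &map, &dup);
  return List::create(_["map"] = wrap(map), _["isdup"] = wrap(dup),
                      _["dups"] = r.dups, _["losses"] = r.losses);
}

// optA/optB: per gene node, the two admissible species-tip assignments for
// tips (equal when unambiguous), 0 for internal nodes.
// [[Rcpp::export]]
List cpp_mul_reconcile(IntegerVector gpar, IntegerVector gpost,
                       IntegerVector optA, IntegerVector optB,
                       IntegerVector spar, IntegerVector sdep, int cap) {
  int ng = gpar.size();
  std::vector<int> tipmap(ng, 0);
  std::vector<int> amb;
  for (int v = 0; v < ng; ++v) {
    if (optA[v] > 0) {
      tipmap[v] = optA[v];
      if (optB[v] > 0 && optB[v] != optA[v]) amb.push_back(v);
    }
  }
  int k = amb.size();
  int best_total = INT_MAX, best_dups = 0, best_losses = 0;
  bool exhaustive = k <= cap;
  if (exhaustive) {
    for (long mask = 0; mask < (1L << k); ++mask) {
      for (int j = 0; j < k; ++j)
        tipmap[amb[j]] = (mask >> j) & 1 ? optB[amb[j]] : optA[amb[j]];
      ReconResult r = recon_core(gpar, gpost, tipmap, spar, sdep,
                                 NULL, NULL);
      int tot = r.dups + r.losses;
      if (tot < best_total ||
          (tot == best_total && r.dups < best_dups)) {
        best_total = tot; best_dups = r.dups; best_losses = r.losses;
      }
    }
  } else {
    // greedy descent (1-flip, then 2-flip neighbourhoods) from
    // deterministic starts
    for (int start = 0; start < 2; ++start) {
      for (int j = 0; j < k; ++j)
        tipmap[amb[j]] = start ? optB[amb[j]] : optA[amb[j]];
      ReconResult cur = recon_core(gpar, gpost, tipmap, spar, sdep,
                                   NULL, NULL);
      bool improved = true;
      while (improved) {
        improved = false;
        for (int j = 0; j < k; ++j) {
          int old = tipmap[amb[j]];
          tipmap[amb[j]] = (old == optA[amb[j]]) ? optB[amb[j]]
                                                 : optA[amb[j]];
          ReconResult r = recon_core(gpar, gpost, tipmap, spar, sdep,
                                     NULL, NULL);
          if (r.dups + r.losses < cur.dups + cur.losses) {
            cur = r; improved = true;
          } else {
            tipmap[amb[j]] = old;
          }
        }
        if (!improved) {
          for (int j = 0; j < k && !improved; ++j) {
            for (int j2 = j + 1; j2 < k && !improved; ++j2) {
              int o1 = tipmap[amb[j]], o2 = tipmap[amb[j2]];
              tipmap[amb[j]] = (o1 == optA[amb[j]]) ? optB[amb[j]]
                                                    : optA[amb[j]];
              tipmap[amb[j2]] = (o2 == optA[amb[j2]]) ? optB[amb[j2]]
                                                      : optA[amb[j2]];
              ReconResult r = recon_core(gpar, gpost, tipmap, spar, sdep,
                                         NULL, NULL);
              if (r.dups + r.losses < cur.dups + cur.losses) {
                cur = r; improved = true;
              } else {
                tipmap[amb[j]] = o1; tipmap[amb[j2]] = o2;
              }
            }
          }
        }
      }
      int tot = cur.dups + cur.losses;
      if (tot < best_total ||
          (tot == best_total && cur.dups < best_dups)) {
        best_total = tot; best_dups = cur.dups; best_losses = cur.losses;
      }
    }
  }
  return List::create(_["dups"] = best_dups, _["losses"] = best_losses,
                      _["total"] = best_total,
                      _["exhaustive"] = exhaustive,
                      _["n_ambiguous"] = k);
}
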