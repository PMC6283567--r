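#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Backward-in-time simulator for one gene under the two-deme demography.
//
// Phase 1 (present back to split_time): discrete-time Wright-Fisher in two
// demes of n_hap haplotypes each with symmetric per-lineage per-generation
// migration probability m.  Sampled lineages span the whole deme, so the
// usual Hudson approximation (n << N) does not hold; backward DTWF with
// simultaneous and multiple mergers is the appropriate model at this scale.
//
// Phase 2 (older than split_time): continuous-time Hudson coalescent in the
// merged ancestral population of anc_hap haplotypes, optionally switching to
// pre_anc_hap haplotypes further back than expansion_time (a step expansion).
//
// Mutations: infinite-sites, rate mu per bp per generation, positions drawn
// uniformly on 1..region_length without replacement.  Uses R's RNG so that
// set.seed() in R fully determines the output.

// [[Rcpp::export(name = ".sim_gene_cpp")]]
List sim_gene_cpp(int n_hap, int split_time, double migration_rate,
                  double anc_hap, double expansion_time, double pre_anc_hap,
                  int region_length, double mutation_rate) {
  const int n_tips = 2 * n_hap;
  std::vector<int> parent;
  std::vector<double> node_time;
  parent.reserve(2 * n_tips);
  node_time.reserve(2 * n_tips);
  for (int i = 0; i < n_tips; ++i) { parent.push_back(-1); node_time.push_back(0.0); }

  // active lineages per deme; tips 0..n_hap-1 are deme A, the rest deme B
  std::vector<int> act[2];
  act[0].reserve(n_hap); act[1].reserve(n_hap);
  for (int i = 0; i < n_hap; ++i) act[0].push_back(i);
  for (int i = 0; i < n_hap; ++i) act[1].push_back(n_hap + i);

  // ---- phase 1: DTWF generations with migration ----
  // slot arrays with generation stamps avoid per-generation clearing; a
  // slot occupant with id >= gen_node_start is a merge node created this
  // generation (node ids only grow)
  std::vector<int> slot_node[2], slot_gen[2], claimed[2];
  for (int d = 0; d < 2; ++d) {
    slot_node[d].assign(n_hap, -1);
    slot_gen[d].assign(n_hap, -1);
    claimed[d].reserve(n_hap);
  }
  for (int g = 1; g <= split_time && (act[0].size() + act[1].size()) > 1; ++g) {
    const int gen_node_start = (int)parent.size();
    claimed[0].clear(); claimed[1].clear();
    for (int d = 0; d < 2; ++d) {
      for (size_t idx = 0; idx < act[d].size(); ++idx) {
        int v = act[d][idx];
        int dd = d;
        if (migration_rate > 0.0 && unif_rand() < migration_rate) dd = 1 - d;
        int s = (int)(unif_rand() * n_hap);
        if (s >= n_hap) s = n_hap - 1;
        if (slot_gen[dd][s] != g) {
          slot_gen[dd][s] = g;
          slot_node[dd][s] = v;
          claimed[dd].push_back(s);
        } else if (slot_node[dd][s] >= gen_node_start) {
          parent[v] = slot_node[dd][s];
        } else {
          int w = (int)parent.size();
          parent.push_back(-1); node_time.push_back((double)g);
          parent[slot_node[dd][s]] = w;
          parent[v] = w;
          slot_node[dd][s] = w;
        }
      }
    }
    for (int d = 0; d < 2; ++d) {
      act[d].clear();
      std::sort(claimed[d].begin(), claimed[d].end());
      for (size_t i = 0; i < claimed[d].size(); ++i)
        act[d].push_back(slot_node[d][claimed[d][i]]);
    }
  }

  // ---- phase 2: Hudson coalescent in the ancestral population ----
  std::vector<int> act2;
  for (int d = 0; d < 2; ++d) act2.insert(act2.end(), act[d].begin(), act[d].end());
  std::sort(act2.begin(), act2.end());
  double t = (double)split_time;
  int k = (int)act2.size();
  while (k > 1) {
    double N = anc_hap;
    if (expansion_time > 0.0 && t >= expansion_time) N = pre_anc_hap;
    double rate = (double)k * (k - 1) / (2.0 * N);
    double dt = exp_rand() / rate;
    if (expansion_time > 0.0 && t < expansion_time && t + dt > expansion_time) {
      t = expansion_time;  // size changes here; redraw under the older size
      continue;
    }
    t += dt;
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int w = (int)parent.size();
    parent.push_back(-1); node_time.push_back(t);
    parent[act2[i]] = w;
    parent[act2[j]] = w;
    act2[i] = w;
    act2[j] = act2[k - 1];
    act2.pop_back();
    --k;
  }

  // ---- mutations ----
  int n_nodes = (int)parent.size();
  std::vector<double> cum(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) total += node_time[parent[v]] - node_time[v];
    cum[v] = total;
  }
  int nmut = (int)R::rpois(mutation_rate * (double)region_length * total);
  if (nmut > region_length) nmut = region_length;  // infinite-sites cap
  std::vector<int> mut_node(nmut), mut_pos(nmut);
  std::unordered_set<int> used_pos;
  for (int m = 0; m < nmut; ++m) {
    double r = unif_rand() * total;
    int lo = 0, hi = n_nodes - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] >= r) hi = mid; else lo = mid + 1; }
    mut_node[m] = lo;
    int pos;
    do {
      pos = (int)(unif_rand() * region_length) + 1;
      if (pos > region_length) pos = region_length;
    } while (used_pos.count(pos));
    used_pos.insert(pos);
    mut_pos[m] = pos;
  }
  // order columns by position
  std::vector<int> ord(nmut);
  for (int m = 0; m < nmut; ++m) ord[m] = m;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return mut_pos[a] < mut_pos[b]; });

  // ---- haplotype matrix ----
  std::vector<int> head(n_nodes, -1), nextsib(n_nodes, -1);
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) { nextsib[v] = head[parent[v]]; head[parent[v]] = v; }
  }
  IntegerMatrix H(n_tips, nmut);
  IntegerVector positions(nmut);
  std::vector<int> stack;
  for (int c = 0; c < nmut; ++c) {
    int m = ord[c];
    positions[c] = mut_pos[m];
    stack.clear();
    stack.push_back(mut_node[m]);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_tips) H(v, c) = 1;
      for (int ch = head[v]; ch >= 0; ch = nextsib[ch]) stack.push_back(ch);
    }
  }
  return List::create(_["H"] = H, _["positions"] = positions);
}
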