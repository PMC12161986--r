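#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Exhaustive enumeration of all set partitions of an n-node graph,
// collecting the distinct (internal-edge-count, internal-pair-count)
// profiles. The CPM quality of a partition is E_in - gamma * P_in, so the
// optimum over all partitions at any resolution gamma is
// max over returned rows of (E - gamma * P). Feasible for n <= ~12
// (Bell(12) ~= 4.2e6); intended as an independent oracle for community
// detection on tiny graphs.
static void enumerate(int i, int n, const IntegerMatrix& adj,
                      std::vector<std::vector<int> >& blocks,
                      int E, int P, std::set<std::pair<int, int> >& out) {
  if (i == n) {
    out.insert(std::make_pair(E, P));
    return;
  }
  for (size_t b = 0; b < blocks.size(); ++b) {
    int e_add = 0;
    for (size_t j = 0; j < blocks[b].size(); ++j)
      if (adj(i, blocks[b][j])) ++e_add;
    int p_add = (int)blocks[b].size();
    blocks[b].push_back(i);
    enumerate(i + 1, n, adj, blocks, E + e_add, P + p_add, out);
    blocks[b].pop_back();
  }
  blocks.push_back(std::vector<int>(1, i));
  enumerate(i + 1, n, adj, blocks, E, P, out);
  blocks.pop_back();
}

// [[Rcpp::export(name = ".cpp_cpm_profiles")]]
IntegerMatrix cpp_cpm_profiles(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n > 13) stop("exhaustive partition enumeration limited to n <= 13");
  std::set<std::pair<int, int> > out;
  std::vector<std::vector<int> > blocks;
  enumerate(0, n, adj, blocks, 0, 0, out);
  IntegerMatrix res(out.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::iterator it = out.begin();
       it != out.end(); ++it, ++r) {
    res(r, 0) = it->first;
    res(r, 1) = it->second;
  }
  colnames(res) = CharacterVector::create("E_in", "P_in");
  return res;
}
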