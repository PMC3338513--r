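#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Intersection of two sorted integer vectors (two-pointer).
static std::vector<int> intersect_sorted(const std::vector<int>& a,
                                         const std::vector<int>& b) {
  std::vector<int> out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { out.push_back(a[i]); ++i; ++j; }
  }
  return out;
}

static bool intersects_sorted(const std::vector<int>& a,
                              const std::vector<int>& b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else return true;
  }
  return false;
}

// Greedy forward chaining scan over one chromosome for one dataset.
//
// terms: per-position sorted integer term codes (empty = unannotated in
//   this dataset). nest: per-position sorted integer ids of chains (from a
//   previous pass, any dataset) the gene belongs to; used to collapse a
//   maximal run of interstitial genes that are all members of a single
//   other chain to an effective gap contribution of 1. max_gap: largest
//   effective gap allowed inside a chain. max_gaps: largest number of gaps
//   allowed (< 0 means unlimited).
//
// A chain opens at the first unassigned annotated position; the scan moves
// forward admitting the nearest unassigned gene that shares at least one
// term of the running common subset, provided the effective length of the
// interstitial run since the last member does not exceed max_gap; on
// admission the common subset is intersected with the new member's terms.
// When the effective run exceeds max_gap the chain closes at its last
// member. Members join at most one chain; chains with >= 2 members are
// emitted.
// [[Rcpp::export]]
List scan_chromosome_cpp(List terms, List nest, int max_gap, int max_gaps) {
  const int L = terms.size();
  std::vector< std::vector<int> > T(L), Nst(L);
  for (int i = 0; i < L; ++i) {
    T[i] = as< std::vector<int> >(terms[i]);
    Nst[i] = as< std::vector<int> >(nest[i]);
  }
  std::vector<bool> assigned(L, false);
  std::vector<List> chains;

  for (int s = 0; s < L; ++s) {
    if (assigned[s] || T[s].empty()) continue;
    std::vector<int> members(1, s);
    std::vector<int> common = T[s];
    std::vector<int> gap_start, gap_raw, gap_eff;
    int pending = 0, eff = 0, last = s, ngaps = 0;
    std::vector<int> cur;
    bool cur_active = false;
    bool capped = false;

    for (int j = s + 1; j < L; ++j) {
      bool share = false;
      if (!assigned[j] && !T[j].empty())
        share = intersects_sorted(common, T[j]);
      if (share) {
        if (pending > 0 && max_gaps >= 0 && ngaps + 1 > max_gaps) { capped = true; break; }
        if (pending > 0) {
          gap_start.push_back(last + 1);
          gap_raw.push_back(pending);
          gap_eff.push_back(eff);
          ++ngaps;
        }
        common = intersect_sorted(common, T[j]);
        members.push_back(j);
        last = j;
        pending = 0; eff = 0; cur.clear(); cur_active = false;
      } else {
        ++pending;
        const std::vector<int>& ids = Nst[j];
        if (ids.empty()) {
          ++eff; cur.clear(); cur_active = false;
        } else if (!cur_active) {
          cur = ids; cur_active = true; ++eff;
        } else {
          std::vector<int> in = intersect_sorted(cur, ids);
          if (in.empty()) { cur = ids; ++eff; }
          else cur = in;
        }
        if (eff > max_gap) break;
      }
    }
    (void)capped;

    if ((int)members.size() >= 2) {
      for (size_t mi = 0; mi < members.size(); ++mi) assigned[members[mi]] = true;
      IntegerVector mem(members.size());
      for (size_t mi = 0; mi < members.size(); ++mi) mem[mi] = members[mi] + 1;
      IntegerVector gs(gap_start.size()), gr(gap_raw.size()), ge(gap_eff.size());
      for (size_t gi = 0; gi < gap_start.size(); ++gi) {
        gs[gi] = gap_start[gi] + 1; gr[gi] = gap_raw[gi]; ge[gi] = gap_eff[gi];
      }
      chains.push_back(List::create(
        _["members"] = mem,
        _["common"] = wrap(common),
        _["gap_start"] = gs,
        _["gap_raw"] = gr,
        _["gap_eff"] = ge));
    }
  }
  return wrap(chains);
}
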