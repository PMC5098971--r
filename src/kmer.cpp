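#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int b2b(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

static void collect_kmers(const std::string& s, int k, std::unordered_set<uint64_t>& out) {
  const int n = (int) s.size();
  if (n < k) return;
  uint64_t v = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = b2b(s[i]);
    if (b < 0) { run = 0; v = 0; continue; }
    v = ((v << 2) | (uint64_t) b) & mask;
    if (++run >= k) out.insert(v);
  }
}

static std::string rc(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i)
    switch (r[i]) { case 'A': r[i]='T'; break; case 'C': r[i]='G'; break;
                    case 'G': r[i]='C'; break; case 'T': r[i]='A'; break;
                    default: r[i]='N'; }
  return r;
}

// Shared-k-mer prefilter for the all-vs-all homology search: for each A
// sequence, the (1-based) indices of B sequences sharing >= min_shared
// distinct k-mers with A on either strand. Unrelated random sequences share
// essentially no long k-mers, so full alignment is only run on survivors.
// [[Rcpp::export]]
List cpp_kmer_candidates(CharacterVector seqsA, CharacterVector seqsB,
                         int k, int min_shared) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  const int nB = seqsB.size(), nA = seqsA.size();
  std::unordered_map<uint64_t, std::vector<int32_t> > bmap;
  for (int j = 0; j < nB; ++j) {
    std::unordered_set<uint64_t> ks;
    collect_kmers(as<std::string>(seqsB[j]), k, ks);
    for (std::unordered_set<uint64_t>::const_iterator it = ks.begin(); it != ks.end(); ++it)
      bmap[*it].push_back(j);
  }
  List out(nA);
  std::vector<int32_t> hits(nB);
  for (int i = 0; i < nA; ++i) {
    std::fill(hits.begin(), hits.end(), 0);
    std::string a = as<std::string>(seqsA[i]);
    std::unordered_set<uint64_t> ks;
    collect_kmers(a, k, ks);
    collect_kmers(rc(a), k, ks);
    for (std::unordered_set<uint64_t>::const_iterator it = ks.begin(); it != ks.end(); ++it) {
      std::unordered_map<uint64_t, std::vector<int32_t> >::const_iterator bt = bmap.find(*it);
      if (bt != bmap.end())
        for (size_t h = 0; h < bt->second.size(); ++h) ++hits[bt->second[h]];
    }
    std::vector<int32_t> sel;
    for (int j = 0; j < nB; ++j) if (hits[j] >= min_shared) sel.push_back(j + 1);
    out[i] = IntegerVector(sel.begin(), sel.end());
  }
  return out;
}
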