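#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char random_other_base(char c) {
  // pick uniformly among the three bases != c (N substitutes to any base)
  char pick;
  do { pick = BASES[(int) (unif_rand() * 4.0) & 3]; } while (pick == c);
  return pick;
}

// Apply point substitutions, per-site indels, and homopolymer-run indels to
// each sequence. Draws come from R's RNG (deterministic under set.seed);
// a rate of exactly zero consumes no randomness for that error class.
//
// sub_rate:       per-site substitution probability
// indel_rate:     per-site probability of a single-base indel (50/50 ins/del)
// hp_indel_rate:  per homopolymer run (>= 3 identical bases) probability of
//                 expanding or contracting the run by one base (50/50) --
//                 the dominant 454 pyrosequencing error mode
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, double sub_rate,
                                double indel_rate, double hp_indel_rate) {
  const int ns = seqs.size();
  CharacterVector out(ns);
  for (int s = 0; s < ns; ++s) {
    std::string x = as<std::string>(seqs[s]);
    if (sub_rate > 0 || indel_rate > 0) {
      std::string y; y.reserve(x.size() + 8);
      for (size_t i = 0; i < x.size(); ++i) {
        char c = x[i];
        if (sub_rate > 0 && unif_rand() < sub_rate) c = random_other_base(c);
        if (indel_rate > 0 && unif_rand() < indel_rate) {
          if (unif_rand() < 0.5) continue;                    // deletion
          y.push_back(BASES[(int) (unif_rand() * 4.0) & 3]); // insertion before
          y.push_back(c);
        } else y.push_back(c);
      }
      x = y;
    }
    if (hp_indel_rate > 0 && x.size() >= 3) {
      std::string y; y.reserve(x.size() + 8);
      size_t i = 0;
      while (i < x.size()) {
        size_t j = i + 1;
        while (j < x.size() && x[j] == x[i]) ++j;
        size_t runlen = j - i;
        size_t outlen = runlen;
        if (runlen >= 3 && unif_rand() < hp_indel_rate)
          outlen = (unif_rand() < 0.5) ? runlen + 1 : runlen - 1;
        y.append(outlen, x[i]);
        i = j;
      }
      x = y;
    }
    out[s] = x;
  }
  return out;
}

// 1-based [first, last] bounds of the end-trimmed region per quality string:
// scan inward from each end discarding bases below `thr` until the first
// base >= thr. Returns first > last for a fully trimmed read.
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int thr) {
  const int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    std::string q = as<std::string>(quals[r]);
    int L = (int) q.size();
    int first = 0;
    while (first < L && ((int) q[first] - 33) < thr) ++first;
    int last = L - 1;
    while (last >= first && ((int) q[last] - 33) < thr) --last;
    out(r, 0) = first + 1;
    out(r, 1) = last + 1;
  }
  return out;
}
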