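#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Exact-substring candidate index over the forward strand of a reference
// set. The mapper's seed (first seed_len bases of the trimmed fragment) is
// split into two blocks; any ungapped placement with <= 1 seed mismatch
// leaves at least one block exact (pigeonhole), so exact lookup of the two
// blocks enumerates every admissible candidate. Reverse-strand placements
// are handled by looking up the reverse complement of the fragment.

struct SeedIndexCpp {
  std::vector<std::string> refs;       // forward-strand sequences, uppercase
  std::vector<std::string> names;
  int seed_len, b1, b2;                // block lengths, b1 + b2 = seed_len
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > > map1, map2;
};

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// Encode s[pos, pos+k) as 2-bit integer; false if it contains N.
static inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t) b;
  }
  out = v;
  return true;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) { case 'A': r[i]='T'; break; case 'C': r[i]='G'; break;
                    case 'G': r[i]='C'; break; case 'T': r[i]='A'; break;
                    default:  r[i]='N'; }
  }
  return r;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector ref_seqs, CharacterVector ref_names, int seed_len) {
  if (seed_len < 2) stop("seed_len must be >= 2");
  SeedIndexCpp* idx = new SeedIndexCpp();
  idx->seed_len = seed_len;
  idx->b1 = seed_len / 2;
  idx->b2 = seed_len - idx->b1;
  if (idx->b1 > 31 || idx->b2 > 31) { delete idx; stop("seed blocks longer than 31 nt unsupported"); }
  idx->refs.reserve(ref_seqs.size());
  for (int r = 0; r < ref_seqs.size(); ++r) {
    idx->refs.push_back(as<std::string>(ref_seqs[r]));
    idx->names.push_back(as<std::string>(ref_names[r]));
    const std::string& s = idx->refs.back();
    uint64_t key;
    if ((int) s.size() >= idx->b1)
      for (size_t p = 0; p + idx->b1 <= s.size(); ++p)
        if (encode_kmer(s, p, idx->b1, key)) idx->map1[key].push_back(std::make_pair((int32_t) r, (int32_t) p));
    if ((int) s.size() >= idx->b2)
      for (size_t p = 0; p + idx->b2 <= s.size(); ++p)
        if (encode_kmer(s, p, idx->b2, key)) idx->map2[key].push_back(std::make_pair((int32_t) r, (int32_t) p));
  }
  XPtr<SeedIndexCpp> xp(idx, true);
  return xp;
}

// Candidate (ref, start) placements for a sequence of length n whose first
// seedL = min(seed_len, n) bases may carry up to max_seed_mm (0 or 1)
// mismatches. seed_off shifts the seed within the placed sequence (used for
// minus-strand placements, where the read's 5' seed sits at the 3' end of
// the reverse-complemented sequence).
static void gather_candidates(const SeedIndexCpp& idx, const std::string& seq,
                              int seed_off, int seedL, int max_seed_mm,
                              std::vector<std::pair<int32_t,int32_t> >& out) {
  const int n = (int) seq.size();
  if (seedL >= idx.b1 + idx.b2 && max_seed_mm <= 1) {
    uint64_t key;
    // block 1: seq[seed_off, seed_off + b1)
    if (encode_kmer(seq, seed_off, idx.b1, key)) {
      std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > >::const_iterator it = idx.map1.find(key);
      if (it != idx.map1.end())
        for (size_t h = 0; h < it->second.size(); ++h)
          out.push_back(std::make_pair(it->second[h].first, it->second[h].second - seed_off));
    }
    // block 2: seq[seed_off + b1, seed_off + seedL_blocks)
    if (encode_kmer(seq, seed_off + idx.b1, idx.b2, key)) {
      std::unordered_map<uint64_t, std::vector<std::pair<int32_t,int32_t> > >::const_iterator it = idx.map2.find(key);
      if (it != idx.map2.end())
        for (size_t h = 0; h < it->second.size(); ++h)
          out.push_back(std::make_pair(it->second[h].first, it->second[h].second - seed_off - idx.b1));
    }
  } else {
    // Short-fragment fallback: scan every placement of every reference.
    for (size_t r = 0; r < idx.refs.size(); ++r) {
      int L = (int) idx.refs[r].size();
      for (int p = 0; p + n <= L; ++p) out.push_back(std::make_pair((int32_t) r, (int32_t) p));
    }
  }
}

// Exact full-length occurrences of `query` on both strands.
// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp_, std::string query) {
  XPtr<SeedIndexCpp> xp(xp_);
  const SeedIndexCpp& idx = *xp;
  std::vector<int> refs; std::vector<int> poss; std::vector<std::string> strands;
  for (int st = 0; st < 2; ++st) {
    std::string s = (st == 0) ? query : revcomp(query);
    const int n = (int) s.size();
    std::vector<std::pair<int32_t,int32_t> > cand;
    int seedL = std::min(idx.seed_len, n);
    gather_candidates(idx, s, 0, seedL, 0, cand);
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (size_t c = 0; c < cand.size(); ++c) {
      int r = cand[c].first, p = cand[c].second;
      if (p < 0 || p + n > (int) idx.refs[r].size()) continue;
      if (idx.refs[r].compare(p, n, s) == 0) {
        bool exact = true;
        for (int i = 0; i < n; ++i) if (s[i] == 'N') { exact = false; break; }
        if (!exact) continue;
        refs.push_back(r + 1); poss.push_back(p);
        strands.push_back(st == 0 ? "+" : "-");
      }
    }
  }
  return DataFrame::create(_["ref"] = refs, _["pos"] = poss, _["strand"] = strands,
                           _["stringsAsFactors"] = false);
}

struct Placement {
  int n_mm, qual_sum, rank, pos, strand_minus, ref;
  bool operator<(const Placement& o) const {
    if (n_mm != o.n_mm) return n_mm < o.n_mm;
    if (qual_sum != o.qual_sum) return qual_sum < o.qual_sum;
    if (rank != o.rank) return rank < o.rank;
    if (pos != o.pos) return pos < o.pos;
    return strand_minus < o.strand_minus;
  }
  bool tie_key_eq(const Placement& o) const {
    return n_mm == o.n_mm && qual_sum == o.qual_sum;
  }
};

// Map trimmed fragments against the index under the mapping policy.
// quals are Phred+33 strings aligned with seqs (pre-trim orientation).
// ref_rank gives the deterministic transcript-id tie order (1 = smallest id).
// Returns one row per fragment: ref index (0 = unmapped), pos, strand,
// n_mismatch, qual_sum, n_ties.
// [[Rcpp::export]]
DataFrame cpp_map_fragments(SEXP xp_, CharacterVector seqs, CharacterVector quals,
                            int trim5, int trim3, int seed_len, int max_seed_mm,
                            int max_qual_sum, IntegerVector ref_rank) {
  XPtr<SeedIndexCpp> xp(xp_);
  const SeedIndexCpp& idx = *xp;
  if (max_seed_mm > 1) stop("max_seed_mismatches > 1 not supported by the two-block index");
  const int nf = seqs.size();
  IntegerVector out_ref(nf), out_pos(nf), out_mm(nf), out_qs(nf), out_ties(nf);
  CharacterVector out_strand(nf);

  for (int f = 0; f < nf; ++f) {
    std::string full = as<std::string>(seqs[f]);
    std::string fq   = as<std::string>(quals[f]);
    int n = (int) full.size() - trim5 - trim3;
    out_ref[f] = 0; out_pos[f] = NA_INTEGER; out_strand[f] = NA_STRING;
    out_mm[f] = NA_INTEGER; out_qs[f] = NA_INTEGER; out_ties[f] = 0;
    if (n < 1) continue;
    std::string fwd = full.substr(trim5, n);
    std::vector<int> qv(n);
    for (int i = 0; i < n; ++i) qv[i] = (int) fq[trim5 + i] - 33;
    std::string rev = revcomp(fwd);
    const int seedL = std::min(seed_len, n);

    bool have_best = false;
    Placement best; best.n_mm = 0; best.qual_sum = 0; best.rank = 0; best.pos = 0; best.strand_minus = 0; best.ref = 0;
    int n_ties = 0;

    for (int st = 0; st < 2; ++st) {
      const std::string& s = (st == 0) ? fwd : rev;
      // read positions i (0-based, post-trim) sit at placed position
      // st == 0 : i            ; seed occupies [0, seedL)
      // st == 1 : n - 1 - i    ; seed occupies [n - seedL, n)
      int seed_off = (st == 0) ? 0 : (n - seedL);
      std::vector<std::pair<int32_t,int32_t> > cand;
      gather_candidates(idx, s, seed_off, seedL, max_seed_mm, cand);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        int r = cand[c].first, p = cand[c].second;
        if (p < 0 || p + n > (int) idx.refs[r].size()) continue;
        const std::string& ref = idx.refs[r];
        int mm = 0, seed_mm = 0, qsum = 0;
        bool ok = true;
        for (int i = 0; i < n && ok; ++i) {
          char rb = ref[p + i], qb = s[i];
          bool is_mm = (rb != qb) || rb == 'N' || qb == 'N';
          if (is_mm) {
            ++mm;
            int read_i = (st == 0) ? i : (n - 1 - i);   // original read coordinate
            qsum += qv[read_i];
            if (i >= seed_off && i < seed_off + seedL) {
              ++seed_mm;
              if (seed_mm > max_seed_mm) ok = false;
            }
            if (qsum > max_qual_sum) ok = false;
          }
        }
        if (!ok) continue;
        Placement pl; pl.n_mm = mm; pl.qual_sum = qsum; pl.rank = ref_rank[r];
        pl.pos = p; pl.strand_minus = st; pl.ref = r;
        if (!have_best) { best = pl; have_best = true; n_ties = 1; }
        else if (pl.tie_key_eq(best)) { ++n_ties; if (pl < best) best = pl; }
        else if (pl < best) { best = pl; n_ties = 1; }
      }
    }
    if (have_best) {
      out_ref[f] = best.ref + 1; out_pos[f] = best.pos;
      out_strand[f] = best.strand_minus ? "-" : "+";
      out_mm[f] = best.n_mm; out_qs[f] = best.qual_sum; out_ties[f] = n_ties;
    }
  }
  return DataFrame::create(_["ref"] = out_ref, _["pos"] = out_pos,
                           _["strand"] = out_strand, _["n_mismatch"] = out_mm,
                           _["qual_mismatch_sum"] = out_qs, _["n_ties"] = out_ties,
                           _["stringsAsFactors"] = false);
}
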