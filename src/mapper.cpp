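// k-mer seeded, ungapped, mismatch-bounded read mapping plus pileup
// accumulation. Seeds partition the read into floor(len/k) non-overlapping
// k-mers; by pigeonhole, any alignment with fewer mismatches than seeds has
// at least one exact seed, so enumeration is complete in that regime.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

namespace {

const int BASE_CODE[256] = {
  // -1 everywhere except A/C/G/T (upper and lower case)
  #define X -1
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
  X,0,X,1,X,X,X,2,X,X,X,X,X,X,X,X, X,X,X,X,3,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,
  X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X, X,X,X,X,X,X,X,X,X,X,X,X,X,X,X,X
  #undef X
};

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

struct KmerIndex {
  int k;
  std::vector<std::string> targets;
  std::vector<std::string> names;
  // key: 2-bit packed k-mer; value: packed (target_idx << 32) | position
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

// encode s[pos, pos+k); returns false if any non-ACGT base
inline bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = BASE_CODE[(unsigned char)s[pos + i]];
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  key = v;
  return true;
}

// count mismatches of read vs target at offset, early exit above bound;
// any non-identical pair (including N on either side) is a mismatch
inline int count_mm(const std::string& read, const std::string& tgt,
                    size_t off, int bound) {
  int mm = 0;
  const size_t n = read.size();
  for (size_t i = 0; i < n; ++i) {
    char a = read[i], b = tgt[off + i];
    // N never matches, even N vs N
    bool match = (a == b) && BASE_CODE[(unsigned char)a] >= 0;
    if (!match && ++mm > bound) return mm;
  }
  return mm;
}

} // namespace

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.hasAttribute("names")
    ? CharacterVector(seqs.names()) : CharacterVector(seqs.size());
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->targets.push_back(s);
    idx->names.push_back(nm[t] == NA_STRING ? "" : as<std::string>(nm[t]));
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      uint64_t key;
      if (encode_kmer(s, p, k, key))
        idx->table[key].push_back(((uint64_t)t << 32) | (uint64_t)p);
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  ptr.attr("class") = "kmer_index_ptr";
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector len(idx->targets.size());
  CharacterVector nm(idx->targets.size());
  for (size_t i = 0; i < idx->targets.size(); ++i) {
    len[i] = (int)idx->targets[i].size();
    nm[i] = idx->names[i];
  }
  return List::create(_["k"] = idx->k, _["n_targets"] = (int)idx->targets.size(),
                      _["n_kmers"] = (double)idx->table.size(),
                      _["target_names"] = nm, _["target_lengths"] = len);
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector reads, SEXP xp, int max_mismatch) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> o_query, o_target, o_pos, o_mm;
  std::vector<int> o_strand; // 1 = forward, 0 = reverse

  std::vector<uint64_t> cand; // packed (target<<32)|start
  for (R_xlen_t q = 0; q < reads.size(); ++q) {
    std::string fwd = as<std::string>(reads[q]);
    if (fwd.empty()) stop("empty read at position %d", (int)(q + 1));
    const size_t rl = fwd.size();
    if ((int)rl < k) continue; // unseedable: no hits reported
    std::string rev = revcomp(fwd);
    for (int strand = 1; strand >= 0; --strand) {
      const std::string& rd = strand ? fwd : rev;
      cand.clear();
      const int nseed = (int)(rl / (size_t)k);
      for (int s = 0; s < nseed; ++s) {
        size_t off = (size_t)s * (size_t)k;
        uint64_t key;
        if (!encode_kmer(rd, off, k, key)) continue;
        auto it = idx->table.find(key);
        if (it == idx->table.end()) continue;
        for (uint64_t pk : it->second) {
          uint64_t t = pk >> 32;
          int64_t tp = (int64_t)(pk & 0xffffffffULL) - (int64_t)off;
          if (tp < 0) continue;
          if ((size_t)tp + rl > idx->targets[t].size()) continue;
          cand.push_back((t << 32) | (uint64_t)tp);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (uint64_t c : cand) {
        uint64_t t = c >> 32;
        size_t tp = (size_t)(c & 0xffffffffULL);
        int mm = count_mm(rd, idx->targets[t], tp, max_mismatch);
        if (mm <= max_mismatch) {
          o_query.push_back((int)q + 1);
          o_target.push_back((int)t + 1);
          o_pos.push_back((int)tp);
          o_strand.push_back(strand);
          o_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(
    _["query"] = o_query, _["target"] = o_target, _["pos"] = o_pos,
    _["strand"] = o_strand, _["mismatches"] = o_mm,
    _["stringsAsFactors"] = false);
}

// Brute-force mapper used nowhere in the pipeline; exported for oracle
// comparison in tests at tiny scale.
// [[Rcpp::export(name = ".cpp_map_bruteforce")]]
DataFrame cpp_map_bruteforce(CharacterVector reads, CharacterVector targets,
                             int max_mismatch) {
  std::vector<int> o_query, o_target, o_pos, o_mm, o_strand;
  for (R_xlen_t q = 0; q < reads.size(); ++q) {
    std::string fwd = as<std::string>(reads[q]);
    std::string rev = revcomp(fwd);
    const size_t rl = fwd.size();
    for (int strand = 1; strand >= 0; --strand) {
      const std::string& rd = strand ? fwd : rev;
      for (R_xlen_t t = 0; t < targets.size(); ++t) {
        std::string tg = as<std::string>(targets[t]);
        if (tg.size() < rl) continue;
        for (size_t p = 0; p + rl <= tg.size(); ++p) {
          int mm = count_mm(rd, tg, p, max_mismatch);
          if (mm <= max_mismatch) {
            o_query.push_back((int)q + 1);
            o_target.push_back((int)t + 1);
            o_pos.push_back((int)p);
            o_strand.push_back(strand);
            o_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["query"] = o_query, _["target"] = o_target, _["pos"] = o_pos,
    _["strand"] = o_strand, _["mismatches"] = o_mm,
    _["stringsAsFactors"] = false);
}

// Per-target base counts (A/C/G/T x position) from ungapped alignments.
// target: 1-based target index per alignment; pos: 0-based start;
// strand: 1 forward / 0 reverse (read is reverse-complemented before adding).
// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(CharacterVector reads, IntegerVector target, IntegerVector pos,
                IntegerVector strand, IntegerVector target_lengths) {
  const int nt = target_lengths.size();
  std::vector<IntegerMatrix> mats;
  mats.reserve(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerMatrix m(4, target_lengths[t]);
    mats.push_back(m);
  }
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    if (strand[i] == 0) rd = revcomp(rd);
    int t = target[i] - 1;
    if (t < 0 || t >= nt) stop("alignment references unknown target");
    if (pos[i] < 0 || pos[i] + (int)rd.size() > target_lengths[t])
      stop("alignment extends beyond gene bounds");
    IntegerMatrix& m = mats[t];
    for (size_t j = 0; j < rd.size(); ++j) {
      int c = BASE_CODE[(unsigned char)rd[j]];
      if (c >= 0) m(c, pos[i] + (int)j) += 1;
    }
  }
  List out(nt);
  for (int t = 0; t < nt; ++t) {
    rownames(mats[t]) = CharacterVector::create("A", "C", "G", "T");
    out[t] = mats[t];
  }
  return out;
}

// Base carried by each alignment at a given target position (0-based),
// 'N'/'-' when the alignment does not cover the site. Vectorized over
// alignment/site pairs.
// [[Rcpp::export(name = ".cpp_base_at")]]
CharacterVector cpp_base_at(CharacterVector reads, IntegerVector pos,
                            IntegerVector strand, IntegerVector site) {
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    if (strand[i] == 0) rd = revcomp(rd);
    int off = site[i] - pos[i];
    if (off < 0 || off >= (int)rd.size()) out[i] = "-";
    else out[i] = std::string(1, rd[off]);
  }
  return out;
}
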