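// k-mer machinery for graft/host read classification and pseudo-alignment.
// k-mers are 2-bit encoded (A=0,C=1,G=2,T=3) into uint64, so k <= 31.
// Canonical form = lexicographic min of a k-mer and its reverse complement.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <fstream>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string bits2string(uint64_t kmer, int k) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[kmer & 3ULL];
    kmer >>= 2;
  }
  return s;
}

// Enumerate canonical k-mers of a sequence (one per position); windows
// containing a non-ACGT base are not emitted. Returns the number emitted,
// so skipped = max(len - k + 1, 0) - emitted.
template <typename F>
static long for_each_canonical(const char* seq, int len, int k, F f) {
  if (len < k) return 0;
  uint64_t fwd = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  long emitted = 0;
  for (int i = 0; i < len; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) {
      valid = 0;
      fwd = 0;
      rc = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      f(std::min(fwd, rc));
      ++emitted;
    }
  }
  return emitted;
}

// minimal non-negative integer parser (avoids strtol and friends)
static long parse_long(const char* s) {
  long v = 0;
  while (*s >= '0' && *s <= '9') v = v * 10 + (*s++ - '0');
  return v;
}

struct KmerIndex {
  int k;
  // 1 = graft_only, 2 = host_only, 3 = both
  std::unordered_map<uint64_t, uint8_t> map;
  long skipped_graft = 0, skipped_host = 0;
};

struct GeneMap {
  int k;
  // value >= 0: unique gene index; value == -1: look up in multi
  std::unordered_map<uint64_t, int32_t> map;
  std::unordered_map<uint64_t, std::vector<int32_t> > multi;
  int n_genes = 0;
};

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector graft, CharacterVector host, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < graft.size(); ++i) {
    SEXP sx = STRING_ELT(graft, i);
    int len = (int)LENGTH(sx);
    long em = for_each_canonical(CHAR(sx), len, k,
                                 [&](uint64_t km) { idx->map[km] = 1; });
    idx->skipped_graft += std::max(len - k + 1, 0) - em;
  }
  for (R_xlen_t i = 0; i < host.size(); ++i) {
    SEXP sx = STRING_ELT(host, i);
    int len = (int)LENGTH(sx);
    long em = for_each_canonical(CHAR(sx), len, k, [&](uint64_t km) {
      auto it = idx->map.find(km);
      if (it == idx->map.end()) idx->map[km] = 2;
      else if (it->second == 1) it->second = 3;
    });
    idx->skipped_host += std::max(len - k + 1, 0) - em;
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_info")]]
List kmer_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  long n1 = 0, n2 = 0, n3 = 0;
  for (auto& kv : idx->map) {
    if (kv.second == 1) ++n1;
    else if (kv.second == 2) ++n2;
    else ++n3;
  }
  return List::create(_["k"] = idx->k, _["n_graft_only"] = (double)n1,
                      _["n_host_only"] = (double)n2, _["n_both"] = (double)n3,
                      _["skipped_graft"] = (double)idx->skipped_graft,
                      _["skipped_host"] = (double)idx->skipped_host);
}

// [[Rcpp::export(name = ".kmer_index_members")]]
CharacterVector kmer_index_members(SEXP xp, int category) {
  XPtr<KmerIndex> idx(xp);
  std::vector<uint64_t> keep;
  for (auto& kv : idx->map)
    if (kv.second == category) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  CharacterVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i)
    out[i] = bits2string(keep[i], idx->k);
  return out;
}

// Versioned sorted-text serialization: one header line, then "kmer\tcategory".
// [[Rcpp::export(name = ".kmer_index_save")]]
void kmer_index_save(SEXP xp, std::string path) {
  XPtr<KmerIndex> idx(xp);
  std::vector<std::pair<uint64_t, uint8_t> > all(idx->map.begin(),
                                                 idx->map.end());
  std::sort(all.begin(), all.end());
  std::ofstream out(path.c_str());
  if (!out) stop("cannot open '%s' for writing", path.c_str());
  out << "pdxsep-kmer-index\tv1\tk=" << idx->k
      << "\tskipped_graft=" << idx->skipped_graft
      << "\tskipped_host=" << idx->skipped_host << "\n";
  for (auto& kv : all)
    out << bits2string(kv.first, idx->k) << "\t" << (int)kv.second << "\n";
}

// [[Rcpp::export(name = ".kmer_index_load")]]
SEXP kmer_index_load(std::string path) {
  std::ifstream in(path.c_str());
  if (!in) stop("cannot open '%s'", path.c_str());
  std::string header;
  std::getline(in, header);
  if (header.compare(0, 17, "pdxsep-kmer-index") != 0)
    stop("'%s' is not a pdxsep k-mer index", path.c_str());
  KmerIndex* idx = new KmerIndex();
  size_t pos = header.find("k=");
  if (pos == std::string::npos) stop("index header lacks k=");
  idx->k = (int)parse_long(header.c_str() + pos + 2);
  pos = header.find("skipped_graft=");
  if (pos != std::string::npos)
    idx->skipped_graft = parse_long(header.c_str() + pos + 14);
  pos = header.find("skipped_host=");
  if (pos != std::string::npos)
    idx->skipped_host = parse_long(header.c_str() + pos + 13);
  std::string km;
  int cat;
  while (in >> km >> cat) {
    uint64_t enc = 0;
    for (size_t i = 0; i < km.size(); ++i)
      enc = (enc << 2) | (uint64_t)base2bits(km[i]);
    idx->map[enc] = (uint8_t)cat;
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// Classify read pairs. Returns h, m, b, u position counts and category code:
// 1 graft, 2 host, 3 both, 4 neither, 5 ambiguous.
// r2 may contain NA for single-end records.
// [[Rcpp::export(name = ".classify_reads")]]
List classify_reads_cpp(CharacterVector r1, CharacterVector r2, SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  R_xlen_t n = r1.size();
  IntegerVector h(n), m(n), b(n), u(n), cat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int hh = 0, mm = 0, bb = 0, uu = 0;
    for (int mate = 0; mate < 2; ++mate) {
      SEXP sx = mate == 0 ? STRING_ELT(r1, i) : STRING_ELT(r2, i);
      if (sx == NA_STRING) continue;
      const char* s = CHAR(sx);
      int len = (int)LENGTH(sx);
      if (len < k)
        stop("read %d: mate length %d shorter than k = %d", (int)(i + 1),
             len, k);
      long em = for_each_canonical(s, len, k, [&](uint64_t km) {
        auto it = idx->map.find(km);
        if (it == idx->map.end()) ++uu;
        else if (it->second == 1) ++hh;
        else if (it->second == 2) ++mm;
        else ++bb;
      });
      // windows spanning a non-ACGT base belong to neither reference
      uu += (int)((len - k + 1) - em);
    }
    h[i] = hh; m[i] = mm; b[i] = bb; u[i] = uu;
    int c;
    if (hh > 0 && mm > 0) c = 5;
    else if (hh > 0) c = 1;
    else if (mm > 0) c = 2;
    else if (bb > 0) c = 3;
    else c = 4;
    cat[i] = c;
  }
  return List::create(_["h"] = h, _["m"] = m, _["b"] = b, _["u"] = u,
                      _["category"] = cat);
}

// [[Rcpp::export(name = ".gene_map_build")]]
SEXP gene_map_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  GeneMap* gm = new GeneMap();
  gm->k = k;
  gm->n_genes = (int)seqs.size();
  for (R_xlen_t g = 0; g < seqs.size(); ++g) {
    SEXP sx = STRING_ELT(seqs, g);
    for_each_canonical(CHAR(sx), (int)LENGTH(sx), k, [&](uint64_t km) {
      auto it = gm->map.find(km);
      if (it == gm->map.end()) {
        gm->map[km] = (int32_t)g;
      } else if (it->second >= 0 && it->second != (int32_t)g) {
        std::vector<int32_t>& v = gm->multi[km];
        v.push_back(it->second);
        v.push_back((int32_t)g);
        it->second = -1;
      } else if (it->second == -1) {
        std::vector<int32_t>& v = gm->multi[km];
        if (std::find(v.begin(), v.end(), (int32_t)g) == v.end())
          v.push_back((int32_t)g);
      }
    });
  }
  XPtr<GeneMap> ptr(gm, true);
  return ptr;
}

// Assign each read pair to the gene containing the most of its k-mers
// (each k-mer position votes once per gene carrying it). Unique argmax wins;
// ties or zero matches give NA. Returns 1-based gene indices.
// [[Rcpp::export(name = ".assign_reads")]]
IntegerVector assign_reads_cpp(CharacterVector r1, CharacterVector r2,
                               SEXP xp) {
  XPtr<GeneMap> gm(xp);
  const int k = gm->k;
  R_xlen_t n = r1.size();
  IntegerVector out(n);
  std::unordered_map<int32_t, int> score;
  for (R_xlen_t i = 0; i < n; ++i) {
    score.clear();
    for (int mate = 0; mate < 2; ++mate) {
      SEXP sx = mate == 0 ? STRING_ELT(r1, i) : STRING_ELT(r2, i);
      if (sx == NA_STRING) continue;
      const char* s = CHAR(sx);
      int len = (int)LENGTH(sx);
      if (len < k) continue;
      for_each_canonical(s, len, k, [&](uint64_t km) {
        auto it = gm->map.find(km);
        if (it == gm->map.end()) return;
        if (it->second >= 0) {
          ++score[it->second];
        } else {
          for (int32_t g : gm->multi[km]) ++score[g];
        }
      });
    }
    if (score.empty()) {
      out[i] = NA_INTEGER;
      continue;
    }
    int best = -1, bestScore = -1;
    bool tie = false;
    for (auto& kv : score) {
      if (kv.second > bestScore) {
        bestScore = kv.second;
        best = kv.first;
        tie = false;
      } else if (kv.second == bestScore) {
        tie = true;
      }
    }
    out[i] = tie ? NA_INTEGER : best + 1;
  }
  return out;
}
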