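// k-mer equivalence-class index and pseudoalignment kernel.
//
// Transcripts are decomposed into canonical k-mers (lexicographic min of the
// k-mer and its reverse complement, k <= 31 so a k-mer fits in 62 bits).
// Each k-mer maps to an interned equivalence class: the sorted set of
// transcripts containing it. A mate's compatibility set is the intersection
// of its k-mers' classes; a read pair's set is the intersection across mates.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <vector>
#include <algorithm>
#include <fstream>

using namespace Rcpp;

struct PQIndex {
  int k;
  std::vector<int32_t> tx_len;
  std::vector<std::vector<int32_t>> ecs;          // ec id -> sorted 0-based tx ids
  std::unordered_map<uint64_t, int32_t> kmap;     // canonical k-mer -> ec id
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// Enumerate canonical k-mers of seq, calling f(kmer) for each valid one.
template <typename F>
static void for_each_canonical_kmer(const char* s, size_t n, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) f(std::min(fwd, rev));
  }
}

// [[Rcpp::export(name = ".px_build_index")]]
List px_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  int n_tx = seqs.size();
  std::unordered_map<uint64_t, std::vector<int32_t>> tmp;
  tmp.reserve(1 << 20);
  PQIndex* idx = new PQIndex();
  idx->k = k;
  idx->tx_len.resize(n_tx);
  LogicalVector skipped(n_tx);
  for (int t = 0; t < n_tx; ++t) {
    const char* s = CHAR(STRING_ELT(seqs, t));
    size_t n = LENGTH(STRING_ELT(seqs, t));
    idx->tx_len[t] = (int32_t)n;
    if ((int)n < k) { skipped[t] = true; continue; }
    for_each_canonical_kmer(s, n, k, [&](uint64_t km) {
      std::vector<int32_t>& v = tmp[km];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
  }
  // intern equivalence classes
  std::map<std::vector<int32_t>, int32_t> ec_lookup;
  idx->kmap.reserve(tmp.size());
  for (auto& kv : tmp) {
    std::vector<int32_t>& v = kv.second;
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
    auto it = ec_lookup.find(v);
    int32_t id;
    if (it == ec_lookup.end()) {
      id = (int32_t)idx->ecs.size();
      idx->ecs.push_back(v);
      ec_lookup.emplace(std::move(v), id);
    } else {
      id = it->second;
    }
    idx->kmap.emplace(kv.first, id);
  }
  XPtr<PQIndex> ptr(idx, true);
  return List::create(_["ptr"] = ptr,
                      _["n_kmers"] = (double)idx->kmap.size(),
                      _["n_ecs"] = (double)idx->ecs.size(),
                      _["skipped"] = skipped);
}

static inline void intersect_sorted(std::vector<int32_t>& a,
                                    const std::vector<int32_t>& b,
                                    std::vector<int32_t>& scratch) {
  scratch.clear();
  std::set_intersection(a.begin(), a.end(), b.begin(), b.end(),
                        std::back_inserter(scratch));
  a.swap(scratch);
}

// Compatibility set of one mate. strict: an absent (or invalid) k-mer makes
// the mate incompatible with everything; skip mode ignores absent k-mers.
// Returns false if the mate has no indexed k-mers at all (no information).
static bool mate_set(const PQIndex& idx, const char* s, size_t n, bool strict,
                     std::vector<int32_t>& out, std::vector<int32_t>& scratch) {
  bool any = false, dead = false;
  int32_t prev_ec = -1;
  int k = idx.k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n && !dead; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {
      valid = 0; fwd = 0; rev = 0;
      if (strict) dead = true;   // invalid base voids exact compatibility
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid < k) continue;
    uint64_t km = std::min(fwd, rev);
    auto it = idx.kmap.find(km);
    if (it == idx.kmap.end()) {
      if (strict) dead = true;
      continue;
    }
    int32_t ec = it->second;
    if (!any) {
      out = idx.ecs[ec];
      any = true;
      prev_ec = ec;
    } else if (ec != prev_ec) {
      intersect_sorted(out, idx.ecs[ec], scratch);
      prev_ec = ec;
      if (out.empty()) dead = true;
    }
  }
  if ((int)n < k) dead = true;   // too short to carry any k-mer
  if (dead) { out.clear(); return any; }
  return any;
}

// Pseudoalign pairs. Returns per-pair id into a table of result sets
// (0 = unassigned) plus the table itself (1-based transcript ids).
// [[Rcpp::export(name = ".px_align")]]
List px_align(SEXP ptr_, CharacterVector mate1, CharacterVector mate2,
              bool strict) {
  XPtr<PQIndex> ptr(ptr_);
  const PQIndex& idx = *ptr;
  int n = mate1.size();
  if (mate2.size() != n) stop("mate vectors differ in length");
  IntegerVector assign(n);
  std::map<std::vector<int32_t>, int32_t> res_lookup;
  std::vector<std::vector<int32_t>> res_sets;
  std::vector<int32_t> s1, s2, scratch;
  for (int i = 0; i < n; ++i) {
    const char* m1 = CHAR(STRING_ELT(mate1, i));
    size_t n1 = LENGTH(STRING_ELT(mate1, i));
    const char* m2 = CHAR(STRING_ELT(mate2, i));
    size_t n2 = LENGTH(STRING_ELT(mate2, i));
    s1.clear(); s2.clear();
    bool any1 = mate_set(idx, m1, n1, strict, s1, scratch);
    if (s1.empty()) { assign[i] = 0; continue; }   // dead or no info => unassigned
    bool any2 = mate_set(idx, m2, n2, strict, s2, scratch);
    if (s2.empty()) { assign[i] = 0; continue; }
    (void)any1; (void)any2;
    intersect_sorted(s1, s2, scratch);
    if (s1.empty()) { assign[i] = 0; continue; }
    auto it = res_lookup.find(s1);
    int32_t id;
    if (it == res_lookup.end()) {
      id = (int32_t)res_sets.size() + 1;
      res_sets.push_back(s1);
      res_lookup.emplace(s1, id);
    } else id = it->second;
    assign[i] = id;
  }
  List sets(res_sets.size());
  for (size_t j = 0; j < res_sets.size(); ++j) {
    IntegerVector v(res_sets[j].size());
    for (size_t q = 0; q < res_sets[j].size(); ++q) v[q] = res_sets[j][q] + 1;
    sets[j] = v;
  }
  return List::create(_["assignment"] = assign, _["sets"] = sets);
}

// [[Rcpp::export(name = ".px_index_info")]]
List px_index_info(SEXP ptr_) {
  XPtr<PQIndex> ptr(ptr_);
  return List::create(_["k"] = ptr->k,
                      _["n_tx"] = (int)ptr->tx_len.size(),
                      _["n_kmers"] = (double)ptr->kmap.size(),
                      _["n_ecs"] = (double)ptr->ecs.size());
}

// Number of k-mers unique to each transcript (singleton equivalence class).
// [[Rcpp::export(name = ".px_unique_kmers")]]
NumericVector px_unique_kmers(SEXP ptr_) {
  XPtr<PQIndex> ptr(ptr_);
  NumericVector out(ptr->tx_len.size());
  for (auto& kv : ptr->kmap) {
    const std::vector<int32_t>& ec = ptr->ecs[kv.second];
    if (ec.size() == 1) out[ec[0]] += 1;
  }
  return out;
}

static const char PQ_MAGIC[8] = {'P','Q','I','D','X','1','\n','\0'};

// [[Rcpp::export(name = ".px_save_index")]]
void px_save_index(SEXP ptr_, std::string path, CharacterVector tx_names,
                   CharacterVector genes) {
  XPtr<PQIndex> ptr(ptr_);
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(PQ_MAGIC, 8);
  int32_t k = ptr->k, n_tx = (int32_t)ptr->tx_len.size();
  f.write((char*)&k, 4);
  f.write((char*)&n_tx, 4);
  auto wstr = [&](const char* s, int32_t len) {
    f.write((char*)&len, 4); f.write(s, len);
  };
  for (int32_t t = 0; t < n_tx; ++t) {
    wstr(CHAR(STRING_ELT(tx_names, t)), LENGTH(STRING_ELT(tx_names, t)));
    wstr(CHAR(STRING_ELT(genes, t)), LENGTH(STRING_ELT(genes, t)));
    f.write((char*)&ptr->tx_len[t], 4);
  }
  int32_t n_ec = (int32_t)ptr->ecs.size();
  f.write((char*)&n_ec, 4);
  for (auto& ec : ptr->ecs) {
    int32_t m = (int32_t)ec.size();
    f.write((char*)&m, 4);
    f.write((char*)ec.data(), 4 * m);
  }
  uint64_t n_km = ptr->kmap.size();
  f.write((char*)&n_km, 8);
  for (auto& kv : ptr->kmap) {
    f.write((char*)&kv.first, 8);
    f.write((char*)&kv.second, 4);
  }
}

// [[Rcpp::export(name = ".px_load_index")]]
List px_load_index(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || memcmp(magic, PQ_MAGIC, 8) != 0)
    stop("'%s' is not a panquant index (bad version header)", path.c_str());
  PQIndex* idx = new PQIndex();
  int32_t n_tx = 0;
  f.read((char*)&idx->k, 4);
  f.read((char*)&n_tx, 4);
  CharacterVector tx_names(n_tx), genes(n_tx);
  idx->tx_len.resize(n_tx);
  std::vector<char> buf;
  auto rstr = [&]() -> std::string {
    int32_t len; f.read((char*)&len, 4);
    buf.resize(len);
    f.read(buf.data(), len);
    return std::string(buf.data(), len);
  };
  for (int32_t t = 0; t < n_tx; ++t) {
    tx_names[t] = rstr();
    genes[t] = rstr();
    f.read((char*)&idx->tx_len[t], 4);
  }
  int32_t n_ec;
  f.read((char*)&n_ec, 4);
  idx->ecs.resize(n_ec);
  for (int32_t e = 0; e < n_ec; ++e) {
    int32_t m; f.read((char*)&m, 4);
    idx->ecs[e].resize(m);
    f.read((char*)idx->ecs[e].data(), 4 * m);
  }
  uint64_t n_km;
  f.read((char*)&n_km, 8);
  idx->kmap.reserve(n_km);
  for (uint64_t i = 0; i < n_km; ++i) {
    uint64_t km; int32_t ec;
    f.read((char*)&km, 8);
    f.read((char*)&ec, 4);
    idx->kmap.emplace(km, ec);
  }
  if (!f) { delete idx; stop("'%s': truncated index file", path.c_str()); }
  XPtr<PQIndex> ptr(idx, true);
  return List::create(_["ptr"] = ptr, _["k"] = idx->k,
                      _["tx_names"] = tx_names, _["genes"] = genes,
                      _["tx_len"] = IntegerVector(idx->tx_len.begin(), idx->tx_len.end()));
}
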