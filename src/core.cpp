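#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything that is not A/C/G/T.
static inline int base2int(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

// Index every k-mer of ref (k <= 31); k-mers containing non-ACGT are skipped.
static KmerIndex build_index(const std::string& ref, int k) {
  KmerIndex idx;
  int L = (int)ref.size();
  if (L < k) return idx;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;  // length of current valid-base run
  for (int i = 0; i < L; ++i) {
    int b = base2int(ref[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) idx[key].push_back(i - k + 1);
  }
  return idx;
}

// k-mer key at offset o of seq, or false if it spans a non-ACGT base.
static bool kmer_at(const std::string& seq, int o, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2int(seq[o + i]);
    if (b < 0) return false;
    key = (key << 2) | (uint64_t)b;
  }
  return true;
}

// Hamming distance of seq placed at ref[pos, pos+len); early abort above cap.
static int hamming_at(const std::string& seq, const std::string& ref,
                      int pos, int cap) {
  int d = 0, len = (int)seq.size();
  for (int i = 0; i < len; ++i) {
    char a = seq[i], b = ref[pos + i];
    int ea = base2int(a), eb = base2int(b);
    if (ea < 0 || eb < 0 || ea != eb) {
      if (++d > cap) return d;
    }
  }
  return d;
}

// Competitive best placement of each read across references.
//
// A candidate placement must be supported by >= min_seed_hits of the
// n_seeds k-mer seeds sampled evenly along the read (fewer if the read is
// short). Among candidates the ungapped edit (Hamming) distance decides;
// ties: earlier reference in input order, then leftmost position. Reads
// whose best distance exceeds floor(max_divergence * length), or with no
// supported candidate, are unmapped.
//
// Returns: ref (1-based index, NA if unmapped), pos (0-based), dist, mapped.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int k, int n_seeds, int min_seed_hits,
                        double max_divergence) {
  int nr = reads.size(), nf = refs.size();
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::vector<std::string> R(nf);
  std::vector<KmerIndex> idx(nf);
  for (int j = 0; j < nf; ++j) {
    R[j] = as<std::string>(refs[j]);
    idx[j] = build_index(R[j], k);
  }
  IntegerVector out_ref(nr), out_pos(nr), out_dist(nr);
  LogicalVector out_map(nr);
  std::unordered_map<int, int> votes;
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int len = (int)rd.size();
    int best_d = INT_MAX, best_ref = -1, best_pos = -1;
    int cap = (int)std::floor(max_divergence * len);
    if (len >= k) {
      int npos = len - k + 1;
      int ns = std::min(n_seeds, npos);
      std::vector<int> offs(ns);
      if (ns == 1) offs[0] = 0;
      else for (int s = 0; s < ns; ++s)
        offs[s] = (int)std::lround((double)s * (npos - 1) / (ns - 1));
      int need = std::min(min_seed_hits, ns);
      for (int j = 0; j < nf; ++j) {
        int Lr = (int)R[j].size();
        if (Lr < len) continue;
        votes.clear();
        for (int s = 0; s < ns; ++s) {
          uint64_t key;
          if (!kmer_at(rd, offs[s], k, key)) continue;
          KmerIndex::const_iterator it = idx[j].find(key);
          if (it == idx[j].end()) continue;
          const std::vector<int>& hits = it->second;
          for (size_t h = 0; h < hits.size(); ++h) {
            int cand = hits[h] - offs[s];
            if (cand >= 0 && cand <= Lr - len) votes[cand] += 1;
          }
        }
        int ref_best_d = INT_MAX, ref_best_pos = -1;
        for (std::unordered_map<int, int>::iterator it = votes.begin();
             it != votes.end(); ++it) {
          if (it->second < need) continue;
          int lim = std::min(best_d, cap + 1);
          int d = hamming_at(rd, R[j], it->first, lim);
          if (d < ref_best_d ||
              (d == ref_best_d && it->first < ref_best_pos)) {
            ref_best_d = d;
            ref_best_pos = it->first;
          }
        }
        if (ref_best_d < best_d) {
          best_d = ref_best_d;
          best_ref = j;
          best_pos = ref_best_pos;
        }
      }
    }
    bool mapped = (best_ref >= 0) && (best_d <= cap);
    out_map[i] = mapped;
    if (mapped) {
      out_ref[i] = best_ref + 1;
      out_pos[i] = best_pos;
      out_dist[i] = best_d;
    } else {
      out_ref[i] = NA_INTEGER;
      out_pos[i] = NA_INTEGER;
      out_dist[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["ref"] = out_ref, _["pos"] = out_pos,
                           _["dist"] = out_dist, _["mapped"] = out_map);
}

// Best ungapped identity of each query fragment against ref, anchored by
// shared k-mer seeds taken at stride k along the fragment. Identity is
// matches / fragment_length at the best-scoring anchored placement.
// NA when no seed anchors the fragment anywhere in ref.
// [[Rcpp::export]]
NumericVector cpp_fragment_identity(CharacterVector fragments,
                                    std::string ref, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  KmerIndex idx = build_index(ref, k);
  int Lr = (int)ref.size();
  int nf = fragments.size();
  NumericVector out(nf);
  std::unordered_map<int, int> seen;
  for (int i = 0; i < nf; ++i) {
    std::string fr = as<std::string>(fragments[i]);
    int len = (int)fr.size();
    out[i] = NA_REAL;
    if (len < k || Lr < len) continue;
    seen.clear();
    int best_d = INT_MAX;
    for (int o = 0; o + k <= len; o += k) {
      uint64_t key;
      if (!kmer_at(fr, o, k, key)) continue;
      KmerIndex::const_iterator it = idx.find(key);
      if (it == idx.end()) continue;
      const std::vector<int>& hits = it->second;
      for (size_t h = 0; h < hits.size(); ++h) {
        int cand = hits[h] - o;
        if (cand < 0 || cand > Lr - len) continue;
        if (seen.count(cand)) continue;
        seen[cand] = 1;
        int d = hamming_at(fr, ref, cand, best_d == INT_MAX ? len : best_d);
        if (d < best_d) best_d = d;
      }
    }
    if (best_d != INT_MAX)
      out[i] = 1.0 - (double)best_d / (double)len;
  }
  return out;
}

// Allele-count pileup: one 4 x L integer matrix (rows A,C,G,T) per
// reference, accumulated over mapped reads. pos is 0-based.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector reads, IntegerVector ref_idx,
                IntegerVector pos, LogicalVector mapped,
                IntegerVector ref_lengths) {
  int nrefs = ref_lengths.size();
  std::vector<IntegerMatrix> mats;
  for (int j = 0; j < nrefs; ++j)
    mats.push_back(IntegerMatrix(4, ref_lengths[j]));
  int nr = reads.size();
  for (int i = 0; i < nr; ++i) {
    if (!mapped[i] || ref_idx[i] == NA_INTEGER) continue;
    int j = ref_idx[i] - 1;
    if (j < 0 || j >= nrefs) stop("read maps to unknown reference index");
    std::string rd = as<std::string>(reads[i]);
    int p0 = pos[i], L = ref_lengths[j];
    for (int t = 0; t < (int)rd.size(); ++t) {
      int b = base2int(rd[t]);
      int p = p0 + t;
      if (b < 0 || p < 0 || p >= L) continue;
      mats[j](b, p) += 1;
    }
  }
  List out(nrefs);
  for (int j = 0; j < nrefs; ++j) {
    rownames(mats[j]) = CharacterVector::create("A", "C", "G", "T");
    out[j] = mats[j];
  }
  return out;
}

// Pairwise proportion of differing sites over comparable (both A/C/G/T)
// positions of two equal-length sequences. Returns (differences, comparable).
// [[Rcpp::export]]
IntegerVector cpp_pdist_counts(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int diff = 0, comp = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int ea = base2int(a[i]), eb = base2int(b[i]);
    if (ea < 0 || eb < 0) continue;
    ++comp;
    if (ea != eb) ++diff;
  }
  return IntegerVector::create(_["diff"] = diff, _["comparable"] = comp);
}
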