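#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; -1 for anything that is not A/C/G/T (N never matches).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

struct KmerIndex {
  int k;
  int prefix_len;
  uint64_t prefix_code;          // encoded prefix, aligned to high bases
  int n_templates;
  std::vector<int> template_length;
  // k-mer -> packed postings (template << 32 | offset)
  std::unordered_map<uint64_t, std::vector<uint64_t> > postings;
  uint64_t n_postings;
};

static inline bool has_prefix(const KmerIndex &idx, uint64_t kmer) {
  if (idx.prefix_len == 0) return true;
  int shift = 2 * (idx.k - idx.prefix_len);
  return (kmer >> shift) == idx.prefix_code;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector templates, int k, std::string prefix) {
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->prefix_len = (int) prefix.size();
  idx->prefix_code = 0;
  idx->n_postings = 0;
  for (size_t i = 0; i < prefix.size(); ++i) {
    int c = base_code(prefix[i]);
    if (c < 0) {
      delete idx;
      stop("index prefix must contain only A/C/G/T");
    }
    idx->prefix_code = (idx->prefix_code << 2) | (uint64_t) c;
  }
  idx->n_templates = templates.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < templates.size(); ++t) {
    std::string seq = as<std::string>(templates[t]);
    idx->template_length.push_back((int) seq.size());
    if ((int) seq.size() < k) continue;  // caller warns
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t p = 0; p < seq.size(); ++p) {
      int c = base_code(seq[p]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) c) & mask;
      if (++valid >= k) {
        if (has_prefix(*idx, kmer)) {
          uint64_t off = (uint64_t) (p - k + 1);
          idx->postings[kmer].push_back(((uint64_t) t << 32) | off);
          idx->n_postings++;
        }
      }
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(
    _["k"] = idx->k,
    _["n_templates"] = idx->n_templates,
    _["n_kmers"] = (double) idx->postings.size(),
    _["n_postings"] = (double) idx->n_postings,
    _["template_length"] = wrap(idx->template_length));
}

// Accumulate per-(template, diagonal) counts for one oriented read.
// diag = template_offset - read_offset: the template position where the
// read's first base would sit under an ungapped placement.
static void score_oriented(const KmerIndex &idx, const std::string &seq,
                          std::unordered_map<uint64_t, int> &diag_counts) {
  const int k = idx.k;
  if ((int) seq.size() < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0;
  int valid = 0;
  for (size_t p = 0; p < seq.size(); ++p) {
    int c = base_code(seq[p]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++valid >= k && has_prefix(idx, kmer)) {
      std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
        it = idx.postings.find(kmer);
      if (it == idx.postings.end()) continue;
      int rpos = (int) (p - k + 1);
      for (size_t j = 0; j < it->second.size(); ++j) {
        uint64_t post = it->second[j];
        int tpl = (int) (post >> 32);
        int tpos = (int) (post & 0xFFFFFFFFULL);
        // diagonal offset shifted to stay non-negative in the key
        uint64_t key = ((uint64_t) tpl << 32) |
          (uint32_t) (tpos - rpos + 0x40000000);
        diag_counts[key]++;
      }
    }
  }
}

// Best diagonal per template for one orientation.
static void best_by_template(const std::unordered_map<uint64_t, int> &diag_counts,
                             std::unordered_map<int, std::pair<int, int> > &best) {
  for (std::unordered_map<uint64_t, int>::const_iterator it = diag_counts.begin();
       it != diag_counts.end(); ++it) {
    int tpl = (int) (it->first >> 32);
    int diag = (int) ((uint32_t) (it->first & 0xFFFFFFFFULL)) - 0x40000000;
    std::unordered_map<int, std::pair<int, int> >::iterator b = best.find(tpl);
    if (b == best.end() || it->second > b->second.first ||
        (it->second == b->second.first && diag < b->second.second)) {
      best[tpl] = std::make_pair(it->second, diag);
    }
  }
}

// Score every read against the index. Returns one row per
// (read, candidate template) pair with the mode-of-diagonal match score,
// the implied template start of the read, and the better orientation
// (+1 forward, -1 reverse complement; forward wins ties).
// [[Rcpp::export]]
DataFrame cpp_score_reads(SEXP xp, CharacterVector reads) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> out_read, out_tpl, out_score, out_start, out_strand;
  for (int r = 0; r < reads.size(); ++r) {
    std::string seq = as<std::string>(reads[r]);
    std::string rc(seq.size(), 'N');
    for (size_t i = 0; i < seq.size(); ++i)
      rc[i] = comp_base(seq[seq.size() - 1 - i]);

    std::unordered_map<uint64_t, int> fwd_counts, rev_counts;
    score_oriented(*idx, seq, fwd_counts);
    score_oriented(*idx, rc, rev_counts);
    std::unordered_map<int, std::pair<int, int> > fwd_best, rev_best;
    best_by_template(fwd_counts, fwd_best);
    best_by_template(rev_counts, rev_best);

    std::unordered_map<int, std::pair<int, int> >::iterator it;
    for (it = fwd_best.begin(); it != fwd_best.end(); ++it) {
      int tpl = it->first;
      int score = it->second.first, start = it->second.second, strand = 1;
      std::unordered_map<int, std::pair<int, int> >::iterator rv =
        rev_best.find(tpl);
      if (rv != rev_best.end() && rv->second.first > score) {
        score = rv->second.first; start = rv->second.second; strand = -1;
      }
      out_read.push_back(r + 1);
      out_tpl.push_back(tpl + 1);
      out_score.push_back(score);
      out_start.push_back(start);
      out_strand.push_back(strand);
    }
    for (it = rev_best.begin(); it != rev_best.end(); ++it) {
      if (fwd_best.count(it->first)) continue;  // handled above
      out_read.push_back(r + 1);
      out_tpl.push_back(it->first + 1);
      out_score.push_back(it->second.first);
      out_start.push_back(it->second.second);
      out_strand.push_back(-1);
    }
  }
  return DataFrame::create(
    _["read"] = wrap(out_read),
    _["template"] = wrap(out_tpl),
    _["score"] = wrap(out_score),
    _["start"] = wrap(out_start),
    _["strand"] = wrap(out_strand));
}

// Pile assigned reads onto one template: per-position A/C/G/T vote counts
// plus total coverage (any base, N included). Placements are clipped to
// the template; starts are 0-based; strand -1 means the read aligns as its
// reverse complement.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int template_length, CharacterVector reads,
                         IntegerVector starts, IntegerVector strands) {
  IntegerMatrix counts(5, template_length);
  for (int r = 0; r < reads.size(); ++r) {
    std::string seq = as<std::string>(reads[r]);
    if (strands[r] < 0) {
      std::string rc(seq.size(), 'N');
      for (size_t i = 0; i < seq.size(); ++i)
        rc[i] = comp_base(seq[seq.size() - 1 - i]);
      seq = rc;
    }
    int s = starts[r];
    for (int i = 0; i < (int) seq.size(); ++i) {
      int pos = s + i;
      if (pos < 0 || pos >= template_length) continue;
      int c = base_code(seq[i]);
      if (c >= 0) counts(c, pos)++;
      counts(4, pos)++;
    }
  }
  return counts;
}
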