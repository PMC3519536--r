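// Pigeonhole k-mismatch matcher for short reads (m <= 2).
//
// A read of length L searched with up to m mismatches is cut into m + 1
// contiguous segments with lengths differing by at most one; any placement
// with <= m mismatches leaves at least one segment exact, so exact lookup
// of every segment in sorted k-mer tables of the reference enumerates a
// complete candidate set, which is then verified by full Hamming
// comparison. 'N' (or any non-ACGT byte) never matches anything, in reads
// or references.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

// one sorted k-mer table: key = 2-bit encoding, code = (seq<<33)|(pos<<1)|strand
struct KmerTable {
  int k;
  std::vector<uint64_t> keys;
  std::vector<uint64_t> codes;
};

struct SeedIndex {
  int read_length;
  int max_mismatches;
  std::vector<int> seg_off;  // segment offsets within the read
  std::vector<int> seg_len;  // segment lengths (sum = read_length)
  std::vector<int> seg_tab;  // table index per segment
  bool both_strands;
  std::vector<std::string> fwd;  // reference sequences, uppercase
  std::vector<std::string> rev;  // reverse complements (both_strands only)
  std::vector<KmerTable> tables;
};

static void index_strand(const std::vector<std::string>& seqs, int strand,
                         int k, std::vector<std::pair<uint64_t, uint64_t> >& out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t si = 0; si < seqs.size(); ++si) {
    const std::string& s = seqs[si];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;  // run length of consecutive ACGT bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) {
        valid = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        uint64_t pos = i + 1 - k;
        out.push_back(std::make_pair(
            key, ((uint64_t)si << 33) | (pos << 1) | (uint64_t)strand));
      }
    }
  }
}

// [[Rcpp::export]]
SEXP si_build(CharacterVector seqs, int read_length, int max_mismatches,
              bool both_strands) {
  if (max_mismatches < 0 || max_mismatches > 2)
    stop("max_mismatches must be 0, 1 or 2");
  if (read_length < max_mismatches + 1)
    stop("read_length must be at least max_mismatches + 1");

  SeedIndex* idx = new SeedIndex();
  idx->read_length = read_length;
  idx->max_mismatches = max_mismatches;
  idx->both_strands = both_strands;

  // segments of length base or base+1, covering the read exactly
  int nseg = max_mismatches + 1;
  int base = read_length / nseg;
  int rem = read_length % nseg;
  int off = 0;
  for (int j = 0; j < nseg; ++j) {
    int len = base + (j < rem ? 1 : 0);
    idx->seg_off.push_back(off);
    idx->seg_len.push_back(len);
    off += len;
  }

  idx->fwd.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    idx->fwd.push_back(as<std::string>(seqs[i]));

  if (both_strands) {
    idx->rev.reserve(idx->fwd.size());
    for (size_t i = 0; i < idx->fwd.size(); ++i) {
      const std::string& s = idx->fwd[i];
      std::string rc(s.size(), 'N');
      for (size_t j = 0; j < s.size(); ++j)
        rc[j] = comp_base(s[s.size() - 1 - j]);
      idx->rev.push_back(rc);
    }
  }

  // one table per distinct (capped) segment length
  for (int j = 0; j < nseg; ++j) {
    int k = std::min(idx->seg_len[j], 31);
    int found = -1;
    for (size_t t = 0; t < idx->tables.size(); ++t)
      if (idx->tables[t].k == k) found = (int)t;
    if (found < 0) {
      KmerTable tab;
      tab.k = k;
      std::vector<std::pair<uint64_t, uint64_t> > entries;
      index_strand(idx->fwd, 0, k, entries);
      if (both_strands) index_strand(idx->rev, 1, k, entries);
      std::sort(entries.begin(), entries.end());
      tab.keys.resize(entries.size());
      tab.codes.resize(entries.size());
      for (size_t i = 0; i < entries.size(); ++i) {
        tab.keys[i] = entries[i].first;
        tab.codes[i] = entries[i].second;
      }
      idx->tables.push_back(tab);
      found = (int)idx->tables.size() - 1;
    }
    idx->seg_tab.push_back(found);
  }

  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List si_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  double postings = 0;
  for (size_t t = 0; t < idx->tables.size(); ++t)
    postings += (double)idx->tables[t].keys.size();
  return List::create(
      _["read_length"] = idx->read_length,
      _["max_mismatches"] = idx->max_mismatches,
      _["segment_lengths"] = IntegerVector(idx->seg_len.begin(),
                                           idx->seg_len.end()),
      _["n_postings"] = idx->tables.empty()
          ? 0.0
          : (double)idx->tables[0].keys.size(),
      _["n_postings_total"] = postings,
      _["n_tables"] = (int)idx->tables.size(),
      _["n_sequences"] = (int)idx->fwd.size(),
      _["both_strands"] = idx->both_strands);
}

// Hamming distance with early exit; non-ACGT never matches.
static inline int verify(const std::string& ref, size_t start,
                         const std::string& read, int max_mm) {
  int mm = 0;
  for (size_t j = 0; j < read.size(); ++j) {
    char a = read[j], b = ref[start + j];
    if (a != b || base_code(a) < 0) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame si_query(SEXP xp, CharacterVector reads) {
  XPtr<SeedIndex> idx(xp);
  const int L = idx->read_length;
  const int m = idx->max_mismatches;
  const int nseg = m + 1;

  std::vector<int> out_read, out_seq, out_start, out_mm;
  std::vector<int> out_strand;
  std::vector<std::pair<uint64_t, int> > hits;  // (candidate code, mismatches)

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* rp = CHAR(STRING_ELT(reads, r));
    std::string read(rp);
    if ((int)read.size() != L)
      stop("read %d has length %d; this index requires length %d", (int)r + 1,
           (int)read.size(), L);
    hits.clear();

    for (int j = 0; j < nseg; ++j) {
      const KmerTable& tab = idx->tables[idx->seg_tab[j]];
      const int k = tab.k;
      const int off = idx->seg_off[j];
      const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      uint64_t key = 0;
      bool ok = true;
      for (int t = 0; t < k; ++t) {
        int b = base_code(read[off + t]);
        if (b < 0) { ok = false; break; }
        key = ((key << 2) | (uint64_t)b) & mask;
      }
      if (!ok) continue;

      std::pair<std::vector<uint64_t>::const_iterator,
                std::vector<uint64_t>::const_iterator>
          rng = std::equal_range(tab.keys.begin(), tab.keys.end(), key);
      for (std::vector<uint64_t>::const_iterator it = rng.first;
           it != rng.second; ++it) {
        uint64_t code = tab.codes[it - tab.keys.begin()];
        int strand = (int)(code & 1);
        uint64_t si = code >> 33;
        int64_t pos = (int64_t)((code >> 1) & 0xFFFFFFFFULL);
        int64_t start = pos - off;
        const std::string& ref = strand ? idx->rev[si] : idx->fwd[si];
        if (start < 0 || start + L > (int64_t)ref.size()) continue;
        int mm = verify(ref, (size_t)start, read, m);
        if (mm <= m)
          hits.push_back(std::make_pair(
              ((uint64_t)si << 33) | ((uint64_t)start << 1) | (uint64_t)strand,
              mm));
      }
    }

    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end());
    for (size_t h = 0; h < hits.size(); ++h) {
      if (h > 0 && hits[h].first == hits[h - 1].first) continue;  // dedup
      uint64_t code = hits[h].first;
      int strand = (int)(code & 1);
      uint64_t si = code >> 33;
      int64_t start = (int64_t)((code >> 1) & 0xFFFFFFFFULL);
      if (strand) start = (int64_t)idx->fwd[si].size() - start - L;
      out_read.push_back((int)r + 1);
      out_seq.push_back((int)si + 1);
      out_start.push_back((int)start);
      out_strand.push_back(strand);
      out_mm.push_back(hits[h].second);
    }
  }

  CharacterVector strand_chr(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand_chr[i] = out_strand[i] ? "-" : "+";

  return DataFrame::create(_["read"] = out_read, _["seq"] = out_seq,
                           _["start"] = out_start, _["strand"] = strand_chr,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// Leftmost 3' adapter alignment. Returns, per read, the 0-based read position
// where the adapter starts (= insert length), or -1 if no acceptable
// alignment exists. Overlap is min(adapter length, read length - pos) and
// must be >= min_overlap; mismatch fraction over the overlap must be
// <= max_mm_rate. Non-ACGT bases count as mismatches.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_mm_rate) {
  int alen = (int)adapter.size();
  if (alen == 0) stop("adapter must be non-empty");
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* rp = CHAR(STRING_ELT(reads, r));
    int len = (int)strlen(rp);
    int found = -1;
    for (int pos = 0; pos + min_overlap <= len; ++pos) {
      int overlap = std::min(alen, len - pos);
      int allowed = (int)(max_mm_rate * overlap + 1e-9);  // mm/overlap <= rate
      int mm = 0;
      for (int t = 0; t < overlap; ++t) {
        char a = rp[pos + t], b = adapter[t];
        if (a != b || base_code(a) < 0) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) { found = pos; break; }
    }
    out[r] = found;
  }
  return out;
}
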