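// Seeded banded semi-global alignment of short 16S miTag reads against
// labelled references. The read is aligned end-to-end; reference
// overhangs are free. A shared seed k-mer defines candidate diagonals;
// affine-gap Gotoh DP runs in a band around each diagonal cluster.
// Gap cost convention: a gap of length L costs gap_open + gap_ext*(L-1)
// (first gapped column pays gap_open).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N and anything else: never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int> revcomp_enc(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (3 - b) : 4;
  }
  return r;
}

// k-mer code -> positions (0-based) of the k-mer in the reference
typedef std::unordered_map<uint32_t, std::vector<int> > SeedIndex;

static SeedIndex build_index(const std::vector<int>& ref, int k) {
  SeedIndex idx;
  if ((int)ref.size() < k) return idx;
  uint32_t code = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0; // consecutive non-N bases ending here
  for (size_t i = 0; i < ref.size(); ++i) {
    if (ref[i] >= 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)ref[i]) & mask;
    if (++run >= k) idx[code].push_back((int)(i - k + 1));
  }
  return idx;
}

// candidate diagonal list (ref_pos - read_pos) from shared seeds
static std::vector<int> seed_diagonals(const std::vector<int>& read,
                                       const SeedIndex& idx, int k) {
  std::vector<int> diags;
  if ((int)read.size() < k) return diags;
  uint32_t code = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1);
  int run = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    if (read[i] >= 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)read[i]) & mask;
    if (++run >= k) {
      SeedIndex::const_iterator it = idx.find(code);
      if (it != idx.end()) {
        int qpos = (int)(i - k + 1);
        for (size_t j = 0; j < it->second.size(); ++j)
          diags.push_back(it->second[j] - qpos);
      }
    }
  }
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  return diags;
}

struct AlnResult {
  bool found;
  int score, matches, aln_len, ref_start, ref_end; // ref coords 1-based
  AlnResult() : found(false), score(NEG_INF), matches(0), aln_len(0),
                ref_start(0), ref_end(0) {}
};

// banded affine DP over diagonals [dlo, dhi]; band column b = j - i - dlo
static void band_align(const std::vector<int>& read,
                       const std::vector<int>& ref,
                       int dlo, int dhi,
                       int match, int mismatch, int gap_open, int gap_ext,
                       AlnResult& best) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int B = dhi - dlo + 1;
  std::vector<int> M((m + 1) * B, NEG_INF), Ix((m + 1) * B, NEG_INF),
      Iy((m + 1) * B, NEG_INF);
  // traceback: for M, predecessor state (0=M,1=Ix,2=Iy); for Ix/Iy,
  // 0=open (from M), 1=extend
  std::vector<unsigned char> tbM((m + 1) * B), tbX((m + 1) * B),
      tbY((m + 1) * B);
  for (int b = 0; b < B; ++b) {
    int j = 0 + dlo + b;
    if (j >= 0 && j <= n) M[b] = 0; // free reference prefix
  }
  for (int i = 1; i <= m; ++i) {
    const int row = i * B, prow = (i - 1) * B;
    for (int b = 0; b < B; ++b) {
      int j = i + dlo + b;
      if (j < 0 || j > n) continue;
      // M: consume read[i-1] vs ref[j-1]; diagonal = same b, prev row
      if (j >= 1) {
        int mprev = M[prow + b], xprev = Ix[prow + b], yprev = Iy[prow + b];
        int bestprev = mprev; unsigned char st = 0;
        if (xprev > bestprev) { bestprev = xprev; st = 1; }
        if (yprev > bestprev) { bestprev = yprev; st = 2; }
        if (bestprev > NEG_INF / 2) {
          int a = read[i - 1], c = ref[j - 1];
          int s = (a == c && a < 4) ? match : mismatch;
          M[row + b] = bestprev + s;
          tbM[row + b] = st;
        }
      }
      // Ix: read[i-1] vs gap; from (i-1, j) -> band b+1 in prev row
      if (b + 1 < B) {
        int mo = M[prow + b + 1], xe = Ix[prow + b + 1];
        int vopen = (mo > NEG_INF / 2) ? mo - gap_open : NEG_INF;
        int vext = (xe > NEG_INF / 2) ? xe - gap_ext : NEG_INF;
        if (vopen >= vext) { Ix[row + b] = vopen; tbX[row + b] = 0; }
        else { Ix[row + b] = vext; tbX[row + b] = 1; }
      }
      // Iy: ref[j-1] vs gap; from (i, j-1) -> band b-1 same row
      if (b >= 1 && j >= 1) {
        int mo = M[row + b - 1], ye = Iy[row + b - 1];
        int vopen = (mo > NEG_INF / 2) ? mo - gap_open : NEG_INF;
        int vext = (ye > NEG_INF / 2) ? ye - gap_ext : NEG_INF;
        if (vopen >= vext) { Iy[row + b] = vopen; tbY[row + b] = 0; }
        else { Iy[row + b] = vext; tbY[row + b] = 1; }
      }
    }
  }
  // free reference suffix: best over last row, states M and Ix
  int bbest = -1, sbest = NEG_INF; unsigned char stbest = 0;
  for (int b = 0; b < B; ++b) {
    int j = m + dlo + b;
    if (j < 0 || j > n) continue;
    if (M[m * B + b] > sbest) { sbest = M[m * B + b]; bbest = b; stbest = 0; }
    if (Ix[m * B + b] > sbest) { sbest = Ix[m * B + b]; bbest = b; stbest = 1; }
  }
  if (bbest < 0 || sbest <= NEG_INF / 2 || sbest <= best.score) return;
  // traceback for matches / aligned columns
  int i = m, b = bbest, matches = 0, cols = 0;
  unsigned char st = stbest;
  int ref_end = m + dlo + bbest, ref_start = ref_end;
  while (i > 0) {
    int j = i + dlo + b;
    if (st == 0) { // M
      int a = read[i - 1], c = ref[j - 1];
      if (a == c && a < 4) ++matches;
      ++cols;
      ref_start = j;
      st = tbM[i * B + b];
      --i; // b unchanged
    } else if (st == 1) { // Ix: read vs gap
      ++cols;
      unsigned char how = tbX[i * B + b];
      st = (how == 0) ? 0 : 1;
      --i; ++b;
    } else { // Iy: ref vs gap
      ++cols;
      ref_start = j;
      unsigned char how = tbY[i * B + b];
      st = (how == 0) ? 0 : 2;
      --b;
    }
  }
  best.found = true;
  best.score = sbest;
  best.matches = matches;
  best.aln_len = cols;
  best.ref_start = ref_start;
  best.ref_end = ref_end;
}

// align one (encoded) read to one indexed reference; tries all seed
// diagonal clusters
static AlnResult align_enc(const std::vector<int>& read,
                           const std::vector<int>& ref,
                           const SeedIndex& idx,
                           int k_seed, int match, int mismatch,
                           int gap_open, int gap_ext, int band) {
  AlnResult best;
  std::vector<int> diags = seed_diagonals(read, idx, k_seed);
  if (diags.empty()) return best;
  const int max_span = 32; // cap band width against repeat seeds
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i;
    while (j + 1 < diags.size() && diags[j + 1] - diags[j] <= band &&
           diags[j + 1] - diags[i] <= max_span)
      ++j;
    band_align(read, ref, diags[i] - band, diags[j] + band,
               match, mismatch, gap_open, gap_ext, best);
    i = j + 1;
  }
  return best;
}

// [[Rcpp::export(name = ".align_one_cpp")]]
List align_one_cpp(std::string read, std::string ref, int k_seed,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int band) {
  std::vector<int> r = encode(read), f = encode(ref);
  SeedIndex idx = build_index(f, k_seed);
  AlnResult a = align_enc(r, f, idx, k_seed, match, mismatch, gap_open,
                          gap_ext, band);
  return List::create(_["found"] = a.found, _["score"] = a.score,
                      _["matches"] = a.matches, _["aln_len"] = a.aln_len,
                      _["ref_start"] = a.ref_start,
                      _["ref_end"] = a.ref_end);
}

// Batch best-hit classification. refs must be supplied pre-sorted by
// ref_id; ties (equal score, identity, aln_len) resolve to the earlier
// reference and forward strand. Returns 1-based ref index, 0 for none.
// [[Rcpp::export(name = ".classify_batch_cpp")]]
DataFrame classify_batch_cpp(CharacterVector reads, CharacterVector refs,
                             int k_seed, int match, int mismatch,
                             int gap_open, int gap_ext, int band,
                             int min_score) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::vector<int> > ref_enc(nf);
  std::vector<SeedIndex> ref_idx(nf);
  for (int f = 0; f < nf; ++f) {
    ref_enc[f] = encode(as<std::string>(refs[f]));
    ref_idx[f] = build_index(ref_enc[f], k_seed);
  }
  IntegerVector out_ref(nr), out_score(nr), out_matches(nr),
      out_len(nr), out_strand(nr);
  for (int q = 0; q < nr; ++q) {
    std::vector<int> fwd = encode(as<std::string>(reads[q]));
    std::vector<int> rc = revcomp_enc(fwd);
    int best_ref = 0, best_strand = 0;
    AlnResult best;
    for (int f = 0; f < nf; ++f) {
      for (int s = 0; s < 2; ++s) {
        const std::vector<int>& rd = (s == 0) ? fwd : rc;
        AlnResult a = align_enc(rd, ref_enc[f], ref_idx[f], k_seed,
                                match, mismatch, gap_open, gap_ext, band);
        if (!a.found || a.score < min_score) continue;
        bool better = false;
        if (!best.found || a.score > best.score) better = true;
        else if (a.score == best.score) {
          // identity: matches/aln_len, compare by cross-multiplication
          long long lhs = (long long)a.matches * best.aln_len;
          long long rhs = (long long)best.matches * a.aln_len;
          if (lhs > rhs) better = true;
          else if (lhs == rhs && a.aln_len > best.aln_len) better = true;
          // equal again: keep earlier ref / forward strand (loop order)
        }
        if (better) { best = a; best_ref = f + 1; best_strand = s; }
      }
    }
    out_ref[q] = best.found ? best_ref : 0;
    out_score[q] = best.found ? best.score : NA_INTEGER;
    out_matches[q] = best.found ? best.matches : NA_INTEGER;
    out_len[q] = best.found ? best.aln_len : NA_INTEGER;
    out_strand[q] = best.found ? best_strand : NA_INTEGER;
  }
  return DataFrame::create(_["ref_index"] = out_ref,
                           _["score"] = out_score,
                           _["matches"] = out_matches,
                           _["aln_len"] = out_len,
                           _["strand"] = out_strand);
}
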