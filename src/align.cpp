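#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Seeded banded alignment engine shared by the ANI, MLST and variant layers.
// Scoring follows the package-wide convention: match +1, mismatch -1,
// affine gaps costing open + len * extend (defaults 10 and 1).

static const int NEG = INT32_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct AlnOut {
  int score = NEG;
  int matches = 0;
  int columns = 0;      // aligned columns (incl. gap columns inside span)
  int both = 0;         // columns with a residue on both sides
  int r_start = 0;      // 0-based inclusive start on reference
  int r_end = -1;       // 0-based inclusive end
  std::string qa, ra;   // gapped alignment strings (only if traceback)
  bool ok = false;
};

// Banded alignment of q against r.  Band covers diagonals (j - i) in
// [min(0, n-m) - band, max(0, n-m) + band].  If free_ref_ends, leading and
// trailing unaligned reference is free (glocal: global in query, local in
// reference); otherwise fully global.
static AlnOut banded_align(const std::string &q, const std::string &r,
                           int band, bool free_ref_ends, bool traceback,
                           int match = 1, int mismatch = -1,
                           int gap_open = 10, int gap_ext = 1) {
  const int m = (int)q.size(), n = (int)r.size();
  AlnOut out;
  if (m == 0 || n == 0) return out;
  const int lo = std::min(0, n - m) - band;
  const int hi = std::max(0, n - m) + band;
  const int W = hi - lo + 1;
  const int open_cost = gap_open + gap_ext;

  std::vector<int> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
  std::vector<int> Mcur(W, NEG), Xcur(W, NEG), Ycur(W, NEG);
  // traceback: 2 bits per state per cell
  // M: 0=fromM,1=fromX,2=fromY ; X: 0=open,1=extend ; Y: 0=open,1=extend
  std::vector<uint8_t> tb;
  if (traceback) tb.assign((size_t)(m + 1) * W, 0);

  auto col = [&](int i, int j) { return j - i - lo; };

  // i = 0 row
  for (int j = std::max(0, lo); j <= std::min(n, hi); ++j) {
    int c = col(0, j);
    if (free_ref_ends) {
      Mprev[c] = 0;  // alignment may start at any reference offset
    } else {
      if (j == 0) Mprev[c] = 0;
      else Xprev[c] = -(gap_open + j * gap_ext);
    }
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    const int jmin = std::max(0, i + lo), jmax = std::min(n, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      const int c = col(i, j);
      uint8_t tbbyte = 0;
      // M
      if (j >= 1 && j - 1 >= (i - 1) + lo && j - 1 <= (i - 1) + hi) {
        const int cd = col(i - 1, j - 1);
        int best = Mprev[cd]; uint8_t dir = 0;
        if (Xprev[cd] > best) { best = Xprev[cd]; dir = 1; }
        if (Yprev[cd] > best) { best = Yprev[cd]; dir = 2; }
        if (best > NEG / 2) {
          int s = (toupper(q[i - 1]) == toupper(r[j - 1])) ? match : mismatch;
          Mcur[c] = best + s;
          tbbyte |= dir;
        }
      }
      // X: gap in query (consumes reference), same i
      if (j >= 1 && j - 1 >= i + lo) {
        const int cl = col(i, j - 1);
        int xo = (Mcur[cl] > NEG / 2) ? Mcur[cl] - open_cost : NEG;
        int xe = (Xcur[cl] > NEG / 2) ? Xcur[cl] - gap_ext : NEG;
        if (xe > xo) { Xcur[c] = xe; tbbyte |= (1 << 2); }
        else if (xo > NEG / 2) Xcur[c] = xo;
      }
      // Y: gap in reference (consumes query)
      if (j >= (i - 1) + lo && j <= (i - 1) + hi) {
        const int cu = col(i - 1, j);
        int yo = (Mprev[cu] > NEG / 2) ? Mprev[cu] - open_cost : NEG;
        int ye = (Yprev[cu] > NEG / 2) ? Yprev[cu] - gap_ext : NEG;
        if (ye > yo) { Ycur[c] = ye; tbbyte |= (1 << 4); }
        else if (yo > NEG / 2) Ycur[c] = yo;
      }
      if (traceback) tb[(size_t)i * W + c] = tbbyte;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // pick end cell
  int best = NEG, bj = -1, bstate = 0;
  if (free_ref_ends) {
    for (int j = std::max(0, m + lo); j <= std::min(n, m + hi); ++j) {
      const int c = col(m, j);
      if (Mprev[c] > best) { best = Mprev[c]; bj = j; bstate = 0; }
      if (Yprev[c] > best) { best = Yprev[c]; bj = j; bstate = 2; }
    }
  } else {
    if (n >= m + lo && n <= m + hi) {
      const int c = col(m, n);
      best = Mprev[c]; bj = n; bstate = 0;
      if (Xprev[c] > best) { best = Xprev[c]; bstate = 1; }
      if (Yprev[c] > best) { best = Yprev[c]; bstate = 2; }
    }
  }
  if (bj < 0 || best <= NEG / 2) return out;
  out.score = best;
  out.ok = true;

  if (!traceback) return out;

  // traceback
  std::string qa, ra;
  int i = m, j = bj, state = bstate;
  out.r_end = j - 1;
  while (i > 0 || (!free_ref_ends && j > 0)) {
    if (free_ref_ends && i == 0) break;
    const uint8_t b = tb[(size_t)i * W + col(i, j)];
    if (state == 0) { // M
      if (i == 0) break;
      qa.push_back(q[i - 1]); ra.push_back(r[j - 1]);
      if (toupper(q[i - 1]) == toupper(r[j - 1])) out.matches++;
      out.both++;
      state = b & 3;
      --i; --j;
    } else if (state == 1) { // X: gap in query
      qa.push_back('-'); ra.push_back(r[j - 1]);
      state = ((b >> 2) & 1) ? 1 : 0;
      --j;
    } else { // Y: gap in ref
      qa.push_back(q[i - 1]); ra.push_back('-');
      state = ((b >> 4) & 1) ? 2 : 0;
      --i;
    }
  }
  out.r_start = j;
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  out.qa = qa; out.ra = ra;
  out.columns = (int)qa.size();
  return out;
}

// ---- k-mer index over a reference ------------------------------------------

struct RefIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int>> pos;
};

static void build_index(const std::string &ref, int k, RefIndex &idx) {
  idx.k = k;
  idx.pos.clear();
  const int n = (int)ref.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(ref[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx.pos[key].push_back(i - k + 1);
  }
}

// best seed diagonal for one query orientation; returns (diag, nseeds) or nseeds=0
static std::pair<int, int> best_diagonal(const std::string &q, const RefIndex &idx,
                                         int band) {
  const int k = idx.k, m = (int)q.size();
  std::vector<int> diags;
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = idx.pos.find(key);
      if (it != idx.pos.end() && (int)it->second.size() <= 50) {
        const int qpos = i - k + 1;
        for (int p : it->second) diags.push_back(p - qpos);
      }
    }
  }
  if (diags.empty()) return {0, 0};
  std::sort(diags.begin(), diags.end());
  // densest window of width `band`
  int bestn = 0, bests = 0;
  size_t lo_i = 0;
  for (size_t i = 0; i < diags.size(); ++i) {
    while (diags[i] - diags[lo_i] > band) ++lo_i;
    int nwin = (int)(i - lo_i + 1);
    if (nwin > bestn) { bestn = nwin; bests = (int)lo_i; }
  }
  return {diags[bests + bestn / 2], bestn};
}

// Map each query onto a reference sequence: seeded diagonal + banded glocal
// alignment.  Returns one row per query.
// [[Rcpp::export]]
DataFrame cpp_map_queries(CharacterVector queries, std::string ref,
                          int k = 15, int band = 32) {
  RefIndex idx;
  build_index(ref, k, idx);
  const int nref = (int)ref.size();
  const int nq = queries.size();
  NumericVector identity(nq), coverage(nq);
  IntegerVector r_start(nq), r_end(nq), score(nq), nseeds(nq);
  CharacterVector strand(nq);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    AlnOut best; char beststrand = '+'; int bestseeds = 0;
    for (int s = 0; s < 2; ++s) {
      std::string qq = (s == 0) ? q : revcomp(q);
      auto dg = best_diagonal(qq, idx, band);
      if (dg.second == 0) continue;
      const int m = (int)qq.size();
      int wstart = std::max(0, dg.first - band - 8);
      int wend = std::min(nref, dg.first + m + band + 8);
      if (wend <= wstart) continue;
      std::string window = ref.substr(wstart, wend - wstart);
      AlnOut a = banded_align(qq, window, band, true, true);
      if (a.ok) { a.r_start += wstart; a.r_end += wstart; }
      if (a.ok && a.score > best.score) {
        best = a; beststrand = (s == 0) ? '+' : '-'; bestseeds = dg.second;
      }
    }
    if (!best.ok) {
      identity[qi] = 0; coverage[qi] = 0; r_start[qi] = NA_INTEGER;
      r_end[qi] = NA_INTEGER; score[qi] = NA_INTEGER; nseeds[qi] = 0;
      strand[qi] = NA_STRING;
      continue;
    }
    identity[qi] = best.columns > 0 ? 100.0 * best.matches / best.columns : 0.0;
    coverage[qi] = q.size() > 0 ? (double)best.both / (double)q.size() : 0.0;
    r_start[qi] = best.r_start + 1;
    r_end[qi] = best.r_end + 1;
    score[qi] = best.score;
    nseeds[qi] = bestseeds;
    strand[qi] = (beststrand == '+') ? "+" : "-";
  }
  return DataFrame::create(_["identity"] = identity, _["coverage"] = coverage,
                           _["ref_start"] = r_start, _["ref_end"] = r_end,
                           _["score"] = score, _["n_seeds"] = nseeds,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Global banded pairwise alignment with traceback (any alphabet).
// [[Rcpp::export]]
List cpp_pair_align(std::string a, std::string b, int band_pad = 32,
                    int match = 1, int mismatch = -1,
                    int gap_open = 10, int gap_ext = 1) {
  AlnOut r = banded_align(a, b, band_pad, false, true,
                          match, mismatch, gap_open, gap_ext);
  if (!r.ok) stop("banded alignment failed; increase band_pad");
  return List::create(_["a"] = r.qa, _["b"] = r.ra, _["score"] = r.score,
                      _["matches"] = r.matches, _["columns"] = r.columns);
}

// Batch global banded alignment statistics (no traceback) for sequence pairs.
// [[Rcpp::export]]
DataFrame cpp_pair_stats(CharacterVector a, CharacterVector b,
                         int band_pad = 48, int match = 1, int mismatch = -1,
                         int gap_open = 10, int gap_ext = 1) {
  const int n = a.size();
  if (b.size() != n) stop("length mismatch");
  NumericVector identity(n), cov_a(n), cov_b(n);
  IntegerVector score(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    AlnOut r = banded_align(sa, sb, band_pad, false, true,
                            match, mismatch, gap_open, gap_ext);
    if (!r.ok) { identity[i] = 0; cov_a[i] = 0; cov_b[i] = 0; score[i] = NA_INTEGER; continue; }
    identity[i] = r.columns > 0 ? 100.0 * r.matches / r.columns : 0.0;
    cov_a[i] = sa.size() ? (double)r.both / sa.size() : 0.0;
    cov_b[i] = sb.size() ? (double)r.both / sb.size() : 0.0;
    score[i] = r.score;
  }
  return DataFrame::create(_["identity"] = identity, _["cov_a"] = cov_a,
                           _["cov_b"] = cov_b, _["score"] = score);
}

// Candidate pairs for ortholog clustering: sequence pairs sharing at least
// `min_shared` distinct k-mers.  Generic alphabet (letters A-Z); k-mers seen
// in more than `max_occ` sequences are skipped as low-information.
// [[Rcpp::export]]
IntegerMatrix cpp_candidate_pairs(CharacterVector seqs, int k = 5,
                                  int min_shared = 4, int max_occ = 256) {
  const int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> kmap;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    std::vector<uint64_t> keys;
    uint64_t key = 0;
    const uint64_t mask = (1ULL << (5 * k)) - 1;
    int run = 0;
    for (char ch : s) {
      char c = toupper(ch);
      if (c < 'A' || c > 'Z') { run = 0; key = 0; continue; }
      key = ((key << 5) | (uint64_t)(c - 'A')) & mask;
      if (++run >= k) keys.push_back(key);
    }
    std::sort(keys.begin(), keys.end());
    keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
    for (uint64_t kk : keys) kmap[kk].push_back(i);
  }
  std::unordered_map<uint64_t, int> paircount;
  for (auto &kv : kmap) {
    auto &v = kv.second;
    if ((int)v.size() < 2 || (int)v.size() > max_occ) continue;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        paircount[(uint64_t)v[x] * (uint64_t)n + (uint64_t)v[y]]++;
  }
  std::vector<int> ii, jj;
  for (auto &kv : paircount) {
    if (kv.second >= min_shared) {
      ii.push_back((int)(kv.first / n) + 1);
      jj.push_back((int)(kv.first % n) + 1);
    }
  }
  IntegerMatrix out((int)ii.size(), 2);
  for (size_t r = 0; r < ii.size(); ++r) { out(r, 0) = ii[r]; out(r, 1) = jj[r]; }
  return out;
}

// ---- composition vectors ---------------------------------------------------

static void count_words(const std::vector<std::string> &seqs, int k,
                        std::unordered_map<uint64_t, int> &counts,
                        long long &total) {
  const uint64_t mask = (1ULL << (5 * k)) - 1;
  for (const auto &s : seqs) {
    uint64_t key = 0; int run = 0;
    for (char ch : s) {
      char c = toupper(ch);
      if (c < 'A' || c > 'Z') { run = 0; key = 0; continue; }
      key = ((key << 5) | (uint64_t)(c - 'A')) & mask;
      if (++run >= k) { counts[key]++; total++; }
    }
  }
}

// Background-subtracted k-peptide scores: for each observed k-word,
// score = (f - f_pred) / f_pred with the (k-2)-order Markov prediction
// f_pred = f(w[1..k-1]) * f(w[2..k]) / f(w[2..k-1]).
// Word keys are base-32 letter codes returned as doubles (exact below 2^53).
// [[Rcpp::export]]
DataFrame cpp_cv_scores(CharacterVector seqs, int k = 6) {
  if (k < 3) stop("k must be >= 3");
  std::vector<std::string> ss(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  std::unordered_map<uint64_t, int> ck, ck1, ck2;
  long long nk = 0, nk1 = 0, nk2 = 0;
  count_words(ss, k, ck, nk);
  count_words(ss, k - 1, ck1, nk1);
  count_words(ss, k - 2, ck2, nk2);
  if (nk == 0) stop("no words of length k observed");
  std::vector<double> keys, scores;
  keys.reserve(ck.size()); scores.reserve(ck.size());
  const uint64_t mask_k1 = (1ULL << (5 * (k - 1))) - 1;
  const uint64_t mask_k2 = (1ULL << (5 * (k - 2))) - 1;
  for (auto &kv : ck) {
    const uint64_t w = kv.first;
    const uint64_t left = w >> 5;            // w[1..k-1]
    const uint64_t right = w & mask_k1;      // w[2..k]
    const uint64_t mid = (w >> 5) & mask_k2; // w[2..k-1]
    const double f = (double)kv.second / (double)nk;
    const double fl = (double)ck1[left] / (double)nk1;
    const double fr = (double)ck1[right] / (double)nk1;
    const double fm = (double)ck2[mid] / (double)nk2;
    double score = 0.0;
    if (fm > 0) {
      const double fp = fl * fr / fm;
      if (fp > 0) score = (f - fp) / fp;
    }
    keys.push_back((double)w);
    scores.push_back(score);
  }
  return DataFrame::create(_["key"] = keys, _["score"] = scores);
}

// Decode base-32 letter-coded word keys back to strings (for inspection).
// [[Rcpp::export]]
CharacterVector cpp_decode_words(NumericVector keys, int k) {
  CharacterVector out(keys.size());
  for (int i = 0; i < keys.size(); ++i) {
    uint64_t w = (uint64_t)keys[i];
    std::string s(k, 'A');
    for (int p = k - 1; p >= 0; --p) { s[p] = (char)('A' + (w & 31)); w >>= 5; }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
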