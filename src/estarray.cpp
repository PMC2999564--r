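#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base code; N and anything else -> -1 (breaks k-mers, scores as mismatch)
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

// columns are identities only when both bases agree and neither is N
static inline bool is_ident(char a, char b) {
  return a == b && a != 'N';
}

// ---------------------------------------------------------------------------
// Affine-gap Smith-Waterman with traceback.
// Penalties arrive as negative integers (BLASTN convention: a gap of length g
// costs gap_open + g * gap_extend). Returns the best local alignment; ties on
// score resolved toward the smallest (q_start, s_start).
// [[Rcpp::export]]
List sw_best_hit_cpp(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const int go = -gap_open, ge = -gap_extend;   // positive costs
  const int NEG = INT32_MIN / 4;

  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);  // gap in subject (vertical)
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);  // gap in query (horizontal)
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(E[idx(i - 1, j)] - ge, H[idx(i - 1, j)] - go - ge);
      int f = std::max(F[idx(i, j - 1)] - ge, H[idx(i, j - 1)] - go - ge);
      int s = is_ident(a[i - 1], b[j - 1]) ? match : mismatch;
      int h = H[idx(i - 1, j - 1)] + s;
      int v = std::max(0, std::max(h, std::max(e, f)));
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = v;
      if (v > best) best = v;
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["found"] = false);
  }

  // all endpoints achieving the best score (row-major order)
  std::vector<std::pair<int,int>> ends;
  for (int i = 1; i <= m && (int)ends.size() < 256; ++i)
    for (int j = 1; j <= n; ++j)
      if (H[idx(i, j)] == best) { ends.push_back({i, j}); if ((int)ends.size() >= 256) break; }

  int bqs = m + 1, bss = n + 1, bqe = 0, bse = 0;
  int bcols = 0, bident = 0, bmis = 0, bgap = 0;
  for (auto& ep : ends) {
    int i = ep.first, j = ep.second;
    int cols = 0, ident = 0, mis = 0, gaps = 0;
    int state = 0;  // 0 = in H, 1 = in E, 2 = in F
    int qe = i, se = j;
    while (true) {
      if (state == 0) {
        int v = H[idx(i, j)];
        if (v == 0) break;
        int s = is_ident(a[i - 1], b[j - 1]) ? match : mismatch;
        if (i > 0 && j > 0 && v == H[idx(i - 1, j - 1)] + s) {
          ++cols; if (is_ident(a[i - 1], b[j - 1])) ++ident; else ++mis;
          --i; --j;
        } else if (v == E[idx(i, j)]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        // vertical gap column: consumes a[i-1]
        ++cols; ++gaps;
        int v = E[idx(i, j)];
        if (i > 1 && v == E[idx(i - 1, j)] - ge) { --i; }
        else { --i; state = 0; }  // came from H[i-1,j] - go - ge
      } else {
        ++cols; ++gaps;
        int v = F[idx(i, j)];
        if (j > 1 && v == F[idx(i, j - 1)] - ge) { --j; }
        else { --j; state = 0; }
      }
    }
    int qs = i, ss = j;
    if (qs < bqs || (qs == bqs && ss < bss)) {
      bqs = qs; bss = ss; bqe = qe; bse = se;
      bcols = cols; bident = ident; bmis = mis; bgap = gaps;
    }
  }

  return List::create(
    _["score"] = best, _["found"] = true,
    _["q_start"] = bqs, _["q_end"] = bqe,     // 0-based half-open
    _["s_start"] = bss, _["s_end"] = bse,
    _["aligned_cols"] = bcols, _["identities"] = bident,
    _["mismatches"] = bmis, _["gaps"] = bgap);
}

// ---------------------------------------------------------------------------
// Exact-word seeding: candidate (query, subject, strand) triples sharing at
// least one w-mer free of N. strand -1 means query vs reverse complement of
// the subject. Indices 1-based. same_set drops qi == si (self comparisons).
// [[Rcpp::export]]
IntegerMatrix seed_pairs_cpp(CharacterVector qseqs, CharacterVector sseqs,
                             int w, bool same_set) {
  const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> index;
  int ns = sseqs.size(), nq = qseqs.size();

  for (int s = 0; s < ns; ++s) {
    std::string seq = as<std::string>(sseqs[s]);
    uint64_t kmer = 0; int run = 0;
    std::unordered_set<uint64_t> seen;
    for (size_t p = 0; p < seq.size(); ++p) {
      int c = base_code(seq[p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= w && seen.insert(kmer).second) index[kmer].push_back(s);
    }
  }

  std::vector<int> qi, si, strand;
  for (int q = 0; q < nq; ++q) {
    std::string fwd = as<std::string>(qseqs[q]);
    for (int st = 0; st < 2; ++st) {
      std::string seq = (st == 0) ? fwd : revcomp_str(fwd);
      std::unordered_set<int> hits;
      uint64_t kmer = 0; int run = 0;
      for (size_t p = 0; p < seq.size(); ++p) {
        int c = base_code(seq[p]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run >= w) {
          auto it = index.find(kmer);
          if (it != index.end())
            for (int s : it->second) hits.insert(s);
        }
      }
      for (int s : hits) {
        if (same_set && s == q) continue;
        qi.push_back(q + 1); si.push_back(s + 1);
        strand.push_back(st == 0 ? 1 : -1);
      }
    }
  }

  IntegerMatrix out(qi.size(), 3);
  for (size_t k = 0; k < qi.size(); ++k) {
    out(k, 0) = qi[k]; out(k, 1) = si[k]; out(k, 2) = strand[k];
  }
  colnames(out) = CharacterVector::create("query", "subject", "strand");
  return out;
}

// ---------------------------------------------------------------------------
// Ungapped window scan on one orientation: best window of >= min_overlap
// consecutive columns whose identity fraction passes min_identity
// (strict: > rather than >=). Scans every diagonal long enough to host a
// window; returns the qualifying window with the highest (fraction, length),
// or found = FALSE. Coordinates 0-based on the given strings.
struct WinBest {
  bool found = false;
  double frac = -1.0;
  int a_start = 0, b_start = 0, len = 0, matches = 0;
};

static WinBest window_scan_pair(const std::string& a, const std::string& b,
                                int min_overlap, double min_identity,
                                bool strict, bool first_only) {
  WinBest best;
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> pre;
  for (int d = -(lb - min_overlap); d <= la - min_overlap; ++d) {
    int as = std::max(0, d), bs = std::max(0, -d);
    int dl = std::min(la - as, lb - bs);
    if (dl < min_overlap) continue;
    pre.assign(dl + 1, 0);
    for (int k = 0; k < dl; ++k)
      pre[k + 1] = pre[k] + (is_ident(a[as + k], b[bs + k]) ? 1 : 0);
    for (int L = min_overlap; L <= dl; ++L) {
      for (int s = 0; s + L <= dl; ++s) {
        int mt = pre[s + L] - pre[s];
        double diff = (double)mt - min_identity * L;
        bool ok = strict ? (diff > 1e-9) : (diff > -1e-9);
        if (!ok) continue;
        double fr = (double)mt / L;
        if (fr > best.frac + 1e-12 ||
            (std::abs(fr - best.frac) <= 1e-12 && L > best.len)) {
          best.found = true; best.frac = fr;
          best.a_start = as + s; best.b_start = bs + s;
          best.len = L; best.matches = mt;
        }
        if (first_only) return best;
      }
    }
  }
  return best;
}

// Seeded variant: restrict to diagonals carrying a shared w-mer, then scan a
// band of diagonals around each (ungapped windows live on one diagonal, so
// the band is just the seeded diagonal itself).
static WinBest window_scan_seeded(const std::string& a, const std::string& b,
                                  int min_overlap, double min_identity,
                                  bool strict, int w) {
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  std::unordered_map<uint64_t, std::vector<int>> bpos;
  {
    uint64_t kmer = 0; int run = 0;
    for (int p = 0; p < (int)b.size(); ++p) {
      int c = base_code(b[p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= w) bpos[kmer].push_back(p - w + 1);
    }
  }
  std::unordered_set<int> diags;
  {
    uint64_t kmer = 0; int run = 0;
    for (int p = 0; p < (int)a.size(); ++p) {
      int c = base_code(a[p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= w) {
        auto it = bpos.find(kmer);
        if (it != bpos.end())
          for (int bp : it->second) diags.insert((p - w + 1) - bp);
      }
    }
  }
  WinBest best;
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> pre;
  for (int d : diags) {
    int as = std::max(0, d), bs = std::max(0, -d);
    int dl = std::min(la - as, lb - bs);
    if (dl < min_overlap) continue;
    pre.assign(dl + 1, 0);
    for (int k = 0; k < dl; ++k)
      pre[k + 1] = pre[k] + (is_ident(a[as + k], b[bs + k]) ? 1 : 0);
    for (int L = min_overlap; L <= dl; ++L) {
      for (int s = 0; s + L <= dl; ++s) {
        int mt = pre[s + L] - pre[s];
        double diff = (double)mt - min_identity * L;
        bool ok = strict ? (diff > 1e-9) : (diff > -1e-9);
        if (!ok) continue;
        double fr = (double)mt / L;
        if (fr > best.frac + 1e-12 ||
            (std::abs(fr - best.frac) <= 1e-12 && L > best.len)) {
          best.found = true; best.frac = fr;
          best.a_start = as + s; best.b_start = bs + s;
          best.len = L; best.matches = mt;
        }
      }
    }
  }
  return best;
}

static List winbest_to_list(const WinBest& wb) {
  return List::create(
    _["found"] = wb.found, _["a_start"] = wb.a_start, _["b_start"] = wb.b_start,
    _["length"] = wb.len, _["matches"] = wb.matches,
    _["identity"] = wb.found ? (double)wb.matches / wb.len : NA_REAL);
}

// [[Rcpp::export]]
List window_best_cpp(std::string a, std::string b, int min_overlap,
                     double min_identity, bool strict, int seed_len) {
  WinBest wb = (seed_len > 0)
    ? window_scan_seeded(a, b, min_overlap, min_identity, strict, seed_len)
    : window_scan_pair(a, b, min_overlap, min_identity, strict, false);
  return winbest_to_list(wb);
}

// ---------------------------------------------------------------------------
// All-pairs similarity, seeded route: global w-mer index over forward strands;
// candidates are unordered pairs sharing a w-mer on either relative
// orientation, each verified by the full per-pair diagonal scan.
// Returns rows (i, j, strand) with i < j, 1-based; strand -1 means seq i is
// similar to the reverse complement of seq j.
// [[Rcpp::export]]
IntegerMatrix similar_pairs_seeded_cpp(CharacterVector seqs, int min_overlap,
                                       double min_identity, bool strict,
                                       int seed_len) {
  const int n = seqs.size();
  const int w = seed_len;
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  std::vector<std::string> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp_str(fwd[i]);
  }
  std::unordered_map<uint64_t, std::vector<int>> index;
  for (int i = 0; i < n; ++i) {
    uint64_t kmer = 0; int run = 0;
    std::unordered_set<uint64_t> seen;
    for (size_t p = 0; p < fwd[i].size(); ++p) {
      int c = base_code(fwd[i][p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= w && seen.insert(kmer).second) index[kmer].push_back(i);
    }
  }
  // candidate pair -> strands to test (bit 1 fwd, bit 2 rc)
  std::unordered_map<uint64_t, int> cand;
  auto add_cand = [&](int i, int j, int bit) {
    if (i == j) return;
    int lo = std::min(i, j), hi = std::max(i, j);
    cand[((uint64_t)lo << 32) | (uint64_t)hi] |= bit;
  };
  for (int i = 0; i < n; ++i) {
    for (int st = 0; st < 2; ++st) {
      const std::string& seq = (st == 0) ? fwd[i] : rc[i];
      uint64_t kmer = 0; int run = 0;
      std::unordered_set<uint64_t> seen;
      for (size_t p = 0; p < seq.size(); ++p) {
        int c = base_code(seq[p]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run >= w && seen.insert(kmer).second) {
          auto it = index.find(kmer);
          if (it != index.end())
            for (int j : it->second) add_cand(i, j, st == 0 ? 1 : 2);
        }
      }
    }
  }
  std::vector<int> ri, rj, rs;
  for (auto& kv : cand) {
    int i = (int)(kv.first >> 32), j = (int)(kv.first & 0xffffffffULL);
    bool fwd_hit = false, rc_hit = false;
    if (kv.second & 1)
      fwd_hit = window_scan_pair(fwd[i], fwd[j], min_overlap, min_identity,
                                 strict, true).found;
    if (kv.second & 2)
      rc_hit = window_scan_pair(fwd[i], rc[j], min_overlap, min_identity,
                                strict, true).found;
    if (fwd_hit) { ri.push_back(i + 1); rj.push_back(j + 1); rs.push_back(1); }
    if (rc_hit)  { ri.push_back(i + 1); rj.push_back(j + 1); rs.push_back(-1); }
  }
  IntegerMatrix out(ri.size(), 3);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k]; out(k, 1) = rj[k]; out(k, 2) = rs[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "strand");
  return out;
}

// Brute-force oracle: every unordered pair, both orientations, exhaustive
// diagonal scan, no seeding. Same output layout as the seeded route.
// [[Rcpp::export]]
IntegerMatrix similar_pairs_brute_cpp(CharacterVector seqs, int min_overlap,
                                      double min_identity, bool strict) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp_str(fwd[i]);
  }
  std::vector<int> ri, rj, rs;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (window_scan_pair(fwd[i], fwd[j], min_overlap, min_identity,
                           strict, true).found) {
        ri.push_back(i + 1); rj.push_back(j + 1); rs.push_back(1);
      }
      if (window_scan_pair(fwd[i], rc[j], min_overlap, min_identity,
                           strict, true).found) {
        ri.push_back(i + 1); rj.push_back(j + 1); rs.push_back(-1);
      }
    }
  }
  IntegerMatrix out(ri.size(), 3);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k]; out(k, 1) = rj[k]; out(k, 2) = rs[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "strand");
  return out;
}

// ---------------------------------------------------------------------------
// Probe window scoring: for every window of the given length, the
// deterministic design score
//   -|GC - 0.5| - 0.05 * max(longest homopolymer - 4, 0)
//               - 0.02 * max(longest self-complementary stretch - 8, 0)
// with -Inf for windows whose N content exceeds 10%. The self-complementary
// stretch is the longest common substring between the window and its own
// reverse complement (a hairpin/self-dimer proxy).
// [[Rcpp::export]]
NumericVector score_windows_cpp(std::string seq, int len) {
  const int L = (int)seq.size();
  if (L < len) return NumericVector(0);
  const int nw = L - len + 1;
  NumericVector out(nw);

  std::vector<int> gc(L + 1, 0), nn(L + 1, 0), run(L, 1);
  for (int p = 0; p < L; ++p) {
    gc[p + 1] = gc[p] + ((seq[p] == 'G' || seq[p] == 'C') ? 1 : 0);
    nn[p + 1] = nn[p] + ((base_code(seq[p]) < 0) ? 1 : 0);
    if (p > 0 && seq[p] == seq[p - 1]) run[p] = run[p - 1] + 1;
  }

  std::vector<int> dp((size_t)(len + 1) * (len + 1));
  for (int s = 0; s < nw; ++s) {
    if (nn[s + len] - nn[s] > 0.10 * len + 1e-9) {
      out[s] = R_NegInf;
      continue;
    }
    double gcfrac = (double)(gc[s + len] - gc[s]) / len;
    int hp = 0;
    for (int p = s; p < s + len; ++p)
      hp = std::max(hp, std::min(run[p], p - s + 1));
    // longest common substring between window and its reverse complement
    std::string w = seq.substr(s, len), wrc = revcomp_str(w);
    int sc = 0;
    std::fill(dp.begin(), dp.end(), 0);
    for (int i = 1; i <= len; ++i)
      for (int j = 1; j <= len; ++j) {
        if (w[i - 1] != 'N' && w[i - 1] == wrc[j - 1]) {
          int v = dp[(size_t)(i - 1) * (len + 1) + (j - 1)] + 1;
          dp[(size_t)i * (len + 1) + j] = v;
          if (v > sc) sc = v;
        }
      }
    double score = -std::abs(gcfrac - 0.5)
      - 0.05 * std::max(hp - 4, 0)
      - 0.02 * std::max(sc - 8, 0);
    out[s] = score;
  }
  return out;
}
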