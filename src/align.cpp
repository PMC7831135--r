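// Affine-gap alignment kernels and k-mer seeded search used by the
// homology-search and ANI modules. Scoring conventions:
//   nucleotide: match +1, mismatch -1, gap open 5, gap extend 2
//               (a gap of length L costs open + L*extend)
//   protein:    BLOSUM62, gap open 11, gap extend 1
// Ambiguity codes outside ACGT / the 20 standard residues score as
// mismatches and never participate in seeding.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int NAA = 24;
static const int BLOSUM62[NAA][NAA] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static int aa_index(char c) {
  const char* p = std::strchr(AA_ORDER, std::toupper(c));
  if (p == nullptr || *p == '\0') return 22; // unknown -> X
  return (int)(p - AA_ORDER);
}

struct Scorer {
  bool protein;
  int gap_open, gap_ext;
  Scorer(const std::string& type) {
    protein = (type == "aa");
    if (protein) { gap_open = 11; gap_ext = 1; }
    else { gap_open = 5; gap_ext = 2; }
  }
  inline int score(char a, char b) const {
    if (protein) return BLOSUM62[aa_index(a)][aa_index(b)];
    char A = std::toupper(a), B = std::toupper(b);
    bool okA = (A=='A'||A=='C'||A=='G'||A=='T');
    bool okB = (B=='A'||B=='C'||B=='G'||B=='T');
    if (!okA || !okB) return -1;      // ambiguity scores as mismatch
    return (A == B) ? 1 : -1;
  }
};

static const int NEG = -100000000;

// Full affine-gap DP with traceback. mode: 0 = local (Smith-Waterman),
// 1 = global (Needleman-Wunsch), 2 = glocal (b ends free: b is a longer
// subject window, a must align end-to-end). Traceback ties broken
// diagonal > up (gap in b) > left (gap in a).
static List align_full(const std::string& a, const std::string& b,
                       const Scorer& sc, int mode) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<int>> M(n+1, std::vector<int>(m+1, NEG));
  std::vector<std::vector<int>> X(n+1, std::vector<int>(m+1, NEG)); // gap in b (up)
  std::vector<std::vector<int>> Y(n+1, std::vector<int>(m+1, NEG)); // gap in a (left)
  M[0][0] = 0;
  for (int i = 1; i <= n; ++i) {
    if (mode == 0) M[i][0] = 0;
    else X[i][0] = -sc.gap_open - i * sc.gap_ext;
  }
  for (int j = 1; j <= m; ++j) {
    if (mode == 0 || mode == 2) M[0][j] = 0;
    else Y[0][j] = -sc.gap_open - j * sc.gap_ext;
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = sc.score(a[i-1], b[j-1]);
      int dm = std::max(M[i-1][j-1], std::max(X[i-1][j-1], Y[i-1][j-1]));
      int mm = (dm == NEG) ? NEG : dm + s;
      if (mode == 0 && mm < 0) mm = 0;
      M[i][j] = mm;
      int xo = (M[i-1][j] == NEG) ? NEG : M[i-1][j] - sc.gap_open - sc.gap_ext;
      int xe = (X[i-1][j] == NEG) ? NEG : X[i-1][j] - sc.gap_ext;
      X[i][j] = std::max(xo, xe);
      int yo = (M[i][j-1] == NEG) ? NEG : M[i][j-1] - sc.gap_open - sc.gap_ext;
      int ye = (Y[i][j-1] == NEG) ? NEG : Y[i][j-1] - sc.gap_ext;
      Y[i][j] = std::max(yo, ye);
      if (mode == 0 && M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }
  int si, sj, sstate; // traceback start
  if (mode == 0) { si = bi; sj = bj; sstate = 0; }
  else if (mode == 1) {
    si = n; sj = m;
    int mv = M[n][m], xv = X[n][m], yv = Y[n][m];
    best = std::max(mv, std::max(xv, yv));
    sstate = (best == mv) ? 0 : (best == xv ? 1 : 2);
  } else { // glocal: free trailing gap in b -> best over last row
    si = n; sj = 0; best = NEG; sstate = 0;
    for (int j = 0; j <= m; ++j) {
      int v = std::max(M[n][j], X[n][j]);
      if (v > best) { best = v; sj = j; sstate = (v == M[n][j]) ? 0 : 1; }
    }
  }
  // traceback
  std::string aa_, bb_;
  int i = si, j = sj, state = sstate;
  int matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    if (mode == 0 && state == 0 && M[i][j] == 0) {
      // prefer the longest optimal alignment: continue through zero-score
      // cells reachable by a genuine diagonal path
      bool cont = i > 0 && j > 0 &&
        std::max(M[i-1][j-1], std::max(X[i-1][j-1], Y[i-1][j-1])) +
          sc.score(a[i-1], b[j-1]) == 0;
      if (!cont) break;
    }
    if (mode == 2 && i == 0) break; // leading b gap is free
    if (state == 0) {
      if (i == 0 || j == 0) { // only in global mode edges
        if (i > 0) state = 1; else state = 2;
        continue;
      }
      int dm = std::max(M[i-1][j-1], std::max(X[i-1][j-1], Y[i-1][j-1]));
      aa_.push_back(a[i-1]); bb_.push_back(b[j-1]);
      if (std::toupper(a[i-1]) == std::toupper(b[j-1])) matches++;
      cols++;
      int ns = (dm == M[i-1][j-1]) ? 0 : (dm == X[i-1][j-1] ? 1 : 2);
      i--; j--; state = ns;
    } else if (state == 1) { // gap in b: consumed a[i-1]
      aa_.push_back(a[i-1]); bb_.push_back('-'); cols++;
      bool from_open = (X[i][j] == ((M[i-1][j] == NEG) ? NEG : M[i-1][j] - sc.gap_open - sc.gap_ext));
      i--; state = from_open ? 0 : 1;
    } else { // gap in a
      aa_.push_back('-'); bb_.push_back(b[j-1]); cols++;
      bool from_open = (Y[i][j] == ((M[i][j-1] == NEG) ? NEG : M[i][j-1] - sc.gap_open - sc.gap_ext));
      j--; state = from_open ? 0 : 2;
    }
  }
  std::reverse(aa_.begin(), aa_.end());
  std::reverse(bb_.begin(), bb_.end());
  double ident = (cols > 0) ? (double)matches / (double)cols : 0.0;
  return List::create(_["score"] = best, _["a_aln"] = aa_, _["b_aln"] = bb_,
                      _["identity"] = ident, _["matches"] = matches,
                      _["columns"] = cols,
                      _["a_start"] = i, _["a_end"] = si,
                      _["b_start"] = j, _["b_end"] = sj);
}

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string a, std::string b, std::string type) {
  Scorer sc(type);
  return align_full(a, b, sc, 0);
}

// [[Rcpp::export(name = ".cpp_global_align")]]
List cpp_global_align(std::string a, std::string b, std::string type,
                      bool free_end_b = false) {
  Scorer sc(type);
  return align_full(a, b, sc, free_end_b ? 2 : 1);
}

// Banded global/glocal alignment of a against b around the main diagonal
// shifted by `shift` (expected b position of a[0]). Returns score/identity
// computed over a traceback within the band. free_end_b frees b's ends.
// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string a, std::string b, int band,
                      std::string type, bool free_end_b = true,
                      int shift = 0) {
  Scorer sc(type);
  int n = a.size(), m = b.size();
  int W = 2 * band + 1;
  auto idx = [&](int i, int j) -> int { // j within band of i+shift
    return j - (i + shift) + band;
  };
  std::vector<int> M((n+1)*W, NEG), X((n+1)*W, NEG), Y((n+1)*W, NEG);
  std::vector<int8_t> TM((n+1)*W, 0), TX((n+1)*W, 0), TY((n+1)*W, 0);
  auto at = [&](std::vector<int>& V, int i, int k) -> int& { return V[i*W + k]; };
  {
    int k0 = idx(0, 0);
    if (k0 >= 0 && k0 < W) at(M, 0, k0) = 0;
    for (int j = std::max(1, 0 + shift - band); j <= std::min(m, 0 + shift + band); ++j) {
      int k = idx(0, j);
      if (free_end_b) at(M, 0, k) = 0;
      else at(Y, 0, k) = -sc.gap_open - j * sc.gap_ext;
    }
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i + shift - band), jhi = std::min(m, i + shift + band);
    for (int j = jlo; j <= jhi; ++j) {
      int k = idx(i, j);
      if (j == 0) {
        at(X, i, k) = -sc.gap_open - i * sc.gap_ext; TX[i*W + k] = 1;
        continue;
      }
      // diagonal
      int kd = idx(i-1, j-1);
      if (kd >= 0 && kd < W) {
        int pm = at(M, i-1, kd), px = at(X, i-1, kd), py = at(Y, i-1, kd);
        int dm = std::max(pm, std::max(px, py));
        if (dm > NEG) {
          at(M, i, k) = dm + sc.score(a[i-1], b[j-1]);
          TM[i*W + k] = (dm == pm) ? 0 : (dm == px ? 1 : 2);
        }
      }
      // up: gap in b (consume a)
      int ku = idx(i-1, j);
      if (ku >= 0 && ku < W) {
        int xo = (at(M, i-1, ku) == NEG) ? NEG : at(M, i-1, ku) - sc.gap_open - sc.gap_ext;
        int xe = (at(X, i-1, ku) == NEG) ? NEG : at(X, i-1, ku) - sc.gap_ext;
        at(X, i, k) = std::max(xo, xe);
        TX[i*W + k] = (xo >= xe) ? 0 : 1;
      }
      // left: gap in a (consume b)
      int kl = idx(i, j-1);
      if (kl >= 0 && kl < W) {
        int yo = (at(M, i, kl) == NEG) ? NEG : at(M, i, kl) - sc.gap_open - sc.gap_ext;
        int ye = (at(Y, i, kl) == NEG) ? NEG : at(Y, i, kl) - sc.gap_ext;
        at(Y, i, k) = std::max(yo, ye);
        TY[i*W + k] = (yo >= ye) ? 0 : 2;
      }
    }
  }
  // endpoint
  int best = NEG, bj = -1, bstate = 0;
  int jlo = std::max(0, n + shift - band), jhi = std::min(m, n + shift + band);
  if (free_end_b) {
    for (int j = jlo; j <= jhi; ++j) {
      int k = idx(n, j);
      int vm = at(M, n, k), vx = at(X, n, k);
      int v = std::max(vm, vx);
      if (v > best) { best = v; bj = j; bstate = (v == vm) ? 0 : 1; }
    }
  } else {
    int k = idx(n, m);
    if (k >= 0 && k < W) {
      int vm = at(M, n, k), vx = at(X, n, k), vy = at(Y, n, k);
      best = std::max(vm, std::max(vx, vy));
      bj = m; bstate = (best == vm) ? 0 : (best == vx ? 1 : 2);
    }
  }
  if (best <= NEG || bj < 0)
    return List::create(_["score"] = NA_REAL, _["identity"] = NA_REAL,
                        _["matches"] = 0, _["columns"] = 0,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  // traceback
  int i = n, j = bj, state = bstate, matches = 0, cols = 0;
  while (i > 0 || (!free_end_b && j > 0)) {
    if (i == 0) break;
    int k = idx(i, j);
    if (state == 0) {
      if (std::toupper(a[i-1]) == std::toupper(b[j-1])) matches++;
      cols++;
      state = TM[i*W + k]; i--; j--;
    } else if (state == 1) {
      cols++; state = TX[i*W + k] == 0 ? 0 : 1; i--;
    } else {
      cols++; state = TY[i*W + k] == 0 ? 0 : 2; j--;
    }
  }
  double ident = (cols > 0) ? (double)matches / (double)cols : 0.0;
  return List::create(_["score"] = best, _["identity"] = ident,
                      _["matches"] = matches, _["columns"] = cols,
                      _["b_start"] = j, _["b_end"] = bj);
}

// ---- k-mer machinery -------------------------------------------------------

static inline int nt2(char c) {
  switch (std::toupper(c)) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline int aa5(char c) { // 0..19 standard, -1 otherwise (no seeding on X/*)
  static const std::string STD = "ARNDCQEGHILKMFPSTWYV";
  size_t p = STD.find(std::toupper(c));
  return (p == std::string::npos) ? -1 : (int)p;
}

// Seeded best local alignment of query against one subject string.
// Exact word matches define diagonals; diagonals are clustered within
// `band` and each cluster's subject window is aligned with full SW.
// Deterministic: clusters scanned in order of subject position.
// [[Rcpp::export(name = ".cpp_seeded_local")]]
List cpp_seeded_local(std::string query, std::string subject, int word,
                      std::string type, int band = 32) {
  bool protein = (type == "aa");
  int n = query.size(), m = subject.size();
  List none = List::create(_["score"] = 0);
  if (n < word || m < word) return none;
  // index subject words
  std::unordered_map<uint64_t, std::vector<int>> sidx;
  uint64_t key = 0, mask;
  int base = protein ? 20 : 4;
  mask = 1; for (int w = 0; w < word; ++w) mask *= base; // base^word
  int run = 0;
  for (int j = 0; j < m; ++j) {
    int c = protein ? aa5(subject[j]) : nt2(subject[j]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = (key * base + c) % mask;
    run++;
    if (run >= word) sidx[key].push_back(j - word + 1);
  }
  // collect diagonals of exact word matches
  std::vector<long> diags;
  key = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int c = protein ? aa5(query[i]) : nt2(query[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = (key * base + c) % mask;
    run++;
    if (run >= word) {
      auto it = sidx.find(key);
      if (it != sidx.end()) {
        int qi = i - word + 1;
        for (int sj : it->second) diags.push_back((long)sj - qi);
      }
    }
  }
  if (diags.empty()) return none;
  std::sort(diags.begin(), diags.end());
  diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
  // cluster nearby diagonals, align each cluster window once
  List bestres = none; int bestscore = 0; long beststart = -1;
  size_t ci = 0;
  while (ci < diags.size()) {
    size_t cj = ci;
    while (cj + 1 < diags.size() && diags[cj+1] - diags[cj] <= band) cj++;
    long dlo = diags[ci], dhi = diags[cj];
    long wlo = dlo - band, whi = dhi + n + band; // subject window
    if (wlo < 0) wlo = 0;
    if (whi > m) whi = m;
    std::string win = subject.substr(wlo, whi - wlo);
    Scorer sc(type);
    List r = align_full(query, win, sc, 0);
    int s = as<int>(r["score"]);
    long bs = wlo + (long)as<int>(r["b_start"]);
    if (s > bestscore || (s == bestscore && bestscore > 0 && bs < beststart)) {
      r["b_start"] = (int)(wlo + as<int>(r["b_start"]));
      r["b_end"] = (int)(wlo + as<int>(r["b_end"]));
      bestres = r; bestscore = s; beststart = bs;
    }
    ci = cj + 1;
  }
  return bestres;
}

// Map genome fragments against an indexed reference (fastANI-style).
// subjects = reference scaffolds followed by their reverse complements
// (caller supplies both; strand of subject s is s < nscaf ? '+' : '-').
// For each fragment: shared exact k-mers vote for (subject, diagonal/band)
// bins; the winning bin (>= min_seeds votes; ties -> smaller subject then
// smaller diagonal) defines the reference window; identity comes from a
// banded glocal alignment of the fragment against that window.
// [[Rcpp::export(name = ".cpp_fragment_map")]]
List cpp_fragment_map(std::vector<std::string> fragments,
                      std::vector<std::string> subjects,
                      int k, int band, int min_seeds) {
  // build reference index
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> ridx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2*k)) - 1);
  for (size_t s = 0; s < subjects.size(); ++s) {
    const std::string& sub = subjects[s];
    uint64_t key = 0; int run = 0;
    for (size_t j = 0; j < sub.size(); ++j) {
      int c = nt2(sub[j]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & mask;
      run++;
      if (run >= k) ridx[key].push_back({(int)s, (int)j - k + 1});
    }
  }
  int nf = fragments.size();
  NumericVector identity(nf, NA_REAL);
  IntegerVector subj(nf, NA_INTEGER), refpos(nf, NA_INTEGER), seeds(nf, 0);
  for (int f = 0; f < nf; ++f) {
    const std::string& fr = fragments[f];
    int n = fr.size();
    // vote per (subject, diagonal bin)
    std::unordered_map<uint64_t, int> votes;
    std::unordered_map<uint64_t, long> diag_min;
    uint64_t key = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = nt2(fr[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & mask;
      run++;
      if (run >= k) {
        auto it = ridx.find(key);
        if (it == ridx.end()) continue;
        int qi = i - k + 1;
        for (auto& pr : it->second) {
          long d = (long)pr.second - qi;
          long bin = (d + 1000000000L) / band; // shift keeps bin positive
          uint64_t vk = ((uint64_t)pr.first << 40) | (uint64_t)bin;
          votes[vk]++;
          auto dm = diag_min.find(vk);
          if (dm == diag_min.end() || d < dm->second) diag_min[vk] = d;
        }
      }
    }
    if (votes.empty()) continue;
    // deterministic winner: max votes, then smaller subject, smaller bin
    uint64_t bestk = 0; int bestv = -1;
    for (auto& kv : votes) {
      if (kv.second > bestv || (kv.second == bestv && kv.first < bestk)) {
        bestv = kv.second; bestk = kv.first;
      }
    }
    seeds[f] = bestv;
    if (bestv < min_seeds) continue;
    int s = (int)(bestk >> 40);
    long d = diag_min[bestk]; // fragment position 0 maps near subject pos d
    const std::string& sub = subjects[s];
    long wlo = d - band; if (wlo < 0) wlo = 0;
    long whi = d + n + band; if (whi > (long)sub.size()) whi = sub.size();
    if (whi <= wlo) continue;
    std::string win = sub.substr(wlo, whi - wlo);
    List r = cpp_banded_align(fr, win, band, "nt", true, (int)(d - wlo));
    // identity over fragment length: unaligned fragment ends count as mismatch
    double mt = as<double>(r["matches"]);
    identity[f] = mt / (double)n;
    subj[f] = s + 1;
    refpos[f] = (int)(wlo);
  }
  return List::create(_["identity"] = identity, _["subject"] = subj,
                      _["refpos"] = refpos, _["seeds"] = seeds);
}

// Best hit of each query protein against a set of subject proteins
// (used for reciprocal-best-hit orthology). Seeded; returns best subject
// index (1-based), score and identity per query; subject index ties broken
// by smaller index.
// [[Rcpp::export(name = ".cpp_best_protein_hits")]]
List cpp_best_protein_hits(std::vector<std::string> queries,
                           std::vector<std::string> subjects,
                           int word = 4) {
  // index all subject words -> (subject, pos)
  std::unordered_map<uint64_t, std::vector<int>> sidx;
  uint64_t mod = 1; for (int w = 0; w < word; ++w) mod *= 20;
  for (size_t s = 0; s < subjects.size(); ++s) {
    const std::string& sub = subjects[s];
    uint64_t key = 0; int run = 0;
    for (size_t j = 0; j < sub.size(); ++j) {
      int c = aa5(sub[j]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = (key * 20 + c) % mod;
      run++;
      if (run >= word) sidx[key].push_back((int)s);
    }
  }
  int nq = queries.size();
  IntegerVector best(nq, NA_INTEGER);
  NumericVector score(nq, 0.0), ident(nq, NA_REAL);
  Scorer sc("aa");
  for (int q = 0; q < nq; ++q) {
    const std::string& qu = queries[q];
    // candidate subjects by shared-word counts
    std::unordered_map<int,int> cand;
    uint64_t key = 0; int run = 0;
    for (size_t i = 0; i < qu.size(); ++i) {
      int c = aa5(qu[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = (key * 20 + c) % mod;
      run++;
      if (run >= word) {
        auto it = sidx.find(key);
        if (it != sidx.end())
          for (int s : it->second) cand[s]++;
      }
    }
    if (cand.empty()) continue;
    std::vector<std::pair<int,int>> cv(cand.begin(), cand.end());
    std::sort(cv.begin(), cv.end(),
              [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
                return a.second > b.second || (a.second == b.second && a.first < b.first);
              });
    int bs = 0, bsub = -1; double bid = 0;
    size_t ncand = std::min(cv.size(), (size_t)25); // top candidates by shared words
    for (size_t ci = 0; ci < ncand; ++ci) {
      int s = cv[ci].first;
      if (cv[ci].second * 4 < bs) break; // cannot beat: each word scores <= ~ high
      List r = align_full(qu, subjects[s], sc, 0);
      int sval = as<int>(r["score"]);
      if (sval > bs || (sval == bs && s < bsub)) {
        bs = sval; bsub = s; bid = as<double>(r["identity"]);
      }
    }
    if (bsub >= 0 && bs > 0) { best[q] = bsub + 1; score[q] = bs; ident[q] = bid; }
  }
  return List::create(_["best"] = best, _["score"] = score, _["identity"] = ident);
}
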