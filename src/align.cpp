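#include <Rcpp.h>
#include <deque>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// All aligners score a gap of length k as -(open + k * ext) and work on
// integer-encoded sequences (0-based indices into the substitution matrix).

static const int NEG = INT_MIN / 4;

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps.
// Tie-break: among equal scores prefer lower subject start, then lower query
// start, then shorter alignment; realised by propagating the path origin.
// ---------------------------------------------------------------------------

struct Origin { int si, qi, len; };

static inline bool origin_better(const Origin& a, const Origin& b) {
  if (a.si != b.si) return a.si < b.si;
  if (a.qi != b.qi) return a.qi < b.qi;
  return a.len < b.len;
}

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  int gap_open, int gap_ext) {
  const int n = q.size(), m = s.size();
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
    F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> bH((n + 1) * (m + 1), 0), bE((n + 1) * (m + 1), 0),
    bF((n + 1) * (m + 1), 0);
  std::vector<Origin> OH((n + 1) * (m + 1), {0, 0, 0});
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  Origin borig = {INT_MAX, INT_MAX, INT_MAX};
  const int go = gap_open + gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (consumes subject)
      int eo = H[at(i, j - 1)] - go, ee = E[at(i, j - 1)] - gap_ext;
      E[at(i, j)] = eo >= ee ? eo : ee;
      bE[at(i, j)] = eo >= ee ? 1 : 0;
      // F: gap in subject (consumes query)
      int fo = H[at(i - 1, j)] - go, fe = F[at(i - 1, j)] - gap_ext;
      F[at(i, j)] = fo >= fe ? fo : fe;
      bF[at(i, j)] = fo >= fe ? 1 : 0;

      int diag = H[at(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
      int val = 0; unsigned char mv = 0; Origin org = {j - 1, i - 1, 0};
      // candidate order irrelevant: explicit tie-break below
      struct Cand { int v; unsigned char mv; Origin o; };
      Origin odiag = H[at(i - 1, j - 1)] == 0 && bH[at(i - 1, j - 1)] == 0
        ? Origin{j - 1, i - 1, 1}
        : Origin{OH[at(i - 1, j - 1)].si, OH[at(i - 1, j - 1)].qi,
                 OH[at(i - 1, j - 1)].len + 1};
      Cand cands[3] = {
        {diag, 1, odiag},
        {E[at(i, j)], 2, {OH[at(i, j - 1)].si, OH[at(i, j - 1)].qi, OH[at(i, j - 1)].len + 1}},
        {F[at(i, j)], 3, {OH[at(i - 1, j)].si, OH[at(i - 1, j)].qi, OH[at(i - 1, j)].len + 1}}};
      for (int c = 0; c < 3; ++c) {
        if (cands[c].v > val ||
            (cands[c].v == val && val > 0 && mv != 0 && origin_better(cands[c].o, org)) ||
            (cands[c].v == val && val > 0 && mv == 0)) {
          val = cands[c].v; mv = cands[c].mv; org = cands[c].o;
        }
      }
      if (val <= 0) { val = 0; mv = 0; org = {j, i, 0}; }
      H[at(i, j)] = val; bH[at(i, j)] = mv; OH[at(i, j)] = org;
      if (val > best || (val == best && val > 0 && origin_better(org, borig))) {
        best = val; bi = i; bj = j; borig = org;
      }
    }
  }

  std::string qa, sa;
  int i = bi, j = bj;
  if (best > 0) {
    unsigned char state = 0;  // 0 = H
    while (!(state == 0 && bH[at(i, j)] == 0)) {
      if (state == 0) {
        unsigned char mv = bH[at(i, j)];
        if (mv == 1) { qa.push_back((char)('0' + 0)); }
        if (mv == 1) { qa.back() = 'M'; sa.push_back('M'); --i; --j; }
        else if (mv == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        qa.push_back('-'); sa.push_back('S');
        if (bE[at(i, j)] == 1) state = 0;
        --j;
      } else {
        qa.push_back('Q'); sa.push_back('-');
        if (bF[at(i, j)] == 1) state = 0;
        --i;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  // qa/sa are move templates: 'M' consume both, 'Q'/'S' consume one side
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi,
                      _["sstart"] = j, _["send"] = bj,
                      _["qmoves"] = qa, _["smoves"] = sa);
}

// ---------------------------------------------------------------------------
// Needleman-Wunsch global alignment with affine gaps, end gaps penalised.
// Tie-break prefers diagonal, then subject gap, then query gap.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nw_global_cpp")]]
List nw_global_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gap_open, int gap_ext) {
  const int n = q.size(), m = s.size();
  const int go = gap_open + gap_ext;
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<int> H((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
    F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> bH((n + 1) * (m + 1), 0), bE((n + 1) * (m + 1), 0),
    bF((n + 1) * (m + 1), 0);
  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    E[at(0, j)] = -(gap_open + j * gap_ext);
    H[at(0, j)] = E[at(0, j)]; bH[at(0, j)] = 2;
    bE[at(0, j)] = j == 1 ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = -(gap_open + i * gap_ext);
    H[at(i, 0)] = F[at(i, 0)]; bH[at(i, 0)] = 3;
    bF[at(i, 0)] = i == 1 ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int eo = H[at(i, j - 1)] - go, ee = E[at(i, j - 1)] - gap_ext;
      E[at(i, j)] = eo >= ee ? eo : ee; bE[at(i, j)] = eo >= ee ? 1 : 0;
      int fo = H[at(i - 1, j)] - go, fe = F[at(i - 1, j)] - gap_ext;
      F[at(i, j)] = fo >= fe ? fo : fe; bF[at(i, j)] = fo >= fe ? 1 : 0;
      int diag = H[at(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
      int val = diag; unsigned char mv = 1;
      if (E[at(i, j)] > val) { val = E[at(i, j)]; mv = 2; }
      if (F[at(i, j)] > val) { val = F[at(i, j)]; mv = 3; }
      H[at(i, j)] = val; bH[at(i, j)] = mv;
    }
  }
  std::string qa, sa;
  int i = n, j = m; unsigned char state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char mv = bH[at(i, j)];
      if (mv == 1) { qa.push_back('M'); sa.push_back('M'); --i; --j; }
      else if (mv == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      qa.push_back('-'); sa.push_back('S');
      if (bE[at(i, j)] == 1) state = 0;
      --j;
    } else {
      qa.push_back('Q'); sa.push_back('-');
      if (bF[at(i, j)] == 1) state = 0;
      --i;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["qmoves"] = qa, _["smoves"] = sa);
}

// ---------------------------------------------------------------------------
// Brute-force local alignment score by explicit enumeration of every gapped
// local alignment (no dynamic-programming state sharing). Reference oracle
// for testing only; exponential in sequence length.
// ---------------------------------------------------------------------------

static void bf_rec(const IntegerVector& q, const IntegerVector& s,
                   const IntegerMatrix& mat, int go, int ge,
                   int i, int j, int score, int last, int& best) {
  // last: 0 none/match, 1 gap-in-query, 2 gap-in-subject
  if (score > best) best = score;
  int n = q.size(), m = s.size();
  if (i < n && j < m)
    bf_rec(q, s, mat, go, ge, i + 1, j + 1, score + mat(q[i], s[j]), 0, best);
  if (j < m)  // gap in query, consume subject
    bf_rec(q, s, mat, go, ge, i, j + 1,
           score - (last == 1 ? ge : go + ge), 1, best);
  if (i < n)  // gap in subject, consume query
    bf_rec(q, s, mat, go, ge, i + 1, j,
           score - (last == 2 ? ge : go + ge), 2, best);
}

// [[Rcpp::export(name = ".bf_local_score_cpp")]]
int bf_local_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                       int gap_open, int gap_ext) {
  int best = 0;
  const int n = q.size(), m = s.size();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      // every alignment must start with a match column (leading gaps never help
      // but are still enumerated from later starts)
      int sc = mat(q[i], s[j]);
      bf_rec(q, s, mat, gap_open, gap_ext, i + 1, j + 1, sc, 0, best);
    }
  return best < 0 ? 0 : best;
}

// Brute-force global score and the identity range over optimal alignments.
static void bf_glob_rec(const IntegerVector& q, const IntegerVector& s,
                        const IntegerMatrix& mat, int go, int ge,
                        int i, int j, int score, int last, int ident, int cols,
                        int& best, int& best_ident_max, int& best_ident_min,
                        int& best_cols_max, int& best_cols_min) {
  int n = q.size(), m = s.size();
  if (i == n && j == m) {
    if (score > best) {
      best = score; best_ident_max = best_ident_min = ident;
      best_cols_max = best_cols_min = cols;
    } else if (score == best) {
      if (ident > best_ident_max) best_ident_max = ident;
      if (ident < best_ident_min) best_ident_min = ident;
      if (cols > best_cols_max) best_cols_max = cols;
      if (cols < best_cols_min) best_cols_min = cols;
    }
    return;
  }
  if (i < n && j < m)
    bf_glob_rec(q, s, mat, go, ge, i + 1, j + 1, score + mat(q[i], s[j]), 0,
                ident + (q[i] == s[j] ? 1 : 0), cols + 1,
                best, best_ident_max, best_ident_min, best_cols_max, best_cols_min);
  if (j < m)
    bf_glob_rec(q, s, mat, go, ge, i, j + 1, score - (last == 1 ? ge : go + ge),
                1, ident, cols + 1,
                best, best_ident_max, best_ident_min, best_cols_max, best_cols_min);
  if (i < n)
    bf_glob_rec(q, s, mat, go, ge, i + 1, j, score - (last == 2 ? ge : go + ge),
                2, ident, cols + 1,
                best, best_ident_max, best_ident_min, best_cols_max, best_cols_min);
}

// [[Rcpp::export(name = ".bf_global_cpp")]]
List bf_global_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gap_open, int gap_ext) {
  int best = NEG, imax = 0, imin = 0, cmax = 0, cmin = 0;
  bf_glob_rec(q, s, mat, gap_open, gap_ext, 0, 0, 0, 0, 0, 0,
              best, imax, imin, cmax, cmin);
  return List::create(_["score"] = best, _["ident_max"] = imax,
                      _["ident_min"] = imin, _["cols_max"] = cmax,
                      _["cols_min"] = cmin);
}

// ---------------------------------------------------------------------------
// Spliced protein-to-DNA alignment (GeneWise-style), local in both query and
// DNA, codon-match states plus intron states in three phases, canonical GT-AG
// donors/acceptors only, flat intron-open penalty, lengths in [min,max].
// ---------------------------------------------------------------------------

// DNA encoding: A=0 C=1 G=2 T=3, anything else 4 (N).
// codon_aa: length 125 lookup, index b1*25+b2*5+b3 -> aa row in `mat`.

struct Donor { int pos; int val; };

class WinMax {
  // sliding-window maximum over donor entries; window in donor position
  std::deque<Donor> dq;
public:
  void push(int pos, int val) {
    if (val <= NEG / 2) return;
    while (!dq.empty() && dq.back().val <= val) dq.pop_back();
    dq.push_back({pos, val});
  }
  // max over donors with pos >= lo (older donors outside max length dropped)
  int query(int lo, int hi) {
    while (!dq.empty() && dq.front().pos < lo) dq.pop_front();
    int best = NEG;
    for (auto& d : dq) { if (d.pos > hi) break; if (d.val > best) { best = d.val; } }
    return best;
  }
  // also need argmax for traceback
  int arg(int lo, int hi, int val) {
    for (auto& d : dq) { if (d.pos > hi) break; if (d.pos >= lo && d.val == val) return d.pos; }
    return -1;
  }
  void clear() { dq.clear(); }
};

// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(IntegerVector q, IntegerVector dna, IntegerMatrix mat,
                       IntegerVector codon_aa, int gap_open, int gap_ext,
                       int intron_open, int intron_min, int intron_max) {
  const int n = q.size(), L = dna.size();
  const int go = gap_open + gap_ext;
  auto at = [L](int i, int j) { return (long)i * (L + 1) + j; };
  auto isGT = [&](int p) { return p >= 0 && p + 1 < L && dna[p] == 2 && dna[p + 1] == 3; };
  auto isAG = [&](int p) { return p >= 1 && p < L && dna[p - 1] == 0 && dna[p] == 2; };
  auto codon = [&](int b1, int b2, int b3) { return codon_aa[b1 * 25 + b2 * 5 + b3]; };

  std::vector<int> M((long)(n + 1) * (L + 1), NEG), GQ((long)(n + 1) * (L + 1), NEG),
    GD((long)(n + 1) * (L + 1), NEG);
  // traceback: move code and aux (donor position for intron moves)
  // moves: 0 local-start, 1 diag codon, 2 from GQ, 3 from GD,
  //        4 intron phase0 (aux=donor), 5 intron phase1 (aux=donor),
  //        6 intron phase2 (aux=donor)
  std::vector<unsigned char> bM((long)(n + 1) * (L + 1), 0);
  std::vector<int> aM((long)(n + 1) * (L + 1), -1);
  std::vector<unsigned char> bGQ((long)(n + 1) * (L + 1), 0), bGD((long)(n + 1) * (L + 1), 0);

  // M[i][j] only defined at codon boundaries of the current gene; local start
  // allowed anywhere with value 0.
  int best = 0, bi = -1, bj = -1;

  // phase-0 window structures are per row; phase-1 keyed by carried base (5),
  // phase-2 by two carried bases (25), built from the previous row.
  WinMax w0[1], w1[5], w2[25];

  // prev-row donor entry values must be pushed in donor-position order as j
  // advances; precompute per row the donor candidates then stream them.
  for (int i = 0; i <= n; ++i) {
    w0[0].clear();
    for (int b = 0; b < 5; ++b) w1[b].clear();
    for (int b = 0; b < 25; ++b) w2[b].clear();
    int next0 = 0, next1 = 0, next2 = 0;  // donor positions streamed so far
    for (int j = 0; j <= L; ++j) {
      // stream donors usable by an acceptor at this j:
      // phase0 resume at j needs donor d <= j - intron_min; entry M[i][d] (same row)
      while (next0 <= j - intron_min) {
        int d = next0++;
        if (isGT(d) && M[at(i, d)] > NEG / 2)
          w0[0].push(d, M[at(i, d)] - intron_open);
      }
      if (i >= 1) {
        // phase1: resume lands at j = a + 3, intron a=j-3, donor d; carried
        // base dna[d-1]; entry M[i-1][d-1]
        while (next1 <= (j - 3) - intron_min + 1) {
          int d = next1++;
          if (d >= 1 && isGT(d) && M[at(i - 1, d - 1)] > NEG / 2)
            w1[dna[d - 1]].push(d, M[at(i - 1, d - 1)] - intron_open);
        }
        // phase2: resume lands at j = a + 2, intron a=j-2, donor d; carried
        // bases dna[d-2],dna[d-1]; entry M[i-1][d-2]
        while (next2 <= (j - 2) - intron_min + 1) {
          int d = next2++;
          if (d >= 2 && isGT(d) && M[at(i - 1, d - 2)] > NEG / 2)
            w2[dna[d - 2] * 5 + dna[d - 1]].push(d, M[at(i - 1, d - 2)] - intron_open);
        }
      }

      int val = 0; unsigned char mv = 0; int aux = -1;  // local start
      // diagonal codon match
      if (i >= 1 && j >= 3) {
        int aa = codon(dna[j - 3], dna[j - 2], dna[j - 1]);
        int v = M[at(i - 1, j - 3)];
        if (v > NEG / 2) {
          v += mat(q[i - 1], aa);
          if (v > val) { val = v; mv = 1; aux = -1; }
        }
      }
      // affine gap states
      if (i >= 1) {
        int o = M[at(i - 1, j)] > NEG / 2 ? M[at(i - 1, j)] - go : NEG;
        int e = GQ[at(i - 1, j)] > NEG / 2 ? GQ[at(i - 1, j)] - gap_ext : NEG;
        GQ[at(i, j)] = o >= e ? o : e; bGQ[at(i, j)] = o >= e ? 1 : 0;
        if (GQ[at(i, j)] > val) { val = GQ[at(i, j)]; mv = 2; aux = -1; }
      }
      if (j >= 3) {
        int o = M[at(i, j - 3)] > NEG / 2 ? M[at(i, j - 3)] - go : NEG;
        int e = GD[at(i, j - 3)] > NEG / 2 ? GD[at(i, j - 3)] - gap_ext : NEG;
        GD[at(i, j)] = o >= e ? o : e; bGD[at(i, j)] = o >= e ? 1 : 0;
        if (GD[at(i, j)] > val) { val = GD[at(i, j)]; mv = 3; aux = -1; }
      }
      // phase-0 intron: acceptor ends at j-1 (AG at j-2..j-1)
      if (j >= 2 && isAG(j - 1)) {
        int lo = (j - 1) - intron_max + 1 > 0 ? (j - 1) - intron_max + 1 : 0;
        int hi = (j - 1) - intron_min + 1;
        int v = w0[0].query(lo, hi);
        if (v > NEG / 2 && v > val) {
          val = v; mv = 4; aux = w0[0].arg(lo, hi, v);
        }
      }
      // phase-1 intron: acceptor at j-4..j-3 (AG), codon completes with
      // dna[j-2], dna[j-1]
      if (i >= 1 && j >= 5 && isAG(j - 3)) {
        int a = j - 3;
        int lo = a - intron_max + 1 > 0 ? a - intron_max + 1 : 0;
        int hi = a - intron_min + 1;
        for (int b = 0; b < 5; ++b) {
          int v = w1[b].query(lo, hi);
          if (v <= NEG / 2) continue;
          int aa = codon(b, dna[j - 2], dna[j - 1]);
          int v2 = v + mat(q[i - 1], aa);
          if (v2 > val) { val = v2; mv = 5; aux = w1[b].arg(lo, hi, v); }
        }
      }
      // phase-2 intron: acceptor at j-3..j-2 (AG), codon completes with dna[j-1]
      if (i >= 1 && j >= 4 && isAG(j - 2)) {
        int a = j - 2;
        int lo = a - intron_max + 1 > 0 ? a - intron_max + 1 : 0;
        int hi = a - intron_min + 1;
        for (int b = 0; b < 25; ++b) {
          int v = w2[b].query(lo, hi);
          if (v <= NEG / 2) continue;
          int aa = codon(b / 5, b % 5, dna[j - 1]);
          int v2 = v + mat(q[i - 1], aa);
          if (v2 > val) { val = v2; mv = 6; aux = w2[b].arg(lo, hi, v); }
        }
      }
      M[at(i, j)] = val; bM[at(i, j)] = mv; aM[at(i, j)] = aux;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }

  if (best <= 0)
    return List::create(_["score"] = 0);

  // traceback: collect coding codon intervals (region coordinates, half-open)
  std::vector<std::pair<int, int>> coding;  // merged later in R
  int i = bi, j = bj;
  while (true) {
    unsigned char mv = bM[at(i, j)];
    if (mv == 0) break;
    if (mv == 1) { coding.push_back({j - 3, j}); i -= 1; j -= 3; }
    else if (mv == 2) {
      // query-residue deletions: walk the affine chain
      while (true) {
        unsigned char op = bGQ[at(i, j)];
        i -= 1;
        if (op == 1) break;
      }
    } else if (mv == 3) {
      while (true) {
        unsigned char op = bGD[at(i, j)];
        coding.push_back({j - 3, j});
        j -= 3;
        if (op == 1) break;
      }
    } else if (mv == 4) {
      int d = aM[at(i, j)];
      j = d;  // resume before the intron (same i)
    } else if (mv == 5) {
      int d = aM[at(i, j)];
      coding.push_back({j - 2, j});      // two bases after the intron
      coding.push_back({d - 1, d});      // one base before the intron
      i -= 1; j = d - 1;
    } else if (mv == 6) {
      int d = aM[at(i, j)];
      coding.push_back({j - 1, j});      // one base after the intron
      coding.push_back({d - 2, d});      // two bases before the intron
      i -= 1; j = d - 2;
    }
  }
  int qstart = i, qend = bi;
  std::reverse(coding.begin(), coding.end());
  // merge adjacent/contiguous coding intervals into exons
  std::vector<int> ex_start, ex_end;
  for (auto& c : coding) {
    if (!ex_end.empty() && ex_end.back() == c.first) ex_end.back() = c.second;
    else { ex_start.push_back(c.first); ex_end.push_back(c.second); }
  }
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
                      _["exon_start"] = wrap(ex_start), _["exon_end"] = wrap(ex_end));
}

// ---------------------------------------------------------------------------
// Profile-profile global alignment for progressive MSA. Columns are residue
// count vectors (rows 0..A-1 residues, row A gaps). Column-column score is the
// count-weighted mean substitution score over residue pairs; gap-open/ext
// penalties are scaled by the occupied fraction of the inserted-against
// profile column.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerMatrix p1, IntegerMatrix p2, IntegerMatrix mat,
                       double gap_open, double gap_ext) {
  const int A = mat.nrow();
  const int n = p1.ncol(), m = p2.ncol();
  // occupancy fractions
  std::vector<double> occ1(n), occ2(m);
  double tot1 = 0, tot2 = 0;
  for (int r = 0; r <= A; ++r) tot1 += p1(r, 0);
  for (int r = 0; r <= A; ++r) tot2 += p2(r, 0);
  for (int j = 0; j < n; ++j) {
    double k = 0; for (int r = 0; r < A; ++r) k += p1(r, j);
    occ1[j] = tot1 > 0 ? k / tot1 : 0;
  }
  for (int j = 0; j < m; ++j) {
    double k = 0; for (int r = 0; r < A; ++r) k += p2(r, j);
    occ2[j] = tot2 > 0 ? k / tot2 : 0;
  }
  auto colscore = [&](int c1, int c2) {
    double s = 0, w = 0;
    for (int a = 0; a < A; ++a) {
      if (p1(a, c1) == 0) continue;
      for (int b = 0; b < A; ++b) {
        if (p2(b, c2) == 0) continue;
        s += (double)p1(a, c1) * p2(b, c2) * mat(a, b);
        w += (double)p1(a, c1) * p2(b, c2);
      }
    }
    return w > 0 ? s / w : 0.0;
  };
  const double NEGD = -1e18;
  std::vector<double> H((n + 1) * (m + 1), NEGD), E((n + 1) * (m + 1), NEGD),
    F((n + 1) * (m + 1), NEGD);
  std::vector<unsigned char> bH((n + 1) * (m + 1), 0), bE((n + 1) * (m + 1), 0),
    bF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  H[0] = 0;
  for (int j = 1; j <= m; ++j) {
    double pen = (gap_open + gap_ext) * occ2[j - 1];
    E[at(0, j)] = (j == 1 ? H[0] - pen : E[at(0, j - 1)] - gap_ext * occ2[j - 1]);
    bE[at(0, j)] = j == 1 ? 1 : 0;
    H[at(0, j)] = E[at(0, j)]; bH[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    double pen = (gap_open + gap_ext) * occ1[i - 1];
    F[at(i, 0)] = (i == 1 ? H[0] - pen : F[at(i - 1, 0)] - gap_ext * occ1[i - 1]);
    bF[at(i, 0)] = i == 1 ? 1 : 0;
    H[at(i, 0)] = F[at(i, 0)]; bH[at(i, 0)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eo = H[at(i, j - 1)] - (gap_open + gap_ext) * occ2[j - 1];
      double ee = E[at(i, j - 1)] - gap_ext * occ2[j - 1];
      E[at(i, j)] = eo >= ee ? eo : ee; bE[at(i, j)] = eo >= ee ? 1 : 0;
      double fo = H[at(i - 1, j)] - (gap_open + gap_ext) * occ1[i - 1];
      double fe = F[at(i - 1, j)] - gap_ext * occ1[i - 1];
      F[at(i, j)] = fo >= fe ? fo : fe; bF[at(i, j)] = fo >= fe ? 1 : 0;
      double diag = H[at(i - 1, j - 1)] + colscore(i - 1, j - 1);
      double val = diag; unsigned char mv = 1;
      if (E[at(i, j)] > val) { val = E[at(i, j)]; mv = 2; }
      if (F[at(i, j)] > val) { val = F[at(i, j)]; mv = 3; }
      H[at(i, j)] = val; bH[at(i, j)] = mv;
    }
  }
  std::string moves;  // 'M' both, 'Q' profile1 column, 'S' profile2 column
  int i = n, j = m; unsigned char state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char mv = bH[at(i, j)];
      if (mv == 1) { moves.push_back('M'); --i; --j; }
      else if (mv == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      moves.push_back('S');
      if (bE[at(i, j)] == 1) state = 0;
      --j;
    } else {
      moves.push_back('Q');
      if (bF[at(i, j)] == 1) state = 0;
      --i;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = H[at(n, m)], _["moves"] = moves);
}
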