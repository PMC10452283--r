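#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gap of length L costs gap_open + L * gap_ext (both arguments negative).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return -2; // non-IUPAC for this pipeline's alphabet
  }
}

// Local affine-gap alignment (Gotoh) with rolling score rows and a packed
// per-cell traceback byte:
//   bits 0-1: H source (0 stop, 1 diagonal, 2 E = gap in query, 3 F = gap in
//             subject); bit 2: E extends E; bit 3: F extends F.
// Deterministic preference: diagonal, then F, then E; gap open preferred to
// extend on score ties. Returns blastn-style statistics: identities /
// alignment columns (gap columns included).
// [[Rcpp::export]]
List sw_affine_cpp(std::string query, std::string subject,
                   double match, double mismatch,
                   double gap_open, double gap_ext) {
  const int n = (int) query.size(), m = (int) subject.size();
  std::vector<int> q(n), s(m);
  for (int i = 0; i < n; ++i) {
    q[i] = base_code(query[i]);
    if (q[i] == -2) stop("query contains a non-IUPAC character");
  }
  for (int j = 0; j < m; ++j) {
    s[j] = base_code(subject[j]);
    if (s[j] == -2) stop("subject contains a non-IUPAC character");
  }
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), Fcol(m + 1, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    double e = NEG;
    const int qi = q[i - 1];
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      double e_open = Hcur[j - 1] + gap_open + gap_ext;
      double e_ext = e + gap_ext;
      unsigned char ebit = 0;
      if (e_ext > e_open) { e = e_ext; ebit = 4; } else { e = e_open; }
      double f_open = Hprev[j] + gap_open + gap_ext;
      double f_ext = Fcol[j] + gap_ext;
      double f; unsigned char fbit = 0;
      if (f_ext > f_open) { f = f_ext; fbit = 8; } else { f = f_open; }
      Fcol[j] = f;
      double d = Hprev[j - 1] + ((qi == s[j - 1] && qi != 4) ? match : mismatch);
      double h; unsigned char code;
      if (d >= f && d >= e) { h = d; code = 1; }
      else if (f >= e)      { h = f; code = 3; }
      else                  { h = e; code = 2; }
      if (h <= 0) { h = 0; code = 0; }
      Hcur[j] = h;
      tbrow[j] = code | ebit | fbit;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["n_ident"] = 0, _["aln_len"] = 0,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                        _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER);
  }
  int i = bi, j = bj, n_id = 0, len = 0;
  int state = 0; // 0 = H, 1 = F, 2 = E
  while (i > 0 && j > 0) {
    unsigned char b = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      int code = b & 3;
      if (code == 0) break;
      if (code == 1) {
        if (q[i - 1] == s[j - 1] && q[i - 1] != 4) ++n_id;
        ++len; --i; --j;
      } else if (code == 3) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // F: gap in subject, consume query
      ++len;
      state = (b & 8) ? 1 : 0;
      --i;
    } else {                 // E: gap in query, consume subject
      ++len;
      state = (b & 4) ? 2 : 0;
      --j;
    }
  }
  return List::create(_["score"] = best, _["n_ident"] = n_id, _["aln_len"] = len,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj);
}

// Global affine-gap alignment of two alignment profiles (Gotoh).
// A, B: integer matrices, rows = sequences, cols = alignment columns;
// codes 0..3 = ACGT, 4 = N, -1 = gap. Column-pair score is the mean pairwise
// substitution score over residue pairs; pairs involving a gap score 0.
// Traceback byte: bits 0-1 source of M (0=M,1=X,2=Y); bits 2-3 source of X;
// bits 4-5 source of Y. Preference on ties: M, then X, then Y.
// Returns merged column paths: for each merged column, the source column in
// A (or 0 for an inserted gap) and likewise for B.
// [[Rcpp::export]]
List nw_profile_cpp(IntegerMatrix A, IntegerMatrix B,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int n = A.ncol(), m = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();
  const double NEG = -1e18;
  // residue lists per column (gaps dropped) for the score kernel
  std::vector<std::vector<int>> ca(n), cb(m);
  for (int i = 0; i < n; ++i)
    for (int x = 0; x < ra; ++x) if (A(x, i) >= 0) ca[i].push_back(A(x, i));
  for (int j = 0; j < m; ++j)
    for (int y = 0; y < rb; ++y) if (B(y, j) >= 0) cb[j].push_back(B(y, j));
  const double norm = 1.0 / (double)(ra * rb);

  std::vector<double> Mp(m + 1, NEG), Xp(m + 1, NEG), Yp(m + 1, NEG),
                      Mc(m + 1, NEG), Xc(m + 1, NEG), Yc(m + 1, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Yp[j] = gap_open + gap_ext * j;
    tb[j] = (j == 1 ? 0 : 2) << 4; // Y from M at j==1, else extends Y
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + gap_ext * i;
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    tbrow[0] = (i == 1 ? 0 : 1) << 2; // X from M at i==1, else extends X
    for (int j = 1; j <= m; ++j) {
      // M from best of previous diagonal states
      double md = Mp[j - 1]; unsigned char msrc = 0;
      if (Xp[j - 1] > md) { md = Xp[j - 1]; msrc = 1; }
      if (Yp[j - 1] > md) { md = Yp[j - 1]; msrc = 2; }
      double sc = 0.0;
      const std::vector<int> &va = ca[i - 1], &vb = cb[j - 1];
      for (size_t x = 0; x < va.size(); ++x)
        for (size_t y = 0; y < vb.size(); ++y)
          sc += (va[x] == vb[y] && va[x] != 4) ? match : mismatch;
      Mc[j] = md + sc * norm;
      // X: consume an A column, gap in B (vertical)
      double xo = Mp[j] + gap_open + gap_ext; unsigned char xsrc = 0;
      double xy = Yp[j] + gap_open + gap_ext;
      double xx = Xp[j] + gap_ext;
      double xv = xo;
      if (xx > xv) { xv = xx; xsrc = 1; }
      if (xy > xv) { xv = xy; xsrc = 2; }
      Xc[j] = xv;
      // Y: consume a B column, gap in A (horizontal)
      double yo = Mc[j - 1] + gap_open + gap_ext; unsigned char ysrc = 0;
      double yx = Xc[j - 1] + gap_open + gap_ext;
      double yy = Yc[j - 1] + gap_ext;
      double yv = yo;
      if (yx > yv) { yv = yx; ysrc = 1; }
      if (yy > yv) { yv = yy; ysrc = 2; }
      Yc[j] = yv;
      tbrow[j] = msrc | (xsrc << 2) | (ysrc << 4);
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // final state (scores now live in the *p arrays after the last swap)
  int state; // 0=M 1=X 2=Y
  if (Mp[m] >= Xp[m] && Mp[m] >= Yp[m]) state = 0;
  else if (Xp[m] >= Yp[m]) state = 1;
  else state = 2;

  std::vector<int> pa, pb;
  pa.reserve(n + m); pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    unsigned char b = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = b & 3;
      --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = (b >> 2) & 3;
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = (b >> 4) & 3;
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

// Pairwise mismatch / valid-site counts with pairwise deletion over an
// alignment stored as an integer matrix (rows = taxa; -1 = gap, 4 = N).
// N is treated as missing (excluded), matching the generator's alphabet.
// [[Rcpp::export]]
List pair_mismatch_cpp(IntegerMatrix aln) {
  const int r = aln.nrow(), n = aln.ncol();
  IntegerMatrix mm(r, r), valid(r, r);
  for (int a = 0; a < r; ++a) {
    for (int b = a + 1; b < r; ++b) {
      int v = 0, d = 0;
      for (int k = 0; k < n; ++k) {
        int x = aln(a, k), y = aln(b, k);
        if (x < 0 || y < 0 || x == 4 || y == 4) continue;
        ++v;
        if (x != y) ++d;
      }
      mm(a, b) = d; mm(b, a) = d;
      valid(a, b) = v; valid(b, a) = v;
    }
  }
  return List::create(_["mismatch"] = mm, _["valid"] = valid);
}
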