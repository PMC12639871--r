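#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

static const double NEG_INF = -1e18;

// Banded affine-gap fitting alignment: the query (read) is aligned end-to-end,
// reference prefix/suffix are free. Gap of length L costs gap_open + L * gap_ext.
// The band constrains |j - i| <= band (reads are full-length amplicons, so the
// optimal path hugs the main diagonal); band >= max(m, n) gives the exact
// unbanded optimum.
//
// Rolling scores rows plus a packed per-cell traceback byte:
//   bits 0-1: predecessor of M at (i,j)   (0=M, 1=X, 2=Y, at i-1,j-1)
//   bits 2-3: predecessor of X at (i,j)   (0=extend X, 1=M, 2=Y, at i,j-1)
//   bits 4-5: predecessor of Y at (i,j)   (0=extend Y, 1=M, 2=X, at i-1,j)
// Tie order is fixed (extension preferred inside gaps) so results are
// deterministic; indel placement is left-normalised downstream.
// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(std::string read, std::string ref,
                   double match = 2.0, double mismatch = -4.0,
                   double gap_open = 6.0, double gap_ext = 1.0,
                   int band = -1) {
  const int m = (int)read.size(), n = (int)ref.size();
  if (m < 1 || n < 1) stop("empty sequence");
  if (band < 0) band = std::abs(n - m) + 64;
  if (band > std::max(n, m)) band = std::max(n, m);
  const int W = 2 * band + 1;
  const double open_cost = gap_open + gap_ext;

  std::vector<double> Mp(W, NEG_INF), Xp(W, NEG_INF), Yp(W, NEG_INF);
  std::vector<double> Mc(W, NEG_INF), Xc(W, NEG_INF), Yc(W, NEG_INF);
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0);

  for (int k = 0; k < W; ++k) {
    int j = k - band;
    if (j >= 0 && j <= n) Mp[k] = 0.0;  // free ref prefix
  }
  for (int i = 1; i <= m; ++i) {
    const char rb = read[i - 1];
    unsigned char* tbi = &tb[(size_t)i * W];
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Xc.begin(), Xc.end(), NEG_INF);
    std::fill(Yc.begin(), Yc.end(), NEG_INF);
    int klo = band - i; if (klo < 0) klo = 0;            // j >= 0
    int khi = n - i + band; if (khi > W - 1) khi = W - 1; // j <= n
    for (int k = klo; k <= khi; ++k) {
      const int j = i + k - band;
      unsigned char t = 0;
      // M: diagonal from (i-1, j-1) -> same k in previous row
      if (j >= 1) {
        double prev = Mp[k];
        unsigned char pm = 0;
        if (Xp[k] > prev) { prev = Xp[k]; pm = 1; }
        if (Yp[k] > prev) { prev = Yp[k]; pm = 2; }
        if (prev > NEG_INF / 2) {
          Mc[k] = prev + ((rb == ref[j - 1]) ? match : mismatch);
          t |= pm;
        }
      }
      // X: gap in read (consume ref) from (i, j-1) -> k-1, current row
      if (j >= 1 && k >= 1) {
        double ext = Xc[k - 1] - gap_ext;
        double opnM = Mc[k - 1] - open_cost;
        double opnY = Yc[k - 1] - open_cost;
        double v = ext; unsigned char px = 0;
        if (opnM > v) { v = opnM; px = 1; }
        if (opnY > v) { v = opnY; px = 2; }
        if (v > NEG_INF / 2) { Xc[k] = v; t |= (px << 2); }
      }
      // Y: gap in ref (consume read) from (i-1, j) -> k+1, previous row
      if (k + 1 < W) {
        double ext = Yp[k + 1] - gap_ext;
        double opnM = Mp[k + 1] - open_cost;
        double opnX = Xp[k + 1] - open_cost;
        double v = ext; unsigned char py = 0;
        if (opnM > v) { v = opnM; py = 1; }
        if (opnX > v) { v = opnX; py = 2; }
        if (v > NEG_INF / 2) { Yc[k] = v; t |= (py << 4); }
      }
      tbi[k] = t;
    }
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
  }
  // end: read fully consumed at any ref column; trailing ref is free
  double best = NEG_INF;
  int bestK = -1, bestState = 0;  // 0 = M, 2 = Y
  int klo = band - m; if (klo < 0) klo = 0;
  int khi = n - m + band; if (khi > W - 1) khi = W - 1;
  for (int k = khi; k >= klo; --k) {
    if (Mp[k] > best) { best = Mp[k]; bestK = k; bestState = 0; }
    if (Yp[k] > best) { best = Yp[k]; bestK = k; bestState = 2; }
  }
  if (bestK < 0) stop("alignment fell outside the band");

  std::string ops;
  ops.reserve(m + 16);
  int i = m, k = bestK, state = bestState;
  while (i > 0) {
    const unsigned char t = tb[(size_t)i * W + k];
    if (state == 0) {  // M consumed (i-1,j-1)
      const int j = i + k - band;
      ops.push_back((read[i - 1] == ref[j - 1]) ? '=' : 'X');
      state = t & 3;
      --i;
    } else if (state == 1) {  // X consumed ref base
      ops.push_back('D');
      const unsigned char px = (t >> 2) & 3;
      state = (px == 0) ? 1 : (px == 1 ? 0 : 2);
      --k;
    } else {  // Y consumed read base
      ops.push_back('I');
      const unsigned char py = (t >> 4) & 3;
      state = (py == 0) ? 2 : (py == 1 ? 0 : 1);
      --i; ++k;
    }
  }
  const int refStart = i + k - band;
  std::vector<char> opChar;
  std::vector<int> opLen;
  for (int p = (int)ops.size() - 1; p >= 0; --p) {
    char c = ops[p];
    if (!opChar.empty() && opChar.back() == c) opLen.back()++;
    else { opChar.push_back(c); opLen.push_back(1); }
  }
  int refEnd = refStart;
  for (size_t q = 0; q < opChar.size(); ++q)
    if (opChar[q] != 'I') refEnd += opLen[q];
  CharacterVector opsOut(opChar.size());
  for (size_t q = 0; q < opChar.size(); ++q) opsOut[q] = std::string(1, opChar[q]);
  return List::create(_["score"] = best,
                      _["ref_start"] = refStart,
                      _["ref_end"] = refEnd,
                      _["op"] = opsOut,
                      _["len"] = IntegerVector(opLen.begin(), opLen.end()));
}
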