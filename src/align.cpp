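#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh) with traceback.
// gapOpen/gapExt arrive as penalties (<= 0); a gap of length L scores
// gapOpen + L * gapExt, matching pairwiseAlignment(gapOpening = -gapOpen,
// gapExtension = -gapExt). Traceback is deterministic: at equal scores the
// diagonal move is preferred, then the move consuming the earlier query base.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, int match, int mismatch,
              int gapOpen, int gapExt) {
  int n = a.size(), m = b.size();
  // H: best ending at (i,j); E: gap in b (consume a); F: gap in a (consume b)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), INT_MIN / 2),
      F((n + 1) * (m + 1), INT_MIN / 2);
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);  // 0 stop,1 diag,2 up(E),3 left(F)
  int best = 0, bi = 0, bj = 0;
  int ext = -gapExt;                 // positive costs
  int open = -gapOpen + ext;         // cost of the first gap base
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = idx - (m + 1), left = idx - 1, diag = up - 1;
      E[idx] = std::max(H[up] - open, E[up] - ext);
      F[idx] = std::max(H[left] - open, F[left] - ext);
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int d = H[diag] + s;
      int h = 0; unsigned char t = 0;
      if (d > h) { h = d; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tb[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, cols = 0;
  int ai = bi, aj = bj;  // start coords (updated during walk)
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (H[idx] == 0 || tb[idx] == 0) break;
    unsigned char t = tb[idx];
    if (t == 1) {
      ++cols; if (a[i - 1] == b[j - 1]) ++matches;
      ai = i; aj = j; --i; --j;
    } else if (t == 2) {
      // gap segment in b: walk up while the E chain continues
      int k = i;
      while (k > 1 && E[k * (m + 1) + j] == E[(k - 1) * (m + 1) + j] - ext)
        --k;
      cols += i - k + 1;
      ai = k; aj = j;
      i = k - 1;
    } else {
      int k = j;
      while (k > 1 && F[i * (m + 1) + k] == F[i * (m + 1) + (k - 1)] - ext)
        --k;
      cols += j - k + 1;
      ai = i; aj = k;
      j = k - 1;
    }
  }
  return List::create(_["score"] = best, _["aStart"] = ai, _["aEnd"] = bi,
                      _["bStart"] = aj, _["bEnd"] = bj,
                      _["matches"] = matches, _["columns"] = cols);
}

// Brute-force best-hit read placement: minimal Hamming distance over every
// ungapped position, both strands (reverse strand = reverse-complemented
// read). Ties broken by leftmost reference position, then '+' strand. Reads
// with min mismatches > maxMM are unaligned (pos = NA).
// [[Rcpp::export(name = ".map_brute")]]
DataFrame map_brute(CharacterVector reads, std::string ref, int maxMM) {
  int L = ref.size();
  int nr = reads.size();
  IntegerVector pos(nr, NA_INTEGER), mism(nr, NA_INTEGER);
  CharacterVector strand(nr, NA_STRING);
  auto rc = [](const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'C': c = 'G'; break;
        case 'G': c = 'C'; break; case 'T': c = 'A'; break;
        default: c = 'N';
      }
    }
    return r;
  };
  for (int r = 0; r < nr; ++r) {
    std::string fw = as<std::string>(reads[r]);
    int rl = fw.size();
    if (rl == 0 || rl > L) continue;
    std::string rv = rc(fw);
    int bestMM = maxMM + 1, bestPos = -1; char bestStr = '+';
    for (int sidx = 0; sidx < 2; ++sidx) {
      const std::string& q = (sidx == 0) ? fw : rv;
      for (int p = 0; p + rl <= L; ++p) {
        int mm = 0;
        bool abort = false;
        for (int k = 0; k < rl; ++k) {
          if (q[k] != ref[p + k] && ++mm > bestMM) { abort = true; break; }
        }
        if (abort) continue;
        bool better = mm < bestMM ||
          (mm == bestMM && bestPos >= 0 && p < bestPos);
        if (better) {
          bestMM = mm; bestPos = p; bestStr = (sidx == 0) ? '+' : '-';
          if (mm == 0 && sidx == 0) break;  // leftmost exact forward hit
        }
      }
    }
    if (bestPos >= 0 && bestMM <= maxMM) {
      pos[r] = bestPos + 1;
      mism[r] = bestMM;
      strand[r] = (bestStr == '+') ? "+" : "-";
    }
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strand,
                           _["mismatches"] = mism,
                           _["stringsAsFactors"] = false);
}
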