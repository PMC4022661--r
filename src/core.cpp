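#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Banded global-in-read alignment of a read against a reference window,
// anchored at the window start (primer anchor). The read must be consumed
// entirely; the reference suffix beyond the last aligned base is free.
// Affine gap penalty (open + len * ext) so a single indel is never split
// into equal-scoring weaves. Returns op runs (M/I/D), score, and
// reference bases consumed. Band limits |readpos - refpos| <= band.
//
// [[Rcpp::export(name = ".nwBandAlign")]]
List nwBandAlign(std::string read, std::string ref, int band,
                 double match, double mismatch,
                 double gapOpen, double gapExt) {
  const int n = read.size(), m = ref.size();
  if (n == 0) stop("empty read");
  if (m == 0) stop("empty reference window");
  if (band < 1) band = 1;
  const double NEG = -1e18;
  const int W = 2 * band + 1;
  const int NS = 3; // states: 0 = M(diag), 1 = D(ref gap), 2 = I(read gap)
  std::vector<double> dp((size_t)(n + 1) * W * NS, NEG);
  std::vector<unsigned char> bt((size_t)(n + 1) * W * NS, 255);
  auto idx = [&](int i, int j, int s) {
    return ((size_t)i * W + (j - i + band)) * NS + s;
  };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j >= i - band && j <= i + band;
  };
  dp[idx(0, 0, 0)] = 0.0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    dp[idx(0, j, 1)] = gapOpen + j * gapExt;
    bt[idx(0, j, 1)] = j == 1 ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      // M: diagonal from any state
      if (j > 0 && inband(i - 1, j - 1)) {
        double sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
        double best = NEG; unsigned char from = 255;
        for (int s = 0; s < NS; ++s) {
          double v = dp[idx(i - 1, j - 1, s)];
          if (v > best) { best = v; from = s; }
        }
        if (best > NEG / 2) {
          dp[idx(i, j, 0)] = best + sub;
          bt[idx(i, j, 0)] = from;
        }
      }
      // D: consume a reference base
      if (j > 0 && inband(i, j - 1)) {
        double best = NEG; unsigned char from = 255;
        double v;
        v = dp[idx(i, j - 1, 0)] + gapOpen + gapExt;
        if (v > best) { best = v; from = 0; }
        v = dp[idx(i, j - 1, 1)] + gapExt;
        if (v > best) { best = v; from = 1; }
        v = dp[idx(i, j - 1, 2)] + gapOpen + gapExt;
        if (v > best) { best = v; from = 2; }
        if (best > NEG / 2) {
          dp[idx(i, j, 1)] = best;
          bt[idx(i, j, 1)] = from;
        }
      }
      // I: consume a read base
      if (inband(i - 1, j)) {
        double best = NEG; unsigned char from = 255;
        double v;
        v = dp[idx(i - 1, j, 0)] + gapOpen + gapExt;
        if (v > best) { best = v; from = 0; }
        v = dp[idx(i - 1, j, 2)] + gapExt;
        if (v > best) { best = v; from = 2; }
        v = dp[idx(i - 1, j, 1)] + gapOpen + gapExt;
        if (v > best) { best = v; from = 1; }
        if (best > NEG / 2) {
          dp[idx(i, j, 2)] = best;
          bt[idx(i, j, 2)] = from;
        }
      }
    }
  }
  // free reference suffix: best cell in row n over all states
  int jbest = -1, sbest_state = -1; double sbest = NEG;
  int jlo = std::max(0, n - band), jhi = std::min(m, n + band);
  for (int j = jlo; j <= jhi; ++j)
    for (int s = 0; s < NS; ++s)
      if (dp[idx(n, j, s)] > sbest) {
        sbest = dp[idx(n, j, s)]; jbest = j; sbest_state = s;
      }
  if (jbest < 0 || sbest < NEG / 2) stop("no alignment within band");
  // traceback
  std::vector<char> ops; std::vector<int> lens;
  int i = n, j = jbest, st = sbest_state;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back() == op) lens.back()++;
    else { ops.push_back(op); lens.push_back(1); }
  };
  while (i > 0 || j > 0) {
    unsigned char from = bt[idx(i, j, st)];
    if (from == 255) break;
    if (st == 0) { push('M'); --i; --j; }
    else if (st == 1) { push('D'); --j; }
    else { push('I'); --i; }
    st = from;
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(lens.begin(), lens.end());
  CharacterVector opv(ops.size());
  IntegerVector lenv(lens.size());
  for (size_t k = 0; k < ops.size(); ++k) {
    opv[k] = std::string(1, ops[k]);
    lenv[k] = lens[k];
  }
  return List::create(_["op"] = opv, _["len"] = lenv,
                      _["score"] = sbest, _["ref_used"] = jbest);
}

static const int A_ = 0, C_ = 1, G_ = 2, T_ = 3, N_ = 4, D_ = 5;

static inline int baseIdx(char b) {
  switch (b) {
    case 'A': case 'a': return A_;
    case 'C': case 'c': return C_;
    case 'G': case 'g': return G_;
    case 'T': case 't': return T_;
    default: return N_;
  }
}

// Quality/soft-clip-aware pileup over a window [win_start, win_end] (1-based,
// closed, single contig). cigars follow SAM conventions (M/I/D/S only).
// Base counts exclude soft-clipped bases and bases with Phred quality below
// min_qual; deletion spans are counted as the deletion allele per column
// (deletions carry no base quality and are never quality-filtered).
// Insertion and deletion events are keyed to their anchor position.
//
// [[Rcpp::export(name = ".pileupCore")]]
List pileupCore(IntegerVector starts, CharacterVector cigars,
                CharacterVector seqs, CharacterVector quals,
                int min_qual, int win_start, int win_end) {
  const int L = win_end - win_start + 1;
  if (L <= 0) stop("empty window");
  IntegerMatrix counts(6, L);   // rows A,C,G,T,N,D
  NumericMatrix qsum(5, L);     // qual sums for base alleles
  std::map<std::pair<long long, std::string>, std::pair<int, double>> insEv;
  std::map<std::pair<long long, int>, int> delEv; // (start pos, len) -> count
  const int nread = starts.size();
  for (int r = 0; r < nread; ++r) {
    const char *cig = CHAR(STRING_ELT(cigars, r));
    const char *sq = CHAR(STRING_ELT(seqs, r));
    const char *ql = CHAR(STRING_ELT(quals, r));
    long long rpos = starts[r]; // next reference pos (1-based)
    int qpos = 0;               // consumed read bases
    int len = 0;
    for (const char *p = cig; *p; ++p) {
      char ch = *p;
      if (ch >= '0' && ch <= '9') { len = len * 10 + (ch - '0'); continue; }
      if (len == 0) stop("malformed CIGAR");
      if (ch == 'M') {
        for (int k = 0; k < len; ++k) {
          long long pos = rpos + k;
          if (pos >= win_start && pos <= win_end) {
            int q = (int)ql[qpos + k] - 33;
            if (q >= min_qual) {
              int b = baseIdx(sq[qpos + k]);
              counts(b, pos - win_start) += 1;
              qsum(b, pos - win_start) += q;
            }
          }
        }
        rpos += len; qpos += len;
      } else if (ch == 'I') {
        long long anchor = rpos - 1; // left-flanking column
        if (anchor >= win_start && anchor <= win_end) {
          double qs = 0;
          for (int k = 0; k < len; ++k) qs += (int)ql[qpos + k] - 33;
          std::string is(sq + qpos, sq + qpos + len);
          auto key = std::make_pair(anchor, is);
          auto it = insEv.find(key);
          if (it == insEv.end()) insEv[key] = std::make_pair(1, qs);
          else { it->second.first += 1; it->second.second += qs; }
        }
        qpos += len;
      } else if (ch == 'D') {
        for (int k = 0; k < len; ++k) {
          long long pos = rpos + k;
          if (pos >= win_start && pos <= win_end)
            counts(D_, pos - win_start) += 1;
        }
        if (rpos >= win_start && rpos <= win_end) delEv[{rpos, len}] += 1;
        rpos += len;
      } else if (ch == 'S') {
        qpos += len;
      } else {
        stop("unsupported CIGAR op");
      }
      len = 0;
    }
  }
  // flatten events
  int ni = insEv.size(), nd = delEv.size();
  NumericVector ipos(ni); CharacterVector iseq(ni);
  IntegerVector icnt(ni); NumericVector iq(ni);
  int k = 0;
  for (auto &e : insEv) {
    ipos[k] = (double)e.first.first; iseq[k] = e.first.second;
    icnt[k] = e.second.first;
    iq[k] = e.second.first > 0
      ? e.second.second / (e.second.first * e.first.second.size()) : NA_REAL;
    ++k;
  }
  NumericVector dpos(nd); IntegerVector dlen(nd), dcnt(nd);
  k = 0;
  for (auto &e : delEv) {
    dpos[k] = (double)e.first.first; dlen[k] = e.first.second;
    dcnt[k] = e.second; ++k;
  }
  return List::create(
    _["counts"] = counts, _["qsum"] = qsum,
    _["ins"] = DataFrame::create(_["pos"] = ipos, _["seq"] = iseq,
                                 _["count"] = icnt, _["mean_qual"] = iq,
                                 _["stringsAsFactors"] = false),
    _["del"] = DataFrame::create(_["pos"] = dpos, _["len"] = dlen,
                                 _["count"] = dcnt));
}
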