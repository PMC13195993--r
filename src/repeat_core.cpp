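#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global (pattern-global, subject-local) edit distance.
// Returns c(start, end, dist) with 0-based half-open [start, end) giving
// the minimum-edit placement of `pattern` inside `subject`. Ties are broken
// towards the smaller (prefer_right = false) or larger (prefer_right =
// true) end, then start, so 5' and 3' flank placements conservatively
// maximise the enclosed span.
//
// Two passes: a distance-only forward DP (free start, free end over the
// subject) locates the best end column; a short anchored reverse DP over at
// most m + dist columns recovers the matching start.
// [[Rcpp::export]]
IntegerVector cpp_semiglobal_anchor(std::string pattern, std::string subject,
                                    bool prefer_right = false) {
  const int m = pattern.size(), n = subject.size();
  if (m == 0 || n == 0) return IntegerVector::create(NA_INTEGER, NA_INTEGER, NA_INTEGER);

  std::vector<int> col(m + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;  // empty subject prefix
  int best_d = m, best_end = 0;
  const char *p = pattern.data(), *s = subject.data();
  for (int j = 1; j <= n; ++j) {
    const char sj = s[j - 1];
    int diag = col[0];  // value of col[i-1] from the previous column
    col[0] = 0;         // free start anywhere in the subject
    for (int i = 1; i <= m; ++i) {
      int d = diag + (p[i - 1] != sj);
      const int up = col[i - 1] + 1, left = col[i] + 1;
      if (up < d) d = up;
      if (left < d) d = left;
      diag = col[i];
      col[i] = d;
    }
    if (col[m] < best_d || (col[m] == best_d && prefer_right)) {
      best_d = col[m]; best_end = j;
    }
  }
  if (best_end == 0)  // whole pattern deleted beats any placement: degenerate
    return IntegerVector::create(0, 0, best_d);

  // anchored reverse pass: align reversed pattern against the reversed
  // subject prefix ending at best_end; the consumed length gives the start
  const int span = std::min(best_end, m + best_d);
  std::vector<int> rcol(m + 1);
  for (int i = 0; i <= m; ++i) rcol[i] = i;
  int best_len = 0, best_rd = m;
  for (int j = 1; j <= span; ++j) {
    const char sj = s[best_end - j];
    int diag = rcol[0];
    rcol[0] = j;  // global: consuming subject characters costs
    for (int i = 1; i <= m; ++i) {
      int d = diag + (p[m - i] != sj);
      const int up = rcol[i - 1] + 1, left = rcol[i] + 1;
      if (up < d) d = up;
      if (left < d) d = left;
      diag = rcol[i];
      rcol[i] = d;
    }
    // prefer_right = rightmost start = smallest consumed length
    if (rcol[m] < best_rd || (rcol[m] == best_rd && !prefer_right)) {
      best_rd = rcol[m]; best_len = j;
    }
  }
  return IntegerVector::create(best_end - best_len, best_end, best_rd);
}

// Per-base coverage mask: position covered iff inside >=1 exact occurrence
// of the 4-mer motif (any phase).
// [[Rcpp::export]]
LogicalVector cpp_motif_mask(std::string seq, std::string motif) {
  const int L = seq.size(), k = motif.size();
  LogicalVector mask(L, false);
  if (L < k) return mask;
  for (int i = 0; i + k <= L; ++i) {
    bool hit = true;
    for (int j = 0; j < k; ++j) if (seq[i + j] != motif[j]) { hit = false; break; }
    if (hit) for (int j = 0; j < k; ++j) mask[i + j] = true;
  }
  return mask;
}

struct Cand { int start, end, motif, matched; };

// Optimal motif-run segmentation over per-motif coverage masks.
//
// A legal segment [a,b) for motif k must (i) start and end on k-covered
// bases, (ii) contain no internal uncovered gap longer than bridge_bp,
// (iii) have covered fraction >= minratio and (iv) length >= minlen_bp.
// Among all non-overlapping sets of legal segments the DP maximises,
// lexicographically: total classified bp, total covered (matched) bp,
// then fewest segments; residual ties prefer a segment starting at the
// current position over leaving it unclassified, then the longer segment,
// then the higher-priority (lower-index) motif.
//
// masks: list of logical vectors (one per motif, priority order), equal length.
// Returns an integer matrix with columns start, end, motif (1-based index
// into masks), matched — classified segments only, sorted by start.
// [[Rcpp::export]]
IntegerMatrix cpp_segment(List masks, int minlen_bp, double minratio,
                          int bridge_bp) {
  const int K = masks.size();
  int L = 0;
  std::vector<std::vector<int>> cum(K);
  for (int k = 0; k < K; ++k) {
    LogicalVector mk = masks[k];
    if (k == 0) L = mk.size();
    cum[k].assign(L + 1, 0);
    for (int i = 0; i < L; ++i) cum[k][i + 1] = cum[k][i] + (mk[i] ? 1 : 0);
  }
  const double eps = 1e-9;
  std::vector<Cand> cands;
  for (int k = 0; k < K; ++k) {
    LogicalVector mk = masks[k];
    // maximal covered blocks
    std::vector<std::pair<int, int>> blocks;
    int i = 0;
    while (i < L) {
      if (mk[i]) {
        int j = i;
        while (j < L && mk[j]) ++j;
        blocks.push_back(std::make_pair(i, j));
        i = j;
      } else ++i;
    }
    const int B = blocks.size();
    for (int bi = 0; bi < B; ++bi) {
      for (int bj = bi; bj < B; ++bj) {
        if (bj > bi && blocks[bj].first - blocks[bj - 1].second > bridge_bp) break;
        int a = blocks[bi].first, b = blocks[bj].second;
        int len = b - a;
        if (len < minlen_bp) continue;
        int matched = cum[k][b] - cum[k][a];
        if (matched + eps < minratio * len) continue;
        Cand c; c.start = a; c.end = b; c.motif = k; c.matched = matched;
        cands.push_back(c);
      }
    }
  }
  // index candidates by start
  std::vector<std::vector<int>> by_start(L);
  for (size_t ci = 0; ci < cands.size(); ++ci) by_start[cands[ci].start].push_back((int)ci);

  std::vector<long long> f_cls(L + 1, 0), f_match(L + 1, 0);
  std::vector<int> f_nseg(L + 1, 0), choice(L + 1, -1);
  for (int pos = L - 1; pos >= 0; --pos) {
    long long bc = f_cls[pos + 1], bm = f_match[pos + 1];
    int bn = f_nseg[pos + 1], bchoice = -1, bend = -1, bmot = K;
    for (size_t q = 0; q < by_start[pos].size(); ++q) {
      const Cand &c = cands[by_start[pos][q]];
      long long cc = (long long)(c.end - c.start) + f_cls[c.end];
      long long cm = (long long)c.matched + f_match[c.end];
      int cn = 1 + f_nseg[c.end];
      bool take = false;
      if (cc > bc) take = true;
      else if (cc == bc) {
        if (cm > bm) take = true;
        else if (cm == bm) {
          if (cn < bn) take = true;
          else if (cn == bn) {
            if (bchoice == -1) take = true;                   // segment beats gap
            else if (c.end > bend) take = true;               // longer run
            else if (c.end == bend && c.motif < bmot) take = true;  // priority
          }
        }
      }
      if (take) {
        bc = cc; bm = cm; bn = cn;
        bchoice = by_start[pos][q]; bend = c.end; bmot = c.motif;
      }
    }
    f_cls[pos] = bc; f_match[pos] = bm; f_nseg[pos] = bn; choice[pos] = bchoice;
  }
  // reconstruct
  std::vector<Cand> out;
  int pos = 0;
  while (pos < L) {
    if (choice[pos] == -1) { ++pos; continue; }
    out.push_back(cands[choice[pos]]);
    pos = cands[choice[pos]].end;
  }
  IntegerMatrix res(out.size(), 4);
  for (size_t r = 0; r < out.size(); ++r) {
    res(r, 0) = out[r].start; res(r, 1) = out[r].end;
    res(r, 2) = out[r].motif + 1; res(r, 3) = out[r].matched;
  }
  colnames(res) = CharacterVector::create("start", "end", "motif", "matched");
  return res;
}
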