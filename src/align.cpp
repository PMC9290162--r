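#include <Rcpp.h>
#include <cstring>
#include <climits>
using namespace Rcpp;

// Glocal (read-global, reference end-gaps free) affine-gap aligner.
//
// Scoring convention: a gap of length g costs -(gap_open) - (g-1)*(-gap_extend)
// i.e. gap_open is the score of the FIRST gapped base, gap_extend of each
// additional one (both passed as negative numbers).
//
// Observation codes per reference position:
//   0 = not covered, 1 = A, 2 = C, 3 = G, 4 = T, 5 = N/other, 6 = deletion.
//
// Traceback tie-break: diagonal (match/mismatch) preferred over deletion
// (gap in read), preferred over insertion (gap in reference). End column
// tie-break: smallest reference position.

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2;
    case 'G': return 3; case 'T': return 4;
    default:  return 5;
  }
}

// traceback pointer packing: bits 0-1 M-pred (0 start, 1 M, 2 X, 3 Y),
// bit 2 X-pred (0 open-from-M, 1 extend), bit 3 Y-pred (0 open, 1 extend)
struct Aln {
  int score = NEG;
  int start = 0, end = 0;                 // 1-based observed reference span
  std::vector<unsigned char> obs;         // length m+1, index 1..m
  std::vector<int> ins_after;             // ref position each insertion follows
  std::vector<std::string> ins_seq;
};

class Aligner {
public:
  Aligner(const std::string& ref, int match, int mismatch,
          int gap_open, int gap_extend, int band_extra)
    : ref_(ref), m_((int)ref.size()), ma_(match), mi_(mismatch),
      go_(gap_open), ge_(gap_extend), w_(band_extra) {
    refc_.resize(m_ + 1);
    for (int j = 1; j <= m_; ++j) refc_[j] = ref_[j - 1];
    M_.assign(2 * (m_ + 1), NEG); X_.assign(2 * (m_ + 1), NEG);
    Y_.assign(2 * (m_ + 1), NEG);
  }

  Aln align(const std::string& read, bool traceback) {
    const int n = (int)read.size();
    Aln out;
    if (n == 0 || m_ == 0) return out;
    // band half-widths: cover any start offset plus indel wiggle
    int dl, dr;
    if (w_ <= 0) { dl = n; dr = m_; }
    else {
      dl = std::max(0, n - m_) + w_;
      dr = std::max(0, m_ - n) + w_;
    }
    if ((size_t)tb_.size() < (size_t)(n + 1) * (m_ + 1))
      tb_.assign((size_t)(n + 1) * (m_ + 1), 0);
    int *Mp = M_.data(), *Mc = M_.data() + (m_ + 1);
    int *Xp = X_.data(), *Xc = X_.data() + (m_ + 1);
    int *Yp = Y_.data(), *Yc = Y_.data() + (m_ + 1);

    for (int i = 1; i <= n; ++i) {
      const char rc = read[i - 1];
      const int lo = std::max(0, i - dl), hi = std::min(m_, i + dr);
      unsigned char *tbrow = tb_.data() + (size_t)i * (m_ + 1);
      // guard cells one beyond the band so the next row never reads stale
      // values from two rows back (rolling arrays)
      const int flo = std::max(0, lo - 1), fhi = std::min(m_, hi + 1);
      std::fill(Mc + flo, Mc + fhi + 1, NEG);
      std::fill(Xc + flo, Xc + fhi + 1, NEG);
      std::fill(Yc + flo, Yc + fhi + 1, NEG);
      if (lo == 0) {
        // leading insertion column (read overhang before the reference)
        Mc[0] = NEG; Xc[0] = NEG;
        if (i == 1) { Yc[0] = go_; tbrow[0] = 0; }
        else { Yc[0] = (Yp[0] > NEG / 2) ? Yp[0] + ge_ : NEG; tbrow[0] = 8; }
      }
      for (int j = std::max(1, lo); j <= hi; ++j) {
        unsigned char ptr = 0;
        const int s = (rc == refc_[j] && rc != 'N') ? ma_ : mi_;
        // M: diagonal
        int mbest; unsigned char mp;
        if (i == 1) { mbest = s; mp = 0; }                 // free ref prefix
        else {
          int a = Mp[j - 1], b = Xp[j - 1], c = Yp[j - 1];
          if (a >= b && a >= c)      { mbest = a; mp = 1; }
          else if (b >= c)           { mbest = b; mp = 2; }
          else                       { mbest = c; mp = 3; }
          mbest = (mbest > NEG / 2) ? mbest + s : NEG;
        }
        Mc[j] = mbest; ptr |= mp;
        // X: gap in read (deletion), same row
        {
          int a = (Mc[j - 1] > NEG / 2) ? Mc[j - 1] + go_ : NEG;
          int b = (Xc[j - 1] > NEG / 2) ? Xc[j - 1] + ge_ : NEG;
          if (a >= b) { Xc[j] = a; }
          else        { Xc[j] = b; ptr |= 4; }
        }
        // Y: gap in reference (insertion), previous row same column
        if (i == 1) { Yc[j] = go_; }                       // open from free state
        else {
          int a = (Mp[j] > NEG / 2) ? Mp[j] + go_ : NEG;
          int b = (Yp[j] > NEG / 2) ? Yp[j] + ge_ : NEG;
          if (a >= b) { Yc[j] = a; }
          else        { Yc[j] = b; ptr |= 8; }
        }
        tbrow[j] = ptr;
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    // after the loop the last computed row lives in *p arrays
    int best = NEG, bj = -1, bstate = 0;   // state 1 = M, 3 = Y
    const int lo = std::max(0, n - dl), hi = std::min(m_, n + dr);
    for (int j = lo; j <= hi; ++j) {
      if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = 1; }
      if (Yp[j] > best) { best = Yp[j]; bj = j; bstate = 3; }
    }
    out.score = best;
    if (!traceback || bj < 0) return out;

    out.obs.assign(m_ + 1, 0);
    std::vector<std::pair<int, char> > ins;  // reversed order
    int smin = m_ + 1, smax = 0;
    tracebackImpl(read, n, bj, bstate, out, ins, smin, smax);
    if (smax >= smin) { out.start = smin; out.end = smax; }
    // merge reversed insertion steps into strings
    for (size_t k = ins.size(); k-- > 0;) {
      int after = ins[k].first;
      std::string s(1, ins[k].second);
      while (k > 0 && ins[k - 1].first == after) { --k; s.push_back(ins[k].second); }
      out.ins_after.push_back(after);
      out.ins_seq.push_back(s);
    }
    return out;
  }

private:
  void tracebackImpl(const std::string& read, int n, int bj, int bstate,
                     Aln& out, std::vector<std::pair<int, char> >& ins,
                     int& smin, int& smax) {
    int i = n, j = bj, state = bstate;
    while (i >= 1) {
      const unsigned char ptr = tb_[(size_t)i * (m_ + 1) + j];
      if (state == 1) {                      // M consumes read[i], ref[j]
        out.obs[j] = (unsigned char)base_code(read[i - 1]);
        if (j < smin) smin = j;
        if (j > smax) smax = j;
        const int p = ptr & 3;
        if (p == 0) return;                  // start of alignment (free prefix)
        --i; --j; state = p;
      } else if (state == 2) {               // X consumes ref[j] (deletion)
        out.obs[j] = 6;
        if (j < smin) smin = j;
        if (j > smax) smax = j;
        state = (ptr & 4) ? 2 : 1;
        --j;
      } else {                               // Y consumes read[i] (insertion)
        ins.push_back(std::make_pair(j, read[i - 1]));
        if (i == 1) return;                  // opened from the free state
        state = (ptr & 8) ? 3 : 1;
        --i;
      }
    }
  }

  std::string ref_;
  std::vector<char> refc_;
  int m_, ma_, mi_, go_, ge_, w_;
  std::vector<int> M_, X_, Y_;
  std::vector<unsigned char> tb_;
};

// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band_extra, bool traceback) {
  const int nr = reads.size(), m = (int)ref.size();
  Aligner al(ref, match, mismatch, gap_open, gap_extend, band_extra);
  IntegerVector scores(nr), starts(nr), ends(nr);
  RawMatrix obs = traceback ? RawMatrix(m, nr) : RawMatrix(0, 0);
  List insertions(traceback ? nr : 0);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    Aln a = al.align(rd, traceback);
    scores[r] = a.score; starts[r] = a.start; ends[r] = a.end;
    if (traceback) {
      Rbyte* col = &obs(0, r);
      for (int j = 1; j <= m; ++j) col[j - 1] = a.obs[j];
      if (!a.ins_after.empty()) {
        insertions[r] = List::create(
          _["after"] = wrap(a.ins_after), _["seq"] = wrap(a.ins_seq));
      }
    }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
    _["score"] = scores, _["start"] = starts, _["end"] = ends);
  if (traceback) { out["obs"] = obs; out["insertions"] = insertions; }
  return out;
}

// [[Rcpp::export(name = ".cpp_pileup")]]
IntegerMatrix cpp_pileup(RawMatrix obs, LogicalVector keep) {
  const int m = obs.nrow(), nr = obs.ncol();
  IntegerMatrix counts(6, m);  // rows: A, C, G, T, N, del
  for (int r = 0; r < nr; ++r) {
    if (!keep[r]) continue;
    const Rbyte* col = &obs(0, r);
    for (int j = 0; j < m; ++j) {
      const int c = col[j];
      if (c >= 1 && c <= 6) counts(c - 1, j)++;
    }
  }
  return counts;
}
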