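#include <Rcpp.h>
#include <string>
#include <algorithm>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// Number of positions where a[i] == b[i], word-at-a-time (SWAR zero-byte
// count on the XOR of eight-byte blocks). Exact for uppercase-DNA
// alphabets: the borrow-chain false positive of the zero-byte trick needs
// an XOR byte of 0x01, which no pair of A/C/G/T/N characters produces.
static inline int count_eq_bytes(const char *a, const char *b, int n) {
  const uint64_t lo = 0x0101010101010101ULL, hi = 0x8080808080808080ULL;
  int eq = 0, i = 0;
  for (; i + 8 <= n; i += 8) {
    uint64_t wa, wb;
    std::memcpy(&wa, a + i, 8);
    std::memcpy(&wb, b + i, 8);
    uint64_t x = wa ^ wb;
    uint64_t zero = (~x & (x - lo)) & hi;  // high bit set per zero byte
#if defined(__GNUC__) || defined(__clang__)
    eq += __builtin_popcountll(zero);
#else
    while (zero) { eq += zero & 1; zero >>= 7; }
#endif
  }
  for (; i < n; ++i)
    if (a[i] == b[i]) ++eq;
  return eq;
}

// Merge read pairs by exhaustive relative-offset scanning.
//
// For each pair, r2 is reverse-complemented and slid along r1 over every
// offset d (start of rc(r2) relative to start of r1) that yields an
// overlap of at least min_overlap. The offset maximising the number of
// matching bases wins (ties: fewer mismatches, then the smaller insert).
// The pair merges when the winning offset's mismatch fraction is at most
// max_mismatch_frac; otherwise the status is "too_many_mismatches" when
// the winning offset still has at least min_overlap matching bases and
// "no_overlap" when it does not. The consensus spans the inferred insert
// (r1 start through rc(r2) end); at overlap disagreements the
// higher-quality base wins, ties going to r1. Bases of either read lying
// outside the insert (adapter read-through) are clipped.
//
// [[Rcpp::export]]
DataFrame merge_pairs_cpp(CharacterVector r1, CharacterVector r2,
                          CharacterVector q1, CharacterVector q2,
                          int min_overlap, double max_mismatch_frac) {
  int n = r1.size();
  if (r2.size() != n || q1.size() != n || q2.size() != n)
    stop("r1, r2, q1, q2 must have equal length");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  CharacterVector status(n), consensus(n), cqual(n);
  IntegerVector overlap_len(n), n_mismatch(n);
  for (int k = 0; k < n; ++k) {
    std::string s1 = as<std::string>(r1[k]);
    std::string s2 = revcomp_str(as<std::string>(r2[k]));
    std::string u1 = as<std::string>(q1[k]);
    std::string u2 = as<std::string>(q2[k]);
    std::reverse(u2.begin(), u2.end());
    int len1 = s1.size(), len2 = s2.size();
    if ((int)u1.size() != len1 || (int)u2.size() != len2)
      stop("quality string length does not match sequence length");
    // best offset overall (for failure diagnosis) and best offset that
    // also satisfies the mismatch-fraction constraint (for merging)
    int any_match = -1, any_mm = 0, any_ov = 0;
    int ok_d = 0, ok_match = -1, ok_mm = 0, ok_ov = 0;
    for (int d = -(len2 - min_overlap); d <= len1 - min_overlap; ++d) {
      int lo = std::max(0, d), hi = std::min(len1, d + len2);
      int ov = hi - lo;
      if (ov < min_overlap) continue;
      // an offset whose whole overlap is shorter than the best admissible
      // match count so far can neither win outright nor win a tie
      if (ok_match >= 0 && (ov < ok_match || (ov == ok_match && ok_mm == 0)))
        continue;
      int match = count_eq_bytes(s1.data() + lo, s2.data() + (lo - d), ov);
      int mm = ov - match;
      if (match > any_match || (match == any_match && mm < any_mm)) {
        any_match = match; any_mm = mm; any_ov = ov;
      }
      if ((double)mm / ov <= max_mismatch_frac &&
          (match > ok_match || (match == ok_match && mm < ok_mm))) {
        ok_match = match; ok_mm = mm; ok_d = d; ok_ov = ov;
      }
    }
    if (ok_match < 0) {  // no admissible offset
      status[k] = (any_match >= min_overlap) ? "too_many_mismatches"
                                             : "no_overlap";
      consensus[k] = NA_STRING; cqual[k] = NA_STRING;
      overlap_len[k] = std::max(any_ov, 0);
      n_mismatch[k] = std::max(any_mm, 0);
      continue;
    }
    int d = ok_d, best_ov = ok_ov, best_mm = ok_mm;
    int ins_len = d + len2;  // insert spans r1 start .. rc(r2) end
    std::string cons(ins_len, 'N'), qual(ins_len, '!');
    for (int i = 0; i < ins_len; ++i) {
      bool in1 = i < len1;
      bool in2 = i >= d;  // i - d < len2 holds because i < d + len2
      if (in1 && in2) {
        char b1 = s1[i], b2 = s2[i - d];
        char v1 = u1[i], v2 = u2[i - d];
        if (b1 == b2) {
          cons[i] = b1; qual[i] = std::max(v1, v2);
        } else if (v2 > v1) {
          cons[i] = b2; qual[i] = v2;
        } else {
          cons[i] = b1; qual[i] = v1;  // tie goes to r1
        }
      } else if (in1) {
        cons[i] = s1[i]; qual[i] = u1[i];
      } else {
        cons[i] = s2[i - d]; qual[i] = u2[i - d];
      }
    }
    status[k] = "merged";
    consensus[k] = cons; cqual[k] = qual;
    overlap_len[k] = best_ov; n_mismatch[k] = best_mm;
  }
  return DataFrame::create(_["status"] = status,
                           _["consensus"] = consensus,
                           _["qual"] = cqual,
                           _["overlap_len"] = overlap_len,
                           _["n_mismatch"] = n_mismatch,
                           _["stringsAsFactors"] = false);
}

static int hamming_find(const std::string &s, const std::string &pat,
                        int from, int max_mm) {
  int n = s.size(), m = pat.size();
  for (int start = from; start + m <= n; ++start) {
    int mm = 0;
    for (int j = 0; j < m && mm <= max_mm; ++j)
      if (s[start + j] != pat[j]) ++mm;
    if (mm <= max_mm) return start;  // leftmost acceptable match
  }
  return -1;
}

// Primer-anchored barcode extraction: locate primer5 (leftmost match with
// at most max_mm substitutions, no indels), then primer3 (leftmost match
// at or after the end of primer5); the enclosed region is the barcode iff
// it has exactly barcode_len bases.
//
// [[Rcpp::export]]
DataFrame extract_barcodes_cpp(CharacterVector seqs, std::string primer5,
                               std::string primer3, int barcode_len,
                               int max_mm) {
  int n = seqs.size();
  CharacterVector barcode(n), reason(n);
  for (int k = 0; k < n; ++k) {
    if (seqs[k] == NA_STRING) {
      barcode[k] = NA_STRING; reason[k] = "primer5_not_found";
      continue;
    }
    std::string s = as<std::string>(seqs[k]);
    int p5 = hamming_find(s, primer5, 0, max_mm);
    if (p5 < 0) {
      barcode[k] = NA_STRING; reason[k] = "primer5_not_found";
      continue;
    }
    int after5 = p5 + primer5.size();
    int p3 = hamming_find(s, primer3, after5, max_mm);
    if (p3 < 0) {
      barcode[k] = NA_STRING; reason[k] = "primer3_not_found";
      continue;
    }
    if (p3 - after5 != barcode_len) {
      barcode[k] = NA_STRING; reason[k] = "bad_barcode_length";
      continue;
    }
    barcode[k] = s.substr(after5, barcode_len);
    reason[k] = NA_STRING;
  }
  return DataFrame::create(_["barcode"] = barcode, _["reason"] = reason,
                           _["stringsAsFactors"] = false);
}

// Apply substitution errors: for error j, read which[j] (1-based index
// into seqs) gets base at pos[j] (1-based) replaced by the base shift[j]
// (1..3) steps away in the cyclic order A->C->G->T->A. Cyclic shifts with
// a uniform 1..3 draw give a uniform choice among the three wrong bases.
//
// [[Rcpp::export]]
CharacterVector inject_errors_cpp(CharacterVector seqs, IntegerVector which,
                                  IntegerVector pos, IntegerVector shift) {
  static const std::string bases = "ACGT";
  int n = seqs.size(), ne = which.size();
  if (pos.size() != ne || shift.size() != ne)
    stop("which, pos, shift must have equal length");
  std::vector<std::string> out(n);
  for (int i = 0; i < n; ++i) out[i] = as<std::string>(seqs[i]);
  for (int j = 0; j < ne; ++j) {
    int w = which[j] - 1, p = pos[j] - 1;
    if (w < 0 || w >= n || p < 0 || p >= (int)out[w].size())
      stop("error index out of range");
    size_t b = bases.find(out[w][p]);
    if (b == std::string::npos) continue;  // leave non-ACGT bases alone
    out[w][p] = bases[(b + shift[j]) % 4];
  }
  return wrap(out);
}
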