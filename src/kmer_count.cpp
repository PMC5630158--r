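#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Map an RNA base to a 2-bit code; -1 for anything outside ACGU.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default: return -1;
  }
}

// Sparse triplets of global and positional k-mer counts for a set of
// validated RNA sequences.  Occurrences are counted with overlaps; a
// positional occurrence is assigned to every 20nt-style window that fully
// contains it.  Windows are anchored at the start AUG (position 0 = first
// base of the AUG) and grown 5'-ward on a regular grid:
//   window w = [-window_len - w*step, -w*step - ... ) i.e. start
//   a_w = -window_len - w*step, end a_w + window_len,
// kept only while fully inside the sequence (a_w >= -aug_offset).
//
// Column layout (1-based on return): the global block (one column per k-mer,
// ordered by length then lexicographically) if include_global, followed by
// the positional block ordered window-major (w = 0, 1, ...) with the same
// k-mer order inside each window.
// [[Rcpp::export(name = ".kmer_triplets")]]
List kmer_triplets(CharacterVector seqs, IntegerVector aug_offsets, int k_max,
                   int window_len, int step, bool include_global,
                   bool include_positional, int n_windows) {
  const int n = seqs.size();
  if (aug_offsets.size() != n) stop("aug_offsets length mismatch");
  if (k_max < 1 || k_max > 5) stop("k_max must be in 1..5");

  // offsets of each k-mer length block within the k-mer ordering
  std::vector<int> koff(k_max + 1, 0);
  for (int k = 1; k <= k_max; ++k) koff[k] = koff[k - 1] + (k == 1 ? 0 : (1 << (2 * (k - 1))));
  int n_kmers = 0;
  for (int k = 1; k <= k_max; ++k) n_kmers += (1 << (2 * k));

  const int global_off = include_global ? n_kmers : 0;
  std::vector<int> gcount(n_kmers, 0), gtouched;
  std::vector<int> wcount((size_t)n_kmers * (n_windows > 0 ? n_windows : 0), 0), wtouched;
  gtouched.reserve(1024);
  wtouched.reserve(4096);

  std::vector<int> ti, tj, tx;

  for (int s = 0; s < n; ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    int L = LENGTH(STRING_ELT(seqs, s));
    int aug = aug_offsets[s];
    if (aug < 1 || aug > L) stop("aug_offset out of range for sequence %d", s + 1);
    std::vector<int> code(L);
    for (int i = 0; i < L; ++i) {
      code[i] = base_code(str[i]);
      if (code[i] < 0) stop("invalid character in sequence %d", s + 1);
    }
    // largest window index fully inside this sequence
    int w_seq = (aug >= window_len) ? (aug - window_len) / step : -1;
    if (w_seq >= n_windows) w_seq = n_windows - 1;

    gtouched.clear();
    wtouched.clear();
    for (int k = 1; k <= k_max; ++k) {
      if (k > L) break;
      int id = 0, mask = (1 << (2 * k)) - 1;
      for (int i = 0; i < k - 1; ++i) id = (id << 2) | code[i];
      for (int i = k - 1; i < L; ++i) {
        id = ((id << 2) | code[i]) & mask;
        int start = i - k + 1;
        int kid = koff[k] + id;
        if (include_global) {
          if (gcount[kid]++ == 0) gtouched.push_back(kid);
        }
        if (include_positional && w_seq >= 0) {
          int p = start - aug;        // AUG-relative occurrence start
          if (p + k <= 0) {           // fully upstream of the AUG
            // containment: a_w <= p and a_w + window_len >= p + k
            int lo = -p - window_len; // w*step >= lo
            int w_lo = lo <= 0 ? 0 : (lo + step - 1) / step;
            int w_hi = (-(p + k)) / step;
            if (w_hi > w_seq) w_hi = w_seq;
            for (int w = w_lo; w <= w_hi; ++w) {
              size_t cell = (size_t)w * n_kmers + kid;
              if (wcount[cell]++ == 0) wtouched.push_back((int)cell);
            }
          }
        }
      }
    }
    if (include_global) {
      for (int kid : gtouched) {
        ti.push_back(s + 1);
        tj.push_back(kid + 1);
        tx.push_back(gcount[kid]);
        gcount[kid] = 0;
      }
    }
    if (include_positional) {
      for (int cell : wtouched) {
        ti.push_back(s + 1);
        tj.push_back(global_off + cell + 1);
        tx.push_back(wcount[cell]);
        wcount[cell] = 0;
      }
    }
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
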