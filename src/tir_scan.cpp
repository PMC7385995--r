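#include <Rcpp.h>
#include <vector>
#include <cstring>

// De novo scan for TIR-bounded windows.
//
// A window [i, i+L) is a candidate when its first t bases and the
// reverse complement of its last t bases agree at >= (1 - max_mm_frac)
// identity (Hamming, no indels) for some t in [min_tir, max_tir].
// The maximal such t is reported, with the extra requirement that the
// TIR's innermost position itself pairs: trailing mismatches are not
// evidence of a longer repeat, they only ride inside the budget.
// Ambiguous bases never match.
//
// The inner scan aborts as soon as the running mismatch count exceeds
// the largest budget any remaining TIR length could allow, which keeps
// the expected per-window cost at a small constant on random sequence.

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // ambiguity: never matches
    }
}

// [[Rcpp::export]]
Rcpp::DataFrame tir_scan_cpp(std::string seq,
                             int min_len, int max_len,
                             int min_tir, int max_tir,
                             double max_mm_frac) {
    const int n = (int) seq.size();
    std::vector<int> out_start, out_end, out_tir, out_mm;

    std::vector<char> comp(n);
    for (int i = 0; i < n; ++i) comp[i] = comp_base(seq[i]);
    const char *s = seq.data();
    const char *cp = comp.data();

    // mismatch budget per TIR length
    std::vector<int> budget(max_tir + 1, 0);
    for (int t = 1; t <= max_tir; ++t) budget[t] = (int) (max_mm_frac * t);

    for (int i = 0; i + min_len <= n; ++i) {
        const int Lmax = std::min(max_len, n - i);
        for (int L = min_len; L <= Lmax; ++L) {
            const int j = i + L - 1;          // last base of the window
            const int t_cap = std::min(max_tir, L / 2);
            if (t_cap < min_tir) continue;
            const int budget_cap = budget[t_cap];
            int mm = 0, best_t = 0, best_mm = 0;
            for (int u = 0; u < t_cap; ++u) {
                const char a = s[i + u];
                const char b = cp[j - u];
                const int t = u + 1;
                if (a != b || b == 0) {
                    ++mm;
                    if (mm > budget_cap) break;
                } else if (t >= min_tir && mm <= budget[t]) {
                    best_t = t;
                    best_mm = mm;
                }
            }
            if (best_t >= min_tir) {
                out_start.push_back(i + 1);   // 1-based inclusive
                out_end.push_back(i + L);
                out_tir.push_back(best_t);
                out_mm.push_back(best_mm);
            }
        }
    }

    return Rcpp::DataFrame::create(
        Rcpp::Named("start") = out_start,
        Rcpp::Named("end") = out_end,
        Rcpp::Named("tir_len") = out_tir,
        Rcpp::Named("tir_mismatch") = out_mm);
}
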