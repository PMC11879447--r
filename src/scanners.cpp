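#include <Rcpp.h>
using namespace Rcpp;

// 0..3 for A/C/G/T (either case), -1 for anything else.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Maximal mirror repeats: for every center boundary p (between positions
// p-1 and p, 0-based) and every spacer length s in 0..max_spacer, extend the
// arms to the largest k with seq[p-1-i] == seq[p+s+i] for all i < k
// (case-insensitive; extension stops at any non-ACGT character or the
// sequence edge). One repeat per (p, s) with k >= min_arm; spans containing
// a non-ACGT character anywhere (the spacer is not touched by arm
// extension) are discarded.
// [[Rcpp::export(name = ".scan_mirror_cpp")]]
List scan_mirror_cpp(std::string seq, int min_arm, int max_spacer, int max_arm) {
    const int n = (int) seq.size();
    std::vector<int> code(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

    std::vector<int> v_start, v_arm, v_spacer;
    for (int p = 1; p < n; ++p) {
        for (int s = 0; s <= max_spacer; ++s) {
            int k = 0;
            while (k < max_arm) {
                const int li = p - 1 - k, ri = p + s + k;
                if (li < 0 || ri >= n) break;
                const int a = code[li], b = code[ri];
                if (a < 0 || b < 0 || a != b) break;
                ++k;
            }
            if (k < min_arm) continue;
            bool clean = true;
            for (int j = p; j < p + s; ++j) {
                if (j >= n || code[j] < 0) { clean = false; break; }
            }
            if (p + s + k > n) clean = false; // spacer spills past the edge
            if (!clean) continue;
            v_start.push_back(p - k);
            v_arm.push_back(k);
            v_spacer.push_back(s);
        }
    }
    return List::create(_["start"] = wrap(v_start),
                        _["arm_len"] = wrap(v_arm),
                        _["spacer_len"] = wrap(v_spacer));
}

// True if the length-u prefix `unit` of s starting at `at` is primitive
// (has no period d < u with d | u).
static bool unit_primitive(const std::vector<int>& code, int at, int u) {
    for (int d = 1; d < u; ++d) {
        if (u % d != 0) continue;
        bool periodic = true;
        for (int j = d; j < u; ++j) {
            if (code[at + j] != code[at + j - d]) { periodic = false; break; }
        }
        if (periodic) return false;
    }
    return true;
}

// Maximal exact tandem runs with primitive unit length 1..max_unit and at
// least min_copies full copies. A run of L consecutive period-u matches
// starting at i spans [i, i + u + L); copies = (u + L) / u (last copy may
// be partial). Runs whose unit is non-primitive re-appear at the smaller
// period and are skipped here, so each run is reported exactly once.
// [[Rcpp::export(name = ".scan_str_cpp")]]
List scan_str_cpp(std::string seq, int max_unit, int min_copies) {
    const int n = (int) seq.size();
    std::vector<int> code(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

    std::vector<int> v_start, v_end, v_unit;
    std::vector<double> v_copies;
    for (int u = 1; u <= max_unit; ++u) {
        int i = 0;
        while (i + u < n) {
            if (code[i] >= 0 && code[i] == code[i + u]) {
                int j = i;
                while (j + u < n && code[j] >= 0 && code[j] == code[j + u]) ++j;
                const int L = j - i;            // number of matches
                if (L >= (min_copies - 1) * u && unit_primitive(code, i, u)) {
                    v_start.push_back(i);
                    v_end.push_back(i + u + L);
                    v_unit.push_back(u);
                    v_copies.push_back((double)(u + L) / (double)u);
                }
                i = j + 1;
            } else {
                ++i;
            }
        }
    }
    return List::create(_["start"] = wrap(v_start),
                        _["end"] = wrap(v_end),
                        _["unit_len"] = wrap(v_unit),
                        _["copies"] = wrap(v_copies));
}
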