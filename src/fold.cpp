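#include <Rcpp.h>
using namespace Rcpp;

// Minimum-energy non-crossing secondary structure under a per-pair energy
// model (no loop or stacking terms).  Bases are encoded 0=A, 1=C, 2=G, 3=T/U.
// Pairs permitted: G:C, A:U, G:U; hairpin loops must enclose >= minLoop
// unpaired bases.  Tie-break in the traceback: the leftmost unresolved base
// is paired whenever a co-optimal pairing exists, and to the largest
// possible partner.

static inline double pair_energy(int a, int b, double eGC, double eAU,
                                 double eGU) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return eGC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return eAU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGU;
    return 1.0; /* sentinel: not pairable (positive, never optimal) */
}

// [[Rcpp::export]]
List nussinov_fold(IntegerVector s, double eGC, double eAU, double eGU,
                   int minLoop) {
    const int n = s.size();
    const double TOL = 1e-9;
    if (n == 0)
        return List::create(_["energy"] = 0.0,
                            _["pairs"] = IntegerVector(0));

    NumericMatrix E(n, n); /* zero-initialised: empty structure */

    /* E(i,j): minimum energy of subsequence [i, j], 0-based */
    for (int span = minLoop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            double best = E(i + 1, j); /* i unpaired */
            for (int k = i + minLoop + 1; k <= j; ++k) {
                double pe = pair_energy(s[i], s[k], eGC, eAU, eGU);
                if (pe > 0) continue;
                double cand = pe
                    + ((i + 1 <= k - 1) ? E(i + 1, k - 1) : 0.0)
                    + ((k + 1 <= j) ? E(k + 1, j) : 0.0);
                if (cand < best) best = cand;
            }
            E(i, j) = best;
        }
    }

    IntegerVector partner(n, 0); /* 1-based partner, 0 = unpaired */
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i <= minLoop) continue;
        double target = E(i, j);
        bool paired = false;
        for (int k = j; k >= i + minLoop + 1; --k) {
            double pe = pair_energy(s[i], s[k], eGC, eAU, eGU);
            if (pe > 0) continue;
            double cand = pe
                + ((i + 1 <= k - 1) ? E(i + 1, k - 1) : 0.0)
                + ((k + 1 <= j) ? E(k + 1, j) : 0.0);
            if (std::abs(cand - target) < TOL) {
                partner[i] = k + 1;
                partner[k] = i + 1;
                if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
                if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }

    return List::create(_["energy"] = E(0, n - 1), _["pairs"] = partner);
}
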