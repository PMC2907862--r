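#include <Rcpp.h>
using namespace Rcpp;

// Scalar affine-gap Smith-Waterman:
//   H(i,j) = max(0, H(i-1,j-1) + sbt(S1[i], S2[j]), E(i,j), F(i,j))
//   E(i,j) = max(H(i,j-1) - (rho + sigma), E(i,j-1) - sigma)
//   F(i,j) = max(H(i-1,j) - (rho + sigma), F(i-1,j) - sigma)
// with H(i,0) = H(0,j) = E(i,0) = F(0,j) = 0.  Only H is clamped at zero;
// E and F are kept as signed integers, exactly as the recurrence dictates.
// Residue codes are 1-based; sbt has one trailing zero row/column for the
// dummy (padding) code.

// [[Rcpp::export]]
int sw_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sbt,
                 int goe, int ge) {
    const int l1 = q.size(), l2 = s.size();
    std::vector<int> H(l1 + 1, 0), E(l1 + 1, 0);
    int best = 0;
    for (int j = 1; j <= l2; ++j) {
        const int sj = s[j - 1] - 1;
        int hdiag = 0;   // H(i-1, j-1)
        int hup = 0;     // H(i-1, j), current column
        int F = 0;       // F(0, j) = 0 boundary, then F(i, j)
        for (int i = 1; i <= l1; ++i) {
            int e = std::max(H[i] - goe, E[i] - ge);   // E(i, j)
            E[i] = e;
            F = std::max(hup - goe, F - ge);           // F(i, j)
            int h = hdiag + sbt(q[i - 1] - 1, sj);
            h = std::max(h, e);
            h = std::max(h, F);
            h = std::max(h, 0);
            hdiag = H[i];
            H[i] = h;
            hup = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// Full H/E/F tables, (l1+1) x (l2+1), boundary row/column zero.
// [[Rcpp::export]]
List sw_full_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sbt,
                 int goe, int ge) {
    const int l1 = q.size(), l2 = s.size();
    IntegerMatrix H(l1 + 1, l2 + 1), E(l1 + 1, l2 + 1), F(l1 + 1, l2 + 1);
    int best = 0;
    for (int j = 1; j <= l2; ++j) {
        const int sj = s[j - 1] - 1;
        for (int i = 1; i <= l1; ++i) {
            int e = std::max(H(i, j - 1) - goe, E(i, j - 1) - ge);
            int f = std::max(H(i - 1, j) - goe, F(i - 1, j) - ge);
            int h = H(i - 1, j - 1) + sbt(q[i - 1] - 1, sj);
            h = std::max(h, e);
            h = std::max(h, f);
            h = std::max(h, 0);
            E(i, j) = e;
            F(i, j) = f;
            H(i, j) = h;
            if (h > best) best = h;
        }
    }
    return List::create(_["H"] = H, _["E"] = E, _["F"] = F,
                        _["best"] = best);
}

// Batch scoring of one encoded query against a list of encoded subjects.
// [[Rcpp::export]]
IntegerVector sw_score_batch_cpp(IntegerVector q, List subjects,
                                 IntegerMatrix sbt, int goe, int ge) {
    const int n = subjects.size();
    IntegerVector out(n);
    for (int k = 0; k < n; ++k) {
        IntegerVector s = subjects[k];
        out[k] = sw_score_cpp(q, s, sbt, goe, ge);
    }
    return out;
}
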