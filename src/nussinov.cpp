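#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum number of nested base pairs in a nucleic acid sequence:
// Watson-Crick (A-T/U, G-C) plus G.U wobble pairing, with a minimum
// hairpin loop of `min_loop` unpaired bases between the two partners.
// O(n^3) dynamic program over the standard recursion
//   M(i,j) = max( M(i+1,j),
//                 max_{k: pair(i,k), k >= i+min_loop+1} 1 + M(i+1,k-1) + M(k+1,j) )

static inline bool can_pair(char a, char b) {
    return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(name = ".nussinov_pairs")]]
int nussinov_pairs(std::string seq, int min_loop = 3) {
    // uppercase, RNA -> DNA alphabet; anything else never pairs
    for (char &c : seq) {
        c = (char) toupper((unsigned char) c);
        if (c == 'U') c = 'T';
    }
    const int n = (int) seq.size();
    if (n < min_loop + 2) return 0;
    std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i + 1][j];           // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                int inner = M[i + 1][k - 1];
                int right = (k + 1 <= j) ? M[k + 1][j] : 0;
                int cand = 1 + inner + right;
                if (cand > best) best = cand;
            }
            M[i][j] = best;
        }
    }
    return M[0][n - 1];
}
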