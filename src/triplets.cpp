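#include <Rcpp.h>
using namespace Rcpp;

// Count 16-cell lagged joint configurations (future target, present target,
// source1, source2) for many triplets over one recorded series.  Cell index
// = bf + 2*bsi + 4*bs1 + 8*bs2 with b = (s+1)/2, matching the R-side
// estimator's ordering.
// [[Rcpp::export]]
IntegerMatrix count_triplets_cpp(IntegerMatrix samples, IntegerMatrix triplets,
                                 int lag) {
    int T = samples.nrow();
    int K = triplets.nrow();
    IntegerMatrix counts(16, K);
    for (int k = 0; k < K; ++k) {
        int ti = triplets(k, 0) - 1;
        int s1 = triplets(k, 1) - 1;
        int s2 = triplets(k, 2) - 1;
        for (int t = 0; t + lag < T; ++t) {
            int bf = (samples(t + lag, ti) + 1) >> 1;
            int bi = (samples(t, ti) + 1) >> 1;
            int b1 = (samples(t, s1) + 1) >> 1;
            int b2 = (samples(t, s2) + 1) >> 1;
            ++counts(bf + 2 * bi + 4 * b1 + 8 * b2, k);
        }
    }
    return counts;
}

// Pairwise 8-cell lagged joint counts for many (target, source) pairs.
// Cell index = bf + 2*bsi + 4*bsrc.
// [[Rcpp::export]]
IntegerMatrix count_pairs_cpp(IntegerMatrix samples, IntegerMatrix pairs,
                              int lag) {
    int T = samples.nrow();
    int K = pairs.nrow();
    IntegerMatrix counts(8, K);
    for (int k = 0; k < K; ++k) {
        int ti = pairs(k, 0) - 1;
        int sr = pairs(k, 1) - 1;
        for (int t = 0; t + lag < T; ++t) {
            int bf = (samples(t + lag, ti) + 1) >> 1;
            int bi = (samples(t, ti) + 1) >> 1;
            int bs = (samples(t, sr) + 1) >> 1;
            ++counts(bf + 2 * bi + 4 * bs, k);
        }
    }
    return counts;
}
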