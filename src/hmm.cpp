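#include <Rcpp.h>
using namespace Rcpp;

// log(exp(a) + exp(b)) guarding -Inf
static inline double lse2(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Log-likelihood ratio of a two-state site/background HMM against the
// background-only model. The generative model emits, at each decision point,
// a background base with probability 1-q, or enters a motif site with
// probability q/2 per strand; a site emits W bases from the PWM columns
// (reverse-complemented columns on the minus strand). Sites may not overlap.
//
// codes: 1..4 = A,C,G,T; 0 = N (emitted with probability 1 by every state).
// logfreq: 4 x W matrix of log column frequencies (rows A,C,G,T).
// logbg: length-4 log background frequencies.
// [[Rcpp::export]]
double hmm_llr_cpp(IntegerVector codes, NumericMatrix logfreq,
                   NumericVector logbg, double q) {
    const int L = codes.size();
    const int W = logfreq.ncol();
    if (L < W) stop("sequence shorter than motif width");
    if (q < 0 || q >= 1) stop("q must be in [0, 1)");

    std::vector<double> lbg(L + 1), mf(L + 1, R_NegInf), mr(L + 1, R_NegInf);
    double lbg_total = 0.0;
    for (int j = 1; j <= L; ++j) {
        int c = codes[j - 1];
        lbg[j] = (c == 0) ? 0.0 : logbg[c - 1];
        lbg_total += lbg[j];
    }
    for (int j = W; j <= L; ++j) {
        double sf = 0.0, sr = 0.0;
        for (int w = 1; w <= W; ++w) {
            int c = codes[j - W + w - 1];
            if (c == 0) continue;  // N: probability 1 under both strands
            sf += logfreq(c - 1, w - 1);
            sr += logfreq(4 - c, W - w);  // complement base, reversed column
        }
        mf[j] = sf;
        mr[j] = sr;
    }

    const double l1q = std::log1p(-q);
    const double lq2 = (q > 0) ? std::log(q / 2.0) : R_NegInf;
    std::vector<double> f(L + 1, R_NegInf);
    f[0] = 0.0;
    for (int j = 1; j <= L; ++j) {
        double v = f[j - 1] + l1q + lbg[j];
        if (j >= W && lq2 != R_NegInf) {
            v = lse2(v, f[j - W] + lq2 + mf[j]);
            v = lse2(v, f[j - W] + lq2 + mr[j]);
        }
        f[j] = v;
    }
    return f[L] - lbg_total;
}
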