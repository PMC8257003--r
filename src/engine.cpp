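#include <Rcpp.h>
using namespace Rcpp;

// Language value: mode of Beta(a, b) with a, b >= 1; the degenerate
// uniform case a = b = 1 reports the symmetric limit 0.5.
static inline double lang_value(double a, double b) {
    double den = a + b - 2.0;
    if (den <= 0.0) return 0.5;
    return (a - 1.0) / den;
}

// Broadcast interaction loop. Adjacency in CSR form (ptr 0-based offsets
// into idx; idx holds 0-based neighbor ids). All randomness goes through
// R's RNG so runs are reproducible with set.seed(). strategy: 0 = SAM
// (sample h from the posterior), 1 = MAP (posterior mode). In asynchronous
// mode listeners update immediately after each speaker; in synchronous
// mode heard counts are accumulated and applied once per iteration.
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(IntegerVector adj_ptr, IntegerVector adj_idx,
                NumericVector alpha_in, NumericVector beta_in,
                LogicalVector fixed, NumericVector fixed_value,
                LogicalVector biased, int strategy, int n_iter,
                bool synchronous) {
    const int n = alpha_in.size();
    NumericVector alpha = clone(alpha_in);
    NumericVector beta = clone(beta_in);

    NumericMatrix series(n_iter + 1, 3);  // all, biased, unbiased
    int n_biased = 0;
    for (int i = 0; i < n; ++i) if (biased[i]) ++n_biased;
    const int n_unbiased = n - n_biased;

    std::vector<int> perm(n);
    std::vector<double> add_k, add_n;
    if (synchronous) { add_k.assign(n, 0.0); add_n.assign(n, 0.0); }

    RNGScope scope;

    auto record = [&](int row) {
        double s_all = 0.0, s_b = 0.0;
        for (int i = 0; i < n; ++i) {
            double lv = fixed[i] ? fixed_value[i] : lang_value(alpha[i], beta[i]);
            s_all += lv;
            if (biased[i]) s_b += lv;
        }
        series(row, 0) = s_all / n;
        series(row, 1) = n_biased ? s_b / n_biased : NA_REAL;
        series(row, 2) = n_unbiased ? (s_all - s_b) / n_unbiased : NA_REAL;
    };

    record(0);

    for (int it = 1; it <= n_iter; ++it) {
        // fresh uniform permutation of speakers (Fisher-Yates)
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(perm[i], perm[j]);
        }
        if (synchronous) {
            std::fill(add_k.begin(), add_k.end(), 0.0);
            std::fill(add_n.begin(), add_n.end(), 0.0);
        }
        for (int s_i = 0; s_i < n; ++s_i) {
            const int s = perm[s_i];
            double h;
            if (fixed[s]) h = fixed_value[s];
            else if (strategy == 0) h = R::rbeta(alpha[s], beta[s]);
            else h = lang_value(alpha[s], beta[s]);
            const double u = (unif_rand() < h) ? 1.0 : 0.0;
            for (int e = adj_ptr[s]; e < adj_ptr[s + 1]; ++e) {
                const int t = adj_idx[e];
                if (fixed[t]) continue;
                if (synchronous) { add_k[t] += u; add_n[t] += 1.0; }
                else { alpha[t] += u; beta[t] += 1.0 - u; }
            }
        }
        if (synchronous) {
            for (int i = 0; i < n; ++i) {
                if (fixed[i]) continue;
                alpha[i] += add_k[i];
                beta[i] += add_n[i] - add_k[i];
            }
        }
        record(it);
    }

    colnames(series) = CharacterVector::create("all", "biased", "unbiased");
    return List::create(_["series"] = series,
                        _["alpha"] = alpha,
                        _["beta"] = beta);
}
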