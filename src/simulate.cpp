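#include <Rcpp.h>
using namespace Rcpp;

// Count-level simulators for the branching model with immigration.
//
// Population level: A_{t+1} = sum_i Y_{t,i} + h_t with offspring drawn
// either as Binomial(kappa * A_t, m/kappa) (matching the network's
// per-connection Bernoulli trials) or Poisson(m * A_t), and h_t ~ Poisson(h).
//
// Network level (annealed disorder, N neurons): per bin, recurrent
// activation attempts succeed Binomial(kappa * A_t, m/kappa) times and the
// targets are distinct neurons drawn uniformly without replacement;
// external input activates each neuron independently with probability
// 1 - exp(-h/N).  Because connectivity is redrawn every step, neuron
// identities are exchangeable: conditional on the number of recurrent
// successes S and externally activated neurons X, the active-set size is
// U = S + X - overlap with overlap ~ Hypergeometric, and the count among
// the n fixed sampled units is Hypergeometric(U, N - U, n).  This is an
// exact count-level reformulation of the per-neuron protocol.
//
// All randomness uses R's RNG (seed via set.seed() before the call).

// [[Rcpp::export(name = ".sim_population_cpp")]]
IntegerVector sim_population_cpp(int L, double m, double h, double kappa,
                                 int A0, double cap, bool poisson_offspring,
                                 bool return_input) {
    IntegerVector A(L);
    IntegerVector h_real(return_input ? L : 0);
    double p = (kappa > 0.0) ? m / kappa : 0.0;
    double At = A0;
    for (int t = 0; t < L; ++t) {
        double off = 0.0;
        if (At > 0.0 && m > 0.0) {
            if (poisson_offspring)
                off = R::rpois(m * At);
            else
                off = R::rbinom(kappa * At, p);
        }
        double ht = (h > 0.0) ? R::rpois(h) : 0.0;
        At = off + ht;
        if (At > cap)
            stop("activity exceeded cap %.0f at bin %d (explosion guard)",
                 cap, t + 1);
        A[t] = (int) At;
        if (return_input) h_real[t] = (int) ht;
    }
    if (return_input) A.attr("input") = h_real;
    return A;
}

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(int L, double m, double h, int N, int n, double kappa,
                     int A0) {
    IntegerVector A(L), a(L);
    double p = (kappa > 0.0) ? m / kappa : 0.0;
    double p_ext = (h > 0.0) ? -std::expm1(-h / (double) N) : 0.0;
    int At = A0;
    bool saturated = false;
    for (int t = 0; t < L; ++t) {
        int S = 0;
        if (At > 0 && p > 0.0)
            S = (int) R::rbinom(kappa * (double) At, p);
        if (S > N) { S = N; saturated = true; }
        int X = (p_ext > 0.0) ? (int) R::rbinom((double) N, p_ext) : 0;
        int ov = (S > 0 && X > 0) ? (int) R::rhyper(S, N - S, X) : 0;
        int U = S + X - ov;
        A[t] = U;
        a[t] = (U > 0 && U < N) ? (int) R::rhyper(U, N - U, n)
                                : (U == N ? n : 0);
        At = U;
    }
    return List::create(_["A"] = A, _["a"] = a, _["saturated"] = saturated);
}

// Assign sampled-unit identities to per-bin sampled counts a_t.  By
// exchangeability the a_t active sampled units form a uniform subset of
// the n sampled units, independently across bins.  Returns 1-based unit
// ids and 0-based bin indices, one row per spike.
// [[Rcpp::export(name = ".assign_units_cpp")]]
List assign_units_cpp(IntegerVector a, int n) {
    int L = a.size();
    long total = 0;
    for (int t = 0; t < L; ++t) total += a[t];
    IntegerVector unit(total), bin(total);
    std::vector<int> pool(n);
    long idx = 0;
    for (int t = 0; t < L; ++t) {
        int k = a[t];
        if (k == 0) continue;
        for (int i = 0; i < n; ++i) pool[i] = i + 1;
        // partial Fisher-Yates: first k entries are a uniform k-subset
        for (int i = 0; i < k; ++i) {
            int j = i + (int) (R::unif_rand() * (n - i));
            if (j >= n) j = n - 1;
            std::swap(pool[i], pool[j]);
            unit[idx] = pool[i];
            bin[idx] = t;
            ++idx;
        }
    }
    return List::create(_["unit"] = unit, _["bin"] = bin);
}

// Lagged cross-products sum_t x_t * x_{t+k} for k = 1..kmax (used by the
// multistep-regression slopes; per-lag means come from cumulative sums).
// [[Rcpp::export(name = ".cross_sums_cpp")]]
NumericVector cross_sums_cpp(NumericVector x, int kmax) {
    int L = x.size();
    NumericVector out(kmax);
    for (int k = 1; k <= kmax; ++k) {
        double s = 0.0;
        for (int t = 0; t + k < L; ++t) s += x[t] * x[t + k];
        out[k - 1] = s;
    }
    return out;
}

// Descendant cascade of a single extra spike: Galton-Watson chain with
// offspring Binomial(kappa * Delta_t, m/kappa), all trials stepped in
// lockstep.  Returns per-trial total size, duration, censoring flag, and
// the across-trial sum of Delta_t per generation (for the trial-averaged
// rate excursion).
// [[Rcpp::export(name = ".cascade_cpp")]]
List cascade_cpp(int trials, double m, double kappa, double max_spikes,
                 int t_keep) {
    double p = (kappa > 0.0) ? m / kappa : 0.0;
    NumericVector size(trials), dur(trials);
    LogicalVector censored(trials);
    NumericVector delta_sum(t_keep); // generation g (1-based) at index g-1
    std::vector<double> d(trials, 1.0), s(trials, 1.0);
    int alive = trials, gen = 1;
    if (t_keep >= 1) delta_sum[0] = trials;
    while (alive > 0) {
        ++gen;
        alive = 0;
        for (int i = 0; i < trials; ++i) {
            if (d[i] <= 0.0 || censored[i]) continue;
            double nxt = (m > 0.0) ? R::rbinom(kappa * d[i], p) : 0.0;
            d[i] = nxt;
            if (nxt > 0.0) {
                s[i] += nxt;
                dur[i] = gen;
                if (gen <= t_keep) delta_sum[gen - 1] += nxt;
                if (s[i] >= max_spikes) { censored[i] = true; continue; }
                ++alive;
            }
        }
    }
    for (int i = 0; i < trials; ++i) {
        size[i] = s[i];
        if (dur[i] == 0.0) dur[i] = 1.0;
    }
    return List::create(_["size"] = size, _["duration"] = dur,
                        _["censored"] = censored,
                        _["delta_sum"] = delta_sum);
}
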