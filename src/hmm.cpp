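#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihood for one observation series.
// logdens: T x S matrix of per-observation log emission densities
// (rows with all-NA are not allowed; missing components must already be
// marginalised out upstream). gamma: S x S row-stochastic transition
// matrix, delta: initial distribution. Scaling is applied at every step
// so the recursion is stable for long series.
// [[Rcpp::export(name = ".forward_loglik_cpp")]]
double forward_loglik_cpp(NumericMatrix logdens, NumericMatrix gamma,
                          NumericVector delta) {
  int T = logdens.nrow(), S = logdens.ncol();
  std::vector<double> alpha(S), anew(S);
  double ll = 0.0;

  // first step: rescale emissions by their row max before exponentiating
  double m = logdens(0, 0);
  for (int s = 1; s < S; ++s) m = std::max(m, logdens(0, s));
  double tot = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = delta[s] * std::exp(logdens(0, s) - m);
    tot += alpha[s];
  }
  if (tot <= 0.0 || !R_finite(tot)) return R_NegInf;
  for (int s = 0; s < S; ++s) alpha[s] /= tot;
  ll += m + std::log(tot);

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logdens(t, s));
    tot = 0.0;
    for (int j = 0; j < S; ++j) {
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += alpha[i] * gamma(i, j);
      anew[j] = acc * std::exp(logdens(t, j) - m);
      tot += anew[j];
    }
    if (tot <= 0.0 || !R_finite(tot)) return R_NegInf;
    for (int s = 0; s < S; ++s) alpha[s] = anew[s] / tot;
    ll += m + std::log(tot);
  }
  return ll;
}

// Viterbi decoding in log space. Ties are broken toward the lowest
// state index for reproducibility. Returns 1-based state indices.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericMatrix gamma,
                          NumericVector delta) {
  int T = logdens.nrow(), S = logdens.ncol();
  NumericMatrix v(T, S);
  IntegerMatrix bp(T, S);
  for (int s = 0; s < S; ++s)
    v(0, s) = std::log(delta[s]) + logdens(0, s);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double cand = v(t - 1, i) + std::log(gamma(i, j));
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logdens(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = v(T - 1, 0);
  int arg = 0;
  for (int s = 1; s < S; ++s)
    if (v(T - 1, s) > best) { best = v(T - 1, s); arg = s; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = bp(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}

// Fast fitting-path likelihood: emission densities (gamma step lengths,
// von Mises turning angles with precomputed cos/sin) evaluated inline.
// starts/lengths delimit independent series within the concatenated
// observation vectors. zero_mass < 0 disables zero inflation.
// [[Rcpp::export(name = ".hmm_negll_cpp")]]
double hmm_negll_cpp(NumericVector steps, NumericVector log_steps,
                     NumericVector cos_turn, NumericVector sin_turn,
                     LogicalVector turn_na,
                     IntegerVector starts, IntegerVector lengths,
                     NumericVector shape, NumericVector rate,
                     NumericVector mu, NumericVector kappa,
                     NumericVector zero_mass,
                     NumericMatrix gamma, NumericVector delta) {
  const int S = shape.size();
  std::vector<double> log_i0(S), cmu(S), smu(S), lgam(S), slr(S), lzm(S),
      l1mz(S);
  for (int s = 0; s < S; ++s) {
    log_i0[s] = std::log(R::bessel_i(kappa[s], 0.0, 2.0)) + kappa[s];
    cmu[s] = std::cos(mu[s]);
    smu[s] = std::sin(mu[s]);
    lgam[s] = R::lgammafn(shape[s]);
    slr[s] = shape[s] * std::log(rate[s]);
    lzm[s] = zero_mass[s] > 0 ? std::log(zero_mass[s]) : R_NegInf;
    l1mz[s] = zero_mass[s] > 0 ? std::log1p(-zero_mass[s]) : 0.0;
  }
  const double l2pi = std::log(2.0 * M_PI);
  double total = 0.0;
  std::vector<double> alpha(S), anew(S), ld(S);
  for (int g = 0; g < starts.size(); ++g) {
    int t0 = starts[g], T = lengths[g];
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      int i = t0 + t;
      double m = R_NegInf;
      for (int s = 0; s < S; ++s) {
        double d;
        if (steps[i] == 0.0 && zero_mass[s] > 0) {
          d = lzm[s];
        } else {
          d = l1mz[s] + slr[s] - lgam[s] +
              (shape[s] - 1.0) * log_steps[i] - rate[s] * steps[i];
        }
        if (!turn_na[i]) {
          d += kappa[s] * (cos_turn[i] * cmu[s] + sin_turn[i] * smu[s]) -
               l2pi - log_i0[s];
        }
        ld[s] = d;
        if (d > m) m = d;
      }
      double tot = 0.0;
      if (t == 0) {
        for (int s = 0; s < S; ++s) {
          alpha[s] = delta[s] * std::exp(ld[s] - m);
          tot += alpha[s];
        }
      } else {
        for (int j = 0; j < S; ++j) {
          double acc = 0.0;
          for (int s = 0; s < S; ++s) acc += alpha[s] * gamma(s, j);
          anew[j] = acc * std::exp(ld[j] - m);
          tot += anew[j];
        }
        for (int s = 0; s < S; ++s) alpha[s] = anew[s];
      }
      if (tot <= 0.0 || !R_finite(tot)) return 1e10;
      for (int s = 0; s < S; ++s) alpha[s] /= tot;
      ll += m + std::log(tot);
    }
    total += ll;
  }
  if (!R_finite(total)) return 1e10;
  return -total;
}
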