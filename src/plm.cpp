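#include <Rcpp.h>
using namespace Rcpp;

// Weighted, L2-regularised negative log-pseudolikelihood for one site of a
// Potts model, with gradient.  Xt holds the partner-column states
// TRANSPOSED (K x M, 1-based) so one sequence's states are contiguous;
// y the states at the focal site.  Parameters are packed as
// theta = c(h[1..q], J[s, t, j]) with J stored column-major over (s, t, j):
// index q + s + q*(t-1) + q*q*(j-1), so z_ms = h_s + sum_j J(s, X_mj, j).
// [[Rcpp::export]]
List plm_site(NumericVector theta, IntegerMatrix Xt, IntegerVector y,
              NumericVector w, int q, double lh, double lj, bool want_grad) {
  const int K = Xt.nrow(), M = Xt.ncol();
  const int qq = q * q;
  const double* th = theta.begin();
  const int* X = Xt.begin();
  std::vector<double> z(q), p(q);
  double nll = 0.0;
  NumericVector grad;
  double* gr = nullptr;
  if (want_grad) { grad = NumericVector(theta.size()); gr = grad.begin(); }

  for (int m = 0; m < M; ++m) {
    const int* xm = X + (size_t)m * K;
    for (int s = 0; s < q; ++s) z[s] = th[s];
    for (int j = 0; j < K; ++j) {
      const double* Jt = th + q + qq * j + q * (xm[j] - 1);
      for (int s = 0; s < q; ++s) z[s] += Jt[s];
    }
    double zmax = z[0];
    for (int s = 1; s < q; ++s) if (z[s] > zmax) zmax = z[s];
    double Z = 0.0;
    for (int s = 0; s < q; ++s) { p[s] = std::exp(z[s] - zmax); Z += p[s]; }
    const int ym = y[m] - 1;
    const double wm = w[m];
    nll += wm * (std::log(Z) + zmax - z[ym]);
    if (want_grad) {
      const double winv = wm / Z;
      for (int s = 0; s < q; ++s) p[s] *= winv;
      p[ym] -= wm;
      for (int s = 0; s < q; ++s) gr[s] += p[s];
      for (int j = 0; j < K; ++j) {
        double* Gt = gr + q + qq * j + q * (xm[j] - 1);
        for (int s = 0; s < q; ++s) Gt[s] += p[s];
      }
    }
  }

  // L2 regularisation: lh on fields, lj on couplings
  const int npar = theta.size();
  double reg = 0.0;
  for (int s = 0; s < q; ++s) reg += lh * th[s] * th[s];
  for (int i = q; i < npar; ++i) reg += lj * th[i] * th[i];
  nll += reg;
  if (want_grad) {
    for (int s = 0; s < q; ++s) gr[s] += 2.0 * lh * th[s];
    for (int i = q; i < npar; ++i) gr[i] += 2.0 * lj * th[i];
    return List::create(_["value"] = nll, _["grad"] = grad);
  }
  return List::create(_["value"] = nll);
}

// One Gibbs sweep over all sites for `nc` parallel chains.  state is the
// nc x L matrix of current states (1-based), fields is L x q, and
// couplings are supplied in sparse per-site form:
// partners[[i]] = integer vector of coupled sites (1-based),
// jmats[[i]] = list of q x q matrices J_{i,partner} (rows = state at i).
// gumbel_all is an nc x (q * L) matrix of fresh Gumbel noise (one block
// per site), passed from R so all randomness flows through R's RNG.
// [[Rcpp::export]]
IntegerMatrix gibbs_sweep(IntegerMatrix state, NumericMatrix fields,
                          List partners, List jmats, NumericMatrix gumbel_all) {
  const int nc = state.nrow(), L = state.ncol(), q = fields.ncol();
  for (int i = 0; i < L; ++i) {
    IntegerVector prt = partners[i];
    List jm = jmats[i];
    const int np = prt.size();
    std::vector<NumericMatrix> J;
    J.reserve(np);
    for (int k = 0; k < np; ++k) J.push_back(as<NumericMatrix>(jm[k]));
    for (int c = 0; c < nc; ++c) {
      double best = -1e300; int arg = 0;
      for (int s = 0; s < q; ++s) {
        double z = fields(i, s);
        for (int k = 0; k < np; ++k)
          z += J[k](s, state(c, prt[k] - 1) - 1);
        z += gumbel_all(c, q * i + s);
        if (z > best) { best = z; arg = s; }
      }
      state(c, i) = arg + 1;
    }
  }
  return state;
}
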