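// Compiled core: SelON site rate matrices, stationary distributions,
// eigendecomposition-cached matrix exponentials, Felsenstein pruning with
// per-node rescaling and Gamma-category mixtures, and the generation-ordered
// Brent branch-length sweeps.
//
// Model layout shared by the pruning entry points ("engine" arrays):
//   Q            distinct 4x4 rate matrices (cube), decomposed once
//   comp_*       flattened mixture components: Q index, rate multiplier,
//                weight, root/equilibrium frequencies (4 x M)
//   prof_ptr     profile p owns components [prof_ptr[p], prof_ptr[p+1])  (0-based)
//   site_prof    profile index per alignment column (0-based)
// SelON: one component per site (rate = 1/C).  GTR+Gamma: one profile with
// ncat components shared by all sites of a partition.

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double LOG_FLOOR = -700.0;    // guard for zero site likelihoods
static const double RESCALE_AT = 1e-120;   // partial-likelihood rescale trigger

// ---------------------------------------------------------------------------
// SelON per-site rate matrices: q_ij = 2 b mu_ij Ne u_ij with u_ij the
// Wright-Fisher fixation probability of mutant j in a resident-i population.
// a = log fitness ratio W(res)/W(mut) at the focal site.
// [[Rcpp::export]]
arma::cube cpp_build_selon_q(const arma::mat& M, const arma::vec& f,
                             const arma::ivec& opt, double ne, double b) {
  const int S = f.n_elem;
  cube Q(4, 4, S, fill::zeros);
  for (int s = 0; s < S; s++) {
    const int o = opt[s];
    const double fk = f[s];
    for (int i = 0; i < 4; i++) {
      double rs = 0.0;
      for (int j = 0; j < 4; j++) {
        if (i == j) continue;
        const double dr = (i != o) ? 1.0 : 0.0;
        const double dm = (j != o) ? 1.0 : 0.0;
        // F is the scaled (Ne s) log-fitness difference; the per-copy
        // fitness ratio is exp(F / Ne), so the drift exponent 2 Ne
        // reconstitutes 2F and Ne cancels from q in the large-Ne limit.
        const double F = (dm - dr) * fk;
        const double a = F / ne;          // actual log fitness ratio
        double u;
        if (std::fabs(F) < 1e-10) {
          u = b / (2.0 * ne);             // neutral limit
        } else if (2.0 * F > 700.0) {
          u = std::exp(b * a - 2.0 * F);  // denominator overflows
        } else {
          const double den = std::expm1(2.0 * F);
          u = std::isinf(den) ? 0.0 : std::expm1(b * a) / den;
        }
        const double q = 2.0 * b * M(i, j) * ne * u;
        Q.slice(s)(i, j) = q;
        rs += q;
      }
      Q.slice(s)(i, i) = -rs;
    }
  }
  return Q;
}

// ---------------------------------------------------------------------------
// Stationary distribution of each Q (left null vector), with a uniqueness
// check on the second-smallest eigenvalue magnitude of Q^T.
// [[Rcpp::export]]
List cpp_stationary(const arma::cube& Q) {
  const int n = Q.n_slices;
  mat Pi(4, n);
  NumericVector resid(n);
  LogicalVector uniq(n);
  for (int k = 0; k < n; k++) {
    cx_vec ev;
    cx_mat evec;
    if (!eig_gen(ev, evec, trans(Q.slice(k)))) stop("eigendecomposition failed");
    uvec ord = sort_index(abs(ev));
    uniq[k] = !(std::abs(ev[ord[1]]) < 1e-9 * std::max(1.0, norm(Q.slice(k), "inf")));
    vec v = real(evec.col(ord[0]));
    if (accu(v) < 0) v = -v;
    for (int i = 0; i < 4; i++)
      if (v[i] < 0 && v[i] > -1e-12) v[i] = 0.0;  // clamp tiny negatives
    const double s = accu(v);
    Pi.col(k) = v / s;
    resid[k] = norm(trans(Q.slice(k)) * Pi.col(k), "inf");
  }
  return List::create(_["pi"] = Pi, _["resid"] = resid, _["unique"] = uniq);
}

// ---------------------------------------------------------------------------
// Eigendecomposition of each distinct Q, with a reconstruction check; slices
// failing it fall back to direct scaling-and-squaring expmat at use time.
// [[Rcpp::export]]
List cpp_decompose(const arma::cube& Q) {
  const int nq = Q.n_slices;
  cx_cube V(4, 4, nq), Vi(4, 4, nq);
  cx_mat lam(4, nq);
  LogicalVector ok(nq);
  for (int k = 0; k < nq; k++) {
    bool good = false;
    cx_vec ev;
    cx_mat evec;
    if (eig_gen(ev, evec, Q.slice(k))) {
      cx_mat vinv;
      if (inv(vinv, evec)) {
        mat recon = real(evec * diagmat(ev) * vinv);
        good = norm(recon - Q.slice(k), "inf") <
               1e-8 * std::max(1.0, norm(Q.slice(k), "inf"));
        if (good) {
          V.slice(k) = evec;
          Vi.slice(k) = vinv;
          lam.col(k) = ev;
        }
      }
    }
    ok[k] = good;
    if (!good) {
      V.slice(k).zeros();
      Vi.slice(k).zeros();
      lam.col(k).zeros();
    }
  }
  return List::create(_["V"] = V, _["Vinv"] = Vi, _["lambda"] = lam,
                      _["ok"] = ok, _["Q"] = Q);
}

// One-pass decomposition: eigensystem for the pruning exponentials plus the
// stationary distribution (left eigenvector at the zero eigenvalue, read off
// V^-1) and the equilibrium substitution rate -sum_i pi_i q_ii per slice.
// [[Rcpp::export]]
List cpp_decompose_pi(const arma::cube& Q) {
  const int nq = Q.n_slices;
  cx_cube V(4, 4, nq), Vi(4, 4, nq);
  cx_mat lam(4, nq);
  LogicalVector ok(nq), uniq(nq);
  mat Pi(4, nq);
  NumericVector rate(nq), resid(nq);
  for (int k = 0; k < nq; k++) {
    bool good = false;
    cx_vec ev;
    cx_mat evec;
    vec pi(4, fill::zeros);
    if (eig_gen(ev, evec, Q.slice(k))) {
      cx_mat vinv;
      if (inv(vinv, evec)) {
        mat recon = real(evec * diagmat(ev) * vinv);
        good = norm(recon - Q.slice(k), "inf") <
               1e-8 * std::max(1.0, norm(Q.slice(k), "inf"));
        if (good) {
          V.slice(k) = evec;
          Vi.slice(k) = vinv;
          lam.col(k) = ev;
          uvec ord = sort_index(abs(ev));
          uniq[k] = !(std::abs(ev[ord[1]]) <
                      1e-9 * std::max(1.0, norm(Q.slice(k), "inf")));
          // left eigenvector at the (near-)zero eigenvalue
          vec v = real(vinv.row(ord[0]).t());
          if (accu(v) < 0) v = -v;
          for (int i = 0; i < 4; i++)
            if (v[i] < 0 && v[i] > -1e-12) v[i] = 0.0;
          pi = v / accu(v);
        }
      }
    }
    ok[k] = good;
    if (!good) {
      V.slice(k).zeros();
      Vi.slice(k).zeros();
      lam.col(k).zeros();
      // fallback: dedicated stationary solve on Q^T
      cx_vec ev2;
      cx_mat evec2;
      if (!eig_gen(ev2, evec2, trans(Q.slice(k))))
        stop("eigendecomposition failed");
      uvec ord2 = sort_index(abs(ev2));
      uniq[k] = !(std::abs(ev2[ord2[1]]) <
                  1e-9 * std::max(1.0, norm(Q.slice(k), "inf")));
      vec v = real(evec2.col(ord2[0]));
      if (accu(v) < 0) v = -v;
      for (int i = 0; i < 4; i++)
        if (v[i] < 0 && v[i] > -1e-12) v[i] = 0.0;
      pi = v / accu(v);
    }
    Pi.col(k) = pi;
    resid[k] = norm(trans(Q.slice(k)) * pi, "inf");
    rate[k] = -dot(pi, Q.slice(k).diag());
  }
  return List::create(_["V"] = V, _["Vinv"] = Vi, _["lambda"] = lam,
                      _["ok"] = ok, _["Q"] = Q, _["pi"] = Pi,
                      _["rate"] = rate, _["resid"] = resid,
                      _["unique"] = uniq);
}

struct Decomp {
  cx_cube V, Vi;
  cx_mat lam;
  std::vector<bool> ok;
  cube Q;
  // spectral rank-one modes: P(t) = sum_m exp(lambda_m t) V[,m] Vinv[m,]
  // flattened as modes(16, 4, nq) complex, column-major within each 4x4
  cx_cube modes;
  explicit Decomp(const List& d)
      : V(as<cx_cube>(d["V"])), Vi(as<cx_cube>(d["Vinv"])),
        lam(as<cx_mat>(d["lambda"])), Q(as<cube>(d["Q"])) {
    LogicalVector o = d["ok"];
    ok.assign(o.begin(), o.end());
    const int nq = Q.n_slices;
    modes.set_size(16, 4, nq);
    for (int k = 0; k < nq; k++) {
      for (int m = 0; m < 4; m++) {
        for (int j = 0; j < 4; j++)
          for (int i = 0; i < 4; i++)
            modes(j * 4 + i, m, k) = V(i, m, k) * Vi(m, j, k);
      }
    }
  }
};

static void pmat_from(const Decomp& dec, int k, double t, mat& out) {
  if (t <= 0.0) {
    out.eye(4, 4);
    return;
  }
  if (dec.ok[k]) {
    double acc[16];
    std::fill(acc, acc + 16, 0.0);
    for (int m = 0; m < 4; m++) {
      const std::complex<double> e =
          std::exp(dec.lam(m, k) * std::complex<double>(t, 0.0));
      const std::complex<double>* B = dec.modes.slice_colptr(k, m);
      const double er = e.real(), ei = e.imag();
      for (int x = 0; x < 16; x++)
        acc[x] += er * B[x].real() - ei * B[x].imag();
    }
    std::copy(acc, acc + 16, out.memptr());
  } else {
    out = expmat(dec.Q.slice(k) * t);
  }
  for (int i = 0; i < 4; i++) {  // clamp rounding noise, keep rows stochastic
    double s = 0.0;
    for (int j = 0; j < 4; j++) {
      if (out(i, j) < 0) out(i, j) = 0.0;
      s += out(i, j);
    }
    if (s > 0) for (int j = 0; j < 4; j++) out(i, j) /= s;
  }
}

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) { return expmat(Q * t); }

// Transition matrices for arbitrary (Q index, effective time) pairs; used by
// the simulator and by transition_probabilities on decomposed models.
// [[Rcpp::export]]
arma::cube cpp_transition_cube(List decomp, IntegerVector qidx,
                               NumericVector teff) {
  Decomp dec(decomp);
  const int n = qidx.size();
  cube out(4, 4, n);
  mat tmp(4, 4);
  for (int i = 0; i < n; i++) {
    pmat_from(dec, qidx[i], teff[i], tmp);
    out.slice(i) = tmp;
  }
  return out;
}

// ---------------------------------------------------------------------------
struct Engine {
  imat tips;       // n_tip x S, 0..3 or -1 for missing
  imat edge;       // E x 2, 1-based ape node ids, postorder
  vec len;
  int n_tip, n_nodes, root;
  ivec site_prof, prof_ptr, comp_q;
  vec comp_rate, comp_w;
  mat comp_pi;     // 4 x M
};

static Engine make_engine(IntegerMatrix tips, IntegerMatrix edge,
                          NumericVector lengths, int n_tip, int n_nodes,
                          int root, IntegerVector site_prof,
                          IntegerVector prof_ptr, IntegerVector comp_q,
                          NumericVector comp_rate, NumericVector comp_w,
                          NumericMatrix comp_pi) {
  Engine en;
  en.tips = as<imat>(tips);
  en.edge = as<imat>(edge);
  en.len = as<vec>(lengths);
  en.n_tip = n_tip;
  en.n_nodes = n_nodes;
  en.root = root;
  en.site_prof = as<ivec>(site_prof);
  en.prof_ptr = as<ivec>(prof_ptr);
  en.comp_q = as<ivec>(comp_q);
  en.comp_rate = as<vec>(comp_rate);
  en.comp_w = as<vec>(comp_w);
  en.comp_pi = as<mat>(comp_pi);
  return en;
}

static void build_P(const Engine& en, const Decomp& dec, cube& Pc) {
  const int E = en.edge.n_rows, M = en.comp_rate.n_elem;
  Pc.set_size(4, 4, (size_t)E * M);
  mat tmp(4, 4);
  for (int e = 0; e < E; e++)
    for (int m = 0; m < M; m++) {
      pmat_from(dec, en.comp_q[m], en.len[e] * en.comp_rate[m], tmp);
      Pc.slice((size_t)e * M + m) = tmp;
    }
}

static void update_P_edge(const Engine& en, const Decomp& dec, cube& Pc, int e) {
  const int M = en.comp_rate.n_elem;
  mat tmp(4, 4);
  for (int m = 0; m < M; m++) {
    pmat_from(dec, en.comp_q[m], en.len[e] * en.comp_rate[m], tmp);
    Pc.slice((size_t)e * M + m) = tmp;
  }
}

// Pruning for one site under one mixture component.
static double site_comp_lnl(const Engine& en, const cube& Pc, int s, int c,
                            mat& partial, vec& logsc) {
  const int E = en.edge.n_rows, M = en.comp_rate.n_elem;
  partial.ones();
  logsc.zeros();
  for (int i = 0; i < en.n_tip; i++) {
    const int st = en.tips(i, s);
    if (st >= 0) {
      partial.col(i).zeros();
      partial(st, i) = 1.0;
    }
  }
  for (int e = 0; e < E; e++) {
    const int par = en.edge(e, 0) - 1, ch = en.edge(e, 1) - 1;
    const double* P = Pc.slice_memptr((size_t)e * M + c);  // column-major 4x4
    const double* pc = partial.colptr(ch);
    double* pp = partial.colptr(par);
    double mx = 0.0;
    for (int i = 0; i < 4; i++) {
      const double v = P[i] * pc[0] + P[4 + i] * pc[1] + P[8 + i] * pc[2] +
                       P[12 + i] * pc[3];
      pp[i] *= v;
      if (pp[i] > mx) mx = pp[i];
    }
    logsc[par] += logsc[ch];
    if (mx > 0 && mx < RESCALE_AT) {
      for (int i = 0; i < 4; i++) pp[i] /= mx;
      logsc[par] += std::log(mx);
    }
  }
  const int r = en.root - 1;
  const double L = dot(en.comp_pi.col(c), partial.col(r));
  if (!(L > 0)) return LOG_FLOOR + logsc[r];
  return std::log(L) + logsc[r];
}

static double site_lnl(const Engine& en, const cube& Pc, int s, mat& partial,
                       vec& logsc) {
  const int p = en.site_prof[s];
  const int c0 = en.prof_ptr[p], c1 = en.prof_ptr[p + 1];
  if (c1 == c0 + 1)
    return std::log(en.comp_w[c0]) + site_comp_lnl(en, Pc, s, c0, partial, logsc);
  double mx = -datum::inf;
  std::vector<double> v(c1 - c0);
  for (int c = c0; c < c1; c++) {
    v[c - c0] = std::log(en.comp_w[c]) + site_comp_lnl(en, Pc, s, c, partial, logsc);
    if (v[c - c0] > mx) mx = v[c - c0];
  }
  double sum = 0.0;
  for (double x : v) sum += std::exp(x - mx);
  return mx + std::log(sum);
}

static double total_lnl(const Engine& en, const cube& Pc, mat& partial,
                        vec& logsc) {
  double s = 0.0;
  const int S = en.site_prof.n_elem;
  for (int i = 0; i < S; i++) s += site_lnl(en, Pc, i, partial, logsc);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_site_loglik(List decomp, IntegerMatrix tips,
                              IntegerMatrix edge, NumericVector lengths,
                              int n_tip, int n_nodes, int root,
                              IntegerVector site_prof, IntegerVector prof_ptr,
                              IntegerVector comp_q, NumericVector comp_rate,
                              NumericVector comp_w, NumericMatrix comp_pi) {
  Decomp dec(decomp);
  Engine en = make_engine(tips, edge, lengths, n_tip, n_nodes, root, site_prof,
                          prof_ptr, comp_q, comp_rate, comp_w, comp_pi);
  cube Pc;
  build_P(en, dec, Pc);
  const int S = en.site_prof.n_elem;
  NumericVector out(S);
  mat partial(4, en.n_nodes);
  vec logsc(en.n_nodes);
  for (int s = 0; s < S; s++) out[s] = site_lnl(en, Pc, s, partial, logsc);
  return out;
}

// Per-component (unweighted) site log-likelihoods; requires every profile to
// own the same number of components (Gamma-mixture use).
// [[Rcpp::export]]
NumericMatrix cpp_site_loglik_bycomp(List decomp, IntegerMatrix tips,
                                     IntegerMatrix edge, NumericVector lengths,
                                     int n_tip, int n_nodes, int root,
                                     IntegerVector site_prof,
                                     IntegerVector prof_ptr,
                                     IntegerVector comp_q,
                                     NumericVector comp_rate,
                                     NumericVector comp_w,
                                     NumericMatrix comp_pi) {
  Decomp dec(decomp);
  Engine en = make_engine(tips, edge, lengths, n_tip, n_nodes, root, site_prof,
                          prof_ptr, comp_q, comp_rate, comp_w, comp_pi);
  const int K = en.prof_ptr[1] - en.prof_ptr[0];
  cube Pc;
  build_P(en, dec, Pc);
  const int S = en.site_prof.n_elem;
  NumericMatrix out(S, K);
  mat partial(4, en.n_nodes);
  vec logsc(4);
  logsc.set_size(en.n_nodes);
  for (int s = 0; s < S; s++) {
    const int p = en.site_prof[s];
    const int c0 = en.prof_ptr[p];
    for (int c = 0; c < K; c++)
      out(s, c) = site_comp_lnl(en, Pc, s, c0 + c, partial, logsc);
  }
  return out;
}

// Bounded scalar minimizer (Brent's localmin on an interval).
template <class F>
static double brent_bounded(F&& f, double a, double b, double tol,
                            double& fx_out) {
  const double gold = 0.3819660112501051;
  double x, w, v, fx, fw, fv, d = 0.0, e = 0.0;
  x = w = v = a + gold * (b - a);
  fx = fw = fv = f(x);
  for (int iter = 0; iter < 200; ++iter) {
    const double m = 0.5 * (a + b);
    const double tol1 = tol, tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      const double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      const double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x < m ? b - x : a - x);
      d = gold * e;
    }
    const double u = (std::fabs(d) >= tol1 ? x + d : x + (d > 0 ? tol1 : -tol1));
    const double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw;
      w = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw;
        w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  fx_out = fx;
  return x;
}

// Generation-ordered branch-length sweeps: every edge is optimized by a
// bounded 1-D Brent search, tips-first (sweep_order), repeated until the
// relative log-likelihood gain of a full sweep drops below rel_tol or
// max_sweeps is reached.  Accept-only-improvement keeps lnL monotone.
// [[Rcpp::export]]
List cpp_optimize_branches(List decomp, IntegerMatrix tips, IntegerMatrix edge,
                           NumericVector lengths, int n_tip, int n_nodes,
                           int root, IntegerVector site_prof,
                           IntegerVector prof_ptr, IntegerVector comp_q,
                           NumericVector comp_rate, NumericVector comp_w,
                           NumericMatrix comp_pi, IntegerVector sweep_order,
                           double lower, double upper, double xtol,
                           int max_sweeps, double rel_tol) {
  Decomp dec(decomp);
  Engine en = make_engine(tips, edge, lengths, n_tip, n_nodes, root, site_prof,
                          prof_ptr, comp_q, comp_rate, comp_w, comp_pi);
  cube Pc;
  build_P(en, dec, Pc);
  mat partial(4, en.n_nodes);
  vec logsc(en.n_nodes);
  double cur = total_lnl(en, Pc, partial, logsc);
  std::vector<double> trace;
  trace.push_back(cur);
  for (int sweep = 0; sweep < max_sweeps; sweep++) {
    const double before = cur;
    for (int oi = 0; oi < sweep_order.size(); oi++) {
      const int e = sweep_order[oi];
      const double t0 = en.len[e];
      auto g = [&](double t) {
        en.len[e] = t;
        update_P_edge(en, dec, Pc, e);
        return -total_lnl(en, Pc, partial, logsc);
      };
      double fbest;
      const double tbest = brent_bounded(g, lower, upper, xtol, fbest);
      if (-fbest > cur) {
        en.len[e] = tbest;
        update_P_edge(en, dec, Pc, e);
        cur = -fbest;
      } else {
        en.len[e] = t0;  // restore: candidate did not improve
        update_P_edge(en, dec, Pc, e);
      }
    }
    trace.push_back(cur);
    if (cur - before < rel_tol * std::fabs(before)) break;
  }
  return List::create(_["lengths"] = NumericVector(en.len.begin(), en.len.end()),
                      _["lnl"] = cur, _["trace"] = wrap(trace));
}
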