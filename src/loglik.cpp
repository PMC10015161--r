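// Pruning-algorithm likelihood core for amino-acid models with invariant
// sites and discrete-gamma rate categories, plus in-place branch-length
// optimization by golden-section search on each edge within preorder
// Gauss-Seidel sweeps (partial likelihoods are kept current along the
// traversal, so every one-dimensional problem is the exact likelihood).
//
// Conventions: nodes are 1-based ape ids (tips 1..ntip); the edge matrix is
// in postorder; Q = U diag(lambda) Uinv with U, Uinv from the symmetric
// eigendecomposition of the reversible rate matrix. Rate categories arrive
// pre-scaled by 1/(1 - p_inv).

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SCALE_FLOOR = 1e-240;

static mat pmat(const mat &U, const mat &Uinv, const vec &lam, double t) {
  mat P = U * diagmat(exp(lam * t)) * Uinv;
  P.for_each([](double &x) { if (x < 0) x = 0; });
  return P;
}

// message from a tip: row p is P(. , state_p), or ones if ambiguous
static mat tip_msg(const mat &P, const ivec &st) {
  const uword npat = st.n_elem;
  mat msg(npat, 20);
  rowvec ones20(20, fill::ones);
  for (uword p = 0; p < npat; ++p) {
    int s = st(p);
    if (s == 0) msg.row(p) = ones20;
    else msg.row(p) = P.col(s - 1).t();
  }
  return msg;
}

// rescale rows whose maximum fell below the floor, accumulating log scalers
static void rescale(mat &m, vec &scal) {
  for (uword p = 0; p < m.n_rows; ++p) {
    double mx = m.row(p).max();
    if (mx > 0 && mx < SCALE_FLOOR) {
      m.row(p) /= mx;
      scal(p) += std::log(mx);
    }
  }
}

// mix per-category site likelihoods (with per-pattern log scalers) and the
// invariant-site class into per-pattern log likelihoods
static vec mix_loglik(const std::vector<vec> &sl, const std::vector<vec> &sc,
                      const vec &l0, double pinv, uword npat) {
  const int k = (int) sl.size();
  const double wcat = (1.0 - pinv) / k;
  vec out(npat);
  for (uword p = 0; p < npat; ++p) {
    // log-sum-exp over k category terms + the invariant class
    double mx = R_NegInf;
    std::vector<double> lg(k + 1, R_NegInf);
    for (int c = 0; c < k; ++c) {
      double v = sl[c](p);
      if (v > 0) lg[c] = std::log(wcat * v) + sc[c](p);
      if (lg[c] > mx) mx = lg[c];
    }
    if (pinv > 0 && l0(p) > 0) {
      lg[k] = std::log(pinv * l0(p));
      if (lg[k] > mx) mx = lg[k];
    }
    if (!std::isfinite(mx)) { out(p) = R_NegInf; continue; }
    double s = 0;
    for (int c = 0; c <= k; ++c)
      if (std::isfinite(lg[c])) s += std::exp(lg[c] - mx);
    out(p) = mx + std::log(s);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List plik_full(Rcpp::IntegerMatrix edge, Rcpp::NumericVector el,
                     int ntip, Rcpp::IntegerMatrix tipstate,
                     Rcpp::NumericVector w, Rcpp::NumericMatrix U_,
                     Rcpp::NumericMatrix Uinv_, Rcpp::NumericVector lam_,
                     Rcpp::NumericVector pi_, Rcpp::NumericVector rates_,
                     double pinv, Rcpp::NumericVector l0_) {
  const mat U(U_.begin(), 20, 20), Uinv(Uinv_.begin(), 20, 20);
  const vec lam(lam_.begin(), 20), pi(pi_.begin(), 20);
  const vec l0(l0_.begin(), l0_.size());
  const vec wt(w.begin(), w.size());
  const int E = edge.nrow();
  const uword npat = tipstate.nrow();
  const int k = rates_.size();
  int nn = 0;
  for (int r = 0; r < E; ++r)
    nn = std::max(nn, std::max(edge(r, 0), edge(r, 1)));
  const int root = edge(E - 1, 0);

  imat ts(tipstate.nrow(), tipstate.ncol());
  for (uword i = 0; i < (uword) tipstate.nrow(); ++i)
    for (uword j = 0; j < (uword) tipstate.ncol(); ++j)
      ts(i, j) = tipstate(i, j);

  std::vector<vec> sl(k), sc(k);
  for (int c = 0; c < k; ++c) {
    double rc = rates_[c];
    std::vector<mat> down(nn + 1);
    std::vector<vec> scal(nn + 1);
    for (int r = 0; r < E; ++r) {
      int par = edge(r, 0), ch = edge(r, 1);
      mat P = pmat(U, Uinv, lam, el[r] * rc);
      mat msg;
      vec msc(npat, fill::zeros);
      if (ch <= ntip) {
        msg = tip_msg(P, ts.col(ch - 1));
      } else {
        rescale(down[ch], scal[ch]);
        msg = down[ch] * P.t();
        msc = scal[ch];
      }
      if (down[par].n_rows == 0) {
        down[par] = msg;
        scal[par] = msc;
      } else {
        down[par] %= msg;
        scal[par] += msc;
      }
    }
    rescale(down[root], scal[root]);
    sl[c] = down[root] * pi;
    sc[c] = scal[root];
  }
  vec site = mix_loglik(sl, sc, l0, pinv, npat);
  return Rcpp::List::create(
      Rcpp::Named("site_loglik") = site,
      Rcpp::Named("loglik") = dot(wt, site));
}

// ---------------------------------------------------------------------------
// branch-length optimization

struct OptimCtx {
  mat U, Uinv;
  vec lam, pi, l0, wt;
  std::vector<double> rates;
  double pinv;
  int ntip, k, nedge, nnode, root;
  uword npat;
  imat ts;                              // npat x ntip tip states
  std::vector<std::vector<int>> kids;   // node -> child edge indices
  std::vector<int> child, parent;       // per edge
  std::vector<double> el;
  // per category, per edge: message toward the root and its log scaler
  std::vector<std::vector<mat>> msg;
  std::vector<std::vector<vec>> msc;
};

static void compute_msg(OptimCtx &C, int e) {
  int ch = C.child[e];
  for (int c = 0; c < C.k; ++c) {
    mat P = pmat(C.U, C.Uinv, C.lam, C.el[e] * C.rates[c]);
    if (ch <= C.ntip) {
      C.msg[c][e] = tip_msg(P, C.ts.col(ch - 1));
      C.msc[c][e].zeros(C.npat);
    } else {
      mat down = C.msg[c][C.kids[ch][0]];
      vec scal = C.msc[c][C.kids[ch][0]];
      for (size_t i = 1; i < C.kids[ch].size(); ++i) {
        down %= C.msg[c][C.kids[ch][i]];
        scal += C.msc[c][C.kids[ch][i]];
      }
      rescale(down, scal);
      C.msg[c][e] = down * P.t();
      C.msc[c][e] = scal;
    }
  }
}

static double full_loglik(OptimCtx &C, vec *site_out) {
  std::vector<vec> sl(C.k), sc(C.k);
  for (int c = 0; c < C.k; ++c) {
    mat down = C.msg[c][C.kids[C.root][0]];
    vec scal = C.msc[c][C.kids[C.root][0]];
    for (size_t i = 1; i < C.kids[C.root].size(); ++i) {
      down %= C.msg[c][C.kids[C.root][i]];
      scal += C.msc[c][C.kids[C.root][i]];
    }
    sl[c] = down * C.pi;
    sc[c] = scal;
  }
  vec site = mix_loglik(sl, sc, C.l0, C.pinv, C.npat);
  if (site_out) *site_out = site;
  return dot(C.wt, site);
}

// total log-likelihood as a function of one edge length, from the
// eigen-projected inner/outer partials with category weights and log
// scalers already folded in (a2_c[p,m])
static double edge_loglik(const OptimCtx &C, const std::vector<mat> &a2,
                          double t) {
  vec mixv = C.pinv > 0 ? vec(C.pinv * C.l0) : vec(C.npat, fill::zeros);
  for (int c = 0; c < C.k; ++c)
    mixv += a2[c] * exp(C.lam * (C.rates[c] * t));
  double ll = 0;
  for (uword p = 0; p < C.npat; ++p) {
    double v = mixv(p);
    ll += C.wt(p) * std::log(v > 1e-300 ? v : 1e-300);
  }
  return ll;
}

// Brent maximization over log branch length (parabolic interpolation with
// golden-section fallback), started from the current length
static double brent_branch(const OptimCtx &C, const std::vector<mat> &a2,
                           double t0, double lo, double hi, double gtol) {
  const double gr = 0.3819660112501051;   // 2 - golden ratio
  double A = std::log(lo), B = std::log(hi);
  auto f = [&](double lx) { return -edge_loglik(C, a2, std::exp(lx)); };
  double x = std::min(std::max(std::log(t0), A), B);
  double wpt = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0, e = 0;
  for (int iter = 0; iter < 50; ++iter) {
    double xm = 0.5 * (A + B);
    double tol1 = gtol * 0.5;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (B - A)) break;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      double r = (x - wpt) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - wpt) * r;
      q = 2.0 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (A - x) &&
          p < q * (B - x)) {
        parab = true;
        d = p / q;
        double u = x + d;
        if (u - A < tol2 || B - u < tol2)
          d = (xm > x) ? tol1 : -tol1;
      }
    }
    if (!parab) {
      e = (x >= xm) ? A - x : B - x;
      d = gr * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d
                                      : x + (d > 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) A = x; else B = x;
      v = wpt; fv = fw;
      wpt = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) A = u; else B = u;
      if (fu <= fw || wpt == x) {
        v = wpt; fv = fw;
        wpt = u; fw = fu;
      } else if (fu <= fv || v == x || v == wpt) {
        v = u; fv = fu;
      }
    }
  }
  return std::exp(x);
}

// [[Rcpp::export]]
Rcpp::List plik_optim(Rcpp::IntegerMatrix edge, Rcpp::NumericVector el0,
                      int ntip, Rcpp::IntegerMatrix tipstate,
                      Rcpp::NumericVector w, Rcpp::NumericMatrix U_,
                      Rcpp::NumericMatrix Uinv_, Rcpp::NumericVector lam_,
                      Rcpp::NumericVector pi_, Rcpp::NumericVector rates_,
                      double pinv, Rcpp::NumericVector l0_, double tol,
                      int max_rounds, double min_el, double max_el,
                      double gtol) {
  OptimCtx C;
  C.U = mat(U_.begin(), 20, 20);
  C.Uinv = mat(Uinv_.begin(), 20, 20);
  C.lam = vec(lam_.begin(), 20);
  C.pi = vec(pi_.begin(), 20);
  C.l0 = vec(l0_.begin(), l0_.size());
  C.wt = vec(w.begin(), w.size());
  C.rates = std::vector<double>(rates_.begin(), rates_.end());
  C.pinv = pinv;
  C.ntip = ntip;
  C.k = rates_.size();
  C.nedge = edge.nrow();
  C.npat = tipstate.nrow();
  C.ts.set_size(tipstate.nrow(), tipstate.ncol());
  for (uword i = 0; i < (uword) tipstate.nrow(); ++i)
    for (uword j = 0; j < (uword) tipstate.ncol(); ++j)
      C.ts(i, j) = tipstate(i, j);
  int nn = 0;
  for (int r = 0; r < C.nedge; ++r)
    nn = std::max(nn, std::max(edge(r, 0), edge(r, 1)));
  C.nnode = nn;
  C.root = edge(C.nedge - 1, 0);
  C.kids.assign(nn + 1, {});
  C.child.resize(C.nedge);
  C.parent.resize(C.nedge);
  C.el.resize(C.nedge);
  for (int r = 0; r < C.nedge; ++r) {
    C.parent[r] = edge(r, 0);
    C.child[r] = edge(r, 1);
    C.el[r] = std::min(std::max((double) el0[r], min_el), max_el);
    C.kids[C.parent[r]].push_back(r);
  }
  C.msg.assign(C.k, std::vector<mat>(C.nedge));
  C.msc.assign(C.k, std::vector<vec>(C.nedge));
  // initial postorder message pass (edge matrix is postorder already)
  for (int r = 0; r < C.nedge; ++r) compute_msg(C, r);

  double ll = full_loglik(C, nullptr);
  int rounds = 0;
  bool converged = false;
  const double wcat = (1.0 - pinv) / C.k;
  std::vector<double> moved(C.nedge, 1.0);  // log-scale move in last round
  int round_no = 1;

  // preorder sweep: A is the outside partial (root frequencies included)
  std::function<void(int, std::vector<mat> &, std::vector<vec> &)> sweep =
      [&](int u, std::vector<mat> &A, std::vector<vec> &As) {
        for (int f : C.kids[u]) {
          int wn = C.child[f];
          std::vector<mat> Af(C.k);
          std::vector<vec> Afs(C.k);
          for (int c = 0; c < C.k; ++c) {
            Af[c] = A[c];
            Afs[c] = As[c];
            for (int g : C.kids[u]) {
              if (g == f) continue;
              Af[c] %= C.msg[c][g];
              Afs[c] += C.msc[c][g];
            }
            rescale(Af[c], Afs[c]);
          }
          // an edge whose length settled in the previous round keeps it
          bool settled = round_no > 1 && moved[f] <= gtol;
          if (!settled) {
            std::vector<mat> a2(C.k);
            for (int c = 0; c < C.k; ++c) {
              mat DwU;
              vec Dws(C.npat, fill::zeros);
              if (wn <= C.ntip) {
                DwU.set_size(C.npat, 20);
                const ivec st = C.ts.col(wn - 1);
                rowvec usum = sum(C.Uinv, 1).t(); // ambiguous tip: sum_j Uinv
                for (uword p = 0; p < C.npat; ++p) {
                  int s = st(p);
                  if (s == 0) DwU.row(p) = usum;
                  else DwU.row(p) = C.Uinv.col(s - 1).t();
                }
              } else {
                mat down = C.msg[c][C.kids[wn][0]];
                Dws = C.msc[c][C.kids[wn][0]];
                for (size_t i = 1; i < C.kids[wn].size(); ++i) {
                  down %= C.msg[c][C.kids[wn][i]];
                  Dws += C.msc[c][C.kids[wn][i]];
                }
                rescale(down, Dws);
                DwU = down * C.Uinv.t();
              }
              a2[c] = (Af[c] * C.U) % DwU;
              a2[c].each_col() %= wcat * exp(Afs[c] + Dws);
            }
            double t_old = C.el[f];
            C.el[f] = brent_branch(C, a2, t_old, min_el, max_el, gtol);
            moved[f] = std::fabs(std::log(C.el[f] / t_old));
          }
          if (wn > C.ntip) {
            std::vector<mat> Anew(C.k);
            for (int c = 0; c < C.k; ++c)
              Anew[c] = Af[c] * pmat(C.U, C.Uinv, C.lam,
                                     C.el[f] * C.rates[c]);
            sweep(wn, Anew, Afs);
          }
          compute_msg(C, f);   // refresh with the new length (and subtree)
        }
      };

  for (rounds = 1; rounds <= max_rounds; ++rounds) {
    round_no = rounds;
    std::vector<mat> A0(C.k);
    std::vector<vec> As0(C.k);
    for (int c = 0; c < C.k; ++c) {
      A0[c] = repmat(C.pi.t(), C.npat, 1);
      As0[c].zeros(C.npat);
    }
    sweep(C.root, A0, As0);
    double ll_new = full_loglik(C, nullptr);
    double gain = ll_new - ll;
    ll = std::max(ll, ll_new);
    if (std::fabs(gain) < tol) { converged = true; break; }
  }

  vec site;
  double ll_final = full_loglik(C, &site);
  return Rcpp::List::create(
      Rcpp::Named("el") = Rcpp::NumericVector(C.el.begin(), C.el.end()),
      Rcpp::Named("loglik") = ll_final,
      Rcpp::Named("site_loglik") = site,
      Rcpp::Named("rounds") = std::min(rounds, max_rounds),
      Rcpp::Named("converged") = converged);
}
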