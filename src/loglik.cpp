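// Fast path for the QMC marginal log-likelihood and the dynamic-prediction
// integrals. Mirrors the R reference implementation in R/likelihood.R; the
// two are tested for agreement.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Borrow an R matrix/vector without copying.
static mat getm(const Rcpp::List& b, const char* nm) {
  Rcpp::NumericMatrix M = b[nm];
  return mat(M.begin(), M.nrow(), M.ncol(), false, true);
}
static vec getv(const Rcpp::List& b, const char* nm) {
  Rcpp::NumericVector V = b[nm];
  return vec(V.begin(), V.size(), false, true);
}

static double lse(const vec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return -datum::inf;
  return m + std::log(accu(exp(v - m)));
}

// log baseline hazard at times t for one cause; B is the (optional)
// B-spline basis at those times.
static vec log_baseline(int variant, const vec& blpars, const vec& t,
                        const mat& B, uword row0, uword nrows) {
  if (variant == 0) {
    return vec(t.n_elem, fill::value(blpars(0)));
  } else if (variant == 1) {
    double lk = std::log(blpars(0)), km1 = blpars(0) - 1.0;
    return lk + km1 * log(t) + blpars(1);
  }
  vec eta(blpars);
  return B.rows(row0, row0 + nrows - 1) * eta;
}

struct CausePar {
  vec gamma;
  double a1, a2, as;
  int variant;
  vec blpars;
};

static std::vector<CausePar> unpack_causes(const Rcpp::List& par) {
  Rcpp::List causes = par["causes"];
  std::vector<CausePar> out(causes.size());
  for (int k = 0; k < causes.size(); ++k) {
    Rcpp::List ck = causes[k];
    out[k].gamma = Rcpp::as<vec>(ck["gamma"]);
    out[k].a1 = Rcpp::as<double>(ck["a1"]);
    out[k].a2 = Rcpp::as<double>(ck["a2"]);
    out[k].as = Rcpp::as<double>(ck["as"]);
    out[k].variant = Rcpp::as<int>(ck["variant"]);
    out[k].blpars = Rcpp::as<vec>(ck["blpars"]);
  }
  return out;
}

// Cumulative hazards of all causes over a 15-node panel block.
// Adds -sum_k Lambda_k into ll (length S). Node block rows [row0, row0+14].
// Fused loops with no per-call heap allocation beyond small vectors.
static void accumulate_survival(vec& ll, const std::vector<CausePar>& cp,
                                const mat& b, const mat& tauM,
                                const vec& mean0s, const vec& slope0s,
                                const vec& logs0s,
                                const mat& Zs, const mat& dZs, const mat& Ms,
                                const vec& tnodes, const vec& wnodes,
                                const std::vector<mat>& Bs,
                                const std::vector<rowvec>& Wrow,
                                uword row0) {
  const uword S = b.n_rows;
  const uword Q = 15;
  const uword nb = b.n_cols, ntau = tauM.n_cols;
  const size_t K = cp.size();
  bool need_y = false, need_yp = false, need_sig = false;
  if (K > 8) Rcpp::stop("at most 8 causes supported");
  double basek[8][15];
  for (size_t k = 0; k < K; ++k) {
    need_y = need_y || cp[k].a1 != 0.0;
    need_yp = need_yp || cp[k].a2 != 0.0;
    need_sig = need_sig || cp[k].as != 0.0;
    vec tq = tnodes.subvec(row0, row0 + Q - 1);
    vec lb = log_baseline(cp[k].variant, cp[k].blpars, tq, Bs[k], row0, Q);
    double wg = cp[k].gamma.n_elem ? dot(Wrow[k], cp[k].gamma) : 0.0;
    for (uword q = 0; q < Q; ++q) {
      basek[k][q] = wnodes(row0 + q) * std::exp(lb(q) + wg);
    }
  }
  double* llp = ll.memptr();
  for (uword q = 0; q < Q; ++q) {
    const double m0 = mean0s(row0 + q), s0 = slope0s(row0 + q),
                 l0 = logs0s(row0 + q);
    for (uword s = 0; s < S; ++s) {
      double yv = m0, yp = s0, ls = l0;
      if (need_y || need_yp) {
        for (uword j = 0; j < nb; ++j) {
          const double bj = b(s, j);
          if (need_y) yv += bj * Zs(row0 + q, j);
          if (need_yp) yp += bj * dZs(row0 + q, j);
        }
      }
      double sg = 0.0;
      if (need_sig) {
        for (uword j = 0; j < ntau; ++j) ls += tauM(s, j) * Ms(row0 + q, j);
        sg = std::exp(ls);
      }
      for (size_t k = 0; k < K; ++k) {
        double lp = cp[k].a1 * yv + cp[k].a2 * yp + cp[k].as * sg;
        llp[s] -= basek[k][q] * std::exp(lp);
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector loglik_subjects_cpp(Rcpp::List par, Rcpp::List bundle,
                                        arma::mat E, bool delayed) {
  const vec beta = Rcpp::as<vec>(par["beta"]);
  const vec mu = Rcpp::as<vec>(par["mu"]);
  const mat L = Rcpp::as<mat>(par["L"]);
  std::vector<CausePar> cp = unpack_causes(par);

  const int N = Rcpp::as<int>(bundle["N"]);
  const int K = Rcpp::as<int>(bundle["K"]);
  const int nb = Rcpp::as<int>(bundle["nb"]);
  const int ntau = Rcpp::as<int>(bundle["ntau"]);
  const vec y = getv(bundle, "y");
  const Rcpp::IntegerVector off = bundle["off"];
  const mat Xl = getm(bundle, "Xl"), Zl = getm(bundle, "Zl");
  const mat Ol = getm(bundle, "Ol"), Ml = getm(bundle, "Ml");
  const vec tnodes = getv(bundle, "tnodes"), wnodes = getv(bundle, "wnodes");
  const mat Xs = getm(bundle, "Xs"), dXs = getm(bundle, "dXs");
  const mat Zs = getm(bundle, "Zs"), dZs = getm(bundle, "dZs");
  const mat Os = getm(bundle, "Os"), Ms = getm(bundle, "Ms");
  const mat XT = getm(bundle, "XT"), dXT = getm(bundle, "dXT");
  const mat ZT = getm(bundle, "ZT"), dZT = getm(bundle, "dZT");
  const mat OT = getm(bundle, "OT"), MT = getm(bundle, "MT");
  const vec Tobs = getv(bundle, "Tobs");
  const Rcpp::IntegerVector delta = bundle["delta"];
  const vec entry = getv(bundle, "entry");
  const bool has_entry = Rcpp::as<bool>(bundle["has_entry"]) && delayed;

  Rcpp::List Wl = bundle["W"], Bsl = bundle["Bs"], BTl = bundle["BT"],
             Bs0l = bundle["Bs0"];
  std::vector<mat> W(K), Bs(K), BT(K), Bs0(K);
  for (int k = 0; k < K; ++k) {
    W[k] = Rcpp::as<mat>(Wl[k]);
    Bs[k] = Rcpp::as<mat>(Bsl[k]);
    BT[k] = Rcpp::as<mat>(BTl[k]);
    Bs0[k] = Rcpp::as<mat>(Bs0l[k]);
  }
  mat t0nodes_m, Xs0, dXs0, Os0, Zs0, dZs0, Ms0;
  vec t0nodes, w0nodes;
  if (has_entry) {
    t0nodes = getv(bundle, "t0nodes");
    w0nodes = getv(bundle, "w0nodes");
    Xs0 = getm(bundle, "Xs0"); dXs0 = getm(bundle, "dXs0");
    Os0 = getm(bundle, "Os0");
    Zs0 = getm(bundle, "Zs0"); dZs0 = getm(bundle, "dZs0");
    Ms0 = getm(bundle, "Ms0");
  }

  const uword S = E.n_rows;
  mat U = E * L.t();
  mat b = U.cols(0, nb - 1);
  mat tauM = U.cols(nb, nb + ntau - 1);
  const double logS = std::log((double) S);
  const double LOG2PI = std::log(2.0 * M_PI);

  // fixed-effect parts, precomputed for all rows at once
  vec mean0l = Xl.n_rows ? vec(Xl * beta) : vec();
  vec logs0l = Ol.n_rows ? vec(Ol * mu) : vec();
  vec mean0s = Xs * beta, slope0s = dXs * beta, logs0s = Os * mu;
  vec meanT = XT * beta, slopeT = dXT * beta, logsT = OT * mu;
  vec mean0s0, slope0s0, logs0s0;
  if (has_entry) {
    mean0s0 = Xs0 * beta; slope0s0 = dXs0 * beta; logs0s0 = Os0 * mu;
  }

  std::vector<rowvec> Wrow(K);
  Rcpp::NumericVector out(N);

  for (int i = 0; i < N; ++i) {
    vec ll(S, fill::zeros);
    // longitudinal part
    int o0 = off[i], o1 = off[i + 1];
    int ni = o1 - o0;
    if (ni > 0) {
      mat dev = b * Zl.rows(o0, o1 - 1).t();
      dev.each_row() -= (y.subvec(o0, o1 - 1) - mean0l.subvec(o0, o1 - 1)).t();
      mat logsig = tauM * Ml.rows(o0, o1 - 1).t();
      logsig.each_row() += logs0l.subvec(o0, o1 - 1).t();
      ll -= 0.5 * ni * LOG2PI + sum(logsig, 1) +
            0.5 * sum(exp(-2.0 * logsig) % square(dev), 1);
    }
    // survival part over [0, T_i]
    for (int k = 0; k < K; ++k) Wrow[k] = W[k].row(i);
    uword row0 = (uword) i * 15;
    accumulate_survival(ll, cp, b, tauM, mean0s, slope0s, logs0s,
                        Zs, dZs, Ms, tnodes, wnodes, Bs, Wrow, row0);
    // event term at T_i
    int di = delta[i];
    if (di > 0) {
      const CausePar& ck = cp[di - 1];
      vec tt(1); tt(0) = Tobs(i);
      vec lb = log_baseline(ck.variant, ck.blpars, tt, BT[di - 1], i, 1);
      double lpk = lb(0) +
        (ck.gamma.n_elem ? dot(Wrow[di - 1], ck.gamma) : 0.0);
      vec ev(S, fill::value(lpk));
      if (ck.a1 != 0.0)
        ev += ck.a1 * (meanT(i) + b * ZT.row(i).t());
      if (ck.a2 != 0.0)
        ev += ck.a2 * (slopeT(i) + b * dZT.row(i).t());
      if (ck.as != 0.0)
        ev += ck.as * exp(logsT(i) + tauM * MT.row(i).t());
      ll += ev;
    }
    double li = lse(ll) - logS;
    if (!std::isfinite(li)) li = -1e10;
    // delayed-entry division by P(event-free at entry)
    if (has_entry && entry(i) > 0) {
      vec ll0(S, fill::zeros);
      accumulate_survival(ll0, cp, b, tauM, mean0s0, slope0s0, logs0s0,
                          Zs0, dZs0, Ms0, t0nodes, w0nodes, Bs0, Wrow, row0);
      double corr = lse(ll0) - logS;
      if (corr > 0) corr = 0;
      li -= corr;
    }
    out[i] = li;
  }
  return out;
}

// Dynamic-prediction integrals for one subject at landmark s, horizon t.
// All node/design matrices are precomputed in R. Returns the numerator and
// denominator QMC averages; the ratio is the predicted probability.
// [[Rcpp::export]]
Rcpp::NumericVector predict_subject_cpp(Rcpp::List par, Rcpp::List sd,
                                        arma::mat E, int cause) {
  const vec beta = Rcpp::as<vec>(par["beta"]);
  const vec mu = Rcpp::as<vec>(par["mu"]);
  const mat L = Rcpp::as<mat>(par["L"]);
  std::vector<CausePar> cp = unpack_causes(par);
  const int K = (int) cp.size();
  const int nb = Rcpp::as<int>(sd["nb"]);
  const int ntau = Rcpp::as<int>(sd["ntau"]);

  const uword S = E.n_rows;
  mat U = E * L.t();
  mat b = U.cols(0, nb - 1);
  mat tauM = U.cols(nb, nb + ntau - 1);
  const double LOG2PI = std::log(2.0 * M_PI);

  // history log-density weights
  vec llh(S, fill::zeros);
  {
    const mat Xh = getm(sd, "Xh"), Zh = getm(sd, "Zh");
    const mat Oh = getm(sd, "Oh"), Mh = getm(sd, "Mh");
    const vec yh = getv(sd, "yh");
    int ni = (int) yh.n_elem;
    if (ni > 0) {
      mat dev = b * Zh.t();
      dev.each_row() -= (yh - Xh * beta).t();
      mat logsig = tauM * Mh.t();
      logsig.each_row() += vec(Oh * mu).t();
      llh -= 0.5 * ni * LOG2PI + sum(logsig, 1) +
             0.5 * sum(exp(-2.0 * logsig) % square(dev), 1);
    }
  }
  vec wdraw = exp(llh - llh.max());

  // cumulative hazards at the 15 outer nodes (inner 15x15 panels) and at s
  const vec tin = getv(sd, "tin"), win = getv(sd, "win");
  const mat Zin = getm(sd, "Zin"), dZin = getm(sd, "dZin"),
            Min = getm(sd, "Min");
  const vec mean0in = vec(getm(sd, "Xin") * beta);
  const vec slope0in = vec(getm(sd, "dXin") * beta);
  const vec logs0in = vec(getm(sd, "Oin") * mu);
  const vec tsn = getv(sd, "tsn"), wsn = getv(sd, "wsn");
  const mat Zsn = getm(sd, "Zsn"), dZsn = getm(sd, "dZsn"),
            Msn = getm(sd, "Msn");
  const vec mean0sn = vec(getm(sd, "Xsn") * beta);
  const vec slope0sn = vec(getm(sd, "dXsn") * beta);
  const vec logs0sn = vec(getm(sd, "Osn") * mu);
  Rcpp::List Binl = sd["Bin"], Boutl = sd["Bout"], Bsnl = sd["Bsn"];
  std::vector<mat> Bin(K), Bout(K), Bsn(K);
  std::vector<rowvec> Wrow(K);
  Rcpp::List Wl = sd["W"];
  for (int k = 0; k < K; ++k) {
    Bin[k] = Rcpp::as<mat>(Binl[k]);
    Bout[k] = Rcpp::as<mat>(Boutl[k]);
    Bsn[k] = Rcpp::as<mat>(Bsnl[k]);
    Wrow[k] = Rcpp::as<rowvec>(Wl[k]);
  }

  // G(u_q) = exp(-sum_c Lambda_c(u_q)) for the 15 outer nodes
  mat negLam(S, 15, fill::zeros);
  for (int q = 0; q < 15; ++q) {
    vec acc(S, fill::zeros);
    accumulate_survival(acc, cp, b, tauM, mean0in, slope0in, logs0in,
                        Zin, dZin, Min, tin, win, Bin, Wrow, (uword) q * 15);
    negLam.col(q) = acc;
  }
  mat G = exp(negLam);

  // lambda_k at the outer nodes
  const vec tout = getv(sd, "tout"), wout = getv(sd, "wout");
  const mat Zout = getm(sd, "Zout"), dZout = getm(sd, "dZout"),
            Mout = getm(sd, "Mout");
  const vec mean0out = vec(getm(sd, "Xout") * beta);
  const vec slope0out = vec(getm(sd, "dXout") * beta);
  const vec logs0out = vec(getm(sd, "Oout") * mu);
  const CausePar& ck = cp[cause - 1];
  vec lb = log_baseline(ck.variant, ck.blpars, tout, Bout[cause - 1], 0, 15);
  double wg = ck.gamma.n_elem ? dot(Wrow[cause - 1], ck.gamma) : 0.0;
  mat lp(S, 15, fill::zeros);
  if (ck.a1 != 0.0) {
    mat Yn = b * Zout.t(); Yn.each_row() += mean0out.t();
    lp += ck.a1 * Yn;
  }
  if (ck.a2 != 0.0) {
    mat Ypn = b * dZout.t(); Ypn.each_row() += slope0out.t();
    lp += ck.a2 * Ypn;
  }
  if (ck.as != 0.0) {
    mat Sg = tauM * Mout.t(); Sg.each_row() += logs0out.t();
    lp += ck.as * exp(Sg);
  }
  lp.each_row() += (lb + wg).t();
  vec numer_s = (G % exp(lp)) * wout;

  // g(s)
  vec acc0(S, fill::zeros);
  accumulate_survival(acc0, cp, b, tauM, mean0sn, slope0sn, logs0sn,
                      Zsn, dZsn, Msn, tsn, wsn, Bsn, Wrow, 0);
  vec gs = exp(acc0);

  double num = dot(wdraw, numer_s);
  double den = dot(wdraw, gs);
  Rcpp::NumericVector out(2);
  out[0] = num; out[1] = den;
  return out;
}
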