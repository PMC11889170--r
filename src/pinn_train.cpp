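// Physics-informed trainer for the reduced-order aggregation models.
//
// One small tanh MLP per experiment maps (scaled) time to the model's
// species concentrations; the kinetic rate constants are shared across all
// experiments (global fit).  The loss is
//     L = w_data * L_MSE + w_phys * L_PI
// with L_MSE the mean squared data misfit over observed entries and L_PI
// the mean absolute ODE residual.  In collocation mode the residual is
// dyhat/dt - f(yhat; a) with dyhat/dt obtained by exact differentiation of
// the network; in literal mode it is f(y; a) - f(yhat; a) applied pointwise.
//
// The time derivative of the surrogate is propagated forward through the
// layers alongside the activations, and the reverse pass differentiates
// both paths, so gradients with respect to the weights include the
// second-order terms the derivative output introduces.

#include <RcppArmadillo.h>
#include <R_ext/Rdynload.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// The deSolve right-hand side lives in ode_chain.c; register it so the
// solver can resolve it by name (dynamic symbol lookup is disabled).
extern "C" {
void rom_initmod(void (*odeparms)(int*, double*));
void rom_derivs(int*, double*, double*, double*, double*, int*);
}

// [[Rcpp::init]]
void rom_register_ode(DllInfo* dll) {
  static const R_CMethodDef CEntries[] = {
    {"rom_initmod", (DL_FUNC) &rom_initmod, 1},
    {"rom_derivs", (DL_FUNC) &rom_derivs, 6},
    {NULL, NULL, 0}
  };
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
}

namespace {

// x^e with integral exponents handled for negative bases; non-integral
// exponents clamp negative bases to zero (the surrogate may dip below 0
// transiently during training).
inline double powg(double x, double e) {
  double ri = std::round(e);
  if (std::abs(e - ri) < 1e-12) return std::pow(x, e);
  if (x < 0.0) return 0.0;
  return std::pow(x, e);
}

inline double dpowg(double x, double e) {  // d/dx x^e
  double ri = std::round(e);
  if (std::abs(e - ri) < 1e-12) {
    if (std::abs(e - 1.0) < 1e-12) return 1.0;
    return e * std::pow(x, e - 1.0);
  }
  if (x < 0.0) return 0.0;
  return e * std::pow(x, e - 1.0);
}

struct Net {
  std::vector<mat> W;  // layer weights; W[0] is width x 1, last is nsp x width
  std::vector<vec> b;
};

struct Reactions {
  uvec sp;      // species index feeding each reaction's rate law (0-based)
  vec  ex;      // exponent on that species
  uvec par;     // rate-parameter index (0-based)
  mat  S;       // nR x nsp net stoichiometric coefficients
};

// f(x; a) for one state column
inline vec rhs_eval(const vec& x, const vec& a, const Reactions& R) {
  vec f(x.n_elem, fill::zeros);
  for (uword r = 0; r < R.sp.n_elem; ++r) {
    double flux = a(R.par(r)) * powg(x(R.sp(r)), R.ex(r));
    for (uword i = 0; i < x.n_elem; ++i) {
      double s = R.S(r, i);
      if (s != 0.0) f(i) += s * flux;
    }
  }
  return f;
}

struct Cache {
  std::vector<mat> A;   // activations per hidden layer (width x N)
  std::vector<mat> Dz;  // pre-activation derivative path W * Dprev
  std::vector<mat> D;   // activation time-derivatives
  mat Nout, Ndot;       // network output and its d/dt (nsp x N)
  mat Yhat, Ydot;       // surrogate prediction and derivative (nsp x N)
};

// Forward pass for one experiment.  x is the network input per time point
// (scaled, possibly warped time) and xd = dx/dt its derivative.  The
// surrogate is
//   yhat(t) = y0 + g(t) .* (s .* N(x(t))),
// where g is a constraint factor supplied per time point (g(0) = 0 pins the
// initial state; g == 1, y0 == 0 gives the unconstrained form) and gd its
// time derivative, so
//   dyhat/dt = s .* (gd .* N + g .* dN/dt).
void forward(const Net& net, const rowvec& x, const rowvec& xd,
             const vec& y0, const vec& s,
             const rowvec& g, const rowvec& gd, Cache& C) {
  size_t L = net.W.size() - 1;  // hidden layers
  C.A.resize(L); C.Dz.resize(L); C.D.resize(L);
  mat H = x;                                 // 1 x N
  mat Dp = xd;                               // dH/dt
  for (size_t l = 0; l < L; ++l) {
    mat Z = net.W[l] * H; Z.each_col() += net.b[l];
    C.A[l]  = tanh(Z);
    C.Dz[l] = net.W[l] * Dp;
    C.D[l]  = (1.0 - square(C.A[l])) % C.Dz[l];
    H = C.A[l]; Dp = C.D[l];
  }
  C.Nout = net.W[L] * H; C.Nout.each_col() += net.b[L];
  C.Ndot = net.W[L] * Dp;
  C.Yhat = C.Nout; C.Yhat.each_row() %= g; C.Yhat.each_col() %= s;
  C.Yhat.each_col() += y0;
  mat t1 = C.Nout; t1.each_row() %= gd;
  mat t2 = C.Ndot; t2.each_row() %= g;
  C.Ydot = t1 + t2; C.Ydot.each_col() %= s;
}

// Reverse pass: given dL/dYhat and dL/dYdot, accumulate weight gradients.
void backward(const Net& net, const rowvec& x, const rowvec& xd,
              const vec& s,
              const rowvec& g, const rowvec& gd, const Cache& C,
              const mat& gY, const mat& gYd,
              std::vector<mat>& gW, std::vector<vec>& gb) {
  size_t L = net.W.size() - 1;
  mat gN = gY; gN.each_row() %= g;
  mat t1 = gYd; t1.each_row() %= gd;
  gN += t1;
  gN.each_col() %= s;
  mat gNd = gYd; gNd.each_row() %= g; gNd.each_col() %= s;
  const mat& Hlast = L > 0 ? C.A[L - 1] : mat(x);
  mat Dlast = L > 0 ? C.D[L - 1] : mat(xd);
  gW[L] += gN * Hlast.t() + gNd * Dlast.t();
  gb[L] += sum(gN, 1);
  mat gA = net.W[L].t() * gN;
  mat gD = net.W[L].t() * gNd;
  for (size_t li = L; li-- > 0;) {
    mat one_m = 1.0 - square(C.A[li]);
    gA += (-2.0 * C.A[li] % C.Dz[li]) % gD;   // D depends on A
    mat gDz = one_m % gD;
    mat gZ  = one_m % gA;
    mat Hp; mat Dp;
    if (li > 0) { Hp = C.A[li - 1]; Dp = C.D[li - 1]; }
    else { Hp = mat(x); Dp = mat(xd); }
    gW[li] += gZ * Hp.t() + gDz * Dp.t();
    gb[li] += sum(gZ, 1);
    if (li > 0) {
      gA = net.W[li].t() * gZ;
      gD = net.W[li].t() * gDz;
    }
  }
}

Net net_from_list(const Rcpp::List& wl) {
  Net n;
  Rcpp::List Ws = wl["W"], bs = wl["b"];
  for (int i = 0; i < Ws.size(); ++i) {
    n.W.push_back(Rcpp::as<mat>(Ws[i]));
    n.b.push_back(Rcpp::as<vec>(bs[i]));
  }
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  Rcpp::List Ws(n.W.size()), bs(n.b.size());
  for (size_t i = 0; i < n.W.size(); ++i) { Ws[i] = n.W[i]; bs[i] = n.b[i]; }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

Reactions reactions_from_list(const Rcpp::List& rl) {
  Reactions R;
  R.sp  = Rcpp::as<uvec>(rl["species"]);
  R.ex  = Rcpp::as<vec>(rl["exponent"]);
  R.par = Rcpp::as<uvec>(rl["param"]);
  R.S   = Rcpp::as<mat>(rl["stoich"]);
  return R;
}

struct LossParts { double mse; double pi; };

// One full loss + gradient evaluation over all experiments.
LossParts loss_and_grad(const std::vector<Net>& nets,
                        const std::vector<rowvec>& xs,
                        const std::vector<rowvec>& xds,
                        const std::vector<mat>& Ys,
                        const std::vector<mat>& Ms,
                        const std::vector<vec>& y0s,
                        const vec& s,
                        const std::vector<rowvec>& gs,
                        const std::vector<rowvec>& gds,
                        const vec& a, const Reactions& R,
                        double w_data, double w_phys, int literal,
                        double n_data, double n_phys,
                        std::vector<std::vector<mat>>& gW,
                        std::vector<std::vector<vec>>& gb,
                        vec& ga, std::vector<Cache>& caches) {
  double mse = 0.0, pi = 0.0;
  ga.zeros();
  uword nsp = s.n_elem;
  for (size_t e = 0; e < nets.size(); ++e) {
    Cache& C = caches[e];
    forward(nets[e], xs[e], xds[e], y0s[e], s, gs[e], gds[e], C);
    const mat& Y = Ys[e]; const mat& M = Ms[e];
    mat res = M % (C.Yhat - Y);
    mse += accu(square(res));
    mat gY = (2.0 * w_data / n_data) * res;
    mat gYd(nsp, xs[e].n_elem, fill::zeros);
    for (uword t = 0; t < xs[e].n_elem; ++t) {
      vec x = C.Yhat.col(t);
      vec f = rhs_eval(x, a, R);
      vec r(nsp);
      if (literal) {
        vec fy = rhs_eval(Y.col(t), a, R);
        r = fy - f;
      } else {
        r = C.Ydot.col(t) - f;
      }
      pi += accu(abs(r));
      vec sg = sign(r) * (w_phys / n_phys);
      if (!literal) gYd.col(t) += sg;
      // d r_i / d a_p and d r_i / d x_q (through -f(yhat))
      for (uword rr = 0; rr < R.sp.n_elem; ++rr) {
        double base = powg(x(R.sp(rr)), R.ex(rr));
        double dfdx = a(R.par(rr)) * dpowg(x(R.sp(rr)), R.ex(rr));
        double acc_a = 0.0, acc_x = 0.0;
        for (uword i = 0; i < nsp; ++i) {
          double S = R.S(rr, i);
          if (S == 0.0) continue;
          acc_a += sg(i) * S;
          acc_x += sg(i) * S;
        }
        // dL/da: residual derivative is -S*base (plus +S*baseY in literal)
        ga(R.par(rr)) += acc_a * (-base);
        if (literal) {
          double baseY = powg(Y(R.sp(rr), t), R.ex(rr));
          ga(R.par(rr)) += acc_a * baseY;
        }
        gY(R.sp(rr), t) += acc_x * (-dfdx);
      }
    }
    backward(nets[e], xs[e], xds[e], s, gs[e], gds[e], C, gY, gYd,
             gW[e], gb[e]);
  }
  return LossParts{ mse / n_data, pi / n_phys };
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List pinn_train_cpp(Rcpp::List x_r, Rcpp::List xd_r,
                          Rcpp::List Y_r, Rcpp::List M_r,
                          Rcpp::List y0_r, arma::vec s,
                          Rcpp::List g_r, Rcpp::List gd_r,
                          Rcpp::List nets_r, arma::vec a0, Rcpp::List reactions,
                          int epochs, double lr, double lr_params,
                          double lr_decay, int warmup,
                          double w_data, double w_phys,
                          int literal, int nonneg) {
  size_t nE = x_r.size();
  std::vector<Net> nets;
  std::vector<rowvec> xs, xds, gs, gds;
  std::vector<mat> Ys, Ms;
  std::vector<vec> y0s;
  for (size_t e = 0; e < nE; ++e) {
    nets.push_back(net_from_list(nets_r[e]));
    xs.push_back(Rcpp::as<rowvec>(x_r[e]));
    xds.push_back(Rcpp::as<rowvec>(xd_r[e]));
    Ys.push_back(Rcpp::as<mat>(Y_r[e]));
    Ms.push_back(Rcpp::as<mat>(M_r[e]));
    y0s.push_back(Rcpp::as<vec>(y0_r[e]));
    gs.push_back(Rcpp::as<rowvec>(g_r[e]));
    gds.push_back(Rcpp::as<rowvec>(gd_r[e]));
  }
  Reactions R = reactions_from_list(reactions);
  uword nP = a0.n_elem;

  double n_data = 0.0, n_phys = 0.0;
  for (size_t e = 0; e < nE; ++e) {
    n_data += accu(Ms[e]);
    n_phys += static_cast<double>(Ys[e].n_elem);
  }
  if (n_data < 1.0) n_data = 1.0;

  // optimized parameter: theta with a = softplus(theta) when nonneg
  vec theta(nP);
  if (nonneg) {
    for (uword i = 0; i < nP; ++i) {
      double x = std::max(a0(i), 1e-8);
      theta(i) = x > 30 ? x : std::log(std::expm1(x));
    }
  } else theta = a0;

  // Adam state
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  std::vector<std::vector<mat>> mW(nE), vW(nE), gW(nE);
  std::vector<std::vector<vec>> mb(nE), vb(nE), gb(nE);
  for (size_t e = 0; e < nE; ++e)
    for (size_t l = 0; l < nets[e].W.size(); ++l) {
      mW[e].push_back(zeros<mat>(size(nets[e].W[l])));
      vW[e].push_back(zeros<mat>(size(nets[e].W[l])));
      gW[e].push_back(zeros<mat>(size(nets[e].W[l])));
      mb[e].push_back(zeros<vec>(size(nets[e].b[l])));
      vb[e].push_back(zeros<vec>(size(nets[e].b[l])));
      gb[e].push_back(zeros<vec>(size(nets[e].b[l])));
    }
  vec ma(nP, fill::zeros), va(nP, fill::zeros), ga(nP, fill::zeros);

  mat loss_hist(3, epochs);
  mat param_hist(nP, epochs);
  std::vector<Cache> caches(nE);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t e = 0; e < nE; ++e)
      for (size_t l = 0; l < gW[e].size(); ++l) {
        gW[e][l].zeros(); gb[e][l].zeros();
      }
    vec a = nonneg ? vec(log1p(exp(-abs(theta))) + clamp(theta, 0.0, datum::inf))
                   : theta;  // stable softplus
    // physics-loss warmup: ramp w_phys linearly over the first `warmup`
    // epochs so the rates are not dragged to zero while the surrogate is
    // still far from the data
    double wp = warmup > 0 && ep < warmup
      ? w_phys * (ep + 1.0) / warmup : w_phys;
    LossParts lp = loss_and_grad(nets, xs, xds, Ys, Ms, y0s, s,
                                 gs, gds, a, R, w_data, wp, literal,
                                 n_data, n_phys, gW, gb, ga, caches);
    double total = w_data * lp.mse + w_phys * lp.pi;
    // geometric learning-rate decay from lr to lr*lr_decay across training
    double fac = lr_decay < 1.0 && epochs > 1
      ? std::pow(lr_decay, ep / (epochs - 1.0)) : 1.0;
    if (!std::isfinite(total))
      Rcpp::stop("non-finite training loss at epoch %d (params: %s)", ep + 1,
                 Rcpp::as<std::string>(Rcpp::wrap("see histories")));
    loss_hist(0, ep) = total;
    loss_hist(1, ep) = lp.mse;
    loss_hist(2, ep) = lp.pi;
    param_hist.col(ep) = a;

    if (nonneg) ga %= 1.0 / (1.0 + exp(-theta));  // chain rule via sigmoid
    double c1 = 1.0 - std::pow(b1, ep + 1), c2 = 1.0 - std::pow(b2, ep + 1);
    ma = b1 * ma + (1 - b1) * ga;  va = b2 * va + (1 - b2) * square(ga);
    theta -= fac * lr_params * (ma / c1) / (sqrt(va / c2) + eps);
    for (size_t e = 0; e < nE; ++e)
      for (size_t l = 0; l < gW[e].size(); ++l) {
        mW[e][l] = b1 * mW[e][l] + (1 - b1) * gW[e][l];
        vW[e][l] = b2 * vW[e][l] + (1 - b2) * square(gW[e][l]);
        nets[e].W[l] -= fac * lr * (mW[e][l] / c1) / (sqrt(vW[e][l] / c2) + eps);
        mb[e][l] = b1 * mb[e][l] + (1 - b1) * gb[e][l];
        vb[e][l] = b2 * vb[e][l] + (1 - b2) * square(gb[e][l]);
        nets[e].b[l] -= fac * lr * (mb[e][l] / c1) / (sqrt(vb[e][l] / c2) + eps);
      }
    if (ep % 500 == 0) Rcpp::checkUserInterrupt();
  }

  vec a_fin = nonneg
    ? vec(log1p(exp(-abs(theta))) + clamp(theta, 0.0, datum::inf))
    : theta;
  Rcpp::List Yhat_out(nE), Ydot_out(nE), nets_out(nE);
  for (size_t e = 0; e < nE; ++e) {
    Cache C;
    forward(nets[e], xs[e], xds[e], y0s[e], s, gs[e], gds[e], C);
    Yhat_out[e] = C.Yhat.t();  // n_t x nsp for R
    Ydot_out[e] = C.Ydot.t();
    nets_out[e] = net_to_list(nets[e]);
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = a_fin,
    Rcpp::Named("loss_hist") = loss_hist.t(),      // epochs x 3
    Rcpp::Named("param_hist") = param_hist.t(),    // epochs x nP
    Rcpp::Named("Yhat") = Yhat_out,
    Rcpp::Named("Ydot") = Ydot_out,
    Rcpp::Named("nets") = nets_out);
}

// Single loss + gradient evaluation, exposed for gradient verification.
// [[Rcpp::export]]
Rcpp::List pinn_loss_grad_cpp(Rcpp::List x_r, Rcpp::List xd_r,
                              Rcpp::List Y_r, Rcpp::List M_r,
                              Rcpp::List y0_r, arma::vec s,
                              Rcpp::List g_r, Rcpp::List gd_r,
                              Rcpp::List nets_r, arma::vec a,
                              Rcpp::List reactions, double w_data,
                              double w_phys, int literal) {
  size_t nE = x_r.size();
  std::vector<Net> nets;
  std::vector<rowvec> xs, xds, gs, gds;
  std::vector<mat> Ys, Ms;
  std::vector<vec> y0s;
  for (size_t e = 0; e < nE; ++e) {
    nets.push_back(net_from_list(nets_r[e]));
    xs.push_back(Rcpp::as<rowvec>(x_r[e]));
    xds.push_back(Rcpp::as<rowvec>(xd_r[e]));
    Ys.push_back(Rcpp::as<mat>(Y_r[e]));
    Ms.push_back(Rcpp::as<mat>(M_r[e]));
    y0s.push_back(Rcpp::as<vec>(y0_r[e]));
    gs.push_back(Rcpp::as<rowvec>(g_r[e]));
    gds.push_back(Rcpp::as<rowvec>(gd_r[e]));
  }
  Reactions R = reactions_from_list(reactions);
  double n_data = 0.0, n_phys = 0.0;
  for (size_t e = 0; e < nE; ++e) {
    n_data += accu(Ms[e]);
    n_phys += static_cast<double>(Ys[e].n_elem);
  }
  if (n_data < 1.0) n_data = 1.0;
  std::vector<std::vector<mat>> gW(nE);
  std::vector<std::vector<vec>> gb(nE);
  for (size_t e = 0; e < nE; ++e)
    for (size_t l = 0; l < nets[e].W.size(); ++l) {
      gW[e].push_back(zeros<mat>(size(nets[e].W[l])));
      gb[e].push_back(zeros<vec>(size(nets[e].b[l])));
    }
  vec ga(a.n_elem, fill::zeros);
  std::vector<Cache> caches(nE);
  LossParts lp = loss_and_grad(nets, xs, xds, Ys, Ms, y0s, s, gs, gds,
                               a, R, w_data, w_phys, literal, n_data, n_phys,
                               gW, gb, ga, caches);
  Rcpp::List gW_out(nE), gb_out(nE), Yhat_out(nE), Ydot_out(nE);
  for (size_t e = 0; e < nE; ++e) {
    Rcpp::List wl(gW[e].size()), bl(gb[e].size());
    for (size_t l = 0; l < gW[e].size(); ++l) { wl[l] = gW[e][l]; bl[l] = gb[e][l]; }
    gW_out[e] = wl; gb_out[e] = bl;
    Yhat_out[e] = caches[e].Yhat.t();
    Ydot_out[e] = caches[e].Ydot.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("mse") = lp.mse, Rcpp::Named("pi") = lp.pi,
    Rcpp::Named("total") = w_data * lp.mse + w_phys * lp.pi,
    Rcpp::Named("grad_params") = ga,
    Rcpp::Named("grad_W") = gW_out, Rcpp::Named("grad_b") = gb_out,
    Rcpp::Named("Yhat") = Yhat_out, Rcpp::Named("Ydot") = Ydot_out);
}
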