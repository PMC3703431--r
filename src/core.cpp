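// Numerical core: Gaussian-kernel currents sums, kernel-parameterized flows,
// the discrete adjoint gradient of the regression functional, exact
// point-to-triangle distances, parity voxelization and 6-connected labelling.
// All geometry is in physical mm; one internal time unit = one delta-t step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;

static inline double sqd(const double* a, const double* b) {
  double d0 = a[0] - b[0], d1 = a[1] - b[1], d2 = a[2] - b[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

// ---------------------------------------------------------------- currents

static double inner_cols(const mat& CA, const mat& NA_, const mat& CB,
                         const mat& NB, double il2) {
  double s = 0.0;
  for (arma::uword i = 0; i < CA.n_cols; ++i) {
    const double* ci = CA.colptr(i);
    const double* ni = NA_.colptr(i);
    for (arma::uword j = 0; j < CB.n_cols; ++j) {
      const double* nj = NB.colptr(j);
      s += std::exp(-sqd(ci, CB.colptr(j)) * il2) *
           (ni[0] * nj[0] + ni[1] * nj[1] + ni[2] * nj[2]);
    }
  }
  return s;
}

// [[Rcpp::export]]
double cpp_currents_inner(const arma::mat& centersA, const arma::mat& normalsA,
                          const arma::mat& centersB, const arma::mat& normalsB,
                          double lambda_w) {
  mat CA = centersA.t(), NA_ = normalsA.t();
  mat CB = centersB.t(), NB = normalsB.t();
  return inner_cols(CA, NA_, CB, NB, 1.0 / (lambda_w * lambda_w));
}

// ------------------------------------------------------------------ flows

static void velocity_cols(const mat& Q, const mat& X, const mat& A,
                          double il2, mat& out) {
  out.set_size(3, Q.n_cols);
  for (arma::uword p = 0; p < Q.n_cols; ++p) {
    const double* q = Q.colptr(p);
    double v0 = 0, v1 = 0, v2 = 0;
    for (arma::uword k = 0; k < X.n_cols; ++k) {
      double w = std::exp(-sqd(X.colptr(k), q) * il2);
      const double* a = A.colptr(k);
      v0 += w * a[0];
      v1 += w * a[1];
      v2 += w * a[2];
    }
    out(0, p) = v0;
    out(1, p) = v1;
    out(2, p) = v2;
  }
}

// [[Rcpp::export]]
arma::mat cpp_velocity(const arma::mat& query, const arma::mat& ctrl,
                       const arma::mat& momenta, double lambda_v) {
  mat Q = query.t(), X = ctrl.t(), A = momenta.t(), V;
  velocity_cols(Q, X, A, 1.0 / (lambda_v * lambda_v), V);
  return V.t();
}

// Explicit Euler integration of the flow ODE on the step grid. Control
// points self-advect; `points` are passive tracers carried by the same field.
// momenta: N x 3 x T.
// [[Rcpp::export]]
Rcpp::List cpp_flow_forward(const arma::mat& points, const arma::mat& ctrl0,
                            const arma::cube& momenta, double lambda_v) {
  const int T = momenta.n_slices;
  const int N = ctrl0.n_rows, P = points.n_rows;
  const double il2 = 1.0 / (lambda_v * lambda_v);
  cube Xtr(N, 3, T + 1), Ytr(P, 3, T + 1);
  Xtr.slice(0) = ctrl0;
  Ytr.slice(0) = points;
  mat X = ctrl0.t(), Y = points.t(), VX, VY;
  double maxdisp = 0.0;
  for (int t = 0; t < T; ++t) {
    mat A = momenta.slice(t).t();
    velocity_cols(X, X, A, il2, VX);
    velocity_cols(Y, X, A, il2, VY);
    if (N > 0) {
      double m = std::sqrt(arma::max(arma::sum(arma::square(VX), 0)));
      if (m > maxdisp) maxdisp = m;
    }
    if (P > 0) {
      double m = std::sqrt(arma::max(arma::sum(arma::square(VY), 0)));
      if (m > maxdisp) maxdisp = m;
    }
    X += VX;
    Y += VY;
    Xtr.slice(t + 1) = X.t();
    Ytr.slice(t + 1) = Y.t();
  }
  return List::create(_["points"] = Ytr, _["ctrl"] = Xtr,
                      _["max_step_disp"] = maxdisp);
}

// Backward integration of the negated field along stored control
// trajectories. Each forward Euler step is z_{t+1} = z_t + v_t(z_t), so the
// backward step solves the implicit equation z_t = z_{t+1} - v_t(z_t) by a
// short fixed-point iteration started at z_{t+1} (the first iterate is the
// plain negated-field Euler step). Slice s holds the state after s backward
// steps (slice 0 = input).
// [[Rcpp::export]]
arma::cube cpp_flow_inverse(const arma::mat& points, const arma::cube& ctrl_traj,
                            const arma::cube& momenta, double lambda_v) {
  const int T = momenta.n_slices;
  const int P = points.n_rows;
  const double il2 = 1.0 / (lambda_v * lambda_v);
  cube out(P, 3, T + 1);
  out.slice(0) = points;
  mat Z = points.t(), V;
  for (int s = 0; s < T; ++s) {
    int t = T - 1 - s;
    mat X = ctrl_traj.slice(t).t();
    mat A = momenta.slice(t).t();
    mat Znext = Z;
    for (int it = 0; it < 3; ++it) {
      velocity_cols(Z, X, A, il2, V);
      Z = Znext - V;
    }
    out.slice(s + 1) = Z.t();
  }
  return out;
}

// [[Rcpp::export]]
double cpp_kinetic_energy(const arma::cube& ctrl_traj, const arma::cube& momenta,
                          double lambda_v) {
  const int T = momenta.n_slices;
  const double il2 = 1.0 / (lambda_v * lambda_v);
  double E = 0.0;
  for (int t = 0; t < T; ++t) {
    mat X = ctrl_traj.slice(t).t();
    mat A = momenta.slice(t).t();
    for (arma::uword i = 0; i < X.n_cols; ++i) {
      const double* xi = X.colptr(i);
      const double* ai = A.colptr(i);
      for (arma::uword j = 0; j < X.n_cols; ++j) {
        const double* aj = A.colptr(j);
        E += std::exp(-sqd(xi, X.colptr(j)) * il2) *
             (ai[0] * aj[0] + ai[1] * aj[1] + ai[2] * aj[2]);
      }
    }
  }
  return E;
}

// ------------------------------------------------- objective and gradient

static void face_geom(const mat& Y, const arma::imat& F, mat& C, mat& Nrm) {
  const int M = F.n_rows;
  C.set_size(3, M);
  Nrm.set_size(3, M);
  for (int f = 0; f < M; ++f) {
    const double* y1 = Y.colptr(F(f, 0));
    const double* y2 = Y.colptr(F(f, 1));
    const double* y3 = Y.colptr(F(f, 2));
    double e1[3], e2[3];
    for (int d = 0; d < 3; ++d) {
      C(d, f) = (y1[d] + y2[d] + y3[d]) / 3.0;
      e1[d] = y2[d] - y1[d];
      e2[d] = y3[d] - y1[d];
    }
    Nrm(0, f) = 0.5 * (e1[1] * e2[2] - e1[2] * e2[1]);
    Nrm(1, f) = 0.5 * (e1[2] * e2[0] - e1[0] * e2[2]);
    Nrm(2, f) = 0.5 * (e1[0] * e2[1] - e1[1] * e2[0]);
  }
}

// Squared currents distance between the mesh (Y, F) and a fixed target
// current (TC, TN) whose self inner product is `self_tt`; optional gradient
// with respect to the mesh vertices (3 x P).
static double data_term(const mat& Y, const arma::imat& F, const mat& TC,
                        const mat& TN, double lambda_w, double self_tt,
                        bool want_grad, mat& gy) {
  const double il2 = 1.0 / (lambda_w * lambda_w);
  mat C, Nrm;
  face_geom(Y, F, C, Nrm);
  const int M = C.n_cols, Q = TC.n_cols;
  mat gc, gn;
  if (want_grad) {
    gc.zeros(3, M);
    gn.zeros(3, M);
  }
  double aa = 0.0, ab = 0.0;
  for (int f = 0; f < M; ++f) {
    const double* cf = C.colptr(f);
    const double* nf = Nrm.colptr(f);
    for (int g = 0; g < M; ++g) {
      const double* cg = C.colptr(g);
      const double* ng = Nrm.colptr(g);
      double w = std::exp(-sqd(cf, cg) * il2);
      double nd = nf[0] * ng[0] + nf[1] * ng[1] + nf[2] * ng[2];
      aa += w * nd;
      if (want_grad) {
        double coef = 2.0 * nd * w * (-2.0 * il2);
        for (int d = 0; d < 3; ++d) {
          gc(d, f) += coef * (cf[d] - cg[d]);
          gn(d, f) += 2.0 * w * ng[d];
        }
      }
    }
    for (int q = 0; q < Q; ++q) {
      const double* cq = TC.colptr(q);
      const double* nq = TN.colptr(q);
      double w = std::exp(-sqd(cf, cq) * il2);
      double nd = nf[0] * nq[0] + nf[1] * nq[1] + nf[2] * nq[2];
      ab += w * nd;
      if (want_grad) {
        double coef = -2.0 * nd * w * (-2.0 * il2);
        for (int d = 0; d < 3; ++d) {
          gc(d, f) += coef * (cf[d] - cq[d]);
          gn(d, f) += -2.0 * w * nq[d];
        }
      }
    }
  }
  double val = aa - 2.0 * ab + self_tt;
  if (want_grad) {
    gy.zeros(3, Y.n_cols);
    for (int f = 0; f < M; ++f) {
      int i1 = F(f, 0), i2 = F(f, 1), i3 = F(f, 2);
      const double* w = gn.colptr(f);
      double e1[3], e2[3];
      for (int d = 0; d < 3; ++d) {
        e1[d] = Y(d, i2) - Y(d, i1);
        e2[d] = Y(d, i3) - Y(d, i1);
      }
      // n = (e1 x e2)/2; chain rule of w.n through the two edge vectors
      double g2[3] = {0.5 * (e2[1] * w[2] - e2[2] * w[1]),
                      0.5 * (e2[2] * w[0] - e2[0] * w[2]),
                      0.5 * (e2[0] * w[1] - e2[1] * w[0])};
      double g3[3] = {0.5 * (w[1] * e1[2] - w[2] * e1[1]),
                      0.5 * (w[2] * e1[0] - w[0] * e1[2]),
                      0.5 * (w[0] * e1[1] - w[1] * e1[0])};
      for (int d = 0; d < 3; ++d) {
        gy(d, i1) += gc(d, f) / 3.0 - g2[d] - g3[d];
        gy(d, i2) += gc(d, f) / 3.0 + g2[d];
        gy(d, i3) += gc(d, f) / 3.0 + g3[d];
      }
    }
  }
  return val;
}

// J = gamma * sum_t sum_ij K_V(x_i(t),x_j(t)) a_i(t).a_j(t)
//     + sum_targets ||current(mesh at target step) - target||^2_W
// with an exact discrete adjoint through the Euler recursion.
// faces are 0-based; target steps are state indices in 1..T.
// [[Rcpp::export]]
Rcpp::List cpp_objective_grad(const arma::mat& vertices, const arma::imat& faces,
                              const arma::mat& ctrl0, const arma::cube& momenta,
                              double lambda_v, double gamma, double lambda_w,
                              const Rcpp::List& targets, bool want_grad) {
  const int T = momenta.n_slices;
  const int N = ctrl0.n_rows, P = vertices.n_rows;
  const double il2 = 1.0 / (lambda_v * lambda_v);

  std::vector<mat> Xs(T + 1), Ys(T + 1), As(T);
  Xs[0] = ctrl0.t();
  Ys[0] = vertices.t();
  double E = 0.0;
  for (int t = 0; t < T; ++t) {
    As[t] = momenta.slice(t).t();
    const mat& X = Xs[t];
    const mat& A = As[t];
    for (int i = 0; i < N; ++i) {
      const double* xi = X.colptr(i);
      const double* ai = A.colptr(i);
      for (int j = 0; j < N; ++j) {
        const double* aj = A.colptr(j);
        E += std::exp(-sqd(xi, X.colptr(j)) * il2) *
             (ai[0] * aj[0] + ai[1] * aj[1] + ai[2] * aj[2]);
      }
    }
    mat VX, VY;
    velocity_cols(X, X, A, il2, VX);
    velocity_cols(Ys[t], X, A, il2, VY);
    Xs[t + 1] = X + VX;
    Ys[t + 1] = Ys[t] + VY;
  }

  double D = 0.0;
  std::vector<mat> dgy(T + 1);
  const int nt = targets.size();
  for (int s = 0; s < nt; ++s) {
    List tg = targets[s];
    int st = as<int>(tg["step"]);
    if (st < 1 || st > T) stop("target step out of range");
    mat tc = as<mat>(tg["centers"]).t();
    mat tn = as<mat>(tg["normals"]).t();
    double self = as<double>(tg["self"]);
    mat gy;
    D += data_term(Ys[st], faces, tc, tn, lambda_w, self, want_grad, gy);
    if (want_grad) {
      if (dgy[st].n_elem == 0)
        dgy[st] = gy;
      else
        dgy[st] += gy;
    }
  }
  double J = gamma * E + D;
  if (!want_grad)
    return List::create(_["value"] = J, _["energy"] = E, _["fidelity"] = D);

  cube grad(N, 3, T, arma::fill::zeros);
  mat px(3, N, arma::fill::zeros), py(3, P, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    if (dgy[t + 1].n_elem) py += dgy[t + 1];
    const mat& X = Xs[t];
    const mat& Y = Ys[t];
    const mat& A = As[t];
    mat ga(3, N, arma::fill::zeros);
    mat px_new = px;
    mat py_new = py;
    for (int k = 0; k < N; ++k) {
      const double* xk = X.colptr(k);
      const double* ak = A.colptr(k);
      const double* pk = px.colptr(k);
      double ga0 = 0, ga1 = 0, ga2 = 0;
      double pxn0 = 0, pxn1 = 0, pxn2 = 0;
      for (int j = 0; j < N; ++j) {
        const double* xj = X.colptr(j);
        const double* aj = A.colptr(j);
        const double* pj = px.colptr(j);
        double w = std::exp(-sqd(xk, xj) * il2);
        ga0 += w * (pj[0] + gamma * 2.0 * aj[0]);
        ga1 += w * (pj[1] + gamma * 2.0 * aj[1]);
        ga2 += w * (pj[2] + gamma * 2.0 * aj[2]);
        double c1 = (pj[0] * ak[0] + pj[1] * ak[1] + pj[2] * ak[2]) +
                    (pk[0] * aj[0] + pk[1] * aj[1] + pk[2] * aj[2]);
        double c2 =
            gamma * 2.0 * (ak[0] * aj[0] + ak[1] * aj[1] + ak[2] * aj[2]);
        double cc = (c1 + c2) * w * (-2.0 * il2);
        pxn0 += cc * (xk[0] - xj[0]);
        pxn1 += cc * (xk[1] - xj[1]);
        pxn2 += cc * (xk[2] - xj[2]);
      }
      ga(0, k) += ga0;
      ga(1, k) += ga1;
      ga(2, k) += ga2;
      px_new(0, k) += pxn0;
      px_new(1, k) += pxn1;
      px_new(2, k) += pxn2;
    }
    for (int p = 0; p < P; ++p) {
      const double* yp = Y.colptr(p);
      const double* pp = py.colptr(p);
      double pyn0 = 0, pyn1 = 0, pyn2 = 0;
      for (int k = 0; k < N; ++k) {
        const double* xk = X.colptr(k);
        const double* ak = A.colptr(k);
        double w = std::exp(-sqd(xk, yp) * il2);
        ga(0, k) += w * pp[0];
        ga(1, k) += w * pp[1];
        ga(2, k) += w * pp[2];
        double pa = pp[0] * ak[0] + pp[1] * ak[1] + pp[2] * ak[2];
        double cc = pa * w * (-2.0 * il2);
        pyn0 += cc * (yp[0] - xk[0]);
        pyn1 += cc * (yp[1] - xk[1]);
        pyn2 += cc * (yp[2] - xk[2]);
        px_new(0, k) += cc * (xk[0] - yp[0]);
        px_new(1, k) += cc * (xk[1] - yp[1]);
        px_new(2, k) += cc * (xk[2] - yp[2]);
      }
      py_new(0, p) += pyn0;
      py_new(1, p) += pyn1;
      py_new(2, p) += pyn2;
    }
    grad.slice(t) = ga.t();
    px = px_new;
    py = py_new;
  }
  return List::create(_["value"] = J, _["energy"] = E, _["fidelity"] = D,
                      _["grad"] = grad);
}

// ------------------------------------------- point-to-triangle distances

// Closest squared distance from p to triangle (a, b, c) (Ericson's
// region-based closest-point construction).
static double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d] - a[d];
    ac[d] = c[d] - a[d];
    ap[d] = p[d] - a[d];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) return sqd(p, a);
  for (int d = 0; d < 3; ++d) bp[d] = p[d] - b[d];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) return sqd(p, b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double q[3] = {a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]};
    return sqd(p, q);
  }
  for (int d = 0; d < 3; ++d) cp[d] = p[d] - c[d];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) return sqd(p, c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double q[3] = {a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]};
    return sqd(p, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                   b[2] + w * (c[2] - b[2])};
    return sqd(p, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                 a[2] + ab[2] * v + ac[2] * w};
  return sqd(p, q);
}

// [[Rcpp::export]]
arma::vec cpp_min_dist(const arma::mat& points, const arma::mat& vertices,
                       const arma::imat& faces) {
  mat P = points.t(), V = vertices.t();
  const int np = P.n_cols, M = faces.n_rows;
  vec out(np);
  for (int p = 0; p < np; ++p) {
    const double* pp = P.colptr(p);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < M; ++f) {
      double d2v = pt_tri_d2(pp, V.colptr(faces(f, 0)), V.colptr(faces(f, 1)),
                             V.colptr(faces(f, 2)));
      if (d2v < best) best = d2v;
    }
    out(p) = std::sqrt(best);
  }
  return out;
}

// --------------------------------------------------------- voxelization

// Parity fill: cast a +z ray through every (x,y) voxel-center column, collect
// triangle crossings, and mark voxel centers lying between crossing pairs.
// Ray origins are offset by tiny deterministic jitters to dodge edge hits;
// odd parity after all retries means the surface is not watertight.
// [[Rcpp::export]]
Rcpp::LogicalVector cpp_voxelize(const arma::mat& vertices,
                                 const arma::imat& faces,
                                 const arma::vec& origin,
                                 const arma::vec& spacing,
                                 const arma::ivec& dims) {
  mat V = vertices.t();
  const int M = faces.n_rows;
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  const double ox = origin(0), oy = origin(1), oz = origin(2);
  const double sx = spacing(0), sy = spacing(1), sz = spacing(2);
  const double jx[3] = {3.1e-5, -5.3e-5, 9.1e-5};
  const double jy[3] = {7.7e-5, 2.3e-5, -8.7e-5};

  LogicalVector out(nx * ny * nz);
  for (int attempt = 0; attempt < 3; ++attempt) {
    std::vector<std::vector<double>> cross(nx * ny);
    const double ex = jx[attempt] * sx, ey = jy[attempt] * sy;
    bool ok = true;
    for (int f = 0; f < M; ++f) {
      const double* a = V.colptr(faces(f, 0));
      const double* b = V.colptr(faces(f, 1));
      const double* c = V.colptr(faces(f, 2));
      double denom = (b[0] - a[0]) * (c[1] - a[1]) -
                     (b[1] - a[1]) * (c[0] - a[0]);
      if (std::fabs(denom) < 1e-14) continue;  // vertical face: no crossing
      double xmin = std::min(a[0], std::min(b[0], c[0]));
      double xmax = std::max(a[0], std::max(b[0], c[0]));
      double ymin = std::min(a[1], std::min(b[1], c[1]));
      double ymax = std::max(a[1], std::max(b[1], c[1]));
      int i0 = std::max(0, (int)std::ceil((xmin - ox - ex) / sx));
      int i1 = std::min(nx - 1, (int)std::floor((xmax - ox - ex) / sx));
      int j0 = std::max(0, (int)std::ceil((ymin - oy - ey) / sy));
      int j1 = std::min(ny - 1, (int)std::floor((ymax - oy - ey) / sy));
      for (int i = i0; i <= i1; ++i) {
        double px = ox + i * sx + ex;
        for (int j = j0; j <= j1; ++j) {
          double py = oy + j * sy + ey;
          double u = ((px - a[0]) * (c[1] - a[1]) -
                      (py - a[1]) * (c[0] - a[0])) / denom;
          double v = ((py - a[1]) * (b[0] - a[0]) -
                      (px - a[0]) * (b[1] - a[1])) / denom;
          if (u >= 0.0 && v >= 0.0 && u + v <= 1.0) {
            double z = a[2] + u * (b[2] - a[2]) + v * (c[2] - a[2]);
            cross[(size_t)j * nx + i].push_back(z);
          }
        }
      }
    }
    std::fill(out.begin(), out.end(), FALSE);
    for (int j = 0; j < ny && ok; ++j) {
      for (int i = 0; i < nx && ok; ++i) {
        std::vector<double>& zs = cross[(size_t)j * nx + i];
        if (zs.empty()) continue;
        if (zs.size() % 2 != 0) {
          ok = false;
          break;
        }
        std::sort(zs.begin(), zs.end());
        for (size_t s = 0; s + 1 < zs.size(); s += 2) {
          int k0 = std::max(0, (int)std::ceil((zs[s] - oz) / sz));
          int k1 = std::min(nz - 1, (int)std::floor((zs[s + 1] - oz) / sz));
          for (int k = k0; k <= k1; ++k)
            out[(size_t)k * nx * ny + (size_t)j * nx + i] = TRUE;
        }
      }
    }
    if (ok) return out;
  }
  stop("voxelize: odd ray-crossing parity; surface is not watertight");
}

// ------------------------------------------------- connected components

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label_components(const Rcpp::LogicalVector& voxels,
                                         const arma::ivec& dims) {
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!voxels[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t qq = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
        if (voxels[qq] && lab[qq] == 0) {
          lab[qq] = cur;
          stack.push_back(qq);
        }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}
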