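// Element kernels for the pressurized-shell indentation solver.
//
// Conventions (package-wide): lengths in um, forces in uN, moduli and
// stresses in MPa.  1 MPa * um^2 = 1 uN, so stiffness comes out in
// uN/um = N/m without further conversion.
//
// Kinematics are total-Lagrangian with Green-Lagrange strain; the
// constitutive law is St. Venant-Kirchhoff (stress linear in E).  The
// 6-node wedge uses an assumed natural transverse-shear strain sampled
// at the in-plane centroid, which removes the transverse shear locking
// a fully integrated linear prism suffers at shell-like aspect ratios.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

typedef arma::mat::fixed<3, 3> mat33;
typedef arma::vec::fixed<3> vec3;

static inline mat33 skew(const vec3 &a) {
  mat33 s;
  s(0, 0) = 0;     s(0, 1) = -a(2); s(0, 2) = a(1);
  s(1, 0) = a(2);  s(1, 1) = 0;     s(1, 2) = -a(0);
  s(2, 0) = -a(1); s(2, 1) = a(0);  s(2, 2) = 0;
  return s;
}

// shape derivative matrix dN (3 x 6): rows d/dr, d/ds, d/dt
static void wedge_dN(double r, double s, double t, mat &dN) {
  double L1 = 1.0 - r - s;
  double a = (1.0 - t) / 2.0, b = (1.0 + t) / 2.0;
  dN(0, 0) = -a; dN(0, 1) = a;  dN(0, 2) = 0;  dN(0, 3) = -b; dN(0, 4) = b; dN(0, 5) = 0;
  dN(1, 0) = -a; dN(1, 1) = 0;  dN(1, 2) = a;  dN(1, 3) = -b; dN(1, 4) = 0; dN(1, 5) = b;
  dN(2, 0) = -L1 / 2.0; dN(2, 1) = -r / 2.0; dN(2, 2) = -s / 2.0;
  dN(2, 3) = L1 / 2.0;  dN(2, 4) = r / 2.0;  dN(2, 5) = s / 2.0;
}

// covariant strain B-matrix rows (Voigt rr, ss, tt, rs, rt, st,
// engineering shears) for all 18 dofs
static void bmat_cov(const mat &dN, const mat33 &g, arma::mat::fixed<6, 18> &B) {
  for (int a = 0; a < 6; ++a) {
    for (int i = 0; i < 3; ++i) {
      int c = 3 * a + i;
      B(0, c) = dN(0, a) * g(i, 0);
      B(1, c) = dN(1, a) * g(i, 1);
      B(2, c) = dN(2, a) * g(i, 2);
      B(3, c) = dN(0, a) * g(i, 1) + dN(1, a) * g(i, 0);
      B(4, c) = dN(0, a) * g(i, 2) + dN(2, a) * g(i, 0);
      B(5, c) = dN(1, a) * g(i, 2) + dN(2, a) * g(i, 1);
    }
  }
}

// congruence transform of a symmetric tensor in Voigt engineering form:
// out = Q^T A Q applied column-wise to B (6 x 18)
static inline void voigt_from_mat(const mat33 &A, arma::vec::fixed<6> &v) {
  v(0) = A(0, 0); v(1) = A(1, 1); v(2) = A(2, 2);
  v(3) = 2.0 * A(0, 1); v(4) = 2.0 * A(0, 2); v(5) = 2.0 * A(1, 2);
}

static inline void mat_from_voigt(const arma::vec::fixed<6> &v, mat33 &A) {
  A(0, 0) = v(0); A(1, 1) = v(1); A(2, 2) = v(2);
  A(0, 1) = A(1, 0) = v(3) / 2.0;
  A(0, 2) = A(2, 0) = v(4) / 2.0;
  A(1, 2) = A(2, 1) = v(5) / 2.0;
}

// [[Rcpp::export]]
List fem_wedge_assemble(const arma::mat &X, const arma::mat &U,
                        const arma::imat &elems, const arma::vec &Evec,
                        const arma::vec &nuvec, int law,
                        bool want_stress) {
  const int n = X.n_rows, m = elems.n_rows;
  vec f(3 * n, arma::fill::zeros);
  arma::ivec ti(m * 324), tj(m * 324);
  vec tv(m * 324, arma::fill::zeros);
  mat stress; // per element: 6 Cauchy comps + von Mises
  if (want_stress) stress.zeros(m, 7);

  // in-plane 3-point rule (degree 2), thickness 2-point Gauss
  const double gr[3] = {1.0 / 6.0, 2.0 / 3.0, 1.0 / 6.0};
  const double gs[3] = {1.0 / 6.0, 1.0 / 6.0, 2.0 / 3.0};
  const double gw = 1.0 / 6.0;
  const double gt[2] = {-0.577350269189626, 0.577350269189626};

  mat dN(3, 6), dNc(3, 6);
  arma::mat::fixed<6, 18> Bcov, Bloc;
  arma::mat::fixed<18, 18> Ke;
  arma::vec::fixed<18> fe;

  for (int e = 0; e < m; ++e) {
    arma::mat::fixed<3, 6> Xe, xe;
    for (int a = 0; a < 6; ++a) {
      int id = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe(i, a) = X(id, i);
        xe(i, a) = X(id, i) + U(id, i);
      }
    }
    double E = Evec(e), nu = nuvec(e);
    double G = E / (2.0 * (1.0 + nu));
    double Ebar = E / (1.0 - nu * nu);
    double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
    double mu = G;

    Ke.zeros();
    fe.zeros();
    mat33 sig_acc;
    sig_acc.zeros();
    double vol_acc = 0.0, detF_acc = 0.0;

    for (int ip = 0; ip < 3; ++ip) {
      for (int it = 0; it < 2; ++it) {
        wedge_dN(gr[ip], gs[ip], gt[it], dN);
        wedge_dN(1.0 / 3.0, 1.0 / 3.0, gt[it], dNc);

        mat33 J = Xe * dN.t();
        double detJ = arma::det(J);
        if (detJ <= 0.0) stop("degenerate wedge element (non-positive Jacobian)");
        mat33 invJ = arma::inv(J);
        mat33 g = xe * dN.t();

        // covariant Green-Lagrange strain
        mat33 Ecov = 0.5 * (g.t() * g - J.t() * J);
        bmat_cov(dN, g, Bcov);

        // assumed transverse shear: sample (r t) and (s t) at centroid
        mat33 Jc = Xe * dNc.t();
        mat33 gc = xe * dNc.t();
        mat33 Ecc = 0.5 * (gc.t() * gc - Jc.t() * Jc);
        Ecov(0, 2) = Ecov(2, 0) = Ecc(0, 2);
        Ecov(1, 2) = Ecov(2, 1) = Ecc(1, 2);
        arma::mat::fixed<6, 18> Bc;
        bmat_cov(dNc, gc, Bc);
        Bcov.row(4) = Bc.row(4);
        Bcov.row(5) = Bc.row(5);

        // local orthonormal shell frame from the reference metric
        vec3 nrm = arma::normalise(J.col(2));
        vec3 e1 = J.col(0) - arma::dot(J.col(0), nrm) * nrm;
        e1 = arma::normalise(e1);
        vec3 e2 = arma::cross(nrm, e1);
        mat33 R;
        R.col(0) = e1; R.col(1) = e2; R.col(2) = nrm;

        mat33 Q = invJ * R; // E_loc = Q^T Ecov Q
        mat33 Eloc = Q.t() * Ecov * Q;

        // transform B columns to the local frame
        arma::vec::fixed<6> col6;
        mat33 tmp;
        for (int c = 0; c < 18; ++c) {
          col6 = Bcov.col(c);
          mat_from_voigt(col6, tmp);
          mat33 out = Q.t() * tmp * Q;
          voigt_from_mat(out, col6);
          Bloc.col(c) = col6;
        }

        // constitutive response in the local frame
        arma::mat::fixed<6, 6> C;
        C.zeros();
        arma::vec::fixed<6> Ev, Sv;
        voigt_from_mat(Eloc, Ev); // engineering shear storage
        if (law == 0) {
          // shell-consistent law: plane-stress in-plane block,
          // uncoupled thickness modulus, transverse shear G
          C(0, 0) = Ebar; C(1, 1) = Ebar; C(0, 1) = C(1, 0) = Ebar * nu;
          C(2, 2) = E;
          C(3, 3) = G; C(4, 4) = G; C(5, 5) = G;
        } else {
          C(0, 0) = C(1, 1) = C(2, 2) = lam + 2.0 * mu;
          C(0, 1) = C(0, 2) = C(1, 0) = C(1, 2) = C(2, 0) = C(2, 1) = lam;
          C(3, 3) = C(4, 4) = C(5, 5) = mu;
        }
        Sv = C * Ev;
        mat33 Sloc;
        Sloc(0, 0) = Sv(0); Sloc(1, 1) = Sv(1); Sloc(2, 2) = Sv(2);
        Sloc(0, 1) = Sloc(1, 0) = Sv(3);
        Sloc(0, 2) = Sloc(2, 0) = Sv(4);
        Sloc(1, 2) = Sloc(2, 1) = Sv(5);

        double w = gw * detJ;
        fe += w * (Bloc.t() * Sv);
        Ke += w * (Bloc.t() * C * Bloc);

        // geometric stiffness from the convected stress components
        mat33 Scart = R * Sloc * R.t();
        mat33 Sconv = invJ * Scart * invJ.t();
        for (int a = 0; a < 6; ++a) {
          for (int b = 0; b < 6; ++b) {
            double coef = 0.0;
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l)
                coef += Sconv(k, l) * dN(k, a) * dN(l, b);
            coef *= w;
            Ke(3 * a, 3 * b) += coef;
            Ke(3 * a + 1, 3 * b + 1) += coef;
            Ke(3 * a + 2, 3 * b + 2) += coef;
          }
        }

        if (want_stress) {
          mat33 F = g * invJ; // F(i,j) = sum_k g(i,k) dxi_k/dX_j
          double detF = arma::det(F);
          mat33 cau = (F * Scart * F.t()) / detF;
          sig_acc += w * cau;
          detF_acc += w * detF;
          vol_acc += w;
        }
      }
    }

    // scatter
    int base = e * 324, p = 0;
    for (int a = 0; a < 6; ++a) {
      int ia = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) f(3 * ia + i) += fe(3 * a + i);
    }
    for (int a = 0; a < 6; ++a) {
      int ia = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        int row = 3 * ia + i;
        for (int b = 0; b < 6; ++b) {
          int ib = elems(e, b) - 1;
          for (int j = 0; j < 3; ++j) {
            ti(base + p) = row + 1;
            tj(base + p) = 3 * ib + j + 1;
            tv(base + p) = Ke(3 * a + i, 3 * b + j);
            ++p;
          }
        }
      }
    }
    if (want_stress) {
      mat33 cau = sig_acc / vol_acc;
      stress(e, 0) = cau(0, 0); stress(e, 1) = cau(1, 1); stress(e, 2) = cau(2, 2);
      stress(e, 3) = cau(0, 1); stress(e, 4) = cau(0, 2); stress(e, 5) = cau(1, 2);
      double sx = cau(0, 0), sy = cau(1, 1), sz = cau(2, 2);
      double vm = std::sqrt(0.5 * ((sx - sy) * (sx - sy) + (sy - sz) * (sy - sz) +
                                   (sz - sx) * (sz - sx)) +
                            3.0 * (cau(0, 1) * cau(0, 1) + cau(0, 2) * cau(0, 2) +
                                   cau(1, 2) * cau(1, 2)));
      stress(e, 6) = vm;
    }
  }

  List out = List::create(_["f"] = f, _["i"] = ti, _["j"] = tj, _["v"] = tv);
  if (want_stress) out["stress"] = stress;
  return out;
}

// St. Venant-Kirchhoff membrane triangle (plane stress, no bending)
// [[Rcpp::export]]
List fem_membrane_assemble(const arma::mat &X, const arma::mat &U,
                           const arma::imat &tris, double h, double E,
                           double nu) {
  const int n = X.n_rows, m = tris.n_rows;
  vec f(3 * n, arma::fill::zeros);
  arma::ivec ti(m * 81), tj(m * 81);
  vec tv(m * 81, arma::fill::zeros);

  double Ebar = E / (1.0 - nu * nu);
  double G = E / (2.0 * (1.0 + nu));
  arma::mat::fixed<3, 3> C;
  C.zeros();
  C(0, 0) = C(1, 1) = Ebar; C(0, 1) = C(1, 0) = Ebar * nu; C(2, 2) = G;

  for (int e = 0; e < m; ++e) {
    int i1 = tris(e, 0) - 1, i2 = tris(e, 1) - 1, i3 = tris(e, 2) - 1;
    vec3 X1 = X.row(i1).t(), X2 = X.row(i2).t(), X3 = X.row(i3).t();
    vec3 x1 = X1 + U.row(i1).t(), x2 = X2 + U.row(i2).t(), x3 = X3 + U.row(i3).t();

    vec3 D1 = X2 - X1, D2 = X3 - X1;
    vec3 nrm = arma::cross(D1, D2);
    double A2 = arma::norm(nrm); // 2 * area
    if (A2 <= 0) stop("degenerate membrane triangle");
    double Aref = A2 / 2.0;
    vec3 t1 = arma::normalise(D1);
    vec3 nn = nrm / A2;
    vec3 t2 = arma::cross(nn, t1);

    // reference in-plane edge matrix and its inverse
    double d11 = arma::dot(D1, t1), d12 = arma::dot(D2, t1);
    double d21 = 0.0, d22 = arma::dot(D2, t2);
    double det = d11 * d22 - d12 * d21;
    double a = d22 / det, bq = -d12 / det, c = -d21 / det, d = d11 / det;
    // nodal weight rows w_n (2): F = sum_n x_n w_n^T
    double W[3][2] = {{-a - c, -bq - d}, {a, bq}, {c, d}};

    // deformation gradient 3x2
    arma::mat::fixed<3, 2> F;
    F.zeros();
    vec3 xs[3] = {x1, x2, x3};
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i) {
        F(i, 0) += xs[nd](i) * W[nd][0];
        F(i, 1) += xs[nd](i) * W[nd][1];
      }
    arma::mat::fixed<2, 2> Cm = F.t() * F;
    arma::vec::fixed<3> Ev;
    Ev(0) = 0.5 * (Cm(0, 0) - 1.0);
    Ev(1) = 0.5 * (Cm(1, 1) - 1.0);
    Ev(2) = Cm(0, 1); // engineering shear 2E12
    arma::vec::fixed<3> Sv = C * Ev;

    // B (3 x 9)
    arma::mat::fixed<3, 9> B;
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i) {
        int cdof = 3 * nd + i;
        B(0, cdof) = F(i, 0) * W[nd][0];
        B(1, cdof) = F(i, 1) * W[nd][1];
        B(2, cdof) = F(i, 0) * W[nd][1] + F(i, 1) * W[nd][0];
      }

    double wv = h * Aref;
    arma::vec::fixed<9> fe = wv * (B.t() * Sv);
    arma::mat::fixed<9, 9> Ke = wv * (B.t() * C * B);
    arma::mat::fixed<2, 2> Sm;
    Sm(0, 0) = Sv(0); Sm(1, 1) = Sv(1); Sm(0, 1) = Sm(1, 0) = Sv(2);
    for (int nd = 0; nd < 3; ++nd)
      for (int md = 0; md < 3; ++md) {
        double coef = 0.0;
        for (int k = 0; k < 2; ++k)
          for (int l = 0; l < 2; ++l) coef += W[nd][k] * Sm(k, l) * W[md][l];
        coef *= wv;
        Ke(3 * nd, 3 * md) += coef;
        Ke(3 * nd + 1, 3 * md + 1) += coef;
        Ke(3 * nd + 2, 3 * md + 2) += coef;
      }

    int ids[3] = {i1, i2, i3};
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i) f(3 * ids[nd] + i) += fe(3 * nd + i);
    int base = e * 81, p = 0;
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i)
        for (int md = 0; md < 3; ++md)
          for (int j = 0; j < 3; ++j) {
            ti(base + p) = 3 * ids[nd] + i + 1;
            tj(base + p) = 3 * ids[md] + j + 1;
            tv(base + p) = Ke(3 * nd + i, 3 * md + j);
            ++p;
          }
  }
  return List::create(_["f"] = f, _["i"] = ti, _["j"] = tj, _["v"] = tv);
}

// follower pressure on oriented triangles of the current surface;
// returns nodal forces (pushing along the triangle normal for P > 0)
// and the (unsymmetric) load-stiffness triplets
// [[Rcpp::export]]
List fem_pressure_assemble(const arma::mat &X, const arma::mat &U,
                           const arma::imat &tris, double P) {
  const int n = X.n_rows, m = tris.n_rows;
  vec f(3 * n, arma::fill::zeros);
  arma::ivec ti(m * 81), tj(m * 81);
  vec tv(m * 81, arma::fill::zeros);

  for (int e = 0; e < m; ++e) {
    int ids[3] = {(int)tris(e, 0) - 1, (int)tris(e, 1) - 1, (int)tris(e, 2) - 1};
    vec3 x1 = X.row(ids[0]).t() + U.row(ids[0]).t();
    vec3 x2 = X.row(ids[1]).t() + U.row(ids[1]).t();
    vec3 x3 = X.row(ids[2]).t() + U.row(ids[2]).t();
    vec3 e21 = x2 - x1, e31 = x3 - x1;
    vec3 cr = arma::cross(e21, e31);
    vec3 fn = (P / 6.0) * cr;
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i) f(3 * ids[nd] + i) += fn(i);

    mat33 D[3];
    D[0] = skew(e31) - skew(e21);
    D[1] = -skew(e31);
    D[2] = skew(e21);
    int base = e * 81, p = 0;
    for (int nd = 0; nd < 3; ++nd)
      for (int i = 0; i < 3; ++i)
        for (int md = 0; md < 3; ++md)
          for (int j = 0; j < 3; ++j) {
            ti(base + p) = 3 * ids[nd] + i + 1;
            tj(base + p) = 3 * ids[md] + j + 1;
            tv(base + p) = (P / 6.0) * D[md](i, j);
            ++p;
          }
  }
  return List::create(_["f"] = f, _["i"] = ti, _["j"] = tj, _["v"] = tv);
}

// signed volume enclosed by an oriented triangulated surface
// [[Rcpp::export]]
double fem_enclosed_volume(const arma::mat &X, const arma::mat &U,
                           const arma::imat &tris) {
  double V = 0.0;
  for (arma::uword e = 0; e < tris.n_rows; ++e) {
    vec3 x1 = X.row(tris(e, 0) - 1).t() + U.row(tris(e, 0) - 1).t();
    vec3 x2 = X.row(tris(e, 1) - 1).t() + U.row(tris(e, 1) - 1).t();
    vec3 x3 = X.row(tris(e, 2) - 1).t() + U.row(tris(e, 2) - 1).t();
    V += arma::dot(x1, arma::cross(x2, x3)) / 6.0;
  }
  return V;
}
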