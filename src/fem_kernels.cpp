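// Finite-strain kernels: constitutive point evaluation (four-term
// Holzapfel-Gasser-Ogden with isochoric/volumetric split; compressible
// neo-Hookean as the degenerate fiber-free case) and updated-Lagrangian
// assembly over tri-linear hexahedra with a mean-dilatation (Q1/P0)
// treatment of the volumetric term and a follower endocardial pressure
// with its load stiffness.
//
// Units throughout: mm - kPa - mN (1 kPa x mm^2 = 1 mN).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using namespace arma;

static const double GP1 = 0.5773502691896257645;

// corner signs, VTK hexahedron ordering
static const int SG[8][3] = {
  {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
  {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}};

// tri-linear shape functions and parametric derivatives at Gauss point q
// (Gauss points ordered like the corners: xi_q = SG[q] * 1/sqrt(3))
static void hex_shape(int q, vec &N, mat &dN) {
  const double xi = SG[q][0]*GP1, eta = SG[q][1]*GP1, ze = SG[q][2]*GP1;
  for (int a = 0; a < 8; ++a) {
    const double sx = SG[a][0], sy = SG[a][1], sz = SG[a][2];
    N(a)    = 0.125*(1.0+sx*xi)*(1.0+sy*eta)*(1.0+sz*ze);
    dN(a,0) = 0.125*sx*(1.0+sy*eta)*(1.0+sz*ze);
    dN(a,1) = 0.125*(1.0+sx*xi)*sy*(1.0+sz*ze);
    dN(a,2) = 0.125*(1.0+sx*xi)*(1.0+sy*eta)*sz;
  }
}

// Isochoric part of the response at one material point.
// prm = (a, b, a_f, b_f, a_s, b_s, a_fs, b_fs, kappa); only the first eight
// are used here, kappa belongs to the volumetric term handled by the caller.
// Returns 0 on success, 1 if det F <= 0.
// sig_iso: isochoric (traceless) Cauchy stress.
// ct: spatial tangent of the isochoric stress in Cauchy measure
//     (Kirchhoff-measure tensor divided by J), minor-symmetric.
static int point_eval(const mat &F, const double *prm,
                      const vec &f0, const vec &s0, bool wantTan,
                      double &J, double &psi, mat &sig_iso,
                      double ct[3][3][3][3]) {
  J = det(F);
  if (!(J > 0.0)) return 1;
  const double Jm13 = std::pow(J, -1.0/3.0);
  const mat Fb = Jm13 * F;
  const mat bb = Fb * Fb.t();
  const double I1 = trace(bb);
  const vec fb = Fb * f0, sb = Fb * s0;
  const double I4f = dot(fb, fb), I4s = dot(sb, sb), I8 = dot(fb, sb);
  const double a = prm[0], b = prm[1], af = prm[2], bf = prm[3],
               as_ = prm[4], bs = prm[5], afs = prm[6], bfs = prm[7];

  const double e1  = std::exp(b*(I1-3.0));
  const double p1  = 0.5*a*e1;
  const double p11 = 0.5*a*b*e1;
  psi = (b > 1e-12) ? a/(2.0*b)*(e1-1.0) : 0.5*a*(I1-3.0);

  double p4f = 0.0, p44f = 0.0, p4s = 0.0, p44s = 0.0, p8 = 0.0, p88 = 0.0;
  if (af > 0.0 && I4f > 1.0) {            // fibers carry tension only
    const double x = I4f-1.0, e = std::exp(bf*x*x);
    p4f  = af*x*e;
    p44f = af*(1.0+2.0*bf*x*x)*e;
    psi += (bf > 1e-12) ? af/(2.0*bf)*(e-1.0) : 0.5*af*x*x;
  }
  if (as_ > 0.0 && I4s > 1.0) {
    const double x = I4s-1.0, e = std::exp(bs*x*x);
    p4s  = as_*x*e;
    p44s = as_*(1.0+2.0*bs*x*x)*e;
    psi += (bs > 1e-12) ? as_/(2.0*bs)*(e-1.0) : 0.5*as_*x*x;
  }
  if (afs > 0.0) {
    const double e = std::exp(bfs*I8*I8);
    p8  = afs*I8*e;
    p88 = afs*(1.0+2.0*bfs*I8*I8)*e;
    psi += (bfs > 1e-12) ? afs/(2.0*bfs)*(e-1.0) : 0.5*afs*I8*I8;
  }

  const mat I3 = eye(3,3);
  const mat Ff = fb*fb.t(), Fs = sb*sb.t();
  const mat H  = fb*sb.t() + sb*fb.t();
  const mat tau  = 2.0*p1*bb + 2.0*p4f*Ff + 2.0*p4s*Fs + p8*H;
  const double trt = trace(tau);
  const mat tiso = tau - (trt/3.0)*I3;
  sig_iso = tiso / J;

  if (wantTan) {
    // P : ctilde : P collapses to dyads of deviatoric pushed structure
    // tensors because ctilde is a sum of rank-one products of symmetric
    // second-order tensors.
    const mat dbb = bb - (I1/3.0)*I3;
    const mat dFf = Ff - (trace(Ff)/3.0)*I3;
    const mat dFs = Fs - (trace(Fs)/3.0)*I3;
    const mat dH  = H  - (trace(H)/3.0)*I3;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) {
            double v = 4.0*p11*dbb(i,j)*dbb(k,l)
                     + 4.0*p44f*dFf(i,j)*dFf(k,l)
                     + 4.0*p44s*dFs(i,j)*dFs(k,l)
                     +     p88*dH(i,j)*dH(k,l)
                     + (2.0/3.0)*trt*(0.5*((i==k)*(j==l)+(i==l)*(j==k))
                                      - (1.0/3.0)*(i==j)*(k==l))
                     - (2.0/3.0)*(tiso(i,j)*(k==l) + (i==j)*tiso(k,l));
            ct[i][j][k][l] = v / J;
          }
  }
  return 0;
}

//' @noRd
// [[Rcpp::export]]
List cpp_point_stress(const arma::mat &F, const arma::vec &prm,
                      const arma::vec &f0, const arma::vec &s0) {
  double J, psi;
  mat sig_iso(3,3);
  double ct[3][3][3][3];
  if (point_eval(F, prm.memptr(), f0, s0, false, J, psi, sig_iso, ct))
    stop("deformation gradient has non-positive determinant (inverted state)");
  const double kappa = prm(8);
  const double p = kappa*(J-1.0);
  mat sig = sig_iso + p*eye(3,3);
  const double psiv = 0.5*kappa*(J-1.0)*(J-1.0);
  return List::create(_["sigma"] = sig, _["sigma_iso"] = sig_iso,
                      _["J"] = J, _["psi"] = psi + psiv,
                      _["psi_iso"] = psi, _["psi_vol"] = psiv);
}

static inline mat skew3(const vec &v) {
  mat S(3,3, fill::zeros);
  S(0,1) = -v(2); S(0,2) =  v(1);
  S(1,0) =  v(2); S(1,2) = -v(0);
  S(2,0) = -v(1); S(2,1) =  v(0);
  return S;
}

// Residual, tangent triplets, energies and volumes for the whole mesh.
// X: reference coordinates (n x 3); U: displacements (n x 3)
// elems: 1-based connectivity (ne x 8); prm: per-element material row (ne x 9)
// f0m, s0m: per-quadrature-point structural vectors, row index e*8+q ((ne*8) x 3)
// pfaces: 1-based pressure-face connectivity (nfa x 4), oriented so that
//         t_xi x t_eta points from the cavity into the wall
// pload: pressure magnitude (kPa); wantK: assemble tangent triplets
// [[Rcpp::export]]
List cpp_assemble(const arma::mat &X, const arma::mat &U,
                  const arma::imat &elems, const arma::mat &prm,
                  const arma::mat &f0m, const arma::mat &s0m,
                  const arma::imat &pfaces, double pload, bool wantK) {
  const int n = X.n_rows, ne = elems.n_rows, nfa = pfaces.n_rows;
  vec fint(3*n, fill::zeros), fext(3*n, fill::zeros);
  double energy = 0.0, vref = 0.0, vcur = 0.0, minJ = datum::inf;

  std::vector<int> Ti, Tj;
  std::vector<double> Tx;
  if (wantK) { size_t cap = (size_t)ne*576 + (size_t)nfa*144;
               Ti.reserve(cap); Tj.reserve(cap); Tx.reserve(cap); }

  vec N(8); mat dN(8,3);
  // per-qp scratch
  mat g[8], sig[8];
  double ctq[8][3][3][3][3];
  double wj[8], wj0[8], psiq[8];

  for (int e = 0; e < ne; ++e) {
    mat Xe(8,3), xe(8,3);
    uvec nd(8);
    for (int a = 0; a < 8; ++a) {
      nd(a) = elems(e,a) - 1;
      Xe.row(a) = X.row(nd(a));
      xe.row(a) = X.row(nd(a)) + U.row(nd(a));
    }
    double prow[9];
    for (int c = 0; c < 9; ++c) prow[c] = prm(e,c);
    const double kappa = prow[8];

    double Ve = 0.0, ve = 0.0;
    mat se(8,3, fill::zeros);   // s_a = int grad_x N_a dv (current)
    bool bad = false;

    for (int q = 0; q < 8; ++q) {
      hex_shape(q, N, dN);
      mat J0 = Xe.t() * dN;            // dX/dxi
      mat Jc = xe.t() * dN;            // dx/dxi
      const double dJ0 = det(J0), dJc = det(Jc);
      if (!(dJ0 > 0.0) || !(dJc > 0.0)) { bad = true; break; }
      mat gq = dN * inv(Jc);           // rows: grad_x N_a
      mat F  = Jc * inv(J0);
      double Jq, psi;
      mat si(3,3);
      vec f0 = f0m.row(e*8+q).t(), s0 = s0m.row(e*8+q).t();
      if (point_eval(F, prow, f0, s0, wantK, Jq, psi, si, ctq[q]))
        { bad = true; break; }
      if (Jq < minJ) minJ = Jq;
      g[q] = gq; sig[q] = si;
      wj[q] = dJc; wj0[q] = dJ0; psiq[q] = psi;
      Ve += dJ0; ve += dJc;
      se += gq * dJc;
    }
    if (bad)
      return List::create(_["ok"] = false, _["elem"] = e + 1);

    const double Jbar = ve / Ve;
    const double pbar = kappa*(Jbar-1.0);
    vref += Ve; vcur += ve;
    for (int q = 0; q < 8; ++q) energy += psiq[q]*wj0[q];
    energy += 0.5*kappa*(Jbar-1.0)*(Jbar-1.0)*Ve;

    // internal force
    for (int q = 0; q < 8; ++q) {
      mat sfull = sig[q] + pbar*eye(3,3);
      mat fa = g[q] * sfull * wj[q];   // 8 x 3 : rows f_a
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          fint(3*nd(a)+i) += fa(a,i);
    }

    if (wantK) {
      double Ke[24][24];
      std::memset(Ke, 0, sizeof(Ke));
      for (int q = 0; q < 8; ++q) {
        const double w = wj[q];
        double g8[8][3];
        for (int a = 0; a < 8; ++a)
          for (int j = 0; j < 3; ++j) g8[a][j] = g[q](a,j);
        double sfull[3][3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            sfull[i][j] = sig[q](i,j) + ((i==j) ? pbar : 0.0);
        // node-pair scalars
        double dg[8][8], geo[8][8], sv[8][3];
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            sv[a][i] = sfull[i][0]*g8[a][0] + sfull[i][1]*g8[a][1]
                     + sfull[i][2]*g8[a][2];
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            dg[a][b] = g8[a][0]*g8[b][0] + g8[a][1]*g8[b][1] + g8[a][2]*g8[b][2];
            geo[a][b] = g8[a][0]*sv[b][0] + g8[a][1]*sv[b][1] + g8[a][2]*sv[b][2];
          }
        // T[a][i][k][l] = sum_j g8[a][j] ct[i][j][k][l]
        double T[8][3][3][3];
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l)
                T[a][i][k][l] = g8[a][0]*ctq[q][i][0][k][l]
                              + g8[a][1]*ctq[q][i][1][k][l]
                              + g8[a][2]*ctq[q][i][2][k][l];
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b)
            for (int i = 0; i < 3; ++i)
              for (int k = 0; k < 3; ++k) {
                double v = T[a][i][k][0]*g8[b][0] + T[a][i][k][1]*g8[b][1]
                         + T[a][i][k][2]*g8[b][2];
                v += pbar * (g8[a][i]*g8[b][k] - g8[a][k]*g8[b][i]
                             - ((i==k) ? dg[a][b] : 0.0));
                if (i == k) v += geo[a][b];
                Ke[3*a+i][3*b+k] += v * w;
              }
      }
      // dilatational coupling: dpbar = (kappa/Ve) dv
      const double kV = kappa / Ve;
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          for (int i = 0; i < 3; ++i)
            for (int k = 0; k < 3; ++k)
              Ke[3*a+i][3*b+k] += kV * se(a,i) * se(b,k);

      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 8; ++b)
            for (int k = 0; k < 3; ++k) {
              Ti.push_back(3*nd(a)+i+1);
              Tj.push_back(3*nd(b)+k+1);
              Tx.push_back(Ke[3*a+i][3*b+k]);
            }
    }
  }

  // follower pressure on faces (bilinear quads, 2x2 Gauss)
  if (nfa > 0 && pload != 0.0) {
    const double gp[2] = {-GP1, GP1};
    for (int f = 0; f < nfa; ++f) {
      uvec nd(4);
      mat xf(4,3);
      for (int a = 0; a < 4; ++a) {
        nd(a) = pfaces(f,a) - 1;
        xf.row(a) = X.row(nd(a)) + U.row(nd(a));
      }
      for (int qa = 0; qa < 2; ++qa)
        for (int qb = 0; qb < 2; ++qb) {
          const double xi = gp[qa], eta = gp[qb];
          vec N4(4); mat dN4(4,2);
          const int s4[4][2] = {{-1,-1},{1,-1},{1,1},{-1,1}};
          for (int a = 0; a < 4; ++a) {
            N4(a)    = 0.25*(1.0+s4[a][0]*xi)*(1.0+s4[a][1]*eta);
            dN4(a,0) = 0.25*s4[a][0]*(1.0+s4[a][1]*eta);
            dN4(a,1) = 0.25*(1.0+s4[a][0]*xi)*s4[a][1];
          }
          vec t1 = xf.t()*dN4.col(0), t2 = xf.t()*dN4.col(1);
          vec nda = cross(t1, t2);     // area-weighted normal (into the wall)
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i)
              fext(3*nd(a)+i) += pload * N4(a) * nda(i);
          if (wantK) {
            // d fext_a = pload N_a [ -skew(t2) dN_b,xi + skew(t1) dN_b,eta ] du_b
            mat S1 = skew3(t1), S2 = skew3(t2);
            for (int a = 0; a < 4; ++a)
              for (int b = 0; b < 4; ++b) {
                mat M = pload * N4(a) * (-dN4(b,0)*S2 + dN4(b,1)*S1);
                for (int i = 0; i < 3; ++i)
                  for (int k = 0; k < 3; ++k) {
                    // residual R = fint - fext  =>  K -= d fext / du
                    Ti.push_back(3*nd(a)+i+1);
                    Tj.push_back(3*nd(b)+k+1);
                    Tx.push_back(-M(i,k));
                  }
              }
          }
        }
    }
  }

  List out = List::create(_["ok"] = true, _["fint"] = fint, _["fext"] = fext,
                          _["energy"] = energy, _["vol_ref"] = vref,
                          _["vol_cur"] = vcur, _["minJ"] = minJ);
  if (wantK) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// Per-element volume-averaged Cauchy stress (mean-dilatation pressure
// included), reference/current volumes and mean J.
// [[Rcpp::export]]
List cpp_element_fields(const arma::mat &X, const arma::mat &U,
                        const arma::imat &elems, const arma::mat &prm,
                        const arma::mat &f0m, const arma::mat &s0m) {
  const int ne = elems.n_rows;
  mat sigv(ne, 6, fill::zeros);   // xx yy zz xy xz yz
  vec vr(ne), vc(ne), jb(ne), psie(ne);
  vec N(8); mat dN(8,3);
  for (int e = 0; e < ne; ++e) {
    mat Xe(8,3), xe(8,3);
    for (int a = 0; a < 8; ++a) {
      int nd = elems(e,a) - 1;
      Xe.row(a) = X.row(nd);
      xe.row(a) = X.row(nd) + U.row(nd);
    }
    double prow[9];
    for (int c = 0; c < 9; ++c) prow[c] = prm(e,c);
    double Ve = 0.0, ve = 0.0, pe = 0.0;
    mat sacc(3,3, fill::zeros);
    mat siso[8]; double wjq[8];
    double ct[3][3][3][3];
    for (int q = 0; q < 8; ++q) {
      hex_shape(q, N, dN);
      mat J0 = Xe.t()*dN, Jc = xe.t()*dN;
      double dJ0 = det(J0), dJc = det(Jc);
      mat F = Jc*inv(J0);
      double Jq, psi; mat si(3,3);
      vec f0 = f0m.row(e*8+q).t(), s0 = s0m.row(e*8+q).t();
      if (point_eval(F, prow, f0, s0, false, Jq, psi, si, ct))
        stop("inverted element in stress recovery");
      siso[q] = si; wjq[q] = dJc;
      Ve += dJ0; ve += dJc; pe += psi*dJ0;
    }
    double Jbar = ve/Ve, pbar = prow[8]*(Jbar-1.0);
    for (int q = 0; q < 8; ++q)
      sacc += (siso[q] + pbar*eye(3,3)) * wjq[q];
    sacc /= ve;
    sigv(e,0)=sacc(0,0); sigv(e,1)=sacc(1,1); sigv(e,2)=sacc(2,2);
    sigv(e,3)=sacc(0,1); sigv(e,4)=sacc(0,2); sigv(e,5)=sacc(1,2);
    vr(e)=Ve; vc(e)=ve; jb(e)=Jbar;
    psie(e)= pe + 0.5*prow[8]*(Jbar-1.0)*(Jbar-1.0)*Ve;
  }
  return List::create(_["sigma"]=sigv, _["vol_ref"]=vr, _["vol_cur"]=vc,
                      _["Jbar"]=jb, _["energy"]=psie);
}
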