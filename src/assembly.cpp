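// Finite-element kernels for the NE shell mechanics and surface evaluation.
//
// Shell mechanics: 10-node (P2) isoparametric tetrahedra for displacement,
// P1 vertex pressure, perturbed-Lagrangian incompressible Mooney-Rivlin
// (W = Escale*(E1*(I1-3) + E2*(I2-3)) - p*(J-1), pressure equation
// phi0*(J-1) + p = 0 in L2-projected form). Volume tangent is analytic
// (directional derivatives); follower surface loads (osmotic pressure, cap
// stress, pillar repulsion) use forward-difference tangents per facet.
// Nucleoplasm extension: P1 compressible neo-Hookean.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ----- quadrature -------------------------------------------------------
// 27-point collapsed Gauss-Jacobi rule on the reference tetrahedron,
// exact for total degree 5; weights sum to 1/6. Barycentric l1,l2,l3
// (l4 = 1 - l1 - l2 - l3).
static const int NQ = 27;
static const double QL1[NQ] = {0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.7050022098884984,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.3470037660383524,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500,0.0729940240731500};
static const double QL2[NQ] = {0.2323578005798647,0.2323578005798647,0.2323578005798647,0.1207918201339027,0.1207918201339027,0.1207918201339027,0.0261332522867350,0.0261332522867350,0.0261332522867350,0.5143386621740915,0.5143386621740915,0.5143386621740915,0.2673803204118845,0.2673803204118845,0.2673803204118845,0.0578476039361429,0.0578476039361429,0.0578476039361429,0.7301650280476314,0.7301650280476314,0.7301650280476314,0.3795782302805909,0.3795782302805909,0.3795782302805909,0.0821215678634428,0.0821215678634428,0.0821215678634428};
static const double QL3[NQ] = {0.0555803583920822,0.0313199947658185,0.0070596311395548,0.1545726670421145,0.0871029849887996,0.0196333029354846,0.2385630566504909,0.1344322689123834,0.0303014811742759,0.1230306325296545,0.0693287858937781,0.0156269392579017,0.3421563578959607,0.1928079567748817,0.0434595556538026,0.5280743882734463,0.2975743150127526,0.0670742417520588,0.1746566452383989,0.0984204739396094,0.0221843026408198,0.4857317270371128,0.2737138728231298,0.0616960186091468,0.7496645282216924,0.4224422040317040,0.0952198798417154};
static const double QW[NQ]  = {0.0005809353158374,0.0009294965053398,0.0005809353158374,0.0019072034149818,0.0030515254639708,0.0019072034149818,0.0016716811314837,0.0026746898103739,0.0016716811314837,0.0028366486956309,0.0045386379130095,0.0028366486956309,0.0093126823794704,0.0149002918071526,0.0093126823794704,0.0081626507665467,0.0130602412264747,0.0081626507665467,0.0030478770905182,0.0048766033448291,0.0030478770905182,0.0100061425721761,0.0160098281154818,0.0100061425721761,0.0087704749296511,0.0140327598874417,0.0087704749296511};

// Dunavant degree-4 rule on the reference triangle (weights sum to 1).
static const int NQF = 6;
static const double FQA[NQF] = {0.445948490915965,0.445948490915965,0.108103018168070,
                                0.091576213509771,0.091576213509771,0.816847572980459};
static const double FQB[NQF] = {0.445948490915965,0.108103018168070,0.445948490915965,
                                0.091576213509771,0.816847572980459,0.091576213509771};
static const double FQW[NQF] = {0.223381589678011,0.223381589678011,0.223381589678011,
                                0.109951743655322,0.109951743655322,0.109951743655322};

// ----- P2 tetrahedron shape functions -----------------------------------
// node order: v1..v4, then edges (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
static void p2_shape(const double l[4], double N[10]) {
  N[0] = l[0]*(2*l[0]-1); N[1] = l[1]*(2*l[1]-1);
  N[2] = l[2]*(2*l[2]-1); N[3] = l[3]*(2*l[3]-1);
  N[4] = 4*l[0]*l[1]; N[5] = 4*l[0]*l[2]; N[6] = 4*l[0]*l[3];
  N[7] = 4*l[1]*l[2]; N[8] = 4*l[1]*l[3]; N[9] = 4*l[2]*l[3];
}
// gradient wrt xi = (l2,l3,l4); l1 = 1 - l2 - l3 - l4
static void p2_grad(const double l[4], double dN[10][3]) {
  for (int a = 0; a < 10; a++) for (int j = 0; j < 3; j++) dN[a][j] = 0.0;
  double d1 = 4*l[0]-1;
  for (int j = 0; j < 3; j++) dN[0][j] = -d1;
  dN[1][0] = 4*l[1]-1; dN[2][1] = 4*l[2]-1; dN[3][2] = 4*l[3]-1;
  // e12 = 4 l1 l2
  dN[4][0] = 4*(l[0]-l[1]); dN[4][1] = -4*l[1]; dN[4][2] = -4*l[1];
  // e13
  dN[5][0] = -4*l[2]; dN[5][1] = 4*(l[0]-l[2]); dN[5][2] = -4*l[2];
  // e14
  dN[6][0] = -4*l[3]; dN[6][1] = -4*l[3]; dN[6][2] = 4*(l[0]-l[3]);
  // e23
  dN[7][0] = 4*l[2]; dN[7][1] = 4*l[1];
  // e24
  dN[8][0] = 4*l[3]; dN[8][2] = 4*l[1];
  // e34
  dN[9][1] = 4*l[3]; dN[9][2] = 4*l[2];
}

// 6-node quadratic triangle, node order v1,v2,v3, e12, e23, e31
static void tri6_shape(double xi, double eta, double N[6]) {
  double l1 = 1-xi-eta, l2 = xi, l3 = eta;
  N[0] = l1*(2*l1-1); N[1] = l2*(2*l2-1); N[2] = l3*(2*l3-1);
  N[3] = 4*l1*l2; N[4] = 4*l2*l3; N[5] = 4*l3*l1;
}
static void tri6_grad(double xi, double eta, double dN[6][2]) {
  double l1 = 1-xi-eta, l2 = xi, l3 = eta;
  dN[0][0] = -(4*l1-1); dN[0][1] = -(4*l1-1);
  dN[1][0] = 4*l2-1;    dN[1][1] = 0;
  dN[2][0] = 0;         dN[2][1] = 4*l3-1;
  dN[3][0] = 4*(l1-l2); dN[3][1] = -4*l2;
  dN[4][0] = 4*l3;      dN[4][1] = 4*l2;
  dN[5][0] = -4*l3;     dN[5][1] = 4*(l1-l3);
}

// ----- small dense helpers ----------------------------------------------
static inline double det3(const double A[3][3]) {
  return A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
       - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
       + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
}
static inline void inv3(const double A[3][3], double Ai[3][3], double det) {
  double id = 1.0/det;
  Ai[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1])*id;
  Ai[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1])*id;
  Ai[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1])*id;
  Ai[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0])*id;
  Ai[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0])*id;
  Ai[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0])*id;
  Ai[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0])*id;
  Ai[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0])*id;
  Ai[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0])*id;
}

// cell geometry at one quadrature point: dNdX (10x3) and volume jacobian
static double cell_geom(const double Xc[10][3], const double l[4],
                        double dNdX[10][3]) {
  double dN[10][3];
  p2_grad(l, dN);
  double Jg[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  for (int a = 0; a < 10; a++)
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++)
        Jg[i][j] += Xc[a][i]*dN[a][j];
  double dJ = det3(Jg);
  double Ji[3][3];
  inv3(Jg, Ji, dJ);
  for (int a = 0; a < 10; a++)
    for (int i = 0; i < 3; i++) {
      dNdX[a][i] = 0.0;
      for (int j = 0; j < 3; j++) dNdX[a][i] += dN[a][j]*Ji[j][i];
    }
  return dJ;
}

// deformation gradient from local displacements (10x3) and dNdX
static void def_grad(const double uc[10][3], const double dNdX[10][3],
                     double F[3][3]) {
  for (int i = 0; i < 3; i++)
    for (int J = 0; J < 3; J++) {
      F[i][J] = (i == J) ? 1.0 : 0.0;
      for (int a = 0; a < 10; a++) F[i][J] += uc[a][i]*dNdX[a][J];
    }
}

// Mooney-Rivlin mixed stress, isochoric invariants: S (2nd PK).
// W = Es*(E1*(I1bar-3) + E2*(I2bar-3)) - p*(J-1),
// I1bar = J^(-2/3) I1, I2bar = J^(-4/3) I2. The deviatoric split keeps the
// reference state exactly stress-free; at incompressibility it coincides
// with the plain two-invariant form.
static void mr_stress(const double F[3][3], double p, double Es,
                      double E1, double E2,
                      double C[3][3], double Ci[3][3], double& J,
                      double S[3][3]) {
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      C[i][j] = 0.0;
      for (int k = 0; k < 3; k++) C[i][j] += F[k][i]*F[k][j];
    }
  J = det3(F);
  double detC = J*J;
  inv3(C, Ci, detC);
  double I1 = C[0][0]+C[1][1]+C[2][2];
  double trC2 = 0.0;
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) trC2 += C[i][j]*C[j][i];
  double I2 = 0.5*(I1*I1 - trC2);
  double a1 = std::pow(J, -2.0/3.0), a2 = a1*a1;
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double eye = (i==j)?1.0:0.0;
      double d1 = a1*(eye - (I1/3.0)*Ci[i][j]);
      double d2 = a2*(I1*eye - C[i][j] - (2.0*I2/3.0)*Ci[i][j]);
      S[i][j] = 2*Es*(E1*d1 + E2*d2) - p*J*Ci[i][j];
    }
}

// [[Rcpp::export]]
List mech_assemble_cpp(const arma::mat& Xp2, const arma::imat& cells10,
                       const arma::vec& u, const arma::vec& p,
                       const arma::vec& Escale,
                       double E1, double E2, double phi0, bool want_K) {
  const int nc = cells10.n_rows, np2 = Xp2.n_rows, nsv = p.n_elem;
  const int ndof_u = 3*np2;
  arma::vec Ru(ndof_u, arma::fill::zeros), Rp(nsv, arma::fill::zeros);
  double minJ = 1e30, vol_def = 0.0, vol_ref = 0.0;

  std::vector<int> Ti, Tj; std::vector<double> Tx;
  if (want_K) { size_t est = (size_t)nc*34*34; Ti.reserve(est); Tj.reserve(est); Tx.reserve(est); }

  double Xc[10][3], uc[10][3], dNdX[10][3];
  for (int c = 0; c < nc; c++) {
    int gid[10];
    for (int a = 0; a < 10; a++) {
      gid[a] = cells10(c, a) - 1;
      for (int i = 0; i < 3; i++) {
        Xc[a][i] = Xp2(gid[a], i);
        uc[a][i] = u[3*gid[a]+i];
      }
    }
    double Ke[34][34];
    if (want_K) for (int i = 0; i < 34; i++) for (int j = 0; j < 34; j++) Ke[i][j] = 0.0;

    for (int q = 0; q < NQ; q++) {
      double l[4] = {QL1[q], QL2[q], QL3[q], 1.0-QL1[q]-QL2[q]-QL3[q]};
      double dJg = cell_geom(Xc, l, dNdX);
      double w = QW[q]*dJg;   // QW sums to the 1/6 ref-tet measure
      double F[3][3], C[3][3], Ci[3][3], S[3][3], J;
      def_grad(uc, dNdX, F);
      double pq = 0.0, Es = 0.0;
      for (int a = 0; a < 4; a++) { pq += l[a]*p[gid[a]]; Es += l[a]*Escale[gid[a]]; }
      mr_stress(F, pq, Es, E1, E2, C, Ci, J, S);
      double I1 = C[0][0]+C[1][1]+C[2][2];
      double trC2 = 0.0;
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++) trC2 += C[i][j]*C[j][i];
      double I2 = 0.5*(I1*I1 - trC2);
      double a1 = std::pow(J, -2.0/3.0), a2 = a1*a1;
      if (J < minJ) minJ = J;
      vol_def += w*J; vol_ref += w;
      // first PK: P = F*S
      double PK[3][3];
      for (int i = 0; i < 3; i++)
        for (int Jj = 0; Jj < 3; Jj++) {
          PK[i][Jj] = 0.0;
          for (int M = 0; M < 3; M++) PK[i][Jj] += F[i][M]*S[M][Jj];
        }
      for (int a = 0; a < 10; a++)
        for (int i = 0; i < 3; i++) {
          double r = 0.0;
          for (int Jj = 0; Jj < 3; Jj++) r += dNdX[a][Jj]*PK[i][Jj];
          Ru[3*gid[a]+i] += w*r;
        }
      for (int a = 0; a < 4; a++)
        Rp[gid[a]] += w*l[a]*(phi0*(J-1.0)+pq);

      if (!want_K) continue;
      // inverse transpose of F
      double Fi[3][3], FiT[3][3];
      inv3(F, Fi, J);
      for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) FiT[i][j] = Fi[j][i];
      // directional derivatives over displacement dofs (b,k)
      for (int b = 0; b < 10; b++) {
        const double* g = dNdX[b];
        for (int k = 0; k < 3; k++) {
          double dC[3][3], dS[3][3], trdC;
          for (int P1_ = 0; P1_ < 3; P1_++)
            for (int Q = 0; Q < 3; Q++)
              dC[P1_][Q] = F[k][P1_]*g[Q] + F[k][Q]*g[P1_];
          trdC = dC[0][0]+dC[1][1]+dC[2][2];
          // dJ = (J/2) Ci:dC
          double CidC = 0.0;
          for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) CidC += Ci[i][j]*dC[i][j];
          double dJ = 0.5*J*CidC;
          // dCi = -Ci dC Ci
          double T1[3][3], dCi[3][3];
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++) {
              T1[i][j] = 0.0;
              for (int m = 0; m < 3; m++) T1[i][j] += Ci[i][m]*dC[m][j];
            }
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++) {
              dCi[i][j] = 0.0;
              for (int m = 0; m < 3; m++) dCi[i][j] -= T1[i][m]*Ci[m][j];
            }
          double trCdC = 0.0;
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++) trCdC += C[i][j]*dC[j][i];
          double dI1 = trdC, dI2 = I1*trdC - trCdC;
          double dlnJ = dJ/J;
          double da1 = -(2.0/3.0)*a1*dlnJ, da2 = -(4.0/3.0)*a2*dlnJ;
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++) {
              double eye = (i==j)?1.0:0.0;
              double dD1 = da1*(eye - (I1/3.0)*Ci[i][j])
                         + a1*(-(dI1/3.0)*Ci[i][j] - (I1/3.0)*dCi[i][j]);
              double dD2 = da2*(I1*eye - C[i][j] - (2.0*I2/3.0)*Ci[i][j])
                         + a2*(dI1*eye - dC[i][j] - (2.0*dI2/3.0)*Ci[i][j]
                               - (2.0*I2/3.0)*dCi[i][j]);
              dS[i][j] = 2*Es*(E1*dD1 + E2*dD2)
                       - pq*(dJ*Ci[i][j] + J*dCi[i][j]);
            }
          // dP = dF*S + F*dS ; dF has only row k = g
          double dP[3][3];
          for (int i = 0; i < 3; i++)
            for (int Jj = 0; Jj < 3; Jj++) {
              double v = 0.0;
              for (int M = 0; M < 3; M++) v += F[i][M]*dS[M][Jj];
              if (i == k) for (int M = 0; M < 3; M++) v += g[M]*S[M][Jj];
              dP[i][Jj] = v;
            }
          int col = 3*b+k;
          for (int a = 0; a < 10; a++)
            for (int i = 0; i < 3; i++) {
              double v = 0.0;
              for (int Jj = 0; Jj < 3; Jj++) v += dNdX[a][Jj]*dP[i][Jj];
              Ke[3*a+i][col] += w*v;
            }
          // pressure-equation row: phi0 * dJ weighted by shape
          for (int a = 0; a < 4; a++)
            Ke[30+a][col] += w*l[a]*phi0*dJ;
        }
      }
      // dP/dp = -J F^{-T} * lambda_b
      for (int b = 0; b < 4; b++) {
        int col = 30+b;
        for (int a = 0; a < 10; a++)
          for (int i = 0; i < 3; i++) {
            double v = 0.0;
            for (int Jj = 0; Jj < 3; Jj++) v += dNdX[a][Jj]*(-l[b]*J*FiT[i][Jj]);
            Ke[3*a+i][col] += w*v;
          }
        for (int a = 0; a < 4; a++)
          Ke[30+a][col] += w*l[a]*l[b];
      }
    }
    if (want_K) {
      int gdof[34];
      for (int a = 0; a < 10; a++)
        for (int i = 0; i < 3; i++) gdof[3*a+i] = 3*gid[a]+i;
      for (int a = 0; a < 4; a++) gdof[30+a] = ndof_u + gid[a];
      for (int r = 0; r < 34; r++)
        for (int s = 0; s < 34; s++)
          if (Ke[r][s] != 0.0) {
            Ti.push_back(gdof[r]); Tj.push_back(gdof[s]); Tx.push_back(Ke[r][s]);
          }
    }
  }
  List out = List::create(_["Ru"] = Ru, _["Rp"] = Rp, _["minJ"] = minJ,
                          _["vol_def"] = vol_def, _["vol_ref"] = vol_ref);
  if (want_K) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// [[Rcpp::export]]
List shell_measures_cpp(const arma::mat& Xp2, const arma::imat& cells10,
                        const arma::vec& u) {
  const int nc = cells10.n_rows;
  double minJ = 1e30, vol_def = 0.0, vol_ref = 0.0;
  double Xc[10][3], uc[10][3], dNdX[10][3];
  for (int c = 0; c < nc; c++) {
    for (int a = 0; a < 10; a++) {
      int g = cells10(c, a)-1;
      for (int i = 0; i < 3; i++) { Xc[a][i] = Xp2(g,i); uc[a][i] = u[3*g+i]; }
    }
    for (int q = 0; q < NQ; q++) {
      double l[4] = {QL1[q], QL2[q], QL3[q], 1.0-QL1[q]-QL2[q]-QL3[q]};
      double dJg = cell_geom(Xc, l, dNdX);
      double w = QW[q]*dJg;
      double F[3][3];
      def_grad(uc, dNdX, F);
      double J = det3(F);
      if (J < minJ) minJ = J;
      vol_def += w*J; vol_ref += w;
    }
  }
  return List::create(_["vol_ref"] = vol_ref, _["vol_def"] = vol_def,
                      _["minJ"] = minJ);
}

// smooth super-Gaussian pillar indicator (window of +-1 lattice cells; the
// super-Gaussian width (r_np + 0.05) is always far below the pitch)
static double h_smooth(double x, double y, double p_np, int n_np, double w4) {
  if (p_np <= 0 || n_np < 0) return 0.0;
  int ix = (int)std::lround(x/p_np), iy = (int)std::lround(y/p_np);
  double out = 0.0;
  for (int dx = -1; dx <= 1; dx++)
    for (int dy = -1; dy <= 1; dy++) {
      int jx = std::min(std::max(ix+dx, -n_np), n_np);
      int jy = std::min(std::max(iy+dy, -n_np), n_np);
      double r2 = (x-jx*p_np)*(x-jx*p_np) + (y-jy*p_np)*(y-jy*p_np);
      out += std::exp(-r2*r2/w4);
    }
  return out;
}

struct FacetCtx {
  double Xf[6][3];      // facet node reference coords
  double Xc[10][3];     // parent cell reference coords
  int fmap[6];          // facet node -> cell local node
  int lv[3];            // facet vertex -> cell local vertex (0..3)
};

// facet residual (18 entries: 6 nodes x 3) for one load type.
// The pillar-contact load (type 3) varies on the sub-facet scale of the
// super-Gaussian indicator, so it is integrated on a 4-fold uniform
// subdivision of the reference facet.
static void facet_residual(const FacetCtx& ctx, const double uc[10][3],
                           int type, const double* pars, double* R) {
  for (int i = 0; i < 18; i++) R[i] = 0.0;
  const int nsub = (type == 3) ? 2 : 1;   // nsub^2 congruent sub-triangles
  for (int sa = 0; sa < nsub; sa++)
  for (int sb = 0; sb < nsub - sa; sb++)
  for (int updown = 0; updown < ((sa + sb <= nsub - 2) ? 2 : 1); updown++)
  for (int q = 0; q < NQF; q++) {
    double xi0 = FQA[q], eta0 = FQB[q];
    double xi, eta, scale = 1.0 / (nsub * nsub);
    if (updown == 0) {
      xi = (sa + xi0) / nsub; eta = (sb + eta0) / nsub;
    } else {
      xi = (sa + 1 - xi0) / nsub; eta = (sb + 1 - eta0) / nsub;
    }
    double N[6], dN[6][2];
    tri6_shape(xi, eta, N);
    tri6_grad(xi, eta, dN);
    double T1[3] = {0,0,0}, T2[3] = {0,0,0};
    for (int a = 0; a < 6; a++)
      for (int i = 0; i < 3; i++) {
        T1[i] += ctx.Xf[a][i]*dN[a][0];
        T2[i] += ctx.Xf[a][i]*dN[a][1];
      }
    double Nt[3] = {T1[1]*T2[2]-T1[2]*T2[1], T1[2]*T2[0]-T1[0]*T2[2],
                    T1[0]*T2[1]-T1[1]*T2[0]};
    double dA = std::sqrt(Nt[0]*Nt[0]+Nt[1]*Nt[1]+Nt[2]*Nt[2]);
    double Nu[3] = {Nt[0]/dA, Nt[1]/dA, Nt[2]/dA};
    // deformed position and reference height at the quadrature point
    double xq[3] = {0,0,0}, Zq = 0.0;
    for (int a = 0; a < 6; a++) {
      Zq += N[a]*ctx.Xf[a][2];
      for (int i = 0; i < 3; i++)
        xq[i] += N[a]*(ctx.Xf[a][i] + uc[ctx.fmap[a]][i]);
    }
    // F at the matching cell point
    double l[4] = {0,0,0,0};
    double bar[3] = {1.0-xi-eta, xi, eta};
    for (int i = 0; i < 3; i++) l[ctx.lv[i]] = bar[i];
    double dNdX[10][3];
    cell_geom(ctx.Xc, l, dNdX);
    double F[3][3];
    def_grad(uc, dNdX, F);
    double J = det3(F);
    double Fi[3][3];
    inv3(F, Fi, J);
    double an[3]; // alpha * n = J F^{-T} N
    for (int i = 0; i < 3; i++) {
      an[i] = 0.0;
      for (int j = 0; j < 3; j++) an[i] += J*Fi[j][i]*Nu[j];
    }
    double alpha = std::sqrt(an[0]*an[0]+an[1]*an[1]+an[2]*an[2]);
    double f[3] = {0,0,0};
    if (type == 1) {               // osmotic pressure on Gamma_inner
      double dP = pars[0];
      for (int i = 0; i < 3; i++) f[i] = dP*an[i];
    } else if (type == 2) {        // actin cap stress, downward on Gamma_outer
      double sc = pars[0]*std::exp((Zq-pars[1])/pars[2]); // sigma_cap, ztop, Z0
      f[2] = -sc*alpha;
    } else if (type == 3) {        // pillar steric repulsion
      double sc0 = pars[0], dst = pars[1];
      double sc = sc0*std::exp(-(xq[2]-dst)/dst);
      double H = h_smooth(xq[0], xq[1], pars[2], (int)pars[3], pars[4]);
      if (pars[5] > 0.5) {         // ez variant
        f[2] = sc*H*alpha;
      } else {                     // along -n (inward repulsion)
        for (int i = 0; i < 3; i++) f[i] = -sc*H*an[i];
      }
    }
    double w = 0.5*FQW[q]*dA*scale; // FQW sums to 1; ref-triangle measure 1/2
    for (int a = 0; a < 6; a++)
      for (int i = 0; i < 3; i++)
        R[3*a+i] -= w*f[i]*N[a];
  }
}

// [[Rcpp::export]]
List facet_loads_cpp(const arma::mat& Xp2, const arma::imat& cells10,
                     const arma::imat& nodes6, const arma::ivec& parent,
                     const arma::vec& u, int type, const arma::vec& pars,
                     bool want_K) {
  const int nf = nodes6.n_rows, np2 = Xp2.n_rows;
  arma::vec Ru(3*np2, arma::fill::zeros);
  std::vector<int> Ti, Tj; std::vector<double> Tx;
  double uc[10][3], uc2[10][3];
  double R0v[18], R1v[18];
  for (int f = 0; f < nf; f++) {
    FacetCtx ctx;
    int cg[10];
    int c = parent[f]-1;
    for (int a = 0; a < 10; a++) {
      cg[a] = cells10(c, a)-1;
      for (int i = 0; i < 3; i++) {
        ctx.Xc[a][i] = Xp2(cg[a], i);
        uc[a][i] = u[3*cg[a]+i];
      }
    }
    int fg[6];
    for (int a = 0; a < 6; a++) {
      fg[a] = nodes6(f, a)-1;
      ctx.fmap[a] = -1;
      for (int b = 0; b < 10; b++) if (cg[b] == fg[a]) { ctx.fmap[a] = b; break; }
      for (int i = 0; i < 3; i++) ctx.Xf[a][i] = Xp2(fg[a], i);
    }
    for (int i = 0; i < 3; i++) ctx.lv[i] = ctx.fmap[i];
    facet_residual(ctx, uc, type, pars.memptr(), R0v);
    for (int a = 0; a < 6; a++)
      for (int i = 0; i < 3; i++)
        Ru[3*fg[a]+i] += R0v[3*a+i];
    if (!want_K) continue;
    const double h = 1e-7;
    for (int b = 0; b < 10; b++)
      for (int k = 0; k < 3; k++) {
        std::memcpy(uc2, uc, sizeof(uc));
        uc2[b][k] += h;
        facet_residual(ctx, uc2, type, pars.memptr(), R1v);
        int col = 3*cg[b]+k;
        for (int a = 0; a < 6; a++)
          for (int i = 0; i < 3; i++) {
            double v = (R1v[3*a+i]-R0v[3*a+i])/h;
            if (v != 0.0) { Ti.push_back(3*fg[a]+i); Tj.push_back(col); Tx.push_back(v); }
          }
      }
  }
  List out = List::create(_["Ru"] = Ru);
  if (want_K) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}

// per-facet measures on the (possibly deformed) quadratic surface
// [[Rcpp::export]]
List facet_measures_cpp(const arma::mat& Xp2, const arma::imat& nodes6,
                        const arma::vec& u) {
  const int nf = nodes6.n_rows;
  arma::vec a_ref(nf, arma::fill::zeros), a_def(nf, arma::fill::zeros);
  arma::vec vflux(nf, arma::fill::zeros);
  for (int f = 0; f < nf; f++) {
    double Xf[6][3], xf[6][3];
    for (int a = 0; a < 6; a++) {
      int g = nodes6(f, a)-1;
      for (int i = 0; i < 3; i++) {
        Xf[a][i] = Xp2(g, i);
        xf[a][i] = Xf[a][i] + u[3*g+i];
      }
    }
    for (int q = 0; q < NQF; q++) {
      double dN[6][2];
      tri6_grad(FQA[q], FQB[q], dN);
      double T1[3]={0,0,0}, T2[3]={0,0,0}, t1[3]={0,0,0}, t2[3]={0,0,0};
      for (int a = 0; a < 6; a++)
        for (int i = 0; i < 3; i++) {
          T1[i] += Xf[a][i]*dN[a][0]; T2[i] += Xf[a][i]*dN[a][1];
          t1[i] += xf[a][i]*dN[a][0]; t2[i] += xf[a][i]*dN[a][1];
        }
      double NR[3] = {T1[1]*T2[2]-T1[2]*T2[1], T1[2]*T2[0]-T1[0]*T2[2], T1[0]*T2[1]-T1[1]*T2[0]};
      double nr[3] = {t1[1]*t2[2]-t1[2]*t2[1], t1[2]*t2[0]-t1[0]*t2[2], t1[0]*t2[1]-t1[1]*t2[0]};
      a_ref[f] += 0.5*FQW[q]*std::sqrt(NR[0]*NR[0]+NR[1]*NR[1]+NR[2]*NR[2]);
      a_def[f] += 0.5*FQW[q]*std::sqrt(nr[0]*nr[0]+nr[1]*nr[1]+nr[2]*nr[2]);
      double N6[6];
      tri6_shape(FQA[q], FQB[q], N6);
      double xq[3] = {0,0,0};
      for (int a = 0; a < 6; a++)
        for (int i = 0; i < 3; i++) xq[i] += N6[a]*xf[a][i];
      vflux[f] += 0.5*FQW[q]*(xq[0]*nr[0]+xq[1]*nr[1]+xq[2]*nr[2]);
    }
  }
  return List::create(_["area_ref"] = a_ref, _["area_def"] = a_def,
                      _["vflux"] = vflux);
}

// per-facet centroid evaluation of kinematics, traction and tension
// [[Rcpp::export]]
List facet_stress_cpp(const arma::mat& Xp2, const arma::imat& cells10,
                      const arma::imat& nodes6, const arma::ivec& parent,
                      const arma::vec& u, const arma::vec& p,
                      const arma::vec& Escale, double E1, double E2,
                      double offset_frac, const arma::vec& center,
                      double dz_hat) {
  const int nf = nodes6.n_rows;
  arma::vec alpha(nf), Jv(nf), gamma(nf), trac_mag(nf), Zrefv(nf);
  arma::mat nrm(nf, 3), xdef(nf, 3), trac(nf, 3), Fout(nf, 9);
  for (int f = 0; f < nf; f++) {
    int c = parent[f]-1;
    int cg[10], fg[6], fmap[6];
    double Xc[10][3], uc[10][3], Xf[6][3];
    for (int a = 0; a < 10; a++) {
      cg[a] = cells10(c, a)-1;
      for (int i = 0; i < 3; i++) { Xc[a][i] = Xp2(cg[a], i); uc[a][i] = u[3*cg[a]+i]; }
    }
    for (int a = 0; a < 6; a++) {
      fg[a] = nodes6(f, a)-1;
      fmap[a] = -1;
      for (int b = 0; b < 10; b++) if (cg[b] == fg[a]) { fmap[a] = b; break; }
      for (int i = 0; i < 3; i++) Xf[a][i] = Xp2(fg[a], i);
    }
    // facet centroid reference normal and measure
    double xi = 1.0/3.0, eta = 1.0/3.0;
    double N6[6], dN6[6][2];
    tri6_shape(xi, eta, N6); tri6_grad(xi, eta, dN6);
    double T1[3]={0,0,0}, T2[3]={0,0,0};
    double Xq[3] = {0,0,0}, xq[3] = {0,0,0};
    for (int a = 0; a < 6; a++)
      for (int i = 0; i < 3; i++) {
        T1[i] += Xf[a][i]*dN6[a][0]; T2[i] += Xf[a][i]*dN6[a][1];
        Xq[i] += N6[a]*Xf[a][i];
        xq[i] += N6[a]*(Xf[a][i]+uc[fmap[a]][i]);
      }
    double Nt[3] = {T1[1]*T2[2]-T1[2]*T2[1], T1[2]*T2[0]-T1[0]*T2[2], T1[0]*T2[1]-T1[1]*T2[0]};
    double dA = std::sqrt(Nt[0]*Nt[0]+Nt[1]*Nt[1]+Nt[2]*Nt[2]);
    double Nu[3] = {Nt[0]/dA, Nt[1]/dA, Nt[2]/dA};
    // cell barycentric point, pulled toward the interior vertex
    double l[4] = {0,0,0,0};
    double bar[3] = {1.0/3.0, 1.0/3.0, 1.0/3.0};
    for (int i = 0; i < 3; i++) l[fmap[i]] = bar[i];
    if (offset_frac > 0) {
      int opp = 0+1+2+3;
      for (int i = 0; i < 3; i++) opp -= fmap[i];
      for (int i = 0; i < 4; i++) l[i] *= (1.0-offset_frac);
      l[opp] += offset_frac;
    }
    double dNdX[10][3];
    cell_geom(Xc, l, dNdX);
    double F[3][3], C[3][3], Ci[3][3], S[3][3], J;
    def_grad(uc, dNdX, F);
    double pq = 0.0, Es = 0.0;
    {
      // P1 interpolation of p, Escale at the evaluation point
      double lp[4];
      for (int i = 0; i < 4; i++) lp[i] = l[i];
      for (int a = 0; a < 4; a++) { pq += lp[a]*p[cg[a]]; Es += lp[a]*Escale[cg[a]]; }
    }
    mr_stress(F, pq, Es, E1, E2, C, Ci, J, S);
    double PK[3][3];
    for (int i = 0; i < 3; i++)
      for (int Jj = 0; Jj < 3; Jj++) {
        PK[i][Jj] = 0.0;
        for (int M = 0; M < 3; M++) PK[i][Jj] += F[i][M]*S[M][Jj];
      }
    double Fi[3][3];
    inv3(F, Fi, J);
    double an[3];
    for (int i = 0; i < 3; i++) {
      an[i] = 0.0;
      for (int j = 0; j < 3; j++) an[i] += J*Fi[j][i]*Nu[j];
    }
    double al = std::sqrt(an[0]*an[0]+an[1]*an[1]+an[2]*an[2]);
    // reference traction P.N, true traction / alpha
    double TR[3];
    for (int i = 0; i < 3; i++) {
      TR[i] = 0.0;
      for (int Jj = 0; Jj < 3; Jj++) TR[i] += PK[i][Jj]*Nu[Jj];
      TR[i] /= al;
    }
    // tension: frame tractions over the in-plane stretches
    double rx = Xq[0]-center[0], ry = Xq[1]-center[1], rz = Xq[2]-center[2];
    double rr = std::sqrt(rx*rx+ry*ry+rz*rz);
    double Nr[3] = {rx/rr, ry/rr, rz/rr};
    double rho = std::sqrt(rx*rx+ry*ry);
    double eT[3], eP[3];
    if (rho > 1e-9) { eT[0] = -ry/rho; eT[1] = rx/rho; eT[2] = 0.0; }
    else { eT[0] = 0.0; eT[1] = 1.0; eT[2] = 0.0; }
    eP[0] = eT[1]*Nr[2]-eT[2]*Nr[1];
    eP[1] = eT[2]*Nr[0]-eT[0]*Nr[2];
    eP[2] = eT[0]*Nr[1]-eT[1]*Nr[0];
    // alphaTheta = |J F^{-T} eP| , alphaPhi = |J F^{-T} eT|
    double v1[3], v2[3];
    for (int i = 0; i < 3; i++) {
      v1[i] = 0.0; v2[i] = 0.0;
      for (int j = 0; j < 3; j++) { v1[i] += J*Fi[i][j]*eP[j]; v2[i] += J*Fi[i][j]*eT[j]; }
    }
    // note: (F^{-T} a)_i = Fi[j][i] a_j ; adjust
    double w1[3], w2[3];
    for (int i = 0; i < 3; i++) {
      w1[i] = 0.0; w2[i] = 0.0;
      for (int j = 0; j < 3; j++) { w1[i] += J*Fi[j][i]*eP[j]; w2[i] += J*Fi[j][i]*eT[j]; }
    }
    double aT = std::sqrt(w1[0]*w1[0]+w1[1]*w1[1]+w1[2]*w1[2]);
    double aP = std::sqrt(w2[0]*w2[0]+w2[1]*w2[1]+w2[2]*w2[2]);
    double sT = 0.0, sP = 0.0;
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        sT += eT[i]*PK[i][j]*eT[j];
        sP += eP[i]*PK[i][j]*eP[j];
      }
    gamma[f] = 0.5*dz_hat*(sT/aT + sP/aP);
    alpha[f] = al; Jv[f] = J; Zrefv[f] = Xq[2];
    trac_mag[f] = std::sqrt(TR[0]*TR[0]+TR[1]*TR[1]+TR[2]*TR[2]);
    for (int i = 0; i < 3; i++) {
      nrm(f, i) = an[i]/al; xdef(f, i) = xq[i]; trac(f, i) = TR[i];
    }
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) Fout(f, 3*i+j) = F[i][j];
  }
  return List::create(_["alpha"] = alpha, _["J"] = Jv, _["gamma"] = gamma,
                      _["traction"] = trac, _["traction_mag"] = trac_mag,
                      _["normal"] = nrm, _["x_def"] = xdef, _["Z_ref"] = Zrefv,
                      _["F"] = Fout);
}

// ----- nucleoplasm: P1 compressible neo-Hookean -------------------------
// W = E1n (I1 - 3) + phin (J - 1)^2, Dirichlet-driven extension field
// [[Rcpp::export]]
List nuc_assemble_cpp(const arma::mat& Xv, const arma::imat& tets,
                      const arma::vec& u, double E1n, double phin,
                      bool want_K) {
  const int nt = tets.n_rows, nv = Xv.n_rows;
  arma::vec Ru(3*nv, arma::fill::zeros);
  double minJ = 1e30, vol_def = 0.0, vol_ref = 0.0;
  std::vector<int> Ti, Tj; std::vector<double> Tx;
  if (want_K) { size_t est = (size_t)nt*144; Ti.reserve(est); Tj.reserve(est); Tx.reserve(est); }
  for (int t = 0; t < nt; t++) {
    int g[4];
    double X[4][3], uc[4][3];
    for (int a = 0; a < 4; a++) {
      g[a] = tets(t, a)-1;
      for (int i = 0; i < 3; i++) { X[a][i] = Xv(g[a], i); uc[a][i] = u[3*g[a]+i]; }
    }
    double E[3][3];
    for (int i = 0; i < 3; i++)
      for (int a = 0; a < 3; a++) E[i][a] = X[a+1][i]-X[0][i];
    double V6 = det3(E);
    double V = V6/6.0;
    double Ei[3][3];
    inv3(E, Ei, V6);
    // grad lambda_a (a = 1..3): rows of Ei; grad lambda_0 = -sum
    double G[4][3];
    for (int a = 0; a < 3; a++)
      for (int i = 0; i < 3; i++) G[a+1][i] = Ei[a][i];
    for (int i = 0; i < 3; i++) G[0][i] = -(G[1][i]+G[2][i]+G[3][i]);
    double F[3][3];
    for (int i = 0; i < 3; i++)
      for (int J = 0; J < 3; J++) {
        F[i][J] = (i==J)?1.0:0.0;
        for (int a = 0; a < 4; a++) F[i][J] += uc[a][i]*G[a][J];
      }
    double J = det3(F);
    if (J < minJ) minJ = J;
    vol_def += V*J; vol_ref += V;
    double C[3][3], Ci[3][3];
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        C[i][j] = 0.0;
        for (int k = 0; k < 3; k++) C[i][j] += F[k][i]*F[k][j];
      }
    inv3(C, Ci, J*J);
    double S[3][3];
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++)
        S[i][j] = 2*E1n*((i==j)?1.0:0.0) + 2*phin*(J-1.0)*J*Ci[i][j];
    double PK[3][3];
    for (int i = 0; i < 3; i++)
      for (int Jj = 0; Jj < 3; Jj++) {
        PK[i][Jj] = 0.0;
        for (int M = 0; M < 3; M++) PK[i][Jj] += F[i][M]*S[M][Jj];
      }
    for (int a = 0; a < 4; a++)
      for (int i = 0; i < 3; i++) {
        double r = 0.0;
        for (int Jj = 0; Jj < 3; Jj++) r += G[a][Jj]*PK[i][Jj];
        Ru[3*g[a]+i] += V*r;
      }
    if (!want_K) continue;
    double Ke[12][12];
    for (int b = 0; b < 4; b++)
      for (int k = 0; k < 3; k++) {
        const double* gr = G[b];
        double dC[3][3];
        for (int P1_ = 0; P1_ < 3; P1_++)
          for (int Q = 0; Q < 3; Q++)
            dC[P1_][Q] = F[k][P1_]*gr[Q] + F[k][Q]*gr[P1_];
        double CidC = 0.0;
        for (int i = 0; i < 3; i++) for (int j = 0; j < 3; j++) CidC += Ci[i][j]*dC[i][j];
        double dJ = 0.5*J*CidC;
        double T1[3][3], dCi[3][3];
        for (int i = 0; i < 3; i++)
          for (int j = 0; j < 3; j++) {
            T1[i][j] = 0.0;
            for (int m = 0; m < 3; m++) T1[i][j] += Ci[i][m]*dC[m][j];
          }
        for (int i = 0; i < 3; i++)
          for (int j = 0; j < 3; j++) {
            dCi[i][j] = 0.0;
            for (int m = 0; m < 3; m++) dCi[i][j] -= T1[i][m]*Ci[m][j];
          }
        double dS[3][3];
        for (int i = 0; i < 3; i++)
          for (int j = 0; j < 3; j++)
            dS[i][j] = 2*phin*((2*J-1.0)*dJ*Ci[i][j] + (J-1.0)*J*dCi[i][j]);
        double dP[3][3];
        for (int i = 0; i < 3; i++)
          for (int Jj = 0; Jj < 3; Jj++) {
            double v = 0.0;
            for (int M = 0; M < 3; M++) v += F[i][M]*dS[M][Jj];
            if (i == k) for (int M = 0; M < 3; M++) v += gr[M]*S[M][Jj];
            dP[i][Jj] = v;
          }
        int col = 3*b+k;
        for (int a = 0; a < 4; a++)
          for (int i = 0; i < 3; i++) {
            double v = 0.0;
            for (int Jj = 0; Jj < 3; Jj++) v += G[a][Jj]*dP[i][Jj];
            Ke[3*a+i][col] = V*v;
          }
      }
    for (int r = 0; r < 12; r++)
      for (int s = 0; s < 12; s++)
        if (Ke[r][s] != 0.0) {
          Ti.push_back(3*g[r/3]+(r%3)); Tj.push_back(3*g[s/3]+(s%3)); Tx.push_back(Ke[r][s]);
        }
  }
  List out = List::create(_["Ru"] = Ru, _["minJ"] = minJ,
                          _["vol_def"] = vol_def, _["vol_ref"] = vol_ref);
  if (want_K) {
    out["Ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["Kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["Kx"] = NumericVector(Tx.begin(), Tx.end());
  }
  return out;
}
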