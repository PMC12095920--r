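#include <Rcpp.h>
#include <cmath>
#include <numeric>
using namespace Rcpp;

// Coarse-grained C-alpha model: one bead per residue.
// Energy terms:
//   bonds:      kb*(r - r0)^2                       (all chains)
//   angles:     ka*(theta - theta0)^2               (folded chains only)
//   dihedrals:  kd*(1 - cos(phi - phi0))            (folded chains only)
//   native LJ:  eps_n*(5*(r0/r)^12 - 6*(r0/r)^10)   (intra-domain contacts)
//   repulsion:  eps_rep*(sigma_rep/r)^12            (non-native pairs)
//   hydrophob: -lambda_hp*h_i*h_j*(sigma_hp/r)^6    (non-native pairs)
//   DH:         B*qi*qj*exp(-r/lambda_D)/r          (charged pairs)
//   walls:      kw*dx^2 outside [0, box] when pbc is off
// Forces are the exact analytic negative gradient of the total energy
// (verified against central differences in the test suite).

struct Topo {
  int n;
  IntegerMatrix bonds;      // col0,col1 0-based
  NumericVector bond_r0;
  double bond_k;
  IntegerMatrix angles;
  NumericVector angle_t0;
  double angle_k;
  IntegerMatrix dihedrals;
  NumericVector dihedral_p0;
  double dihedral_k;
  IntegerMatrix pairs;      // nonbonded candidate pairs, 0-based
  IntegerVector pair_native;
  NumericVector pair_r0;
  NumericVector pair_qq;
  NumericVector pair_hh;
  double eps_native, eps_rep, sigma_rep, lambda_hp, sigma_hp;
  double B_dh, lambda_d;
  double box;
  bool pbc;
  double wall_k;
};

static Topo unpack(const List &topo) {
  Topo T;
  T.n = as<int>(topo["n"]);
  T.bonds = as<IntegerMatrix>(topo["bonds"]);
  T.bond_r0 = as<NumericVector>(topo["bond_r0"]);
  T.bond_k = as<double>(topo["bond_k"]);
  T.angles = as<IntegerMatrix>(topo["angles"]);
  T.angle_t0 = as<NumericVector>(topo["angle_t0"]);
  T.angle_k = as<double>(topo["angle_k"]);
  T.dihedrals = as<IntegerMatrix>(topo["dihedrals"]);
  T.dihedral_p0 = as<NumericVector>(topo["dihedral_p0"]);
  T.dihedral_k = as<double>(topo["dihedral_k"]);
  T.pairs = as<IntegerMatrix>(topo["pairs"]);
  T.pair_native = as<IntegerVector>(topo["pair_native"]);
  T.pair_r0 = as<NumericVector>(topo["pair_r0"]);
  T.pair_qq = as<NumericVector>(topo["pair_qq"]);
  T.pair_hh = as<NumericVector>(topo["pair_hh"]);
  T.eps_native = as<double>(topo["eps_native"]);
  T.eps_rep = as<double>(topo["eps_rep"]);
  T.sigma_rep = as<double>(topo["sigma_rep"]);
  T.lambda_hp = as<double>(topo["lambda_hp"]);
  T.sigma_hp = as<double>(topo["sigma_hp"]);
  T.B_dh = as<double>(topo["B_dh"]);
  T.lambda_d = as<double>(topo["lambda_d"]);
  T.box = as<double>(topo["box"]);
  T.pbc = as<bool>(topo["pbc"]);
  T.wall_k = as<double>(topo["wall_k"]);
  return T;
}

static inline void min_image(double d[3], double box, bool pbc) {
  if (!pbc) return;
  for (int a = 0; a < 3; ++a) {
    d[a] -= box * std::round(d[a] / box);
  }
}

// breakdown order: bond, angle, dihedral, native, rep, dh, hp, wall
static void compute(const Topo &T, const NumericMatrix &x,
                    NumericMatrix &F, NumericVector &E) {
  std::fill(F.begin(), F.end(), 0.0);
  std::fill(E.begin(), E.end(), 0.0);

  // bonds
  for (int b = 0; b < T.bonds.nrow(); ++b) {
    int i = T.bonds(b, 0), j = T.bonds(b, 1);
    double d[3] = {x(j,0)-x(i,0), x(j,1)-x(i,1), x(j,2)-x(i,2)};
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    double dr = r - T.bond_r0[b];
    E[0] += T.bond_k * dr * dr;
    double f = -2.0 * T.bond_k * dr / r;  // along d on bead j
    for (int a = 0; a < 3; ++a) {
      F(j,a) += f * d[a];
      F(i,a) -= f * d[a];
    }
  }

  // angles
  for (int b = 0; b < T.angles.nrow(); ++b) {
    int i = T.angles(b,0), j = T.angles(b,1), k = T.angles(b,2);
    double u[3] = {x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2)};
    double v[3] = {x(k,0)-x(j,0), x(k,1)-x(j,1), x(k,2)-x(j,2)};
    double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    double c = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu*nv);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double s = std::sqrt(1.0 - c*c);
    if (s < 1e-8) s = 1e-8;
    double dth = th - T.angle_t0[b];
    E[1] += T.angle_k * dth * dth;
    double coef = 2.0 * T.angle_k * dth / s;  // = -dU/dcos * (-1/s) sign folded in
    // dcos/du_a = v_a/(nu*nv) - c*u_a/nu^2 ; F_i = -dU/dth * dth/du = coef * dcos/du
    for (int a = 0; a < 3; ++a) {
      double dcdu = v[a]/(nu*nv) - c*u[a]/(nu*nu);
      double dcdv = u[a]/(nu*nv) - c*v[a]/(nv*nv);
      double Fi = coef * dcdu;
      double Fk = coef * dcdv;
      F(i,a) += Fi;
      F(k,a) += Fk;
      F(j,a) -= (Fi + Fk);
    }
  }

  // dihedrals
  for (int b = 0; b < T.dihedrals.nrow(); ++b) {
    int i1 = T.dihedrals(b,0), i2 = T.dihedrals(b,1),
        i3 = T.dihedrals(b,2), i4 = T.dihedrals(b,3);
    double b1[3] = {x(i2,0)-x(i1,0), x(i2,1)-x(i1,1), x(i2,2)-x(i1,2)};
    double b2[3] = {x(i3,0)-x(i2,0), x(i3,1)-x(i2,1), x(i3,2)-x(i2,2)};
    double b3[3] = {x(i4,0)-x(i3,0), x(i4,1)-x(i3,1), x(i4,2)-x(i3,2)};
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue;  // degenerate (collinear)
    double m1[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                    n1[0]*n2[1]-n1[1]*n2[0]};
    double y = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / nb2;
    double xdot = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double phi = std::atan2(y, xdot);
    double dphi = phi - T.dihedral_p0[b];
    E[2] += T.dihedral_k * (1.0 - std::cos(dphi));
    double dU = T.dihedral_k * std::sin(dphi);  // dU/dphi
    double A[3], D[3];
    for (int a = 0; a < 3; ++a) {
      A[a] = -nb2 / n1sq * n1[a];         // dphi/dr1
      D[a] =  nb2 / n2sq * n2[a];         // dphi/dr4
    }
    double c12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2*nb2);
    double c32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2*nb2);
    for (int a = 0; a < 3; ++a) {
      double d2 = -A[a] - c12*A[a] + c32*D[a];   // dphi/dr2
      double d3v = -D[a] + c12*A[a] - c32*D[a];  // dphi/dr3
      F(i1,a) -= dU * A[a];
      F(i2,a) -= dU * d2;
      F(i3,a) -= dU * d3v;
      F(i4,a) -= dU * D[a];
    }
  }

  // nonbonded pairs
  double s12 = std::pow(T.sigma_rep, 12);
  double sh6 = std::pow(T.sigma_hp, 6);
  for (int p = 0; p < T.pairs.nrow(); ++p) {
    int i = T.pairs(p,0), j = T.pairs(p,1);
    double d[3] = {x(j,0)-x(i,0), x(j,1)-x(i,1), x(j,2)-x(i,2)};
    min_image(d, T.box, T.pbc);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    double r = std::sqrt(r2);
    if (r < 0.1)
      stop("bead overlap (r < 0.1 A) between beads %d and %d", i + 1, j + 1);
    double fmag = 0.0;  // dU/dr; force on j along +d is -fmag*d/r
    if (T.pair_native[p] == 1) {
      double q = T.pair_r0[p] / r;
      double q10 = std::pow(q, 10);
      double q12 = q10 * q * q;
      E[3] += T.eps_native * (5.0*q12 - 6.0*q10);
      fmag += T.eps_native * (-60.0*q12 + 60.0*q10) / r;
    } else {
      double inv12 = s12 / std::pow(r2, 6);
      E[4] += T.eps_rep * inv12;
      fmag += -12.0 * T.eps_rep * inv12 / r;
      if (T.pair_hh[p] != 0.0 && T.lambda_hp != 0.0) {
        double inv6 = sh6 / (r2*r2*r2);
        E[6] += -T.lambda_hp * T.pair_hh[p] * inv6;
        fmag += 6.0 * T.lambda_hp * T.pair_hh[p] * inv6 / r;
      }
    }
    if (T.pair_qq[p] != 0.0 && T.B_dh != 0.0) {
      double ex = std::exp(-r / T.lambda_d);
      double u = T.B_dh * T.pair_qq[p] * ex / r;
      E[5] += u;
      fmag += -u * (1.0/r + 1.0/T.lambda_d);
    }
    double f = -fmag / r;
    for (int a = 0; a < 3; ++a) {
      F(j,a) += f * d[a];
      F(i,a) -= f * d[a];
    }
  }

  // reflecting walls
  if (!T.pbc && T.wall_k > 0.0) {
    for (int i = 0; i < T.n; ++i) {
      for (int a = 0; a < 3; ++a) {
        double xi = x(i,a);
        double dx = 0.0;
        if (xi < 0.0) dx = xi;
        else if (xi > T.box) dx = xi - T.box;
        if (dx != 0.0) {
          E[7] += T.wall_k * dx * dx;
          F(i,a) -= 2.0 * T.wall_k * dx;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cg_forces")]]
List cg_forces(NumericMatrix x, List topo) {
  Topo T = unpack(topo);
  NumericMatrix F(T.n, 3);
  NumericVector E(8);
  compute(T, x, F, E);
  E.attr("names") = CharacterVector::create(
    "bond", "angle", "dihedral", "native", "repulsion", "debye_huckel",
    "hydrophobic", "wall");
  double pot = std::accumulate(E.begin(), E.end(), 0.0);
  return List::create(_["forces"] = F, _["energies"] = E,
                      _["potential"] = pot);
}

// BAOAB Langevin integrator (reduces to velocity Verlet when friction = 0).
// Uses R's RNG so trajectories are reproducible under set.seed().
// [[Rcpp::export(name = ".cg_run")]]
List cg_run(NumericMatrix x0, NumericMatrix v0, List topo, double dt,
            double friction, double temperature, int n_steps,
            int save_interval, double blowup_tol) {
  Topo T = unpack(topo);
  int n = T.n;
  NumericMatrix x = clone(x0), v = clone(v0);
  NumericMatrix F(n, 3);
  NumericVector E(8);
  compute(T, x, F, E);

  int n_frames = (n_steps == 0) ? 1 : n_steps / save_interval;
  NumericVector frames(n_frames * n * 3);
  NumericMatrix elog(n_frames, 11);  // 8 terms + kinetic + potential + total
  int fr = 0;

  auto record = [&](int frame_idx) {
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        frames[frame_idx + n_frames * (i + (size_t)n * a)] = x(i, a);
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) ke += 0.5 * v(i,a) * v(i,a);
    double pe = 0.0;
    for (int a = 0; a < 8; ++a) { elog(frame_idx, a) = E[a]; pe += E[a]; }
    elog(frame_idx, 8) = ke;
    elog(frame_idx, 9) = pe;
    elog(frame_idx, 10) = ke + pe;
  };

  if (n_steps == 0) {
    record(0);
  } else {
    double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
    double c2 = (friction > 0.0)
      ? std::sqrt(temperature * (1.0 - c1 * c1)) : 0.0;
    NumericMatrix xprev(n, 3);
    for (int step = 0; step < n_steps; ++step) {
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) xprev(i,a) = x(i,a);
      // B: half kick
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) v(i,a) += 0.5 * dt * F(i,a);
      // A: half drift
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) x(i,a) += 0.5 * dt * v(i,a);
      // O: thermostat
      if (friction > 0.0) {
        for (int i = 0; i < n; ++i)
          for (int a = 0; a < 3; ++a)
            v(i,a) = c1 * v(i,a) + c2 * norm_rand();
      }
      // A: half drift
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) x(i,a) += 0.5 * dt * v(i,a);
      // B: half kick with fresh forces
      compute(T, x, F, E);
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a) {
          if (!std::isfinite(F(i,a)))
            stop("non-finite force at step %d; reduce dt", step + 1);
          v(i,a) += 0.5 * dt * F(i,a);
        }
      for (int i = 0; i < n; ++i) {
        double dx2 = 0.0;
        for (int a = 0; a < 3; ++a) {
          double d = x(i,a) - xprev(i,a);
          dx2 += d * d;
        }
        if (dx2 > blowup_tol * blowup_tol)
          stop("integration blow-up at step %d (bead %d moved %.2f A); "
               "reduce dt", step + 1, i + 1, std::sqrt(dx2));
      }
      if ((step + 1) % save_interval == 0 && fr < n_frames) {
        record(fr);
        ++fr;
      }
    }
  }

  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  colnames(elog) = CharacterVector::create(
    "bond", "angle", "dihedral", "native", "repulsion", "debye_huckel",
    "hydrophobic", "wall", "kinetic", "potential", "total");
  return List::create(_["frames"] = frames, _["energies"] = elog,
                      _["x"] = x, _["v"] = v);
}
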