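// Metropolis Monte Carlo engine for the bead-discretized worm-like chain
// with rigid bonds and bending energy k_bend * sum_i (1 - u_i . u_{i+1}).
//
// Fixed-extension ensemble: crankshaft moves only (rotate the sub-chain
// strictly between two anchor beads about the axis through them), which
// conserve every bond length and both end positions exactly.
// Fixed-force ensemble: crankshaft + end-pivot moves, Boltzmann weight
// exp(-(E_bend + f * R)) with R the current end-to-end distance.
//
// Uses R's RNG so set.seed() gives bit-reproducible sample streams.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Chain {
  int nb;
  std::vector<double> x;  // 3*nb, bead coordinates
  double kbend;

  double joint_energy(int b) const {
    // joint at bead b (1..nb-2): k (1 - u_{b-1} . u_b), bonds unnormalized
    // but all of equal length ds, so normalize by ds^2
    const double *r0 = &x[3*(b-1)], *r1 = &x[3*b], *r2 = &x[3*(b+1)];
    double ax = r1[0]-r0[0], ay = r1[1]-r0[1], az = r1[2]-r0[2];
    double bx = r2[0]-r1[0], by = r2[1]-r1[1], bz = r2[2]-r1[2];
    double la = std::sqrt(ax*ax+ay*ay+az*az), lb = std::sqrt(bx*bx+by*by+bz*bz);
    return kbend * (1.0 - (ax*bx+ay*by+az*bz)/(la*lb));
  }
  double total_energy() const {
    double e = 0.0;
    for (int b = 1; b <= nb-2; ++b) e += joint_energy(b);
    return e;
  }
  double end_distance() const {
    double dx = x[3*(nb-1)] - x[0], dy = x[3*(nb-1)+1] - x[1], dz = x[3*(nb-1)+2] - x[2];
    return std::sqrt(dx*dx+dy*dy+dz*dz);
  }
};

// rotate beads [b0, b1] about unit axis u through point c by angle phi
static void rotate_span(std::vector<double> &x, int b0, int b1,
                        const double *c, const double *u, double phi) {
  double cp = std::cos(phi), sp = std::sin(phi), omc = 1.0 - cp;
  for (int b = b0; b <= b1; ++b) {
    double vx = x[3*b]-c[0], vy = x[3*b+1]-c[1], vz = x[3*b+2]-c[2];
    double du = u[0]*vx + u[1]*vy + u[2]*vz;
    double cx = u[1]*vz - u[2]*vy, cy = u[2]*vx - u[0]*vz, cz = u[0]*vy - u[1]*vx;
    x[3*b]   = c[0] + vx*cp + cx*sp + u[0]*du*omc;
    x[3*b+1] = c[1] + vy*cp + cy*sp + u[1]*du*omc;
    x[3*b+2] = c[2] + vz*cp + cz*sp + u[2]*du*omc;
  }
}

// [[Rcpp::export]]
List cpp_mc(NumericMatrix pos0, double kbend, double f, bool fixed_R,
            int n_equil, int n_prod, int stride, int n_snap,
            double pivot_frac = 0.3) {
  Chain ch;
  ch.nb = pos0.ncol();
  ch.kbend = kbend;
  ch.x.resize(3*ch.nb);
  for (int b = 0; b < ch.nb; ++b)
    for (int d = 0; d < 3; ++d) ch.x[3*b+d] = pos0(d, b);
  int nb = ch.nb;

  double E = ch.total_energy();
  double R = ch.end_distance();
  double dc = 0.5, dp = 0.5;          // crankshaft / pivot amplitudes
  long acc_c = 0, try_c = 0, acc_p = 0, try_p = 0;
  long acc_c_tot = 0, try_c_tot = 0, acc_p_tot = 0, try_p_tot = 0;

  int n_samp = n_prod / stride;
  NumericVector Esamp(n_samp), Rsamp(n_samp);
  NumericMatrix snaps(n_snap > 0 ? 3*nb : 0, n_snap > 0 ? n_snap : 0);
  int isamp = 0, isnap = 0;
  int snap_every = n_snap > 0 ? std::max(1, n_prod / n_snap) : 0;
  double maxviol = 0.0;
  double R0 = R;
  std::vector<double> save(3*nb);   // reusable undo buffer

  for (int sweep = 0; sweep < n_equil + n_prod; ++sweep) {
    bool prod = sweep >= n_equil;
    for (int mv = 0; mv < nb; ++mv) {
      bool pivot = !fixed_R && unif_rand() < pivot_frac;
      if (!pivot) {
        // crankshaft: anchors i < j with at least one interior bead
        int i = (int)(unif_rand() * (nb-2)); if (i > nb-3) i = nb-3;
        int j = i + 2 + (int)(unif_rand() * (nb-1-(i+2)+1)); if (j > nb-1) j = nb-1;
        double ax = ch.x[3*j]-ch.x[3*i], ay = ch.x[3*j+1]-ch.x[3*i+1], az = ch.x[3*j+2]-ch.x[3*i+2];
        double la = std::sqrt(ax*ax+ay*ay+az*az);
        if (la < 1e-14) continue;     // anchors coincide; skip
        double u[3] = {ax/la, ay/la, az/la};
        double phi = dc * (2.0*unif_rand() - 1.0);
        double e_old = 0.0;
        if (i >= 1) e_old += ch.joint_energy(i);
        if (j <= nb-2) e_old += ch.joint_energy(j);
        std::copy(ch.x.begin()+3*(i+1), ch.x.begin()+3*j, save.begin());
        rotate_span(ch.x, i+1, j-1, &ch.x[3*i], u, phi);
        double e_new = 0.0;
        if (i >= 1) e_new += ch.joint_energy(i);
        if (j <= nb-2) e_new += ch.joint_energy(j);
        double dE = e_new - e_old;
        try_c++;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) { E += dE; acc_c++; }
        else std::copy(save.begin(), save.begin()+3*(j-i-1), ch.x.begin()+3*(i+1));
      } else {
        // end-pivot: rotate one arm about a random axis through the pivot
        int m = 1 + (int)(unif_rand() * (nb-2)); if (m > nb-2) m = nb-2;
        bool head = unif_rand() < 0.5;
        double z = 2.0*unif_rand() - 1.0, phi0 = 2.0*M_PI*unif_rand();
        double s = std::sqrt(std::max(0.0, 1.0 - z*z));
        double u[3] = {s*std::cos(phi0), s*std::sin(phi0), z};
        double phi = dp * (2.0*unif_rand() - 1.0);
        double e_old = ch.joint_energy(m);
        double R_old = ch.end_distance();
        int b0 = head ? 0 : m+1, b1 = head ? m-1 : nb-1;
        std::copy(ch.x.begin()+3*b0, ch.x.begin()+3*(b1+1), save.begin());
        rotate_span(ch.x, b0, b1, &ch.x[3*m], u, phi);
        double e_new = ch.joint_energy(m);
        double R_new = ch.end_distance();
        double dE = (e_new - e_old) + f*(R_new - R_old);
        try_p++;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) { E += (e_new - e_old); R = R_new; acc_p++; }
        else std::copy(save.begin(), save.begin()+3*(b1-b0+1), ch.x.begin()+3*b0);
      }
    }
    E = ch.total_energy();   // refresh; kills incremental round-off drift
    if (!fixed_R) R = ch.end_distance();

    if (!prod) {
      // amplitude tuning toward ~40% acceptance, frozen before production
      if ((sweep+1) % 100 == 0) {
        if (try_c > 0) {
          double a = (double)acc_c/try_c;
          if (a > 0.45) dc *= 1.15; else if (a < 0.35) dc /= 1.15;
          if (dc > M_PI) dc = M_PI;
          if (dc < 1e-4) dc = 1e-4;
        }
        if (try_p > 0) {
          double a = (double)acc_p/try_p;
          if (a > 0.45) dp *= 1.15; else if (a < 0.35) dp /= 1.15;
          if (dp > M_PI) dp = M_PI;
          if (dp < 1e-4) dp = 1e-4;
        }
        acc_c = try_c = acc_p = try_p = 0;
      }
    } else {
      acc_c_tot += acc_c; try_c_tot += try_c; acc_p_tot += acc_p; try_p_tot += try_p;
      acc_c = try_c = acc_p = try_p = 0;
      int psweep = sweep - n_equil;
      if ((psweep+1) % stride == 0 && isamp < n_samp) {
        Esamp[isamp] = E;
        Rsamp[isamp] = fixed_R ? ch.end_distance() : R;
        isamp++;
      }
      if (fixed_R) {
        double v = std::fabs(ch.end_distance() - R0);
        if (v > maxviol) maxviol = v;
      }
      if (n_snap > 0 && (psweep % snap_every) == 0 && isnap < n_snap) {
        for (int q = 0; q < 3*nb; ++q) snaps(q, isnap) = ch.x[q];
        isnap++;
      }
    }
  }

  NumericMatrix posend(3, nb);
  for (int b = 0; b < nb; ++b)
    for (int d = 0; d < 3; ++d) posend(d, b) = ch.x[3*b+d];
  double acc_all = (double)(acc_c_tot + acc_p_tot) /
                   std::max(1L, try_c_tot + try_p_tot);
  return List::create(
    _["Epoly"] = Esamp, _["R"] = Rsamp, _["acceptance"] = acc_all,
    _["acc_crank"] = try_c_tot ? (double)acc_c_tot/try_c_tot : NA_REAL,
    _["acc_pivot"] = try_p_tot ? (double)acc_p_tot/try_p_tot : NA_REAL,
    _["delta_crank"] = dc, _["delta_pivot"] = dp,
    _["max_R_violation"] = maxviol, _["positions"] = posend,
    _["snapshots"] = snaps);
}
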