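// Numerical core for the worm-like chain Green function in Fourier-Laplace
// space: the continued-fraction representation, Newton root-finding on the
// characteristic polynomial of its truncated operator, residue extraction,
// and continuation ("marching") of the pole set along a wavevector grid.
//
// All variables are dimensionless: wavevector K conjugate to r = R/(2lp),
// Laplace variable p conjugate to N = L/(2lp).
#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;
typedef std::complex<double> cplx;

static double al2(int l) { return (double)l * l / ((2.0*l+1.0)*(2.0*l-1.0)); }

// truncation level: the fraction converges once l(l+1) dominates (a_l K)^2
static int lmax_for(double K) {
  int lm = (int)std::ceil(3.2*std::sqrt(K)) + 40;
  return lm < 40 ? 40 : lm;
}

// continued fraction G(K;p) = 1/(P0 + (a1 K)^2/(P1 + ...)) by backward
// recurrence from level lmax
static cplx cf_value(double K, cplx p, int lmax) {
  cplx D = p + (double)lmax*(lmax+1.0);
  double K2 = K*K;
  for (int l = lmax-1; l >= 0; --l)
    D = (p + (double)l*(l+1.0)) + al2(l+1)*K2/D;
  return 1.0/D;
}

// [[Rcpp::export]]
ComplexVector cpp_cf_value(double K, ComplexVector p, int lmax) {
  int n = p.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    cplx g = cf_value(K, cplx(p[i].r, p[i].i), lmax);
    out[i] = Rcomplex{g.real(), g.imag()};
  }
  return out;
}

// characteristic polynomial det(pI - A) of the truncated tridiagonal
// operator (diagonal l(l+1), coupling a_l K), with first and second
// derivative in p, via the jointly rescaled three-term recurrence
//   d_l = (p + l(l+1)) d_{l-1} + a_l^2 K^2 d_{l-2}
struct DetVal { cplx d, dp, dpp; double lex; };  // det = d * e^{lex}

static DetVal det_eval(double K, cplx p, int lmax) {
  double K2 = K*K;
  cplx dm1 = 1.0, d0 = p;
  cplx qm1 = 0.0, q0 = 1.0;
  cplx sm1 = 0.0, s0 = 0.0;
  double lex = 0.0;
  const double lg = 150*std::log(10.0);
  for (int l = 1; l <= lmax; ++l) {
    cplx t = p + (double)l*(l+1.0);
    double c = al2(l)*K2;
    cplx d1 = t*d0 + c*dm1;
    cplx q1 = d0 + t*q0 + c*qm1;
    cplx s1 = 2.0*q0 + t*s0 + c*sm1;
    dm1 = d0; d0 = d1; qm1 = q0; q0 = q1; sm1 = s0; s0 = s1;
    double m = std::abs(d0) + std::abs(q0);
    if (m > 1e150) { dm1*=1e-150; d0*=1e-150; qm1*=1e-150; q0*=1e-150; sm1*=1e-150; s0*=1e-150; lex += lg; }
    else if (m < 1e-150 && m > 0) { dm1*=1e150; d0*=1e150; qm1*=1e150; q0*=1e150; sm1*=1e150; s0*=1e150; lex -= lg; }
  }
  DetVal out; out.d = d0; out.dp = q0; out.dpp = s0; out.lex = lex;
  return out;
}

// first minor M_00 (levels 1..lmax); residue of G at a root p* of det is
// M_00(p*) / det'(p*)
static void minor00(double K, cplx p, int lmax, cplx &m, double &lex) {
  double K2 = K*K;
  cplx dm1 = 1.0, d0 = p + 2.0;
  lex = 0.0;
  const double lg = 150*std::log(10.0);
  for (int l = 2; l <= lmax; ++l) {
    cplx t = p + (double)l*(l+1.0);
    double c = al2(l)*K2;
    cplx d1 = t*d0 + c*dm1;
    dm1 = d0; d0 = d1;
    double mm = std::abs(d0);
    if (mm > 1e150) { dm1 *= 1e-150; d0 *= 1e-150; lex += lg; }
    else if (mm < 1e-150 && mm > 0) { dm1 *= 1e150; d0 *= 1e150; lex -= lg; }
  }
  m = d0;
}

// acc_abs: absolute stagnation-acceptance radius; a pole localized to
// acc_abs contributes a phase error ~ acc_abs * N to e^{pN}, so callers
// pass ~(phase budget)/N
static bool newton_det(double K, cplx &p, int lmax, double acc_abs = 1e-9) {
  // deep roots sit at the rounding noise floor of the rescaled recurrence,
  // where the step stagnates above the nominal tolerance: accept the best
  // stagnated iterate if it is still a tight localization
  cplx pbest = p;
  double sbest = 1e300;
  for (int it = 0; it < 60; ++it) {
    DetVal v = det_eval(K, p, lmax);
    if (std::abs(v.dp) < 1e-300) break;
    cplx step = v.d / v.dp;
    p -= step;
    double s = std::abs(step);
    if (s < sbest) { sbest = s; pbest = p; }
    if (s < 1e-13*(1.0 + std::abs(p))) return true;
    if (it >= 10 && s > 4.0*sbest) break;   // bouncing in the noise ball
  }
  if (sbest < std::min(1e-5*(1.0 + std::abs(pbest)), acc_abs)) {
    p = pbest;
    return true;
  }
  return false;
}

static bool newton_detp(double K, cplx &p, int lmax) {
  for (int it = 0; it < 60; ++it) {
    DetVal v = det_eval(K, p, lmax);
    if (std::abs(v.dpp) < 1e-300) return false;
    cplx step = v.dp / v.dpp;
    p -= step;
    if (std::abs(step) < 1e-12*(1.0 + std::abs(p))) return true;
  }
  return false;
}

static cplx residue_at(double K, cplx p, int lmax) {
  DetVal v = det_eval(K, p, lmax);
  cplx m; double lexm;
  minor00(K, p, lmax, m, lexm);
  return (m / v.dp) * std::exp(lexm - v.lex);
}

// two roots have merged or share a Newton basin near `base`: locate the
// extremum of det between them and seed both roots of the local quadratic
// model det ~ det(x*) + det''(x*)(x-x*)^2/2 (real pair on one side of the
// branch point, conjugate pair on the other)
// quadratic-model seeds at an extremum x of det, Newton-polished
static int seeds_from_extremum(double K, cplx x, int lmax, cplx &r1, cplx &r2,
                               double acc_abs) {
  DetVal v = det_eval(K, x, lmax);
  if (std::abs(v.dpp) < 1e-300) return 0;
  cplx off = std::sqrt(-2.0*v.d/v.dpp);
  cplx s1 = x + off, s2 = x - off;
  int n = 0;
  if (newton_det(K, s1, lmax, acc_abs)) { r1 = s1; n++; }
  if (newton_det(K, s2, lmax, acc_abs)) { if (n) r2 = s2; else r1 = s2; n++; }
  return n;
}

// recover the two roots that merged between `a` and `b` (their previous
// positions). For a real pair the extremum of det between them is
// bracketed by [a, b]: det' changes sign exactly once between adjacent
// roots, so bisection is guaranteed to find the correct extremum; the
// quadratic-model seeds then come out real or conjugate-complex depending
// on which side of the branch point K has landed.
static int recover_pair(double K, cplx a, cplx b, int lmax, cplx &r1, cplx &r2,
                        double acc_abs) {
  bool realpair = std::abs(std::imag(a)) < 1e-9 && std::abs(std::imag(b)) < 1e-9;
  if (realpair && std::abs(a - b) > 1e-12) {
    double lo = std::min(std::real(a), std::real(b));
    double hi = std::max(std::real(a), std::real(b));
    DetVal vlo = det_eval(K, cplx(lo, 0.0), lmax);
    DetVal vhi = det_eval(K, cplx(hi, 0.0), lmax);
    double slo = std::real(vlo.dp) * ((vlo.lex > vhi.lex) ? 1.0 : 1.0);
    // rescaled det' values share no common exponent; only signs matter
    double flo = (std::real(vlo.dp) > 0) - (std::real(vlo.dp) < 0);
    double fhi = (std::real(vhi.dp) > 0) - (std::real(vhi.dp) < 0);
    (void)slo;
    if (flo != fhi && flo != 0 && fhi != 0) {
      for (int it = 0; it < 200 && hi - lo > 1e-15*(1.0 + std::abs(lo)); ++it) {
        double mid = 0.5*(lo + hi);
        DetVal vm = det_eval(K, cplx(mid, 0.0), lmax);
        double fm = (std::real(vm.dp) > 0) - (std::real(vm.dp) < 0);
        if (fm == flo) lo = mid; else hi = mid;
      }
      cplx x(0.5*(lo + hi), 0.0);
      int n = seeds_from_extremum(K, x, lmax, r1, r2, acc_abs);
      if (n == 2) return 2;
    }
  }
  // fallbacks: Newton on det' from the midpoint, then complex nudges
  cplx x = 0.5*(a + b);
  if (newton_detp(K, x, lmax)) {
    int n = seeds_from_extremum(K, x, lmax, r1, r2, acc_abs);
    if (n == 2) return 2;
  }
  for (double off = 0.25; off <= 16.0; off *= 4.0) {
    cplx p = 0.5*(a + b) + cplx(0.0, off*(1.0 + 0.01*std::abs(a)));
    if (newton_det(K, p, lmax, acc_abs)) {
      r1 = p;
      cplx q = std::conj(p);
      if (std::abs(std::imag(p)) > 1e-9 && newton_det(K, q, lmax, acc_abs)) { r2 = q; return 2; }
      return 1;
    }
  }
  return 0;
}

struct PoleSet {
  std::vector<cplx> p;
  std::vector<cplx> v;    // dp/dK from the last clean step (0 = unknown)
  std::vector<char> ok;   // polished (contributes to sums); unpolished deep
                          // poles are carried for continuity only
  double K = 0.0;
  int ncollide = 0, nlost = 0;
};

static bool is_dup(const std::vector<cplx> &v, cplx p) {
  for (size_t m = 0; m < v.size(); ++m)
    if (std::abs(p - v[m]) < 1e-4*(1.0 + std::abs(v[m]))) return true;
  return false;
}

static bool step_to(PoleSet &ps, double Knew, double N, double prune_rel,
                    bool force = false) {
  int lmax = lmax_for(Knew);
  double dK = Knew - ps.K;
  double acc_abs = 3e-7 / N;   // phase budget over the pole-sum exponent
  if (ps.v.size() != ps.p.size()) ps.v.assign(ps.p.size(), cplx(0.0, 0.0));
  if (ps.ok.size() != ps.p.size()) ps.ok.assign(ps.p.size(), 1);
  double relead_prev = -1e300;
  for (size_t j = 0; j < ps.p.size(); ++j)
    if (std::real(ps.p[j]) > relead_prev) relead_prev = std::real(ps.p[j]);
  std::vector<cplx> uniq, src;          // src: previous position per root
  std::vector<cplx> vel;                // velocity estimate per root
  std::vector<char> okf;                // polished flag per root
  std::vector<cplx> troubleA, troubleB; // merged pair: old positions
  std::vector<cplx> failed;             // Newton non-convergence (old pos)
  for (size_t j = 0; j < ps.p.size(); ++j) {
    cplx p = ps.p[j] + ps.v[j]*dK;      // velocity predictor
    if (!newton_det(Knew, p, lmax, acc_abs)) {
      failed.push_back(ps.p[j]);
      continue;
    }
    bool dup = false;
    for (size_t m = 0; m < uniq.size(); ++m)
      if (std::abs(p - uniq[m]) < 1e-4*(1.0 + std::abs(uniq[m]))) {
        troubleA.push_back(ps.p[j]); troubleB.push_back(src[m]);
        dup = true; break;
      }
    if (!dup) {
      uniq.push_back(p); src.push_back(ps.p[j]);
      vel.push_back(dK > 0 ? (p - ps.p[j])/dK : cplx(0.0, 0.0));
      okf.push_back(1);
    }
  }
  // Newton fails exactly when a real pair has just crossed its branch
  // point (real iterates cannot reach complex roots): pair the failures
  // with their nearest co-failure and recover them together
  while (!failed.empty()) {
    cplx a = failed.back(); failed.pop_back();
    size_t jb = 0; double best = 1e300;
    for (size_t m = 0; m < failed.size(); ++m) {
      double d = std::abs(failed[m] - a);
      if (d < best) { best = d; jb = m; }
    }
    // only pair genuinely adjacent failures (conjugate partners of an
    // unrelated pair are far apart and must not be bracketed together)
    if (!failed.empty() && best < 0.2*(1.0 + std::abs(a))) {
      troubleA.push_back(a); troubleB.push_back(failed[jb]);
      failed.erase(failed.begin() + jb);
    } else {
      // singleton failure: its partner converged -- bracket against the
      // nearest surviving root's previous position
      cplx b = a;
      double best = 1e300;
      for (size_t m = 0; m < src.size(); ++m) {
        double d = std::abs(src[m] - a);
        if (d > 1e-12 && d < best) { best = d; b = src[m]; }
      }
      troubleA.push_back(a); troubleB.push_back(b);
    }
  }
  int lost = 0;
  for (size_t j = 0; j < troubleA.size(); ++j) {
    ps.ncollide++;
    cplx r1, r2;
    int n = recover_pair(Knew, troubleA[j], troubleB[j], lmax, r1, r2, acc_abs);
    bool added = false;
    if (n >= 1 && !is_dup(uniq, r1)) { uniq.push_back(r1); src.push_back(troubleA[j]);
                                       vel.push_back(cplx(0.0, 0.0)); okf.push_back(1);
                                       added = true; }
    if (n == 2 && !is_dup(uniq, r2)) { uniq.push_back(r2); src.push_back(troubleB[j]);
                                       vel.push_back(cplx(0.0, 0.0)); okf.push_back(1);
                                       added = true; }
    if (!added) {
      // unrecoverable: deep poles transit a zone where the characteristic
      // polynomial is too ill-conditioned to polish; their contributions
      // are < 1e-4 of the lead, so they are carried through on the smooth
      // drift prediction, excluded from sums until they polish again
      // the carry threshold sits below the ringing gate of the radial
      // pipeline (1e-6 of the peak for N >= 0.1, 1e-4 for stiffer chains)
      double carry_rel = (N >= 0.1) ? 1e-7 : 1e-4;
      if ((std::real(troubleA[j]) - relead_prev)*N < std::log(carry_rel)) {
        cplx pred = troubleA[j] +
                    dK*cplx(0.0, std::imag(troubleA[j])/std::max(ps.K, 1.0));
        if (!is_dup(uniq, pred)) {
          uniq.push_back(pred); src.push_back(troubleA[j]);
          vel.push_back(cplx(0.0, 0.0)); okf.push_back(0);
        }
      } else lost++;
    }
  }
  if (lost > 0 && !force) return false;
  ps.nlost += lost;
  double relead = -1e300;
  for (size_t j = 0; j < uniq.size(); ++j)
    if (std::real(uniq[j]) > relead) relead = std::real(uniq[j]);
  double cut = relead + std::log(prune_rel)/N;
  std::vector<cplx> kp, kv;
  std::vector<char> ko;
  for (size_t j = 0; j < uniq.size(); ++j)
    if (std::real(uniq[j]) > cut) {
      kp.push_back(uniq[j]); kv.push_back(vel[j]); ko.push_back(okf[j]);
    }
  ps.p = kp; ps.v = kv; ps.ok = ko; ps.K = Knew;
  return true;
}

// internal step-size control: fine steps while real poles remain (the
// collision-rich phase), sqrt(K)-scaled steps once the retained spectrum is
// fully complex (level gaps then grow ~ sqrt(K)); failed steps are bisected
static void advance_to(PoleSet &ps, double Ktarget, double N, double prune_rel) {
  while (ps.K < Ktarget) {
    bool anyreal = false;
    for (size_t j = 0; j < ps.p.size(); ++j)
      if (std::abs(std::imag(ps.p[j])) < 1e-6) { anyreal = true; break; }
    double h = anyreal ? std::max(0.2, 0.005*ps.K)
                       : std::max(1.0, std::min(0.02*ps.K, 0.5*std::sqrt(ps.K)));
    double Knew = std::min(Ktarget, ps.K + h);
    PoleSet trial = ps;
    if (step_to(trial, Knew, N, prune_rel)) { ps = trial; continue; }
    bool done = false;
    for (int depth = 0; depth < 7 && !done; ++depth) {
      trial = ps;
      int nsub = 1 << (depth+1);
      bool ok = true;
      for (int q = 1; q <= nsub && ok; ++q)
        ok = step_to(trial, ps.K + (Knew - ps.K)*q/nsub, N, prune_rel);
      if (ok) { ps = trial; done = true; }
    }
    if (!done)
      step_to(ps, Knew, N, prune_rel, true);
  }
}

// march a pole set from (K0, poles0) through the sorted grid Kvec,
// accumulating G(K;N) = sum_j res_j exp(p_j N) at every node
// [[Rcpp::export]]
List cpp_march(NumericVector Kvec, double N, ComplexVector poles0, double K0,
               double prune_rel = 1e-15) {
  int nk = Kvec.size();
  NumericVector G(nk), Gim(nk);
  IntegerVector npole(nk);
  PoleSet ps;
  ps.K = K0;
  for (int j = 0; j < poles0.size(); ++j)
    ps.p.push_back(cplx(poles0[j].r, poles0[j].i));
  for (int ik = 0; ik < nk; ++ik) {
    advance_to(ps, Kvec[ik], N, prune_rel);
    int lmax = lmax_for(Kvec[ik]);
    cplx s = 0.0;
    for (size_t j = 0; j < ps.p.size(); ++j) {
      if (!ps.ok.empty() && !ps.ok[j]) continue;
      s += residue_at(Kvec[ik], ps.p[j], lmax) * std::exp(ps.p[j]*N);
    }
    G[ik] = std::real(s); Gim[ik] = std::imag(s);
    npole[ik] = (int)ps.p.size();
  }
  ComplexVector pend(ps.p.size());
  for (size_t j = 0; j < ps.p.size(); ++j)
    pend[j] = Rcomplex{ps.p[j].real(), ps.p[j].imag()};
  return List::create(_["G"] = G, _["Gim"] = Gim, _["npoles"] = npole,
                      _["poles"] = pend, _["ncollide"] = ps.ncollide,
                      _["nlost"] = ps.nlost);
}

// Newton-polish candidate poles (e.g. eigenvalue estimates) and return the
// polished roots with residues; non-converged entries are flagged NA
// [[Rcpp::export]]
List cpp_polish(double K, ComplexVector p0, int lmax = 0,
                double acc_abs = 1e-9) {
  if (lmax <= 0) lmax = lmax_for(K);
  int n = p0.size();
  ComplexVector poles(n), res(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    cplx p(p0[i].r, p0[i].i);
    bool conv = newton_det(K, p, lmax, acc_abs);
    ok[i] = conv;
    if (conv) {
      cplx r = residue_at(K, p, lmax);
      poles[i] = Rcomplex{p.real(), p.imag()};
      res[i] = Rcomplex{r.real(), r.imag()};
    } else {
      poles[i] = Rcomplex{NA_REAL, NA_REAL};
      res[i] = Rcomplex{NA_REAL, NA_REAL};
    }
  }
  return List::create(_["poles"] = poles, _["residues"] = res, _["converged"] = ok);
}

// residues at given pole locations
// [[Rcpp::export]]
ComplexVector cpp_residues(double K, ComplexVector p, int lmax = 0) {
  if (lmax <= 0) lmax = lmax_for(K);
  int n = p.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    cplx r = residue_at(K, cplx(p[i].r, p[i].i), lmax);
    out[i] = Rcomplex{r.real(), r.imag()};
  }
  return out;
}

// [[Rcpp::export]]
int cpp_lmax_for(double K) { return lmax_for(K); }

// march to each K in Kvec and return the full pole set with residues at
// every node (for sparse-sample tail quadrature)
// [[Rcpp::export]]
List cpp_march_samples(NumericVector Kvec, double N, ComplexVector poles0,
                       double K0, double prune_rel = 1e-15) {
  int nk = Kvec.size();
  List out(nk);
  PoleSet ps;
  ps.K = K0;
  for (int j = 0; j < poles0.size(); ++j)
    ps.p.push_back(cplx(poles0[j].r, poles0[j].i));
  for (int ik = 0; ik < nk; ++ik) {
    advance_to(ps, Kvec[ik], N, prune_rel);
    int lmax = lmax_for(Kvec[ik]);
    std::vector<int> keep;
    for (size_t j = 0; j < ps.p.size(); ++j)
      if (ps.ok.empty() || ps.ok[j]) keep.push_back((int)j);
    int np = (int)keep.size();
    ComplexVector pol(np), res(np);
    for (int j = 0; j < np; ++j) {
      cplx r = residue_at(Kvec[ik], ps.p[keep[j]], lmax);
      pol[j] = Rcomplex{ps.p[keep[j]].real(), ps.p[keep[j]].imag()};
      res[j] = Rcomplex{r.real(), r.imag()};
    }
    out[ik] = List::create(_["poles"] = pol, _["residues"] = res);
  }
  ComplexVector pend(ps.p.size());
  for (size_t j = 0; j < ps.p.size(); ++j)
    pend[j] = Rcomplex{ps.p[j].real(), ps.p[j].imag()};
  return List::create(_["samples"] = out, _["poles"] = pend,
                      _["ncollide"] = ps.ncollide, _["nlost"] = ps.nlost);
}

// diagnostic: march with per-event reporting of unrecovered pole losses
// [[Rcpp::export]]
List cpp_march_debug(double Kto, double N, ComplexVector poles0, double K0,
                     double prune_rel = 1e-15) {
  PoleSet ps;
  ps.K = K0;
  for (int j = 0; j < poles0.size(); ++j)
    ps.p.push_back(cplx(poles0[j].r, poles0[j].i));
  std::vector<double> evK;
  std::vector<cplx> evP;
  while (ps.K < Kto) {
    bool anyreal = false;
    for (size_t j = 0; j < ps.p.size(); ++j)
      if (std::abs(std::imag(ps.p[j])) < 1e-6) { anyreal = true; break; }
    double h = anyreal ? std::max(0.2, 0.005*ps.K)
                       : std::max(1.0, std::min(0.02*ps.K, 0.5*std::sqrt(ps.K)));
    double Knew = std::min(Kto, ps.K + h);
    PoleSet trial = ps;
    if (!step_to(trial, Knew, N, prune_rel)) {
      bool done = false;
      for (int depth = 0; depth < 7 && !done; ++depth) {
        trial = ps;
        int nsub = 1 << (depth+1);
        bool ok = true;
        for (int q = 1; q <= nsub && ok; ++q)
          ok = step_to(trial, ps.K + (Knew - ps.K)*q/nsub, N, prune_rel);
        if (ok) done = true;
      }
      if (!done) {
        // record which poles vanish across the forced step
        PoleSet forced = ps;
        step_to(forced, Knew, N, prune_rel, true);
        for (size_t j = 0; j < ps.p.size(); ++j) {
          double best = 1e300;
          for (size_t m = 0; m < forced.p.size(); ++m)
            best = std::min(best, std::abs(ps.p[j] - forced.p[m]));
          if (best > 0.5) { evK.push_back(Knew); evP.push_back(ps.p[j]); }
        }
        trial = forced;
      }
    }
    ps = trial;
  }
  int ne = (int)evK.size();
  NumericVector eK(ne); ComplexVector eP(ne);
  for (int i = 0; i < ne; ++i) {
    eK[i] = evK[i];
    eP[i] = Rcomplex{evP[i].real(), evP[i].imag()};
  }
  ComplexVector pend(ps.p.size());
  for (size_t j = 0; j < ps.p.size(); ++j)
    pend[j] = Rcomplex{ps.p[j].real(), ps.p[j].imag()};
  return List::create(_["event_K"] = eK, _["event_pole"] = eP,
                      _["poles"] = pend, _["nlost"] = ps.nlost);
}
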