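#include <Rcpp.h>
using namespace Rcpp;

// Space-free reaction term: chi*gamma*u - alpha2*u/(alpha1+u^2) + mu - alpha0*u.
// The inhibition term is defined as 0 when alpha2 == 0 (degenerate linear kinetics),
// which also covers alpha1 == 0 in that case.
static inline double reaction(double u, double chi, double g, double a1,
                              double a2, double a0, double mu) {
  double inhib = (a2 == 0.0) ? 0.0 : a2 * u / (a1 + u * u);
  return chi * g * u - inhib + mu - a0 * u;
}

static void check_finite(double v, double dt, int step) {
  if (!R_finite(v) || v < -1e-8)
    stop("numerical instability (non-finite or negative u) at step %d; "
         "reduce dt (current dt = %g)", step, dt);
}

// Explicit Euler integration of the histamine reaction-diffusion equation on a
// square 2-D grid with zero-flux (mirrored ghost cell) boundaries.
//
// State per cell: u (histamine), U (cumulative release, integral of gamma*u while
// the store lasts), chi (1 until U exceeds utot, then 0 forever), dir (+1 while u
// was last rising, -1 falling).
//
// Snapshots (u, U, chi, dir) are recorded every snap_every steps.
// [[Rcpp::export]]
List rd_core_2d(NumericMatrix u_in, NumericMatrix U_in, NumericMatrix chi_in,
                NumericMatrix dir_in,
                double g, double a1, double a2, double a0, double mu,
                double du, double utot, double h, double dt,
                int nsteps, int snap_every) {
  const int n = u_in.nrow();
  if (u_in.ncol() != n) stop("u must be square");
  std::vector<double> u(u_in.begin(), u_in.end());
  std::vector<double> U(U_in.begin(), U_in.end());
  std::vector<double> chi(chi_in.begin(), chi_in.end());
  std::vector<double> dir(dir_in.begin(), dir_in.end());
  std::vector<double> unew(n * n);

  const double dh2 = du / (h * h);
  int nsnap = (snap_every > 0) ? nsteps / snap_every : 0;
  List us(nsnap), Us(nsnap), chis(nsnap), dirs(nsnap);
  NumericVector times(nsnap);
  int isnap = 0;

  for (int k = 1; k <= nsteps; ++k) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        const int id = i + n * j;
        const double uc = u[id];
        const double ul = (i > 0)     ? u[id - 1] : uc;  // mirrored ghosts
        const double ur = (i < n - 1) ? u[id + 1] : uc;
        const double ud = (j > 0)     ? u[id - n] : uc;
        const double uu = (j < n - 1) ? u[id + n] : uc;
        const double lap = dh2 * (ul + ur + ud + uu - 4.0 * uc);
        const double rate = reaction(uc, chi[id], g, a1, a2, a0, mu);
        if (chi[id] == 1.0) {
          U[id] += g * uc * dt;
          if (U[id] > utot) chi[id] = 0.0;  // store exhausted, one-way switch
        }
        double un = uc + dt * (lap + rate);
        check_finite(un, dt, k);
        if (un < 0.0) un = 0.0;  // clip roundoff-scale negatives
        if (un > uc) dir[id] = 1.0;
        else if (un < uc) dir[id] = -1.0;
        unew[id] = un;
      }
    }
    u.swap(unew);
    if (snap_every > 0 && k % snap_every == 0) {
      NumericMatrix mu_(n, n), mU(n, n), mc(n, n), md(n, n);
      std::copy(u.begin(), u.end(), mu_.begin());
      std::copy(U.begin(), U.end(), mU.begin());
      std::copy(chi.begin(), chi.end(), mc.begin());
      std::copy(dir.begin(), dir.end(), md.begin());
      us[isnap] = mu_; Us[isnap] = mU; chis[isnap] = mc; dirs[isnap] = md;
      times[isnap] = k * dt;
      ++isnap;
    }
  }

  NumericMatrix fu(n, n), fU(n, n), fc(n, n), fd(n, n);
  std::copy(u.begin(), u.end(), fu.begin());
  std::copy(U.begin(), U.end(), fU.begin());
  std::copy(chi.begin(), chi.end(), fc.begin());
  std::copy(dir.begin(), dir.end(), fd.begin());
  return List::create(_["times"] = times, _["u"] = us, _["U"] = Us,
                      _["chi"] = chis, _["dir"] = dirs,
                      _["u_final"] = fu, _["U_final"] = fU,
                      _["chi_final"] = fc, _["dir_final"] = fd);
}

// Axisymmetric (1-D radial) finite-volume reduction on r in [0, rmax].
// Cell centers r_i = (i + 1/2) h; fluxes through faces r = i h vanish at both
// ends (zero flux at the axis by symmetry and at the outer edge).
// [[Rcpp::export]]
List rd_core_radial(NumericVector u_in, NumericVector U_in, NumericVector chi_in,
                    NumericVector dir_in,
                    double g, double a1, double a2, double a0, double mu,
                    double du, double utot, double h, double dt,
                    int nsteps, int snap_every) {
  const int n = u_in.size();
  std::vector<double> u(u_in.begin(), u_in.end());
  std::vector<double> U(U_in.begin(), U_in.end());
  std::vector<double> chi(chi_in.begin(), chi_in.end());
  std::vector<double> dir(dir_in.begin(), dir_in.end());
  std::vector<double> unew(n), clo(n), chi_coef(n), cup(n);

  for (int i = 0; i < n; ++i) {
    const double rc = (i + 0.5) * h;
    clo[i] = du * (i * h) / (rc * h * h);        // lower face r = i h
    cup[i] = du * ((i + 1) * h) / (rc * h * h);  // upper face r = (i+1) h
  }

  int nsnap = (snap_every > 0) ? nsteps / snap_every : 0;
  List us(nsnap), Us(nsnap), chis(nsnap), dirs(nsnap);
  NumericVector times(nsnap);
  int isnap = 0;

  for (int k = 1; k <= nsteps; ++k) {
    for (int i = 0; i < n; ++i) {
      const double uc = u[i];
      const double flo = (i > 0)     ? clo[i] * (u[i - 1] - uc) : 0.0;
      const double fup = (i < n - 1) ? cup[i] * (u[i + 1] - uc) : 0.0;
      const double rate = reaction(uc, chi[i], g, a1, a2, a0, mu);
      if (chi[i] == 1.0) {
        U[i] += g * uc * dt;
        if (U[i] > utot) chi[i] = 0.0;
      }
      double un = uc + dt * (flo + fup + rate);
      check_finite(un, dt, k);
      if (un < 0.0) un = 0.0;
      if (un > uc) dir[i] = 1.0;
      else if (un < uc) dir[i] = -1.0;
      unew[i] = un;
    }
    u.swap(unew);
    if (snap_every > 0 && k % snap_every == 0) {
      us[isnap] = NumericVector(u.begin(), u.end());
      Us[isnap] = NumericVector(U.begin(), U.end());
      chis[isnap] = NumericVector(chi.begin(), chi.end());
      dirs[isnap] = NumericVector(dir.begin(), dir.end());
      times[isnap] = k * dt;
      ++isnap;
    }
  }

  return List::create(_["times"] = times, _["u"] = us, _["U"] = Us,
                      _["chi"] = chis, _["dir"] = dirs,
                      _["u_final"] = NumericVector(u.begin(), u.end()),
                      _["U_final"] = NumericVector(U.begin(), U.end()),
                      _["chi_final"] = NumericVector(chi.begin(), chi.end()),
                      _["dir_final"] = NumericVector(dir.begin(), dir.end()));
}
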