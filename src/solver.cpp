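// Staggered-grid (MAC) projection solver for 2D incompressible flow with
// variable (regularized Casson) viscosity, Brinkman volume penalization of
// the vessel wall and a Darcy momentum sink for the coil region.
//
// Layout (0-based): cells (nx, ny); u on x-faces (nx+1, ny); v on y-faces
// (nx, ny+1); nodes (nx+1, ny+1). Isotropic spacing dx.
//
// Time scheme: explicit second-order upwind advection; stress-form
// variable-viscosity diffusion with the diagonal treated implicitly
// (point-implicit, unconditionally stable for diffusion); penalization and
// Darcy sinks implicit pointwise; exact pressure projection each step via a
// direct fast Poisson solver (cosine eigen-transform across y, Thomas
// sweeps along x; Neumann at inlet/walls, Dirichlet p = 0 at the outlet).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double casson_mu(double g, double eta, double tau_y, double m) {
  double reg = (g > 0.0) ? (-std::expm1(-m * g) / g) : m;
  double s = std::sqrt(eta) + std::sqrt(tau_y * reg);
  return 0.1 * s * s;
}

// Solve  Lap(p) + (lam_k in y) = rhs  with Neumann left/top/bottom and
// Dirichlet p=0 at the outlet face. V: orthonormal cosine eigenvectors
// (ny x ny), lam: eigenvalues of the 1D Neumann Laplacian across y.
static void poisson_direct(const mat& rhs, const mat& V, const vec& lam,
                           double dx, mat& p, mat& work,
                           vec& a, vec& b, vec& c, vec& d) {
  const int nx = rhs.n_rows, ny = rhs.n_cols;
  const double idx2 = 1.0 / (dx * dx);
  work = rhs * V; // transform to eigenspace across y
  for (int k = 0; k < ny; ++k) {
    // tridiagonal in x: sub/sup = idx2, diag = -2 idx2 + lam_k,
    // Neumann at i=0 (+idx2), Dirichlet ghost at i=nx-1 (-idx2)
    for (int i = 0; i < nx; ++i) {
      a(i) = idx2; c(i) = idx2;
      b(i) = -2.0 * idx2 + lam(k);
      d(i) = work(i, k);
    }
    b(0) += idx2;
    b(nx - 1) -= idx2;
    // Thomas
    for (int i = 1; i < nx; ++i) {
      double w = a(i) / b(i - 1);
      b(i) -= w * c(i - 1);
      d(i) -= w * d(i - 1);
    }
    d(nx - 1) /= b(nx - 1);
    for (int i = nx - 2; i >= 0; --i)
      d(i) = (d(i) - c(i) * d(i + 1)) / b(i);
    for (int i = 0; i < nx; ++i) work(i, k) = d(i);
  }
  p = work * V.t(); // back-transform
}

// [[Rcpp::export]]
arma::mat poisson_solve_cpp(const arma::mat& rhs, const arma::mat& V,
                            const arma::vec& lam, double dx) {
  mat p(rhs.n_rows, rhs.n_cols), work(rhs.n_rows, rhs.n_cols);
  vec a(rhs.n_rows), b(rhs.n_rows), c(rhs.n_rows), d(rhs.n_rows);
  poisson_direct(rhs, V, lam, dx, p, work, a, b, c, d);
  return p;
}

// [[Rcpp::export]]
Rcpp::List run_flow_cpp(Rcpp::List setup) {
  const int nx = Rcpp::as<int>(setup["nx"]);
  const int ny = Rcpp::as<int>(setup["ny"]);
  const double dx = Rcpp::as<double>(setup["dx"]);
  const double dt = Rcpp::as<double>(setup["dt"]);
  const double t_end = Rcpp::as<double>(setup["t_end"]);
  const double rho = Rcpp::as<double>(setup["rho"]);
  const double eta = Rcpp::as<double>(setup["eta"]);
  const double tau_y = Rcpp::as<double>(setup["tau_y"]);
  const double m_reg = Rcpp::as<double>(setup["m"]);
  const double eps_pen = Rcpp::as<double>(setup["eps"]);
  const double Kperm = Rcpp::as<double>(setup["K"]); // <=0: no coil
  const mat chi_u = Rcpp::as<mat>(setup["chi_u"]);     // (nx+1, ny) solid fraction
  const mat chi_v = Rcpp::as<mat>(setup["chi_v"]);     // (nx, ny+1)
  const mat sdf_u = Rcpp::as<mat>(setup["sdf_u"]);     // level fn at u-faces
  const mat sdf_v = Rcpp::as<mat>(setup["sdf_v"]);     // level fn at v-faces
  const mat chic_u = Rcpp::as<mat>(setup["chic_u"]);   // coil fraction on u-faces
  const mat chic_v = Rcpp::as<mat>(setup["chic_v"]);
  const umat lumen = Rcpp::as<umat>(setup["lumen"]);   // (nx, ny)
  const umat sacm = Rcpp::as<umat>(setup["sac"]);
  const umat deep = Rcpp::as<umat>(setup["deep_solid"]); // >= 1 cell into wall
  const mat inlet_prof = Rcpp::as<mat>(setup["inlet_prof"]); // (ny, nt_in)
  const double in_t0 = Rcpp::as<double>(setup["inlet_t0"]);
  const double in_dt = Rcpp::as<double>(setup["inlet_dt"]);
  const mat V = Rcpp::as<mat>(setup["V"]);
  const vec lam = Rcpp::as<vec>(setup["lam"]);
  const vec rec_times = Rcpp::as<vec>(setup["rec_times"]);
  const int series_every = Rcpp::as<int>(setup["series_every"]);

  const int n_in = inlet_prof.n_cols;
  const int nrec = rec_times.n_elem;
  const long nsteps = (long)std::ceil(t_end / dt - 1e-9);

  mat u(nx + 1, ny, fill::zeros), v(nx, ny + 1, fill::zeros);
  mat us(nx + 1, ny, fill::zeros), vs(nx, ny + 1, fill::zeros);
  mat p(nx, ny, fill::zeros), mu(nx, ny, fill::zeros);
  mat dudx_c(nx, ny, fill::zeros), dvdy_c(nx, ny, fill::zeros);
  mat Sn(nx + 1, ny + 1, fill::zeros), mun(nx + 1, ny + 1, fill::zeros);
  // dSn/du for the face above/below each node and dSn/dv for the face
  // right/left of it (one-sided sub-cell stencils at wall-adjacent nodes)
  mat au_hi(nx + 1, ny + 1, fill::zeros), au_lo(nx + 1, ny + 1, fill::zeros);
  mat av_hi(nx + 1, ny + 1, fill::zeros), av_lo(nx + 1, ny + 1, fill::zeros);
  mat rhs(nx, ny, fill::zeros), work(nx, ny, fill::zeros);
  mat dp(nx, ny, fill::zeros);
  vec ta(nx), tb(nx), tc(nx), td(nx);

  cube uc_snap(nx, ny, nrec, fill::zeros), vc_snap(nx, ny, nrec, fill::zeros);
  cube p_snap(nx, ny, nrec, fill::zeros), mu_snap(nx, ny, nrec, fill::zeros);
  vec rec_actual(nrec, fill::zeros);
  int rec_ptr = 0;

  std::vector<double> ser_t, ser_qin, ser_qout, ser_div, ser_ke, ser_uslip;

  // open outlet rows (for the global mass correction)
  std::vector<int> open_rows;
  for (int j = 0; j < ny; ++j)
    if (chi_u(nx, j) < 0.5) open_rows.push_back(j);
  if (open_rows.empty()) Rcpp::stop("outlet entirely solid");

  const double mu_newt = 0.1 * eta; // infinite-shear plateau

  auto inlet_at = [&](int j, double t) -> double {
    double s = (t - in_t0) / in_dt;
    if (s <= 0) return inlet_prof(j, 0);
    if (s >= n_in - 1) return inlet_prof(j, n_in - 1);
    int k = (int)std::floor(s);
    double f = s - k;
    return (1.0 - f) * inlet_prof(j, k) + f * inlet_prof(j, k + 1);
  };

  double t = 0.0;
  for (long step = 0; step < nsteps; ++step) {
    const double t_new = t + dt;

    // ---- viscosity from the current field -------------------------------
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        dudx_c(i, j) = (u(i + 1, j) - u(i, j)) / dx;
        dvdy_c(i, j) = (v(i, j + 1) - v(i, j)) / dx;
      }
    const double dmin = 0.3 * dx, dmax = dx;
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        // dudy across the node, wall-aware: when exactly one of the two
        // u-faces is solid, the wall position interpolated from the face
        // level function replaces the solid value by the no-slip point
        double dudy, c_hi = 0.0, c_lo = 0.0;
        if (j == 0) { dudy = 2.0 * u(i, 0) / dx; c_hi = 2.0 / dx; }
        else if (j == ny) { dudy = -2.0 * u(i, ny - 1) / dx; c_lo = -2.0 / dx; }
        else {
          bool sol_hi = chi_u(i, j) >= 0.5, sol_lo = chi_u(i, j - 1) >= 0.5;
          if (sol_hi == sol_lo) {
            dudy = (u(i, j) - u(i, j - 1)) / dx;
            c_hi = 1.0 / dx; c_lo = -1.0 / dx;
          } else if (sol_lo) { // fluid above, wall below
            double d = dx * (-sdf_u(i, j)) / (sdf_u(i, j - 1) - sdf_u(i, j));
            d = std::min(std::max(d, dmin), dmax);
            dudy = u(i, j) / d; c_hi = 1.0 / d;
          } else {             // fluid below, wall above
            double d = dx * (-sdf_u(i, j - 1)) / (sdf_u(i, j) - sdf_u(i, j - 1));
            d = std::min(std::max(d, dmin), dmax);
            dudy = -u(i, j - 1) / d; c_lo = -1.0 / d;
          }
        }
        double dvdx, cv_hi = 0.0, cv_lo = 0.0;
        if (i == 0) { dvdx = 2.0 * v(0, j) / dx; cv_hi = 2.0 / dx; }
        else if (i == nx) { dvdx = 0.0; }
        else {
          bool sol_r = chi_v(i, j) >= 0.5, sol_l = chi_v(i - 1, j) >= 0.5;
          if (sol_r == sol_l) {
            dvdx = (v(i, j) - v(i - 1, j)) / dx;
            cv_hi = 1.0 / dx; cv_lo = -1.0 / dx;
          } else if (sol_l) { // fluid right, wall left
            double d = dx * (-sdf_v(i, j)) / (sdf_v(i - 1, j) - sdf_v(i, j));
            d = std::min(std::max(d, dmin), dmax);
            dvdx = v(i, j) / d; cv_hi = 1.0 / d;
          } else {            // fluid left, wall right
            double d = dx * (-sdf_v(i - 1, j)) / (sdf_v(i, j) - sdf_v(i - 1, j));
            d = std::min(std::max(d, dmin), dmax);
            dvdx = -v(i - 1, j) / d; cv_lo = -1.0 / d;
          }
        }
        Sn(i, j) = dudy + dvdx;
        au_hi(i, j) = c_hi; au_lo(i, j) = c_lo;
        av_hi(i, j) = cv_hi; av_lo(i, j) = cv_lo;
      }
    if (tau_y > 0.0) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double Sc = 0.25 * (Sn(i, j) + Sn(i + 1, j) + Sn(i, j + 1) + Sn(i + 1, j + 1));
          double g = std::sqrt(2.0 * dudx_c(i, j) * dudx_c(i, j)
                               + 2.0 * dvdy_c(i, j) * dvdy_c(i, j) + Sc * Sc);
          mu(i, j) = casson_mu(g, eta, tau_y, m_reg);
        }
    } else {
      mu.fill(mu_newt);
    }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int il = std::max(i - 1, 0), ir = std::min(i, nx - 1);
        int jb = std::max(j - 1, 0), jt = std::min(j, ny - 1);
        mun(i, j) = 0.25 * (mu(il, jb) + mu(ir, jb) + mu(il, jt) + mu(ir, jt));
      }

    // ---- tentative u ----------------------------------------------------
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        double ua = u(i, j);
        double va = 0.25 * (v(i - 1, j) + v(i, j) + v(i - 1, j + 1) + v(i, j + 1));
        double dudx;
        if (ua >= 0)
          dudx = (i >= 2) ? (3 * u(i, j) - 4 * u(i - 1, j) + u(i - 2, j)) / (2 * dx)
                          : (u(i, j) - u(i - 1, j)) / dx;
        else
          dudx = (i <= nx - 2) ? (-3 * u(i, j) + 4 * u(i + 1, j) - u(i + 2, j)) / (2 * dx)
                               : (u(i + 1, j) - u(i, j)) / dx;
        double dudy;
        if (va >= 0)
          dudy = (j >= 2) ? (3 * u(i, j) - 4 * u(i, j - 1) + u(i, j - 2)) / (2 * dx)
               : (j == 1) ? (u(i, j) - u(i, j - 1)) / dx
                          : 2.0 * u(i, 0) / dx;
        else
          dudy = (j <= ny - 3) ? (-3 * u(i, j) + 4 * u(i, j + 1) - u(i, j + 2)) / (2 * dx)
               : (j == ny - 2) ? (u(i, j + 1) - u(i, j)) / dx
                               : -2.0 * u(i, ny - 1) / dx;
        double adv = ua * dudx + va * dudy;
        double t11R = 2.0 * mu(i, j) * dudx_c(i, j);
        double t11L = 2.0 * mu(i - 1, j) * dudx_c(i - 1, j);
        double t12T = mun(i, j + 1) * Sn(i, j + 1);
        double t12B = mun(i, j) * Sn(i, j);
        double diff = ((t11R - t11L) + (t12T - t12B)) / (dx * rho);
        double adiag = (2.0 * mu(i, j) + 2.0 * mu(i - 1, j)) / (rho * dx * dx)
                     + (mun(i, j) * au_hi(i, j)
                        - mun(i, j + 1) * au_lo(i, j + 1)) / (rho * dx);
        double mu_f = 0.5 * (mu(i - 1, j) + mu(i, j));
        double sigma = chi_u(i, j) / eps_pen
                     + ((Kperm > 0) ? chic_u(i, j) * mu_f / (rho * Kperm) : 0.0);
        double gradp = (p(i, j) - p(i - 1, j)) / (dx * rho);
        us(i, j) = (u(i, j) + dt * (-adv + diff - gradp + adiag * u(i, j)))
                 / (1.0 + dt * adiag + dt * sigma);
      }

    // ---- tentative v ----------------------------------------------------
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double va = v(i, j);
        double ua = 0.25 * (u(i, j - 1) + u(i + 1, j - 1) + u(i, j) + u(i + 1, j));
        double dvdy;
        if (va >= 0)
          dvdy = (j >= 2) ? (3 * v(i, j) - 4 * v(i, j - 1) + v(i, j - 2)) / (2 * dx)
                          : (v(i, j) - v(i, j - 1)) / dx;
        else
          dvdy = (j <= ny - 2) ? (-3 * v(i, j) + 4 * v(i, j + 1) - v(i, j + 2)) / (2 * dx)
                               : (v(i, j + 1) - v(i, j)) / dx;
        double dvdx;
        if (ua >= 0)
          dvdx = (i >= 2) ? (3 * v(i, j) - 4 * v(i - 1, j) + v(i - 2, j)) / (2 * dx)
               : (i == 1) ? (v(i, j) - v(i - 1, j)) / dx
                          : 2.0 * v(0, j) / dx;
        else
          dvdx = (i <= nx - 3) ? (-3 * v(i, j) + 4 * v(i + 1, j) - v(i + 2, j)) / (2 * dx)
               : (i == nx - 2) ? (v(i + 1, j) - v(i, j)) / dx
                               : 0.0;
        double adv = ua * dvdx + va * dvdy;
        double t22T = 2.0 * mu(i, j) * dvdy_c(i, j);
        double t22B = 2.0 * mu(i, j - 1) * dvdy_c(i, j - 1);
        double t12R = mun(i + 1, j) * Sn(i + 1, j);
        double t12L = mun(i, j) * Sn(i, j);
        double diff = ((t22T - t22B) + (t12R - t12L)) / (dx * rho);
        double adiag = (2.0 * mu(i, j) + 2.0 * mu(i, j - 1)) / (rho * dx * dx)
                     + (mun(i, j) * av_hi(i, j)
                        - mun(i + 1, j) * av_lo(i + 1, j)) / (rho * dx);
        double mu_f = 0.5 * (mu(i, j - 1) + mu(i, j));
        double sigma = chi_v(i, j) / eps_pen
                     + ((Kperm > 0) ? chic_v(i, j) * mu_f / (rho * Kperm) : 0.0);
        double gradp = (p(i, j) - p(i, j - 1)) / (dx * rho);
        vs(i, j) = (v(i, j) + dt * (-adv + diff - gradp + adiag * v(i, j)))
                 / (1.0 + dt * adiag + dt * sigma);
      }

    // ---- boundary conditions on the tentative field ---------------------
    double qin = 0.0;
    for (int j = 0; j < ny; ++j) {
      us(0, j) = inlet_at(j, t_new);
      qin += us(0, j);
    }
    double qout = 0.0;
    for (int j = 0; j < ny; ++j) {
      us(nx, j) = (chi_u(nx, j) >= 0.5) ? 0.0 : us(nx - 1, j);
      qout += us(nx, j);
    }
    double dq = (qin - qout) / (double)open_rows.size();
    for (int j : open_rows) us(nx, j) += dq;
    for (int i = 0; i < nx; ++i) { vs(i, 0) = 0.0; vs(i, ny) = 0.0; }

    // ---- projection ------------------------------------------------------
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        rhs(i, j) = rho / dt * ((us(i + 1, j) - us(i, j))
                                + (vs(i, j + 1) - vs(i, j))) / dx;
    poisson_direct(rhs, V, lam, dx, dp, work, ta, tb, tc, td);
    for (int j = 0; j < ny; ++j) {
      for (int i = 1; i < nx; ++i)
        us(i, j) -= dt / rho * (dp(i, j) - dp(i - 1, j)) / dx;
      us(nx, j) -= dt / rho * (-2.0 * dp(nx - 1, j)) / dx; // Dirichlet ghost
    }
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        vs(i, j) -= dt / rho * (dp(i, j) - dp(i, j - 1)) / dx;
    p += dp;

    u = us; v = vs; t = t_new;

    // ---- diagnostics / recording ----------------------------------------
    if (step % series_every == 0 || step == nsteps - 1) {
      double maxdiv = 0.0, ke = 0.0, uslip = 0.0;
      double qi = 0.0, qo = 0.0;
      for (int j = 0; j < ny; ++j) { qi += u(0, j); qo += u(nx, j); }
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double dv = std::fabs((u(i + 1, j) - u(i, j)) + (v(i, j + 1) - v(i, j))) / dx;
          if (lumen(i, j) && dv > maxdiv) maxdiv = dv;
          double ucc = 0.5 * (u(i, j) + u(i + 1, j));
          double vcc = 0.5 * (v(i, j) + v(i, j + 1));
          if (sacm(i, j)) ke += 0.5 * rho * (ucc * ucc + vcc * vcc) * dx * dx;
          if (deep(i, j)) {
            double sp = std::sqrt(ucc * ucc + vcc * vcc);
            if (sp > uslip) uslip = sp;
          }
        }
      ser_t.push_back(t); ser_qin.push_back(qi * dx); ser_qout.push_back(qo * dx);
      ser_div.push_back(maxdiv); ser_ke.push_back(ke); ser_uslip.push_back(uslip);
      if (!u.is_finite() || !v.is_finite()) {
        uvec badu = find_nonfinite(u);
        uvec badv = find_nonfinite(v);
        int idx = badu.is_empty() ? (int)badv(0) : (int)badu(0);
        Rcpp::stop("non-finite velocity at t = %f (first offending face index %d)",
                   t, idx);
      }
    }
    while (rec_ptr < nrec && t >= rec_times(rec_ptr) - 1e-12) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          uc_snap(i, j, rec_ptr) = 0.5 * (u(i, j) + u(i + 1, j));
          vc_snap(i, j, rec_ptr) = 0.5 * (v(i, j) + v(i, j + 1));
          p_snap(i, j, rec_ptr) = p(i, j);
          mu_snap(i, j, rec_ptr) = mu(i, j);
        }
      rec_actual(rec_ptr) = t;
      ++rec_ptr;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  // flush any snapshot scheduled within rounding of the final time
  while (rec_ptr < nrec && rec_times(rec_ptr) <= t + dt) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        uc_snap(i, j, rec_ptr) = 0.5 * (u(i, j) + u(i + 1, j));
        vc_snap(i, j, rec_ptr) = 0.5 * (v(i, j) + v(i, j + 1));
        p_snap(i, j, rec_ptr) = p(i, j);
        mu_snap(i, j, rec_ptr) = mu(i, j);
      }
    rec_actual(rec_ptr) = t;
    ++rec_ptr;
  }

  return Rcpp::List::create(
    Rcpp::Named("uc") = uc_snap, Rcpp::Named("vc") = vc_snap,
    Rcpp::Named("p") = p_snap, Rcpp::Named("mu") = mu_snap,
    Rcpp::Named("rec_t") = rec_actual,
    Rcpp::Named("n_recorded") = rec_ptr,
    Rcpp::Named("series") = Rcpp::DataFrame::create(
      Rcpp::Named("t") = ser_t, Rcpp::Named("q_in") = ser_qin,
      Rcpp::Named("q_out") = ser_qout, Rcpp::Named("max_div") = ser_div,
      Rcpp::Named("ke_sac") = ser_ke, Rcpp::Named("max_u_solid") = ser_uslip),
    Rcpp::Named("u_final") = u, Rcpp::Named("v_final") = v,
    Rcpp::Named("p_final") = p, Rcpp::Named("mu_final") = mu,
    Rcpp::Named("t_final") = t, Rcpp::Named("dt") = dt);
}
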