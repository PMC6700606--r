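#include "models.h"

using namespace Rcpp;

namespace lf {

bool add_fene(const std::vector<double>& x, int N, const FeneParams& p,
              std::vector<double>& f, double& energy) {
  const double R02 = p.R0 * p.R0;
  for (int i = 0; i < N - 1; ++i) {
    double d[3] = {x[3 * (i + 1)] - x[3 * i], x[3 * (i + 1) + 1] - x[3 * i + 1],
                   x[3 * (i + 1) + 2] - x[3 * i + 2]};
    double r2 = dot3(d, d);
    if (r2 >= R02) return false;  // bond overstretched
    energy += -0.5 * p.k * R02 * std::log(1.0 - r2 / R02);
    // dU/dr = k r / (1 - r^2/R0^2); force on i+1 is -dU/dr * rhat
    double coef = -p.k / (1.0 - r2 / R02);  // force factor per component
    for (int c = 0; c < 3; ++c) {
      f[3 * (i + 1) + c] += coef * d[c];
      f[3 * i + c] -= coef * d[c];
    }
  }
  return true;
}

void add_wca(const std::vector<double>& x, int N, double eps, double sigma,
             bool exclude_bonded, const std::vector<char>& excl,
             std::vector<double>& f, double& energy) {
  const double s2 = sigma * sigma;
  const double rc2 = std::cbrt(2.0) * s2;  // (2^{1/6} sigma)^2
  const bool have_excl = !excl.empty();
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (exclude_bonded && j == i + 1) continue;
      if (have_excl && excl[(size_t)i * N + j]) continue;
      double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                     x[3 * j + 2] - x[3 * i + 2]};
      double r2 = dot3(d, d);
      if (r2 >= rc2) continue;
      double sr2 = s2 / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      energy += 4.0 * eps * (sr12 - sr6) + eps;
      double fr = 24.0 * eps * (2.0 * sr12 - sr6) / r2;  // (-dU/dr)/r
      for (int c = 0; c < 3; ++c) {
        f[3 * j + c] += fr * d[c];
        f[3 * i + c] -= fr * d[c];
      }
    }
  }
}

void add_bending(const std::vector<double>& x, int N,
                 const std::vector<double>& theta0,
                 const std::vector<double>& kbend, std::vector<double>& f,
                 double& energy) {
  for (int t = 0; t < N - 2; ++t) {
    const double* ri = &x[3 * t];
    const double* rj = &x[3 * (t + 1)];
    const double* rk = &x[3 * (t + 2)];
    double a[3] = {ri[0] - rj[0], ri[1] - rj[1], ri[2] - rj[2]};
    double b[3] = {rk[0] - rj[0], rk[1] - rj[1], rk[2] - rj[2]};
    double na = norm3(a), nb = norm3(b);
    if (na < 1e-12 || nb < 1e-12) continue;
    double ct = dot3(a, b) / (na * nb);
    ct = std::max(-1.0, std::min(1.0, ct));
    double theta = std::acos(ct);
    double dth = theta - theta0[t];
    energy += kbend[t] * dth * dth;
    // sin(theta) in the denominator is cancelled by the sin(theta) decay
    // of dcos/dr, so dtheta/dr stays bounded at collinearity; the guard
    // only protects against rounding at sin(theta) ~ 1e-6
    double st = std::sqrt(std::max(1e-12, 1.0 - ct * ct));
    double dUdth = 2.0 * kbend[t] * dth;
    // dtheta/dri = -1/sin * dcos/dri; dcos/dri = b/(na nb) - ct a/na^2
    for (int c = 0; c < 3; ++c) {
      double dci = b[c] / (na * nb) - ct * a[c] / (na * na);
      double dck = a[c] / (na * nb) - ct * b[c] / (nb * nb);
      double gi = -dci / st;  // dtheta/dri
      double gk = -dck / st;
      f[3 * t + c] -= dUdth * gi;
      f[3 * (t + 2) + c] -= dUdth * gk;
      f[3 * (t + 1) + c] += dUdth * (gi + gk);
    }
  }
}

void add_torsion(const std::vector<double>& x, int N,
                 const std::vector<double>& phi0,
                 const std::vector<double>& k1,
                 const std::vector<double>& k3, std::vector<double>& f,
                 double& energy) {
  for (int t = 0; t < N - 3; ++t) {
    const double* p1 = &x[3 * t];
    const double* p2 = &x[3 * (t + 1)];
    const double* p3 = &x[3 * (t + 2)];
    const double* p4 = &x[3 * (t + 3)];
    double b1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double b2[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
    double b3[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double nb2 = norm3(b2);
    if (n1sq < 1e-14 || n2sq < 1e-14 || nb2 < 1e-12) continue;
    double phi = std::atan2(nb2 * dot3(b1, n2), dot3(n1, n2));
    double dphi = phi - phi0[t];
    energy += k1[t] * (1.0 - std::cos(dphi)) + k3[t] * (1.0 - std::cos(3.0 * dphi));
    // The dihedral gradient diverges like 1/sin(theta) when either
    // flanking bond angle approaches linearity (where the dihedral itself
    // is ill-conditioned). The torque is tapered smoothly to zero below
    // sin(theta) = 0.2 so stretched, near-collinear chains stay
    // integrable at dt = 5e-4; the taper is exactly 1 in the well-bent
    // regime of folded and folding structures.
    double b1sq = dot3(b1, b1), b3sq = dot3(b3, b3);
    double s1sq = n1sq / (b1sq * nb2 * nb2);
    double s2sq = n2sq / (b3sq * nb2 * nb2);
    double smin = std::sqrt(std::min(s1sq, s2sq));
    double taper = 1.0;
    if (smin < 0.2) {
      double u = smin / 0.2;
      taper = u * u * (3.0 - 2.0 * u);
    }
    double dUdphi =
        taper *
        (k1[t] * std::sin(dphi) + 3.0 * k3[t] * std::sin(3.0 * dphi));
    double g1[3], g4[3];
    for (int c = 0; c < 3; ++c) {
      g1[c] = -nb2 / n1sq * n1[c];      // dphi/dr1
      g4[c] = nb2 / n2sq * n2[c];       // dphi/dr4
    }
    double c12 = dot3(b1, b2) / (nb2 * nb2);
    double c32 = dot3(b3, b2) / (nb2 * nb2);
    for (int c = 0; c < 3; ++c) {
      double g2 = (-1.0 - c12) * g1[c] + c32 * g4[c];  // dphi/dr2
      double g3 = c12 * g1[c] + (-1.0 - c32) * g4[c];  // dphi/dr3
      f[3 * t + c] -= dUdphi * g1[c];
      f[3 * (t + 1) + c] -= dUdphi * g2;
      f[3 * (t + 2) + c] -= dUdphi * g3;
      f[3 * (t + 3) + c] -= dUdphi * g4[c];
    }
  }
}

void add_shifted_lj(const std::vector<double>& x, int i, int j, double eps,
                    double sigma, double rc, std::vector<double>& f,
                    double& energy) {
  double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                 x[3 * j + 2] - x[3 * i + 2]};
  double r = norm3(d);
  if (r >= rc || r < 1e-12) return;
  auto ulj = [&](double rr) {
    double sr6 = std::pow(sigma / rr, 6);
    return 4.0 * eps * (sr6 * sr6 - sr6);
  };
  auto dulj = [&](double rr) {
    double sr6 = std::pow(sigma / rr, 6);
    return -24.0 * eps * (2.0 * sr6 * sr6 - sr6) / rr;
  };
  energy += ulj(r) - ulj(rc) - (r - rc) * dulj(rc);
  double dudr = dulj(r) - dulj(rc);
  double fr = -dudr / r;  // force on j along +d
  for (int c = 0; c < 3; ++c) {
    f[3 * j + c] += fr * d[c];
    f[3 * i + c] -= fr * d[c];
  }
}

void add_contact_1210(const std::vector<double>& x, int i, int j, double E,
                      double r0, std::vector<double>& f, double& energy) {
  double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                 x[3 * j + 2] - x[3 * i + 2]};
  double r = norm3(d);
  if (r < 1e-12) return;
  double q = r0 / r;
  double q10 = std::pow(q, 10);
  double q12 = q10 * q * q;
  energy += E * (5.0 * q12 - 6.0 * q10);
  double dudr = -60.0 * E * (q12 - q10) / r;
  double fr = -dudr / r;
  for (int c = 0; c < 3; ++c) {
    f[3 * j + c] += fr * d[c];
    f[3 * i + c] -= fr * d[c];
  }
}

bool EfmModel::eval(const std::vector<double>& x, std::vector<double>& f,
                    EnergyBreakdown& e) const {
  std::fill(f.begin(), f.end(), 0.0);
  e = EnergyBreakdown();
  if (!add_fene(x, N, fene, f, e.bonds)) return false;
  add_wca(x, N, wca_eps, wca_sigma, exclude_bonded, std::vector<char>(), f,
          e.steric);
  add_bending(x, N, theta0, kbend, f, e.bending);
  add_torsion(x, N, phi0, k1, k3, f, e.torsion);
  if (bridges_enabled) {
    for (size_t b = 0; b < br_i.size(); ++b)
      add_shifted_lj(x, br_i[b], br_j[b], br_eps[b], br_sigma[b], br_rc[b], f,
                     e.pairs);
  }
  return true;
}

bool GoModel::eval(const std::vector<double>& x, std::vector<double>& f,
                   EnergyBreakdown& e) const {
  std::fill(f.begin(), f.end(), 0.0);
  e = EnergyBreakdown();
  for (int i = 0; i < N - 1; ++i) {
    double d[3] = {x[3 * (i + 1)] - x[3 * i],
                   x[3 * (i + 1) + 1] - x[3 * i + 1],
                   x[3 * (i + 1) + 2] - x[3 * i + 2]};
    double r = norm3(d);
    if (r < 1e-12) continue;
    double dr = r - bond_r0[i];
    e.bonds += k_bond * dr * dr;
    double fr = -2.0 * k_bond * dr / r;
    for (int c = 0; c < 3; ++c) {
      f[3 * (i + 1) + c] += fr * d[c];
      f[3 * i + c] -= fr * d[c];
    }
  }
  add_bending(x, N, theta0, kbend, f, e.bending);
  add_torsion(x, N, phi0, k1, k3, f, e.torsion);
  for (size_t m = 0; m < ct_i.size(); ++m)
    add_contact_1210(x, ct_i[m], ct_j[m], ct_E[m], ct_r0[m], f, e.pairs);
  // purely repulsive excluded volume for non-contact, non-local pairs:
  // force-shifted 12-power, cutoff ev_rc (in units of sigma via rc passed)
  for (int i = 0; i < N; ++i) {
    for (int j = i + ev_min_sep; j < N; ++j) {
      if (is_contact[(size_t)i * N + j]) continue;
      double d[3] = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                     x[3 * j + 2] - x[3 * i + 2]};
      double r = norm3(d);
      if (r >= ev_rc || r < 1e-12) continue;
      auto u12 = [&](double rr) { return ev_eps * std::pow(ev_sigma / rr, 12); };
      auto du12 = [&](double rr) { return -12.0 * u12(rr) / rr; };
      e.steric += u12(r) - u12(ev_rc) - (r - ev_rc) * du12(ev_rc);
      double fr = -(du12(r) - du12(ev_rc)) / r;
      for (int c = 0; c < 3; ++c) {
        f[3 * j + c] += fr * d[c];
        f[3 * i + c] -= fr * d[c];
      }
    }
  }
  return true;
}

static std::vector<double> as_vec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

EfmModel build_efm_model(NumericMatrix pos, List ref, List ff, List params,
                         List bridges) {
  EfmModel m;
  m.N = pos.nrow();
  m.fene.k = as<double>(params["k_fene"]);
  m.fene.R0 = as<double>(params["R0"]);
  m.wca_eps = as<double>(params["epsilon"]);
  m.wca_sigma = as<double>(params["sigma"]);
  m.exclude_bonded = as<bool>(params["wca_exclude_bonded"]);
  m.theta0 = as_vec(ref["theta0"]);
  m.phi0 = as_vec(ref["phi0"]);
  m.kbend = as_vec(ff["k_bend"]);
  m.k1 = as_vec(ff["k1_tor"]);
  m.k3.resize(m.k1.size());
  for (size_t i = 0; i < m.k1.size(); ++i) m.k3[i] = m.k1[i] / 3.0;
  m.bridges_enabled = as<bool>(bridges["enabled"]);
  if (m.bridges_enabled) {
    IntegerMatrix pr = bridges["pairs0"];  // 0-based index pairs
    NumericVector eb = bridges["epsilon_b"], sb = bridges["sigma_b"],
                  rc = bridges["r_cut"];
    for (int b = 0; b < pr.nrow(); ++b) {
      m.br_i.push_back(pr(b, 0));
      m.br_j.push_back(pr(b, 1));
      m.br_eps.push_back(eb[b]);
      m.br_sigma.push_back(sb[b]);
      m.br_rc.push_back(rc[b]);
    }
  }
  if ((int)m.theta0.size() != m.N - 2 || (int)m.phi0.size() != m.N - 3 ||
      (int)m.kbend.size() != m.N - 2 || (int)m.k1.size() != m.N - 3)
    stop("inconsistent dimensions between configuration, reference and force field");
  return m;
}

GoModel build_go_model(int N, List goff, List params) {
  GoModel m;
  m.N = N;
  m.k_bond = as<double>(goff["k_bond"]);
  m.bond_r0 = as_vec(goff["bond_r0"]);
  m.theta0 = as_vec(goff["theta0"]);
  m.phi0 = as_vec(goff["phi0"]);
  double kb = as<double>(goff["k_bend_homog"]);
  double k1 = as<double>(goff["k1_tor_homog"]);
  double k3 = as<double>(goff["k3_tor_homog"]);
  m.kbend.assign(N - 2, kb);
  m.k1.assign(N - 3, k1);
  m.k3.assign(N - 3, k3);
  IntegerMatrix ct = goff["contacts0"];  // 0-based i, j
  NumericVector E = goff["E_ij"], r0 = goff["r_native"];
  m.is_contact.assign((size_t)N * N, 0);
  for (int k = 0; k < ct.nrow(); ++k) {
    int i = ct(k, 0), j = ct(k, 1);
    m.ct_i.push_back(i);
    m.ct_j.push_back(j);
    m.ct_E.push_back(E[k]);
    m.ct_r0.push_back(r0[k]);
    m.is_contact[(size_t)i * N + j] = 1;
    m.is_contact[(size_t)j * N + i] = 1;
  }
  m.ev_eps = as<double>(goff["ev_epsilon"]);
  m.ev_sigma = as<double>(goff["ev_sigma"]);
  m.ev_rc = as<double>(goff["ev_r_cut"]);
  m.ev_min_sep = as<int>(goff["ev_min_sep"]);
  return m;
}

List eval_to_list(const Model& m, NumericMatrix pos) {
  int N = m.n_beads();
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  EnergyBreakdown e;
  if (!m.eval(x, f, e)) stop("bond overstretched");
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) F(i, c) = f[3 * i + c];
  return List::create(
      _["energy"] = e.total(), _["forces"] = F,
      _["components"] = NumericVector::create(
          _["steric"] = e.steric, _["bonds"] = e.bonds,
          _["bending"] = e.bending, _["torsion"] = e.torsion,
          _["pairs"] = e.pairs));
}

List chain_angles_impl(NumericMatrix pos) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos(i, c);
  NumericVector theta(std::max(0, N - 2)), phi(std::max(0, N - 3));
  for (int t = 0; t < N - 2; ++t) {
    double a[3], b[3];
    for (int c = 0; c < 3; ++c) {
      a[c] = x[3 * t + c] - x[3 * (t + 1) + c];
      b[c] = x[3 * (t + 2) + c] - x[3 * (t + 1) + c];
    }
    double ct = dot3(a, b) / (norm3(a) * norm3(b));
    theta[t] = std::acos(std::max(-1.0, std::min(1.0, ct)));
  }
  for (int t = 0; t < N - 3; ++t) {
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = x[3 * (t + 1) + c] - x[3 * t + c];
      b2[c] = x[3 * (t + 2) + c] - x[3 * (t + 1) + c];
      b3[c] = x[3 * (t + 3) + c] - x[3 * (t + 2) + c];
    }
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    if (dot3(n1, n1) < 1e-14 || dot3(n2, n2) < 1e-14) {
      phi[t] = NA_REAL;
    } else {
      phi[t] = std::atan2(norm3(b2) * dot3(b1, n2), dot3(n1, n2));
    }
  }
  return List::create(_["theta"] = theta, _["phi"] = phi);
}

}  // namespace lf

// [[Rcpp::export]]
List efm_energy_forces_cpp(NumericMatrix pos, List ref, List ff, List params,
                           List bridges) {
  lf::EfmModel m = lf::build_efm_model(pos, ref, ff, params, bridges);
  return lf::eval_to_list(m, pos);
}

// [[Rcpp::export]]
List go_energy_forces_cpp(NumericMatrix pos, List goff, List params) {
  lf::GoModel m = lf::build_go_model(pos.nrow(), goff, params);
  return lf::eval_to_list(m, pos);
}

// Bending and dihedral angles of a chain; the same conventions as the
// potentials (interior angle in [0, pi]; signed dihedral in (-pi, pi]).
// Degenerate dihedrals (collinear quadruplets) are returned as NA.
// [[Rcpp::export]]
List chain_angles_cpp(NumericMatrix pos) { return lf::chain_angles_impl(pos); }
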