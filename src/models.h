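#ifndef LASSOFOLD_MODELS_H
#define LASSOFOLD_MODELS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

namespace lf {

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Per-term energy accumulator. Forces are -grad of the summed energy.
struct EnergyBreakdown {
  double steric = 0.0, bonds = 0.0, bending = 0.0, torsion = 0.0,
         pairs = 0.0;  // bridges (EFM) or native contacts (Go)
  double total() const { return steric + bonds + bending + torsion + pairs; }
};

// Abstract force provider: fills f (length 3N, xyz-interleaved) with forces
// and returns the potential energy. Returns ok=false on an overstretched
// FENE bond (energy undefined).
class Model {
 public:
  virtual ~Model() {}
  virtual bool eval(const std::vector<double>& x, std::vector<double>& f,
                    EnergyBreakdown& e) const = 0;
  virtual int n_beads() const = 0;
};

struct FeneParams {
  double k = 30.0, R0 = 1.5;
};

// FENE bonds between consecutive beads. Returns false if any r >= R0.
bool add_fene(const std::vector<double>& x, int N, const FeneParams& p,
              std::vector<double>& f, double& energy);

// WCA sterics over all pairs, optionally excluding bonded neighbours and an
// arbitrary exclusion set (symmetric boolean matrix, may be empty).
void add_wca(const std::vector<double>& x, int N, double eps, double sigma,
             bool exclude_bonded, const std::vector<char>& excl,
             std::vector<double>& f, double& energy);

// Structure-based bending (k (theta-theta0)^2) and torsion
// (k1 [1-cos(dphi)] + k3 [1-cos(3 dphi)]) terms.
void add_bending(const std::vector<double>& x, int N,
                 const std::vector<double>& theta0,
                 const std::vector<double>& kbend, std::vector<double>& f,
                 double& energy);
void add_torsion(const std::vector<double>& x, int N,
                 const std::vector<double>& phi0,
                 const std::vector<double>& k1,
                 const std::vector<double>& k3, std::vector<double>& f,
                 double& energy);

// Truncated, force-shifted LJ pair term (disulfide bridges and the Go-model
// excluded-volume tail use this shape).
void add_shifted_lj(const std::vector<double>& x, int i, int j, double eps,
                    double sigma, double rc, std::vector<double>& f,
                    double& energy);

// 12-10 native-contact term, minimum at r0 with depth E.
void add_contact_1210(const std::vector<double>& x, int i, int j, double E,
                      double r0, std::vector<double>& f, double& energy);

class EfmModel : public Model {
 public:
  int N = 0;
  FeneParams fene;
  double wca_eps = 1.0, wca_sigma = 1.0;
  bool exclude_bonded = true;
  std::vector<double> theta0, phi0, kbend, k1, k3;
  // bridges
  bool bridges_enabled = false;
  std::vector<int> br_i, br_j;
  std::vector<double> br_eps, br_sigma, br_rc;

  bool eval(const std::vector<double>& x, std::vector<double>& f,
            EnergyBreakdown& e) const override;
  int n_beads() const override { return N; }
};

class GoModel : public Model {
 public:
  int N = 0;
  // Clementi-type harmonic bonds at the native bond lengths
  double k_bond = 100.0;
  std::vector<double> bond_r0;
  std::vector<double> theta0, phi0, kbend, k1, k3;
  // native contacts
  std::vector<int> ct_i, ct_j;
  std::vector<double> ct_E, ct_r0;
  // excluded volume for non-contact pairs with |i-j| >= ev_min_sep
  double ev_eps = 1.0, ev_sigma = 1.0, ev_rc = 2.0;
  int ev_min_sep = 3;
  std::vector<char> is_contact;  // N*N boolean

  bool eval(const std::vector<double>& x, std::vector<double>& f,
            EnergyBreakdown& e) const override;
  int n_beads() const override { return N; }
};

EfmModel build_efm_model(Rcpp::NumericMatrix pos_dims_only, Rcpp::List ref,
                         Rcpp::List ff, Rcpp::List params, Rcpp::List bridges);
GoModel build_go_model(int N, Rcpp::List goff, Rcpp::List params);

}  // namespace lf

#endif
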