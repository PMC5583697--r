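#include <Rcpp.h>
#include <cmath>

// 1D characteristic-matrix reflectance of stacks of homogeneous layers at
// normal incidence. For lossless (real-index) media the stack matrix keeps
// the form [[A, iB], [iC, D]] with A, B, C, D real, so the whole product
// runs in real arithmetic. Layer phases are split as delta = theta0 + eps
// with theta0 = k*dz*n0 shared across the column; sin/cos of the small
// per-layer eps use a Taylor polynomial (|eps| < 0.05 keeps the truncation
// below double-precision roundoff), which avoids two libm calls per layer.

static inline void small_sincos(double e, double &s, double &c) {
  if (std::fabs(e) < 0.05) {
    double e2 = e * e;
    s = e * (1.0 - e2 / 6.0 * (1.0 - e2 / 20.0));
    c = 1.0 - e2 / 2.0 * (1.0 - e2 / 12.0 * (1.0 - e2 / 30.0));
  } else {
    s = std::sin(e);
    c = std::cos(e);
  }
}

// [[Rcpp::export]]
Rcpp::List tm_reflectance_cpp(Rcpp::NumericMatrix n_layers, double dz_nm,
                              Rcpp::NumericVector wavelengths_nm,
                              double n_ambient, double n_substrate,
                              double n_ref, bool with_transmission) {
  const int nz = n_layers.nrow();
  const int nprof = n_layers.ncol();
  const int nl = wavelengths_nm.size();
  Rcpp::NumericMatrix R(nl, nprof);
  Rcpp::NumericMatrix T(with_transmission ? nl : 1,
                        with_transmission ? nprof : 1);

  for (int p = 0; p < nprof; ++p) {
    const double *n = &n_layers(0, p);
    for (int j = 0; j < nz; ++j) {
      if (!(n[j] > 0.0))
        Rcpp::stop("non-physical refractive index (<= 0) in layer %d", j + 1);
    }
    for (int l = 0; l < nl; ++l) {
      const double k = 2.0 * M_PI / wavelengths_nm[l];
      const double theta0 = k * dz_nm * n_ref;
      const double c0 = std::cos(theta0), s0 = std::sin(theta0);
      double A = 1.0, B = 0.0, C = 0.0, D = 1.0;
      for (int j = 0; j < nz; ++j) {
        const double eps = k * dz_nm * (n[j] - n_ref);
        double se, ce;
        small_sincos(eps, se, ce);
        const double cd = c0 * ce - s0 * se;   // cos(delta_j)
        const double sd = s0 * ce + c0 * se;   // sin(delta_j)
        const double bj = sd / n[j];
        const double cj = sd * n[j];
        const double A2 = A * cd - B * cj;
        const double B2 = A * bj + B * cd;
        const double C2 = C * cd + D * cj;
        const double D2 = D * cd - C * bj;
        A = A2; B = B2; C = C2; D = D2;
      }
      const double re_num = n_ambient * A - n_substrate * D;
      const double im_num = n_ambient * n_substrate * B - C;
      const double re_den = n_ambient * A + n_substrate * D;
      const double im_den = n_ambient * n_substrate * B + C;
      const double den2 = re_den * re_den + im_den * im_den;
      R(l, p) = (re_num * re_num + im_num * im_num) / den2;
      if (with_transmission)
        T(l, p) = 4.0 * n_ambient * n_substrate / den2;
    }
  }
  if (with_transmission)
    return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("T") = T);
  return Rcpp::List::create(Rcpp::Named("R") = R);
}
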