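#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Deposit complex scatterer amplitudes onto a pixel grid with a separable
// Gaussian point-spread function. Pixel (iz, ix) is centred at
// (iz * dz_um, ix * dx_um); the PSF is truncated at 3 sigma.
// [[Rcpp::export]]
arma::cx_mat deposit_scatterers(const arma::vec& x_um,
                                const arma::vec& z_um,
                                const arma::cx_vec& amp,
                                int n_z, int n_x,
                                double dz_um, double dx_um,
                                double sigma_z_um, double sigma_x_um) {
  arma::cx_mat img(n_z, n_x, arma::fill::zeros);
  const int wz = (int)std::ceil(3.0 * sigma_z_um / dz_um);
  const int wx = (int)std::ceil(3.0 * sigma_x_um / dx_um);
  const double inv2sz = 1.0 / (2.0 * sigma_z_um * sigma_z_um);
  const double inv2sx = 1.0 / (2.0 * sigma_x_um * sigma_x_um);
  for (arma::uword s = 0; s < x_um.n_elem; ++s) {
    const int iz0 = (int)std::lround(z_um[s] / dz_um);
    const int ix0 = (int)std::lround(x_um[s] / dx_um);
    const int izlo = std::max(0, iz0 - wz), izhi = std::min(n_z - 1, iz0 + wz);
    const int ixlo = std::max(0, ix0 - wx), ixhi = std::min(n_x - 1, ix0 + wx);
    for (int ix = ixlo; ix <= ixhi; ++ix) {
      const double ddx = ix * dx_um - x_um[s];
      const double gx = std::exp(-ddx * ddx * inv2sx);
      for (int iz = izlo; iz <= izhi; ++iz) {
        const double ddz = iz * dz_um - z_um[s];
        img(iz, ix) += amp[s] * (gx * std::exp(-ddz * ddz * inv2sz));
      }
    }
  }
  return img;
}
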