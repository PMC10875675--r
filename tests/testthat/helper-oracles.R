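# Independent numerical oracles and random-instance generators shared by
# the test files.  The oracles integrate in momentum space: for spherical
# Gaussians every closed-form quantity reduces to a 1-D radial integral
# over |q|, evaluated with adaptive quadrature -- a route that never
# touches the package's erf/polynomial closed forms.

`%||%` <- function(a, b) if (is.null(a)) b else a

# sin(x)/x, stable at 0
sinc_ <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

# finite upper integration limit: beyond it q^(2k+2) e^{-c q^2} is below
# ~e^{-60} of its peak, so truncation is harmless and the adaptive rule
# stays well-conditioned (integrating to Inf trips roundoff detection for
# the high-k oscillatory integrands)
.qmax <- function(c_, k = 0) sqrt((80 + 30 * k) / c_)

# Coulomb integral of two unit-normalized Gaussians (weights excluded):
# Int Int g_a g_b / |r - r'|  =  (2/pi) Int dq e^{-q^2 (1/4a + 1/4b)} sinc(qd)
oracle_coulomb_ss <- function(alpha, beta, d) {
  c_ <- 1 / (4 * alpha) + 1 / (4 * beta)
  (2 / pi) * stats::integrate(function(q)
    exp(-q^2 * c_) * sinc_(q * d), 0, .qmax(c_),
    rel.tol = 1e-9, abs.tol = 0, subdivisions = 500L)$value
}

# Coulomb integral of a unit Gaussian against a unit point charge
oracle_coulomb_sp <- function(alpha, d) {
  c_ <- 1 / (4 * alpha)
  (2 / pi) * stats::integrate(function(q)
    exp(-q^2 * c_) * sinc_(q * d), 0, .qmax(c_),
    rel.tol = 1e-9, abs.tol = 0, subdivisions = 500L)$value
}

# Int (Lap^k g_a) g_b dr for unit-normalized Gaussians (weights excluded)
oracle_ee_k <- function(alpha, beta, d, k) {
  c_ <- 1 / (4 * alpha) + 1 / (4 * beta)
  (-1)^k / (2 * pi^2) * stats::integrate(function(q)
    q^(2 * k + 2) * exp(-q^2 * c_) * sinc_(q * d), 0, .qmax(c_, k),
    rel.tol = 1e-9, abs.tol = 0, subdivisions = 500L)$value
}

# (Lap^k g)(x) at distance d from the center of a unit Gaussian
oracle_lap_density <- function(alpha, d, k) {
  c_ <- 1 / (4 * alpha)
  (-1)^k / (2 * pi^2) * stats::integrate(function(q)
    q^(2 * k + 2) * exp(-q^2 * c_) * sinc_(q * d), 0, .qmax(c_, k),
    rel.tol = 1e-9, abs.tol = 0, subdivisions = 500L)$value
}

# |actual - expected| < rel * (|expected| + floor): a relative comparison
# with an additive floor so oscillatory quantities may pass through zero
expect_close <- function(actual, expected, rel = 1e-6, floor = 1e-9) {
  testthat::expect_lt(abs(actual - expected), rel * (abs(expected) + floor))
}

# random shell with log-uniform exponent, placed at `center`
random_shell <- function(center = c(0, 0, 0), wmin = 0.2, wmax = 3) {
  gaussian_shell(stats::runif(1, wmin, wmax),
                 exp(stats::runif(1, log(0.1), log(10))), center)
}

# random small molecule: n_atoms atoms in a box, 1..3 shells each
random_molecule <- function(n_atoms = 2L, spread = 2, name = "rnd") {
  atoms <- lapply(seq_len(n_atoms), function(i) {
    ctr <- stats::runif(3, -spread, spread)
    ns <- sample(1:3, 1)
    atom_density(element = "X", effective_Z = stats::runif(1, 1, 8),
                 shells = data.frame(
                   weight = stats::runif(ns, 0.2, 2),
                   exponent = exp(stats::runif(ns, log(0.2), log(8)))),
                 center = ctr)
  })
  molecule_density(atoms, name = name)
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q %*% diag(c(1, 1, det(Q)))
}

# rigidly transform a molecule_density (rotation R then translation t, bohr)
transform_molecule <- function(mol, R, t) {
  mol$atoms <- lapply(mol$atoms, function(a) {
    ctr <- as.numeric(R %*% a$center + t)
    a$center <- ctr
    a$shells <- lapply(a$shells, function(s) { s$center <- ctr; s })
    a
  })
  mol
}

# water dimer fixture: one O...O geometry with the bundled parameters
water_dimer_fixture <- function(d = 3.0, theta_index = 1L, n_angular = 1L,
                                mode = "ecp") {
  spec <- scan_spec("oxygen_scan", c(d, d), 1L, n_angular)
  g <- water_dimer_scan(spec)[[theta_index]]
  dens <- dimer_densities(g, default_density_params(),
                          charges = c(O = -0.66, H = 0.33), mode = mode)
  list(geom = g, A = dens$A, B = dens$B)
}

water_charges <- c(O = -0.66, H = 0.33)

# truth coefficients used by closure/recovery tests (order 3, ECP scale)
truth_coeffs_order3 <- function()
  xc_coefficients(3, c(0.5, 0.05, 0.005, 5e-4),
                  c(0.2, 0.02, 0.002, 2e-4), basis_mode = "ecp")

# trapezoid quadrature of a vectorized integrand over a centered cube;
# smooth decaying integrands make the trapezoid rule spectrally accurate
grid_integral_3d <- function(f, half = 8, n = 72) {
  x <- seq(-half, half, length.out = n)
  h <- x[2] - x[1]
  gx <- expand.grid(x = x, y = x, z = x)
  sum(f(gx$x, gx$y, gx$z)) * h^3
}
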