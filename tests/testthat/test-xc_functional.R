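test_that("laplacian_polynomial reproduces the first orders analytically", {
  expect_equal(laplacian_polynomial(2.4, 0), 1)
  # one application of the radial Laplacian to e^{-a d^2}:
  # P_1(d^2) = 4 a^2 d^2 - 6 a
  a <- 1.7
  expect_equal(laplacian_polynomial(a, 1), c(-6 * a, 4 * a^2))
  expect_equal(laplacian_polynomial(a, 2),
               c(60 * a^2, -80 * a^3, 16 * a^4))
})

test_that("laplacian_polynomial order k matches a finite-difference Laplacian of order k-1", {
  # apply a 3D central-difference Laplacian to the closed-form k=2 result
  # and compare with the closed-form k=3 polynomial
  a <- 0.8
  f_k <- function(k) {
    P <- laplacian_polynomial(a, k)
    function(x, y, z) {
      d2 <- x^2 + y^2 + z^2
      pref <- 0
      for (j in seq_along(P)) pref <- pref + P[j] * d2^(j - 1)
      pref * (a / pi)^1.5 * exp(-a * d2)
    }
  }
  f2 <- f_k(2); f3 <- f_k(3)
  h <- 1e-3
  pts <- list(c(0.3, -0.2, 0.5), c(1.1, 0.4, -0.9), c(0, 0, 0.2))
  for (p in pts) {
    lap_fd <- (f2(p[1] + h, p[2], p[3]) + f2(p[1] - h, p[2], p[3]) +
                 f2(p[1], p[2] + h, p[3]) + f2(p[1], p[2] - h, p[3]) +
                 f2(p[1], p[2], p[3] + h) + f2(p[1], p[2], p[3] - h) -
                 6 * f2(p[1], p[2], p[3])) / h^2
    expect_equal(lap_fd, f3(p[1], p[2], p[3]),
                 tolerance = 1e-6 * max(abs(f3(p[1], p[2], p[3])), 1))
  }
})

test_that("xc_ee_term matches its closed-form limits and the quadrature oracle", {
  mk1 <- function(w, a, z) molecule_density(list(atom_density(
    "X", 1, data.frame(weight = w, exponent = a), c(0, 0, z))))
  # k = 0 at zero displacement: Gaussian convolution with mu = 1/2
  expect_equal(xc_ee_term(mk1(1, 1, 0), mk1(1, 1, 0), 0),
               (1 / (2 * pi))^1.5, tolerance = 1e-14)
  set.seed(23)
  for (i in 1:25) {
    aa0 <- exp(stats::runif(1, log(0.2), log(6)))
    bb0 <- exp(stats::runif(1, log(0.2), log(6)))
    # stay where the cancelled quadrature remainder is resolvable
    d <- stats::runif(1, 0, min(4, sqrt(15 / (aa0 * bb0 / (aa0 + bb0)))))
    A <- mk1(stats::runif(1, 0.2, 2), aa0, 0)
    B <- mk1(stats::runif(1, 0.2, 2), bb0, d)
    wa <- A$atoms[[1]]$shells[[1]]$weight
    wb <- B$atoms[[1]]$shells[[1]]$weight
    aa <- A$atoms[[1]]$shells[[1]]$exponent
    bb <- B$atoms[[1]]$shells[[1]]$exponent
    for (k in c(0L, 2L, 5L)) {
      want <- wa * wb * oracle_ee_k(aa, bb, d, k)
      expect_close(xc_ee_term(A, B, k), want, rel = 1e-6, floor = 1e-10)
    }
  }
})

test_that("moving the Laplacian between the densities does not change the ee integral", {
  # integration-by-parts identity, checked by 3D grid quadrature of the
  # two different integrands (Lap^k g_a) g_b and g_a (Lap^k g_b)
  a <- 1.1; b <- 0.7; d <- 1.4; k <- 2
  lap_gauss <- function(alpha, x, y, z, z0, k) {
    P <- laplacian_polynomial(alpha, k)
    d2 <- x^2 + y^2 + (z - z0)^2
    pref <- 0
    for (j in seq_along(P)) pref <- pref + P[j] * d2^(j - 1)
    pref * (alpha / pi)^1.5 * exp(-alpha * d2)
  }
  gauss <- function(alpha, x, y, z, z0)
    (alpha / pi)^1.5 * exp(-alpha * (x^2 + y^2 + (z - z0)^2))
  i1 <- grid_integral_3d(function(x, y, z)
    lap_gauss(a, x, y, z, 0, k) * gauss(b, x, y, z, d), half = 7, n = 70)
  i2 <- grid_integral_3d(function(x, y, z)
    gauss(a, x, y, z, 0) * lap_gauss(b, x, y, z, d, k), half = 7, n = 70)
  expect_close(i1, i2, rel = 1e-8, floor = 1e-10)
  # and both equal the package's closed form
  A <- molecule_density(list(atom_density(
    "X", 1, data.frame(weight = 1, exponent = a), c(0, 0, 0))))
  B <- molecule_density(list(atom_density(
    "X", 1, data.frame(weight = 1, exponent = b), c(0, 0, d))))
  expect_close(xc_ee_term(A, B, k), i1, rel = 1e-6)
})

test_that("higher-order ee terms oscillate in sign along a distance scan", {
  mk1 <- function(z) molecule_density(list(atom_density(
    "X", 1, data.frame(weight = 1, exponent = 1), c(0, 0, z))))
  ds <- seq(0.05, 6, length.out = 200)
  for (k in 2:4) {
    vals <- sapply(ds, function(d) xc_ee_term(mk1(0), mk1(d), k))
    expect_gte(sum(diff(sign(vals)) != 0), 1)
  }
})

test_that("xc_en_term reduces to density evaluation at k = 0 and matches finite differences at k = 1", {
  fx <- water_dimer_fixture(d = 3.2)
  want0 <- sum(sapply(fx$B$atoms, function(at)
    at$effective_Z * density_at(fx$A, at$center))) +
    sum(sapply(fx$A$atoms, function(at)
      at$effective_Z * density_at(fx$B, at$center)))
  expect_equal(xc_en_term(fx$A, fx$B, 0), want0, tolerance = 1e-12)
  # k = 1 against a central-difference Laplacian of density_at
  h <- 1e-3
  lap_fd <- function(mol, p)
    (density_at(mol, p + c(h, 0, 0)) + density_at(mol, p - c(h, 0, 0)) +
       density_at(mol, p + c(0, h, 0)) + density_at(mol, p - c(0, h, 0)) +
       density_at(mol, p + c(0, 0, h)) + density_at(mol, p - c(0, 0, h)) -
       6 * density_at(mol, p)) / h^2
  want1 <- sum(sapply(fx$B$atoms, function(at)
    at$effective_Z * lap_fd(fx$A, at$center))) +
    sum(sapply(fx$A$atoms, function(at)
      at$effective_Z * lap_fd(fx$B, at$center)))
  expect_close(xc_en_term(fx$A, fx$B, 1), want1, rel = 1e-5, floor = 1e-12)
  # symmetric under exchanging the molecules, by construction
  expect_equal(xc_en_term(fx$B, fx$A, 2), xc_en_term(fx$A, fx$B, 2),
               tolerance = 1e-14)
})

test_that("xc_energy is exactly linear in the coefficients and equals the feature dot product", {
  fx <- water_dimer_fixture(d = 2.8)
  K <- 4
  f <- featurize(fx$A, fx$B, K)
  expect_length(f, 2 * (K + 1))
  set.seed(31)
  c1 <- stats::rnorm(2 * (K + 1)); c2 <- stats::rnorm(2 * (K + 1))
  mkco <- function(v) xc_coefficients(K, v[1:(K + 1)], v[(K + 2):(2 * K + 2)])
  e1 <- xc_energy(fx$A, fx$B, mkco(c1))
  e2 <- xc_energy(fx$A, fx$B, mkco(c2))
  expect_equal(e1, sum(c1 * f), tolerance = 1e-12 * max(abs(e1), 1))
  # superposition
  e12 <- xc_energy(fx$A, fx$B, mkco(2 * c1 - 0.5 * c2))
  expect_equal(e12, 2 * e1 - 0.5 * e2,
               tolerance = 1e-12 * max(abs(e12), 1))
  # zero weights give zero; a single unit ee weight picks out that term
  expect_identical(xc_energy(fx$A, fx$B, mkco(rep(0, 2 * K + 2))), 0)
  only_c0 <- mkco(c(1, rep(0, 2 * K + 1)))
  expect_equal(xc_energy(fx$A, fx$B, only_c0), xc_ee_term(fx$A, fx$B, 0),
               tolerance = 1e-14)
})

test_that("featurize vanishes at large separation", {
  mk1 <- function(z) molecule_density(list(atom_density(
    "X", 1, data.frame(weight = 1, exponent = 1), c(0, 0, z))))
  f <- featurize(mk1(0), mk1(50), 3)
  expect_true(all(abs(f) < 1e-20))
})

test_that("total_interaction_energy composes naive and XC parts and checks basis modes", {
  fx <- water_dimer_fixture(d = 3.0)
  zero <- xc_coefficients(2, rep(0, 3), rep(0, 3), basis_mode = "ecp")
  expect_equal(total_interaction_energy(fx$A, fx$B, zero),
               naive_interaction_energy(fx$A, fx$B)$total, tolerance = 1e-14)
  co <- truth_coeffs_order3()
  expect_equal(total_interaction_energy(fx$B, fx$A, co),
               total_interaction_energy(fx$A, fx$B, co), tolerance = 1e-13)
  expect_error(total_interaction_energy(fx$A, fx$B, co, basis_mode = "full"),
               "basis_mode")
})
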