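test_that("coulomb_shell_shell has the right limits and is continuous at the switchover", {
  # point-charge limit: erf saturates, E -> w_a w_b / d
  s1 <- gaussian_shell(1, 1, c(0, 0, 0))
  s2 <- gaussian_shell(1, 1, c(0, 0, 20))
  expect_equal(coulomb_shell_shell(s1, s2), 1 / 20, tolerance = 1e-12)
  # analytic d = 0 limit
  a <- 1.3; b <- 0.6
  s3 <- gaussian_shell(1, a, c(0, 0, 0))
  s4 <- gaussian_shell(1, b, c(0, 0, 0))
  expect_equal(coulomb_shell_shell(s3, s4),
               2 * sqrt(a * b / (pi * (a + b))), tolerance = 1e-14)
  # continuity across the series/erf branch point at gamma*d = 1e-4
  gam <- sqrt(a * b / (a + b))
  for (d in c(0.9999e-4, 1.0001e-4) / gam) {
    s5 <- gaussian_shell(1, b, c(0, 0, d))
    expect_equal(coulomb_shell_shell(s3, s5),
                 (2 * stats::pnorm(gam * d * sqrt(2)) - 1) / d,
                 tolerance = 1e-13, label = sprintf("d = %g", d))
  }
})

test_that("coulomb_shell_point has point-density and on-center limits", {
  # very sharp density acts as a point charge
  s <- gaussian_shell(1, 1e8, c(0, 0, 0))
  expect_equal(coulomb_shell_point(s, 2, c(0, 0, 1.7)), 2 / 1.7,
               tolerance = 1e-6)
  # on-center limit 2 w Z sqrt(alpha/pi)
  s0 <- gaussian_shell(1, 1, c(0, 0, 0))
  expect_equal(coulomb_shell_point(s0, 1, c(0, 0, 0)), 2 / sqrt(pi),
               tolerance = 1e-14)
})

test_that("closed-form Coulomb integrals agree with momentum-space quadrature", {
  set.seed(101)
  for (i in 1:40) {
    d <- stats::runif(1, 0, 6)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    sa <- random_shell(c(0, 0, 0))
    sb <- random_shell(d * dir)
    expect_close(coulomb_shell_shell(sa, sb),
                 sa$weight * sb$weight *
                   oracle_coulomb_ss(sa$exponent, sb$exponent, d),
                 rel = 1e-6)
    Z <- stats::runif(1, 1, 8)
    expect_close(coulomb_shell_point(sa, Z, d * dir),
                 sa$weight * Z * oracle_coulomb_sp(sa$exponent, d),
                 rel = 1e-8)
  }
  # a representative fixed case: w=1, alpha=0.7, Z=8, d=2.1 bohr
  s <- gaussian_shell(1, 0.7, c(0, 0, 0))
  expect_close(coulomb_shell_point(s, 8, c(0, 0, 2.1)),
               8 * oracle_coulomb_sp(0.7, 2.1), rel = 1e-8)
})

test_that("nuclear repulsion sums pairwise charges and rejects coincident nuclei", {
  hA <- molecule_density(list(atom_density("H", 1, list(), c(0, 0, 0))))
  hB <- molecule_density(list(atom_density("H", 1, list(), c(0, 0, 1))))
  expect_equal(nuclear_repulsion(hA, hB), 1)
  oA <- molecule_density(list(atom_density("O", 6, list(), c(0, 0, 0))))
  oB <- molecule_density(list(atom_density("O", 6, list(), c(0, 0, 2))))
  expect_equal(nuclear_repulsion(oA, oB), 18)
  expect_error(nuclear_repulsion(hA, hA), "coincident")
})

test_that("electron-nuclear attraction is symmetric and has the point-charge limit", {
  set.seed(7)
  A <- random_molecule(2)
  B <- random_molecule(2)
  expect_equal(electron_nuclear_attraction(A, B),
               electron_nuclear_attraction(B, A), tolerance = 1e-14)
  # neutral-H density against a bare unit charge at large d: ~ -1/d
  h <- molecule_density(list(atom_density(
    "H", 1, data.frame(weight = 1, exponent = 1), c(0, 0, 0))))
  bare <- molecule_density(list(atom_density("H", 1, list(), c(0, 0, 15))))
  expect_equal(electron_nuclear_attraction(h, bare), -1 / 15,
               tolerance = 1e-10)
})

test_that("molecule-level Coulomb sums match an independently coded direct summation", {
  # direct-summation oracle: plain loops over shells/nuclei, written
  # against the textbook formulas rather than the package's vector path
  erf0 <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  direct <- function(A, B) {
    ee <- 0; en <- 0; nn <- 0
    for (aa in A$atoms) for (bb in B$atoms) {
      d <- sqrt(sum((aa$center - bb$center)^2))
      nn <- nn + aa$effective_Z * bb$effective_Z / d
      for (sa in aa$shells) for (sb in bb$shells) {
        g <- sqrt(sa$exponent * sb$exponent / (sa$exponent + sb$exponent))
        ee <- ee + sa$weight * sb$weight *
          (if (d == 0) 2 * g / sqrt(pi) else erf0(g * d) / d)
      }
      for (sa in aa$shells)
        en <- en - sa$weight * bb$effective_Z * erf0(sqrt(sa$exponent) * d) / d
      for (sb in bb$shells)
        en <- en - sb$weight * aa$effective_Z * erf0(sqrt(sb$exponent) * d) / d
    }
    list(e_ee = ee, e_en = en, e_nn = nn, total = ee + en + nn)
  }
  fx <- water_dimer_fixture(d = 3.0)
  got <- naive_interaction_energy(fx$A, fx$B)
  want <- direct(fx$A, fx$B)
  expect_equal(got$e_ee, want$e_ee, tolerance = 1e-12)
  expect_equal(got$e_en, want$e_en, tolerance = 1e-12)
  expect_equal(got$e_nn, want$e_nn, tolerance = 1e-12)
  # the total is a ~1e-3 difference of ~10-hartree components, so agreement
  # is asserted at 1e-12 of the component scale
  expect_lt(abs(got$total - want$total), 1e-12 * abs(want$e_ee))
  set.seed(19)
  for (i in 1:10) {
    A <- random_molecule(2)
    B <- transform_molecule(random_molecule(2), diag(3), c(0, 0, 8))
    w <- direct(A, B)
    expect_lt(abs(naive_interaction_energy(A, B)$total - w$total),
              1e-12 * max(abs(w$e_ee), abs(w$e_nn), 1))
  }
})

test_that("naive energy components satisfy sum, sign and limit properties", {
  fx <- water_dimer_fixture(d = 3.0)
  nb <- naive_interaction_energy(fx$A, fx$B)
  expect_identical(nb$total, nb$e_ee + nb$e_en + nb$e_nn)
  expect_gt(nb$e_ee, 0); expect_gt(nb$e_nn, 0); expect_lt(nb$e_en, 0)
  # perfectly screened neutral atoms: exponential decay of the total
  mk <- function(z) molecule_density(list(atom_density(
    "X", 2, data.frame(weight = 2, exponent = 1), c(0, 0, z))))
  expect_lt(abs(naive_interaction_energy(mk(0), mk(12))$total), 1e-12)
  # bare charges: exactly Coulombic
  hp <- function(z) molecule_density(list(atom_density("H", 1, list(),
                                                       c(0, 0, z))))
  expect_equal(naive_interaction_energy(hp(0), hp(4))$total, 1 / 4,
               tolerance = 1e-14)
})
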