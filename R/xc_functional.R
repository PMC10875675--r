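#' Iterated radial Laplacian of a spherical Gaussian, as a polynomial
#'
#' Applying the Laplace operator `k` times to the unit-normalized Gaussian
#' `g(d) = (a/pi)^(3/2) exp(-a d^2)` leaves a polynomial prefactor:
#' `Lap^k g = P_k(d^2) * g(d)` with `deg P_k = k` in `d^2`.  For a radial
#' function the Laplacian is `f'' + (2/d) f'`, which for
#' `F(u) = P(u) exp(-a u)`, `u = d^2`, gives the exact coefficient
#' recursion
#'
#'   `Q(u) = 6 (P' - a P) + 4 u (P'' - 2 a P' + a^2 P)`.
#'
#' The coefficients are homogeneous in the exponent:
#' `P_k(u) = sum_j A[k,j] a^(k+j) u^j` with integer `A[k,j]`, so the
#' integer table is computed once (and cached) and rescaled for any
#' exponent.  Examples: `P_0 = 1`, `P_1 = 4 a^2 d^2 - 6 a`,
#' `P_2 = 16 a^4 d^4 - 80 a^3 d^2 + 60 a^2`.
#'
#' @param alpha Gaussian exponent, inverse bohr^2.
#' @param k number of Laplacian applications (>= 0).
#' @return numeric vector of length `k + 1`: coefficients of `P_k` in
#'   ascending powers of `d^2`.
#' @export
laplacian_polynomial <- function(alpha, k) {
  stopifnot(is.numeric(alpha), alpha > 0, k >= 0)
  k <- as.integer(k)
  A <- .lap_int_table(k)
  A[k + 1L, seq_len(k + 1L)] * alpha^(k + seq_len(k + 1L) - 1L)
}

# cache for the integer Laplacian coefficient table
.lap_cache <- new.env(parent = emptyenv())

# integer table A[k+1, j+1] with P_k(u) = sum_j A[k,j] a^(k+j) u^j;
# rows 0..kmax.  Recursion (alpha scaled out):
#   b_j = 6 (j+1) a_{j+1} - 6 a_j + 4 j (j+1) a_{j+1} - 8 j a_j + 4 a_{j-1}
.lap_int_table <- function(kmax) {
  key <- "table"
  have <- .lap_cache[[key]]
  if (!is.null(have) && nrow(have) >= kmax + 1L)
    return(have[seq_len(kmax + 1L), , drop = FALSE])
  A <- matrix(0, nrow = kmax + 1L, ncol = kmax + 1L)
  A[1L, 1L] <- 1
  if (kmax >= 1L) {
    for (k in seq_len(kmax)) {
      a <- A[k, ]
      b <- numeric(kmax + 1L)
      for (j in 0:k) {
        aj   <- if (j <= kmax) a[j + 1L] else 0
        ajp1 <- if (j + 1L <= kmax) a[j + 2L] else 0
        ajm1 <- if (j >= 1L) a[j] else 0
        b[j + 1L] <- 6 * (j + 1) * ajp1 - 6 * aj +
          4 * j * (j + 1) * ajp1 - 8 * j * aj + 4 * ajm1
      }
      A[k + 1L, ] <- b
    }
  }
  .lap_cache[[key]] <- A
  A
}

# Vectorized core of the ee functional: for vectors w (pair weight
# products), mu (reduced exponents a*b/(a+b)) and d2 (squared distances),
# the value of sum_pairs Int (Lap^k g_a) g_b dr for each k in `ks`.
# The overlap Int g_a g_b dr is the Gaussian S0(d) = (mu/pi)^(3/2)
# exp(-mu d^2); moving Lap^k onto the displacement gives P_k(d^2; mu) S0.
.xc_ee_core <- function(w, mu, d2, ks) {
  S0 <- w * (mu / pi)^1.5 * exp(-mu * d2)
  A <- .lap_int_table(max(ks))
  vapply(ks, function(k) {
    P <- rep(0, length(mu))
    for (j in 0:k) P <- P + A[k + 1L, j + 1L] * mu^(k + j) * d2^j
    sum(S0 * P)
  }, numeric(1))
}

# Vectorized core of the en functional: shells (w, alpha) evaluated at
# squared distances d2 from partner nuclei with charges Z.
.xc_en_core <- function(w, alpha, Z, d2, ks) {
  g <- w * (alpha / pi)^1.5 * exp(-alpha * d2)
  A <- .lap_int_table(max(ks))
  vapply(ks, function(k) {
    P <- rep(0, length(alpha))
    for (j in 0:k) P <- P + A[k + 1L, j + 1L] * alpha^(k + j) * d2^j
    sum(Z * g * P)
  }, numeric(1))
}

# cheap flat representation of a molecule: plain numeric vectors, no
# data frames (performance-critical for scans over thousands of dimers)
.flat_mol <- function(mol) {
  atoms <- mol$atoms
  nsh <- vapply(atoms, function(a) length(a$shells), 0L)
  w <- unlist(lapply(atoms, function(a)
    vapply(a$shells, `[[`, 0, "weight")), use.names = FALSE)
  a <- unlist(lapply(atoms, function(a)
    vapply(a$shells, `[[`, 0, "exponent")), use.names = FALSE)
  ctr <- t(vapply(atoms, `[[`, numeric(3), "center"))
  list(w = w, a = a,
       sx = rep(ctr[, 1], nsh), sy = rep(ctr[, 2], nsh),
       sz = rep(ctr[, 3], nsh),
       Z = vapply(atoms, `[[`, 0, "effective_Z"),
       nx = ctr[, 1], ny = ctr[, 2], nz = ctr[, 3])
}

.cross_d2 <- function(x1, y1, z1, x2, y2, z2)
  as.numeric(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2 +
               outer(z1, z2, "-")^2)

# flatten one dimer into the pair arrays used by the xc and naive sums;
# computed once per dimer and reused across all orders and components
.pair_arrays <- function(A, B) {
  fa <- .flat_mol(A); fb <- .flat_mol(B)
  ns_a <- length(fa$w); ns_b <- length(fb$w)
  d2ss <- .cross_d2(fa$sx, fa$sy, fa$sz, fb$sx, fb$sy, fb$sz)
  aa <- rep(fa$a, times = ns_b)
  bb <- rep(fb$a, each = ns_a)
  list(
    w_ss = rep(fa$w, times = ns_b) * rep(fb$w, each = ns_a),
    mu = aa * bb / (aa + bb), d2_ss = d2ss, d_ss = sqrt(d2ss),
    aa = aa, bb = bb,
    # shells of A at nuclei of B, then shells of B at nuclei of A
    w_en = c(rep(fa$w, times = length(fb$Z)),
             rep(fb$w, times = length(fa$Z))),
    alpha_en = c(rep(fa$a, times = length(fb$Z)),
                 rep(fb$a, times = length(fa$Z))),
    Z_en = c(rep(fb$Z, each = ns_a), rep(fa$Z, each = ns_b)),
    d2_en = c(.cross_d2(fa$sx, fa$sy, fa$sz, fb$nx, fb$ny, fb$nz),
              .cross_d2(fb$sx, fb$sy, fb$sz, fa$nx, fa$ny, fa$nz)),
    Z_nn = rep(fa$Z, times = length(fb$Z)) * rep(fb$Z, each = length(fa$Z)),
    d_nn = sqrt(.cross_d2(fa$nx, fa$ny, fa$nz, fb$nx, fb$ny, fb$nz)))
}

# naive Coulomb components from a precomputed pair-array workspace
.naive_from_arrays <- function(p) {
  e_ee <- sum(p$w_ss * erf_over_d_vec(sqrt(p$mu), p$d_ss))
  d_en <- sqrt(p$d2_en)
  e_en <- -sum(p$w_en * p$Z_en * erf_over_d_vec(sqrt(p$alpha_en), d_en))
  if (any(p$d_nn == 0))
    stop("nuclear_repulsion: coincident intermolecular nuclei")
  e_nn <- sum(p$Z_nn / p$d_nn)
  list(e_ee = e_ee, e_en = e_en, e_nn = e_nn, total = e_ee + e_en + e_nn)
}

# stacked ee/en feature vector from a workspace
.features_from_arrays <- function(p, K) {
  ks <- 0:K
  c(.xc_ee_core(p$w_ss, p$mu, p$d2_ss, ks),
    .xc_en_core(p$w_en, p$alpha_en, p$Z_en, p$d2_en, ks))
}

#' Electron-electron term of the exchange-correlation series
#'
#' The `k`-th ee functional: `Int (Lap^k rho_A)(r) rho_B(r) dr`, summed
#' in closed form over all intermolecular shell pairs.  Because the
#' Laplacian acts an even number of times, integration by parts moves it
#' freely between the two densities, so the value is unchanged if the
#' roles of A and B are swapped.  Each pair contributes
#' `P_k(d^2; mu) * w_a w_b (mu/pi)^(3/2) exp(-mu d^2)` with
#' `mu = a b/(a + b)`; the term decays as a Gaussian in the separation and
#' oscillates in sign with distance for `k >= 2`.
#'
#' @param A,B [molecule_density()] objects.
#' @param k iteration count (>= 0); `k = 0` is the plain density overlap.
#' @return functional value (bohr-dimensioned; the calibrated weights
#'   absorb the dimensions).
#' @export
xc_ee_term <- function(A, B, k) {
  stopifnot(k >= 0)
  p <- .pair_arrays(A, B)
  .xc_ee_core(p$w_ss, p$mu, p$d2_ss, as.integer(k))
}

#' Electron-nuclear term of the exchange-correlation series
#'
#' The `k`-th en functional: the iterated-Laplacian density of each
#' monomer evaluated at the partner's nuclei, weighted by the effective
#' atomic numbers:
#' `sum_b Z_b (Lap^k rho_A)(R_b) + sum_a Z_a (Lap^k rho_B)(R_a)`.
#' Symmetric under A/B exchange by construction.  `k = 0` reduces to the
#' density at the partner nuclei.
#'
#' @inheritParams xc_ee_term
#' @return functional value (bohr-dimensioned).
#' @export
xc_en_term <- function(A, B, k) {
  stopifnot(k >= 0)
  p <- .pair_arrays(A, B)
  .xc_en_core(p$w_en, p$alpha_en, p$Z_en, p$d2_en, as.integer(k))
}

#' Exchange-correlation coefficient set
#'
#' Weights of the ee and en functional series up to order `K` (the series
#' index runs `k = 0..K` inclusive, so each series has `K + 1` weights and
#' the model has `2 (K + 1)` parameters).  The weights carry the units that
#' make `xc_energy` come out in hartree.
#'
#' @param order non-negative integer K.
#' @param ee_weights,en_weights numeric vectors of length `order + 1`.
#' @param basis_mode `"ecp"` or `"full"`; fits are only applicable to
#'   densities expanded in the same mode.
#' @return An object of class `xc_coefficients`.
#' @export
xc_coefficients <- function(order, ee_weights, en_weights,
                            basis_mode = c("ecp", "full")) {
  basis_mode <- match.arg(basis_mode)
  order <- as.integer(order)
  if (order < 0) stop("xc_coefficients: order must be >= 0")
  ee_weights <- as.numeric(ee_weights)
  en_weights <- as.numeric(en_weights)
  if (length(ee_weights) != order + 1L || length(en_weights) != order + 1L)
    stop("xc_coefficients: need order + 1 weights in each series")
  structure(list(order = order, ee_weights = ee_weights,
                 en_weights = en_weights, basis_mode = basis_mode),
            class = "xc_coefficients")
}

#' @export
print.xc_coefficients <- function(x, ...) {
  cat(sprintf("<xc_coefficients> order %d (%s basis), %d weights\n",
              x$order, x$basis_mode, 2L * (x$order + 1L)))
  cat("  ee:", format(x$ee_weights, digits = 6), "\n")
  cat("  en:", format(x$en_weights, digits = 6), "\n")
  invisible(x)
}

#' Feature vector of XC functional values for one dimer
#'
#' Stacks `xc_ee_term(A, B, k)` for `k = 0..K` then `xc_en_term(A, B, k)`
#' for `k = 0..K`; [xc_energy()] is exactly the dot product of this vector
#' with the stacked coefficient weights, which is what makes calibration a
#' linear least-squares problem.
#'
#' @param A,B [molecule_density()] objects.
#' @param K maximum order (>= 0).
#' @return numeric vector of length `2 (K + 1)`, names `ee0.. , en0..`.
#' @export
featurize <- function(A, B, K) {
  stopifnot(K >= 0)
  p <- .pair_arrays(A, B)
  v <- .features_from_arrays(p, K)
  names(v) <- c(paste0("ee", 0:K), paste0("en", 0:K))
  v
}

#' Exchange-correlation interaction energy
#'
#' `sum_k [ c_k * ee_k + d_k * en_k ]` with the fitted weights; exactly
#' linear in the coefficients and vanishing at large separation.
#'
#' @param A,B [molecule_density()] objects.
#' @param coeffs an [xc_coefficients()].
#' @return energy in hartree.
#' @export
xc_energy <- function(A, B, coeffs) {
  stopifnot(inherits(coeffs, "xc_coefficients"))
  f <- featurize(A, B, coeffs$order)
  sum(c(coeffs$ee_weights, coeffs$en_weights) * f)
}

#' Total interaction energy: naive Coulomb plus XC correction
#'
#' @param A,B [molecule_density()] objects (same basis mode as `coeffs`).
#' @param coeffs an [xc_coefficients()].
#' @param basis_mode optional basis mode of the densities; if supplied it
#'   must match `coeffs$basis_mode`.
#' @return energy in hartree.
#' @export
total_interaction_energy <- function(A, B, coeffs, basis_mode = NULL) {
  if (!is.null(basis_mode) && !identical(basis_mode, coeffs$basis_mode))
    stop(sprintf("basis_mode mismatch: densities '%s' vs coefficients '%s'",
                 basis_mode, coeffs$basis_mode))
  stopifnot(inherits(coeffs, "xc_coefficients"))
  p <- .pair_arrays(A, B)
  .naive_from_arrays(p)$total +
    sum(c(coeffs$ee_weights, coeffs$en_weights) *
          .features_from_arrays(p, coeffs$order))
}
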