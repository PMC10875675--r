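#' Closed-form Coulomb integral between two s-type Gaussian shells
#'
#' The electron-electron repulsion between two unit-normalized spherical
#' Gaussians reduces to `erf(sqrt(a*b/(a+b)) * d) / d` with `d` the
#' center-center distance; the shell weights multiply the result.  For
#' `gamma*d` below 1e-4 the Maclaurin series of `erf(g d)/d` is used, which
#' is continuous with the erf branch to machine precision and avoids the
#' 0/0 cancellation, with limit `2*sqrt(a*b/(pi*(a+b)))` at `d = 0`.
#'
#' @param a,b [gaussian_shell()] objects.
#' @return interaction energy in hartree.
#' @export
coulomb_shell_shell <- function(a, b) {
  stopifnot(inherits(a, "gaussian_shell"), inherits(b, "gaussian_shell"))
  d <- sqrt(sum((a$center - b$center)^2))
  gam <- sqrt(a$exponent * b$exponent / (a$exponent + b$exponent))
  a$weight * b$weight * erf_over_d(gam, d)
}

#' Closed-form Coulomb integral between a Gaussian shell and a point charge
#'
#' `w * Z * erf(sqrt(alpha) * d) / d`, with the small-`d` series branch as
#' in [coulomb_shell_shell()]; the `d = 0` limit is `2 w Z sqrt(alpha/pi)`.
#' The sign convention is positive (a bare Coulomb magnitude); callers
#' attach the attraction sign.
#'
#' @param a a [gaussian_shell()].
#' @param Z point charge (e.g. an effective atomic number).
#' @param P numeric length-3 position of the charge, bohr.
#' @return Coulomb energy magnitude in hartree.
#' @export
coulomb_shell_point <- function(a, Z, P) {
  stopifnot(inherits(a, "gaussian_shell"))
  P <- as.numeric(P)
  d <- sqrt(sum((a$center - P)^2))
  a$weight * Z * erf_over_d(sqrt(a$exponent), d)
}

# erf(g d)/d for scalar g, d, with the Maclaurin branch below g*d = 1e-4:
# erf(x)/x = (2/sqrt(pi)) (1 - x^2/3 + x^4/10 - ...), so erf(g d)/d = g * that.
erf_over_d <- function(g, d) {
  x <- g * d
  if (x < 1e-4) g * (2 / sqrt(pi)) * (1 - x^2 / 3 + x^4 / 10) else erf_(x) / d
}

# base-R error function
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# vector core used by the molecule-level sums: gamma and d are equal-length
erf_over_d_vec <- function(g, d) {
  x <- g * d
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- g[small] * (2 / sqrt(pi)) *
    (1 - x[small]^2 / 3 + x[small]^4 / 10)
  out[!small] <- erf_(x[!small]) / d[!small]
  out
}

#' Nuclear-nuclear repulsion between two molecules
#'
#' Pairwise `Z_a Z_b / d_ab` over all intermolecular nucleus pairs, using
#' the effective atomic numbers stored on the atoms.  Intramolecular pairs
#' never enter: the model is a pair interaction between frozen monomers.
#'
#' @param A,B [molecule_density()] objects.
#' @return repulsion energy in hartree (positive).
#' @export
nuclear_repulsion <- function(A, B) {
  na <- nucleus_table(A); nb <- nucleus_table(B)
  d <- .cross_dist(na, nb)
  if (any(d == 0))
    stop("nuclear_repulsion: coincident intermolecular nuclei")
  sum(outer(na$Z, nb$Z) / d)
}

# matrix of distances between rows of two (x,y,z) tables
.cross_dist <- function(ta, tb) {
  sqrt(outer(ta$x, tb$x, "-")^2 + outer(ta$y, tb$y, "-")^2 +
         outer(ta$z, tb$z, "-")^2)
}

#' Electron-nuclear attraction between two frozen monomer densities
#'
#' Sum of each molecule's density attracted by the partner's nuclei:
#' `-sum_B Z_b Int rho_A/|r - R_b| - sum_A Z_a Int rho_B/|r - R_a|`,
#' each integral in closed form.  Symmetric under exchanging A and B by
#' construction.
#'
#' @param A,B [molecule_density()] objects.
#' @return attraction energy in hartree (negative for positive densities).
#' @export
electron_nuclear_attraction <- function(A, B) {
  -.en_sum(A, B) - .en_sum(B, A)
}

# sum over shells of `mol` against nuclei of `other` (positive magnitude)
.en_sum <- function(mol, other) {
  st <- shell_table(mol); nt <- nucleus_table(other)
  if (nrow(st) == 0L || nrow(nt) == 0L) return(0)
  d <- .cross_dist(st, nt)                       # shells x nuclei
  g <- sqrt(st$exponent)
  val <- erf_over_d_vec(rep(g, times = nrow(nt)), as.numeric(d))
  sum(rep(st$weight, times = nrow(nt)) *
        rep(nt$Z, each = nrow(st)) * val)
}

#' Electron-electron repulsion between two frozen monomer densities
#'
#' Closed-form double integral `Int Int rho_A rho_B / |r - r'|` as the sum
#' of [coulomb_shell_shell()] over all intermolecular shell pairs.
#'
#' @param A,B [molecule_density()] objects.
#' @return repulsion energy in hartree.
#' @export
electron_electron_repulsion <- function(A, B) {
  sa <- shell_table(A); sb <- shell_table(B)
  if (nrow(sa) == 0L || nrow(sb) == 0L) return(0)
  d <- as.numeric(.cross_dist(sa, sb))
  aa <- rep(sa$exponent, times = nrow(sb))
  bb <- rep(sb$exponent, each = nrow(sa))
  g <- sqrt(aa * bb / (aa + bb))
  w <- rep(sa$weight, times = nrow(sb)) * rep(sb$weight, each = nrow(sa))
  sum(w * erf_over_d_vec(g, d))
}

#' Naive (pure-Coulomb) interaction energy of two frozen monomers
#'
#' The interaction energy under the assumption that each monomer's
#' electrons are unaffected by the other monomer: the classical Coulomb
#' energy between the two frozen densities and nuclei, partitioned into
#' electron-electron, electron-nuclear and nuclear-nuclear components.
#' For two neutral monomers the total decays exponentially once the
#' densities stop overlapping; for net monomer charges `q_A, q_B` it tends
#' to `q_A q_B / d`.
#'
#' @param A,B [molecule_density()] objects.
#' @return An object of class `naive_energy`: list with `e_ee`, `e_en`,
#'   `e_nn` and `total` (hartree), `total` being their exact sum.
#' @export
naive_interaction_energy <- function(A, B) {
  structure(.naive_from_arrays(.pair_arrays(A, B)), class = "naive_energy")
}

#' @export
print.naive_energy <- function(x, ...) {
  cat(sprintf(
    "<naive_energy> ee %+0.8f  en %+0.8f  nn %+0.8f  total %+0.8f hartree\n",
    x$e_ee, x$e_en, x$e_nn, x$total))
  invisible(x)
}
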