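#' s-type Gaussian density shell
#'
#' One term of an atomic electron density expanded in unit-normalized
#' spherical Gaussians.  The shell carries `weight` electrons distributed as
#' `(alpha/pi)^(3/2) * exp(-alpha * |r - center|^2)`, so it integrates to
#' exactly `weight` electrons for any positive exponent.
#'
#' @param weight electrons carried by the shell (dimensionless multiplier of
#'   the unit-normalized primitive; may be signed if a signed expansion is
#'   used).
#' @param exponent Gaussian exponent alpha, in inverse bohr squared; must be
#'   positive.
#' @param center numeric length-3 vector, bohr.
#' @return An object of class `gaussian_shell`.
#' @examples
#' g <- gaussian_shell(1, 1, c(0, 0, 0))
#' @export
gaussian_shell <- function(weight, exponent, center = c(0, 0, 0)) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight))
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent))
  if (exponent <= 0) stop("gaussian_shell: exponent must be > 0")
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))
  structure(list(weight = weight, exponent = exponent, center = center),
            class = "gaussian_shell")
}

#' Atomic density: Gaussian shells plus nuclear data
#'
#' An atom's frozen electron density is the sum of its s-type Gaussian
#' shells, all centered on the nucleus.  `effective_Z` is the nuclear charge
#' entering the Coulomb terms: the atomic number in full-electron mode, or
#' the valence charge when core electrons are folded into an effective core
#' potential (ECP).  `mulliken_charge` is the signed partial charge used to
#' rescale the shell populations for intramolecular charge redistribution
#' (see [scale_to_population()]).
#'
#' @param element chemical symbol, e.g. `"O"`.
#' @param effective_Z positive nuclear/core charge.
#' @param shells list of [gaussian_shell()] objects sharing `center`, or a
#'   data frame with columns `weight` and `exponent` (centers are then taken
#'   from `center`).
#' @param center numeric length-3 nuclear coordinate, bohr.
#' @param mulliken_charge signed partial charge in electrons (default 0).
#' @return An object of class `atom_density`.
#' @export
atom_density <- function(element, effective_Z, shells, center,
                         mulliken_charge = 0) {
  stopifnot(is.character(element), length(element) == 1L)
  if (!is.numeric(effective_Z) || effective_Z <= 0)
    stop("atom_density: effective_Z must be > 0")
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (is.data.frame(shells)) {
    shells <- Map(function(w, a) gaussian_shell(w, a, center),
                  shells$weight, shells$exponent)
  } else {
    shells <- lapply(shells, function(s) {
      stopifnot(inherits(s, "gaussian_shell"))
      if (max(abs(s$center - center)) > 1e-12)
        stop("atom_density: all shells must be centered on the nucleus")
      s
    })
  }
  structure(list(element = element, effective_Z = effective_Z,
                 mulliken_charge = mulliken_charge,
                 shells = shells, center = center),
            class = "atom_density")
}

#' Molecular density: an ordered set of atomic densities
#'
#' The frozen monomer density is the sum of its atoms' shell expansions;
#' the total electron count is `sum(effective_Z - mulliken_charge)` over
#' atoms once populations have been scaled.
#'
#' @param atoms list of [atom_density()] objects.
#' @param name label for reports.
#' @return An object of class `molecule_density`.
#' @export
molecule_density <- function(atoms, name = "molecule") {
  stopifnot(length(atoms) >= 1L)
  lapply(atoms, function(a) stopifnot(inherits(a, "atom_density")))
  structure(list(atoms = atoms, name = name), class = "molecule_density")
}

#' @export
print.molecule_density <- function(x, ...) {
  st <- shell_table(x)
  cat(sprintf("<molecule_density> %s: %d atoms, %d shells, %.6f electrons\n",
              x$name, length(x$atoms), nrow(st), sum(st$weight)))
  invisible(x)
}

#' Flat shell and nucleus tables of a molecular density
#'
#' Internal workhorses: flatten a `molecule_density` into vectorized tables
#' used by all closed-form integrals.
#'
#' @param mol a [molecule_density()].
#' @return `shell_table`: data frame with columns `weight`, `exponent`,
#'   `x`, `y`, `z` (bohr), `atom`.  `nucleus_table`: data frame with columns
#'   `element`, `Z`, `x`, `y`, `z` (bohr).
#' @keywords internal
#' @export
shell_table <- function(mol) {
  stopifnot(inherits(mol, "molecule_density"))
  rows <- lapply(seq_along(mol$atoms), function(i) {
    a <- mol$atoms[[i]]
    if (length(a$shells) == 0L) return(NULL)
    data.frame(weight = vapply(a$shells, `[[`, 0, "weight"),
               exponent = vapply(a$shells, `[[`, 0, "exponent"),
               x = a$center[1], y = a$center[2], z = a$center[3], atom = i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(weight = numeric(0), exponent = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      atom = integer(0))
  out
}

#' @rdname shell_table
#' @keywords internal
#' @export
nucleus_table <- function(mol) {
  stopifnot(inherits(mol, "molecule_density"))
  data.frame(
    element = vapply(mol$atoms, `[[`, "", "element"),
    Z = vapply(mol$atoms, `[[`, 0, "effective_Z"),
    x = vapply(mol$atoms, function(a) a$center[1], 0),
    y = vapply(mol$atoms, function(a) a$center[2], 0),
    z = vapply(mol$atoms, function(a) a$center[3], 0))
}

#' Evaluate a molecular density at a point
#'
#' Sums `weight * (alpha/pi)^(3/2) * exp(-alpha * |p - R|^2)` over all
#' shells.  Non-negative whenever all shell weights are non-negative.
#'
#' @param mol a [molecule_density()].
#' @param point numeric length-3 position, bohr.
#' @return density in electrons/bohr^3.
#' @export
density_at <- function(mol, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L, all(is.finite(point)))
  st <- shell_table(mol)
  if (nrow(st) == 0L) return(0)
  d2 <- (point[1] - st$x)^2 + (point[2] - st$y)^2 + (point[3] - st$z)^2
  sum(st$weight * (st$exponent / pi)^1.5 * exp(-st$exponent * d2))
}

#' Scale shell populations to match the Mulliken-adjusted electron count
#'
#' Multiplies all shell weights of an atom by one common factor so that the
#' summed population equals `effective_Z - mulliken_charge`.  Exponents (and
#' hence the normalized radial shape) are untouched: only the amplitude of
#' the atomic density changes.  This is how intramolecular charge
#' redistribution, quantified by Mulliken partial charges of the isolated
#' monomer, is folded into the frozen-density model.
#'
#' @param atom an [atom_density()].
#' @return A new `atom_density` whose weights sum to
#'   `effective_Z - mulliken_charge`.
#' @export
scale_to_population <- function(atom) {
  stopifnot(inherits(atom, "atom_density"))
  target <- atom$effective_Z - atom$mulliken_charge
  if (target <= 0)
    stop(sprintf(
      "scale_to_population: target population %.4f <= 0 for %s (bare cation cores cannot be represented)",
      target, atom$element))
  tot <- sum(vapply(atom$shells, `[[`, 0, "weight"))
  if (tot <= 0)
    stop("scale_to_population: total shell weight must be positive")
  f <- target / tot
  atom$shells <- lapply(atom$shells, function(s) {
    s$weight <- s$weight * f
    s
  })
  atom
}

#' Fit an atomic radial density with s-type Gaussians
#'
#' Least-squares fit of sampled radial density values `rho(r)` by
#' `sum_i w_i (a_i/pi)^(3/2) exp(-a_i r^2)`, with the constraint
#' `sum(w_i) = target_electrons` built into the parameterization.  Residuals
#' are weighted by `r^2` (the spherical volume element), so the fit
#' reproduces the radial distribution function `4 pi r^2 rho(r)` that
#' controls all integrated quantities.
#'
#' Optimization is a seeded multi-start over log-exponents, each start
#' polished with Nelder-Mead followed by BFGS.  With
#' `nonnegative = TRUE` (default) the weights are parameterized as
#' `target * softmax(theta)`, keeping them positive and exactly on the
#' population constraint; with `nonnegative = FALSE` the weights are solved
#' exactly by equality-constrained linear least squares at each candidate
#' exponent set, allowing signed weights.
#'
#' @param radial_samples data frame (or list) with components `r` (bohr,
#'   >= 0) and `rho` (electrons/bohr^3, >= 0).
#' @param n_gaussians number of shells to fit (>= 1).
#' @param target_electrons required integral of the fitted density.
#' @param seed integer seed; the fit is deterministic for a fixed seed.
#' @param nonnegative logical, constrain weights to be positive.
#' @param n_starts number of random multi-starts.
#' @return list of [gaussian_shell()] (centered at the origin), with
#'   attributes `rss` (weighted residual sum of squares) and `target`.
#' @export
fit_radial_density <- function(radial_samples, n_gaussians, target_electrons,
                               seed = 1L, nonnegative = TRUE,
                               n_starts = 24L) {
  r <- as.numeric(radial_samples$r)
  rho <- as.numeric(radial_samples$rho)
  if (length(r) == 0L) stop("fit_radial_density: no samples")
  if (!all(is.finite(r)) || !all(is.finite(rho)))
    stop("fit_radial_density: non-finite samples")
  if (any(r < 0) || any(rho < 0))
    stop("fit_radial_density: r and rho must be non-negative")
  if (n_gaussians < 1L) stop("fit_radial_density: n_gaussians must be >= 1")
  n_free <- 2L * n_gaussians  # weights + exponents (one constraint removed)
  if (length(r) < n_free)
    stop(sprintf("fit_radial_density: %d samples cannot determine %d free parameters",
                 length(r), n_free))
  if (target_electrons <= 0 && nonnegative)
    stop("fit_radial_density: target_electrons must be > 0 for a non-negative fit")

  wts <- r^2
  # basis matrix of unit-normalized gaussians at given exponents
  basis <- function(alphas)
    vapply(alphas, function(a) (a / pi)^1.5 * exp(-a * r^2), numeric(length(r)))

  # signed weights: minimize ||W^(1/2)(B w - rho)|| s.t. sum(w) = target
  solve_signed <- function(alphas) {
    B <- basis(alphas) * sqrt(wts)
    y <- rho * sqrt(wts)
    n <- length(alphas)
    # eliminate constraint: w = target*e1 + N t, N a basis of {sum = 0}
    if (n == 1L) {
      w <- target_electrons
      return(list(w = w, rss = sum((B * w - y)^2)))
    }
    N <- rbind(diag(n - 1L), -1)
    w0 <- c(target_electrons, rep(0, n - 1L))
    t <- tryCatch(qr.solve(B %*% N, y - B %*% w0), error = function(e) NULL)
    if (is.null(t)) return(list(w = rep(NA_real_, n), rss = Inf))
    w <- as.numeric(w0 + N %*% t)
    list(w = w, rss = sum((B %*% w - y)^2))
  }

  obj_signed <- function(lalpha) {
    if (any(!is.finite(lalpha)) || any(abs(lalpha) > 50)) return(1e30)
    v <- solve_signed(exp(lalpha))$rss
    if (!is.finite(v)) 1e30 else v
  }
  obj_softmax <- function(par) {
    n <- n_gaussians
    lalpha <- par[seq_len(n)]
    theta <- c(0, par[-seq_len(n)])  # first logit pinned for identifiability
    w <- target_electrons * exp(theta - max(theta)) /
      sum(exp(theta - max(theta)))
    B <- basis(exp(lalpha))
    sum(wts * (as.numeric(B %*% w) - rho)^2)
  }

  # spread of initial exponents guided by the sampled radial extent
  rspan <- max(r[rho > max(rho) * 1e-6], max(r) / 10, 0.1)
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    lalpha0 <- log(sort(exp(stats::runif(n_gaussians,
                                         log(0.25 / rspan^2),
                                         log(50 / rspan^2)))))
    # 1-parameter problems use Brent (Nelder-Mead is unreliable there)
    polish <- function(par0, obj) {
      fit <- if (length(par0) == 1L)
        stats::optim(par0, obj, method = "Brent", lower = par0 - 25,
                     upper = par0 + 25)
      else stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      tryCatch(
        stats::optim(fit$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) fit)
    }
    fit <- if (nonnegative)
      polish(c(lalpha0, stats::rnorm(n_gaussians - 1L, 0, 0.5)),
             obj_softmax)
    else polish(lalpha0, obj_signed)
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  if (nonnegative) {
    lalpha <- best$par[seq_len(n_gaussians)]
    theta <- c(0, best$par[-seq_len(n_gaussians)])
    w <- target_electrons * exp(theta - max(theta)) /
      sum(exp(theta - max(theta)))
    alphas <- exp(lalpha)
  } else {
    alphas <- exp(best$par)
    w <- solve_signed(alphas)$w
  }
  o <- order(alphas)
  shells <- Map(function(wi, ai) gaussian_shell(wi, ai, c(0, 0, 0)),
                w[o], alphas[o])
  attr(shells, "rss") <- best$value
  attr(shells, "target") <- target_electrons
  shells
}
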