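#' Dimer geometry container
#'
#' Element symbols and Cartesian coordinates (Angstrom) for two monomers,
#' with the monomer split given as the atom count of the first monomer
#' (atoms `1..split` belong to molecule A).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, n x 3, Angstrom.
#' @param split number of atoms in monomer A (1 <= split < n).
#' @param meta free-form list (scan family, probed distance, angle, ...).
#' @return An object of class `dimer_geometry`.
#' @export
dimer_geometry <- function(elements, coords, split, meta = list()) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3L,
            all(is.finite(coords)))
  split <- as.integer(split)
  if (split < 1L || split >= length(elements))
    stop("dimer_geometry: split must leave at least one atom per monomer")
  structure(list(elements = as.character(elements), coords = coords,
                 split = split, meta = meta),
            class = "dimer_geometry")
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat(sprintf("<dimer_geometry> %s | %s",
              paste(x$elements[seq_len(x$split)], collapse = ""),
              paste(x$elements[-seq_len(x$split)], collapse = "")))
  if (!is.null(x$meta$distance))
    cat(sprintf("  (%s, d = %.3f A)",
                x$meta$family %||% "?", x$meta$distance))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum intermolecular atom-atom distance of a dimer
#'
#' @param geom a [dimer_geometry()].
#' @return distance in Angstrom.
#' @export
min_intermolecular_distance <- function(geom) {
  ia <- seq_len(geom$split)
  ca <- geom$coords[ia, , drop = FALSE]
  cb <- geom$coords[-ia, , drop = FALSE]
  min(sqrt(outer(ca[, 1], cb[, 1], "-")^2 +
             outer(ca[, 2], cb[, 2], "-")^2 +
             outer(ca[, 3], cb[, 3], "-")^2))
}

#' Scan specification
#'
#' @param family `"oxygen_scan"` (water O...O), `"hydrogen_scan"` (water
#'   O...H) or `"o2_colinear"` (colinear O2 dimer).
#' @param distance_range length-2 numeric, Angstrom; min must be > 0.
#' @param n_distance number of evenly spaced probe distances (>= 1).
#' @param n_angular number of angular grid points (ignored for
#'   `o2_colinear`).
#' @param seed integer recorded with the spec (generation is deterministic;
#'   the seed feeds any downstream noise).
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(family = c("oxygen_scan", "hydrogen_scan",
                                 "o2_colinear"),
                      distance_range, n_distance, n_angular = 1L,
                      seed = 1L) {
  family <- match.arg(family)
  distance_range <- as.numeric(distance_range)
  stopifnot(length(distance_range) == 2L, distance_range[1] > 0,
            distance_range[2] >= distance_range[1])
  if (n_distance < 1L) stop("scan_spec: n_distance must be >= 1")
  if (n_angular < 1L) stop("scan_spec: n_angular must be >= 1")
  structure(list(family = family, distance_range = distance_range,
                 n_distance = as.integer(n_distance),
                 n_angular = as.integer(n_angular),
                 seed = as.integer(seed)),
            class = "scan_spec")
}

# rigid gas-phase water monomer, O at origin, bisector along +z,
# hydrogens in the xz plane.  r(OH) = 0.9572 A, HOH angle 104.52 deg.
.water_monomer <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c( sin(half) * r_oh, 0, cos(half) * r_oh),
        H2 = c(-sin(half) * r_oh, 0, cos(half) * r_oh))
}

# rotation by angle about the x axis
.rot_x <- function(theta)
  rbind(c(1, 0, 0),
        c(0, cos(theta), -sin(theta)),
        c(0, sin(theta), cos(theta)))

#' Generate rigid water-dimer scan geometries
#'
#' Two rigid water monomers on a distance x angle grid.  Monomer A sits at
#' the origin with its dipole (HOH bisector) pointing away from the
#' partner.  For the `oxygen_scan` family the probed distance is O...O
#' along the z axis and the angular coordinate tilts monomer B about an
#' axis through its oxygen, perpendicular to the intermolecular axis,
#' evenly over `[0, pi]` (hydrogens pointing away from A at 0, towards A at
#' pi).  For the `hydrogen_scan` family one O-H bond of monomer B points at
#' A's oxygen, the probed distance is that O...H contact, and the tilt is
#' about an axis through the contact hydrogen, evenly over `[0, pi/3]`, so
#' the probed distance is preserved exactly.  Spin about the
#' intermolecular axis is fixed at zero.  Every emitted monomer is rigid:
#' r(OH) = 0.9572 Angstrom, HOH angle = 104.52 degrees.
#'
#' The default calibration design uses 100 distances x 50 angles per
#' family, i.e. 5000 configurations each.
#'
#' @param spec a [scan_spec()] with family `oxygen_scan` or
#'   `hydrogen_scan`.
#' @param clash_floor minimum allowed intermolecular atom distance,
#'   Angstrom; generation stops with an error if violated.
#' @return list of [dimer_geometry()], length
#'   `n_distance * n_angular`, ordered distance-major.
#' @export
water_dimer_scan <- function(spec, clash_floor = 0.5) {
  stopifnot(inherits(spec, "scan_spec"))
  if (!spec$family %in% c("oxygen_scan", "hydrogen_scan"))
    stop("water_dimer_scan: family must be oxygen_scan or hydrogen_scan")
  dists <- if (spec$n_distance == 1L) spec$distance_range[1] else
    seq(spec$distance_range[1], spec$distance_range[2],
        length.out = spec$n_distance)
  theta_max <- if (spec$family == "oxygen_scan") pi else pi / 3
  thetas <- if (spec$n_angular == 1L) 0 else
    seq(0, theta_max, length.out = spec$n_angular)
  w <- .water_monomer()
  # A: bisector along -z (hydrogens below the xy plane), O at origin
  A <- w %*% diag(c(1, 1, -1))
  out <- vector("list", spec$n_distance * spec$n_angular)
  idx <- 1L
  r_oh <- 0.9572
  for (d in dists) {
    for (j in seq_along(thetas)) {
      th <- thetas[j]
      if (spec$family == "oxygen_scan") {
        # B's bisector starts along +z; tilt about x through its O
        B <- w %*% t(.rot_x(th))
        B <- sweep(B, 2, c(0, 0, d), "+")
      } else {
        # B with one O-H bond along -z: H1 at the contact point
        B0 <- rbind(O  = c(0, 0, r_oh),
                    H1 = c(0, 0, 0),
                    H2 = .h2_position(r_oh))
        B <- B0 %*% t(.rot_x(th))               # tilt about x through H1
        B <- sweep(B, 2, c(0, 0, d), "+")
      }
      g <- dimer_geometry(c("O", "H", "H", "O", "H", "H"),
                          rbind(A, B), split = 3L,
                          meta = list(family = spec$family, distance = d,
                                      angle = th, angular_index = j))
      if (min_intermolecular_distance(g) < clash_floor)
        stop(sprintf("water_dimer_scan: clash below %.2f A at d = %.3f, theta = %.3f",
                     clash_floor, d, th))
      out[[idx]] <- g
      idx <- idx + 1L
    }
  }
  out
}

# second hydrogen of the contact-oriented monomer: O at (0,0,r_oh), H1 at
# the origin.  O->H1 points along -z; O->H2 is that direction rotated by
# the rigid HOH angle about x, keeping the monomer in the yz plane.
.h2_position <- function(r_oh) {
  ang <- 104.52 * pi / 180
  c(0, r_oh * sin(ang), r_oh - r_oh * cos(ang))
}

#' Generate colinear O2-dimer scan geometries
#'
#' Two O2 molecules (bond length 1.208 Angstrom) on one axis; the probed
#' distance is the separation between the two facing oxygen atoms,
#' taking `n_distance` evenly spaced values over `distance_range`.  The
#' default evaluation grid uses 300 points.
#'
#' @param spec a [scan_spec()] with family `o2_colinear`.
#' @return list of [dimer_geometry()], length `n_distance`.
#' @export
o2_dimer_scan <- function(spec) {
  stopifnot(inherits(spec, "scan_spec"))
  if (spec$family != "o2_colinear")
    stop("o2_dimer_scan: family must be o2_colinear")
  r_oo <- 1.208
  dists <- if (spec$n_distance == 1L) spec$distance_range[1] else
    seq(spec$distance_range[1], spec$distance_range[2],
        length.out = spec$n_distance)
  lapply(seq_along(dists), function(i) {
    d <- dists[i]
    coords <- rbind(c(0, 0, -r_oo), c(0, 0, 0),
                    c(0, 0, d), c(0, 0, d + r_oo))
    dimer_geometry(c("O", "O", "O", "O"), coords, split = 2L,
                   meta = list(family = "o2_colinear", distance = d,
                               distance_index = i))
  })
}

#' Synthetic reference interaction energies from known coefficients
#'
#' Evaluates the full model (naive Coulomb + XC with `true_coeffs`) on each
#' geometry and adds seeded Gaussian noise, producing a
#' [reference_set()] that stands in for an ab initio reference table.  With
#' zero noise, refitting at the generating order recovers `true_coeffs`
#' exactly (closure).
#'
#' @param geometries list of [dimer_geometry()].
#' @param densities per-entry list of `list(A = , B = )` monomer
#'   densities matching `geometries` (e.g. via [dimer_densities()]).
#' @param true_coeffs an [xc_coefficients()].
#' @param noise_sd Gaussian noise standard deviation, kJ/mol (>= 0).
#' @param seed integer seed for the noise.
#' @param tags passed to [reference_set()].
#' @return a [reference_set()] with energies in kJ/mol and provenance
#'   recording the generator inputs.
#' @export
synthetic_reference_energies <- function(geometries, densities, true_coeffs,
                                         noise_sd = 0, seed = 1L,
                                         tags = "other") {
  stopifnot(noise_sd >= 0, length(geometries) == length(densities))
  clean <- vapply(seq_along(geometries), function(i)
    hartree_to_kjmol(total_interaction_energy(
      densities[[i]]$A, densities[[i]]$B, true_coeffs)),
    numeric(1))
  set.seed(as.integer(seed))
  eps <- if (noise_sd > 0) stats::rnorm(length(clean), 0, noise_sd) else
    numeric(length(clean))
  reference_set(geometries, clean + eps, tags = tags,
                provenance = list(generator = "synthetic_reference_energies",
                                  order = true_coeffs$order,
                                  basis_mode = true_coeffs$basis_mode,
                                  ee_weights = true_coeffs$ee_weights,
                                  en_weights = true_coeffs$en_weights,
                                  noise_sd = noise_sd,
                                  seed = as.integer(seed)))
}
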