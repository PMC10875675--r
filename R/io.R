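#' Read and write (multi-structure) XYZ geometry files
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom, coordinates in Angstrom; multiple frames
#' are concatenated.  The comment line carries whitespace-separated
#' `key=value` pairs; the key `split=N` marks the first `N` atoms as
#' monomer A, which is how a dimer file encodes its monomer partition.
#'
#' @param path file path.
#' @param default_split monomer split to assume when a frame's comment
#'   lacks `split=`; `NULL` means such frames error.
#' @return `read_xyz`: list of [dimer_geometry()] objects.
#' @export
read_xyz <- function(path, default_split = NULL) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("read_xyz: line %d: expected an atom count, got '%s'",
                   i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("read_xyz: line %d: truncated frame (%d atoms declared)",
                   i, n))
    comment <- lines[i + 1L]
    meta <- .parse_kv(comment)
    atoms <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(atoms), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4L)
    if (length(bad))
      stop(sprintf("read_xyz: line %d: malformed atom record '%s'",
                   i + 1L + bad[1], atoms[bad[1]]))
    elements <- vapply(parts, `[[`, "", 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords)))
      stop(sprintf("read_xyz: non-numeric coordinates in frame %d", frame))
    split <- if (!is.null(meta$split)) as.integer(meta$split) else
      default_split
    if (is.null(split))
      stop(sprintf("read_xyz: frame %d has no split= key and no default_split",
                   frame))
    if (split < 1L || split >= n)
      stop(sprintf("read_xyz: frame %d: split=%d out of range for %d atoms",
                   frame, split, n))
    meta$split <- NULL
    out[[frame]] <- dimer_geometry(elements, coords, split, meta = meta)
    i <- i + 2L + n
  }
  out
}

.parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 1L))
}

#' @rdname read_xyz
#' @param geoms list of [dimer_geometry()] (or a single one).
#' @return `write_xyz`: the path, invisibly.
#' @export
write_xyz <- function(geoms, path) {
  if (inherits(geoms, "dimer_geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    meta <- g$meta
    meta$split <- g$split
    kv <- paste(vapply(names(meta), function(k) {
      v <- meta[[k]]
      if (is.numeric(v)) sprintf("%s=%.12g", k, v) else
        sprintf("%s=%s", k, as.character(v))
    }, ""), collapse = " ")
    writeLines(c(sprintf("%d", length(g$elements)), kv), con)
    for (j in seq_along(g$elements))
      writeLines(sprintf("%-3s %18.12f %18.12f %18.12f", g$elements[j],
                         g$coords[j, 1], g$coords[j, 2], g$coords[j, 3]),
                 con)
  }
  invisible(path)
}

#' Read and write density parameter tables
#'
#' Tab-separated table with one row per Gaussian term:
#' columns `element`, `mode` (`ecp` or `full`), `effective_Z`, `weight`,
#' `exponent` (inverse bohr^2).  A `#`-prefixed header documents the
#' columns.  All terms of one element/mode share its `effective_Z`.
#'
#' @param path file path.
#' @return data frame with those columns.
#' @export
read_density_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "mode", "effective_Z", "weight", "exponent")
  if (!all(need %in% names(df)))
    stop(sprintf("read_density_params: missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (any(df$exponent <= 0))
    stop("read_density_params: exponents must be > 0")
  if (any(df$effective_Z <= 0))
    stop("read_density_params: effective_Z must be > 0")
  df
}

#' @rdname read_density_params
#' @param params data frame as returned by `read_density_params`.
#' @export
write_density_params <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# edff density parameter table: s-type Gaussian expansion per element and basis mode", con)
  writeLines("# weight in electrons (unit-normalized primitives), exponent in 1/bohr^2", con)
  utils::write.table(params, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic per-element density parameters
#'
#' Gaussian expansion parameters fitted (with [fit_radial_density()]) to
#' synthetic Slater-type atomic radial densities bundled with the package:
#' 3 terms per element in ECP mode (valence densities, effective core
#' charges) and 9 terms in full-electron mode.  These are stand-ins of the
#' right shape and scale, not quantum-chemistry results; see the bundled
#' `radial_density_synthetic.tsv` for the generating samples.
#'
#' @return data frame in the [read_density_params()] layout.
#' @export
default_density_params <- function() {
  read_density_params(system.file("extdata", "density_params_synthetic.tsv",
                                  package = "edff", mustWork = TRUE))
}

#' Read and write Mulliken charge tables
#'
#' Tab-separated, columns `atom` (1-based index) and `charge` (electrons,
#' signed).
#'
#' @param path file path.
#' @return numeric vector of charges ordered by atom index.
#' @export
read_mulliken <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("atom", "charge") %in% names(df)))
    stop("read_mulliken: need columns atom, charge")
  df <- df[order(df$atom), ]
  if (!identical(as.integer(df$atom), seq_len(nrow(df))))
    stop("read_mulliken: atom indices must be 1..n")
  df$charge
}

#' @rdname read_mulliken
#' @param charges numeric vector of per-atom charges.
#' @export
write_mulliken <- function(charges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# edff Mulliken charges (electrons)", con)
  utils::write.table(data.frame(atom = seq_along(charges), charge = charges),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write XC coefficient files
#'
#' YAML with fields `basis_mode`, `order`, `ee_weights`, `en_weights` and a
#' free-form `provenance` block (calibration seed, data hash, ...).
#'
#' @param path file path.
#' @return an [xc_coefficients()]; the provenance block is attached as the
#'   `"provenance"` attribute.
#' @export
read_xc_coefficients <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("basis_mode", "order", "ee_weights", "en_weights")
  if (!all(need %in% names(y)))
    stop(sprintf("read_xc_coefficients: missing fields: %s",
                 paste(setdiff(need, names(y)), collapse = ", ")))
  co <- xc_coefficients(y$order, unlist(y$ee_weights), unlist(y$en_weights),
                        basis_mode = y$basis_mode)
  attr(co, "provenance") <- y$provenance
  co
}

#' @rdname read_xc_coefficients
#' @param coeffs an [xc_coefficients()].
#' @param provenance list recorded alongside the weights.
#' @export
write_xc_coefficients <- function(coeffs, path, provenance = list()) {
  stopifnot(inherits(coeffs, "xc_coefficients"))
  if (length(provenance) == 0 && !is.null(attr(coeffs, "provenance")))
    provenance <- attr(coeffs, "provenance")
  yaml::write_yaml(list(basis_mode = coeffs$basis_mode,
                        order = coeffs$order,
                        units = "weights scale bohr-dimensioned functionals to hartree",
                        ee_weights = as.numeric(coeffs$ee_weights),
                        en_weights = as.numeric(coeffs$en_weights),
                        provenance = provenance),
                   path, precision = 17)
  invisible(path)
}

#' Read and write reference-energy sets
#'
#' A reference set is stored as two files: `<stem>.tsv` with columns `id`,
#' `energy_kjmol`, `tag`, and `<stem>.xyz` holding the geometries in the
#' same order (multi-structure XYZ with `split=` keys).  Provenance is
#' stored in `#!`-prefixed YAML header lines of the table.
#'
#' @param stem path without extension.
#' @return a [reference_set()].
#' @export
read_reference_set <- function(stem) {
  tsv <- paste0(stem, ".tsv"); xyz <- paste0(stem, ".xyz")
  lines <- readLines(tsv)
  prov_lines <- sub("^#! ?", "", lines[startsWith(lines, "#!")])
  prov <- if (length(prov_lines))
    yaml::yaml.load(paste(prov_lines, collapse = "\n")) else list()
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  geoms <- read_xyz(xyz)
  if (length(geoms) != nrow(df))
    stop(sprintf("read_reference_set: %d table rows but %d geometries",
                 nrow(df), length(geoms)))
  reference_set(geoms, df$energy_kjmol, tags = df$tag, provenance = prov)
}

#' @rdname read_reference_set
#' @param refset a [reference_set()].
#' @export
write_reference_set <- function(refset, stem) {
  stopifnot(inherits(refset, "reference_set"))
  tsv <- paste0(stem, ".tsv"); xyz <- paste0(stem, ".xyz")
  con <- file(tsv, "w")
  prov <- yaml::as.yaml(refset$provenance)
  writeLines(paste0("#! ", strsplit(prov, "\n")[[1]]), con)
  df <- data.frame(id = seq_along(refset$energies),
                   energy_kjmol = sprintf("%.12g", refset$energies),
                   tag = refset$tags)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_xyz(refset$geometries, xyz)
  invisible(stem)
}

#' Build monomer densities from a dimer geometry
#'
#' Expands each atom of a [dimer_geometry()] into its Gaussian density
#' using a parameter table, applies Mulliken population scaling, and
#' returns the two frozen monomer densities with coordinates converted to
#' bohr.
#'
#' @param geom a [dimer_geometry()].
#' @param params density parameter table ([read_density_params()] layout);
#'   defaults to the bundled synthetic table.
#' @param charges Mulliken charges: either a named per-element vector
#'   (e.g. `c(O = -0.66, H = 0.33)`), a per-atom numeric vector over the
#'   whole dimer, or `NULL` for neutral atoms.
#' @param mode basis mode, `"ecp"` or `"full"`.
#' @return list with elements `A` and `B`, each a [molecule_density()].
#' @export
dimer_densities <- function(geom, params = default_density_params(),
                            charges = NULL, mode = c("ecp", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geom, "dimer_geometry"))
  n <- length(geom$elements)
  q <- if (is.null(charges)) rep(0, n)
  else if (!is.null(names(charges))) {
    miss <- setdiff(unique(geom$elements), names(charges))
    if (length(miss))
      stop(sprintf("dimer_densities: no charge for element(s) %s",
                   paste(miss, collapse = ", ")))
    as.numeric(charges[geom$elements])
  } else {
    stopifnot(length(charges) == n)
    as.numeric(charges)
  }
  build_atom <- function(i) {
    el <- geom$elements[i]
    rows <- params[params$element == el & params$mode == mode, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop(sprintf("dimer_densities: element %s not in parameter table (mode %s)",
                   el, mode))
    ctr <- ang_to_bohr(geom$coords[i, ])
    a <- atom_density(el, rows$effective_Z[1],
                      data.frame(weight = rows$weight,
                                 exponent = rows$exponent),
                      center = ctr, mulliken_charge = q[i])
    scale_to_population(a)
  }
  ia <- seq_len(geom$split)
  list(A = molecule_density(lapply(ia, build_atom), name = "A"),
       B = molecule_density(lapply(setdiff(seq_len(n), ia), build_atom),
                            name = "B"))
}
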