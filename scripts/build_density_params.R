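#!/usr/bin/env Rscript
# Regenerates the bundled synthetic per-element density fixtures:
#   inst/extdata/radial_density_synthetic.tsv  (Slater-type radial samples)
#   inst/extdata/density_params_synthetic.tsv  (Gaussian fits to them)
# The samples are analytic Slater-model atomic densities (exact hydrogenic
# 1s for H; Slater-rule exponents for O), not quantum-chemistry output --
# hence the _synthetic suffix.  Run from the repository root.

library(edff)

slater_1s <- function(r, zeta) (zeta^3 / pi) * exp(-2 * zeta * r)   # 1 e-
slater_2sp <- function(r, zeta) (zeta^5 / (3 * pi)) * r^2 * exp(-2 * zeta * r)

r_grid <- function(rmax, n) {
  # denser near the nucleus, where the density varies fastest
  u <- seq(0, 1, length.out = n)
  rmax * u^2
}

blocks <- list(
  list(element = "H", mode = "ecp", effective_Z = 1,
       rho = function(r) slater_1s(r, 1), rmax = 8, n = 90),
  list(element = "H", mode = "full", effective_Z = 1,
       rho = function(r) slater_1s(r, 1), rmax = 8, n = 90),
  # O valence (ECP): 6 electrons in 2s/2p-shaped density, zeta = 2.275
  list(element = "O", mode = "ecp", effective_Z = 6,
       rho = function(r) 6 * slater_2sp(r, 2.275), rmax = 6, n = 90),
  # O full: 2 x 1s core (zeta = 7.65) + 6 x valence
  list(element = "O", mode = "full", effective_Z = 8,
       rho = function(r) 2 * slater_1s(r, 7.65) + 6 * slater_2sp(r, 2.275),
       rmax = 6, n = 120))

samples <- do.call(rbind, lapply(blocks, function(b) {
  r <- r_grid(b$rmax, b$n)
  data.frame(element = b$element, mode = b$mode,
             effective_Z = b$effective_Z,
             r = sprintf("%.8f", r), rho = sprintf("%.10e", b$rho(r)))
}))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
con <- file("inst/extdata/radial_density_synthetic.tsv", "w")
writeLines(c(
  "# Synthetic Slater-model atomic radial densities (NOT ab initio data).",
  "# H: exact hydrogenic 1s.  O: Slater-rule exponents (1s 7.65, 2s2p 2.275).",
  "# r in bohr, rho in electrons/bohr^3; effective_Z is the ECP-reduced",
  "# nuclear charge in ecp mode and the atomic number in full mode."), con)
write.table(samples, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

# signed weights: the shell-like O valence density vanishes at the
# nucleus, which a small negative sharp Gaussian captures far better than
# any positive combination
params <- cli_fit_density("inst/extdata/radial_density_synthetic.tsv",
                          out = "inst/extdata/density_params_synthetic.tsv",
                          n_ecp = 3L, n_full = 9L, seed = 20260901L,
                          nonnegative = FALSE)
print(params)

# report fit quality per block
for (b in blocks) {
  rows <- params[params$element == b$element & params$mode == b$mode, ]
  r <- r_grid(b$rmax, 400)
  fitted <- rowSums(sapply(seq_len(nrow(rows)), function(i)
    rows$weight[i] * (rows$exponent[i] / pi)^1.5 *
      exp(-rows$exponent[i] * r^2)))
  rel <- sqrt(sum(r^2 * (fitted - b$rho(r))^2) / sum(r^2 * b$rho(r)^2))
  cat(sprintf("%s/%s: weighted rel. residual %.3e, sum(w) = %.6f\n",
              b$element, b$mode, rel, sum(rows$weight)))
}
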