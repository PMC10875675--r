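---
title: "Methods: an electron-density pair force field with a Laplacian-order exchange-correlation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an electron-density pair force field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edff)
```

## The model

`edff` computes the interaction energy of a pair of molecules from the
electron densities of the *isolated* monomers, frozen in place.  Each
atom's density is a short linear combination of unit-normalized s-type
Gaussians centered on its nucleus,

$$\rho_a(\mathbf r) = \sum_i w_i \left(\frac{\alpha_i}{\pi}\right)^{3/2}
  e^{-\alpha_i |\mathbf r - \mathbf R_a|^2},$$

so every integral the model needs has a closed form.  The starting point
is the *naive* assumption that the electrons of one monomer are entirely
unaffected by the other.  Under that assumption the interaction energy is
the classical Coulomb energy between the two frozen charge distributions,
partitioned into three components:

* electron–electron repulsion
  $E_{ee} = \iint \rho_A(\mathbf r)\,\rho_B(\mathbf r')/|\mathbf r -
  \mathbf r'| \, d\mathbf r\, d\mathbf r'$, which for s-Gaussian pairs
  reduces to $w_a w_b\,\mathrm{erf}(\sqrt{\alpha\beta/(\alpha+\beta)}\,
  d)/d$ per shell pair;
* electron–nuclear attraction $E_{en}$, the analogous
  $\mathrm{erf}(\sqrt\alpha\, d)/d$ sums against the partner nuclei, with
  a negative sign;
* nuclear–nuclear repulsion $E_{nn} = \sum_{ab} Z_a Z_b / d_{ab}$.

Only *inter*molecular pairs ever enter: the model is strictly a pair
interaction between rigid monomers.  Nuclear charges are *effective*
atomic numbers: the full atomic number in full-electron mode, or the
valence charge when the density table was built against an effective-core
description (H 1, Li–Ne minus the 1s core, Na–Ar minus the 1s2s2p core).

The naive model is qualitatively wrong wherever the densities overlap: it
has no exchange repulsion and no correlation.  The correction is an
additive exchange–correlation (XC) energy expanded in iterated-Laplacian
functionals of the frozen densities,

$$E_{xc} = \sum_{k=0}^{K} \left[ c_k \int (\Delta^k \rho_A)\,\rho_B \,
  d\mathbf r + d_k \sum_{b} Z_b\, (\Delta^k \rho_A)(\mathbf R_b)
  \right] + (A \leftrightarrow B),$$

with the $2(K+1)$ weights $c_k, d_k$ fitted to reference interaction
energies.  Because the Laplacian acts an even number of times,
integration by parts moves $\Delta^k$ freely between the two densities,
which makes every term symmetric under exchanging the monomers — a
requirement for any interaction energy.  The series index starts at
$k = 0$ (the plain density overlap and the density at the partner
nuclei), so "order six" means 14 weights.

Everything reduces to one algebraic fact: applying the radial Laplacian
$f'' + (2/d) f'$ to $P(d^2)\,e^{-\alpha d^2}$ returns a polynomial of one
higher degree times the same Gaussian, with the exact coefficient
recursion

$$Q(u) = 6\,(P' - \alpha P) + 4u\,(P'' - 2\alpha P' + \alpha^2 P),
  \qquad u = d^2 .$$

The coefficients are homogeneous in $\alpha$
($P_k(u) = \sum_j A_{kj}\,\alpha^{k+j} u^j$ with integer $A_{kj}$), so the
integer table is built once and rescaled per exponent; the ee term of
order $k$ is then $P_k(d^2;\mu)$ times the Gaussian overlap
$S_0(d) = w_a w_b (\mu/\pi)^{3/2} e^{-\mu d^2}$, $\mu = \alpha\beta/
(\alpha + \beta)$, and the en term is $P_k(d^2;\alpha)$ times the density
at the nucleus.  `laplacian_polynomial()` exposes the recursion;
$P_1 = 4\alpha^2 d^2 - 6\alpha$.

The en series deserves a caveat: evaluating the iterated-Laplacian
density at the partner nuclei, weighted by effective atomic numbers, is
the natural electron–nuclear analogue of the ee overlap series and is
symmetric by construction, but other integral forms could serve the same
role.  The operation contract would accept such a swap without touching
the calibration machinery.

## Units and conversions

All internal computation is in Hartree atomic units — bohr for lengths,
hartree for energies — where the integrals are dimensionless.  Files and
reports use Angstrom and kJ/mol with fixed constants
(1 bohr = 0.52917721067 Å, 1 hartree = 2625.4996394798 kJ/mol).  The
fitted weights absorb the bohr dimensions of the functionals, so
`xc_energy()` is in hartree; coefficient files record this convention.

## Densities, populations, and the bundled tables

`fit_radial_density()` fits sampled radial densities with $n$ Gaussians
under the exact population constraint $\sum w_i = N_e$, weighting
residuals by $r^2$ so that the radial distribution function — the thing
that controls every integrated quantity — is what is reproduced.  The
optimizer is a seeded multi-start (Nelder–Mead, then BFGS) over
log-exponents; weights are either kept positive via a softmax
parameterization (the default) or solved exactly by equality-constrained
linear least squares when signed weights are allowed.  Signed weights
matter in practice: a shell-like valence density vanishes at the nucleus,
and a small negative sharp Gaussian reproduces that dip far better than
any positive combination.

Intramolecular charge redistribution is folded in through Mulliken
partial charges: `scale_to_population()` multiplies an atom's shell
weights by one common factor so the population equals
$Z_{\mathrm{eff}} - q_{\mathrm{Mulliken}}$.  Uniform scaling preserves
the normalized radial shape exactly; it changes only the amplitude.  This
is an assumption — other redistribution schemes (e.g. moving population
between shells) are conceivable — but it keeps the model density-only and
is exactly invertible.  An atom whose scaled population would be
non-positive (a bare cation core) is rejected.

The package ships per-element parameter tables fitted from bundled
radial-density samples.  Both are *synthetic*, Slater-type model
densities, marked as such in their file names: H is the exact hydrogenic
1s density, O uses Slater-rule exponents (1s 7.65, 2s2p 2.275), with
3-Gaussian expansions in ECP mode and 9-Gaussian expansions in
full-electron mode, mirroring the usual coarse/fine split.  They have the
right shape and scale for exercising the model and calibrating against
synthetic references, but they are not quantum-chemistry densities;
`scripts/build_density_params.R` regenerates them, and
`read_density_params()` accepts user tables fitted to real DFT output in
the same layout.  The bundled water Mulliken charges (O −0.66, H +0.33)
are likewise representative values, not computed ones.

## Calibration

With the densities frozen, the total model energy is *linear* in the XC
weights: $E = E_{\mathrm{naive}} + \mathbf w \cdot \mathbf f$, where
$\mathbf f$ is the stacked vector of ee/en functional values
(`featurize()`).  `fit_xc_coefficients()` therefore solves the
least-squares problem exactly by QR factorization with column scaling,
and reports classical standard errors
($\hat\sigma^2 (X^\top X)^{-1}$).  A seeded real-coded genetic algorithm
followed by BFGS polish (`method = "ga_bfgs"`) is retained for parity
with derivative-free global fitting workflows and for any future
nonlinear extension; on the linear problem the two agree to optimizer
precision, which the tests exercise.  A rank-deficient feature matrix —
for instance from duplicated geometries — is an error that names the
degenerate orders rather than a silently unstable solution.

The error metric is the relative absolute error
$\mathrm{RAE} = \sum_i |E_i - E^{\mathrm{ref}}_i| / \sum_i
|E^{\mathrm{ref}}_i|$, aggregated over the whole set.  The aggregate form
stays finite when individual reference energies cross zero, which they do
along any scan through a potential well; a per-point mean-of-ratios
variant is available behind a flag for sensitivity checks.  One subtlety
is deliberate: the fit minimizes *squared* residuals while the RAE sums
*absolute* ones, so along a nested order scan (`order_scan()`) the RMS
error column is exactly non-increasing while the RAE can fluctuate by
parts in $10^4$ at the noise floor.  Both columns are reported.

Fitting is joint over the ee and en series, with uniform weighting of
the reference entries (a Boltzmann-style energy weighting would be a
one-line extension but is off by default), and the reported RAE is a
training error, as in order-scan analyses; a held-out split can be
arranged by the caller since reference sets are ordinary R objects.

## The scan generators and synthetic references

The calibration design is two families of 5,000 rigid water dimers
(100 distances × 50 angles each, 10,000 total) plus a 300-point colinear
O₂ scan for evaluation.  Monomer geometries are the standard rigid
gas-phase values: r(OH) = 0.9572 Å, ∠HOH = 104.52°, r(OO) = 1.208 Å for
O₂ — generated monomers reproduce them to $10^{-10}$.

The angular coordinate of the water families is a package choice, since
only the grid sizes are pinned down externally: the far monomer tilts
about an axis through its contact atom, perpendicular to the
intermolecular axis — through its oxygen over $[0, \pi]$ for the O···O
family, and through the contact hydrogen over $[0, \pi/3]$ for the O···H
family, which preserves the probed O···H distance exactly.  Spin about
the intermolecular axis is held at zero.  Default distance ranges are
O···O 2.0–4.5 Å, O···H 1.2–3.8 Å and O₂ 1.5–6.0 Å, chosen to cover the
repulsive wall into the near-well region while keeping every generated
pair above a 0.5 Å clash floor (enforced, not assumed).  All of these are
configurable through `scan_spec()`.

`synthetic_reference_energies()` closes the loop without any external
data: it evaluates the full model with *known* coefficients on a set of
geometries and adds seeded Gaussian noise.  With zero noise, refitting at
the generating order recovers the coefficients to the precision of the
linear algebra (the closure test); with noise, recovered coefficients
land within their standard errors.  What synthetic references do *not*
probe is model misspecification: real CCSD(T) energies contain physics —
polarization, charge transfer, anisotropic exchange — that no setting of
the weights reproduces exactly, so passing closure tests says the
machinery is right, not that the physics is complete.  The calibration
against real reference tables goes through the same
`read_reference_set()` path.

## Numerical choices

* `erf(γd)/d` switches to its Maclaurin series below $γd = 10^{-4}$;
  the two branches agree to machine precision at the switchover, and the
  $d = 0$ limits ($2γ/\sqrt\pi$ per unit weights) are exact.
* The integer Laplacian coefficient table is cached once per session and
  rescaled per exponent; coefficients grow like $4^k k!$, harmless in
  double precision through the orders of interest ($k \lesssim 10$).
* Feature columns are rescaled to unit RMS before solving; the fitted
  weights are mapped back exactly.  The functional magnitudes span many
  decades across orders ($\mu^{k+j}$ growth), and without scaling the
  normal equations would be numerically singular long before rank
  deficiency is real.
* Coincident intermolecular nuclei are an error (the Coulomb energy
  diverges); coincident shell centers are fine (the erf limits are
  finite).
* All randomness — fitting multi-starts, the GA, synthetic noise — flows
  from explicit integer seeds, and regeneration under a fixed seed is
  bit-identical.

## Problem sizes used by the tests and the acceptance script

The unit tests run scenes of 30–150 dimers; the deeper checks use 2,000
dimers for closure and noisy-recovery statistics and the full 5,000-dimer
family for the order-scan monotonicity check, with quadrature-oracle
comparisons on 100+ random shell pairs per integral family.  These sizes
were chosen so the full pipeline — generation, density expansion,
featurization, fitting — is exercised at calibration scale while the
whole suite stays fast enough to run habitually.

## Known limitations

* The model is nonpolarizable and pairwise: no charge transfer, no
  three-body terms, no intramolecular relaxation.
* Densities scaled to anionic or cationic populations inherit the
  neutral-atom shape; interactions involving charged, open-shell species
  are exactly the regime where frozen scaled densities are least
  trustworthy.
* The higher-order ee functionals oscillate in sign along a distance
  scan (provably: $P_k$ has $k$ real roots in $d^2$), so high-order fits
  extrapolate poorly outside the sampled distance range; this is visible
  in the tests as the sign-change property and is the practical reason
  to prefer modest orders unless the calibration set covers the target
  distances.
* Neutral monomers still interact at long range through their
  Mulliken-induced multipoles ($E \sim 1/d^3$ for two dipoles); only the
  monopole term vanishes.  The naive + XC split leaves all long-range
  electrostatics to the naive part, since the XC functionals decay as
  Gaussians.
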