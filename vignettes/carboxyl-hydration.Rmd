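---
title: "Modelling carboxyl hydration from isotope-contrast neutron scattering"
author: "epsrlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carboxyl hydration from isotope-contrast neutron scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epsrlite)
```

This vignette is the package's own account of its model, its numerical
choices, and what its tests do and do not demonstrate.

## The measurement being modelled

A total-scattering neutron diffractometer measures, per sample, the total
interference differential scattering cross section
$$
F(Q) \;=\; \sum_{\alpha\le\beta} (2-\delta_{\alpha\beta})\,
c_\alpha c_\beta\, b_\alpha b_\beta\, \bigl(S_{\alpha\beta}(Q)-1\bigr),
$$
the Faber–Ziman interference form: $c_\alpha$ is the atomic fraction of
site species $\alpha$ in the sample, $b_\alpha$ its bound coherent
scattering length, and $S_{\alpha\beta}(Q)$ the partial structure factor,
related to the site–site radial distribution function by
$$
S_{\alpha\beta}(Q)-1 \;=\; 4\pi\rho_0 \int_0^\infty r^2
\bigl(g_{\alpha\beta}(r)-1\bigr)\,\frac{\sin Qr}{Qr}\,w(r)\,\mathrm{d}r ,
$$
with $\rho_0$ the total atomic number density and $w(r)$ a modification
window (Lorch by default; the choice is recorded in output metadata).
Replacing ¹H ($b=-3.739$ fm) by ²H ($b=+6.671$ fm) changes the weights
$c_\alpha c_\beta b_\alpha b_\beta$ without changing the chemistry, so each
isotopologue sample provides an independent linear constraint on the same
set of partials. Exchangeable hydrogens (amino/amidinium protons, water
hydrogens) follow the solvent H/D ratio; their effective $b$ is the
population-weighted mean, i.e. isotopic mixtures are treated at the
coherent-average level, with no incoherence correction. That average is
exact for the intermolecular (distinct) part of $F$ when molecules are
labeled independently — a property the test suite checks by enumerating
labelings on a fixed configuration.

Only the distinct intermolecular contribution is computed: hydration-shell
conclusions live there, and the fixed intramolecular term of a rigid
molecule carries no configurational information. Instrument effects
(inelasticity, attenuation, multiple scattering, absolute calibration) are
out of scope; synthetic targets therefore live on the same footing as the
model curves.

## The simulation model

Solutes are **rigid bodies**: site positions are fixed local coordinates,
and a configuration is a center plus a unit quaternion per molecule in a
periodic cubic box. The built-in force fields are the reference
(OPLS-heritage) Lennard-Jones + fractional-charge site parameters for
glycine, betaine, ectoine and trigonelline, with SPC/E water. Cross
interactions use the **geometric mean for both ε and σ** (the OPLS
convention the solute models descend from). Box compositions follow the
printed recipes (e.g. 30 glycine + 900 waters; 60 trigonelline + 60 Cl⁻ +
60 H⁺ + 3000 waters), scalable while preserving the water:solute ratio.

Where the sources give no numbers, the package fixes ambient-solution
conventions once: total atomic number density 0.1 atoms/Å³ (pure water at
1 g/cm³), temperature 298.15 K. Internal geometries are idealized standard
geometries (carboxylate C–O 1.25 Å with O–C–O = 126°, tetrahedral sp³
centers, planar rings), stored as explicit coordinates so they are
inspectable and overridable through the TOML-dialect config files. Two
assumed multiplicities deserve note: the ectoine ring carries four `C`
sites and one `Hn1`/`Hn2` pair, and the trigonelline ring four `Cr` plus
the carboxylate-bearing `C` — in both cases the unique multiset that makes
the zwitterion electroneutral with the printed charges. Trigonelline's
counter-ions follow the stated convention: standard OPLS chloride, and H⁺
as a charged site without Lennard-Jones core (adequate for composition
bookkeeping; such a bare charge binds unphysically tightly to water oxygens,
so trigonelline runs are electrostatically crude at the H⁺ sites).

Energies: Lennard-Jones truncated at the cutoff plus **shifted-force
Coulomb** (energy and force zero at the cutoff; default 9 Å, capped at
L/2). This is a deliberate desk-scale approximation relative to Ewald
summation — adequate for the short-range shell structure analyzed here,
inadequate for dielectric or long-wavelength properties.

Sampling is NVT Metropolis Monte Carlo. One *sweep* (the package's reading
of an "iteration") is one attempted move per molecule; moves are 50%
translations / 50% rotations (single-site species only translate); rejected
moves restore the state exactly. Step sizes are tuned toward 40% acceptance
during equilibration and frozen for production. Initial configurations are
random insertions with overlap rejection (1.8 Å between heavy atoms, 1.2 Å
when a hydrogen is involved) followed by soft-core warm-up sweeps in which
the Lennard-Jones core is clamped at 0.8σ and the Coulomb distance at
0.8 Å, relaxing the packing before normal equilibration. All randomness
flows through R's RNG, so a seed makes runs bit-reproducible; the
incremental energy bookkeeping is asserted against full recomputation in
the tests.

## The refinement loop

The empirical-potential refinement treats the difference between model and
target $F(Q)$ sets as evidence about the pair potentials:

1. simulate under seed potential + current tabulated perturbation
   $U_{\mathrm{ep}}$;
2. misfit $= \sum_k w_k \int \Delta F_k(Q)^2\,\mathrm{d}Q$, with
   inverse-variance weights $w_k = 1/\sigma_k^2$ whenever the targets state
   a per-contrast uncertainty (uniform otherwise) — heteroscedastic curve
   sets make uniform weights overweight the deuterated, large-$|F|$
   contrasts;
3. back-transform each residual $\Delta F_k$ to $r$-space (the inverse of
   the forward transform), attribute the discrepancy to site pairs by
   least squares on the contrast weight matrix
   $W[k,(\alpha\beta)]=(2-\delta)c_\alpha c_\beta b^{(k)}_\alpha
   b^{(k)}_\beta$ via Moore–Penrose pseudo-inverse (with 36 pairs and at
   most 5 contrasts the system is under-determined; pairs outside the row
   space are flagged, and collinear families — all X–Hw pairs, for
   instance — share the correction in proportion to their weights, exactly
   the non-uniqueness real contrast sets have);
4. increment $U_{\mathrm{ep}}$ by $\mathrm{gain}\times kT$ times the
   attributed discrepancy, lightly smoothed along $r$ (3-point running
   mean) to damp bin-level noise chasing, clamped to ±cap (default
   2.5 kJ/mol) and tapered to zero over the last 10% of the grid;
5. keep the update only if the misfit decreases; otherwise halve the gain
   and retry. Because a rejection under Monte Carlo evaluation noise is
   ambiguous, rejections only count toward the stopping criterion once the
   gain has collapsed below 1/64 of its initial value; the loop stops after
   three consecutive sub-tolerance iterations (tol $10^{-3}$ relative) or
   `max_iter`, then runs production sampling under the frozen perturbation.

This concrete update rule is this package's own algorithm — EPSR-inspired,
not a reimplementation of the EPSR code's numerics. The perturbation grid
is deliberately coarse (0.1 Å) — fine enough for hydrogen-bond-width
features, coarse enough to limit the degrees of freedom available for
fitting noise.

## The synthetic measurement

`truth_spec()` defines the stand-in for a measured contrast set: the
glycine box simulated under the seed potential **plus a known Gaussian
well** on the O–Hw pair (depth −1.5 kJ/mol ≈ 0.6 kT at 1.8 Å, width
0.25 Å — a hydrogen-bond-strengthening perturbation on exactly the pair the
analysis fingerprints), with i.i.d. Gaussian noise of σ = 1% of max|F| per
contrast, and the truth g(r) archived for recovery scoring. The truth run
uses 10³ equilibration sweeps and 10⁴ production sweeps, mirroring the
stated measurement-analysis protocol. The five glycine contrasts pair each
solute labeling with matching water (H5/D2 in H₂O, D3/D5 in D₂O, 50/50 in
1:1) — the solvent pairing is not stated by the source and is documented
here as a shipped assumption.

What the generator emulates: contrast weighting, counting statistics
entering through finite sampling, stated point noise, seed-reproducibility.
What it does not: instrument resolution, Placzek/inelasticity distortions,
detector banks, absolute normalization. Passing the recovery test therefore
shows the inverse loop works on ideal-instrument data, not that it would
absorb real reduction artefacts.

A quantitative caveat the package's own recovery experiments make
explicit: at liquid density the O–Hw hydrogen bond is already ~20 kT deep
and the shell is saturated, so a 0.6 kT well changes g(O–Hw) by a
shift/broadening of order 0.2 rather than the factor-1.8 a dilute-gas
estimate suggests. Integrated over the measured Q-range, the clean
perturbation signal in the F(Q) set is therefore comparable to (about
equal to, under inverse-variance weighting) the stated 1%-of-max|F| noise
floor. That fixes the best honestly attainable misfit contraction: with
weights w, the expected initial misfit ≈ floor + signal (+ sampling bias)
and the expected terminal misfit ≥ floor, so terminal/initial cannot fall
below floor/(floor + signal) ≈ 0.5 *in expectation* for any consistent
weighting unless the loop also "fits" the stated measurement noise — which
the Lorch-windowed update deliberately resists. Single-seed ratios scatter
widely around that bound (observed 0.13–0.74) because the initial
evaluation is itself a noisy Monte Carlo estimate. The structural recovery itself —
the refined ensemble's g(O–Hw) moving toward the archived truth curve — is
the scientifically meaningful outcome, and is what the recovery study
scores; with only five contrasts the attribution is non-unique
(all X–Hw corrections are collinear), so the imposed well is recovered as
a weight-shared correction across the Hw pairs rather than localized on
O–Hw, exactly the indeterminacy real contrast sets carry. The recovery
study uses a 3-solute + 90-water box: large enough for usable O-site
statistics, small enough to sample deeply; its slowly-relaxing
solute–solute arrangement is the main residual systematic, which the long
initial equilibration keeps out of the baseline.

## Analysis conventions

* **RDFs**: minimum-image histograms with exact shell-volume normalization
  and the partner number density; intramolecular pairs excluded; the tail
  of a liquid RDF must sit within 1 ± 0.05 (asserted in tests).
* **Peak positions**: the first local maximum of a lightly smoothed g(r)
  (running mean, default 5 bins) locates the peak; the quadratic
  three-point refinement is evaluated on the *raw* histogram, because a
  running mean skews the apex of an asymmetric peak.
* **First-shell cutoff**: first local minimum after the first maximum of a
  smoothed g(r) (default 9 bins ≈ 0.27 Å at dr = 0.03 Å), with a
  prominence guard — a dip only counts if g later recovers by ≥20% of the
  peak-to-dip drop — so sampling wiggles on the shoulder are not mistaken
  for the shell boundary.
* **Angle distributions**: α (and β) are the angles at the oxygen vertex
  between the rays O→Co and O→water-atom; a water collinear beyond O reads
  180°. Every qualifying (O, water-atom) pair within the shell cutoff
  counts — waters bonded to both oxygens are counted at each, and β uses
  all Hw within the cutoff, not only the nearest. Shell cutoffs default to
  3.3 Å for O⋯Ow and 2.4 Å for O⋯Hw (hydrogen-bond first-minimum
  conventions; configurable). Histograms are raw angle frequencies with no
  sin θ Jacobian, normalized to unit integral; the convention is recorded
  in output metadata. The two equivalent oxygens of glycine/betaine share
  one site type (the printed models do not distinguish them); ectoine and
  trigonelline O and Oh are always analyzed separately.
* **SDF**: water oxygens within r_cut of the carboxyl carbon, mapped into
  the right-handed local frame (z along the O–Co–O bisector, x toward the
  first oxygen in the O–Co–O plane), binned on a 0.25 Å voxel grid. The
  in-shell voxel set includes a half-diagonal margin so its integral equals
  the mean first-shell count exactly; no mirror symmetrization is applied.
  The isodensity level for occupancy fraction f sorts in-shell voxels by
  density (ties by index) and accumulates to f — monotone in f by
  construction.

## Problem sizes and expectations

The bundled analyses run on reduced boxes chosen to resolve first-shell
statistics comfortably on a desk machine: 5 solutes + 150 waters
(L ≈ 17 Å, cutoff L/2) with 2×10⁴ production sweeps for the headline
structural numbers, 3 solutes + 90 waters for the refinement recovery
study, and 10³-molecule-scale short runs inside unit tests. At these sizes
the hydrogen-bond-scale quantities are converged to ~0.01 Å (first peaks)
and a few degrees (angle modes), verified by split-half comparisons.

Two honest discrepancies against the published refined-fit values persist
under the seed potentials and are expected rather than bugs: the simulated
O–Hw / O–Ow first peaks sit ~0.02–0.05 Å below the 1.7–1.8 / 2.7–2.8 Å
bands (the seed OPLS/SPC/E hydrogen bond is slightly tighter than the
refined experimental structure), and the betaine α mode comes out ~113–114°
as the maximum of a broad 105–135° plateau whose 130° shoulder is where the
refined distribution peaks sharply. Refinement against the real
measurements — which are not public — is precisely what would move these
numbers; the package states them as computed.

## Known limitations

Rigid molecules (no intramolecular disorder); shifted-force electrostatics
(no Ewald); NVT only; coherent-average isotope mixing; H⁺ as a bare
charge; refinement non-uniqueness inherent to few-contrast data. None of
these affect the package's purpose — a transparent, testable desk-scale
realization of the contrast-refinement route to carboxyl hydration shells.
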