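---
title: "Methods: quantitative biophysics of CAF-1-histone architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative biophysics of CAF-1-histone architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caf1arch)
```

# Scope

`caf1arch` implements the quantitative analysis layer of a multi-technique
study of how the histone chaperone CAF-1 (subunits Cac1, Cac2, Cac3) binds
H3/H4 and assembles (H3/H4)~2~ tetramers: equilibrium binding fits from
fluorescence anisotropy, FRET quantification by acceptor enhancement,
tetrasome quantification from native-gel densitometry, differential
hydrogen/deuterium exchange (HX-MS), cross-linking MS (XL-MS) filtering and
structural validation, and the structural metrics (SASA, buried interface
area, superposition RMSD) used to characterize the Cac1 winged-helix (WH)
homodimer. Instrument-level processing (isotope-envelope assignment,
spectral search engines, crystallographic refinement) is out of scope; the
package consumes their tabular exports. Every stage is paired with a
seed-controlled generator so the pipeline is testable without instrument
data.

# Equilibrium binding with ligand depletion

Anisotropy titrations use a labeled species A\* at a concentration
comparable to the dissociation constant, so free-titrant approximations
fail. The observable model is the exact one-site quadratic,

$$F_i = F_0 + F_{max}\cdot
\frac{(K_D + [A^*] + [B]_i) - \sqrt{(K_D + [A^*] + [B]_i)^2 - 4[A^*][B]_i}}
{2[A^*]},$$

implemented in rationalized form ($2[B]_i/(s+\sqrt{s^2-4[A^*][B]_i})$) to
avoid cancellation in the weak-binding tail. The baseline $F_0$ is fitted
(default initialization near 1, the normalized-anisotropy convention)
rather than fixed, so raw anisotropies can be fitted without
pre-normalization.

`fit_kd()` performs Levenberg-Marquardt least squares
(via `minpack.lm`) with multi-start initialization: $K_D$ starts at the
titrant concentration of half-maximal signal and at 0.3x / 3x that value,
with $K_D$ bounded positive. A fit is reported as **not calculable**
("n.c."), never as a number, when the plateau is unconstrained: estimated
$K_D$ beyond the largest titrant concentration, relative standard error of
$K_D$ above 50%, or no convergence. This mirrors how weak binders whose
titrations do not saturate are reported in this assay family.

**Quench correction.** Binding often quenches the pyrene label. The
observed anisotropy is then an intensity-weighted average of free and bound
species. When the endpoint intensities differ by more than 10%
(`quench_exceeds_trigger()`), `quench_corrected_anisotropy()` inverts the
weighting:

$$r = \frac{\frac{A-A_f}{A_b-A}\frac{Q_f}{Q_b}A_b + A_f}
{1+\frac{A-A_f}{A_b-A}\frac{Q_f}{Q_b}}.$$

The correction is exactly the identity at $Q_f = Q_b$, and composing it
with the forward intensity-weighted mixing model returns the population
(intensity-unweighted) anisotropy to machine precision — a property the
test suite exercises on random inputs.

**Coupled equilibria.** The scheme behind the apparent constants couples
chaperone binding of one or two histone dimers ($K_1$, $K_2$) to free-dimer
tetramerization ($K_{tet} = [D]^2/[T]$). `solve_coupled_equilibrium()`
eliminates free chaperone in closed form and root-finds the free-dimer
concentration on the dimer mass balance, which is provably strictly
increasing in $[D]$, so `uniroot` on $[0, D_{tot}]$ is deterministic and
cannot miss the root; a Newton polish brings conservation residuals to
$<10^{-9}$ relative. When $K_{tet}$ and $K_2$ are weak — the regime the
binding experiments operate in, since unlabeled histones produce no
anisotropy shift up to 10 µM — the solution collapses to the one-site
quadratic above, which is why a single apparent $K_{Dapp}$ is reported
rather than separate $K_1$ and $K_2$.

# FRET by acceptor enhancement

With a CPM donor and FM acceptor on separate H3/H4 dimers, tetramerization
brings the labels within the Förster radius ($R_0 = 52$ Å). The FRET
Effect is the ratio of sensitized acceptor emission (donor-band excitation,
385 nm) to directly excited acceptor emission (491 nm). `fret_effect()`
extracts the sensitized component by a scalar least-squares fit of the
donor-only spectrum to the dual-label spectrum over a donor-dominated
window (default 400–480 nm), subtracts it, and integrates the residual and
the direct-excitation spectrum over the acceptor window (default
500–560 nm):

$$\mathrm{FRET\ Effect} = F_{385}/F_{491}.$$

Windowed *areas* are used rather than single-wavelength peaks for noise
robustness; both windows are configurable because the original read-out
windows are not public. Spectra on different grids are linearly
interpolated onto the dual-spectrum grid.

The extraction is exact when donor and acceptor bands do not overlap the
opposite window. The synthetic generator's default bands (donor 470 nm,
acceptor 520 nm, sd 15 nm — realistic widths for these dyes) overlap
slightly, biasing the round-trip by well under 1%; the test suite therefore
asserts the default-band round-trip at 2% and the exact (1 ppm) recovery on
a well-separated construction. The excimer-band ratio
(`excimer_ratio()`, 465 nm band over the 375 nm monomer band, ±5 nm
windows) quantifies pyrene-pyrene stacking as a conformational probe.

# EMSA tetrasome fraction

A tetrasome carries two labeled H3/H4 dimers, a disome one, so fluorescent
band intensities over-count tetrasomes two-fold in particle units.
`fraction_tetrasome()` background-subtracts both bands, halves the entire
tetrasome signal, and forms $T'/(T'+D')$. The printed form of this
statistic is ambiguous about whether the divisor applies to the whole
background-subtracted signal or to the background alone; the molar
(whole-signal) reading is the default because it is the one under which the
statistic round-trips a known molar fraction through the label
stoichiometry, and `literal = TRUE` reproduces the alternative precedence
for comparison. Negative background-subtracted bands are clamped to zero
with a warning. `emsa_summary()` reports mean ± sd over replicate lanes.

# Differential HX-MS

`match_and_difference()` pairs peptides between bound and free samples on
the full key (protein, start, end, sequence) — the sequence guards against
coordinate collisions between different digests — and reports
$\Delta = \mathrm{bound} - \mathrm{free}$ deuterons at one exposure time;
unmatched peptides are excluded and counted. No back-exchange correction is
applied: back exchange is condition-independent, so it cancels in the
difference. Deltas are classified into $2k+1$ ordinal bins by thresholds
mirrored about zero (default ±0.3, ±0.6, ±1.0 deuterons, a 7-bin palette;
configurable because published color legends rarely state their cutoffs).
`residue_paint()` assigns each covered residue the class of the
largest-$|\Delta|$ covering peptide — a conservative
strongest-signal-wins convention adopted here — and labels uncovered
residues distinctly; `coverage_fraction()` is the interval-union coverage.
Uptake is validated against the exchangeable-amide count
(residues − prolines − 1).

# XL-MS filtering and validation

`filter_crosslinks()` applies the confirmation thresholds score > 20 and
expect < 1e-5 at the record level (as exported by the search engine).
`build_linkage_map()` classifies links intra/inter, deduplicates repeated
pairs with multiplicity, and carries 50-residue segmentation ticks.
`validate_against_structure()` measures Cα–Cα distances after an explicit
user-supplied mapping from sequence to structure numbering (the
crystallized fragment covers only part of the sequence, with a disordered
"wing"), using chemistry-specific thresholds: DSS ≤ 24 Å (11.4 Å spacer
plus two lysine side chains) and EDC ≤ 16 Å (zero-length chemistry). These
are standard Cα-level XL-MS practice values — the chemistry itself fixes
spacer lengths, not Cα thresholds — and they are recorded in the output.
Unmapped links are flagged and excluded from satisfaction rates, not
silently dropped. `sequence_mass()` provides average and monoisotopic
peptide masses for fragment identification.

# Structural metrics

SASA is Shrake–Rupley with a deterministic Fibonacci sphere lattice
(default 960 points/atom, probe 1.4 Å), Bondi van der Waals radii, and
hydrogens ignored (the target structures have none). Determinism makes
results reproducible bit-for-bit at fixed parameters; the lattice is fixed
in space, so rigid motion changes results only within the ~1% sampling
resolution at 960 points. Points falling exactly on a neighbor's expanded
sphere are occluded only by earlier-indexed atoms, so degenerate duplicated
atoms count their shared surface exactly once. `buried_surface_area()`
reports both the total ΔSASA and its half, since both conventions appear in
the literature for "interface area"; downstream comparisons record which
convention matched. `superpose_rmsd()` is a Kabsch SVD superposition with
reflections excluded, matching atoms on (chain, residue, atom name) with an
optional numbering offset; `symmetry_mate()` applies an explicit
fractional-space operator plus unit cell, deliberately avoiding space-group
expansion machinery.

# Synthetic data: what it does and does not emulate

Each generator is a deterministic function of its parameters and seed
(`.Random.seed` is restored, so generators never perturb the caller's
stream), and each closes the loop with its analyzer: noiseless generation
followed by analysis returns the generating parameter to numerical
precision.

The study conditions baked into the defaults: titrations use 12 points
log-spaced over 0.1–10x $K_D$ with Gaussian anisotropy noise of 0.005 on a
normalized baseline of 1 with amplitude 0.5, matching the precision of a
well-run anisotropy series; labeled-species concentrations follow the
assays (5 nM for CAF-1 titrations, 25 nM for histone-labeled subunit
titrations, 10 nM for Cac1-fragment experiments, as recorded in
`reference_affinities()`). Gel simulations implement the 2x tetrasome label
stoichiometry with multiplicative band noise; HX tables tile a random
proline-free sequence and embed an additive per-residue protection profile;
cross-link lists draw true links from sub-threshold Cα pairs with passing
statistics and decoys from distant pairs with failing statistics.

Noise is Gaussian and homoscedastic by default — real instruments show
heteroscedastic, occasionally correlated errors; real HX uptake saturates
in time rather than being time-independent; real spectra have asymmetric
vibronic structure rather than Gaussian bands; real gels have smears and
lane distortions. Passing round-trip tests therefore demonstrates
correctness of the estimators under their own observable models, not
robustness to every instrument artifact.

# Numerical and design choices

* Concentrations are carried in molar units internally; readers accept
  nM/µM columns and convert on input. Residue coordinates are 1-based and
  inclusive everywhere.
* The ligand-depletion quadratic is evaluated in rationalized form; its
  discriminant is clamped at zero against rounding (it is algebraically
  nonnegative).
* The coupled solver is parameterized directly on free dimer concentration
  with a proven-monotone residual rather than multi-dimensional
  root-finding; this cannot diverge and needs no starting guess.
* Bin edges in HX classification are left-open: a delta exactly at a
  threshold takes the lower (more conservative) bin.
* Ties in residue painting go to the earlier peptide, making the map
  deterministic under reordering of equal-magnitude signals.
* The n.c. rule (Kd above max titrant, or relative SE > 50%) was fixed
  before any fitting of noisy data and is deliberately conservative: a
  number with a half-width its own size is not a measurement.
* Problem sizes in the analysis scripts (100-seed recovery ensembles,
  proteins of a few hundred residues, 960-point SASA lattices) were chosen
  as the smallest sizes at which the Monte-Carlo and lattice errors are
  comfortably below the tolerances being tested.

# Known limitations

* Only single-curve fits: no global multi-construct fitting, no kinetics.
* $K_1$ and $K_2$ are not separable from a single titration (by design the
  package reports an apparent constant; the coupled solver is for forward
  simulation and regime checks).
* XL-MS validation is Cα-distance based; no side-chain modeling or
  solvent-accessible-path distances.
* The structural reference computations (crystallographic homodimer
  interface of the WH domain, superposition onto the search model, fragment
  mass from the database sequence) require the deposited coordinate files
  and sequence, which are not redistributed with the package; place
  `5jbm.pdb`, `5ejo.pdb` and `cac1_rlf2.fasta` under
  `inst/extdata/reference/` to enable them in `analysis/06` and the
  corresponding acceptance tests.
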