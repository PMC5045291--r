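# caf1arch

Quantitative biophysics of CAF-1–histone chaperone architecture.

The histone chaperone CAF-1 (subunits Cac1, Cac2, Cac3) deposits
(H3/H4)₂ tetramers onto newly replicated DNA. Dissecting which subunit
binds histones, and which region tetramerizes them, rests on a set of
quantitative readouts: equilibrium dissociation constants from
fluorescence anisotropy titrations fitted in the ligand-depletion regime,
FRET between mixed-labeled histone dimers quantified by acceptor
enhancement, tetrasome fractions from native-gel densitometry,
differential hydrogen/deuterium-exchange (HX-MS) protection maps,
cross-linking MS (XL-MS) contact maps validated against structures, and
structural metrics (buried interface area, superposition RMSD) for the
Cac1 winged-helix homodimer. `caf1arch` implements that analysis layer as
a tested R package, together with seed-controlled synthetic-data
generators that emulate each experiment so every stage can be exercised
end to end.

## The core model

Anisotropy titrations of a labeled species A\* (fixed at 5–25 nM, i.e.
comparable to K_D) against titrant B are fitted with the exact one-site
ligand-depletion isotherm

    F_i = F0 + Fmax * ((K_D + [A*] + [B]_i) - sqrt((K_D + [A*] + [B]_i)^2
          - 4 [A*][B]_i)) / (2 [A*])

by bounded Levenberg–Marquardt least squares with multi-start
initialization. Titrations that do not constrain the plateau are reported
as *not calculable* rather than as a number. When binding quenches the
fluorophore by more than 10%, observed anisotropies are first corrected
for intensity weighting:

    r = ( ((A-Af)/(Ab-A)) (Qf/Qb) Ab + Af ) / ( 1 + ((A-Af)/(Ab-A)) (Qf/Qb) )

A coupled-equilibrium solver (chaperone + dimer ⇌ complex, second dimer,
and free-dimer tetramerization) shows when the single-site reduction is
valid and conserves mass to 1e-9.

## Worked example

Simulate a homo-dimerization titration of the Cac1 C-terminal fragment
(10 nM labeled tracer, ground-truth K_D 26 nM) and fit it back:

```r
library(caf1arch)
ts <- gen_titration(kd = 2.6e-8, a_star = 10e-9, seed = 1)
fit_kd(ts)
#> Binding fit: Kd = 2.59e-08 M (SE 1.1e-09), f0 = 0.9988, fmax = 0.5045
```

The fitted K_D (25.9 nM from this one noisy series) recovers the
generating constant, `f0`/`fmax` the
baseline and amplitude. A titration that never approaches saturation is
refused honestly:

```r
weak <- gen_titration(kd = 1e-6, a_star = 10e-9,
                      b_grid = seq(1e-9, 1e-7, length.out = 8),
                      noise_sd = 0.003, seed = 7)
fit_kd(weak)
#> Binding fit: Kd not calculable (estimated Kd exceeds maximum titrant
#> concentration (no saturation))
```

FRET round-trip at the Förster radius of the CPM–FM pair:

```r
fret_effect(gen_spectra(distance = 52))$fret_effect
#> [1] 0.49992
```

The `analysis/` directory holds the full workflow as numbered scripts
(binding recovery, FRET/excimer, EMSA, HX protection map, XL-MS map,
structure metrics), each writing tables under `results/`.

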