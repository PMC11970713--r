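# irafold

Probabilistic NOE assignment and restrained structure calculation for
protein domains that coexist in a folded and an unfolded form — the
situation encountered for the N-terminal metal-binding domain (MBD) of a
bacterial Cu⁺/Ag⁺-transporting P1B-type ATPase, which populates a
structured (S) and an unstructured (U) conformation simultaneously in
solution. Because both forms contribute complete resonance sets to every
spectrum, conventional automated NOESY assignment would convert
unstructured-form cross peaks into bogus structural restraints. This
package implements the inferential restraint assignment (IRA) analysis
that solves the problem, plus everything around it: restraint generation,
a desk-scale restrained-annealing engine with coupled apo/metal-bound
refinement, metal-titration chemical-shift-perturbation analysis, and a
seeded synthetic-data generator with full ground truth.

## The model

Every NOESY cross peak receives assignment candidates — atom tuples whose
assigned shifts match all spectral dimensions. A candidate's probability
is

```
P = P_F · P_D
P_F = ∏_d exp(−Δ_d²/2),  Δ_d = (μ_d − a_d) / √(σ_F,d² + γ_F,d²)
P_D = k_D · Φ( n (r_min − r_0) / √(n² σ_D² + γ_D²) ),  n = 6
```

where `μ` is the assigned shift, `a` the peak position, `r_0` the
candidate's proton–proton distance in a template structure (class priors
1.0/0.5/0.3/0.2/0.15/0.1 for intra-residue … long-range before one
exists), and `Φ` the standard normal CDF. Candidates with `P_F ≤ 0.07`
are never considered. Five cycles of assignment and structure calculation
alternate; per peak, candidates with `P < P_max/f` are stripped with
`f = 50, 50, 20, 10, 5` while the template distance uncertainty shrinks
(`σ_D = 0.15, 0.15, 0.15, 0.1, 0.05`). Surviving structured-form
candidates become ambiguous distance restraints (`d = d_max (I/I_min)^(−1/6)`,
`d_max = 4.25 Å`, flat well `±0.33 d`, `r_eff = (Σ r⁻⁶)^(−1/6)`),
refined together with TALOS-style dihedral restraints, β-sheet
hydrogen-bond restraints, and trigonal metal coordination restraints
(Ag–S 2.3 Å, S–Ag–S 120°, Ag–S–C 109.5°; or implicit 4.0 Å S–S). The apo
and metal-bound forms can be refined simultaneously with an NCS penalty
holding shared segments superimposable while the metal-binding loops move
freely. Titrations are summarized per residue by the weighted truncated
statistic

```
Δδ_rms = (1/n) Σ_i χ(|δᵃ_i − δᵇ_i| / σ_i, τ_i),   χ(x, τ) = x² if x ≥ 2τ else 0
```

with σ = 1.0/10.0/4.0 ppm for H/N/C and thresholds τ estimated from
unperturbed reference residues.

See `vignettes/irafold-methods.Rmd` for the full account, including what
the synthetic generator does and does not emulate.

## Worked example: locating the metal site from a titration

```r
library(irafold)

truth <- make_toy_fold(6, seed = 1)       # 30-residue sheet + knuckle toy
ser   <- simulate_titration(truth)        # HSQC series, ratios 0 .. 1.2

out <- run_titration_pipeline(list(
  series            = ser,
  shifts_apo        = simulate_shifts(truth),
  shifts_bound      = simulate_shifts(truth, state = "bound"),
  reference_residues = c(1:2, truth$n_residues),
  k = 3))

out$ranking
#>   residue_index      value
#> 1            12 0.05962857
#> 2            21 0.05962857
#> 3            18 0.05962857

out$broadened_residues
#> [1] 12 18 21

truth$site_residues
#> [1] 12 18 21
```

The three top-ranked residues — and exactly the residues whose peaks
broaden out at intermediate metal:protein ratios — are the generator's
tri-sulfur site (the loop-1 methionine and the Cys/Met pair of the
knuckle), mirroring how the real domain's binding site was located from
the clustering of the largest shift perturbations and the
intermediate-exchange dropout. The `value` column is Δδ_rms (dimensionless,
sigma-scaled); the site residues share one value here because the
generator injects perturbations of fixed magnitude per atom class.

The numbered scripts under `analysis/` run the full study end to end:
`01_simulate.R` (generate the synthetic system and write all NMR input
files), `02_assign.R` (the five IRA cycles, with audit), `03_structure.R`
(final ensembles, coupled apo/bound refinement, accuracy against ground
truth), `04_titrate.R` (the analysis above). Outputs land in `results/`.

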