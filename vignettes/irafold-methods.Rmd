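---
title: "Probabilistic NOE assignment and dual-form structure calculation: methods"
author: "irafold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic NOE assignment and dual-form structure calculation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Small metal-binding domains of P1B-type ATPases can coexist in solution as
two conformations of the same polypeptide: a folded, metal-competent form
(here the *S*-form) and a disordered form (*U*-form). Both forms contribute
a complete resonance set to every spectrum, so a NOESY cross peak can be
explained by atom pairs of either form. Standard automated NOE assignment
assumes one molecule and would happily interpret unstructured-form peaks as
structural restraints for the folded form; the analysis implemented here
instead ranks every assignment possibility probabilistically, identifies
peaks likely to belong to the unstructured form, and leaves them out of the
structure calculation.

The pipeline covers four stages, each usable on its own:

1. **Inferential restraint assignment (IRA)** — probabilistic candidate
   scoring and iterative stripping (`generate_candidates()`, `run_cycles()`).
2. **Restraint generation** — ambiguous NOE distance restraints, beta-sheet
   hydrogen-bond restraints, backbone dihedral restraints, trigonal metal
   coordination restraints, and NCS coupling between the apo and
   metal-bound forms (`assignments_to_restraints()`, `make_*_restraints()`).
3. **Structure calculation** — desk-scale restrained annealing with
   distance-geometry embedding, coupled two-form refinement, and ensemble
   selection by combined energy and chemical-shift pseudo-energy
   (`anneal()`, `anneal_coupled()`, `select_ensemble()`).
4. **Titration analysis** — peak tracking through a metal titration,
   per-residue weighted truncated rms shift differences, and binding-site
   ranking (`track_titration()`, `compute_delta_rms()`,
   `rank_binding_site()`).

A seeded synthetic-data generator (`make_toy_fold()` and the `simulate_*`
functions) supplies every stage with inputs whose ground truth is known,
so the whole analysis closes the loop against a controlled system.

## The assignment probability model

Every cross peak receives candidates: atom tuples whose assigned shifts
match all spectral dimensions. A candidate's probability is the product

$$P = P_F \, P_D$$

of a frequency-agreement factor and a distance-plausibility factor.

**Frequency agreement.** Per dimension $d$, the standardized deviation
between assigned shift $\mu_d$ and peak position $a_d$ is
$\Delta_d = (\mu_d - a_d) / \sqrt{\sigma_{F,d}^2 + \gamma_{F,d}^2}$, and

$$P_F = \prod_d \exp(-\Delta_d^2 / 2).$$

$\sigma_F$ is the per-resonance uncertainty, estimated from repeated
observations of the same resonance across the peak lists
(`estimate_sigma_f()`), with a floor of $\gamma_F/2$ when only a single
observation exists. $\gamma_F$ is a fixed per-nucleus floor: 0.2, 0.02,
0.3 and 0.05 ppm for N, amide H, C and other H. Candidates with
$P_F \le 0.07$ are never considered; under the unit-max kernel this gate
corresponds to about 2.3 combined standardized deviations. The kernel is
deliberately not density-normalized (the default), so that the gate has
this interpretation; a density-normalized variant is available via
`ira_config(normalized_pf = TRUE)`.

**Distance plausibility.** NOESY intensity falls off as $r^{-n}$ with
$n = 6$. Writing $r_\min$ for the distance below which half of all peaks
are statistically observable, and $r_0$ for the candidate's proton-proton
distance in a template structure,

$$P_D = k_D \, \Phi\!\left( \frac{n (r_\min - r_0)}
        {\sqrt{n^2 \sigma_D^2 + \gamma_D^2}} \right),$$

with $\Phi$ the standard normal CDF, $\gamma_D = 1.0$ the intensity
(log-normal) uncertainty, and $\sigma_D$ the distance uncertainty of the
template. For a template ensemble the structure-dependent factor is
averaged over the models. $k_D = 1$: only probability ratios matter for
the stripping rule. $r_\min$ defaults to the maximum calibration distance
4.25 Å. Before any template exists, class priors replace $P_D$: 1.0, 0.5,
0.3, 0.2, 0.15 and 0.1 for intra-residue, sequential, residue-difference
2, 3, 4 and long-range candidates.

**Cycles and stripping.** Five consecutive cycles of assignment and
structure calculation are run. Per peak, candidates with
$P_i < P_{\max}/f$ are stripped (strict inequality: the top candidate and
exact ties always survive). The schedules are $f = 50, 50, 20, 10, 5$ and
$\sigma_D = 0.15, 0.15, 0.15, 0.1, 0.05$ — stripping tightens and the
template is trusted more as the structure converges. Both forms' candidates
are scored against the (structured-form) template; unstructured-form
possibilities whose protons are far apart in the template lose plausibility
and vanish, which is the mechanism that excludes U-form peaks from
restraint generation. U-form candidates at sequence separation of four or
fewer residues are excluded from the start (`excluded_medium_range_U`):
those are the contacts an unstructured chain produces, so they mark the
peak as potentially unstructured rather than generating a restraint.
Candidates pair atoms within one form only — a cross peak arises within
one molecule, and the two forms are distinct species in solution.

## Restraint generation

* **NOE calibration**: $d = d_{\max} (I/I_{\min})^{-1/6}$ with
  $d_{\max} = 4.25$ Å and $I_{\min}$ the weakest intensity in the peak
  set; the square well spans $d \pm 0.33\,d$. Intensities below
  $I_{\min}$ clamp to $I_{\min}$ (weakest-peak convention, warned).
  Upper bounds of restraints involving methyl pseudo-atoms get +1.0 Å.
* **Ambiguity**: a restraint's member pairs are all surviving
  structured-form candidates of its peak; the effective distance is
  $r_\mathrm{eff} = (\sum_i r_i^{-6})^{-1/6}$, never larger than the
  closest member.
* **Hydrogen bonds**: residues with beta-strand probability above 0.75
  contribute two ambiguous HN/C' restraints each (target 1.7 Å, bounds
  1.4–2.0 Å), encoding that at least one edge of the strand is hydrogen
  bonded: (1) HN($i$)/C'($x$) or HN($x$)/C'($i-1$), and (2)
  HN($i+1$)/C'($x$) or HN($x$)/C'($i$), with $x$ free over the modeled
  range at a sequence-separation floor of 2. Proline HN and off-terminus
  partners are omitted with a message.
* **Dihedrals**: only predictions classified `Strong` are used; the
  square-well halfwidth is twice the prediction spread (a zero spread is
  replaced by a configurable minimum, default 5°).
* **Metal site**: explicit mode places the ion (initialized at the sulfur
  centroid) with three 2.3 Å metal–S bonds, three 120° S–metal–S and
  three 109.5° metal–S–C angles; implicit mode carries no ion and uses
  three pairwise S–S restraints of 4.0 Å — consistent with ideal trigonal
  geometry, $2 \times 2.3 \times \sin 60^\circ \approx 3.98$ Å. Only the
  trigonal three-sulfur site is supported, and the coordinating atoms are
  always caller-specified. Coordination terms are applied at covalent
  strength — narrow wells and force-constant multipliers an order of
  magnitude above the NOE terms — since a dative metal-sulfur bond is far
  stiffer than any distance restraint it competes with.
* **NCS coupling**: named residue segments of the apo and bound forms are
  kept superimposable through a harmonic penalty on backbone atoms in the
  optimally superposed frame; the metal-hosting loops are recorded as free
  segments and feel no penalty.

## The structure engine

The engine is a deliberately compact stand-in for a full structure
calculation program, adequate for restraint-driven folding of toys up to
~40 residues.

**Representation.** Backbone N, HN, CA, HA, C', O per residue, CB plus a
single beta pseudo-proton HB for every non-glycine residue, any further
side-chain atoms referenced by restraints (SG for Cys; CG, SD, CE for
Met), and an optional metal atom. Covalent geometry is encoded as
harmonic distance terms: bonds, 1–3 distances derived from ideal angles
by the law of cosines, and a trans-peptide CA–CA distance of 3.80 Å.
CA chirality is a signed-volume term fixing the L-configuration; sterics
are a soft-sphere repulsion between atoms more than three bonds apart.

**Annealing.** Each conformer starts from a metric-matrix
distance-geometry embedding: exact bounds from the covalent terms, upper
bounds from unambiguous distance restraints, triangle-inequality
smoothing, a random distance matrix sampled toward the mid-range of the
bounds, classical multidimensional scaling to 3D, and the hand (mirror
image) chosen by the chirality targets. The embedded coordinates are
settled under softened geometry, then a schedule of seeded random
displacements of decaying amplitude alternates with L-BFGS quenches while
covalent stiffness, torsion restraints and sterics ramp to full weight;
two full-weight quenches end the run, so the energy tail is monotone
nonincreasing. Identical `(topology, restraints, seed, schedule)` give
bit-identical conformers. Pools derive per-conformer seeds from a base
seed (`anneal_pool()`).

**Coupled two-form refinement.** The apo and bound coordinate sets are
optimized jointly. Every superposition round the bound form's coupled
segment is optimally superposed onto the apo form's and the inter-form
harmonic penalty acts in that frame; free segments (the metal-binding
loops) move independently. The superposition is recomputed a configurable
number of times per stage rather than every step, for cost control.

**Ensemble selection.** Conformers are ranked by the sum of their energy
decomposition plus a chemical-shift pseudo-energy: the sum of squared
differences between observed shifts and shifts back-calculated from the
conformer, scaled per nucleus by the same 1/10/4 weights as the CSP
statistic so that proton, nitrogen and carbon deviations are commensurate.
The default back-calculator (`default_shift_predictor()`) is random-coil
values plus beta-strand offsets for locally extended residues — the same
forward model the synthetic generator uses, so the pseudo-energy term is
exercised end to end without an external predictor. The 10 lowest-scoring
structures are kept (ties break by conformer index).

## Chemical-shift perturbation analysis

Per residue, over the $n$ atoms present in both states,

$$\Delta\delta_\mathrm{rms} = \frac{1}{n} \sum_i
  \chi\!\left(\frac{|\delta_i^a - \delta_i^b|}{\sigma_i}, \tau_i\right),
  \qquad \chi(x, \tau) = \begin{cases} x^2 & x \ge 2\tau \\ 0 & x < 2\tau
  \end{cases}$$

with $\sigma$ = 1.0, 10.0, 4.0 ppm for H, N, C. Despite the "rms" name
the statistic is the mean of truncated squares; `apply_sqrt = TRUE` takes
the root. The truncation thresholds $\tau$ are per atom class (amide H
0.01977, N 0.01761, C' 0.01780, other H 0.02620, other C 0.042974) and
represent measurement precision; `estimate_tau()` re-derives them as the
sample (n−1) standard deviation of the sigma-scaled shift differences
over reference residues known to be unaffected (the unstructured tails).
The estimate is on the sigma-scaled axis because that is the axis the
threshold is compared on. Residues sharing no atoms between the states
are absent from the profile rather than zero.

Titration series are tracked point to point by greedy nearest-neighbour
matching within per-dimension radii; a trajectory unmatched at a point is
`broadened_out` (the intermediate-exchange signature of binding-site
residues), and `reappeared` once matched again near saturation.
Binding-site ranking sorts residues by profile value; zero-valued
residues never rank.

## The synthetic system

`make_toy_fold()` builds a 30-residue miniature of the fold class under
study: three antiparallel beta strands (the first in the middle of the
sheet, the second only two residues long), two loops whose tips meet, and
a trigonal tri-sulfur site formed by a loop-1 methionine and a
Cys-Pro-X-Met knuckle on loop 2 (site residues 12, 18, 21 at the default
size). Pairwise S–S distances are 3.8–4.2 Å in the apo form and ideal
trigonal (≈3.98 Å) around the silver ion in the bound form, whose loops
are displaced by roughly 1.5 Å — the fast- vs intermediate-exchange
contrast of the titration rests on that difference. Coordinates are
produced by relaxing an ideal design (CA trace, site pins, sheet
hydrogen-bond pins) under the engine's own covalent geometry, with the
design pins softened at the end so the truth is near the engine's
geometric optimum.

Simulated observables and their noise model (`noise_model()` defaults):

* **Shifts**: random-coil tables plus beta-strand offsets plus a fixed
  seeded per-residue "tertiary dispersion" (sd 0.35/2.5/0.30/0.25 ppm for
  HN/N/HA/HB, 0.8 for carbons) for the S-form; coil plus a small offset
  (low dispersion) for the U-form; entry jitter of half the per-nucleus
  position jitter.
* **NOESY**: one directed peak per proton pair within 5.0 Å — a 3D
  15N-edited list for amide origins and a 3D 13C-edited list for HA/HB
  origins (the attached-carbon dimension is what separates alpha from
  beta protons, as in the real experiments). Intensity $\propto r^{-6}$
  with log-normal noise (sdlog 0.3), positions jittered per nucleus
  (0.004 ppm H, 0.04 N, 0.05 C), 5% of peaks missing, and U-form decoy
  peaks (intra-residue and sequential contacts at U-form positions) at
  rate 0.5.
* **Titration**: single-site stoichiometric binding (protein
  concentration 1, $K_d$ 0.005 in the same units) sets the bound
  fraction; non-site peaks drift linearly with it (fast exchange), site
  peaks are absent while the bound fraction is inside (0.2, 0.8)
  (intermediate exchange) and reappear at perturbed positions, and
  U-form intensities scale with the unbound fraction (the unstructured
  population converts upon binding).

What the generator does **not** emulate: spin diffusion, relaxation and
lineshapes, peak overlap at the detection stage (peaks are points, not
lineshapes), aromatic and full side-chain proton inventories beyond the
beta pseudo-proton, solvent exchange, and chemical-shift prediction
errors beyond the simple coil+offset model. Passing tests therefore show
that the inference machinery is correct under the stated statistical
model, not that it would handle every pathology of real spectra.

## Accuracy conventions and problem sizes

Two conventions used by the validation suite deserve explanation.

**Assignment correctness.** The generator labels one true origin per
peak. In a compact fold, however, distinct proton pairs can lie at
coincident chemical shifts *and* both within NOE contact distance; such
candidates are equally valid interpretations of the peak and are exactly
what ambiguous distance restraints are designed to carry. Assignment
accuracy is therefore scored as the fraction of surviving structured-form
candidates whose proton pair lies within the simulation's observability
cutoff (5 Å) in the ground-truth structure — the restraint-correctness
convention of the automated-assignment literature. Exact-origin recall is
tracked alongside.

**Ensemble accuracy.** Backbone RMSD to the toy truth is computed over
the fold core (residues 3 to n−1), excluding the flexible tails that
carry almost no restraints — the usual convention of reporting RMSD over
the ordered region of an NMR ensemble.

Desk-scale defaults: conformer pools of 8–30 (the published protocol's
4000-structure pool is an HPC-scale choice; pool size is configurable and
equivalence at 4000 is not asserted), template ensembles of 3–4 models
per assignment cycle, 8 annealing stages of 150 L-BFGS iterations. These
sizes were chosen so a complete analysis runs in minutes on one CPU while
every qualitative behaviour of the protocol is preserved.

## Numerical choices and degenerate inputs

* Quadratic (harmonic) penalties outside all square wells; well bounds
  are inclusive and the energy is continuous (value and slope zero) at
  the boundary.
* Negative peak intensities are folded to magnitude (flagged);
  zero-intensity peaks are rejected.
* Peaks matching no resonance in some dimension get no candidates and
  are dropped from restraint generation but retained in the audit;
  stripping ties at $P_{\max}$ all survive (strict inequality).
* Titration matching ties resolve by smallest radius-scaled displacement,
  then stable input order.
* The annealing objective guards against zero interatomic distances;
  non-finite energies abort with diagnostics.
* All randomness flows through explicit seeds; pool members derive seeds
  as `(seed + 7919 i) mod (2^31 - 1)`.

## Known limitations

* With the ambiguity variable $x$ free over the whole modeled range, the
  hydrogen-bond restraints' $r^{-6}$-pooled effective distance can sit
  below the well even when every individual HN/C' pair is at its native
  geometry, so on the toy system these restraints distort rather than
  help; they are exercised by the unit tests but left out of the recovery
  analyses. On real data the practical reading restricts $x$ to plausible
  strand partners.

* The engine has no attractive nonbonded term, no explicit hydrogen-bond
  geometry potential and no torsion-space dynamics; it folds because the
  restraints say so. Precision beyond ~1 Å backbone RMSD on a 30-residue
  toy is not its design goal.
* Ambiguity that is genuinely unresolvable at the published uncertainty
  floors (e.g. two beta protons 0.03 ppm apart, both near the origin
  proton) survives the stripping schedule by construction; the ensemble
  absorbs it through $r^{-6}$ effective distances. A consequence at toy
  scale is that the final ensembles computed from assignment-derived
  ambiguous restraints are markedly less precise (several Angstrom) than
  those computed from the same engine under unambiguous ground-truth
  restraints (~1 Å): the toy offers roughly an order of magnitude fewer
  restraints per residue than a real structure determination, so residual
  assignment ambiguity dominates its final precision.
* Exchange-regime model fitting ($K_d$ estimation from titration curves)
  and lineshape analysis are out of scope; the titration module treats
  dropout as a binary signature.
* The NMR-STAR reader is a reduced convenience dialect, not a full schema
  implementation.
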