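---
title: "Analysing sodium-pumping NDQ rhodopsins with ndqkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sodium-pumping NDQ rhodopsins with ndqkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndqkit)
```

## Scope

Light-driven sodium-pumping rhodopsins (the NDQ clade, named for the
Asn–Asp–Gln triplet on helix C) are characterized by a combination of
sequence analysis, time-resolved spectroscopy, titration experiments,
electronic-structure bookkeeping and structural metrics. `ndqkit`
implements that workflow as five analysis stages plus seeded synthetic-data
generators so the whole pipeline runs and is testable offline:

1. **Motif classification** — reference-anchored motif extraction from an
   MSA, filtering, identity reduction, subgroup assignment.
2. **Lifetime-distribution analysis (LDA)** — Tikhonov-regularized inverse
   Laplace transformation of transient-absorption surfaces with L-curve
   factor selection.
3. **Titration fits** — multi-pKa Henderson–Hasselbalch curves, the Hill
   equation, monoexponential photocurrent decay, linear I–V readout,
   spectrum utilities.
4. **Protonation patterns** — enumeration of counterion protonation
   microstates and selection of the pattern consistent with an
   experimental excitation energy.
5. **Structure metrics** — contact distances, Kabsch superposition RMSD
   and modeled-residue bookkeeping on PDB/mmCIF models.

## Motif classification

All position-based operations are anchored to a reference record (KR2
numbering by convention): `build_reference_map()` maps reference residue
numbers to alignment columns by counting non-gap characters in the
reference row, so gaps anywhere in the alignment never shift the anchors.
The canonical sodium-pump motif is spelled from six anchors in the order
109, 112, 116, 123, 251, 216 — the order in which the positions are
conventionally listed, which spells `RNDQDK` (ascending order would spell
`RNDQKD`). The anchor set is fully configurable; note that the
conventional list uses K216 although the retinal-binding lysine of KR2 is
elsewhere numbered K255 — we ship the conventional list as the default and
leave the choice to the user.

Filtering keeps a record iff its motif letters are allowed at every anchor
(`X` matches nothing), its ungapped length is *strictly* greater than 250
residues, and its exact ungapped sequence has not occurred earlier
(case-insensitive, first occurrence wins). Identity reduction follows the
CD-HIT convention: identity = identical matched columns divided by the
smaller ungapped length, and a greedy incremental clustering (records
sorted by length descending, ties by id) in which each record joins the
first representative at or above the threshold (default 0.90) or seeds a
new cluster. This guarantees representatives are mutually below the
threshold. Subgroups are assigned from the letter at the column homologous
to KR2 L74: glutamate marks Subgroup 2, leucine/isoleucine Subgroup 1,
anything else (including a gap) is unassigned. Manual inspection steps
(e.g. checking for seven complete transmembrane helices) are not
algorithmic and are out of scope.

`nj_tree()` provides a neighbor-joining Newick writer (via `ape`) as
plumbing for tree visualization; maximum-likelihood inference and
bootstrapping are deliberately not reimplemented.

## Lifetime-distribution analysis

The transient surface $\Delta A(t, \lambda)$ is modelled per wavelength as
a superposition of exponential decays over a log-even lifetime grid
$\tau_j$:

$$\Delta A(t_i) \approx \sum_j x_j\, e^{-t_i/\tau_j},$$

an ill-posed inverse Laplace transform stabilized by Tikhonov
regularization,

$$\hat x(\alpha) = \arg\min_x \lVert A x - y \rVert^2 +
  \alpha^2 \lVert x \rVert^2 .$$

Numerical choices:

* **Penalty scale.** The penalty is written $\alpha^2\lVert x\rVert^2$ so
  the conventional regularization factors 0.01–5 act on the amplitude-norm
  scale; `penalty = "alpha"` switches to $\alpha\lVert x\rVert^2$.
* **Identity operator.** Plain ridge (no derivative-smoothness operator)
  and **no non-negativity constraint**: lifetime-distribution maps are
  signed, with positive lobes for photoproduct absorption and negative
  lobes for ground-state bleach.
* **Grids.** Default lifetime grids are 200 log-even points, 0.03–5400 ps
  on the ultrafast timescale and 0.4 µs to three times the last
  experimental time point on the ns–s timescale; the factor grid is 200
  log-spaced points from 0.01 to 5.
* **Solver.** One SVD of the design matrix per dataset; the whole factor
  path is then obtained from filter factors, which also guarantees the
  residual norm is non-decreasing and the solution norm non-increasing
  along the path. At $\alpha = 0$ a rank-deficient system returns the
  minimum-norm solution and is flagged.
* **L-curve corner.** The factor is chosen at the maximum curvature of the
  (log residual norm, log solution norm) path, estimated by central
  finite differences over the path index with endpoints excluded and ties
  resolved toward the smaller factor. A degenerate flat curve falls back
  to the median factor with a warning.
* **Artifact region.** Times at or below a configurable threshold
  (default 0) are dropped before inversion.

**Known limitation.** For *pure-noise* input the exponential kernel gives
a corner-free L-curve: its singular values decay geometrically, so the
residual and solution norms vary smoothly over the whole factor range and
the curvature maximum is essentially arbitrary. The corner criterion is
meaningful when the data contain exponential structure; with pure noise
the chosen factor should not be interpreted.

Peak lifetimes are read off as local maxima of $|x(\tau)|$ above a
relative amplitude floor (default 5% of the maximum), reported with their
sign — they are approximate by construction. Each photointermediate
transition appears at its own informative wavelengths; recovery checks
therefore collect peaks across the wavelength axis.

Data reduction (`reduce_transient()`) block-averages raw points into
logarithmic bins beyond a linear pass-through segment; the bin schedule is
exposed as points-per-decade because instrument software varies here.
`normalize_at_time()` rescales transients to a common interpolated value
at a reference delay (0.1 ms by default), as used for sodium-dependence
comparisons.

## Titration and kinetics fits

The spectral titration model is

$$y(\mathrm{pH}) = \mathrm{baseline} + \sum_k
  \frac{A_k}{1 + 10^{\mathrm{pH} - \mathrm{p}K_{a,k}}},$$

i.e. each transition contributes its full amplitude at low pH, matching
acid-induced red shifts; amplitude signs are free. The observable defaults
to the absorption maximum versus pH, but nothing in the fit assumes it —
absorbance at a fixed wavelength works identically (the experimental
literature does not always state which was fitted, so both are supported).
Starting values come from an inflection scan of the numerical derivative;
the starting amplitude and baseline are offset from the exact
endpoint-interpolating values by 0.1% of the amplitude because an exactly
endpoint-matching start can degenerate the underlying nonlinear
least-squares model matrix. Fitted pKa values are reported in ascending
order with curvature-based standard errors.

The Hill fit $y = y_\max c^n / (K^n + c^n)$ leaves the coefficient $n$
free (initialized at 1). Monoexponential decay fits
$I(t) = A e^{-t/t_\mathrm{off}} + C$ are initialized by log-linear
regression; non-decaying or offset-only input is flagged rather than
fitted. Photocurrents at a target voltage are read from the ordinary
least-squares line through the positive-voltage I–V points. The Gaussian
beam helper returns $r_{95} = \sigma\sqrt{2\ln 20} \approx 2.448\,\sigma$,
the radius enclosing 95% of the power of an isotropic 2-D Gaussian.

## Protonation patterns

For an ordered set of titratable carboxylic residues (default E64, D105,
D242 — the counterion complex of the retinal Schiff base), each residue is
deprotonated or protonated with one of four geometric proton orientations.
Orientations are *not* deduplicated by symmetry: the canonical counts
(1 zero-, 12 single-, 48 double-protonation, 61 total for the defaults)
presuppose distinct starting placements. Triple protonation is excluded by
default but `max_protonated` is a parameter. Enumeration order is
canonical (proton count, then lexicographic over per-residue states in a
fixed C locale) so pattern ids are stable.

Model selection consumes an externally computed energy table (quantum
chemistry itself is out of scope): patterns whose vertical excitation
energy falls within a tolerance (default 0.3 eV, the typical error of
excited-state methods) of the experimental value — obtainable from an
absorption maximum via $E[\mathrm{eV}] = 1239.842/\lambda[\mathrm{nm}]$ —
form the shortlist, and the lowest ground-state energy wins; ties are all
reported and an empty shortlist is an explicit result, not an error.
Ground-state energies must carry a single unit tag; mixed units are
rejected.

## Structure metrics

Structures load from PDB or mmCIF into a tidy atom table; alternate
locations are resolved by highest occupancy with ties to `A`.
`min_distance()` scans the cross-product of two selections (e.g. the
carboxyl oxygens of E64 and D105, whose ~2.1 Å contact indicates a
low-barrier hydrogen bond). `kabsch_rmsd()` pairs atoms by chain, residue
number and atom name — Cα by default, waters excluded — and computes the
optimal proper rotation via SVD with determinant correction; the test
suite cross-checks it against an independent quaternion-method oracle.
The retinal Schiff-base nitrogen can be addressed as the NZ atom of the
retinal-linked lysine; which atoms define published Schiff-base distances
is often unstated, so selections are always explicit here.

## Synthetic data: what it emulates, and what it does not

The generators encode the study conditions used throughout the tests:

* **Photocycle surfaces.** A strictly sequential unidirectional chain
  (Bateman closed form, or matrix exponential for degenerate lifetimes)
  with one Gaussian band per intermediate *in wavelength* (not
  wavenumber), additive i.i.d. Gaussian noise, and a combined
  linear/logarithmic time base. The default scheme is a five-intermediate
  K1→K2→M→O1→O2 chain with lifetimes 2 ps, 7 µs, 1 ms, 5 ms, 6 s, K/O
  bands at 590/620 nm, M at 400 nm and a 525 nm parent band. A lifetime
  here is the decay constant of its intermediate. Branched photocycles
  (e.g. parallel O1/O2 routes), back-reactions, instrument-response
  convolution, shot noise and coherent artifacts are not modelled — tests
  passing on these surfaces say nothing about such features in real data.
* **Titration/Hill curves.** Two-pKa defaults at 3.34 and 5.71 with
  amplitudes 6.5 and 3.0 nm on a 535.5 nm baseline; Hill default
  K½ = 190 mM. These printed constants serve as generator parameters, so
  recovery tests are self-consistency checks, not external validation.
* **Sequence families.** A scaffold with planted motif residues and a
  class-specific subgroup letter; mutations and gaps never touch planted
  columns, so ground-truth labels are exact. The packaged 60-member
  family uses mutation rate 0.20 so that every pairwise identity is
  several standard deviations below the 0.90 clustering threshold and the
  expected representative count is unambiguous. Database-scale counts of
  real NDQ sequences depend on the source databases and are deliberately
  not reproduced.
* **Toy structures.** Rigid-transformed point sets with optional Gaussian
  jitter; the expected superposition RMSD is
  $\sigma\sqrt{3}\sqrt{1 - 2/n}$.

## Problem sizes

The test suite and examples run on deliberately compact problems: lifetime
grids of 80–120 points and factor grids of 60–100 points for inversion
tests (the 200-point defaults are asserted separately), 20-replicate
seeded Monte-Carlo for lifetime recovery at SNR 100, 30–50 replicates for
titration/Hill noise studies, and fuzzing loops of 20–200 cases for the
combinatorial and geometric oracles. These sizes were chosen so the full
suite completes in well under a minute while every statistical check
retains a comfortable margin.

## Worked example

```{r example, eval = FALSE}
# simulate a photocycle measurement and invert it
ds <- simulate_transient_dataset(
  photocycle_scheme(c("M", "O"), c(1e-3, 1e-1), c(400, 620), c(28, 35)),
  simulation_config(seed = 1, noise_sigma = 0.01, time_end = 2,
                    points_per_decade = 15))
ldm <- compute_ldm(ds, grid = build_lifetime_grid(1e-5, 6, 100))
peak_lifetimes(ldm, 620, amplitude_floor = 0.1)
autoplot(ldm)

# titration analysis
fit <- fit_multi_pka(simulate_titration_curve(noise_sigma = 0.1, seed = 2),
                     n_transitions = 2)
tidy(fit)

# protonation bookkeeping
count_by_level(enumerate_patterns())
```
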