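# ndqkit

Analysis toolkit for light-driven sodium-pumping rhodopsins (the **NDQ
clade**, named for the Asn–Asp–Gln triplet on helix C). Characterizing
these pumps combines several computational stages that this package
implements as one tested, offline-runnable pipeline:

* **Motif classification** — extract residue motifs from a multiple
  sequence alignment at reference-anchored positions (KR2 numbering),
  filter by motif/length/duplication, reduce at 90% identity (CD-HIT
  convention), and assign Subgroup 1 (Leu/Ile at the position homologous
  to KR2 L74) versus Subgroup 2 (Glu).
* **Lifetime-distribution analysis (LDA)** — model-free inversion of
  transient-absorption surfaces ΔA(t, λ) into signed lifetime
  distributions by Tikhonov-regularized inverse Laplace transformation,

  &nbsp;&nbsp;&nbsp;&nbsp;x̂(α) = argmin ‖Ax − y‖² + α²‖x‖²,&nbsp;
  A[i,j] = exp(−t_i/τ_j),

  with the regularization factor chosen by the L-curve criterion
  (maximum curvature of the log residual-norm vs log solution-norm
  trade-off).
* **Titration fits** — multi-pKa Henderson–Hasselbalch curves
  y(pH) = baseline + Σ A_k/(1 + 10^(pH − pKa_k)), the Hill equation
  y = y_max·cⁿ/(Kⁿ + cⁿ), monoexponential photocurrent decay, linear
  I–V extraction, and spectrum utilities (sub-grid λ_max, A₂₈₀
  normalization, Gaussian-beam 95%-power radius).
* **Protonation patterns** — enumerate protonation microstates of the
  Schiff-base counterion triad (E64/D105/D242; four proton orientations
  each, up to double protonation → 61 patterns) and select the pattern
  whose vertical excitation energy matches experiment with the lowest
  ground-state energy.
* **Structure metrics** — PDB/mmCIF atom tables, minimum contact
  distances between selections, Kabsch superposition RMSD, modeled
  residue ranges.
* **Synthetic data** — seeded generators for photocycle surfaces
  (sequential first-order chain with Gaussian bands), titration/Hill
  curves, labelled aligned sequence families with planted motifs, and
  rigid-transformed toy structures, so every stage runs without network
  access or instrument data.

The package is tidyverse-native: functions take data frames and return
tibbles, fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a two-intermediate photocycle measurement (M → O; lifetimes
1 ms and 100 ms; 1% noise) and invert it:

```r
library(ndqkit)

ds <- simulate_transient_dataset(
  photocycle_scheme(c("M", "O"), c(1e-3, 1e-1), c(400, 620), c(28, 35)),
  simulation_config(seed = 1, noise_sigma = 0.01, time_end = 2,
                    points_per_decade = 15))
ds
#> <transient_dataset> 110 times (1e-07..2 s) x 73 wavelengths (340..700 nm)

ldm <- compute_ldm(ds, grid = build_lifetime_grid(1e-5, 6, 100))
peak_lifetimes(ldm, 620, amplitude_floor = 0.1)
#> # A tibble: 5 × 2
#>   lifetime amplitude
#>      <dbl>     <dbl>
#> 1 0.000192    0.0205
#> 2 0.000965   -0.111
#> 3 0.106       0.105
#> 4 0.534      -0.0205
#> 5 6          -0.0135
```

At the O-band wavelength (620 nm) the two dominant lobes sit at
0.000965 s and 0.106 s — the planted 1 ms and 100 ms lifetimes, each
within one step of the 100-point lifetime grid. The negative 1 ms lobe is
the rise of the red-shifted O state, the positive 106 ms lobe its decay;
the small flanking lobes are regularization ringing below the reporting
floor one would normally use.

Titration analysis of a noisy two-pKa curve (generated at pKa 3.34/5.71):

```r
fit <- fit_multi_pka(simulate_titration_curve(noise_sigma = 0.1, seed = 2),
                     n_transitions = 2)
tidy(fit)
#> # A tibble: 5 × 3
#>   term     estimate std_error
#>   <chr>       <dbl>     <dbl>
#> 1 pKa1         3.38    0.0286
#> 2 pKa2         5.78    0.0654
#> 3 A1           6.58    0.106
#> 4 A2           2.90    0.106
#> 5 baseline   536.      0.0633
```

Counterion protonation bookkeeping:

```r
count_by_level(enumerate_patterns())
#> # A tibble: 3 × 2
#>   n_protons count
#>       <int> <int>
#> 1         0     1
#> 2         1    12
#> 3         2    48
```

Classification of a packaged synthetic NDQ family (60 members plus a
reference, planted `RNDQDK` motif, Leu/Ile vs Glu subgroup letters):

```r
aln <- ref_alignment(read_fasta(system.file("extdata", "ndq_family_aln.fasta",
                                            package = "ndqkit")),
                     reference_id = "REF")
report <- classify_ndq(aln)
dplyr::count(report, subgroup)
#> # A tibble: 2 × 2
#>   subgroup      n
#>   <chr>     <int>
#> 1 Subgroup1    31
#> 2 Subgroup2    30
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/ndqkit.R` (`Rscript ndqkit.R patterns --out results/`), and
`ndq_run()` exposes every subcommand as a library call with a provenance
record.

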