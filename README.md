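# fretscape

Fluorescence-lifetime FRET analysis of DNA conformational landscapes,
plus the DNA-geometry descriptors used to interpret them.

## What it does, and for whom

A FRET donor inside duplex DNA reports on conformation through its
excited-state lifetime: transfer efficiency is **E = 1 − τ_DA/τ_D**,
where τ_DA and τ_D are the donor lifetimes with and without acceptor.
When the DNA exchanges between several conformations, a time-correlated
single-photon counting (TCSPC) decay is a mixture of exponentials, one
lifetime per state with amplitude equal to that state's population:

    μ_k = b + Σ_i α_i · exp(−t_k / τ_i),    counts_k ~ Poisson(μ_k)

`fretscape` is for experimentalists and modelers who need to turn such
decays into conformational landscapes and connect them to structure:

- **Simulation** — `simulate_decay()` generates TCSPC histograms with
  Poisson statistics at realistic acquisition settings (100 ns window,
  4096 channels, 10 000 peak counts), optionally IRF-convolved, with
  known ground truth.
- **Maximum-entropy inversion** — `mem_fit()` recovers a non-negative
  lifetime distribution α(τ) on a log grid by minimizing
  χ²/2 − λ·S(α), with S the Shannon–Jaynes entropy, λ chosen from the
  attainable χ² minimum, Poisson-aware tail pooling, and a convex
  Newton solver.
- **Landscapes** — `fit_gaussians()` decomposes the distribution into
  Gaussian peaks in log-lifetime (BIC model selection); peak areas are
  fractional populations; `fret_efficiency()` / `average_fret()` apply
  E = 1 − τ_DA/τ_D and ⟨E⟩ = 1 − (Σ A_i τ_DA,i)/τ_D.
- **DNA geometry** — base-pair frames, step/cumulative twist and the
  untwist angle (Twist_initial − Twist), bend angle, bend-direction
  pseudo-dihedral (negative toward the minor groove), base-extrusion
  pseudo-dihedral, Watson–Crick hydrogen bonds, and block-averaged
  uncertainties for correlated ensembles — from standard (multi-MODEL)
  PDB files or from `build_duplex()`, an idealized duplex generator
  with injectable perturbations for ground-truth testing.
- **Pipeline** — `run_pipeline()` chains all stages deterministically
  under one seed; `autoplot()`, `tidy()` and `glance()` methods cover
  every result type.

## Worked example

Simulate the heterogeneous three-state sample (lifetimes 0.40/1.7/5.2 ns,
populations 39/33/28%), invert it, and read off the landscape:

```r
library(fretscape)

comps <- lifetime_components(c(0.40, 1.7, 5.2), c(0.39, 0.33, 0.28))
trace <- simulate_decay(comps, acquisition(seed = 2))
fit   <- mem_fit(trace)

glance(fit)
#> # A tibble: 1 × 7
#>   reduced_chisq    lambda iterations converged background flux_ratio n_grid
#>           <dbl>     <dbl>      <int> <lgl>          <dbl>      <dbl>  <int>
#> 1          1.02 0.0000001        557 TRUE         0.00118      0.999    120

count_peaks(fit)
#> [1] 3

landscape <- conformational_landscape(fit_gaussians(fit), tau_D = 4.9)
landscape
#> <conformational_landscape> 3 peak(s), tau_D = 4.9 ns, <E> = 0.554
#> # A tibble: 3 × 7
#>   center_ns width_log10 height  area fractional_population   E_raw E_peak
#>       <dbl>       <dbl>  <dbl> <dbl>                 <dbl>   <dbl>  <dbl>
#> 1     0.400      0.0126  3078.  97.2                 0.375  0.918   0.918
#> 2     1.62       0.0126  2738.  86.5                 0.334  0.669   0.669
#> 3     5.13       0.0126  2388.  75.4                 0.291 -0.0469  0
```

The inversion converged at reduced χ² 1.02 with the model flux matching
the collected photons (flux ratio 0.999). Three lifetime peaks are
resolved at 0.40, 1.6 and 5.1 ns with populations 37.5/33.4/29.1% —
recovering the simulated 39/33/28% — and map to a high-FRET (E ≈ 0.92),
a mid-FRET (E ≈ 0.67) and a zero-FRET state (raw E slightly negative,
clamped to 0: the lifetime is indistinguishable from donor-only). The
amplitude-weighted average is ⟨E⟩ = 0.554. A donor-only sample analyzed
the same way yields a single peak at τ_D ≈ 4.9 ns, and
`fret_efficiency(0.32, 4.9)` gives 0.93 for a high-FRET B-DNA-like peak.

Geometry, from a generated fixture:

```r
dx <- build_duplex(duplex_spec(strrep("GC", 12),
  bend = data.frame(hinge = 12, degrees = 20, direction = 0)))
bend_angle(dx, hinge_pair = 12, arm_length = 5)        # 20
bend_direction_dihedral(dx, hinge_pair = 12, arm_length = 5)  # < 0: minor groove
```

See `vignette("lifetime-fret-landscapes")` for the model, the numerical
choices and their rationale, and known limitations.

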