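---
title: "Lifetime-FRET conformational landscapes and DNA geometry descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime-FRET conformational landscapes and DNA geometry descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscape)
```

# The problem

A FRET donor embedded in duplex DNA decays faster when an acceptor is
nearby: the efficiency of energy transfer is

$$E = 1 - \frac{\tau_{DA}}{\tau_D},$$

where $\tau_{DA}$ and $\tau_D$ are the donor excited-state lifetimes with
and without the acceptor. When the DNA exchanges between several
conformations that place the probes at different separations, the donor
decay is a *mixture* of exponentials: each conformation contributes one
lifetime $\tau_{DA,i}$ with a fractional amplitude $\alpha_i$ equal to the
population of that state. A time-correlated single-photon counting
(TCSPC) histogram therefore encodes the whole conformational landscape,
and the analysis problem is to invert

$$\mu_k = b + \sum_i \alpha_i\, e^{-t_k/\tau_i}$$

for a non-negative amplitude distribution $\alpha(\tau)$ without assuming
the number of states in advance. `fretscape` implements that inversion
(a maximum-entropy method, MEM), the downstream decomposition of the
lifetime distribution into Gaussian peaks whose areas are fractional
populations, the FRET arithmetic, and a set of DNA-geometry descriptors
(twist/untwist, bend angle and direction, base-extrusion pseudo-dihedral,
hydrogen bonds, block-averaged uncertainties) used to interpret such
landscapes structurally. A synthetic-data layer generates TCSPC decays
and idealized duplexes with known ground truth so that every stage is
testable end to end.

# The simulator and what it emulates

`simulate_decay()` forward-models the acquisition used in lifetime-FRET
work on labelled duplexes: a 100 ns window resolved into 4096 channels,
collected until the peak channel holds 10 000 counts (the
`acquisition()` defaults). Channel values are independent Poisson draws
of the multi-exponential expectation — TCSPC counts are Poisson by
physics, so noise amplitude is not a free parameter. Time zero sits at
the decay peak, channel times are bin centers, and an optional Gaussian
instrument response (IRF) of given FWHM can be convolved in; the default
is a delta-function IRF, with reconvolution retained for robustness
checks since real instruments blur the rising edge.

What the simulator does *not* emulate: acceptor photophysics, bleaching,
anisotropy decay, pile-up, after-pulsing, or a measured (non-Gaussian)
IRF. Passing tests on these synthetic decays therefore demonstrates the
correctness of the inversion and bookkeeping, not immunity to every
instrumental artifact of real data.

Two component sets recur throughout the package because they define the
regimes of interest: a mono-exponential donor-only sample
($\tau_D \approx 4.9$ ns) and a heterogeneous three-state
donor-acceptor sample with lifetimes 0.40/1.7/5.2 ns and amplitudes
0.39/0.33/0.28 — a high-FRET, a mid-FRET, and a low/zero-FRET
conformation.

# Maximum-entropy inversion

`mem_fit()` minimizes

$$C(\alpha) = \tfrac{1}{2}\chi^2(\alpha) - \lambda S(\alpha), \qquad
S(\alpha) = \sum_i \left[\alpha_i - m_i - \alpha_i
\ln\frac{\alpha_i}{m_i}\right],$$

over $\alpha \ge 0$ on a log-spaced lifetime grid (default 120 points,
0.02–20 ns, bracketing every lifetime of interest with margin), with
$\chi^2$ weighted by $\sigma_k = \sqrt{\max(y_k, 1)}$ and a constant
background $b$ profiled out analytically. $S$ is the Shannon–Jaynes
entropy against a flat prior $m$; the objective is convex, so the
solution is unique.

Numerical choices that matter:

* **Prior scale.** The kernel columns are unit height at the peak, so
  $\sum_i \alpha_i$ is on the order of the *peak-channel* counts, not the
  total counts. The flat prior is therefore
  $m_i = (\text{peak counts})/G$. A prior pinned to total counts (two
  orders of magnitude larger) drags the solution toward a flat elevated
  background and visibly destroys lifetime resolution.
* **Adaptive tail pooling.** Gaussian weights misrepresent Poisson zeros:
  thousands of nearly empty tail channels contribute almost nothing to
  $\chi^2$ whatever the model predicts, biasing the reduced chi-square
  downward (the Neyman $\chi^2$ problem). Trailing channels are pooled
  into bins holding at least 25 counts (`min_bin_counts`); sums of
  Poisson counts are Poisson and the model is linear in $\alpha$, so the
  pooling is lossless for the fit while restoring
  $E[\chi^2_\nu] \approx 1$. Channels near the peak exceed the threshold
  individually and stay unpooled.
* **Choice of $\lambda$.** The reduced chi-square attainable at vanishing
  regularization fluctuates by a few percent between noise realizations
  (the fit has $G$ adjustable amplitudes), so an absolute discrepancy
  level is itself noisy. `mem_fit()` relaxes $\lambda$ by warm-started
  decades to measure the attainable minimum, then keeps the largest
  $\lambda$ whose $\chi^2_\nu$ stays within 0.5% of that minimum and
  below $0.98\times$`chi2_target`. The fit is flagged converged when the
  final $\chi^2_\nu \le 1.10\times$`chi2_target`; a value slightly below
  the nominal band is a mild overfit accepted in exchange for lifetime
  resolution.
* **Inner solver.** Each $\lambda$-subproblem is solved by Newton
  iteration in $u = \log\alpha$ (positivity automatic, entropy keeps the
  Hessian well conditioned near zero amplitudes), with an
  infinity-norm step cap and backtracking. Because the weights are fixed
  by the data, $\chi^2$ reduces to precomputed quadratic forms and the
  per-iteration cost is independent of the channel count; a full
  4096-channel inversion takes a fraction of a second.
* **Degenerate inputs.** An all-zero trace raises an error; fewer than
  1000 total counts warns; failure to reach the chi-square band returns
  the best solution with `converged = FALSE` and a warning, never a
  silent success.

```{r mem-example}
comps <- lifetime_components(c(0.40, 1.7, 5.2), c(0.39, 0.33, 0.28))
trace <- simulate_decay(comps, acquisition(seed = 2))
fit <- mem_fit(trace)
glance(fit)
count_peaks(fit)
```

# From distribution to landscape

`fit_gaussians()` decomposes the distribution as a sum of Gaussians in
$\log_{10}\tau$ — the natural domain of a log-gridded MEM result — with
the component count chosen by BIC over 1..`max_components` (default 4),
keeping the smallest count within 10 BIC units of the minimum (smaller
differences are weak evidence for the larger model). Initial centers are
seeded at smoothed local maxima exceeding 2% of the total amplitude;
centers are box-constrained to the grid range and widths to
[half a grid step, the full span]. Peak areas are integrated over the
measured lifetime axis only, and components below the 2% threshold are
discarded as fit artifacts. The area fractions are the fractional
populations; `conformational_landscape()` attaches per-peak efficiencies
$E = 1 - \tau_{\text{peak}}/\tau_D$ (clamped at zero for reporting, raw
value kept, because a peak at $\tau_{DA} \gtrsim \tau_D$ means zero
transfer within precision) and the amplitude-weighted average

$$\langle E \rangle = 1 - \frac{\sum_i A_i \tau_{DA,i}}{\tau_D},
\qquad A_i = \frac{\alpha_i}{\sum_i \alpha_i}.$$

$\tau_D$ is supplied per sample, normally the peak center of a
donor-only landscape.

```{r landscape-example}
peaks <- fit_gaussians(fit)
landscape <- conformational_landscape(peaks, tau_D = 4.9)
landscape
glance(landscape)
```

# DNA geometry descriptors

The descriptor layer answers the structural question behind the
landscape: how twisted, bent, and base-flipped is the duplex in each
model of an ensemble?

* **Frames.** Each base pair gets a frame from its two C1′ atoms: origin
  at their midpoint, y along the C1′→C1′ vector, z the consecutive-origin
  direction orthogonalized against y, x = y × z. This deliberately
  simplified convention (full standard-reference-frame fitting is not
  attempted) is shared exactly with the duplex builder, so round-trip
  tests recover builder parameters to numerical precision; for
  *differences* such as the untwist angle the simplification cancels.
* **Twist.** `step_twist()` is the signed angle between successive y axes
  about the mean z; `cumulative_twist()` sums steps over a span (a
  six-base-pair span covers five steps). `untwist_angle()` subtracts a
  caller-supplied reference — a number or a reference sub-ensemble to
  average, e.g. the early segment of a trajectory — with positive values
  meaning further unwinding.
* **Bend.** `bend_angle()` is the angle between principal axes of the
  base-pair origins of the 5′ and 3′ arms flanking a hinge. The bend
  *direction* is a pseudo-dihedral whose central bond runs along the 5′
  arm: it measures the azimuth of the bend displacement about the helix
  axis from a reference at the hinge's top-strand C1′ (the backbone
  flank). A reference placed symmetrically between the grooves cannot
  separate minor from major bending by sign — both lie in the same mirror
  plane — which is why the off-plane backbone reference is used. The sign
  is calibrated on builder fixtures: bending toward the minor groove is
  negative, matching the field's reporting convention. Below 2° of bend
  the direction is undefined and `NA` is returned rather than noise.
* **Base extrusion.** A dihedral over four centroids (the base pair 3′ of
  the flip site, the 3′-neighbor sugar, the flipping nucleotide's sugar,
  the flipping base's ring), reported against the stacked-duplex
  baseline. The builder's extrusion perturbation rotates the base about
  the axis through the two sugar centroids, so the dihedral shifts by
  exactly the injected angle.
* **Hydrogen bonds.** Heavy-atom donor–acceptor pairs from a
  Watson–Crick table (extensible by the caller) within 3.5 Å, with a
  D–H…A angle test when explicit hydrogens exist. An ideal G:C pair
  yields exactly its three bonds, A:T two.
* **Uncertainties.** `block_average()` splits a per-model series into
  contiguous blocks and reports the standard deviation of block means —
  for correlated trajectories a more honest error bar than the naive
  standard error; for iid data it approaches $\sigma/\sqrt{L}$.

The builder (`build_duplex()`) is a cylindrical fiber model: planar
idealized base-pair templates stacked with uniform rise and twist, with
perturbations (extra untwist at a step, a hinge bend with direction,
base rotation about the backbone pivot) applied as rigid rotations. Its
geometry is synthetic — base atom positions are plausible but not
crystallographic — which is exactly what makes generator/analyzer round
trips sharp tests.

```{r geometry-example}
dx <- build_duplex(duplex_spec(
  strrep("GC", 12),
  bend = data.frame(hinge = 12, degrees = 20, direction = 0)
))
bend_angle(dx, hinge_pair = 12, arm_length = 5)
bend_direction_dihedral(dx, hinge_pair = 12, arm_length = 5)
```

# Pipeline, reproducibility, problem sizes

`run_pipeline()` chains simulate → invert → decompose → FRET (plus the
geometry stage when a structure is configured) under a single seed; all
randomness flows from it, outputs are byte-identical across runs, and
every written file embeds the configuration hash and package version.

The test suite runs the full-scale acquisition (4096 channels, 10 000
peak counts, 120-point grid) for the peak-recovery checks — ten seeds per
sample, a few minutes in total — and reduced sizes (512–1024 channels,
32–80 grid points) for oracle comparisons and unit checks, where the
properties under test are size-independent. Descriptor ensembles use
10–40 models of 12–24 bp, and the block-averaging closed-form check uses
$10^4$ iid points.

# Known limitations

* The inversion assumes a delta or Gaussian IRF; measured IRFs and
  reconvolution with color shift are out of scope.
* Lifetimes closer than roughly a factor of two at these counts merge
  into one mode — an information-theoretic limit of multi-exponential
  inversion, not a solver artifact; the Gaussian decomposition reports
  the merged state.
* Fractional populations are *amplitude* fractions; converting to molar
  fractions would require equal radiative rates across states.
* The duplex builder is not a substitute for crystallographic or MD
  coordinates; it exists to provide ground truth for the descriptors,
  which also read standard (multi-MODEL) PDB ensembles.
* Base-pair inference in `read_structure()` is a contact heuristic plus
  caller override; non-canonical pairs should be supplied explicitly.
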