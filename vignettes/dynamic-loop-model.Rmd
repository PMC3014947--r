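---
title: "Entropic interactions between looping chromosomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic interactions between looping chromosomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Interphase chromosomes occupy distinct territories and intermingle far less
than generic linear polymers would.  `dlchrom` implements a coarse-grained
model in which this segregation emerges purely entropically from transient
chromatin loops: the Dynamic Loop model on the bond-fluctuation lattice.

A chromosome is a chain of `N` beads, each bead representing a fixed stretch
of chromatin (400 kb per bead in the physical mapping used throughout).
Beads occupy 2x2x2 cubes of simple-cubic lattice sites; successive beads are
connected by one of 108 allowed bond vectors (the classes (2,0,0), (2,1,0),
(2,1,1), (2,2,1), (3,0,0), (3,1,0) closed under lattice symmetry, bond
lengths 2, sqrt 5, sqrt 6, 3, sqrt 10).  Together with hard excluded volume
this bond set makes chain crossing impossible, so the dynamics preserves
topology.  Monte Carlo moves displace one bead by one lattice unit; a sweep
is `N` attempted moves.

Loops form by diffusion alone.  After every trial move one bead is picked at
random; if another bead of the same chain (excluding bonded neighbours) lies
within the co-localization distance (3 lattice units, strict), a loop forms
there with probability `p`.  A loop is a constraint holding its two beads
co-localized; it carries a lifetime drawn from a Poisson distribution with
mean `lambda` sweeps and dissolves when the lifetime expires.  `p` and
`lambda` are the only loop parameters: `p` controls how many loops coexist
(reported as mean simultaneous loops per monomer), `lambda` how long each
lasts.

## Estimating the effective potential

The entropic interaction between two chromosomes is the potential of mean
force between their centers of mass, estimated by superposition rejection
sampling: draw two conformations from independently equilibrated
single-chain ensembles, rotate each by a random element of the 48-element
cubic symmetry group (lattice-exact, so all invariants are preserved),
translate the second so the center-of-mass distance is as close as possible
to the target `r` along the x axis (integer shifts; the realized `r` is
recorded and reported per bin), and accept the pair iff no lattice site is
shared.  Then

    U_eff(r) = -ln( N_accepted / N_total )   [units of kT]

with binomial standard error `sqrt((1 - f) / (f N_total))`.  Bins with zero
acceptances are censored and reported as the lower bound
`U_eff >= ln(N_total)`, never as infinities.

All structural statistics of a pair at distance `r` — the swelling factor
`alpha(r) = R_g(r) / R_g(iso)`, the asphericity ratio `A(r) / A_iso`, the
mutual alignment angle `beta` between largest gyration-tensor axes, the
projected monomer densities along the center-of-mass axis (1-lattice-unit
bins) and their overlap fraction `sum_k min(a_k, b_k)` — are computed over
*accepted* pairs only: the conditional ensemble of the potential-of-mean-force
framework.  The asphericity is the normalized gyration-tensor invariant
`A = [(l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2] / (2 (l1+l2+l3)^2)`, 0 for a sphere
and 1 for a rod; for two independently oriented chains the mean alignment
angle is 1 radian (57.296 degrees), the natural "no alignment" baseline.

## Decorrelation, equilibration, and the loop lifetime

The pipeline in `dl_simulate()` measures the integrated autocorrelation time
of the squared radius of gyration with the self-consistent windowing
estimator (`tau_int = 1/2 + sum rho(t)` up to the smallest window `W >= 6
tau_int(W)`), measured away from the initial transient; it discards a
burn-in of `10 tau_int` (capped at half the run) and thins snapshots to a
chosen spacing, reporting `n_independent = T / (2 tau_int)`.

Three empirical facts shape the defaults:

* In the looping phase, conformational relaxation is slow — `tau_int` of
  R_g^2 is about 1e5 sweeps at N = 128 — and is *not* set by the loop
  lifetime: it is essentially unchanged between `lambda` = 1e3 and 1e5
  sweeps.
* Bulk equilibrium observables at matched mean loop count are insensitive
  to the lifetime over `lambda = tau_int x {0.01, 1, 100}`: R_g^2 and the
  internal-distance curve agree within error, and the test suite checks the
  potential itself at N = 32.
* The *conditional* accepted-pair statistics deep in the repulsive core are
  a different story.  They are dominated by rare open, elongated
  conformations, and with the lifetime tied to `tau_int` the looping phase
  is still slowly collapsing on any feasible run length: how much of that
  transient, partially-quenched shape diversity an ensemble retains then
  depends on run length, burn-in and lifetime, and the accepted-pair
  swelling and asphericity ratios vary severalfold between
  equal-parameter builds.  The model on this timescale is effectively
  non-ergodic.  A short lifetime combined with a looping-phase pre-burn
  (`loop_burn_sweeps`) drives the system to a *stationary* state whose
  conditional statistics are reproducible — and noticeably weaker than the
  transient ones, because the stationary looped chain is more compact and
  more homogeneous.

The package default ties `lambda` to the SAW-calibrated `tau_int`
(`lifetime_multiplier = 1`), the model's stated choice.  The reproduction
runs instead sample the stationary state (`lifetime_multiplier = 0.01`
plus a pre-burn of several conformational decorrelation times), preferring
reproducibility: the bulk targets are unaffected, while the conditional
deformation measures come out below the strongest transient values and are
reported as such.  Ensembles store snapshots densely (spacing a few
lifetimes, well below `2 tau_int`) to cover loop-set diversity, and quote
`n_independent` separately.  Near-saturation loop densities (above ~1.45
per monomer at N = 128) are avoided — there the constraint network
percolates, moves are almost all vetoed, and the dynamics arrest in a
swollen, aspherical glass; ensemble builders detect that state (by its
inverted size and shape trend) and back off `p`.

## Looping regimes and the physical mapping

Calibration of `p` to a target loop density uses bisection on `log p` with
short probe runs started from an equilibrated SAW conformation
(`dl_calibrate_p()`); the count is monotone in `p`, but steeply so in the
interesting range, and it equilibrates on the conformational (not the loop)
timescale, so probes span several hundred thousand sweeps.

Physical units come from matching the plateau of the model's mean-square
internal distance curve MSD(s) to FISH-style measurements
(`dl_fit_spatial_scale()`): with 400 kb per bead the published calibration
is 177 nm per lattice unit at N = 256 (equivalently ~480 nm per 2.7-lattice-
unit bond).  Separations given in micrometers are converted with that
constant.  The reproduction runs use N = 128 (the study's own result that
the scaled potential is independent of coarse-graining licenses this), and a
physical separation is transferred between chain lengths at matched
`r / R_g`: the N = 256 coil size is reconstructed from the *measured* MSD
curve through the identity `R_g^2 = (1/2N^2) sum_{i,j} MSD(|i-j|)`
(`dl_rg2_from_msd()`), extending the curve beyond the measured lags by its
plateau when it has leveled off and by a power law otherwise.  For
self-avoiding walks the transfer uses the measured Flory exponent
(`R_g ~ N^nu`, `nu` fitted over N = 16..128).

Loop-density regimes also need translating between chain lengths: the mean
*genomic span* of diffusion-formed loops grows with `N`, so matched loops
per monomer compacts a longer chain more strongly.  The study anchors its
headline looping regime to the leveling-off of MSD(s) against the FISH data,
and we adopt that anchor: at N = 128 the end-trimmed MSD curve (ends are
floppier, so the top lags of an untrimmed curve bend upward; we trim N/4 at
each end) plateaus at about 1.0 loops per monomer.  The reproduction ladder
is therefore 0.7 (partially leveling), 1.0 (leveling — the regime matched to
chromosome-11 FISH data), and 1.3 loops per monomer (above the highest
reported regime, still below kinetic saturation).

## What the reproduction runs compute

`scripts/acceptance.R` regenerates everything from a single seed at N = 128:
SAW ensembles at N = 16..128 (~100-150 independent conformations each), the
three-regime ladder (1.2e7-sweep productions, several hundred stored
snapshots, ~30-60 independent by the `2 tau_int` criterion), and the
superposition measurements (1e4 to 2e7 trials per bin, adaptively extended
until enough accepted pairs exist).  The quantities written out are the
overlap fraction at the 2-micrometer separation for linear and high-loop
chains, the asphericity increase of linear chains at full overlap, and the
asphericity increase and swelling factor of leveling-regime chains near
`r ~ R_g`.

## Numerical choices and degenerate cases

* Bond membership is a 7x7x7 lookup table; excluded volume is an occupancy
  lattice addressed modulo 256 (chains are free in space; the kernel tracks
  the largest span seen and warns long before wrap-around could matter).
* Loop partner searches use a cell list (cells of 4 lattice units); the
  formation coin is flipped before the candidate search (independent draws,
  identical distribution, large constant-factor saving at small `p`).
* The superposition sampler pre-screens pairs with a bounding-box test and
  uses a stamped occupancy array, so rejected trials cost microseconds.
* Gyration tensors with degenerate leading eigenvalues (relative gap below
  1e-9) are excluded from alignment-angle averages and counted per bin;
  the principal axis of a near-degenerate tensor is chosen deterministically
  (largest-magnitude component made positive).
* A lifetime drawn as 0 dissolves at the end of its creation sweep; at most
  one loop per unordered pair; bonded neighbours never loop.
* Zero-variance series and too-short series are errors in the
  autocorrelation estimator, not silent answers.

## Limitations

* The superposition estimator tests excluded volume only; catenation and
  other topological constraints between the two chains are not imposed.
* Accepted-pair statistics deep in the repulsive core condition on rare
  conformations; below the accessible acceptance frontier (acceptance
  below ~1e-7) the conditional ensemble is empty and bins are censored
  rather than extrapolated.  The swelling factor in particular saturates at
  the frontier: its divergence as two looped chains are forced ever closer
  is expressed here as vanishing acceptance, not as a measured large alpha.
* The synthetic FISH generator produces a clean saturating curve with
  lognormal noise; real FISH distance tables carry structure (arm-level
  heterogeneity, measurement floors) that it does not emulate, so passing
  the round-trip calibration test shows the fitting machinery is correct,
  not that real-data calibration is this clean.
* Isolated two-chain superposition ignores the dense nuclear environment;
  crowding by other chromosomes is outside the model's scope here.
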