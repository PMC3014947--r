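# dlchrom — entropic repulsion between looping chromosomes

Interphase chromosomes keep to distinct territories and intermingle far
less than ordinary linear polymers would. `dlchrom` quantifies how much of
that segregation follows from chromatin loops alone. It implements the
Dynamic Loop model — a coarse-grained chromosome as a lattice polymer whose
loops form purely by diffusional encounters and dissolve after a random
lifetime — and measures the entropic interaction between two such model
chromosomes.

The package is aimed at polymer-physics and chromatin-organization
researchers who want a self-contained, reproducible lattice Monte Carlo
pipeline: simulate, diagnose decorrelation, and measure pair interactions,
all from R (or from a thin command-line driver).

## Model and estimator

* **Chain**: bond-fluctuation model on the cubic lattice. Each of `N` beads
  (400 kb of chromatin per bead under the physical mapping) occupies a
  2×2×2 cube of sites; bonds come from the 108-vector set with lengths
  {2, √5, √6, 3, √10}, which together with excluded volume forbids chain
  crossing. Local single-site moves; one sweep = `N` trial moves.
* **Loops**: after each trial move a random bead is checked for chain
  partners within 3 lattice units; a loop forms there with probability `p`
  and holds the pair co-localized for a Poisson(λ)-distributed number of
  sweeps.
* **Effective potential**: for two independently equilibrated chains,
  superposition rejection sampling gives the potential of mean force
  between centers of mass,

      U_eff(r) = −ln(N_acc / N_tot)   (units of k_BT),

  from random cubic-group rotations plus an integer shift targeting
  center-of-mass distance `r`; a pair is accepted iff the chains share no
  lattice site. Structural statistics over accepted pairs — swelling factor
  α(r) = R_g(r)/R_g(∞), asphericity ratio A(r)/A_iso, alignment angle β,
  projected densities and their overlap fraction — characterize how the
  chains deform and segregate.
* **Diagnostics**: integrated autocorrelation times by Sokal's
  self-consistent window; ensembles carry burn-in, thinning and
  independence metadata. FISH-style mean-square-distance tables calibrate
  lattice units to nanometers (177 nm per lattice unit at the published
  N = 256 calibration).

## Worked example

```r
library(dlchrom)

# an equilibrated self-avoiding-walk ensemble (no loops) of 24-bead chains
ens <- dl_simulate(24, p = 0, n_conformations = 120, seed = 1)
ens
#> Dynamic Loop ensemble: N = 24  p = 0
#>   120 decorrelated conformations (spacing 2459 sweeps)
#>   tau_int = 1230 sweeps; 316019 production sweeps
#>   <R_g> = 7.381 lattice units; <A> = 0.483

# entropic repulsion between two such chains
set.seed(42)
u <- dl_estimate_potential(ens, ens, r_grid = c(0, 5, 10, 20),
                           trials_per_bin = 2000)
u
#> Effective potential curve (4 bins, rg_iso = 7.381)
#>       r r_over_rg n_total n_accepted   u_eff   stderr censored
#>  0.4804   0.06508    2000        118 2.83022 0.089300    FALSE
#>  5.0453   0.68351    2000        274 1.98777 0.056122    FALSE
#> 10.0386   1.35999    2000       1108 0.59059 0.020063    FALSE
#> 20.0225   2.71258    2000       1975 0.01258 0.002516    FALSE
```

Two 24-bead self-avoiding walks pay about 2.8 k_BT of free energy to share
a center of mass, and the repulsion is essentially gone beyond ~2.7 R_g —
the classic soft-colloid picture of polymer coils. Switching loops on
(`p > 0`) compacts the chains and raises this barrier several-fold; the
accepted-pair profile (`dl_pair_shape_profile()`) then shows the chains
swelling, elongating and aligning perpendicular to the center-of-mass axis
instead of intermingling.

A file-based workflow (config in YAML, ensembles and tables on disk) is
available through the driver script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dlchrom.R", package = "dlchrom"))')" \
    simulate config.yaml out/
```

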