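# rpmmc

Canonical Metropolis Monte Carlo for **restricted primitive model (RPM)
electrolytes with local dielectric saturation**: charged hard spheres whose
Coulomb interaction uses a distance-dependent relative permittivity

    beta u_ij(r) = Inf                              for r < d
    beta u_ij(r) = z_i z_j l_B(eps_r(r)) / r        for r >= d

where `l_B(eps) = e0^2 / (4 pi eps0 eps kB T)` is the Bjerrum length and
`eps_r(r)` ramps linearly from a saturated contact value to the bulk solvent
value across one hydration-layer thickness:

    eps_r(r) = eps_c                                   r <= d
             = eps_c + (eps_b - eps_c) (r - d)/Delta   d < r < d + Delta
             = eps_b                                   r >= d + Delta

with defaults `d = 3 A`, `Delta = 3 A`, `eps_c = 23`, `eps_b = 78.3`,
`T = 298 K`, roughly mimicking aqueous NaCl. The reduced permittivity inside
the hydration shell deepens unlike-ion contact attraction (~ -8.1 kT instead
of ~ -2.4 kT) without the long-ranged like-ion repulsions a uniformly low
permittivity would create, so the model forms large ion clusters at molar
concentrations. Setting `eps_c = eps_b` recovers the classic uniform-eps RPM
comparison modes.

The package is aimed at people studying screening in concentrated
electrolytes — underscreening, ion clustering, electric double layers — who
want a small, fully scriptable simulator with the matching observable stack:

* **Geometries**: periodic cubic bulk with full minimum-image Coulomb
  truncation, and a slit of width `H` between impenetrable charged hard
  walls (lateral long range handled by the charged-sheet construction,
  completed by the discrete-image Fourier terms so slit energies track
  explicit lateral image summation well inside 0.1%).
* **Sampling**: single-particle displacements plus rigid cluster
  translations with a merge-rejection guard (detailed balance); seeded,
  checkpointable, bitwise-reproducible runs with continuous energy
  bookkeeping against full recomputation.
* **Observables**: species-resolved radial distribution functions pooled as
  (g++ + g--)/2 and (g+- + g-+)/2, the density-density `g_nn` and
  charge-charge `g_cc` combinations, connected-cluster decomposition under
  the distance criterion `delta = d + 0.5 A` with the ion-resolved size
  distribution `P_ion(N_c)`, Yukawa tail fits `h ~ A exp(-r/lambda)/r`, a
  ghost-pair (Widom-type) screening-length estimator, a tail-slope
  phase-separation diagnostic, and slit density profiles `n+(z)`, `n-(z)`,
  `dn(z)`.

## Worked example

A small bulk run of the saturation model at 0.25 M (200 ion pairs), with the
screening length estimated two ways:

```r
library(rpmmc)

cfg <- default_config()
cfg$thermo$molarity   <- 0.25
cfg$geometry$L        <- (400 / molar_to_density(0.5))^(1/3)  # 400 ions
cfg$schedule$equil_sweeps <- 4000
cfg$schedule$prod_sweeps  <- 15000
cfg$schedule$cluster_frac <- 0.15
cfg$schedule$cluster_step <- 3
cfg$observables$rdf_bin   <- 0.25
cfg$seed <- 125

sim <- simulate_bulk(cfg)
print(sim$run)
#> MC run: 1500 samples, final beta*U = -1228.277
#>   displacement acceptance 34.2%, cluster acceptance 73.9%
#>   max energy-bookkeeping drift 1.09e-10 kT

mean_cluster_size(sim$clusters)
#> [1] 2.433577
debye_length(0.25)
#> [1] 6.074831
```

At 0.25 M the saturation model already keeps each ion, on average, in a
~2.4-ion cluster (the uniform-eps RPM at this state point stays near 1), and
the fitted decay length of the charge-charge correlation sits at or above
the Debye length — the onset of underscreening. The same run can be written
to disk (`rdf.tsv`, `clusters.tsv`, manifest) through the command-line
driver:

```sh
./exec/rpmmc simulate-bulk --config cfg.yaml --out out/
./exec/rpmmc debye --c 2.6
# lambda_D = 1.88372 A
```

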