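---
title: "Monte Carlo simulation of primitive-model electrolytes with local dielectric saturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo simulation of primitive-model electrolytes with local dielectric saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The restricted primitive model (RPM) describes an electrolyte as equal-diameter
charged hard spheres in a structureless dielectric continuum. `rpmmc`
implements a modified RPM in which the relative permittivity entering the
Coulomb term depends on the ion-ion separation:

$$\beta u_{ij}(r) = \begin{cases}\infty & r < d\\
z_i z_j\, l_B(\varepsilon_r(r))/r & r \ge d,\end{cases}
\qquad
\varepsilon_r(r) = \begin{cases}\varepsilon_c & r \le d\\
\varepsilon_c + (\varepsilon_b-\varepsilon_c)\frac{r-d}{\Delta} & d < r < d+\Delta\\
\varepsilon_b & r \ge d+\Delta.\end{cases}$$

Physically, water inside an ion's hydration shell is rotationally constrained
by the large local field, so its dielectric response is *saturated* — much
smaller than the bulk value. The linear ramp is the simplest pairwise
caricature of that local saturation: at contact two ions interact through
solvent with $\varepsilon_c \approx 23$, while beyond one solvent layer
($\Delta \approx 3$ Å) the ordinary bulk $\varepsilon_b = 78.3$ applies. The
modification is therefore a *short-ranged* extra attraction between unlike
ions (and repulsion between like ions) on top of a standard
$\varepsilon_b$-RPM. Two properties matter for the physics the package is
built to explore:

* contact ion pairs are strongly bound ($\beta u \approx -8.1$ instead of
  $-2.4$ at $d = 3$ Å, 298 K), so large clusters form at molar
  concentrations;
* unlike a *uniformly* reduced permittivity, the long-range interaction
  between like-charged ions within a cluster stays weak (it is still
  screened by $\varepsilon_b$), so cluster growth is not opposed by
  accumulated like-charge repulsion. The uniform
  $\varepsilon_r=\varepsilon_c$ model is retained as a comparison mode
  (`eps_c == eps_b`), and with `eps_c = eps_b` the pair energy reduces
  *exactly* to the standard RPM.

### Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `d` | hard-sphere contact distance | 3 | Å |
| `delta` | ramp (hydration-layer) thickness | 3 | Å |
| `eps_c` | contact (saturated) permittivity | 23 | — |
| `eps_b` | bulk solvent permittivity | 78.3 | — |
| `temperature` | temperature | 298 | K |
| `delta` (cluster) | cluster membership distance | `d + 0.5` | Å |
| `sigma_inverse` | inverse wall-charge area (slit) | 70 | Å²/e₀ |

`eps_c = 23` is the value at which, for `d = 3` Å, the bulk solution at
3.45 M is clustered but no longer phase-separates (the scan is part of the
acceptance suite); it also roughly reproduces NaCl-like solubility limits.
All internal units are Å, $k_BT$, and $e_0$; CODATA 2018 constants are
centralized in one internal table, and molarity conversion uses
1 M = 6.02214×10⁻⁴ ions/Å³.

## Geometries and electrostatics

**Bulk.** A periodic cube of side $L$ with *full cubic minimum-image (MI)
truncation* of the Coulomb term — each pair interacts once, with its nearest
image, with no spherical cutoff. This follows the validated practice for
structural properties of concentrated primitive-model electrolytes. The
constructor enforces $L > 2(d+\Delta)$ so the saturation ramp can never wrap.
A displacement of exactly $L/2$ is mapped to $+L/2$; a probability-zero
tie-break fixed for determinism.

**Slit.** A laterally periodic $L\times L$ box bounded by impenetrable
charged hard walls at $z=\pm H/2$; ion *centers* are confined to
$|z|\le (H-d)/2$ (spheres touch the wall at half a diameter — $H$ is the
wall-to-wall distance; the accessible width convention is recorded here
because either choice could be read from the problem statement). Wall charge
is entered the way it is usually quoted, as inverse area per elementary
charge; counterions required by electroneutrality are added explicitly and
the wall charge density is then set to exactly the value those counterions
neutralize (the constructor enforces $\sum_i z_i + 2\sigma L^2 = 0$).
Because the two walls carry equal charge, their fields cancel between them:
the position-dependent wall term is a constant, taken as zero, and the
double-layer physics enters through the counterion content.

Long-ranged lateral interactions use the charged-sheet construction: the
periodic images of each ion beyond the minimum image are replaced by an
infinite uniform sheet at the ion's height minus the centrally represented
patch, evaluated with $\varepsilon_b$ (the ramp is strictly a contact-shell
property and applies only to the explicit minimum-image term). The plain
sheet (the $G=0$, laterally smeared term) carries a discreteness error of a
few times $10^{-3}$ kT per pair at desk-scale $L$, which is visible against
a brute-force image sum; `rpmmc` therefore *completes* the sheet with the
rapidly converging Fourier modes of the image lattice (an erfc-split
summation in the two periodic directions); the geometry tests verify total
slit energies against a Richardson-extrapolated brute-force image sum at the
0.1% level, which the completed correction passes with two orders of margin.
For the sweep kernels the correction factor — a smooth, even function of
$(|dx|,|dy|,|dz|)$ — is tabulated once per geometry on a 0.2 Å grid and
trilinearly interpolated; the running-energy bookkeeping and the full
recomputation use the same table, so reconciliation is exact.

## Sampling

Canonical Metropolis Monte Carlo. A sweep is $N$ attempted moves; each
attempt is a single-particle displacement (uniform in a cube of side
$2\times$`step`) or, with probability `cluster_frac`, a rigid translation of
the connected cluster grown from a uniformly chosen seed ion under the
connectivity distance `delta_mv` (default the analysis criterion
$d + 0.5$ Å; the cluster-move radius is configurable independently of the
analysis δ). A cluster translation is rejected outright if the translated
cluster would *gain* any member — the standard merge-rejection guard that
preserves detailed balance, since rigid translations cannot split a cluster
and the guard removes the asymmetric merge pathway. Clusters larger than
`cluster_max` are likewise rejected outright; the rejection is symmetric in
the proposal, so detailed balance is untouched, and it prevents wasted
$O(N^2)$ work at state points where the connectivity cluster percolates
(near phase separation the percolating component would be merge-rejected
anyway). Rotations are not
implemented; translations alone satisfy detailed balance and are what the
acceptance checks exercise. Cluster moves matter enormously at molar
concentrations: bound pairs and larger aggregates diffuse as units, and
without them the charge structure decorrelates extremely slowly.

`step` is tuned toward 30–50% acceptance *during equilibration only* and
frozen for production (adapting during production would violate detailed
balance). All randomness flows through R's global RNG, so `set.seed()` makes
entire runs — including compiled sweeps — bitwise reproducible; checkpoints
store positions, counters, the frozen schedule and the RNG state, and a
resumed run reproduces the uninterrupted observable stream exactly.

The running energy is updated with every accepted move's $\Delta U$ and
periodically reconciled against a full $O(N^2)$ recomputation; the run
aborts if the discrepancy exceeds `energy_tol` (default $10^{-6} k_BT$ per
ion), and the test suite bounds the drift over $10^4$ sweeps at that level.

## Observables

* **RDFs** are species-pooled — $(g_{++}+g_{--})/2$ and $(g_{+-}+g_{-+})/2$ —
  because the two members of each pair are identical on average in a 1:1
  system and pooling halves the noise. The derived combinations are
  $g_{nn} = (g_{pp}+g_{pm})/2$ and $g_{cc} = (g_{pm}-g_{pp})/2$, identical
  to the four-term species sums. Default bin width 0.1 Å (0.25 Å in the
  bundled study runs), range $L/2$.
* **Clusters**: connected components under MI distance $\le \delta$
  (inclusive, "within a distance δ or less"), $\delta = d + 0.5$ Å by
  default; clusters may wrap the box and are counted by total membership.
  $P_\mathrm{ion}(N_c)$ is the probability that an ion lives in a cluster of
  size $N_c$, normalized per frame and averaged.
* **Yukawa fits**: weighted least squares of $\ln(r|h|)$ against $r$; sign
  changes inside the window make the fit *not applicable* (oscillatory
  regime) rather than silently wrong. An optional variant refits with a free
  additive constant, $h = A e^{-r/\lambda}/r + B$: canonical-ensemble RDFs
  carry a small $O(1/N)$ constant bias in the tail which otherwise shortens
  the apparent decay length materially at desk scale; the consistency checks
  in the test suite use the offset-aware variant for this reason, and the
  electroneutrality check likewise anchors the $g_{cc}$ baseline on its far
  tail before integrating.
* **Phase-separation diagnostic**: linear regression of $g_{++}$ over a tail
  window (default $[L/4, L/2]$); "separated" when $|$slope$|\times$window
  length exceeds 0.05 *and* the maximum deviation of the tail from 1 exceeds
  0.1 (the maximum rather than the mean: a steep separated tail can cross
  unity and leave its mean near 1, while a homogeneous tail hugs 1
  everywhere). The thresholds are package conventions — the underlying
  signature is the pronounced long-ranged tail slope; the reference
  classification is by eye.
* **Slit profiles**: z-histograms over the accessible range normalized by
  $L^2\Delta z$, reported in mol/L; the "bulk" concentration of a slit run
  is the midplane mean of $(n_++n_-)/2$. Reported slit molarities use the
  accessible volume $L^2(H-d)$, stated in the output metadata.

## The ghost-pair (Widom-type) screening estimator

The effective charge-screening length is also estimated without fitting
RDF tails: a $+q/-q$ *ghost* pair is inserted at random positions and
orientations into stored equilibrium frames at a set of separations $r_k$
(never perturbing the configurations), and

$$w(r_k) = -\ln\left\langle e^{-\beta\Delta U}\right\rangle$$

is accumulated, where $\Delta U$ includes both ghost-medium interactions
(same ramp potential and hard core as real ions) and the direct ghost-ghost
term. In an empty box $w$ is the bare pair interaction; in the
Debye–Hückel regime it is the screened Coulomb interaction, so its decay
length estimates the screening length of the medium. The fitted form is
$w(r) = -A e^{-r/\lambda}/r + C$ with a free offset that absorbs the
reference subtraction and its noise; bootstrap over frames gives the
uncertainty. This ghost-pair route is adopted as the operational definition
of the "modified Widom" estimate: it is fully specified, testable against
the Debye–Hückel limit, and rests on the same Yukawa-form assumption as the
free-energy-functional derivation it stands in for (outputs are tagged
`widom-pair`). Two practical notes, both visible in the test suite:

* the estimator is exact in the $q\to 0$ linear-response limit, and at
  strongly coupled state points a *reduced* test charge (q = 0.3–0.5) tames
  the otherwise heavy-tailed Boltzmann average (rare deep-contact insertions
  weight $e^{+8}$ at $q=1$); the default remains $q=1$;
* at molar concentrations $g_{cc}$ becomes oscillatory and the Yukawa
  assumption degrades — the fit then still returns an *effective* length
  but carries a quality flag.

## Study conditions and problem sizes

The bundled tests and the acceptance script run the model at the reference-study
state points — $d=3$ Å, $\Delta=3$ Å, $\varepsilon_c=23$,
$\varepsilon_b=78.3$, 298 K; bulk concentrations 0.05–3.45 M; slit
$H = 50$ Å at $\sigma = -1/70\,e_0$/Å² — but at desk scale: **200 ion pairs**
(400 ions) in the bulk, ~10⁴ production sweeps (1.6×10⁴ for the dilute
reference run) after 2–3×10³ equilibration sweeps, sampled every 10 sweeps;
the 3.45 M phase scan uses 10⁴ equilibration + 8×10³ production sweeps (the
homogeneous point needs the long equilibration to shed transient aggregates
from the random start); slit systems of ~130 ions run 7×10³ production
sweeps. The reference study uses 5000 pairs and
correspondingly long runs; at 1/25 of that size the qualitative structure
(cluster growth, loss of co-ion exclusion, slow slit $\Delta n$ decay,
phase-boundary location in $\varepsilon_c$) is reproducible, while absolute
tail amplitudes carry visible finite-size effects — most prominently the
canonical $O(1/N)$ tail bias discussed above, which is why the
screening-length fits used in the checks are the offset-aware variants.
Statistical margins quoted by the acceptance checks (15% on the
Debye-consistency ratio, strict inequalities on trend contrasts) were chosen
for that size, not tightened afterwards.

What passing these checks shows — and what it does not: the synthetic-data
runs demonstrate internal correctness (oracle equivalence, detailed balance,
closed-form limits) and the *direction and rough magnitude* of the model's
headline effects at reduced size. They do not certify production-scale tail
asymptotics beyond ~$L/2 \approx 35$ Å, crystalline-phase thermodynamics, or
surface forces (out of scope).

## Numerical choices and degenerate inputs

* Hard-core overlap is an infinite-energy *sentinel*, never an error, so
  Metropolis rejection handles it uniformly; trial moves that would overlap
  are rejected before any exponential is evaluated.
* The slit correction table spacing (0.2 Å) keeps interpolation error two
  orders below the 0.1% slit-energy validation tolerance; the brute-force
  validation oracle itself is Richardson-extrapolated in the image cutoff
  because the raw lateral lattice sum converges only like $1/M$.
* Empty systems (0 ions), single ions, and zero production sweeps are legal
  and return zero energies / empty accumulators.
* `initialize_configuration` uses seeded random insertion with a per-ion
  attempt budget; exceeding it reports overpacking rather than looping.
* Cluster-move connectivity at exactly $\delta$ is inclusive, matching the
  analysis criterion.
* Fits guard their preconditions: fewer than 4 usable points, sign changes,
  or non-decaying profiles return flagged, non-applicable estimates instead
  of numbers.

## Known limitations

* The dielectric ramp is pairwise; the many-body character of real
  dielectric saturation (labile cluster peripheries, reduced solvation
  inside clusters) is deliberately not modeled.
* MI truncation is validated for *structure*; energies/pressures would need
  proper lattice summation in the bulk as well.
* The slit does not include dielectric-discontinuity image charges at the
  walls, and surface forces are not computed.
* Grand-canonical sampling, cluster rotations, and parallel tempering are
  not implemented; at ≳3 M with deep saturation, equilibration from random
  starts relies on cluster translations and is the slowest part of the
  suite.
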