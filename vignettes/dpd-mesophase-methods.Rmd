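---
title: "Coarse-grained simulation and mesophase analysis of ethoxylated sulfate surfactants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained simulation and mesophase analysis of ethoxylated sulfate surfactants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdmeso)
```

## The system and the model

Sodium lauryl ether sulfate (SLE~n~S) is an anionic surfactant with a
C12 alkyl tail, `n` ethoxy (-OCH~2~CH~2~-) units and a sulfate head;
`n = 0` is SDS, and commercial AES is a polydisperse mixture over `n`.
In water these molecules self-assemble: spherical micelles at low weight
fraction, worm-like micelles, hexagonally packed infinite rods, and
lamellar bilayer stacks as concentration rises. `dpdmeso` implements a
dissipative particle dynamics (DPD) model of this system together with
the structural analyses that turn particle configurations into the
quantities of interest: aggregation numbers and radii of gyration for
micelles, the bilayer d-spacing for lamellar phases, and the average
inter-rod spacing $r_S$ for hexagonal phases — plus the closed-form
enumeration of the periodicities a finite periodic box permits.

### Coarse graining and interactions

Beads represent small groups of atoms: a water bead is two H~2~O, the
alkyl tail is a terminal [CH~3~CH~2~] bead plus five [CH~2~CH~2~] beads,
each ethoxy unit is one bead, the sulfate head [OSO~3~]^-^ carries charge
-1, and a hydrated sodium bead (Na^+^ + 2 H~2~O) carries +1. Non-bonded
beads interact through the soft linear repulsion

$$F^C_{ij} = a_{ij}\,(1 - r_{ij}/R^C_{ij})\,\hat r_{ij}, \qquad r_{ij} < R^C_{ij},$$

where both the maximum repulsion $a_{ij}$ and the cutoff $R^C_{ij}$ vary
per species pair; per-pair cutoffs let bead molar volumes differ while
the solvent-solvent cutoff defines the length unit, $R^C_{WW} \equiv r_C
= 1$. Temperature is maintained by the standard pairwise thermostat: a
dissipative force $-\gamma\,\omega^D(r)(\hat r \cdot v_{ij})\hat r$ and a
random force $\sigma\,\omega^R(r)\,\zeta_{ij}\,\Delta t^{-1/2}\hat r$
with $\omega^D = (\omega^R)^2$, $\omega^R = 1 - r/R^C$ and
$\sigma^2 = 2\gamma k_BT$ (fluctuation–dissipation). The working values
are $\sigma = 3$ (hence $\gamma = 4.5$ at $k_BT = 1$) and
$\Delta t = 0.01$.

Chains are held together by harmonic bonds $U = \tfrac{C}{2}(r - l_0)^2$
with $C = 150$ and rest lengths from a heavy-atom rule (below), and
straightened by harmonic angles $U = \tfrac{D}{2}(\theta - \theta_0)^2$
with $D = 5$, $\theta_0 = 180^\circ$ on every consecutive bead triple.

Charged beads interact through a Slater-smeared Coulomb potential,

$$u(r) = \frac{\Gamma q_i q_j}{4\pi r}\left[1 - (1+\beta^* r)e^{-2\beta^* r}\right],$$

finite at contact (soft beads may overlap) and Coulombic at long range,
with $\beta^* = 0.929\,r_C^{-1}$ and the coupling
$\Gamma = e^2/(k_BT\,\varepsilon_0\varepsilon_r r_C)$ evaluated from the
unit map ($\Gamma \approx 15.9$ at 25 °C with $\varepsilon_r = 78.3$).
Periodic sums use Ewald splitting under tinfoil boundary conditions,
auto-tuned for about $10^{-4}$ relative force accuracy; a direct
image-sum reference implementation ships for cross-validation on small
boxes. The Ewald solver assumes an orthogonal cell, so electrostatics
and an accumulated Lees-Edwards offset cannot be combined — runs under
shear must disable electrostatics (all shear demonstrations here use
uncharged fluid).

### Unit mapping

Reduced units set $r_C = m = k_BT = 1$. Matching the reduced bead
density $\rho r_C^3 = 3$ to the experimental mass density of water at
25 °C (997 kg/m³, two molecules per bead, CODATA constants) gives

```{r}
um <- build_unit_map(298.15, 997, 2, 3)
um
```

about 5.65 Å per $r_C$ and $\tau = r_C\sqrt{m/k_BT} \approx 2.15$ ps.
A caveat worth recording: published real-unit tables for this mapping
are usually computed from already-rounded inputs ($k_B = 1.38\times
10^{-23}$, $r_C = 5.65$ Å), which shifts several derived entries by one
unit in the third significant digit relative to the full-precision
chain (e.g. $0.01\tau = 2.153\times10^{-14}$ s here versus a printed
$2.16\times10^{-14}$ s). The acceptance tests therefore compare at one
unit in the third significant digit.

### The force-field table is a reconstruction

The $a_{ij}$/$R^C_{ij}$ matrices and the bond-length rule for this bead
scheme come from a published alkyl-sulfate parameterization whose tables
are not redistributed here. The shipped file
`inst/extdata/forcefield_slens_synthetic.json` is a clearly-labelled
**synthetic reconstruction** that follows the scheme's structure
(Groot–Warren baseline $a_{WW} = 25$ at $\rho = 3$; strongly repulsive
water–alkyl contrast; per-pair cutoffs $R^C_{ij} = (R^C_{ii} +
R^C_{jj})/2$ from bead molar volumes relative to water; a linear
heavy-atom bond rule $l_0 = 0.1125\,(n_i + n_j)$ calibrated to the
projected C–C backbone geometry). Every operation is parametric in this
table and no test hard-codes its entries, so substituting a transcribed
table is a pure data edit. Quantitative claims about the real surfactant
require that substitution; the shipped values are adequate for the
qualitative physics the tests exercise (assembly, thermostat behaviour,
phase geometry).

## Simulation engine

The integrator is the modified velocity-Verlet scheme standard in DPD,
with velocity-prediction parameter $\lambda = 0.65$ for the dissipative
force. Pair search uses a Verlet neighbour list (skin 0.45) over linked
cells; an all-pairs reference path is kept and the two agree to
$10^{-12}$, which the tests assert on mixed-species boxes.

Thermostat noise comes from a counter-based stream keyed on
`(seed, step, sorted pair ids)`: $\zeta_{ij} = \zeta_{ji}$ by
construction, results are independent of pair traversal order, and a
run restarted from a checkpoint (state plus the stored force array)
continues bitwise identically — the restart contract the tests enforce.
Gaussian deviates are produced by inverting the normal CDF
(Beasley–Springer–Moro, |error| < 3×10⁻⁹).

Lees-Edwards boundaries impose homogeneous shear (flow along x,
gradient along z): image particles across the z boundary are displaced
by the accumulated offset and carry an image-velocity correction, with
the offset advancing by `shear_rate * L * dt` per step modulo L. Sheared
water develops a linear velocity profile whose slope matches the imposed
rate within 10% in the acceptance run.

Deliberate degenerate-input rules: exactly coincident beads (legal for
soft potentials at random initialization) repel at the full $a_{ij}$
along a seeded random direction; collinear angle triples at
$\theta_0 = 180^\circ$ take the analytic zero-force limit rather than a
division by zero.

## Building systems

`build_slens(n)` assembles the chain CT–CM×5–EO×n–ES with rule-derived
bond lengths; each chain is balanced by one free sodium bead.
`composition_from_weight_percent()` solves the molecule/water counts for
a requested surfactant weight percent at total bead count
$\mathrm{round}(3L^3)$. Weight percent is defined on an as-is molecular
basis: the surfactant mass includes the bare Na counterion (22.99
g/mol), while the two waters hydrating the sodium bead count as water.
This accounting is a convention choice (the alternative — counting the
whole hydrated bead as surfactant — shifts realized percentages by
under one point at these compositions) and is implemented in one place,
`molecule_molar_mass()` plus the composition solver, so it can be
swapped. Realized percentages land within 0.5 of the request across
7–80% in the boxes tested.

The polydisperse AES composition is represented by a distribution over
$n \in \{0,1,2,3\}$. Only its mean (0.76) is publicly stated; the
shipped default `aes_distribution()` hits that mean with a plausible
monotone-decreasing profile (0.52, 0.28, 0.12, 0.08) and is replaceable
wherever a distribution argument is accepted.

Initial placement is uniform for solvent with chains as Gaussian random
walks at their rest lengths — soft potentials tolerate the resulting
overlaps, so no insertion rejection is performed. Velocities are
Maxwell–Boltzmann at $k_BT = 1$, shifted to zero total momentum.

## Micelle analysis

Micelles are connected components of the molecule contact graph: two
molecules touch when any pair of their *tail* beads lies within the
contact cutoff (1 $r_C$ throughout), tails being what forms the
hydrophobic core. Whole molecules follow their tail assignment. The
mean aggregation number $N_{agg}$ is the unweighted mean over micelles,
monomers included; the mass-weighted alternative and monomer exclusion
are options, since the choice materially affects comparisons with
scattering experiments, but the unweighted mean is the default used in
every headline number here.

Equilibration is detected on the $N_{agg}$ time series by block
averages (block span 5000 time units): the plateau starts at the
earliest block from which every later block mean stays within one
pooled within-block standard deviation of their joint mean. On
ramp-then-plateau series with unit noise the detector lands within one
block of the true changepoint in at least 95% of 200 seeded replicates
(a calibration the test suite re-runs).

Micelle shape uses the radius of gyration of the tail-bead core,
computed after unwrapping the cluster across periodic images by
minimum-image chaining over its contact graph; clusters spanning more
than half the box are flagged as percolating and their $R_G$ treated as
unreliable. Computing $R_G$ over the core rather than the whole micelle
keeps the uniform-density-sphere identities exact — $R_G =
\sqrt{3/5}\,R$ for a uniform sphere of radius $R$, inverted by
`sphere_radius()` — which is also how the synthetic micelle generator is
validated. For spherical micelles of constant core density $R_G^3
\propto N$, so the binned profile of $R_G^3/N$ (bin width 5) is flat
where micelles are spherical; its minimum, located by a quadratic fit
through the three lowest bins (the published analyses locate "curve
minima" without stating a method; a local parabola is the simplest
estimator with sub-bin resolution), gives the most-spherical
aggregation number $N^*$ and the corresponding $R_G^*$.

For polydisperse systems, `composition_mixing()` asks whether micelles
recruit ethoxylation lengths in the overall ratios: each micelle's
n-histogram gets a chi-squared distance to the global distribution and
a quantile under the multinomial null (micelle size as draw count,
seeded simulation). By construction about 5% of well-mixed micelles
exceed the 0.95 quantile, which the suite checks.

## Mesophase analysis

### Lamellar

The director is the principal eigenvector of the nematic tensor
$Q = \langle 3uu^T - I\rangle/2$ of head-to-tail unit vectors — robust
to the head/tail sign ambiguity, unlike a mean end-to-end vector. A
configuration has no director when the two leading eigenvalues are
within 0.05 of each other (absolute gap): this catches both isotropic
melts and the planar-degenerate orientation field of a rod phase.

Periodic boundaries quantize the layer normal: the density wave of a
commensurate stack is an integer wave vector $\kappa$, giving
$d = L/|\kappa|$, equivalently $L\cos\theta = \kappa_{max} d$ with
$\theta$ the tilt to the director-matched box axis. `layer_count()`
finds the dominant commensurate wave within 30° of the director
(structure factor over integer $\kappa$, $|\kappa_i| \le 12$) and
rejects configurations whose best aligned peak is below twice the
strongest off-director power — for structureless configurations the
aligned and off-director extremes are statistically identical, so the
max-statistic background makes the 2× dominance criterion discriminate
where a median background would not. For speed the structure factor is
evaluated on a deterministic subsample of at most 8000 beads and ~300
background vectors; the dominant wave of an ordered stack exceeds the
background by orders of magnitude, so the subsampling does not affect
the call. The allowed-spacing catalog `allowed_d_spacings()` realizes
the box constraint as $d = L/\sqrt{\kappa_x^2+\kappa_y^2+\kappa_z^2}$
over non-negative integers — the one-dimensional triangle construction
generalized to an arbitrary commensurate normal — deduplicated at 3
significant figures.

### Hexagonal

Rods align with a box axis (under shear, the flow axis); the analysis
identifies that axis as the one whose transverse plane carries the
strongest Bragg peak, projects the tail density onto the transverse
plane, and takes periodic density-peak components as rod centres
(components that span the cell in one grid direction are stripes —
layers, not rods — and are rejected). The lattice fit takes the two
shortest independent minimum-image difference vectors among rod centres
(each averaged over all matching pairs), Lagrange-reduces the basis,
verifies the tiling constraint — integer combinations of $(\vec a, \vec
b)$ must reach the periodic images $(L, 0)$ and $(0, L)$ — and reports
the three nearest-neighbour lengths $|\vec a|, |\vec b|, |\vec a - \vec
b|$ and their mean, the average inter-rod spacing $r_S$. Orientation is
judged on all three nearest-neighbour vectors (the reduced basis is only
defined up to unimodular transforms): a cell with an axis-aligned vector
within 5° is "parallel" (in-plane) or "perpendicular", otherwise
"other".

The catalog `allowed_r_s()` enumerates every lattice permitted by the
box: superlattices of $L\,\mathbb{Z}^2$ via the Hermite-normal-form
parametrization (complete by construction; the index bound covers all
spacings above ~2 $r_C$ for $L \le 50$, and the tests verify exact
agreement with a bounded brute-force scan over integer index matrices).
Each lattice is reduced to its shortest basis; the near-hexagonality
cutoff $d_{co} = 1.5$ is applied to all three pairwise differences of
the three nearest-neighbour lengths — the published phrasing ("vectors
defining the unit cell") is ambiguous between two and three lengths;
three is chosen because $r_S$ itself averages three, and the choice is
an exposed argument. Averages are deduplicated at 3 significant
figures, matching the precision at which spacings are reported
(mirror-image cells collapse automatically because they share lengths).

For $L = 40$ this catalog reproduces the published geometry exactly:
it contains 7.52 (the $n = 0$ spacing, 4.25 nm in real units) and 9.65
(the cell with an axis-aligned lattice vector of length 10, observed to
prefer the parallel orientation), and holds exactly 10 distinct values
in $(7.5, 11)$. For $L = 50$ the same complete enumeration gives **21**
distinct values in the same interval, not the published 45. Because the
enumeration is provably complete (HNF parametrization, brute-force
cross-check) and reproduces every checkable $L = 40$ number, and because
no variant tried — unreduced bases, a two-length cutoff, exact-value
deduplication, wider integer bounds, nearby ranges — yields 45 while
keeping the $L = 40$ count at 10 (the $L = 50$ spectrum is in fact
empty between 10.2 and 11), the discrepancy is attributed to an
undocumented difference in the published counting convention. The
acceptance suite asserts the published 45 and is expected to fail
there; the value reported by `scripts/acceptance.R` is the computed 21.

When two allowed cells share a nearest-neighbour length of exactly 10
(averages 9.65 and 10.8), the acceptance script reports the one with
the smallest spread of its three lengths — the most nearly hexagonal
cell, which is the energy-minimizing arrangement.

### Phase classification

`classify_phase()` is rule-based on the percolation dimensionality of
the tail clusters: finite aggregates are micellar (worm-like when a
large cluster is elongated more than 4:1); one-axis percolation with a
successful rod-lattice fit is hexagonal, otherwise worm-like micellar;
two- or three-axis percolation with a successful layer fit is lamellar,
labelled imperfect when water bridges appear in more than 5% of frames
(a bridge frame is one where the water beads form fewer distinct slabs
than there are bilayers); when both a rod lattice and a layer stack fit,
the hybrid label is returned. The 5% bridge threshold and the 4:1
elongation ratio are operating points chosen here, exposed as
arguments.

### Concentration model and interpolation

If the surfactant-layer thickness $d_s$ is concentration independent,
volume balance gives $d = d_s\,(N_sV_s + N_IV_I + N_wV_w)/(N_sV_s)$;
`fit_d_model()` fits the single parameter $d_s$ by least squares
through the origin and recovers generating values to ±0.01 on
model-generated data. Bead volumes derive from species self-cutoffs
with radius $R^C_{ii}/2$ by default (the full-cutoff convention is
selectable; the model's volume *ratio* is scale invariant, so the
convention only matters if absolute volumes are quoted). A polydisperse
spacing is placed between its monodisperse neighbours by
$n_{Int} = (d_{poly} - d_0)/(d_1 - d_0)$; when composition is all that
matters this equals the mixture's mean ethoxylation.

## The synthetic generators, and what passing tests do not show

`make_micelle_field()`, `make_lamellar()` and `make_hexagonal()` build
configurations with known ground truth so every analysis stage is
testable without long simulations. Micelle cores sample tail beads
uniformly within a sphere of radius $\sqrt{5/3}\,R_G$ (so the measured
core $R_G$ matches the target up to finite-N fluctuation), heads and
counterions sit on/near the shell, and micelles are placed with shells
separated by more than the clustering cutoff. Lamellar stacks realize
an integer wave vector exactly; hexagonal fixtures place molecules
radially around lattice-point rods. Chain beads receive a "thermal"
Gaussian spread (0.2–0.25 $r_C$) so tails fill their regions like a
liquid — without it, rigid molecular lines at realistic densities do
not tail-percolate and classification would see isolated molecules; the
spread does not bias any density wave. Optional seeded jitter stands in
for thermal fluctuation.

These fixtures are geometric scaffolds, not thermodynamic states: they
have no equation of state, no interfacial width, no defect population
beyond the inserted bridges, and their molecules are not relaxed under
the force field. Passing the round-trip tests therefore demonstrates
that the *analyses* are correct on structures of known geometry — it
does not validate the force field against real SLE~n~S data, which
would need the transcribed parameter tables and production-scale runs.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale systems chosen as the
smallest sizes at which each property is cleanly measurable: 200-bead
boxes for force-path equivalence, 3000 beads ($L = 10$, $\rho = 3$) for
thermostat accuracy (10⁴ steps, kinetic temperature within
[0.98, 1.05]), sheared-profile and self-assembly runs at the same size
(the 30 wt% box assembles within the first 2×10⁴ of the budgeted 2×10⁵
steps), $L = 40$ fixtures for mesophase geometry, and 200-replicate
simulation studies for the statistical calibrations. Production-scale
phase-diagram work ($L = 40$–50, 10⁷+ steps) is out of scope by design.

Other fixed numerical choices: cluster cutoff 1 $r_C$ everywhere;
neighbour-list skin 0.45 with rebuilds triggered at half-skin
displacement; Ewald real-space cutoff $\min(L/2, 5)$ (the Slater
correction tail decays as $e^{-2\beta^* r}$ and is negligible beyond
5 $r_C$); catalog deduplication at 3 significant figures; structure
factors on ≤8000-bead subsamples.
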