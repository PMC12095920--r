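---
title: "Methods: aggregation kinetics and coarse-grained simulation of tau inhibition by chaperonin apical domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation kinetics and coarse-grained simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`apichap` implements a two-armed analysis used to characterise how isolated
chaperonin (CCT/TRiC) apical domains inhibit aggregation of the tau 4R
(K18) fragment:

1. a **kinetics arm** — ThT plate-reader time courses are averaged,
   control-subtracted, normalised and fitted with a two-baseline sigmoid;
   half-times are compared across conditions and regressed against monomer
   concentration on double-logarithmic axes; candidate aggregation
   mechanisms are forward-simulated and globally fitted;
2. a **simulation arm** — a coarse-grained C-alpha model of a folded
   apical domain plus a disordered tau chain is propagated with Langevin
   dynamics, and residue-residue interaction probabilities are distilled
   into binned heat maps and contiguous binding segments.

A synthetic-data module generates every input either arm consumes, so the
whole pipeline is testable offline.

## The two-baseline sigmoid

Aggregation traces are fitted with

$$F(t) = (m_1 t + n_1)\,(1 - L(t)) + (m_2 t + n_2)\,L(t), \qquad
L(t) = \frac{1}{1 + e^{k (t_{0.5} - t)}},$$

where $m_1, n_1$ describe the pre-transition baseline, $m_2, n_2$ the
post-transition baseline, $t_{0.5}$ the transition midpoint (the
*half-time*) and $k$ the transition steepness. Conventions worth stating
explicitly:

* the logistic weight $L$ **rises** with time for $k > 0$ and multiplies
  the *post*-transition line, so the curve moves from $(m_1, n_1)$ to
  $(m_2, n_2)$; at $t = t_{0.5}$ the model passes exactly through the mean
  of the two baselines. Published formulations of this equation differ in
  which line carries the logistic factor; we fix the convention by the
  universally shared prose definition (subscript 1 = pre-transition).
* $k$ is treated as having units of 1/h. The literature often prints the
  "rate constant" of this equation with hour units; only 1/h makes the
  exponent dimensionless. Because either reading may be wanted when
  comparing against printed tables, the fit table emits both `k` and
  `inv_k = 1/k`.
* normalisation uses $F_n = (F - F_\min)/(F_\max - F_\min)$ with
  $F_\min$ = the initial (minimum) and $F_\max$ = the plateau (maximum)
  value of the reference curve. Curves measured with an inhibitor are
  normalised against the *uninhibited* reference at the same tau
  concentration, so a suppressed plateau correctly reads below 1.

Fitting is nonlinear least squares (`nls`, `"port"`) with deterministic
data-driven starts: $t_{0.5}$ from the half-maximal crossing, $k$ from
four times the steepest finite-difference slope (a unit-amplitude logistic
has maximal slope $k/4$), baselines from linear fits to the first and last
10% of points. Start values are floored at $10^{-6}$ of the signal
amplitude because an exactly zero start produces a numerically zero
Jacobian column; a `scaleOffset` equal to the amplitude makes the
convergence test meaningful on noise-free curves. Up to three restarts
with jittered starts (fixed RNG) precede a `converged = FALSE` verdict —
non-convergence is reported, never thrown. Standard errors come from the
residual-variance-scaled Jacobian covariance.

Half-times are compared with
$Z = |t_{0.5,a} - t_{0.5,b}| / \sqrt{se_a^2 + se_b^2}$ and a two-sided
normal p-value computed on the log scale; p-values below double-precision
underflow are reported as the underflow bound with a flag, so a
"vanishingly small" p remains printable.

## Mechanism models

Fibril formation is described by two moments — number concentration $P$
and mass concentration $M$, monomer $m = m_0 - M$:

$$\frac{dP}{dt} = k_n m^{n_c} \;+\;
\begin{cases}0 & \text{nucleation-elongation}\\
k_2 m^{n_2} M & \text{secondary nucleation}\\
k_- M & \text{fragmentation (also saturating variant)}
\end{cases}$$

$$\frac{dM}{dt} = \frac{2 k_+ m P}{1 + m/K_S \ (\text{saturating variant only})}$$

with $P(0) = M(0) = 0$ and output $M(t)/m_0 \in [0, 1]$. Nucleus sizes
default to $n_c = n_2 = 2$, the usual convention when data cannot pin them
down. Integration is an adaptive Cash-Karp Runge-Kutta 4(5) in C++ at
relative tolerance $10^{-8}$ (no ODE solver package exists in the target
R stack; the integrator is cross-checked in the tests against an
independent fixed-step RK4 oracle at $10^{-6}$ agreement).

The half-time concentration-scaling exponents follow the standard theory:
$-n_c/2$ for nucleation-elongation, $-(n_2+1)/2$ for secondary
nucleation, $-1/2$ for fragmentation, and $\to 0$ for saturating
elongation + fragmentation at $m_0 \gg K_S$.

**Default rate constants sit in the secondary-process-dominated regime**
(generator defaults: fragmentation $k_n = 10^{-18}$, $k_+ = 80$,
$k_- = 0.01$ in concentration-µM, time-h units). The $-1/2$ law is an
asymptotic statement: the half-time is $t_{0.5} \simeq g/\kappa$ with
$\kappa = \sqrt{2 k_+ k_- m_0}$ and a logarithmic factor
$g \sim \ln(\kappa^2 / (2k_+ k_n m_0^{n_c}))$ that adds roughly $-1/g$ to
the measured slope. Primary nucleation must therefore be many decades
slower than the secondary process for the textbook exponent to emerge —
which is also the physically relevant regime for tau, whose aggregation is
dominated by fibril fragmentation. With these defaults the measured slope
is $-0.53$ over a 16-fold concentration range.

Global fitting shares one parameter set across all concentrations,
minimising the summed squared residuals by multi-start Nelder-Mead in
log10 parameter space (20 starts, fixed seed). Starts are drawn
log-uniformly over $[10^{-10}, 10^{2}]$ — wider than a naive six-decade
window precisely because the dominated-nucleation regime puts $k_n$ far
below the other constants. The model-selection statistic is the **MRE**,
the mean squared residual over all points; only the combination
$\kappa = \sqrt{2 k_+ k_- m_0}$ is identifiable from unseeded data, so
parameter-recovery checks score $\kappa$, not $k_+$ and $k_-$
individually. Ties in MRE raise an error rather than being silently
broken. The saturating model is provided as a forward simulator and fit
option, but no acceptance check depends on fitting it (its practical use
case — near-flat scaling — leaves the global fit ill-conditioned).

## Coarse-grained model

One bead per residue at the C-alpha position; reduced units with
$\varepsilon = k_B = m = 1$, lengths in Å. The reduced temperature 0.4
corresponds to roughly 300 K, which fixes the electrostatic energy scale.
Terms:

* **bonds** (all chains): harmonic, $k_b = 100$, rest length = native
  distance for folded chains, 3.8 Å for disordered ones;
* **angles/dihedrals** (folded chains only): harmonic angles
  ($k_a = 20$) and $k_d (1 - \cos(\phi - \phi_0))$ dihedrals restrained to
  the reference structure. The disordered chain deliberately has neither,
  leaving its backbone torsions free;
* **native contacts** (within folded chains only): 12-10 Lennard-Jones
  wells $\varepsilon_n [5 (r_0/r)^{12} - 6 (r_0/r)^{10}]$ on all pairs
  with sequence separation $\ge 4$ and reference distance $\le 9$ Å (the
  cutoff is configurable; shadow-map extraction is out of scope). Chains
  never share native contacts — tau is disordered by construction;
* **excluded volume** on all non-native nonbonded pairs:
  $\varepsilon_{rep} (\sigma_{rep}/r)^{12}$, $\sigma_{rep} = 4$ Å;
* **Debye-Hückel electrostatics** on charged pairs (+1 for Lys/Arg, −1
  for Asp/Glu, His neutral): $B q_i q_j e^{-r/\lambda_D}/r$ with
  $\lambda_D$ from the closed form at ionic strength 0.02 M (≈ 21.8 Å at
  300 K, $\epsilon_r = 80$) and $B = 0.4\,l_B$ with $l_B$ the Bjerrum
  length — i.e. $k_BT$ at the mapped room temperature times $l_B$ in
  reduced units;
* **hydrophobic attraction** on non-native nonbonded pairs:
  $-\lambda_{hp} h_i h_j (\sigma_{hp}/r)^6$ with $\sigma_{hp} = 5$ Å and
  the per-residue values $h_i$ from a data file. The packaged scale is an
  explicitly labelled **synthetic stand-in** (min-max normalised
  Kyte-Doolittle); the learned scale this class of model uses in
  production is published elsewhere and is not redistributable here. The
  mixing rule (product of per-residue values) is isolated in the pair
  list so the scale and rule can be swapped wholesale. The attractive
  term is smooth and untruncated rather than cut at $2\sigma$: a
  truncation would introduce a force discontinuity that violates the
  package's own exact force-consistency invariant, and the systems are
  small enough that no cutoff is needed for speed.

Dynamics use the BAOAB Langevin splitting (friction default 0.1 reduced —
low friction accelerates conformational sampling; with friction 0 the
integrator reduces exactly to velocity Verlet, which is how the
energy-conservation check is run). The default step $dt = 0.005$ reduced
time units stands in for the "2 fs" of the production-scale model — a
coarse-grained model has no literal femtoseconds, and the mapping is fixed
here once. Velocities are initialised from the Maxwell-Boltzmann
distribution with each replica's seed; replica seeds are
`master_seed + replica - 1`, and trajectories are bitwise reproducible.
The 250 Å cubic box is periodic with minimum-image convention by default
(reflecting harmonic walls are available via `pbc = FALSE`); periodic
boundaries avoid wall artifacts while the box is large enough to keep
images irrelevant at contact range. A step moving any bead by more than
10 Å aborts with advice to reduce `dt`.

## Contact analysis

An interaction is counted when two residue centres (the C-alpha beads —
the model's only per-residue coordinate) are within 6 Å, the conventional
cutoff for C-alpha models. Probabilities are the fraction of frames pooled
over replicas, after discarding the first 10% of each replica as
equilibration (configurable, 0 for exact hand-built tests). Maps are
binned into groups of three consecutive residues; the default block
aggregator is the **maximum** (peak-preserving — localized binding
signals survive binning), with the block mean available behind the same
switch. No cap is imposed on probabilities. Binding segments are
contiguous runs of tau rows whose peak probability reaches a threshold,
reported in author numbering and ranked by peak.

## The synthetic world

* Plate curves are the two-baseline sigmoid plus i.i.d. Gaussian noise —
  the simplest model consistent with replicate averaging; the default
  grid is 0-24 h at 5-minute sampling (mirroring an overnight, ~23 h
  experiment) and 12 replicates per condition. The default plate uses the
  published condition parameters (tau alone: $t_{0.5} = 4.41$ h,
  $k = 1.79$; +7 µM apiCCT3: 11.22 h, 0.69; +15 µM apiCCT7: 17.60 h,
  0.72) and extends the tau-alone series across 2.5-20 µM following the
  published scaling law $t_{0.5} \propto c^{-0.56}$.
* Mechanism series are forward simulations of the chosen model with
  optional Gaussian noise; ground truth goes to a JSON sidecar.
* Structure fixtures are canonical helix geometry (rise 1.5 Å,
  100°/residue, radius 2.3 Å, consecutive C-alpha ≈ 3.83 Å) or a
  two-helix hairpin with an exactly-3.8 Å two-bead loop and hand-countable
  inter-helix contacts. They are geometry, not biology, and are labelled
  synthetic.
* The packaged tau 4R (K18) sequence covers author residues 244-372
  (129 residues). The experimental construct definition specifies an
  alanine at position 332 and the packaged default honours it, although
  canonical 2N4R tau numbering puts a proline there (the construct's
  cysteines are at 291/322); `c332a = FALSE` restores the canonical
  residue. Whether the simulated chain carries the substitution is a
  user choice — it is charge-neutral either way.

What a green test establishes: the estimators recover known ground truth
from data generated under the model's own assumptions, the simulator
obeys its own Hamiltonian, and the analysis chain is deterministic and
self-consistent. What it does not establish: behaviour under real plate
artifacts (drift, evaporation, outlier wells — no outlier rejection is
implemented), ThT photophysics (fluorescence is taken proportional to
fibril mass), the adequacy of the stand-in hydrophobicity scale, or
production-scale sampling (desk runs are $10^5$-$10^6$ steps against
$10^8$ in production; the folded-domain stability and binding-segment
calls at desk scale are smoke-level, not converged estimates).

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| ODE tolerances | rtol 1e-8, atol 1e-12 (1e-30 in scaling studies) | atol must sit far below the minuscule early-time moments in dominated-nucleation regimes |
| nls scaleOffset | signal amplitude | zero-residual convergence |
| start flooring | 1e-6 x amplitude | avoids zero Jacobian columns |
| multi-start | 20 starts, log-uniform 1e-10..1e2, fixed seed | covers dominated-nucleation decades |
| native cutoff | 9 Å, sep >= 4 | conventional C-alpha contact definition |
| interaction cutoff | 6 Å | conventional for C-alpha residue centres |
| binning | 3 residues, block max | peak-preserving display |
| equilibration discard | 10% of frames | cheap insurance; 0 for exact tests |
| Q formation tolerance | r < 1.2 r0 | standard native-contact scoring |
| blow-up guard | 10 Å/step | catches unstable dt early |
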