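---
title: "Methods: allosteric switch kinetics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allosteric switch kinetics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

`allokin` implements the quantitative pipeline used to study allosteric
inhibition of conformational-switch enzymes: enhanced-sampling free-energy
landscapes, pathway and barrier extraction, transition-state-theory (TST)
rates, an allosteric Michaelis–Menten model, trajectory featurization, and
attribution-ranked gradient-boosted models. This vignette explains the
models, their assumptions, the tunable parameters, and the choices made
where the underlying methods leave the design open. Every empirical
statement here is one the package's own test suite or acceptance script
computes.

## 1. The kinetic model

The enzyme switches between an inactive (closed, autoinhibited) and an
active (open) conformation. Only the active conformation is catalytically
competent, and an allosteric inhibitor binds preferentially to the closed
state. Writing $K_a$ ($K_a'$) for the active/inactive equilibrium constant
of the free (inhibitor-bound) enzyme and $K_i'$ for the inhibitor
dissociation constant, steady-state analysis of the scheme gives

$$\frac{1}{V} = \frac{K_M}{V_{max}}
  \underbrace{\left(1 + \frac{[I]}{K_i'} + \frac{1}{K_a}
  + \frac{[I]}{K_i' K_a'}\right)}_{\alpha}\frac{1}{[S]}
  + \frac{1}{V_{max}}\underbrace{\left(1 + \frac{[I]}{K_i'}\right)}_{\alpha'},$$

so $V = V_{max}[S]/(\alpha K_M + \alpha'[S])$, with apparent constants
$K_{M,app} = \alpha K_M/\alpha'$ and $V_{max,app} = V_{max}/\alpha'$.
Because $\alpha > \alpha' > 1$ whenever $[I] > 0$, the model predicts mixed
(noncompetitive) inhibition with preference for the free enzyme:
$V_{max,app}$ falls and $K_{M,app}$ rises with inhibitor concentration.
`classify_inhibition()` encodes these regimes. One wrinkle is preserved
deliberately: the symbol list of the published form of this model also
names a free-enzyme dissociation constant $K_i$ that does not appear in
$\alpha$ as printed. `interaction_constants()` implements the printed form
by default and offers the textbook mixed-inhibition variant
($[I]/K_i$ in $\alpha$) behind `form = "conventional"`; the package does
not guess which was intended.

### Rates and equilibrium constants

TST converts an activation free energy into a rate,
$k = A\,e^{-\Delta G^\ddagger/RT}$. The prefactor $A$ is the attempt
frequency, which is unknown for a large-scale conformational transition;
`tst_rate()` therefore defaults to the *unit prefactor* $A = 1\,s^{-1}$, so
rates are bare Boltzmann factors, comparable across systems but with no
absolute time scale. The Eyring prefactor $k_BT/h$ is available via
`prefactor = "eyring"` — note it shifts every rate by ~12 orders of
magnitude and is *not* the convention under which published panels of this
kind are internally consistent. Detailed balance,
$k_{active}/k_{inactive} = e^{-(\Delta G^\ddagger_a - \Delta G^\ddagger_i)/RT}$,
holds to machine precision and is tested.

Potency conversions use $\Delta G_{exp} = RT\ln(\mathrm{IC50}/1\,\mu M)$
(an operational convention: the micromolar standard state makes a 1 µM
inhibitor the zero point) and $K_i' = e^{\Delta G_{bind}/RT}$ on a 1 mol/L
standard state. $K_i'$ is always a user input; the package offers the
conversion but never derives it silently. The composite descriptor
$1/(K_i' K_a')$ multiplies binding and conformational suppression.
`potency_correlation()` regresses $\Delta G_{exp}$ on
$\log_{10}$(composite) and reports slope and $r^2$; published correlation
values for this quantity are *not* asserted anywhere, because the transform
behind them (log base, direction, panel membership) is not derivable from
printed information.

Temperature defaults to 310 K throughout (the physiological simulation
temperature; also the value under which the IC50 conversions reproduce
printed panels). Energies are kJ/mol, concentrations mol/L except IC50 in
µM, rates s⁻¹. The gas constant is 8.314 J mol⁻¹ K⁻¹.

A caveat the tests encode explicitly: recomputing a published kinetic
panel from barriers printed at two decimals reproduces each rate to three
significant figures only up to one unit in the last digit, and the
composite descriptor — a product of two independently rounded 3-s.f.
numbers — only to ~1%. That is the precision arithmetic permits, not an
implementation artifact.

### End-point binding energies

`energy_decomposition()` keeps the standard end-point bookkeeping
$\Delta G_{bind} = \Delta E_{vdw} + \Delta E_{ele} + \Delta G_{GB} +
\Delta G_{SA} - (-T\Delta S)$ with the entropy term defaulting to zero
(for congeneric ligand series its contribution to *relative* binding
energies is commonly neglected). Only the bookkeeping identity and the
nonpolar term $\Delta G_{SA} = \gamma\,\Delta SASA$
($\gamma = 0.02267$ kJ mol⁻¹ Å⁻²) are in scope; implicit-solvent and
normal-mode solvers are not.

## 2. Toy well-tempered metadynamics

The real system's sampler is all-atom molecular dynamics; at desk scale the
package replaces it with overdamped Langevin dynamics directly in the 2-D
collective-variable space,

$$s \leftarrow s - \mu \nabla(U + V_{bias})\,\Delta t
  + \sqrt{2\mu k_B T \Delta t}\,\xi,$$

which preserves exactly the part under test: the bias/free-energy
mathematics. Boundaries reflect (the domain, 0–10 CV-units per axis,
mirrors the practice of bounding CVs to exclude physically meaningless
regions). Hills are 2-D Gaussians of width $\sigma = 0.30$ CV-units and
initial height $w_0 = 1.20$ kJ/mol — the published deposition settings for
this system — deposited at the walker's position every `interval` steps
with the well-tempered height
$w = w_0\,e^{-V_{bias}(s)/((\gamma-1)k_BT)}$. The bias factor $\gamma$ is
not stated in the source analysis; the default is 10, configurable. The
free energy is reconstructed as
$F(s) = -\frac{\gamma}{\gamma-1}V_{bias}(s)$, anchored so the global grid
minimum is exactly 0 (the convention that puts the inactive basin at the
zero point).

Numerical choices:

- the bias is *accumulated on a fine grid* (0.1 CV-units) and evaluated by
  bilinear interpolation during sampling, so the cost per step is
  independent of the hill count — the same device production engines use;
  reconstruction, by contrast, sums the explicitly stored hills;
- deposition pace is expressed in steps (default 100 at the demonstration
  scale) because the physical "per picosecond" pace is engine-specific;
- sampler defaults ($\mu = 10^{-3}$, demonstration runs use
  $3\times10^{-3}$; $\Delta t = 1$) give a thermal RMS step of ~0.07–0.12
  CV-units at 310 K, well below the hill width.

The recovery demonstration runs 400,000 steps (4,000 hills) on a symmetric
double well with a 20 kJ/mol barrier; it reconstructs the barrier to
within 2 kJ/mol and the surface to < 2 kJ/mol RMS over the region below
30 kJ/mol, in about a minute on one CPU. Convergence is monitored the way
long simulations are checked against their own earlier checkpoints: the
maximum |ΔF| between reconstructions at increasing hill counts, after
re-anchoring, over the low-energy region. Checkpoints are placed at 2%,
20% and 100% of the deposited hills: the first interval spans the
basin-filling phase and the drop in deviation is then a systematic
property of well-tempered convergence. Between two *late* checkpoints the
deviation is fluctuation-dominated and need not decrease monotonically for
any single run — a property of the estimator, not a defect.

The deposited-height decay invariant is checked at a *fixed* probe point:
$w_0 e^{-V_{bias}(s^*,t)/((\gamma-1)k_BT)}$ is non-increasing in $t$
because the bias only grows. (Heights of the actually deposited hills are
not a monotone sequence — the walker moves.)

## 3. Pathways on gridded landscapes

`find_minima()` reports interior grid nodes strictly below all 8 neighbors
(deterministic (row, col) tie-break); an energy cap separates genuine
basins from shallow noise wells — the depth threshold published analyses
use for this is unstated, so the cap is explicit and user-set.
`label_states()` assigns the inactive/active labels by proximity to
reference CV coordinates (the initial closed structure; the active-crystal
CV position), nearest-wins with energy tie-break.

`mfep()` runs Dijkstra on the grid graph (8-connected by default). The
published analysis names Dijkstra but not the edge cost; since what is
reported downstream is "the highest barrier that must be overcome", the
default cost is **minimax** — minimize the maximum node energy along the
path, the widest-path variant — with a Boltzmann-weighted sum
($\sum e^{F/k_BT}\ell$) as the configurable alternative. Neither is
asserted to be the original authors' functional. Frontier ties break on
lower free energy, then (row, col), making paths deterministic. The
minimax barrier is validated against two independent oracles: exhaustive
simple-path enumeration (small grids) and threshold connectivity — the
smallest level $\lambda$ at which source and target connect through nodes
with $F \le \lambda$, found by flood fill — which is exact at any size.

`second_path()` finds an alternative channel by masking a disk
(`exclusion_radius` cells, default 2) around the first path's highest
node and re-running the search. On an open 2-D domain a small mask never
disconnects the endpoints — a re-run can simply skirt the mask at slightly
higher cost — so the alternative is accepted only if its highest node lies
farther than twice the exclusion radius from the masked transition state;
otherwise a no-second-path condition is reported. Barriers are measured
from the basin minimum (0 for the global-minimum basin), matching the
convention of kinetic tables built on such landscapes.

## 4. Featurization

The three feature families mirror what practitioners extract from
trajectories:

- **Trajectory descriptors**: Kabsch (optimal-superposition) RMSD, mass-
  weighted radius of gyration with the per-axis decomposition
  $R_g^2 = R_g[X]^2 + R_g[Y]^2 + R_g[Z]^2$ (lab-frame axes, no
  principal-axis alignment — the published axis convention is ambiguous,
  so the identity-preserving one is used and tested), Shrake–Rupley SASA
  on a deterministic golden-spiral quadrature (960 points default; the
  total changes < 0.5% on doubling), backbone φ/ψ, hydrogen bonds
  (donor–acceptor ≤ 3.5 Å and D–H⋯A ≥ 120°, a standard criterion chosen
  because none is published for this analysis; a heavy-atom proxy mode
  serves hydrogen-free models), and named group–group distances (COM
  default, minimum-heavy-atom alternative).
- **Residue contact matrices**: per-frame minimum heavy-atom distance for
  residue pairs within 6.5 Å; waters and ligand atoms excluded;
  sequence-adjacent pairs included by default (exclusion flag provided).
  The cell-list implementation must equal the brute-force double loop
  exactly, and does on every tested instance.
- **Interaction fingerprints**: binary presence per residue of seven
  contact classes — hydrophobic (apolar C⋯C ≤ 4.0 Å), hydrogen bond,
  halogen bond (C–X⋯A ≤ 3.5 Å, angle ≥ 140°), π-stacking (centroids ≤
  5.5 Å, planes within 30° or 60–90°), π-cation (≤ 6.0 Å), salt bridge
  (opposite charges ≤ 5.5 Å), water bridge (two hydrogen-bond legs through
  one water). These are a documented geometric re-implementation of the
  conventions of standard profiling tools, not a clone of any program:
  rings come from residue templates (protein) and planar 5/6-cycles of a
  distance-based bond graph (ligand); charges from residue templates and
  ligand valence heuristics. All thresholds are exposed in
  `fingerprint_rules()`.

All descriptors are invariant under rigid motion of a frame, and identical
inputs produce byte-identical feature tables.

## 5. Interpretable learning

Feature tables carry one row per frame with a `label` (binary
strong/weak activity at the 0.050 µM IC50 threshold — strictly below is
strong, the boundary itself falls to weak since the published definitions
are strict inequalities — or a continuous free energy) and a `group`
(source system). `split_train_test()` offers the published protocol
(random rows, 70/30) and a grouped mode that keeps all frames of a system
on one side; random-row splitting of frame-correlated trajectories can
leak, so the grouped mode is the recommended-practice alternative, and the
package documents rather than hides the difference.

The main model is gradient-boosted trees (learning rate 0.1, max depth 11,
min child weight 4 — the published grid-search optimum). Tree count
defaults to 500 at synthetic scale; the published 10,000 is one `params`
entry away. Baselines: k-NN, logistic/linear regression, random forest,
SVM, decision tree. Metrics: accuracy/precision/recall/F1 with "strong"
positive, or R²/MSE/RMSE/MAE.

Attribution uses exact tree-path Shapley values
(`predict(..., predcontrib = TRUE)`); per sample, base value plus
attributions equals an independently computed model output (margin scale
for classifiers) within 1e-4 — the residual is single-precision tree
arithmetic. Non-tree models fall back to a seeded permutation-sampling
estimate (128 permutations/sample) with a warning. `rank_features()`
orders by mean |attribution| with a deterministic name tie-break and
summarizes directionality as the fraction of above-median-value samples
with positive attribution (the red/blue reading of attribution beeswarm
plots).

`run_scheme()` wires the four labeling schemes (trajectory descriptors /
fingerprints / contacts against activity; contacts against free energy —
regression only) end to end with per-replicate seeds derived from the
master seed. For scheme 4 the free-energy label of a frame is the grid
value at the frame's CV coordinates (how per-frame labels were assigned in
the original analysis is unstated; grid lookup is the default choice).

## 6. Synthetic data and what passing tests show

The generators emit every input family with ground truth alongside:
planted-feature tables (informative features shifted between classes or
coupled to a continuous label), inhibitor panels with
$\ln IC50 = b + s\,\ln(K_i'K_a') + \epsilon$ (defaults $s = 0.12$,
$b = 7.6$, ranges $K_i' \in 10^{-35..-25}$, $K_a' \in 10^{-18..-2}$ —
chosen to span the decade structure of measured allosteric panels and to
make the $\Delta G_{exp}$-vs-log-composite regression negative), two-state
bead trajectories whose designated residue pairs sit inside the 6.5 Å
cutoff in state A and outside in state B, and free-energy surfaces that
interpolate prescribed minima and saddles (Gaussian RBF against a high
background, so the low-energy channel runs through the prescribed
points).

These toys emulate the *structure* of the real data — two-basin
landscapes, contact differences between conformations, potency laws with
noise — but not its physics: no solvent, no force field, beads not atoms,
2-D CV spaces rather than 10⁴ coordinates. Passing the recovery suites
therefore certifies the machinery (the sampler's statistics, the
reconstruction identity, pathway optimality, attribution correctness), not
any measurement that depends on real trajectories: published model
accuracies (0.61–0.84), binding-energy ranges, specific landscape
topographies, or a particular potency-correlation value are outside what
synthetic scale can or should reproduce.

## 7. Known limitations

- The unit TST prefactor leaves absolute rates undefined up to a common
  factor; only ratios and comparisons are meaningful.
- Minimax paths on coarse grids can differ from continuous-space minimum
  free energy paths by up to a cell; barriers carry O(grid spacing ×
  gradient) discretization error.
- The fingerprint rules approximate profiler behavior; equivalence with
  any specific program's output is not claimed.
- The permutation-sampling attribution fallback is approximate and slow;
  it exists for completeness, not production use.
- The Langevin engine is 2-D only, by design; it is a test bed for the
  bias mathematics, not a simulator.
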