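# allokin

Allosteric switch kinetics from free-energy landscapes and interpretable
trajectory features.

## The problem

Conformational-switch enzymes such as the tyrosine phosphatase SHP2 are
inhibited allosterically: the inhibitor binds a tunnel site away from the
catalytic cleft and stabilizes the closed, autoinhibited conformation. The
potency of such an inhibitor is not explained by binding affinity alone —
it depends jointly on the thermodynamics of binding (the dissociation
constant K<sub>i</sub>′ in the closed state) and on the kinetics of the
enzyme's inactive ↔ active conformational equilibrium (the equilibrium
constant K<sub>a</sub>′ of the bound enzyme). `allokin` packages the
quantitative machinery of this analysis for desk-scale use:

- a **toy well-tempered metadynamics engine** on analytic 2-D model
  potentials: overdamped Langevin sampling in collective-variable (CV)
  space, Gaussian hill deposition with heights scaled by
  exp(−V<sub>bias</sub>/((γ−1)k<sub>B</sub>T)), reconstruction
  F(s) = −γ/(γ−1)·V<sub>bias</sub>(s), convergence checkpoints, and
  HILLS-style text I/O;
- **free-energy-surface analysis**: basin detection, inactive/active state
  labeling, minimum free energy paths by a minimax (widest-path) Dijkstra
  search with an exp-weighted alternative, second-pathway discovery by
  transition-state masking, 1-D profiles;
- the **kinetic core**: transition-state-theory rates
  k = exp(−ΔG<sup>‡</sup>/RT) (unit prefactor, 1 s⁻¹),
  K<sub>a</sub>′ = k<sub>active</sub>/k<sub>inactive</sub>,
  ΔG<sub>exp</sub> = RT·ln(IC50/µM), the composite potency descriptor
  1/(K<sub>i</sub>′K<sub>a</sub>′), and the allosteric Michaelis–Menten
  model V = V<sub>max</sub>[S]/(αK<sub>M</sub> + α′[S]) with
  α = 1 + [I]/K<sub>i</sub>′ + 1/K<sub>a</sub> + [I]/(K<sub>i</sub>′K<sub>a</sub>′),
  α′ = 1 + [I]/K<sub>i</sub>′, K<sub>M,app</sub> = αK<sub>M</sub>/α′,
  V<sub>max,app</sub> = V<sub>max</sub>/α′, plus end-point binding-energy
  bookkeeping with the nonpolar term γ·ΔSASA (γ = 0.02267 kJ mol⁻¹ Å⁻²);
- **featurization** of structures and trajectories: Kabsch RMSD, radius of
  gyration (total and per axis), Shrake–Rupley SASA, backbone φ/ψ,
  hydrogen-bond counts, group distances, residue contact matrices (minimum
  heavy-atom distance ≤ 6.5 Å), and a seven-class geometric ligand–receptor
  interaction fingerprint (HPI, HB, XB, PST, PIC, SB, WB);
- **interpretable learning**: gradient-boosted trees (and k-NN, logistic /
  linear regression, random forest, SVM, decision tree baselines) with
  exact per-sample Shapley attributions for tree models, mean-|attribution|
  feature ranking, and four end-to-end labeling schemes;
- **synthetic-data generators** with known ground truth for every input
  family, so the whole pipeline is testable without external trajectories.

## Worked example

Recompute the kinetic panel of an allosteric-inhibitor study from its
printed activation/inactivation barriers:

```r
library(allokin)
kt <- kinetic_table(allokin_table1(), temperature = 310)
kt[, c("system", "k_active", "Ka_prime", "composite")]
#       system     k_active     Ka_prime    composite
# 1        apo 1.437057e-12 2.800940e-01           NA
# 2   RMC-4550 5.945665e-23 4.633385e-18 2.398055e+51
# 3 IACS-13909 4.284405e-22 1.024270e-18 9.124350e+46
# 4     SHP389 1.931953e-17 4.308666e-12 1.261361e+45
# 5     SHP099 4.089497e-22 3.635027e-08 2.620011e+37
# 6 Compound-7 4.480694e-21 2.293227e-02 8.483788e+26
```

`k_active = exp(−ΔG‡_active/RT)` is the (unit-prefactor) rate of the
inactive→active transition: binding of RMC-4550 raises the activation
barrier from 70.28 to 131.90 kJ/mol and so slows activation by ten orders
of magnitude. The composite descriptor `1/(Ki'·Ka')` combines binding and
conformational kinetics; it is largest for the most potent inhibitor.

A full synthetic demonstration — build a landscape with prescribed critical
points, extract the pathway, and convert the barrier to rates:

```r
grid <- gen_fes(minima = data.frame(cv1 = c(3, 7), cv2 = 5, energy = c(0, 5)),
                saddles = data.frame(cv1 = 5, cv2 = 5, energy = 20))
m <- label_states(find_minima(grid, energy_cap = 10),
                  list(inactive = c(3, 5), active = c(7, 5)))
p <- mfep(grid, m[m$label == "inactive", ], m[m$label == "active", ])
c(barrier = p$barrier_forward, k_active = tst_rate(p$barrier_forward))
#      barrier     k_active
# 20.061825820  0.000416374
```

A command-line entry point covering each stage ships as
`system.file("bin", "allokin", package = "allokin")` (subcommands
`kinetics`, `mm-curves`, `metad-demo`, `fes-analyze`, `featurize`, `ml`,
`synth`, `demo`).

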