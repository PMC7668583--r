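---
title: "Contact-guided REMD: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-guided REMD: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remdguide)
```

## The problem and the method

Residue–residue contact predictions (coevolution analysis, sparse NMR,
cross-linking) carry real structural signal mixed with false positives.
`remdguide` implements a method that injects such contacts into
replica-exchange molecular dynamics (REMD) as a soft attractive bias, so
that the enhanced sampling of parallel tempering and the contact
information cooperate: the ladder's hot replicas cross barriers, the bias
funnels low-temperature replicas toward conformations that satisfy the
contacts. The package covers the full workflow — contact selection at a
controlled true-positive rate (TPR), bias construction, ladder
generation, exchange bookkeeping, a desk-scale simulator, and the
evaluation suite (RMSD, GDT, significance tables, enrichment histograms,
local accuracy).

Everything geometric operates on Cα traces only. Published "backbone"
RMSDs typically include N, C (and O) atoms, so absolute RMSD values here
differ slightly from backbone-atom conventions; comparisons *within* the
package are consistent.

## Units

Internal length unit is the nanometre, matching the bias-potential
parameters (α in nm⁻¹, r0 in nm); Ångström appears only at PDB I/O and in
reported scores (RMSD, GDT cutoffs), which are conventionally quoted in
Å. Energies are kJ/mol, temperatures K, times ps (trajectory timestamps
ns), k_B = 0.008314462618 kJ/mol/K.

## The sigmoid bias

$$V(r) = k\,\sigma(r), \qquad
  \sigma(r) = \frac{A}{1 + e^{-\alpha (r - r_0)}}$$

| parameter | default | units | role |
|---|---|---|---|
| A | 1 | — | plateau of σ; fixed to 1 so strength lives in k |
| α | 2.5 | nm⁻¹ | steepness of the S-shape |
| r0 | 1.6 | nm | inflection point = distance of maximal force |
| k | 10 | kJ/mol | force coefficient, ≈ 4 kT at 300 K |

The potential is attractive everywhere and bounded by kA: the force
magnitude $kA\alpha\,p(1-p)$ (with $p = \text{plogis}(\alpha(r-r_0))$)
peaks at $r_0$ at $kA\alpha/4 = 6.25$ kJ/mol/nm and decays
logistically — below 10% of the peak beyond $2 r_0 \approx 3.2$ nm. A
false-positive restraint between residues that never approach therefore
contributes almost nothing; one between residues already close costs at
most a hydrogen-bond-scale energy (V at the 0.6 nm contact distance is
≈ 0.76 kJ/mol below the plateau's complement — the well depth from the
plateau is ≈ 9.2 kJ/mol). The logistic is evaluated via `stats::plogis()`
in the numerically stable branch form.

`tabulate_potential()` materializes (r, V, −dV/dr) on a uniform grid for
engines that consume tabulated bonded interactions. Defaults (spacing
0.002 nm, range 0–6 nm) are engine-conventional choices: at 0.002 nm the
linear-interpolation error is below 10⁻⁶ kJ/mol. The table stores V as
written; a constant offset (tabulating V − V(∞) instead) would not change
forces. For the GROMACS convention — table holds unit-strength σ, per-pair
k on the interaction line — tabulate with k = 1 and pass the real k to
`patch_topology()`, which appends function-type-9 tabulated bonds and
leaves all other topology text byte-identical.

## Contacts and scenarios

Native contacts: $r_{ij} \le 0.6$ nm and $|i-j| \ge 4$ on the reference
Cα trace. The sequence-separation floor is applied to the non-native
candidate list as well — a deliberate design choice: near-diagonal pairs
are satisfied by chain connectivity alone and would carry no information
as "false" restraints. Non-native candidates also exclude the nine
neighbor cells (i′, j′), i′ ∈ {i−1, i, i+1}, j′ ∈ {j−1, j, j+1} of every
native contact (after i < j canonicalization), so mislabeled near-hits
cannot leak into the non-native pool.

`select_restraints()` draws `round(tpr · n_total)` native pairs
(half-up — consistent with every cell of the 14-scenario benchmark grid,
e.g. 0.75 × 12 = 9) and fills up with non-native ones, uniformly without
replacement. Each scenario is an independent draw from the pools with its
own recorded seed; pools are not reused across scenarios. The
`scenario_grid()` (reference + TPR ∈ {100, 75, 50}% × up to 48 pairs)
reproduces the benchmark bookkeeping exactly.

## Temperature ladder and exchange

The plain exponential ladder $T_i = T_0 e^{g i}$ gives geometric spacing;
the modified generator

$$T_i = T_{i-1} + a_i \, T_0 (e^{g i} - e^{g (i-1)}), \qquad
  a_i = (1 + 0.04)^{\lfloor i / 10 \rfloor}$$

widens steps by 4% every ten replicas to keep exchange rates more nearly
constant across a wide range. The schedule $a_i = 1.04^{\lfloor i/10
\rfloor}$ is the simplest multiplicative reading of "increase every ten
replicas by 4%" and reduces to $a_i = 1$ (hence the plain exponential,
to machine precision) when the boost is zero. A printed formula of the
plain generator omits the replica index in the exponent; the recursion
makes the intended $T_0 e^{g i}$ form unambiguous, and that is what is
implemented. Per-system growth parameters are not published, so
`calibrate_growth()` bisects g to reproduce printed endpoints (300 K →
625 K over 60 replicas, to 10⁻³ K).

Exchange uses the Metropolis rule $w = \min(1, e^{-\Delta})$,
$\Delta = (\beta_j - \beta_i)(E_i - E_j)$, between adjacent slots only,
with parity alternating between sweeps so every adjacent pair is
attempted every two sweeps. Swap semantics: configurations migrate
between temperature slots, each slot keeps its thermostat, velocities are
rescaled by $\sqrt{T_\text{new}/T_\text{old}}$. A temperature slot's
frame series is therefore directly the demultiplexed constant-temperature
trajectory that all ensemble statistics use.

## The desk-scale simulator

The published demonstrations of this method are cluster-scale (60–100
replicas, 250 ns, explicit solvent, all-atom force fields). The package
instead ships a deliberately small Cα-bead model whose only job is to
make the *method* exercisable and testable end to end; it reproduces the
mechanism (bias-driven enrichment), not any all-atom number.

Terms and defaults:

* harmonic virtual bonds, k = 8000 kJ/mol/nm², r0 = 0.38 nm;
* harmonic pseudo-angles, k = 20 kJ/mol/rad², θ0 = 1.85 rad;
* purely repulsive r⁻¹² excluded volume (σ = 0.40 nm, ε = 1 kJ/mol) for
  pairs with |i−j| ≥ 3 that are not reference contacts;
* a weak Gō-like 12-10 well (ε = 3 kJ/mol ≈ 1.2 kT) at the reference
  contact distances, giving the landscape a native funnel so that
  folding is *possible* but not trivial on the simulated timescale;
* the sigmoid restraints, evaluated by closed form (no interpolation
  inside the engine).

The integrator is BAOAB-split Langevin (dt = 0.01 ps, friction 1 ps⁻¹,
bead mass 110 g/mol — the bond period of ≈ 0.74 ps is resolved by ~70
steps). Friction 0 disables the O-step entirely, leaving velocity Verlet
for energy-conservation checks. All random draws (initial velocities,
thermostat noise, exchange decisions) come from R's RNG under one master
seed, so entire REMD runs replay bit-identically; the exchange log
records energies, Δ, probability and the uniform draw of every attempt,
allowing exact replay verification.

What the toy model does **not** emulate: solvent and hydrodynamics,
side-chain packing, secondary-structure propensity, realistic kinetics,
and system sizes where ladder design becomes delicate. Passing the toy
enrichment test shows the machinery — restraint selection, bias forces,
exchange bookkeeping, evaluation — behaves as designed; it says nothing
quantitative about all-atom systems.

### Study conditions of the enrichment check

The end-to-end check runs a 20-residue helix-loop-helix target, 8
replicas (300–500 K), 2 × 10⁵ steps (2 ns of toy time), 12 contacts
(≈ L/2, the point past which extra perfect contacts stopped paying off in
the benchmark), exchange attempts every 1000 steps, over three seeds.
Under these fixed conditions the 100%-TPR bias must enrich
native-like frames (lowest-temperature RMSD < 0.4 nm) over the unbiased
reference in at least two of three seeds, and the 50%-TPR bias must not
match that margin — the toy analogue of the finding that ~75% TPR is the
quality floor for useful guidance.

## Synthetic fixtures

`make_folded_fixture()` builds ideal α-helical Cα traces (rise 1.5 Å,
100° turn, 2.3 Å radius; consecutive Cα–Cα ≈ 3.8 Å) and, for
`helix_loop_helix`, packs two antiparallel helices 0.55 nm apart so
inter-helix native contacts exist — a minimal compact fold with ≥ L/2
contacts. A seeded 0.02 Å jitter makes seeds distinct without disturbing
the geometry. `make_unfolded_fixture()` grows a persistent self-avoiding
random walk (bond 0.38 nm; pairs at separation ≥ 2 kept beyond 0.45 nm,
at separation ≥ 4 beyond 0.62 nm) so starts have, by construction, zero
native contacts and high RMSD to any folded fixture — mirroring the
high-RMSD, structure-free starting conformations the method assumes.
Generation retries within bounded budgets and errors (suggesting a new
seed) rather than silently violating the constraints.

## Evaluation suite

**Superposition** is the least-squares rigid fit (proper rotation), via
`bio3d::fit.xyz()`; tests cross-check it against an independent
rotational-grid + refinement minimizer.

**GDT** uses one global superposition followed by thresholding over the
20-cutoff schedule 0.5–10 Å — not the iterative maximal-subset search of
CASP's LGA program. For well-fitting models the two agree; for poor
models the single-fit scores are conservative. GDT_TS > 50 is read as
"topologically accurate", strictly.

**Percentiles** use the nearest-rank (lower) method: reported
percentiles are attained scores, which is why benchmark GDT percentiles
for a 20-residue protein land on multiples of 1.25 = 100/(4·20).
Significance rules: shaded means P_x ≥ P_x,ref; bold means
P_x ≥ P_x,ref + w (P100,ref − P_x,ref) with w = 0.5; both inclusive, the
reference row exempt. At the 100th percentile the headroom is zero, so
matching the reference maximum is flagged significant — visible in the
shipped benchmark tables. The two printed benchmark percentile tables
(20-residue and 35-residue test proteins) are included as CSV fixtures
and the test suite reproduces every printed bold flag from the values
alone, with zero mismatches.

**ΔN histograms** difference per-bin counts between equal-length score
series (default bin width 0.2 Å; the demo uses 0.5 Å for its shorter
series). Unequal lengths are an error, with an explicit
truncate-to-shorter opt-in, because count differences are only
meaningful for equal sampling.

**Local accuracy** ranks frames by GDT_HA and bins post-fit per-residue
displacements into classes (< 1, 1–2, 2–4, 4–8, > 8 Å by default).

## Numerical choices and edge cases

* Logistic evaluated via `plogis` (no overflow for large |α(r−r0)|).
* `round_half_up()` for restraint counts (R's `round()` is banker's).
* Ladder calibration: `uniroot` on g, bracketed by the boost-free closed
  form (an upper bound, since boosts only enlarge the ladder top).
* Exchange with zero replicas or an incomplete trailing block attempts
  nothing (a run shorter than one exchange interval is plain MD).
* PDB altLoc: first occurrence wins; multi-chain files merge into one
  renumbered chain by default (mirroring single-topology treatment of
  multi-chain systems); coordinates beyond ±9999 Å refuse to write
  (fixed-width PDB fields).
* Integrator divergence (non-finite energy or |x| > 10⁴ nm) raises an
  error advising a smaller dt rather than returning garbage.

## Problem sizes

The test suite and demo run at deliberately small sizes — 10–40 residues,
3–8 replicas, ≤ 2 × 10⁵ steps, chosen as the smallest systems that
exhibit each property being tested (the enrichment experiment is the
largest, ~2 minutes). The same code paths scale to user-sized problems;
`run_remd()` cost is linear in steps × replicas and quadratic in chain
length.

## Known limitations

* Cα-only geometry throughout (documented deviation from backbone-atom
  RMSD conventions).
* Single-fit GDT (conservative for poor models).
* The toy engine is a stand-in: no solvent, electrostatics, or all-atom
  detail; its force-field defaults are package choices, not fits.
* Exchange acceptance in the toy is high (small system, narrow ladder);
  ladder-design questions for large systems are out of scope.
* Percentile tables assume the reference row is present in every score
  column; mixed frame counts across scenarios are the caller's concern.
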