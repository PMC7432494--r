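---
title: "From HSQC peak positions to open/closed state populations of Lys48-linked ubiquitin chains"
author: "ubconform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From HSQC peak positions to open/closed state populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Lys48-linked polyubiquitin chains interconvert in solution between *open*
conformers, in which a unit's hydrophobic patch (Leu8, Ile44, Val70) is
solvent-exposed, and *closed* conformers in which that patch is shielded by
a Ub–Ub contact. The equilibrium matters because ubiquitin-recognizing
proteins engage the hydrophobic patch: a unit that is mostly closed is
mostly unavailable. `ubconform` quantifies this equilibrium for each unit
of a chain from standard ¹H-¹⁵N HSQC peak positions, and then deconvolves
the per-unit numbers into populations of discrete whole-chain
conformational states.

## The observation model: fast exchange and the dividing ratio

When a residue exchanges between two environments faster than their
chemical-shift difference (here on the order of 100 Hz), its HSQC peak
appears at the population-weighted average of the two pure-state
positions. With monomeric ubiquitin as the fully open reference and cyclic
diubiquitin (whose two units pack their patches against each other) as the
fully closed reference, the peak of a chain unit must therefore lie on the
straight line joining the two reference peaks, and the internal division
ratio of that segment equals the closed-state fraction:

$$\delta_{obs} = (1 - f_{closed})\,\delta_{open} + f_{closed}\,\delta_{closed}.$$

`project_fraction()` computes the ratio as the orthogonal-projection
parameter $t$ of the observed peak onto the reference segment in composite
coordinates $(\delta_H, \alpha_N \delta_N)$, with $t = 0$ at the open
reference. Three numerical choices are involved:

* **Projection in 2D rather than on one axis.** The published analysis does
  not state whether ratios were read off a single axis or in the plane; we
  project orthogonally in the composite plane. For exactly collinear
  triples the two definitions agree and the ratio is invariant under any
  affine map of the plane (this is tested); for noisy peaks the orthogonal
  projection uses both coordinates and is the natural least-squares
  estimate.
* **Composite ¹⁵N weight** `alpha_N = 0.14`, the common convention for
  amide chemical-shift-perturbation distances. Because collinear ratios are
  weight-invariant, the choice affects only the deviation diagnostics and
  the noise behaviour; it is configurable everywhere.
* **Informativeness floor** `min_separation = 0.02` composite ppm: dividing
  a near-zero reference segment amplifies position noise without bound, so
  closer reference pairs are flagged `uninformative` and excluded.

The orthogonal residual, expressed relative to the reference separation
(`rel_deviation`), is the collinearity diagnostic. A residue deviating by
more than `rel_dev_threshold = 0.10` is flagged `off_line` and excluded
from aggregation — this is the quantitative form of the criterion that
disqualified cyclic triubiquitin as a closed-state reference (its
three-fold symmetric structure leaves the patches partially exposed, so
its peaks fall visibly off the monomer/cyclic-dimer line). The 0.10
default encodes "significant deviation" as a testable cutoff and is
configurable.

Raw ratios are reported unclamped at residue level (values slightly
outside [0, 1] are legitimate noise diagnostics, and `out_of_range` flags
fire beyond ±0.05). Clamping into [0, 1] happens only when residue ratios
are aggregated into per-unit fractions, so the solvers always receive
feasible inputs while diagnostics stay honest.

Aggregation (`unit_open_fractions()`) defaults to the single-probe policy
with Val70 — the probe used for the published percentages, and the
best-dispersed patch residue. The alternative `weighted_mean` policy
averages all non-excluded residues weighted by squared reference
separation (better-dispersed probes carry more information) and reports a
weighted standard error.

## The state model: matchings and the linear inversion

A whole-chain conformational state is modeled as a *matching* on the
units: a set of closed Ub–Ub contacts in which each unit shields its patch
against at most one partner. For the trimer with all contacts allowed this
yields exactly four states — A (all open), B (Ub2–Ub3), C (Ub1–Ub2), and D
(the end-to-end Ub1–Ub3 contact leaving the middle unit open) — and the
matching model is exactly the published four-state scheme. The state count
for chains of 2–5 units follows the telephone numbers 2, 4, 10, 26.

With incidence matrix $M$ ($M_{is} = 1$ iff unit $i$ is open in state
$s$), per-unit open fractions are $f = MP$ and the inversion solves
$MP = f$, $\sum_s P_s = 1$. For the trimer the augmented system is square
and nonsingular, so the populations follow exactly; in closed form
$P_A = (\sum_i f_i - 1)/2$. Three design decisions:

* **Infeasible exact solutions are never clipped.** Fraction vectors such
  as $(0,0,0)$ have no nonnegative solution (no matching closes all three
  units at once); the exact solver returns the negative component, flags
  `feasible = FALSE`, and warns. Silently projecting onto the simplex
  would hide model misfit.
* **Underdetermined chains** (the 10-state tetramer, or restricted contact
  sets) are solved by nonnegative least squares with the normalization
  enforced through a heavily weighted row (weight 10⁶, followed by exact
  renormalization), and — more informatively — characterized by
  `feasibility_bounds()`: per-state minimum and maximum populations over
  the polytope $\{P \ge 0, \sum P = 1, MP = f\}$ via linear programming.
  The tetramer state space is a generalization beyond the published
  four-state trimer model and is labeled as such in reports.
* **Uncertainty propagation** is by parametric bootstrap: unit fractions
  are perturbed by independent Gaussians (the simplest defensible model,
  since no measurement uncertainties are published), re-solved, and
  summarized as 2.5/97.5 percentile intervals. Draws are clamped to
  [0, 1]; the whole procedure is deterministic given its seed.

## What the synthetic generator emulates — and what it does not

No peak lists are deposited for this system, so the package generates its
own inputs. `simulate_chain_peaklists()` realizes exactly the observation
model above: each unit's peak for each probe residue is placed at the
population-weighted average of its open and closed reference positions
plus independent Gaussian position noise (defaults 0.003 ppm ¹H / 0.02 ppm
¹⁵N, typical HSQC peak-position precision). Reference lists are emitted
noise-free, reflecting that references come from separate well-resolved
spectra of pure species. The reference geometry is a deterministic
synthetic fixture (open positions in the amide region, closed positions
displaced by 0.1–0.5 ppm ¹H and 0.5–2.0 ppm ¹⁵N in residue-dependent,
mutually non-parallel directions); the real reference shifts exist only in
published figures and are deliberately not imitated.

Consequently, passing tests demonstrate correctness of the *inference
machinery* under the stated model — they cannot validate the fast-exchange
assumption itself, peak-assignment correctness, or behaviour under
intermediate/slow exchange. Exchange broadening, which real spectra show
to varying degrees, is modeled at most as an optional intensity
attenuation proportional to $f_{open}(1-f_{open})$; lineshapes, relaxation
and exchange-rate estimation are out of scope. `simulate_offline_peak()`
provides controlled violations of collinearity for testing the
diagnostics.

## Problem sizes and numerical tolerances

The test suite exercises: exact-recovery and affine-invariance properties
at tolerances 10⁻¹²–10⁻¹⁰ (the operations are closed-form linear algebra);
agreement with a brute-force grid-search projection oracle (step 10⁻⁶) to
10⁻⁵; 1000-point simplex sweeps for the noise-free
simulate→project→solve identity at 10⁻¹⁰; and 200-replicate noise studies
per noise level, at which the mean absolute population error under default
noise is below 0.05 and decreases as noise shrinks over a 10× range. These
sizes give stable statistics at interactive runtimes; all stochastic runs
are seeded.

## Known limitations

* Two-state (open/closed) fast exchange per unit is assumed throughout;
  partial or intermediate-exchange behaviour biases dividing ratios in
  ways the collinearity check only partially detects.
* The matching state model excludes states in which one unit contacts two
  partners simultaneously.
* For chains longer than three units the per-unit fractions no longer
  identify the populations; only feasibility intervals (and NNLS point
  estimates within them) are available.
* The single-probe policy inherits any idiosyncrasy of the probe residue;
  the weighted-mean policy trades that for sensitivity to residues with
  small reference separations, mitigated by the separation² weighting.
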