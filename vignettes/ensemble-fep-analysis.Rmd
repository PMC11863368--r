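---
title: "Ensemble analysis of alchemical free-energy simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of alchemical free-energy simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepens)
```

## The problem

Alchemical free-energy perturbation (FEP) estimates the relative binding free
energy of two ligands by transforming one into the other along a coupling
parameter $\lambda$, both bound to the protein and free in water:
$\Delta\Delta G_{\mathrm{bind}} = \Delta G_{\mathrm{bound}} - \Delta
G_{\mathrm{free}}$. A single simulation stays near its starting point in phase
space, so the statistical uncertainty it reports (the estimator's internal
$\sigma$) understates the real run-to-run spread. The remedy is an *ensemble*
of independent replicas, generated either by randomising the starting
velocities (velocity-induced independent simulations, VIS) or by solvating
the solute with different equilibrated water-box snapshots (solvent-induced,
SIS), which also changes the water count and topology. This package is the
analysis layer for such ensembles: it estimates per-replica free energies
from reduced potentials, aggregates replicas, closes thermodynamic cycles,
tests whether two replica-generation protocols disagree, and scores
predictions against experiment — all backed by synthetic generators with
known exact answers.

## Free-energy estimation

### MBAR

The multistate Bennett acceptance ratio operates on the matrix of reduced
potentials $u_{k,n}$ (sample $n$, evaluated at state $k$, in units of $kT$)
and solves the self-consistency equations

$$ f_i = -\log \sum_{n} \frac{\exp(-u_{i,n})}{\sum_k N_k \exp(f_k - u_{k,n})} $$

for the dimensionless free energies $f_i$, anchored at $f_1 = 0$. `mbar()`
iterates these equations from $f = 0$, switching to Newton steps on the
equivalent convex objective once the iterate is close (each Newton step is
accepted only if a subsequent self-consistent sweep confirms a smaller
residual, so the accelerated path can never diverge past the plain
iteration). Convergence is declared when the largest self-consistent update
falls below `tolerance` (default $10^{-8}\,kT$); non-convergence is an error
that reports the final residual, never a silent result.

Every exponential sum in the package goes through log-sum-exp. This is a
correctness requirement: reduced-potential differences of hundreds of $kT$
are routine for poorly overlapping states and would overflow naive
exponentials.

Uncertainties come from the standard asymptotic covariance of the MBAR
estimates, evaluated from the normalised weight matrix
$W_{n,k} = \exp(f_k - u_{k,n}) / \sum_j N_j \exp(f_j - u_{j,n})$ in the
spectral form $\hat\Theta = V S\, (I - S V^\top N V S)^{+} S V^\top$ with
$W^\top W = V S^2 V^\top$, which only requires $K \times K$ linear algebra.
The tests calibrate this estimate empirically: over 200 seeded repetitions of
a two-state harmonic system the replicate spread of $\hat{\Delta f}$ agrees
with the mean reported $\sigma$ within 30%.

Two simpler estimators serve as internal cross-checks, not alternatives:
exponential (Zwanzig) averaging `exp_estimate()` ($\Delta f = -\log\langle
e^{-w}\rangle$, with the Gaussian-work limit $\mu - \sigma^2/2$) and the
two-state Bennett acceptance ratio `bar_estimate()`, to which MBAR reduces
exactly at $K = 2$ — the suite asserts agreement to $10^{-7}\,kT$.

### Overlap diagnostics

`overlap_matrix()` returns the row-stochastic matrix $O_{ij} = \sum_n W_{n,i}
W_{n,j} N_j$; vanishing off-diagonals flag disjoint neighbours.
`pi_bias_measure()` implements the Wu–Kofke overlap bias measure. For the
direction that samples state $a$ and targets state $b$,

$$ \Pi_{a\to b} = \sqrt{2 \ln N_a} - \sqrt{2 s_a}, $$

where $s_a$ is the relative entropy (mean dissipated reduced work) of $a$
with respect to $b$, estimated as the mean forward work minus the BAR
free-energy difference and clamped at zero, and $N_a$ is the sample count.
The intuition: exponential estimates are dominated by the rare samples in the
important region of the target, and roughly $e^{s}$ samples are needed before
those have been seen; $\Pi$ grows with sampling and shrinks as the states
separate. The reported value is the minimum over the two directions. The
gate follows the field's convention: $\Pi < 0.5$ flags the pair as
inadequately overlapped and emits a recommendation to insert a $\lambda$
window between the two states; the boundary value 0.5 itself passes. The
measure is refused below 10 samples per state, where the asymptotic argument
behind it is meaningless.

## Replicate ensembles

`aggregate_replicates()` reduces each (transformation, condition) group of
$n \ge 2$ replicas to its mean and ensemble standard error — the sample
standard deviation with the $n-1$ denominator divided by $\sqrt n$. That
denominator convention reproduces every self-consistent printed standard
error in the packaged fixture tables, which is why it is fixed rather than
configurable. The *precision ratio*, ensemble SE over the mean per-replica
MBAR $\sigma$, quantifies how over-optimistic a single run's uncertainty is;
on the packaged studies it reaches 3.5 (bromodomain) and 7.6 (lysozyme),
with exactly one sub-unity exception in each. The denominator is the mean of
the replicate $\sigma$s (the convention that reproduces the published upper
endpoint); the function also accepts an explicit $\sigma$ if a caller wants
a different convention.

`cycle_closure()` takes a signed cycle definition, validates that the ligand
path actually closes (a step with sign $-1$ traverses its transformation
backwards), and enumerates the full Cartesian product of replicate choices in
lexicographic order — $5^3 = 125$ combinations for the packaged
three-transformation cycles. It reports the mean, extrema, the standard
deviation over all sums, and as `se` the quadrature sum of the
per-transformation ensemble SEs: that is the uncertainty of the *mean*
closure, and it is the convention that matches the published
$-1.08 \pm 0.5$ / $0.17 \pm 0.5$ / $-0.59 \pm 0.3$ values. The mean closure
is exactly the signed sum of ensemble means (linearity), which the tests
assert against brute-force enumeration.

### Does a second replica-generation protocol change the answer?

`compare_conditions()` asks whether two conditions (e.g. VIS and SIS) could
share one distribution. The observed statistic is the difference of the
condition means with SE $\sqrt{SE_A^2 + SE_B^2}$. The null model pools all
$n_A + n_B$ replicate values into one Gaussian (grand mean, pooled sample
sd); the Monte-Carlo p-value is the fraction of seeded repetitions in which
two synthetic groups of the original sizes differ at least as much in
absolute mean, and the analytic p-value is the corresponding two-sided
Gaussian tail with scale $sd\sqrt{1/n_A + 1/n_B}$. The two must and do agree
within binomial noise. The default is $10^6$ repetitions with the seed echoed
in the output; the observed threshold uses unrounded means. On the packaged
lysozyme study only the Eth$\to$Tol transformation is flagged
($0.61 \pm 0.15$ kJ/mol, $p \approx 1.3\%$); the recomputed probability is
slightly below the published rounded 1.4%, consistent with that value having
been quoted from a single stochastic run at coarser precision. The test
suite also calibrates the procedure's type-I error: on offset-free synthetic
studies it rejects at $p < 0.1$ in $\approx 10\%$ of 500 seeded repetitions.
Because the null sd is estimated from only ten values, the analytic tail is
approximate — the calibration test is the evidence that the approximation is
adequate at this design size.

## Quality against experiment

Four measures score calculated against experimental $\Delta\Delta G$s:

* **MAD** and **Max** — mean and maximum absolute signed error.
* **Bidirectional $R^2$** — the direction of a relative transformation is
  arbitrary, and plain Pearson $R^2$ depends on it; the bidirectional variant
  augments the point set with the sign-mirrored copy of every transformation.
  The augmented set has exact zero means, so $R^2 =
  (\sum xy)^2 / (\sum x^2 \sum y^2)$, which the tests verify against an
  independent `stats::cor()` route.
* **$\tau_r$** — Kendall concordance over the transformations actually
  studied (never over chained ligand pairs). Note that $\tau$ is *not*
  direction-free: it compares values across transformations, so flipping one
  transformation's sign reorders its comparisons with the others. That is
  precisely the motivation for the mirrored $R^2$; the suite asserts
  direction invariance only for MAD, Max and $R^2$, where it holds exactly.
* **$\tau_{r90}$** — the same concordance after dropping transformations
  whose calculated value is not significantly different from zero at the 90%
  level, $|x| \ge z\,SE$ with $z = 1.645$ (two-sided normal; a $t$ quantile
  would change the published inclusion pattern, so the normal quantile is the
  default and $z$ is exposed). When experimental $\sigma$s are supplied the
  same filter applies to experiment. Fewer than two survivors yields an
  undefined (`NA`) value, not an error.

Tied experimental values force a convention choice, and published tables mix
two: `ties = "count"` keeps tied pairs in the denominator ($\tau_a$ style,
reproducing the lysozyme VIS value $10/15 = 0.67$), `ties = "drop"` excludes
them (reproducing the fully concordant 1.00 values). Both are implemented
behind the explicit flag and never mixed silently.

Experimental lower bounds (the lysozyme Ben$\to$Phe affinity) are used at
face value, matching the published practice; the quality report flags them.

`quality_report()` attaches parametric-bootstrap uncertainties: each
bootstrap set perturbs every calculated value by Gaussian noise with its
supplied SE (and experimental values with their $\sigma$ where provided),
recomputes all metrics, and reports the sd over sets; the central values are
always the unperturbed point estimates. With the ensemble SEs of the
packaged lysozyme study this reproduces the published Max uncertainty
($\pm 0.4$); the published MAD uncertainty ($\pm 0.3$) is not reproducible
under any single perturbation convention we could construct (SE-based and
replicate-sd-based conventions give 0.08 and 0.18), so the suite asserts the
structural bootstrap properties and the Max uncertainty rather than that
cell.

## Solvation replicas

`solvate()` implements the overlay step whose arbitrariness SIS exploits,
with the randomness explicit: the snapshot box is rigidly rotated (uniform
quaternion rotation) and translated (uniform within one box period) under a
seeded generator, wrapped molecule-whole by minimum image on the snapshot's
cubic period, tiled to cover the target box (solute bounding box plus a
`margin` of 12 Å per axis by default, cubified), and every water with any
atom within `cutoff` of any solute atom is deleted whole. Neither the margin
nor the cull radius of typical MD setup tools is published as part of the
studies this package re-analyses; the default cutoff of 2.4 Å approximates a
heavy-atom van der Waals contact and is configurable. The post-cull clash
invariant is verified in the tests by an exhaustive distance scan, and
distinct snapshots or seeds provably change the water set — the SIS premise.
Counterion placement is out of scope; manifests record the net charge as
metadata only. `ensemble_manifest()` encodes the two protocols: VIS emits
one structure with $n$ velocity seeds, SIS emits $n$ structures (distinct
snapshot ids required) each with a fresh velocity seed, all recorded.

## Synthetic ground truth

Every stage has a generator with a known exact answer, so no MD engine or
download is needed to validate the pipeline:

* `gen_harmonic_alchemy()` — one-dimensional harmonic states
  $u_k(x) = \kappa_k (x - c_k)^2 / 2$ with exact free energies
  $f_k = \tfrac12 \log(\kappa_k/\kappa_1)$, independent of the centres. This
  exercises the estimators' actual code path (multi-state reduced-potential
  matrices) against a closed form, including translated identical states
  and evaluation-only states.
* `gen_replicate_study()` — Gaussian replicate tables around known truths
  with scatter $\sigma_{rep}$, an optional systematic offset on one
  condition (the situation the Eth$\to$Tol analysis suspects), and the
  published study design as defaults: 5 + 5 replicates, scatter 0.39 kJ/mol
  and nominal per-replica $\sigma$ 0.1 kJ/mol, matching the pooled values of
  the transformation that motivated the Gaussian simulation.
* `gen_water_box()` — rigid three-site waters (O–H 0.9572 Å, H–O–H 104.52°)
  on a jittered cubic lattice with random orientations; the default
  24.8 Å / 512-water box has density within 2% of liquid water.

What the generators deliberately do **not** emulate: autocorrelated MD time
series (samples are independent by construction), non-Gaussian replicate
scatter, force-field or sampling bias, and any water–water structure (the
boxes are geometric stand-ins with no interaction model). Passing tests
therefore demonstrate the correctness of the *analysis* — estimators,
aggregation, statistics — not the behaviour of the estimators on correlated
production data. In particular, decorrelation/subsampling of time series is
**not implemented anywhere in the package**; samples are taken as given, and
users feeding correlated trajectories must subsample upstream or expect
optimistic MBAR uncertainties (the ensemble SE over replicas, the package's
preferred uncertainty, is robust to this).

All randomness flows through one named generator (Mersenne–Twister with
inversion sampling), every generator records its seed, and `run_study()`
expands a single top-level seed deterministically per stage and embeds every
stage seed in its report, so full reports are byte-stable under a fixed
seed.

## Numerical choices and degenerate inputs

* MBAR: deterministic initialisation at $f = 0$; tolerance $10^{-8}\,kT$ on
  the maximum residual; states with zero samples are allowed as
  evaluation-only states; a sampled state with zero effective weight makes
  the covariance singular and is reported by name.
* BAR: monotone one-dimensional root, bracketed by the two one-directional
  exponential estimates and expanded geometrically if needed.
* Identical replicate values give SE exactly 0; a zero mean $\sigma_{MBAR}$
  makes the precision ratio an error (division by zero), not `Inf`.
* Exactly tied experimental values are the reason for the `ties` flag; ties
  in *calculated* values (measure-zero for real data) follow the same
  convention.
* Unit boundary: estimators work and report in dimensionless $kT$;
  conversion to kJ/mol happens only at the reporting layer via
  `kt_to_kjmol()` with a configurable temperature defaulting to 300 K, the
  production temperature of the fixtures' studies.

## Problem sizes used by the test suite

The suite validates the estimators at sizes chosen to make the statistical
assertions sharp but quick: harmonic-oracle recovery at $5\times 10^4$
samples per state, the 100-repetition 4$\sigma$ recovery sweep at 5000
samples per state, uncertainty calibration over 200 seeds at 1000 samples
per state, the Gaussian-limit checks at $2\times 10^5$ work samples, the
Eth$\to$Tol Monte-Carlo probability at $10^6$ repetitions and the type-I
calibration over 500 synthetic studies. These are the package's own
validation choices; all are parameters, and nothing in the implementation
depends on them.

## Known limitations

* No decorrelation or equilibration detection (see above).
* $\tau_r$ inherits the direction dependence of relative values; report it
  together with the transformation directions used.
* The Gaussian null of `compare_conditions()` estimates its sd from the
  pooled replicates; at 5 + 5 replicates the analytic tail is mildly
  approximate (the Monte-Carlo route shares the same null by construction).
* Water boxes and solvated systems are geometric starting structures, not
  equilibrated ensembles; no topology or parameter files are produced.
* Quality metrics score relative ($\Delta\Delta G$) predictions only;
  absolute-affinity scoring and hierarchical pooling across transformations
  are out of scope.
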