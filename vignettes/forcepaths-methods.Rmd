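---
title: "Methods: unfolding kinetics and force-propagation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unfolding kinetics and force-propagation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcepaths)
library(dplyr)
```

`forcepaths` implements the two computational arms of a single-molecule
protein-mechanics analysis: (1) extraction of unfolding kinetics from AFM
force-extension curves — peak detection, worm-like-chain (WLC) fitting,
contour-length increments, kernel-density most-probable forces, Bell–Evans
dynamic force spectroscopy, Arrhenius barrier heights — together with a
Monte-Carlo pulling simulator that generates synthetic datasets with known
ground truth; and (2) dynamic-network analysis of residue trajectories —
occupancy-filtered contact networks weighted by motion correlations,
centrality profiles, and enumeration of optimal and suboptimal
force-propagation paths, with a correlated-trajectory generator standing in
for steered-MD output.

The scientific context is the comparison of two pulling geometries for a
multidomain adhesion protein: *handle-assisted pulling* (HAP), where the
molecule is pulled directly via a terminal handle, and *partner-assisted
pulling* (PAP), where force arrives through a bound partner protein. The two
geometries produce distinct unfolding fingerprints (a long ~75 nm initial
entropic stretch and a preference for long ~24.5/33 nm increments in HAP; a
short ~6.5 nm initial stretch and a preference for the ~6.5 nm increment in
PAP) and distinct kinetic parameters per increment class.

## The mechanical model

### Worm-like chain

A stretched polypeptide at extension $x$ with contour length $L_c$ and
persistence length $p$ resists with the Marko–Siggia interpolation force

$$F(x) = \frac{k_B T}{p}\left[\frac14\left(1-\frac{x}{L_c}\right)^{-2} -
\frac14 + \frac{x}{L_c}\right],$$

zero at $x = 0$ and divergent as $x \to L_c$ (`wlc_force()`). Forces are in
pN and lengths in nm throughout; $k_B T = 4.114$ pN nm at the default
298 K (the temperature is configurable everywhere; the data this mirrors
were recorded near room temperature).

In a constant-velocity AFM experiment the piezo position $z$ is shared
between the chain extension and the cantilever deflection,
$x + F/k_c = z$; `solve_force_balance()` finds the unique root by
safeguarded Newton iteration (tolerance $10^{-9}$ pN on the residual; the
WLC divergence guarantees a solution with $x < L_c$ for any finite $z$).

### Bell kinetics and the pulling simulator

Each unfolding unit (a domain, linker, or partial-unfolding intermediate)
carries Bell kinetics: at force $F$ it unfolds at rate
$k(F) = k^0_u\,e^{F x_\beta / k_B T}$, where $k^0_u$ is the zero-force
unfolding rate (lifetime $\tau = 1/k^0_u$) and $x_\beta$ the distance to
the transition state. `simulate_curve()` advances the piezo by $v\,\Delta t$
per step, solves the force balance, and unfolds each still-folded unit with
probability $1 - e^{-k(F)\Delta t}$ (force held constant within a step).
An unfolding event adds the unit's $\Delta L_c$ to the chain contour
length, producing the sawtooth. Recorded force adds i.i.d. Gaussian noise
(default SD 5 pN); no drift or 1/f component is modelled. If the expected
per-step unfolding probability exceeds 0.1 anywhere, the curve is flagged
as undersampled. The default sampling rate is 10 kHz; the simulation
studies below use a fixed piezo step of 0.025 nm (sampling rate $v/0.025$)
so that this hazard bound holds across the whole 500–5000 nm/s velocity
ladder.

The default synthetic datasets (`dataset_config()`, `generate_dataset()`)
emulate the study conditions: velocities 500, 1000, 2000, 3000, 5000 nm/s,
a ~30 pN/nm cantilever (the class of cantilever used; the study does not
print its spring constants), persistence length 0.5 nm for unfolded
polypeptide, and per-mode increment classes with the published kinetic
parameters — HAP classes at 6.4/15.8/24.5/33.7 nm and PAP classes at
6.5/16.9/24.6/33.2 nm, each with its $\tau$ and $x_\beta$ from the
corresponding kinetic table. Class weights default to (0.10, 0.20, 0.30,
0.40) for HAP and (0.50, 0.20, 0.20, 0.10) for PAP, reproducing the
published direction of the geometry contrast (the study prints the
probability distributions only graphically); the initial contour length
defaults to 75 nm (HAP spacer) and 6.5 nm (PAP). A construct is assembled
per curve by sampling `n_units` units from the class weights, so dataset
class frequencies are binomial around the configured weights.

What the generator does *not* emulate: surface-chemistry failure modes,
multiple tethers, baseline drift, the approach/dwell contact phase, and
refolding. Passing recovery tests on this generator therefore demonstrates
correctness of the analysis pipeline under the modelled physics, not
robustness to every experimental artifact.

## Curve analysis

`detect_unfolding_peaks()` smooths the force with an 11-sample moving mean
and calls a rupture wherever a smoothed local maximum above
`min_peak_force` (default 20 pN) is followed within 5 nm of extension by a
drop of at least `min_drop` (default 20 pN). The rupture index is then
refined on the *raw* trace as the largest single-step force drop near the
candidate — the unfolding discontinuity dwarfs the noise, which makes the
refined index exact to a few samples. All detection parameters are exposed
because the original study's criteria are unpublished.

Each inter-rupture rising stretch is fitted with the WLC by bounded
Levenberg–Marquardt (`fit_wlc_segment()`; $p \in [0.1, 2]$ nm, $L_c$
initialised at 1.1× the largest extension and bounded just above it). The
per-event unfolding force is the fitted WLC force evaluated at the rupture
extension — forces are read off the model fit, not the noisy raw maximum.
A fit with the persistence length pinned at a bound is flagged.

Contour-length increments are differences of consecutive fitted contour
lengths; increment $i$ (released by rupture $i$) is paired with event $i$'s
force, and the last event of a curve — which has no following fit — stays
unclassified. Negative increments are retained but flagged and excluded
from histograms by default. The *initial stretch* of a curve is defined
operationally as the fitted contour length of its first peak; the study
text does not pin down its convention, and this definition reproduces the
~75 nm (HAP) vs ~6.5 nm (PAP) contrast directly.

Classification assigns each increment to the nearest class centre (defaults
6.5, 16, 24.5, 33 nm), with exact midpoints going to the lower centre and
increments farther than 5 nm from every centre left `"unclassified"`. The
documented two-pass workflow re-fits centres from the Gaussian-mixture
histogram (`fit_gaussian_mixture_hist()`) and re-classifies.

## Distributions and kinetics

### Histogram mixtures

`fit_gaussian_mixture_hist()` fits a sum of $K$ Gaussians to histogram bin
counts by bounded least squares, mirroring the "Gaussian fits to the
histogram" convention rather than raw-data EM; Freedman–Diaconis binning is
the default and overridable. Standard errors of the component means come
from the fit covariance.

### Most probable force

Rupture-force samples per (mode, class, velocity) are summarised by the
mode of a Gaussian-kernel KDE whose bandwidth follows the rule

$$H = 1.06\,n^{-1/5}\,\sigma,\qquad
\sigma = \min\{\sigma_x,\ \mathrm{IQR}/1.34\},$$

with $\sigma_x$ the sample SD ($n-1$ denominator) and quartiles by linear
interpolation (R type 7). Both conventions are stated because the numeric
value depends on them; for the sample $\{1,2,3,4,5\}$ the rule gives
$H = 1.147$. The density is evaluated on a 512-point grid extended four
bandwidths beyond the sample range — four rather than three so the grid
captures essentially all kernel mass and the density normalizes to 1
within $10^{-3}$; exact density ties break to the lower force. A
zero-spread sample falls back to a nominal bandwidth with a warning.

### Bell–Evans fitting

The most probable force grows logarithmically with loading rate
($LR = k_c v$),

$$F_{mp} = \frac{k_B T}{x_\beta}
\ln\frac{LR\,x_\beta}{k^0_u\,k_B T},$$

which is exactly linear in $\ln LR$. `fit_bell_evans()` therefore uses
linear regression (slope $a = k_B T / x_\beta$, intercept $c$ giving
$k^0_u = e^{-c/a}/a$), which shares its optimum with the nonlinear fit but
has closed-form standard errors, propagated to $(k^0_u, \tau, x_\beta)$ by
the delta method. Per-point $1/\mathrm{SE}^2$ weighting is available but
off by default (the study does not state weighting). A non-positive slope
raises an error rather than returning unphysical parameters.

Barrier heights use the Arrhenius relation
$\Delta G^* = -k_B T \ln(k^0_u / A)$ with prefactor $A = 10^9\,s^{-1}$
(the standard protein-dynamics attempt frequency, configurable), reported
as a multiple of $k_B T$. The critical force is
$F_C = \Delta G^* / x_\beta$. **A units caveat:** the published tables
divide the $k_B T$-multiple of $\Delta G^*$ by $x_\beta$ in nm and label
the result pN, implicitly treating $k_B T$ as numerically 1 pN nm. The
package reproduces this printed convention by default (verified
self-consistent across all eight published rows) and provides the
physically dimensioned value (× 4.114 pN nm) behind
`physical_units = TRUE`. Relatedly, the published $F_C$ column derives
from the *rounded* one-decimal $\Delta G^*$; `kinetic_table()` uses the
unrounded value, so its $F_C$ can differ from print by up to ~0.6 table
units.

## Simulation studies and their design

Two properties of the faithful WLC + Bell simulation shape any recovery
benchmark, and both are worth stating because they are real physics, not
artifacts:

* **Slack-phase attrition.** With lifetimes of tens of milliseconds
  (published values are $\tau \approx 0.01$–$0.06$ s), units unfold at
  near-zero force whenever the chain is slack — during the initial
  entropic approach and after each rupture — at rates comparable to the
  inverse of the time the piezo needs to re-tension the chain. Such events
  produce no detectable force peak. They deplete event counts at low
  velocities and hide short increments behind merged contour-length jumps.
* **Compliance-limited loading.** The nominal loading rate $k_c v$
  overstates the true $\dot F$ at rupture whenever the WLC stiffness is
  comparable to $k_c$; fitted rates then absorb the ratio, shifting
  $\ln k^0_u$ by $\ln(k_c/k_\mathrm{eff})$.

The kinetics-recovery benchmark (300 curves at each of the five velocities,
30 pN/nm cantilever, truth $\tau = 0.061$ s, $x_\beta = 0.074$ nm — the
~33 nm PAP class) therefore uses the standard calibration design of
experimental force spectroscopy: a short construct with one unit of
interest plus one mechanically stable *marker* domain
($k^0_u = 0.1\,s^{-1}$, $x_\beta = 0.1$ nm) and a 5 nm entropic stub. The
marker survives to far higher forces, so the unit of interest is the first
detected rupture and its increment is measured against the marker's fitted
contour length; a construct with two *identical* units under load would
instead shift the first-rupture force mode down by
$(k_B T/x_\beta)\ln 2 \approx 38$ pN (rupture-race statistics), and a long
chain would add the compliance shift. With this geometry the pipeline
recovers $x_\beta$ to within ~10% and $\ln \tau$ to within ~0.2 at the
benchmark's sample sizes, comfortably inside the acceptance bands (15% and
0.7).

The geometry-contrast study (40 curves per mode) runs at the top of the
velocity ladder (5000 nm/s) because the long HAP spacer plus fast published
rates otherwise push most events below the detection floor; at that
velocity both modes yield classified events and the PAP-vs-HAP preference
for the ~6.5 nm class is recovered through the full pipeline as well as in
the generator's ground-truth logs.

Problem sizes in the test suite and the acceptance script (300 curves per
velocity for kinetics recovery, 40 per mode for the contrast, 100 seeds
for noisy WLC round-trips, 50 random graphs for shortest-path oracles)
were chosen as the package's own benchmark conditions; they keep each
study's Monte-Carlo error well inside the tolerance it is checked against.

## Dynamic networks

### Construction

Residue nodes are alpha carbons. An edge joins residues whose heavy atoms
come within 4.5 Å in at least 75% of trajectory frames (`contact_edges()`);
sequence neighbours are excluded because they always touch and only add
trivial paths. For reduced, CA-only trajectories (all synthetic fixtures)
the criterion is necessarily a CA–CA distance, with a larger 8 Å default
cutoff as the documented proxy.

Edges are weighted from the displacement cross-correlation
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$
(`correlation_matrix()`; frames may first be superposed on the mean
structure — whether the original trajectories were superposed is not
stated, so it is a flag). The weight is $w_{ij} = -\log|C_{ij}|$, the
convention of the dynamical-network tooling the study used, which the
study itself does not print: strongly correlated contacts make short
edges, so shortest paths follow chains of correlated motion. Both choices
are recorded here as design decisions.

### Centralities and paths

Closeness is $(n_\mathrm{reach}-1)/\sum_j d(i,j)$ on weighted
shortest-path distances (isolated nodes score 0); betweenness is standard
equal-splitting shortest-path betweenness normalized by $(n-1)(n-2)/2$,
computed via igraph's Brandes implementation and cross-checked against
closed forms on path and star graphs in the tests.

All-pairs distances use Floyd–Warshall with a next-hop matrix
(`all_pairs_shortest_paths()`), validated against per-source Dijkstra.
`suboptimal_paths()` enumerates *all* simple source→sink paths whose total
weight is within `offset` of the optimum, by depth-first search pruned
with the exact remaining-distance bound, in deterministic order. The
study describes its suboptimal path set as "within 20 nodes of the optimal
path", which is ambiguous between a weight tolerance and a node budget;
the package exposes a weight `offset` as the primary control and a
`max_nodes` cap behind a flag, claiming neither as the original intent. A
configurable path-count cap (default $10^4$) aborts runaway enumerations
with advice to reduce the offset.

`merge_path_sets()` unions path sets from several pulling points onto a
common sink — the multipoint-pulling analysis — summing per-node
participation and keeping per-source provenance. On the package's fixture
networks (three chains converging on a sink) the merged set covers
strictly more nodes than any single-source set, the fixture-level version
of the claim that spatially distributed pulling spreads force propagation
over more of the structure. Frame selection (e.g. truncating a trajectory
at the first domain unfolding) is left to the caller: the module analyses
whatever frames it is given.

## Numerical choices and degenerate inputs

* Force-balance solver: warm-started safeguarded Newton, residual
  tolerance $10^{-9}$ pN, bisection fallback; non-convergence is an error,
  never a silent result.
* WLC fits: error on non-convergence (carrying the message), warning when
  $p$ pins at a bound; segments shorter than 8 samples are not fitted.
* KDE: zero-spread samples fall back to a nominal bandwidth with a
  warning; the returned grid argmax ties to the lower force.
* Mixture fits: amplitudes bounded at 0, component SDs bounded below at a
  tenth of the bin width; a component collapsing below half the bin width
  triggers a warning.
* Correlation: zero-variance residues get zero off-diagonal correlation
  with a warning; edges with exactly zero correlation are dropped (infinite
  weight) with a warning.
* Increment classification: exact midpoint ties go to the lower centre
  (deterministic), outlier radius 5 nm.
* Seeds: every stochastic generator takes an explicit integer seed and is
  bit-reproducible given it.

## Known limitations

* The simulator's Bell hazard has no force-history or rebinding effects
  and a single persistence length for all states; it cannot reproduce
  refolding, unfolding intermediates within a class, or anticorrelated
  noise.
* KDE mode estimation on skewed rupture-force distributions carries a
  downward bias of order the bandwidth; it is part of the mirrored method,
  not corrected.
* The printed-table $F_C$ convention is dimensionally loose (see above);
  the package reproduces it deliberately.
* Slack-phase unfolding means event *counts* from simulated datasets
  underestimate the configured number of units at low velocities; analyses
  that need complete event recovery should use the calibration geometry or
  high velocities.
* Suboptimal-path enumeration is exponential in the offset; the path cap
  makes this fail loudly rather than hang.
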