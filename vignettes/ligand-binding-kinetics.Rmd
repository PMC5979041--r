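---
title: "Inferring ligand binding kinetics with Markov state models, transition path theory and biased sampling"
author: "ligandMSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ligand binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandMSM)
```

# The scientific problem

A small hydrophobic ligand binds a buried, solvent-inaccessible protein
cavity surprisingly fast (on-rates of order 10^6 M^-1 s^-1 for benzene
binding the engineered cavity of a lysozyme mutant). Quantifying how fast,
along which pathways, and over what barriers requires turning raw
trajectory data into a kinetic model: a Markov state model (MSM) over
conformational microstates, coarse-grained into a handful of metastable
macrostates (unbound bulk state, gateway intermediates, bound state), from
which mean first passage times (MFPTs), rate constants, binding free
energies, committors and reactive fluxes follow.

ligandMSM implements that whole inference chain, together with two biased
free-energy methods that complement it — umbrella sampling with WHAM
reconstruction of a potential of mean force (PMF), and infrequent
well-tempered metadynamics with acceleration-factor rescaling of escape
times — and a synthetic-data module that generates trajectories with known
ground truth so every stage can be verified end-to-end without molecular
dynamics input.

# The model-building chain

## Featurization

Trajectory frames are converted to binary ligand–residue contact indicators
(1 when the minimum heavy-atom distance between the ligand and a residue is
at most 0.5 nm). The binding pocket is the set of protein heavy atoms
within 0.5 nm of the bound ligand in a holo reference structure; the
pocket–ligand distance is the distance between mass-weighted centroids.
Bound-state labelling requires the pocket RMSD (after optimal rigid-body
superposition, computed by the SVD construction with the proper rotation
enforced) to stay at or below 0.5 nm *and* the pocket–ligand distance at or
below 0.2 nm continuously for at least 100 ns. All thresholds are
inclusive; this is a deliberate choice so boundary cases are deterministic.
Whether a contact feature should be a binary indicator or a distance is not
uniquely determined by the criterion it implements; the binary choice is
flagged in the documentation, and the distance series remain available
through `pocketLigandDistance()`.

## tICA

Time-lagged independent component analysis estimates the mean-centred
instantaneous covariance $C_0$ and symmetrized time-lagged covariance
$C_\tau$ at a correlation lag (default 20 ns) and solves
$C_\tau v = \lambda C_0 v$. Symmetrization guarantees a real spectrum; a
diagonal regularization $\varepsilon = 10^{-10}\,\mathrm{tr}(C_0)/d$ keeps
the problem well-posed for rank-deficient binary contact features. The
kinetic variance fraction of component $i$ is
$\lambda_i^2/\sum_j \lambda_j^2$ over the positive spectrum. Both selection
rules are supported: a fixed component count, or the smallest count whose
cumulative kinetic variance reaches a threshold (default 0.95). For the
low-dimensional synthetic features used by the bundled benchmark the
pipeline keeps all three components by default; the variance rule is
intended for high-dimensional contact featurizations, where rare-state
processes can carry a tiny share of the kinetic variance and the fixed
count is the safer choice.

## Discretization

k-means (default 100 clusters) with a seeded k-means++ initialization,
Lloyd refinement, nearest-centre tie-breaks to the lowest index, and
re-seeding of empty clusters from the farthest point. These determinism
details are part of the contract: the same seed reproduces the same
discretization bit-for-bit.

## MSM estimation

Sliding-window transition counts at the model lag (default 10 ns) are
restricted to the largest connected set of the symmetrized count graph,
then the reversible maximum-likelihood transition matrix is found by the
standard self-consistent fixed point on symmetric pair counts
$x_{ij} \leftarrow (c_{ij}+c_{ji})\,/\,(c_i/x_i + c_j/x_j)$, iterated until
the transition-matrix change falls below $10^{-10}$. Detailed balance then
holds by construction, the spectrum is real, and the stationary
distribution is $\pi_i = x_i/\sum x$. Lag choice is validated by implied
timescales $t_i(\tau) = -\tau/\ln\lambda_i(\tau)$ levelling off in $\tau$.
Convergence can be slow (hundreds of thousands of sweeps) when populations
span five orders of magnitude, which is why the default iteration cap is
high; non-convergence is an error, never silently accepted.

## Coarse-graining

Macrostate memberships are initialized by PCCA+ (the inner-simplex
spectral variant) and refined by Baum–Welch estimation of a
discrete-emission hidden Markov model: each hidden macrostate emits
microstate indices from a categorical distribution. This emission structure
is simpler than projected-HMM variants but does real work here: microstate
assignments carry misassignment noise wherever feature distributions
overlap, and at the microstate level that noise appears as spurious fast
exchange that biases the slowest implied timescale downward (by roughly a
factor of two on the bundled benchmark). The HMM absorbs it into the
emission probabilities, and the coarse transition matrix recovers the true
slowest relaxation to within a few percent. Populations come from the
stationary distribution of the refined coarse matrix; lifetimes are
$\tau/(1-\tilde T_{kk})$. EM runs at a fixed iteration cap with a
log-likelihood convergence tolerance of $10^{-8}$, and a decrease of the
likelihood is treated as an implementation bug, not a warning.

# Kinetics and thermodynamics

With bound and unbound macrostates identified (most populated = bound;
longest-lived of the rest = unbound — in a binding system the bulk state
outlives gateway intermediates by orders of magnitude), the package
computes:

* MFPTs by solving $(I - T_{CC})\,m = \tau\,\mathbf 1$ over the complement
  of the target set, averaging over the source set with stationary weights
  (uniform weighting available), so indirect routes through intermediates
  are included;
* $k_{\mathrm{on}} = 1/(\mathrm{MFPT}_{\mathrm{on}}\,C)$ and
  $k_{\mathrm{off}} = 1/\mathrm{MFPT}_{\mathrm{off}}$ at ligand
  concentration $C$ (default 9.55 mM);
* $\Delta G = -k_BT\ln(\pi_{\mathrm{bound}}/\pi_{\mathrm{unbound}})$ and
  its 1 M standard-state counterpart
  $\Delta G^0 = \Delta G + RT\ln(C/1\,\mathrm{M})$. This standard-state
  convention reproduces the worked example (−6.9 kcal/mol from populations
  99.83%/0.11% at 9.55 mM and 303 K) and is therefore adopted;
* activation barriers from transition path times via
  $k_{\mathrm{off}} = (1/\tau_{\mathrm{TPT}})e^{-\Delta G^*/RT}$ and the
  cycle $\Delta G^*_{\mathrm{bind}} = \Delta G_{\mathrm{bind}} +
  \Delta G^*_{\mathrm{unbind}}$;
* uncertainties by trajectory-level bootstrap (default 100 replicates,
  seeded); the error model behind published ± values is rarely stated, and
  resampling whole trajectories is the assumption-light choice.

Transition path times are extracted from an order-parameter series by a
two-threshold rule: a segment starts at the first frame after leaving the
origin region (e.g. ligand–cavity distance at or above 0.6 nm) and ends at
the first frame inside the destination region (at or below 0.38 nm);
excursions within the intermediate region are absorbed, and re-entering the
origin region aborts the segment. Re-crossing handling is not uniquely
implied by the two thresholds; breaking segments only on origin re-entry is
this package's documented convention.

# Transition path theory

Committors solve the discrete Laplace system with exact 0/1 boundary
values; backward committors use the time-reversed chain (equal to
$1-q^+$ for reversible models). Reactive fluxes
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$ are checked for conservation at every
intermediate state (a residual above $10^{-8}$ of the total flux is an
error). Pathways are extracted greedily: repeatedly find the
maximum-bottleneck path through the net flux, subtract its bottleneck, stop
when the residual falls below 1% of the total. Greedy subtraction is the
common convention; its order-dependence means overlapping pathways can
trade flux, which is why pathway fractions should be read as a ranked
decomposition, not unique physical probabilities.

# Biased sampling

## Umbrella sampling and WHAM

Windows restrain the collective variable with a harmonic spring (default
8000 kJ/mol/nm², converted internally to kcal/mol), spaced 0.05 nm apart
and sampled for 20 ns each. WHAM iterates the standard self-consistency
between unbiased bin probabilities and window free-energy shifts until the
maximum relative shift change falls below $10^{-8}$; the PMF is pinned to
zero at its minimum and reported only on populated bins. The default bin
width is half the window spacing. Numerical caveats that matter at this
spring stiffness: the overdamped integrator needs
$\mathrm{d}t\,k/\gamma \ll 1$ (the package default for window harvesting
uses $\mathrm{d}t = 2\times10^{-6}$ ns, giving 2% variance inflation
instead of 23% at a coarser step), and the coarse default binning carries a
discretization floor of order 0.1 kT — profiles converge to the analytic
potential only once bins resolve the window width.

## Infrequent metadynamics

Well-tempered hills (start height 1.2 kJ/mol, bias factor Γ = 6, width
0.025 CV units by default, deposition every 10 ps) accelerate escape from
the bound basin; the run stops when the CV crosses the escape threshold.
The acceleration factor $\alpha = \langle e^{V(s,t)/k_BT}\rangle_t$ is
accumulated with the bias evaluated at the current position *before* any
deposition at that step, consistent with keeping transition states
relatively bias-free; rescaled escape time = simulated time × α. Escape
times are then subjected to the Poisson reliability analysis: an
exponential fit by maximum likelihood and a Kolmogorov–Smirnov test with
the asymptotic p-value. Estimating the mean from the same sample inflates
the p-value somewhat; that is the common usage of this check and is
documented rather than corrected. Censored (non-escaping) runs are
reported but excluded from the fit. A printed hill width of 0.025 Å for a
nm-scale distance coordinate appears in the methodological literature this
implements; that value is implausibly small for such a coordinate, so the
width is configurable with a documented default of 0.025 nm on the toy
landscape.

# The synthetic benchmark

`benchmarkNetwork()` is a four-state kinetic network (unbound bulk MS0,
gateway intermediates MS1/MS2, bound MS3) with exact stationary, MFPT and
committor oracles (`ctmcOracle()`). Its stationary populations are
0.11%, 6.4×10⁻³%, 4.7×10⁻²% and 99.83%, and the MS0/MS1/MS2 lifetimes are
2600, 69 and 742 ns. Those eight numbers plus detailed balance
overdetermine a four-state network, so the remaining freedom is fixed by
making MS1 commit to the bound state with probability 0.8 and giving the
direct MS0→MS3 channel a modest share of the flux; the bound-state
lifetime then comes out near 7.5×10⁵ ns and MS2's committor near 0.78.
These last two quantities are artifacts of that choice, which is why
pathway-split percentages are validated against exhaustive enumeration on
toy networks rather than against any particular published split.

The default pipeline ensemble mirrors an adaptive-sampling study design: 12
long runs of 5×10⁵ ns started in the bulk and bound states plus 400 short
runs of 10⁴ ns seeded in the gateway intermediates, at 10 ns frames (10⁶
frames total). The seeding matters: states with equilibrium weight
~6×10⁻⁵ would otherwise contribute so few frames that k-means would never
allocate them a centre. The reversible estimator recovers equilibrium
populations from the transition statistics regardless of the biased start
distribution. Gaussian state-conditioned emissions (spread 0.25 nm around
well-separated 3D centres) emulate metastable observables; they do not
emulate slow within-state relaxation, anisotropic or multimodal state
densities, or measurement noise correlated in time — so passing recovery
tests demonstrates the correctness of the estimators, not robustness to
every pathology of real trajectories.

What the tests demonstrate at these problem sizes (chosen as desk-scale
study conditions): macrostate populations are recovered within
trajectory-bootstrap uncertainty; on- and off-rates within a factor 1.5 of
the oracle (median over three seeds — the off-rate rests on only ~11
unbinding events per 10⁶ frames, so per-seed scatter is ~30%); the slowest
relaxation time within 10%; WHAM PMFs within 0.2 kT RMSD of the analytic
double well; and median rescaled metadynamics escape times within a factor
2 of brute-force unbiased escape times over 15 runs.

# Units, seeds and conventions

Internally: time in ns, length in nm, energy in kcal/mol,
$k_B = 0.0019872041$ kcal/mol/K, default temperature 303 K; kJ/mol inputs
are converted by 1 kcal = 4.184 kJ. Rates are reported in 1/s and
1/(M·s). Discretization of jump processes is point sampling on the frame
grid (the state occupied at each grid time), matching how simulation
frames are saved. State indices are 1-based throughout the R interface.
Ensembles derive one seed per trajectory from a master seed via
`derivedSeed()` (a fixed affine counter scheme), so ensembles are
reproducible as a whole and members are independent streams.

# Known limitations

* The HMM lag, initialization and emission structure of published
  coarse-grainings are usually unspecified; this package's choices
  (PCCA+ init, categorical emissions) are explicit and recorded in the
  model objects, but other variants can give somewhat different fuzzy
  memberships.
* Greedy max-bottleneck pathway decomposition is order-dependent where
  pathways overlap.
* The MFPT of a lag-discretized chain systematically exceeds the
  continuous-time MFPT by roughly $\mathrm{MFPT}\times P(\text{target
  dwell} < \tau)$, because point sampling misses visits shorter than the
  lag — material when target lifetimes approach the lag.
* No Chapman–Kolmogorov test beyond implied-timescale plateaus; no
  Bayesian MSM posterior sampling; no MBAR alternative to WHAM; no
  multi-dimensional metadynamics CVs.
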