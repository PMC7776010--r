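---
title: "Orientation-resolved relaxation-diffusion fibre metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-resolved relaxation-diffusion fibre metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfibre)
```

## The signal model

`rdfibre` analyses MRI data acquired with multidimensional (tensor-valued)
diffusion encoding at multiple echo times. A heterogeneous voxel is modelled
as a collection of microscopic water environments, each with an effective
transverse relaxation rate $R_2$ and an axisymmetric apparent diffusion
tensor parameterised by its axial and radial diffusivities
$(D_\parallel, D_\perp)$ and orientation $(\theta, \phi)$. Writing
$D_\mathrm{iso} = (D_\parallel + 2 D_\perp)/3$ and
$D_\Delta = (D_\parallel - D_\perp)/(3 D_\mathrm{iso}) \in [-1/2, 1]$, the
signal of one environment under an axisymmetric b-tensor of trace $b$,
normalised anisotropy $b_\Delta$ and symmetry axis at angle $\beta$ from the
tensor axis, measured at echo time $\tau_E$, decays as

$$
K = \exp(-\tau_E R_2)\,
\exp\!\left(-b D_\mathrm{iso}\left[1 + 2 b_\Delta D_\Delta
P_2(\cos\beta)\right]\right),
\qquad P_2(x) = \tfrac{3x^2 - 1}{2}.
$$

The voxel signal is a weighted sum over environments,
$\mathbf{s} = \mathbf{K}\mathbf{w}$, where column $n$ of $\mathbf{K}$
evaluates the kernel for one discrete configuration
$(R_{2,n}, D_{\parallel,n}, D_{\perp,n}, \theta_n, \phi_n)$ and
$\mathbf{w} \ge 0$ holds signal fractions. The weights absorb the
unweighted amplitude $S_0$; no separate $S_0$ fit is performed. Because
every orientation carries its own $(R_2, D_\mathrm{iso}, D_\Delta)$, no
common response kernel across fibre populations is assumed: crossing
bundles may have different relaxation and diffusion properties, which is
precisely the information the package extracts.

The built-in acquisition table (`default_shells()`, expanded by
`default_protocol()`) is a 666-point 5D protocol with Stejskal-Tanner
shells at $\tau_E = 60$ ms (b up to $2\times10^9$ s m$^{-2}$) and 80 ms
(up to $4\times10^9$), plus linear, prolate, spherical and planar b-tensor
shells ($b_\Delta = 1, 0.5, 0, -0.5$) repeated at $\tau_E = 80, 110,
150$ ms. Each printed shell row lists one more b-value (a leading
$b = 0$) than direction counts; the builder acquires $b = 0$ once per
repetition and lets the first printed count cover $b = 0$ plus the first
non-zero shell, which reproduces every printed row total exactly. The in
vivo session additionally contains a few reversed-blip $b = 0$ volumes
for distortion correction (a 686-volume session in total); these carry no
additional encoding and are not part of the analysis table.

## Monte-Carlo inversion

Estimating $\mathbf{w}$ from a noisy $\mathbf{s}$ is a severely
ill-conditioned nonnegative inverse problem. Instead of imposing
smoothness or sparsity penalties, the package explores the solution space
with a two-cycle Monte-Carlo scheme around a Lawson-Hanson non-negative
least-squares (NNLS) core (compiled; `nnls_fit()`):

* **Proliferation** (`proliferate()`): for each of $N_p = 20$ rounds,
  $N_\mathrm{in} = 200$ fresh candidates are drawn uniformly in
  $(\log_{10} R_2, \log_{10} D_\parallel, \log_{10} D_\perp, \cos\theta,
  \phi)$ over the box $0 < \log_{10}(R_2/\mathrm{s^{-1}}) < 1.5$,
  $-11.3 < \log_{10}(D/\mathrm{m^2 s^{-1}}) < -8.3$ (both eigenvalues),
  $0 < \cos\theta < 1$, $0 < \phi < 2\pi$; survivors of the previous
  round are appended, NNLS is solved, and only non-zero-weight components
  are kept. The residual is non-increasing because each pool contains the
  previous support.
* **Mutation** (`mutate()`): for each of $N_m = 20$ rounds the current
  components are duplicated, the duplicates perturbed by additive
  Gaussians in the sampling coordinates (standard deviation
  `mutation_scale` = 5% of each interval width, clipped to the box), and
  originals and mutants compete through a joint NNLS on their union: the
  solver's weights decide which copy survives. We deliberately implement
  the competition through the union fit rather than a whole-set
  accept/reject: a joint perturbation of all coordinates of ~30
  components is almost never an improvement as a block, so a literal
  accept/reject mutation stalls (on a noiseless two-fibre signal it
  leaves the relative residual two orders of magnitude higher over the
  same 20 rounds), while the union fit lets each favourable move be
  adopted independently and keeps the residual monotone.

The final solution keeps the $N = 20$ highest-weight components,
refitting their weights by NNLS (`solve_voxel()`). Per-voxel uncertainty
comes from `bootstrap_invert()`: $N_b$ resamples of the $M$ measurements
with replacement (default 96; the in-silico validations use 16), each
solved independently with a sub-seed derived from the top-level seed by
counter-based mixing, so results do not depend on evaluation order.
Resampling is unrestricted over the $M$ measurements by default -- the
straightforward reading of "bootstrap with replacement" -- with a
stratified per-shell mode available. The fixed round counts
$(N_p, N_m)$ are the stopping rule; no explicit noise-floor test is
applied. Weights below $10^{-12}$ of the maximum are treated as
numerical zeros of the NNLS active set.

## Bins and the fibre subset

Components are classified in
$(\log_{10} D_\parallel/D_\perp, \log_{10} D_\mathrm{iso}, \log_{10} R_2)$
space into three disjoint open boxes (`default_bins()`): *thin*
(elongated, fibre-like; ratio $10^{0.6}$-$10^{3.5}$, $D_\mathrm{iso}$
$10^{-10}$-$10^{-8.7}$ m$^2$s$^{-1}$), *thick* (low anisotropy,
grey-matter-like) and *big* (fast-diffusing, CSF-like), all with
$-0.5 < \log_{10}(R_2/\mathrm{s^{-1}}) < 2$. All logarithms are base 10,
which puts the sampling box at physically sensible decade scales
($R_2 \in [1, 31.6]$ s$^{-1}$, $D \in [5\times10^{-12},
5\times10^{-9}]$ m$^2$s$^{-1}$). Intervals are open as printed: a
component exactly on a boundary belongs to no bin. The Monte-Carlo
sampler cannot produce $D_\perp = 0$, but simulator input can, so an
infinite eigenvalue ratio is clipped to $\log_{10}$ ratio $\pm 3$ (the
sampling-box edge) before classification. Per-voxel bin weight fractions
(medians over bootstraps; `bin_fraction_maps()`) and in-bin
weight-weighted metric means (`bin_parameter_means()`) reproduce the
standard bin-resolved maps; $f_\mathrm{thin}$ is normalised by total
ensemble weight.

## From thin components to ODFs

The thin subset of each bootstrap solution (`thin_subset()`) is mapped to
a smooth orientation distribution function by kernel density estimation
on the sphere with an antipodally symmetric Watson kernel
(`odf_single()`):

$$
P(\mu) = \sum_{i \in \mathrm{thin}} w_i
\exp\!\left[\kappa (\mu \cdot u_i)^2\right],
$$

evaluated by the exact sum at every vertex $\mu$ of a triangulated mesh.
The concentration $\kappa$ relates to a Gaussian angular spread via
$\sigma = (2\kappa)^{-1/2}$; the default $\kappa = 14.9$
($\sigma = 10.5^\circ$) is calibrated so that the kernel retains
$\nu = (\mathrm{e}^{\kappa\cos^2\Delta\beta} - 1)/(\mathrm{e}^{\kappa}-1)
= 0.95$ of its influence at the largest mesh gap of a 1000-vertex mesh
($\approx 3.5^\circ$) -- no component can fall through the mesh -- while
still decaying to $\nu = 0.64$ at $10^\circ$, which caps the achievable
angular resolution at about $20^\circ$ and in practice (with the
acquisition above, at SNR $\approx 70$) at $30$-$35^\circ$. The voxel
ODF is the vertex-wise median over bootstraps (`odf_median()`), and
orientation-resolved means of $X \in \{T_2, R_2, D_\mathrm{iso},
D_\Delta^2\}$ are Watson-weighted convex combinations
$\hat{E}[X](\mu) = \sum_i w_i X_i \mathrm{e}^{\kappa(\mu\cdot u_i)^2} /
P(\mu)$, again medians over bootstraps (`orientation_means()`,
`odf_from_ensemble()`). $T_2$ is the weighted mean of per-component
$1/R_2$, not the reciprocal of $\hat{E}[R_2]$. Vertices where $P$ falls
below $10^{-6}$ of its maximum are flagged invalid rather than divided
through.

### Meshes

Meshes (`make_mesh()`) place `n_verts` vertices by electrostatic
repulsion -- projected gradient descent with heavy-ball momentum from a
seeded random start -- and triangulate them with a gift-wrapping convex
hull (compiled; no 3D hull package is available in the R ecosystem used
here, and points on a sphere are always in convex position). Defaults of
1000 vertices for glyphs and maps and 3994 for peak extraction give
median nearest-neighbour angles of about 6.5-7 and 3.3-3.5 degrees. Two
geometric points deserve emphasis:

* The orientation bins hold *axes*: tensor symmetry axes are undirected
  and the Watson kernel depends only on $(\mu\cdot u)^2$, so the bin set
  effectively seen by a component is the union of the vertices and their
  antipodes. Coverage statistics (`mesh_coverage()`) therefore use the
  axis metric $\arccos|u\cdot v|$.
* Well-converged pure-Coulomb layouts are nearly centrally symmetric,
  which makes vertex and antipode holes coincide and degrades axis
  coverage. The mesh energy therefore adds a mild mirror-charge term
  (weight 0.08) that pushes the layout away from central symmetry; the
  union then covers orientation space with a maximum gap of
  $\approx 3.9^\circ$ for 1000 vertices at a small cost in
  nearest-neighbour spacing. Gradient-direction schemes for protocols
  (`repulsion_directions(hemisphere = TRUE)`) instead use the fully
  antipodally symmetric energy, the standard construction for
  half-sphere encoding direction sets.

### Peaks and fibre populations

Peaks (`extract_peaks()`) are vertices strictly greater than their
1-ring neighbours with amplitude at least 10% of the maximum, at most 4
per voxel. On a full-sphere mesh each lobe appears twice; peaks closer
than 2.5 mesh edges in the axis metric are merged (the representative
with positive z, ties positive x, is kept). Ties in the local-maximum
test are broken by vertex index through strict comparison. Each peak
carries $\hat{E}[X]$ evaluated at its vertex (`peak_metrics()`).
`population_stats()` divides orientation space into regions around the
peak axes and their antipodes, assigns every thin component of every
bootstrap to the peak with largest $|u \cdot p|$ (exact ties to the
lowest peak index), and reports medians and interquartile ranges over
bootstraps of per-population weighted means -- fraction, $R_2$,
$D_\mathrm{iso}$, $D_\Delta^2$ and mean orientation.

## The in-silico validation systems

`make_crossing_system()` builds the crossing-fibre systems used for
validation: up to three fibres sharing $D_\mathrm{iso} =
0.75\times10^{-9}$ m$^2$s$^{-1}$ and $D_\Delta = 0.9$, with component 1
fixed at $T_2 = 60$ ms along $z$, component 2 at polar angle
$\theta_\mathrm{cross}$ with $T_2 = T_{2,\mathrm{cross}}$, component 3
(three-fibre systems) rotated to $\phi = 90^\circ$, each with weight
$f_\mathrm{thin}/n_\mathrm{fibre}$; plus, when $f_\mathrm{thin} < 1$, a
grey-matter-like component ($T_2 = 90$ ms, $D_\mathrm{iso} =
0.8\times10^{-9}$ m$^2$s$^{-1}$, $D_\Delta = 0.2$) with weight
$1 - f_\mathrm{thin}$. Signals are computed by the forward model on the
666-point protocol and perturbed with real-valued Gaussian noise of
standard deviation $1/\mathrm{SNR}$ relative to a reference amplitude
(`generate_signals()`); no magnitude operation is applied, matching the
stated noise model. The default SNR is 70. The reference amplitude is
the noiseless signal at the protocol's SNR measurement point -- the
spherical-encoding shell at $b = 0.3\times10^9$ s m$^{-2}$,
$\tau_E = 80$ ms, where SNR is measured empirically on real data; a
$b = 0$/shortest-echo convention is available
(`snr_ref = "b0_min_te"`). Evaluation (`evaluate_peaks()`,
`run_experiment()`) matches each detected peak to its antipodally
nearest ground-truth fibre (many-to-one allowed; surplus peaks still
count in the peak number) and aggregates angular and metric biases
across noise realisations.

What the simulator does *not* emulate: Rician/magnitude noise,
intra-bundle orientation dispersion, exchange, frequency-dependent
diffusion, imaging artefacts (motion, eddy currents, distortions) and
spatial correlations -- the in vivo preprocessing chain that handles
those is outside the package's scope. Passing the in-silico checks
therefore demonstrates correctness of the inversion and mapping
machinery under the stated noise model, not robustness to everything a
scanner produces.

## Problem sizes, determinism and numerical choices

* The validation experiments run at reduced replication chosen to keep a
  full run on one CPU core comfortable: 10 noise realisations and 16
  bootstrap solutions per realisation (instead of 40-100 and 96). At
  these sizes the two-fibre checks reproduce the reference behaviour
  with margin: a $60^\circ$ crossing with a 30% grey-matter fraction
  yields 2 peaks with mean angular bias $\approx 1.5^\circ$ (bound
  $2.5^\circ$) and $D_\mathrm{iso}$ peak biases below
  $0.06\times10^{-9}$ m$^2$s$^{-1}$ (bound $0.1\times10^{-9}$).
* One top-level seed drives everything; per-bootstrap, per-voxel and
  per-realisation sub-seeds are derived by counter-based mixing modulo
  $2^{31}-1$, so identical configurations give byte-identical numeric
  output regardless of evaluation order or worker count.
* NNLS tolerances scale with the problem's magnitude
  ($10\,\epsilon\,\max|K|\,\max|s|\,\max(M,N)$); an anti-cycling guard
  drops the most negative coordinate on a numerical stall.
* The repulsion descent halves its step and restarts momentum on energy
  increase; convergence is declared at a relative energy decrease of
  $10^{-12}$ (meshes use at most 500 iterations, which reaches the
  plateau of the spacing statistics).
* Degenerate inputs: an all-zero voxel signal yields an empty, flagged
  solution rather than an error; empty thin subsets yield a zero ODF and
  no peaks; a bin empty in more than half the bootstraps yields `NA`
  map values (masked).

## Known limitations

* The Monte-Carlo ensemble characterises solution variability, not a
  posterior: bootstrap spread underestimates uncertainty where the
  problem is degenerate along directions the resampling does not probe.
* Angular resolution is bounded by $\kappa$ (crossings below
  $\approx 20^\circ$ merge into one lobe by construction) and by the
  protocol/SNR (crossings below $\approx 30^\circ$ resolve unreliably).
* $\hat{E}[X]$ at a peak summarises a lobe by one number; dispersion
  within a lobe is only available through `population_stats()`.
* Regularised inversion variants, real-time tractography, gradient
  waveform design and scanner-side preprocessing are out of scope.
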