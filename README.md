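# rdfibre

Orientation-resolved relaxation–diffusion MRI fibre metrics in R.

White-matter voxels are heterogeneous: crossing fibre bundles, grey matter
and CSF all contribute to the signal, and different bundles can have
different relaxation and diffusion properties. `rdfibre` implements a 5D
relaxation–diffusion correlation analysis for multi-echo, tensor-valued
(b-tensor) diffusion MRI that resolves this heterogeneity without assuming
a common fibre response function:

1. **Forward model.** Each microscopic environment is an axisymmetric
   diffusion tensor with an effective relaxation rate; its signal at echo
   time τE under a b-tensor (b, bΔ) is
   `exp(−τE R2) · exp(−b Diso [1 + 2 bΔ DΔ P2(cos β)])` with
   `P2(x) = (3x² − 1)/2`. The voxel signal is `s = K w`, `w ≥ 0`.
2. **Nonparametric Monte-Carlo inversion.** A two-cycle algorithm around a
   compiled Lawson–Hanson NNLS solver — proliferation (random candidate
   injection, survivor selection by the solver's weights) and mutation
   (perturb-and-compete refinement) — estimates discrete
   `(R2, D∥, D⊥, θ, φ, w)` distributions; bootstrap resampling of the
   measurements yields per-voxel solution ensembles.
3. **Binning.** Components are classified into disjoint 'thin'
   (fibre-like), 'thick' (GM-like) and 'big' (CSF-like) boxes in
   `(log D∥/D⊥, log Diso, log R2)` space; bin fractions and in-bin means
   become parameter maps.
4. **Fibre ODFs with metrics.** Thin-bin components are smoothed onto an
   electrostatic-repulsion sphere mesh with a Watson kernel
   `exp(κ(μ·u)²)` (κ = 14.9, σ = 10.5°); bootstrap-median ODFs carry
   orientation-resolved means of T2, R2, Diso and DΔ² at every vertex, and
   up to four ODF peaks per voxel are extracted with their per-peak
   metrics and population statistics.
5. **In-silico validation.** A crossing-fibre simulator reproduces the
   published validation systems (shared fibre diffusion features,
   per-fibre T2, optional GM-like component, Gaussian noise at SNR 70 on
   a 666-point acquisition scheme) and evaluates peak counts, angular and
   metric biases.

## Worked example

Two orthogonal fibres with distinct T2 (60 and 100 ms), equal weights, no
GM, at SNR 70 on the built-in 666-point protocol:

```r
library(rdfibre)
scheme <- default_protocol(seed = 1)
mesh   <- make_mesh(1000, seed = 1)
sys    <- make_crossing_system(n_fibre = 2, theta_cross = 90,
                               t2_cross = 0.100, f_thin = 1)
sig    <- generate_signals(sys, scheme, snr = 70, n_noise = 1, seed = 2)
ens    <- bootstrap_invert(scheme, sig[, 1],
                           config = mc_config(n_boot = 16, seed = 2))
odf    <- odf_from_ensemble(ens, mesh)
peaks  <- peak_metrics(extract_peaks(odf), odf)
print(peaks[, c("x", "y", "z", "amplitude", "t2", "d_iso")])
evaluate_peaks(peaks, sys)
```

```
            x          y          z amplitude         t2        d_iso
1  0.01058977 0.01342631 0.99985378   1439679 0.05800723 7.786151e-10
2 -0.99942007 0.01436231 0.03087457   1334356 0.10162821 7.750254e-10
  peak fibre dbeta_deg          dt2       dd_iso  dd_delta2
1    1     1  0.979804 -0.001992768 2.861508e-11 0.01167892
2    2     2  1.951393  0.001628209 2.502544e-11 0.03072280
```

The two peaks sit within one to two degrees of the true fibre axes and
carry their own T2 values: ~58 ms on the θ = 0 lobe (truth 60 ms) and
~102 ms on the θ = 90° lobe (truth 100 ms) — the fibre-specific
relaxation contrast the method is built to recover. `d_iso` is within a
few percent of the shared ground truth 0.75e-9 m²/s.

A command-line front-end (`inst/cli/rdfibre.R`) exposes the pipeline as
`mesh`, `simulate`, `invert`, `peaks` and `evaluate` subcommands over
NIfTI/TSV/PLY files.

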