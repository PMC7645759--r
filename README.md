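# t1rhomap

Accelerated mono- and biexponential T1rho mapping of knee cartilage from
undersampled multi-coil MRI, in R.

T1rho — the spin-lattice relaxation time in the rotating frame — is a
quantitative MRI biomarker sensitive to the proteoglycan content of
cartilage, and biexponential T1rho analysis can separate water compartments
that a single relaxation time blurs together. The obstacle is scan time: a
T1rho map needs a series of volumes at increasing spin-lock times (TSLs).
This package implements the computational side of accelerating such
acquisitions by k-space undersampling, for researchers who develop or
evaluate quantitative-MRI reconstruction: the multi-coil acquisition model,
retrospective Poisson-disk undersampling, compressed-sensing (CS) and
variational-network (VN) reconstruction, complex-valued relaxometry fitting
with statistical model selection, a synthetic phantom generator with known
ground truth, and the error/repeatability metrics to judge the resulting
parameter maps.

## The models

Acquisition: `y = S F C x + eta`, with `x` the complex 2D+time image
sequence (one frame per TSL), `C` the coil sensitivities and low-order phase
compensation, `F` the unitary 2D Fourier transform, `S` the binary sampling
pattern and `eta` complex Gaussian noise. The fully sampled reference
reconstruction is the adjoint `C* F* y`.

CS reconstruction solves

    min_x  || y_S - S F C x ||_2^2  +  lambda || T x ||_1

with `T` spatial (SFD) or spatio-temporal (STFD) finite differences, a
monotone FISTA solver, and `lambda = beta * ||C* F* S* y||_inf` with `beta`
tuned on training data over a 12-point log grid (ratio 12.3285) plus
bisection. The VN instead unrolls M learned gradient-like layers

    x_{m+1} = x_m - sum_i K*_{m,i} Phi'_{m,i}(K_{m,i} x_m)
                  + alpha_m C* F* S* (y_S - S F C x_m)

whose filters `K`, pointwise activations `Phi'` (Gaussian radial-basis
mixtures) and step sizes `alpha` are trained with ADAM.

Relaxometry fits each ROI voxel with the complex-valued models

    mono:   x(t) = c exp(-t / tau)
    biexp:  x(t) = c ( f_s exp(-t / tau_s) + f_l exp(-t / tau_l) ),  f_s + f_l = 1

by bounded trust-region least squares (complex fitting avoids the Rician
bias of magnitude fitting). A voxel is called biexponential when the nested
F-ratio exceeds the 0.95 quantile of F(2, n-4) — 5.14 at the 10-TSL protocol
— and both fractions are at least 5%. Maps are compared by nRMSE (images),
NAD/MNAD (parameters, median over an ROI), ROI mean/SD, two-scan CV and
one-way ANOVA.

## Worked example

```r
library(t1rhomap)

# Simulate one slice: 32 x 32 grid, 10 TSLs, 4 coils, 30 dB k-space noise,
# with a Poisson-disk mask at acceleration factor 4
ds <- make_dataset(ny = 32, nz = 32, nc = 4, af = 4, seed = 7,
                   config = list(phase0 = 0, phase_ramp = c(0, 0)))
ds$mask
#> <sampling_mask> 32 x 32 x 10, calib 11 x 11, achieved AF 4.000

# Reconstructions: zero-filled adjoint vs spatio-temporal compressed sensing
coils <- estimate_sensitivities(ds$kspace, c(15, 15))
zf  <- mri_adjoint(ds$kspace, coils, ds$mask)
cs  <- cs_reconstruct(ds$kspace, coils, ds$mask,
                      cs_config("STFD", beta = 0.01))$x
ref <- mri_adjoint(ds$kspace, coils)          # fully sampled reference

round(c(ZF = nrmse(zf, ds$truth), CS_ST = nrmse(cs, ds$truth),
        REF = nrmse(ref, ds$truth)), 4)
#>     ZF  CS_ST    REF
#> 0.1229 0.0376 0.0519

# Relaxometry: complex-valued mono/biexponential fitting over the ROIs,
# scored against the maps fitted on the fully sampled reference
ref_maps <- fit_map(ref, ds$maps$roi_labels)
cs_maps  <- fit_map(cs,  ds$maps$roi_labels)
round(c(mnad_tau = mnad(cs_maps, ref_maps, "tau"),
        f_cutoff = f_test(2, 1, 10)$threshold), 4)
#> mnad_tau f_cutoff
#>   0.0596   5.1433
```

At four-fold acceleration the zero-filled image misses 75% of k-space and
shows strong aliasing (nRMSE 0.12); the tuned spatio-temporal CS
reconstruction reaches nRMSE 0.038 — here even better than the noisy fully
sampled reference (0.052), because the temporal penalty also denoises — and
its monoexponential T1rho map deviates from the reference map by a median of
6%. The printed `f_cutoff` is the biexponential selection
threshold implied by the implementation's degrees of freedom.

The full study design — train/test phantom groups, per-transform beta
tuning, VN training, an acceleration-factor sweep and per-method nRMSE/MNAD
tables — is one call:

```r
out <- run_experiment(experiment_config(seed = 11))
out$summary
```

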