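# lrmdenoise

Patch-based denoising of 2-D MRI slices with a Gaussian-mixture patch prior
and per-cluster low-rank recovery, plus the synthetic phantoms, noise models
and quality metrics needed to evaluate it reproducibly.

## The problem and the method

Magnitude MR images are corrupted during acquisition and transmission —
classically by Rician noise, well approximated as additive Gaussian at
clinical signal-to-noise — and the resulting grain obscures exactly the
small, low-contrast findings (e.g. 2–5 mm hypointense microbleeds) that
matter for stroke assessment. Local structure in brain MRI is highly
repetitive: collect the overlapping `p × p` blocks of a slice and blocks
showing the same edge, boundary or flat tissue recur many times. Stacked as
columns of a matrix, a group of such similar blocks is approximately
low-rank, while i.i.d. noise is full-rank; separating the two is the basis
of the method.

The pipeline:

1. **Patch extraction.** The slice is decomposed into overlapping `p × p`
   blocks on a stride-`s` grid (defaults `p = 8`, `s = 4`), edge-snapped so
   every pixel is covered.
2. **Gaussian mixture prior.** Clean patches `x ∈ R^{p²}` (mean intensity
   removed) are modelled as a mixture
   `p(x | Φ) = Σ_h w_h N(x; μ_h, Σ_h)`, `Φ = {w_h, μ_h, Σ_h}, h = 1..H`,
   fitted by EM on patches of a noise-free image. Noisy patches are assigned
   to classes by the posterior under noise-inflated covariances
   `Σ_h + σ² I`.
3. **Low-rank recovery.** The `d(h)` patches of class `h` form the cluster
   matrix `P̄_h = Q_h + T_h` (clean + noise). `Q_h` minimises the energy
   `E(Q) = τ‖Q‖₊ + (1/σ²)‖P̄_h − Q‖_F²` (`‖·‖₊` the nuclear norm), whose
   closed-form solution soft-thresholds the singular values of `P̄_h` at
   `λ = τσ²/2` (SVT). The default solver is the weighted variant (WNNM),
   with weights `w_i = C√d(h)·σ²/(s_i + ε)` recomputed from the current
   spectrum, so strong structural components are shrunk least.
4. **Aggregation and iteration.** Shrunk patches are averaged back into an
   image; cluster–denoise rounds repeat (default 3) with the working noise
   level re-estimated as `σ_k = γ·sqrt(max(σ₀² − var(noisy − current), 0))`.

Quality is scored by RMSE (intensity units), PSNR
(`10·log10(I_max²/MSE)`, dB) and mean SSIM (Gaussian-weighted 11×11
windows, SD 1.5).

Because no clinical images ship with the package, `make_phantom()` builds
brain-like piecewise-smooth phantoms (nested elliptical tissue regions, a
small hypointense disc lesion) and `add_noise()` corrupts them with
calibrated Gaussian or Rician noise, where "x% noise" means
`σ = x/100 · I_max`.

## Worked example

```r
library(lrmdenoise)

ph    <- make_phantom(size = 128, n_tissue_regions = 3, lesion_diameter = 8, seed = 0)
noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 100))   # sigma = 12.75

prior  <- fit_gmm_prior(extract_patches(ph$image, 8, 4), H = 8, seed = 0)
result <- denoise_image(noisy, prior, denoise_config(), reference = ph$image,
                        data_range = 255)
result
#> <lrmd_denoise> 128x128 image, 3 outer iteration(s), wnnm shrinkage, sigma0 = 13.344
#> # A tibble: 3 × 7
#>   iteration sigma_used n_clusters_used max_cluster recon_err   loglik  psnr
#>       <int>      <dbl>           <int>       <int>     <dbl>    <dbl> <dbl>
#> 1         1      13.3                8         808  3.55e-15 -257569.  28.3
#> 2         2      10.2                8         811  1.78e-15 -240818.  29.2
#> 3         3       9.10               8         813  1.78e-15 -232771.  29.8

quality_report(ph$image, noisy, data_range = 255)
#> # A tibble: 1 × 4
#>    rmse  psnr  ssim data_range
#>   <dbl> <dbl> <dbl>      <dbl>
#> 1  12.7  26.0 0.494        255
quality_report(ph$image, result$image, data_range = 255)
#> # A tibble: 1 × 4
#>    rmse  psnr  ssim data_range
#>   <dbl> <dbl> <dbl>      <dbl>
#> 1  8.25  29.8 0.696        255
```

Reading the output: the noise SD was estimated at 13.3 (true 12.75) and
decays over the three rounds as noise is removed; `recon_err` confirms the
exact `Q + T` split of every cluster matrix; PSNR climbs from 26.0 dB
(noisy) to 29.8 dB and SSIM from 0.49 to 0.70. The sweep driver does this
over a grid:

```r
res <- run_experiment(noise_levels = c(1, 3, 5, 7), H_values = c(4, 8, 16),
                      n_seeds = 1, seed = 0)
summarise_experiment(res)
autoplot(res)               # PSNR vs number of classes, per noise level
plot_rmse_vs_noise(res)     # RMSE degradation with noise intensity
```

A thin command-line wrapper with verbs `phantom`, `noise`, `fit-prior`,
`denoise`, `score` and `experiment` is installed at
`system.file("cli/lrmd.R", package = "lrmdenoise")`.

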