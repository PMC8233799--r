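# rnlmstar

Particle-preserving Rician non-local means denoising for magnitude MR
images, with the full evaluation apparatus around it: parametric noise
generators, image-quality metrics, random-search parameter optimization,
dynamic-noise robustness sweeps, and segmentation-performance analysis —
all runnable offline on built-in synthetic phantoms.

## The problem and the method

Magnitude MR images carry Rician noise: the observed intensity is
`M = sqrt((A + n1)^2 + n2^2)` with `n1, n2 ~ N(0, σ²)`, so
`E[M²] = A² + 2σ²` and dark regions are biased upward. Non-local means
(NLM) estimates each pixel as a weighted average over a search window,
with weights `w(i,j) ∝ exp(−‖N(i) − N(j)‖² / h²)` from patch distances;
its Rician-corrected form (RNLM) averages squared intensities and removes
the bias:

    x̂(i) = sqrt( max( Σⱼ w(i,j) · y(j)² − 2σ², 0 ) )

NLM-type filters blur tiny high-contrast spots (1–3 pixel lesions): an
isolated particle matches no patch in its window and gets averaged away.
The core filter here, **RNLM\***, multiplies patch similarity by a pixel
similarity `ρ(i,j) = 1 / (1 + (|y(i)−y(j)|/degc)^ω)` and rescales the
self-weight by

    ϑ(i,k) = 1 + (2·radp+1)² / (1 + (degc/|y(i)−y(k)|)^ω)

where `k` is the most similar non-central pixel — so weight re-concentrates
on the center exactly where the center resembles nothing nearby, and small
particles survive. See the methods vignette
(`vignettes/particle-preserving-rician-nlm.Rmd`) for the model, parameter
units and defaults, and the design decisions.

## Worked example

```r
library(rnlmstar)

spec  <- phantom_spec(size = c(48, 48), n_bands = 3, n_particles = 4,
                      particle_contrast = 0.5, seed = 7)
clean <- make_phantom(spec)                       # noise-free ground truth
noisy <- add_rician(clean, sigma = 0.1, seed = 7) # magnitude MR noise model

params <- filter_params(h = 0.6, radp = 1, rads = 3, degc = 0.2, omega = 4)
den <- rnlm_star_filter(noisy, params, sigma = 0.1)

round(metric_report(clean, noisy), 4)
#>      mse snr_db psnr_db q_index   ssim   corr
#> 1 0.0095 11.369 20.2313  0.7754 0.7803 0.7868
round(metric_report(clean, den), 4)
#>      mse  snr_db psnr_db q_index   ssim  corr
#> 1 0.0021 17.0882  26.822  0.9387 0.9403 0.939

m <- particle_mask(spec)   # ground-truth particle pixels
mean(clean[m] - den[m])                                        # 0.1737
mean(clean[m] - rnlm_filter(noisy, params, sigma = 0.1)[m])    # 0.4136
```

Denoising cuts the MSE against the ground truth from 0.0095 to 0.0021 and
lifts SSIM from 0.78 to 0.94; the last two lines measure how much particle
peak intensity each filter gives up — the particle-preserving weights lose
0.17 of the 0.5 particle contrast where plain RNLM loses 0.41.

Other entry points: `add_salt_pepper()` / `add_speckle()` /
`estimate_sigma_background()` (noise module), `average_filter()` /
`median_filter()` (local baselines), `optimize_filter_params()` (random
search over `h`, `degc`, `radp`, `ω`), `noise_sweep()` /
`compare_filters()` / `id_distribution_study()` (robustness curves),
`fuzzy_soft_threshold()` / `segmentation_sweep()` (segmentation analysis),
`read_image()` / `write_image()` / `run_config()` (I/O and reproducible
runs). A command-line front end over the same functions is installed at
`inst/cli/rnlmstar.R`; every command writes a manifest from which the run
can be reproduced bit-identically.

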