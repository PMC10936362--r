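# bayesTICS

Local estimation of diffusion coefficients of individual fluorescent spots
in time-lapse (TIRF) microscopy, by fitting closed-form nonstationary
temporal autocorrelation models to region-of-interest (ROI) signals with
approximate Bayesian computation (ABC).

## The problem

During the late steps of exocytosis, a vesicle fuses with the plasma
membrane and its cargo proteins (e.g. Transferrin Receptor tagged with
pHluorin) spread laterally by free diffusion. Each fusion event is a
transient, *nonstationary* signal: a sharp bright spot that appears at the
fusion time and fades as it spreads. Classical fluorescence correlation
methods (FCS, TICS, STICS, kICS) assume temporally stationary fluctuations
and estimate one global diffusion coefficient; they are poorly suited to a
single short-lived spot in a small window. This package estimates a *local*
diffusion coefficient `D`, per spot, from a single image sequence, and
returns a full posterior distribution for it.

## The model

Fick's second law with all `C0` molecules concentrated at the fusion site
`x0` at the fusion time gives the 2D heat kernel

    C(x, t) = C0 / (4 pi D t) * exp(-|x - x0|^2 / (4 D t)),

and imaging through an isotropic Gaussian PSF of bandwidth `sigma` (with a
lumped intensity gain `g`) gives a Gaussian spot whose per-axis variance
grows linearly in time:

    i(x, t) = g C0 N(x; x0, (sigma^2 + 2 D t) I).

Because the process is nonstationary, the temporal autocorrelation is
anchored at a reference frame (the first post-fusion frame, elapsed time
`t_ref = 1`) rather than averaged over a sliding time origin:

    G(tau) = < i(x, t_ref) i(x, t_ref + tau) >_ROI.

Substituting the Gaussian profile yields the uniform-background model

    G1(tau) = a / (Mx My (sigma_e^2 + D (2 t_ref + tau))),

with a single amplitude nuisance `a = g^2 C0^2 / (4 pi)` and effective
squared width `sigma_e^2` (the PSF plus optional reference-frame smoothing).
`1/G1` is exactly affine in the lag. For nonuniform or cluttered
backgrounds, the fluctuation model `G2` subtracts the scalar spatiotemporal
mean; its closed form adds correction terms driven by the fraction of spot
mass still inside the ROI, which decay with the total observation time `T`
so that `G2 -> G1` for long sequences.

`(D, a)` are estimated by ABC rejection: draw 100 000 parameter pairs from
uniform priors, evaluate the model curve for each, keep the best 1% by a
(shape-normalized) squared-Euclidean distance to the observed curve, and
report the posterior mean (MMSE) and histogram mode (MAP) of `D`, in
pixel²/frame.

The package also ships the full validation machinery: an analytic renderer
and an independent Brownian-particle Monte Carlo renderer for ground-truthed
synthetic sequences, preprocessing for raw stacks (median background
subtraction, fusion-frame detection, generalized Anscombe variance
stabilization), and a command line.

## Worked example

Simulate one fusion event (true `D = 0.5` px²/frame, fusion at frame 41,
tilted-plane background, additive Gaussian noise) and estimate `D` back:

```r
library(bayesTICS)

scene <- scene_spec(
  image_dims = c(61, 61), T = 400,
  spot       = diffusion_params(D = 0.5, C0 = 500, x0 = c(31.4, 30.7), t0 = 41),
  optics     = optics_params(sigma_psf = 1.3, gain = 1),
  background = list(b0 = 8, br = 0.05, bc = -0.04),
  noise_sigma = 3.7, seed = 7)
stack <- render_analytic(scene)
stack$seq
#> Image sequence: 61 x 61 px, 400 frames

res <- estimate_spot(stack$seq, center = c(31, 31),
                     run_config(model = "g1", seed = 1, T_fit = 300L,
                                max_lag = 50L))
res$fit
#> BayesTICS ABC fit (g1 model)
#>   accepted: 1000 / 100000 samples (rate 0.0100, realized eps 0.04822)
#>   D (MAP)  = 0.4664 px^2/frame
#>   D (MMSE) = 0.4595 px^2/frame
#>   a (MMSE) = 5.834e+05 a.u.
summary(res$fit)
#> D: MAP 0.4664, MMSE 0.4595 px^2/frame
#>   2.5%    25%    50%    75%  97.5%
#> 0.4109 0.4333 0.4602 0.4846 0.5094
```

The pipeline found the fusion frame, subtracted the pre-fusion median
background, computed the reference-frame autocorrelation over 50 lags, and
recovered the generating `D = 0.5` within 8% (MMSE 0.46, posterior 95%
interval 0.41–0.51). `plot(res$fit)` draws the marginal posterior;
`plot(res$obs)` the observed autocorrelation curve. To convert to physical
units, multiply by `pixel_size_um^2 * frame_rate_hz`.

## Command line

```sh
Rscript inst/cli/bayestics.R simulate --preset snr-sweep --out sims --seed 1
Rscript inst/cli/bayestics.R estimate --input sims/snr_8.tif \
    --roi-list rois.csv --model g1 --out results
Rscript inst/cli/bayestics.R batch --config run.yaml
```

`estimate` writes per-ROI JSON estimates, a CSV of accepted posterior
samples, an autocorrelation-overlay plot and a posterior histogram; every
output embeds the config hash and seed.

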