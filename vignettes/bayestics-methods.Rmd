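---
title: "Local diffusion estimation by temporal image correlation and ABC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local diffusion estimation by temporal image correlation and ABC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(bayesTICS)
```

This vignette is the package's account of its science: the physical model,
the autocorrelation models and the estimator that matches them, the ABC
sampler and its settings, what the synthetic-data generator does and does
not emulate, and the numerical choices that a maintainer would want
explained.

## 1. Physical model

A fusion event releases `C0` molecules at a point `x0` of the plasma
membrane at the fusion instant. Free lateral diffusion (Fick's second law,
$\partial_t C = D \Delta C$) with that delta initial condition has the 2D
heat-kernel solution

$$C(x,t) = \frac{C_0}{4\pi D t}\,
  \exp\!\Big(\!-\frac{\|x-x_0\|^2}{4 D t}\Big),$$

with total mass $C_0$ at every $t>0$. The microscope blurs this field with
an isotropic Gaussian PSF of bandwidth $\sigma$ (pixels); collection
efficiency, absorption and quantum yield enter only as one lumped intensity
factor $g$ (`gain`). A Gaussian convolved with a Gaussian is Gaussian, so
the imaged spot is

$$i(x,t) = g\,C_0\, \mathcal N\!\big(x;\, x_0,\, (\sigma^2 + 2Dt)\,I\big):$$

its per-axis variance grows linearly with slope $2D$ and its spatial
integral $g C_0$ is constant. These two facts are the package's physics
invariants (checked by quadrature and moment regression in the tests).

**Units.** `D` is carried in pixel²/frame. With pixel size $p$ (µm) and
frame interval $\Delta t$ (s), $D_{\mu m^2/s} = D\,p^2/\Delta t$. Pixel
size and frame interval are metadata only.

**Coordinates and time.** Pixel centers sit at integer 1-based coordinates;
`x0` is continuous in the same frame. Inside the models, elapsed time is
measured from fusion with the first usable frame at $t=1$ frame (the
`t_ref` default), which avoids the $t=0$ singularity of the heat kernel;
the offset is configurable. Frames are rendered by point evaluation at
pixel centers — for PSF widths of a pixel or more, the difference from
pixel-area integration is far below all tolerances used here.

## 2. Autocorrelation models

### The nonstationary estimator

A spreading spot is not a stationary process: the statistics depend on real
time, not only on the lag. Averaging products $i(t)\,i(t+\tau)$ over a
sliding origin $t$ would (i) make the expected curve depend on the total
observation time $T$ at every lag and (ii) destroy the affine structure of
$1/G_1$ that makes the model identifiable and interpretable. The estimator
is therefore *anchored*: for lag $\tau$,

$$\hat G(\tau) = \frac{1}{M_x M_y}\sum_{x\in\Omega}
  j(x, t_\mathrm{ref})\; j(x, t_\mathrm{ref}+\tau),$$

with $j=i$ (`variant = "uniform"`) or $j = i - m$, $m$ the scalar
spatiotemporal mean of the series (`variant = "fluctuation"`). The
reference frame is the first post-fusion frame, where the spot is sharpest
— which also makes the pixel sum insensitive to ROI truncation, because
the *product* of the sharp reference with any later frame is narrower than
either factor.

### G1: isolated spot, uniform background

Replacing the ROI sum by a plane integral (exact up to lattice and border
terms that are negligible at the widths used here) gives

$$G_1(\tau) = \frac{a}{M_x M_y\,\big(\sigma_e^2 + D(2t_\mathrm{ref} +
\tau)\big)}, \qquad a = \frac{g^2 C_0^2}{4\pi},$$

The amplitude nuisance $a$ folds gain, molecule count and the PSF
normalization into one scalar; $\sigma_e$ is an effective width (below).
Two structural facts follow immediately and are tested:

* $1/G_1(\tau)$ is **exactly affine** in $\tau$ with slope
  $M_xM_y D/a$ — `inverse_g1_line()` returns the two coefficients, and
  $D = \sigma_e^2\,s/(c - 2t_\mathrm{ref}\,s)$ recovers $D$ from the fitted
  line without knowing $a$;
* the ROI size enters only as the factor $1/(M_xM_y)$, so it rescales the
  curve without moving the fitted $D$ — the basis of the ROI-size
  invariance property.

### G2: nonuniform and cluttered background

When background or neighbouring spots make the mean non-negligible, the
fluctuation variant subtracts the scalar spatiotemporal mean $m$. Carrying
$m$ through the same algebra gives

$$G_2(\tau; T) = G_1(\tau) - m(T)\,[\mu(t_\mathrm{ref}) +
\mu(t_\mathrm{ref}+\tau)] + m(T)^2,$$

where $\mu(t) = g C_0\,E(t)/(M_xM_y)$ is the model ROI-mean of the spot
image and $E(t)$ the fraction of the spread Gaussian's mass inside the ROI
(an erf product, evaluated for a centered spot). The total observation time
$T$ enters **only** through $m(T) = \frac1T\sum_t \mu(t)$: as the movie
lengthens the spot's mass spreads out of the window, $m(T)\to 0$
(like $\log T / T$), and $G_2 \to G_1$. The out-of-equilibrium correction
is an additive offset; measured relative to the curve scale
($\|G_2-G_1\|_\infty / \|G_1\|_\infty$) it falls monotonically from ~3.7%
at $T=300$ to below 1% at $T=4800$ for the reference conditions. A static
background of any spatial shape cancels from neither model's *derivation*
explicitly because it is removed earlier, by background subtraction in
preprocessing; the mean subtraction in `G2` handles what remains.

### Noise conditioning of the estimator (exactness-preserving)

Two refinements keep the anchored estimator usable at low SNR. Both are
absorbed *exactly* by the models, so all closed-form properties survive.

* **Reference smoothing** (`ref_smooth`, default 2 px). The reference frame
  multiplies every lagged frame, so its pixel noise never averages out over
  lags. Convolving it with a Gaussian of width $\varsigma$ suppresses the
  noise-product variance about $4\pi\varsigma^2$-fold, while the model
  simply replaces $\sigma^2$ by $\sigma_e^2 = \sigma^2 + \varsigma^2/2$
  (and widens the G2 reference mean accordingly): $1/G_1$ remains exactly
  affine, and the noise-free estimator-model match stays at discretization
  error ($\sim 10^{-9}$ relative). The smoothing kernel is normalized to
  unit sum with edge-replicate padding and support $\pm 6\varsigma$, so it
  is mass-preserving, exact for constant images, and its truncation error
  is below lattice precision.
* **Multi-reference averaging** (`n_ref`). A single-reference curve rests
  on one frame pair per lag. Averaging the single-reference curves anchored
  at frames $t_\mathrm{ref},\dots,t_\mathrm{ref}+R-1$ cuts the per-lag
  noise by $\approx 1/\sqrt R$, and the models average over the same
  reference times in closed form. The canonical mathematical objects
  default to $R=1$ (exact affine inverse); the analysis pipeline
  (`estimate_spot()`, `run_config()`) defaults to $R=8$, which in the
  simulated sweeps keeps estimates stable down to peak-SNR ≈ 2. With $R>1$
  the averaged $1/G_1$ is no longer exactly affine; the linearization
  diagnostics refer to the $R=1$ object.

## 3. ABC rejection sampler

The posterior $p(\theta \mid x) \propto p(x\mid\theta)\,p(\theta)$ for
$\theta = (D, a)$ is sampled by rejection: draw $N$ pairs from the prior,
simulate the model curve for each, and keep the draws whose distance to the
observed curve passes a 0–1 cut-off. Accepted draws are i.i.d. from the
approximate posterior; `d_mmse` is their mean (posterior expectation) and
`d_map` the mode of the binned marginal.

Settings and their rationale:

* **$N$ = 100 000 samples, quantile acceptance 1%** (exactly the best 1000
  draws). Quantile acceptance makes the cut-off scale-free; an absolute
  $\varepsilon$ mode exists and fails loudly when nothing is accepted. All
  $N$ model evaluations are vectorized; batching cannot change the values
  (the suite cross-checks batched rows against single-draw calls).
* **Priors.** Uniform on intervals, per parameter. Default
  $D \in [0.01, 10]$ px²/frame — wide, because the default distance (next
  point) identifies $D$ through curve shape alone. Bounds for $a$ are
  moment-matched from the first observed value and span four orders of
  magnitude.
* **Distance.** Both models are exactly proportional to $a$, so under a
  raw squared-Euclidean distance the data constrain mostly $a/D$: the
  minimum-over-$a$ residual saturates at a few percent of
  $\|obs\|^2$ along a ridge of $(D,a)$ pairs, and with $N=10^5$/1% the
  accepted set spreads along that ridge (this is also why the raw-distance
  posterior mean sits *slightly above* the true $D$: the ridge extends
  further upward). The default distance therefore first divides each curve
  by its own first-lag value and compares decay shapes; $a$ cancels
  exactly, $D$ is identified on its own, and self-consistency recovery is
  better than 1% (MMSE) under the wide default prior. `distance = "raw"`
  remains available and then calls for a tight, process-informed $D$ prior
  — the classical practice. A least-squares projection distance (free
  scale) was evaluated and rejected: at low SNR the noise vector projects
  well onto extreme-$D$ shapes and the fit runs to the prior edge.
* **MAP.** Histogram mode over the prior interval with Freedman–Diaconis
  binning computed from the accepted samples (capped at 10–1000 bins),
  ties broken toward the lowest $D$; the bin count is configurable, and
  doubling it moves the mode by at most one original bin width on unimodal
  posteriors.
* **Determinism.** The sampler seeds the RNG from its config; identical
  seeds and inputs give bit-identical fits.
* The estimator settings recorded on the observed curve (`t_ref`,
  `ref_smooth`, `n_ref`) take precedence over the ABC config, so simulated
  and observed curves always share conventions.

## 4. Preprocessing raw stacks

`preprocess_roi()` turns a stack plus a spot location into a fit-ready
series: crop (no border padding — an ROI crossing the image edge is an
error), optional variance stabilization, fusion-frame detection, static
background subtraction, truncation to the post-fusion window.

* **Fusion-frame detection** uses the maximum over frames of a 3×3
  box-averaged frame. The spot's *peak* is sharply maximal at fusion and
  decays as $1/(\sigma^2+2Dt)$; the ROI *total*, by contrast, is conserved
  while the spot stays inside the window, so post-fusion frames nearly tie
  and noise would pick an arbitrary late frame ("total" is available but
  not the default). Detection runs before background subtraction — a
  time-constant background shifts every frame's statistic equally.
* **Background** is the pixelwise temporal median over 20 frames,
  projected onto a tilted plane by default. Two deliberate choices here:
  (i) the raw median keeps a residual noise pattern of variance
  $\approx \frac{\pi}{2}\sigma^2/n$; subtracted identically from every
  frame, that pattern is frame-correlated and adds a lag-independent
  offset to the autocorrelation, biasing $D$ low — the plane projection
  removes it while keeping smooth nonuniformity (a quadratic field and the
  raw median are options). (ii) *Which* frames: by default the frames just
  before the detected fusion frame, which are spot-free by construction;
  for recordings that begin mid-event the classical last-frames window is
  used instead (`background_from = "last"`). Late frames always contain
  the spot of interest's residual density, roughly $C_0/(4\pi D t_{end})$
  per pixel; using them is safe only once that is small against the
  background.
* **Truncation** keeps `T_fit` frames from the fusion frame (defaults 100
  for G1, 300 for G2 — minima for stable curves; use more when the movie
  allows). The lag grid runs from $\tau=1$ (the zero-lag value is
  noise-variance dominated and excluded, as in standard FCS/TICS practice)
  to `T_fit/4` by default.
* **Generalized Anscombe transform** for Poisson–Gaussian camera noise,
  $f(x) = \frac{2}{g}\sqrt{g x + \frac38 g^2 + \sigma_r^2 - g\,o}$,
  clamped at its domain floor; with $g=1,\sigma_r=0,o=0$ it reduces to the
  classical $2\sqrt{x+3/8}$. When camera metadata are missing, offset and
  read noise are estimated robustly from the darkest decile of pixels.

## 5. The synthetic-data generator

`scene_spec()` + `render_analytic()` produce ground-truthed sequences: sum
of analytic spot profiles (one main spot; optional static or diffusing
clutter spots), a constant or tilted-plane background, and i.i.d. additive
Gaussian noise — bit-reproducible given the seed. **SNR is defined as the
main spot's peak noiseless amplitude at its first post-fusion frame divided
by the noise sd**; the literature rarely defines SNR numerically, so the
definition is stated here once and used everywhere (`snr_sweep()`).

`render_particles()` is an *independent physical oracle*: the spot's mass
is carried by Brownian walkers (per-axis step variance $2D$ per frame, all
starting at `x0`), each rendered as a PSF-shaped kernel. It shares no code
path with the closed forms beyond the PSF constant, so the agreement of
(particle renderer) ↔ (analytic renderer) ↔ (G1 model) — the oracle
triangle, verified to <3% / <2% in the acceptance tests — is a genuine
three-way cross-validation of the physics, the rendering and the estimator.

Reference conditions used throughout validation (chosen once): `D` = 0.5
px²/frame, `C0` = 500 molecules, unit gain, $\sigma$ = 1.3 px, 31×31
window, `T` = 300 frames, SNR sweep {2, 4, 8, 16, 32}. The six-scene
battery (`scenario_suite()`) varies spot position, window size and shape,
clutter and SNR.

**What the generator does not emulate:** camera-realistic noise (EMCCD gain
registers, fixed-pattern noise), photobleaching and blinking, anomalous or
confined diffusion, axial (3D) motion. Passing tests therefore demonstrate
correctness of the method under its own model class and robustness to
additive noise, window geometry and simple clutter — not robustness to
every artifact of real acquisitions. In particular, synthetic spots never
bleach, which is why late-frame background windows self-subtract part of
the spot (Section 4) more than they would on real pHluorin data.

## 6. Numerical choices and degenerate inputs

* Gaussian lattice sums vs. plane integrals: for widths ≥1 px the relative
  discrepancy is $\sim e^{-2\pi^2 v}$ — negligible; the sharp reference
  frame keeps border truncation negligible even in 15×15 windows.
* `model_g2`'s $m(T)$ is an $O(T)$ sum of erf products; the batched sampler
  evaluates it chunked (~2·10⁶ values per chunk) so $N=10^5$ G2 draws fit
  comfortably in memory.
* Degenerate inputs fail loudly and early: non-positive $D$, $a$,
  $\sigma$; $t\le 0$ for the heat kernel; `max_lag` ≥ `T`; mismatched lag
  grids in the distance; ROI crossing the image border; epsilon acceptance
  with zero accepted samples. A zero-width histogram interval (all
  accepted samples equal) widens by machine-scale padding rather than
  failing.
* Even ROI sizes are accepted with a half-pixel center convention and a
  warning; odd sizes are the norm so a detected spot can sit on a center
  pixel.
* Negative fluctuation-curve values are never clipped; only the
  `"normalized"` distance requires a positive first-lag value and says so
  when it is violated (switch to `"raw"` in that case).

## 7. Known limitations

* The method needs long sequences (≥100 frames for G1, ≥300 for G2) — a
  property of correlation estimation itself — and at peak-SNR ≈ 2 the
  estimate spread grows markedly even with reference averaging: single
  events at that noise level should be interpreted with the posterior
  width, not the point estimate, in hand.
* The G2 correction terms assume the spot near the window center when
  evaluating the in-ROI mass fraction; strongly off-center spots push G2
  toward G1 behaviour earlier than the closed form suggests.
* Dynamic interference (a *moving* neighbour entering the window during
  the fit) is not modeled; static clutter and smooth background are.
* The amplitude nuisance `a` is reported but, under the default
  shape-normalized distance, its posterior is essentially the prior; treat
  `a_mmse` as a diagnostic only.

## 8. Problem sizes used in validation

The test-suite and acceptance computations use the reference conditions
above with: 200 seed replicates × 1000 particles for the renderer
cross-check; $N = 10^5$ ABC draws per fit (quantile 1%); five SNR levels
and four ROI sizes (15–41 px); $T$ doublings 300→4800 for the G2 limit;
2·10⁴ Monte-Carlo draws per intensity level for the variance-stabilization
check. The full suite runs in well under a minute of compute for the
models and a few tens of seconds for the simulation-heavy parts.
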