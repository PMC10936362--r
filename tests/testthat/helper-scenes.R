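# Shared fixtures, built in code at test time.

# amplitude nuisance corresponding to gain * C0 with the unit-mass PSF
a_of <- function(gain, C0) (gain * C0)^2 / (4 * pi)

# peak noiseless amplitude at the first post-fusion frame
peak_amp <- function(D, C0 = 500, gain = 1, sigma = 1.3) {
  gain * C0 / (2 * pi * (sigma^2 + 2 * D))
}

# default validation scene: one centered spot, D = 0.5 px^2/frame, 31x31
base_scene <- function(T = 300, noise_sigma = 0, seed = 1L, D = 0.5,
                       dims = c(31, 31)) {
  scene_spec(image_dims = dims, T = T,
             spot = diffusion_params(D, 500, (dims + 1) / 2, t0 = 1),
             optics = optics_params(1.3, 1),
             noise_sigma = noise_sigma, seed = seed)
}

# noise-free uniform-variant curve of the base scene
base_obs <- function(max_lag = 50, T = 300, D = 0.5, dims = c(31, 31)) {
  out <- render_analytic(base_scene(T = T, D = D, dims = dims))
  empirical_autocorr(roi_series(out$seq$data), max_lag = max_lag)
}
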