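#' Image sequence container
#'
#' A `H x W x T` stack of fluorescence intensities with frame-interval
#' metadata.
#'
#' @param data Numeric `H x W x T` array (a matrix is taken as one frame).
#' @param frame_interval Seconds per frame (metadata only).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(data, frame_interval = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, frame_interval = frame_interval),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image sequence: %d x %d px, %d frames\n", d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.image_sequence <- function(x) dim(x$data)

#' Scene specification for the synthetic-sequence simulator
#'
#' Describes a ground-truthed scene: one main diffusing spot, optional
#' clutter spots (diffusing or static), a constant or tilted-plane
#' background, and additive white Gaussian noise. The defaults mirror the
#' simulation protocol used throughout the package's validation: a single
#' centered spot with `D = 0.5` pixel^2/frame in a 31 x 31 window observed
#' for 300 frames.
#'
#' A spot's fusion frame `t0` is the 1-based index of its first post-fusion
#' frame; at frame `k >= t0` the spot has been diffusing for `k - t0 + 1`
#' frame intervals (the fusion instant itself, where the intensity profile
#' is the bare PSF, falls between frames). Frames before `t0` contain no
#' spot signal.
#'
#' @param image_dims Integer `c(H, W)` (pixels).
#' @param T Number of frames, `>= 2`.
#' @param spot Main-spot [diffusion_params()] (its `t0` is the 1-based first
#'   post-fusion frame; default 1). Default `D = 0.5`, `C0 = 500`, centered.
#' @param optics [optics_params()] shared by all spots.
#' @param clutter List of extra spots, each a list with `D` (`>= 0`; 0 means
#'   a static spot), `C0`, `x0`, and optional `t0` (default 1).
#' @param background A single constant level, or `list(b0, br, bc)` for the
#'   tilted plane `b0 + br * (row - 1) + bc * (col - 1)`.
#' @param noise_sigma Additive Gaussian noise sd (a.u.), `>= 0`.
#' @param seed Integer RNG seed.
#' @param frame_interval Seconds per frame (metadata only).
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_dims = c(31, 31), T = 300,
                       spot = NULL, optics = optics_params(1.3, 1),
                       clutter = list(), background = 0,
                       noise_sigma = 0, seed = 1L,
                       frame_interval = NA_real_) {
  stopifnot(T >= 2, noise_sigma >= 0, length(image_dims) == 2)
  if (is.null(spot))
    spot <- diffusion_params(D = 0.5, C0 = 500,
                             x0 = (as.integer(image_dims) + 1) / 2, t0 = 1)
  if (spot$t0 < 1) spot$t0 <- 1
  inside <- function(x0) all(x0 >= 1) && x0[1] <= image_dims[1] &&
    x0[2] <= image_dims[2]
  if (!inside(spot$x0)) stop("main spot lies outside the image", call. = FALSE)
  for (cl in clutter)
    if (!inside(cl$x0)) stop("clutter spot lies outside the image", call. = FALSE)
  if (is.numeric(background) && length(background) == 1)
    background <- list(b0 = background, br = 0, bc = 0)
  structure(list(image_dims = as.integer(image_dims), T = as.integer(T),
                 spot = spot, optics = optics, clutter = clutter,
                 background = background, noise_sigma = noise_sigma,
                 seed = as.integer(seed), frame_interval = frame_interval),
            class = "scene_spec")
}

# Gaussian spot profile on the lattice; D = 0 gives a static PSF-shaped spot.
spot_profile <- function(dims, elapsed, D, C0, x0, sigma, gain) {
  v <- sigma^2 + 2 * D * elapsed
  gy <- exp(-((seq_len(dims[1]) - x0[1])^2) / (2 * v))
  gx <- exp(-((seq_len(dims[2]) - x0[2])^2) / (2 * v))
  (gain * C0 / (2 * pi * v)) * outer(gy, gx)
}

background_field <- function(dims, bg) {
  bg$b0 + outer(bg$br * (seq_len(dims[1]) - 1), bg$bc * (seq_len(dims[2]) - 1), "+")
}

noiseless_frames <- function(scene) {
  d <- scene$image_dims
  bg <- background_field(d, scene$background)
  o <- scene$optics
  spots <- c(list(list(D = scene$spot$D, C0 = scene$spot$C0,
                       x0 = scene$spot$x0, t0 = scene$spot$t0)),
             lapply(scene$clutter, function(cl) {
               if (is.null(cl$t0)) cl$t0 <- 1
               cl
             }))
  arr <- array(0, dim = c(d, scene$T))
  for (k in seq_len(scene$T)) {
    frame <- bg
    for (sp in spots) {
      if (k >= sp$t0)
        frame <- frame + spot_profile(d, k - sp$t0 + 1, sp$D, sp$C0, sp$x0,
                                      o$sigma_psf, o$gain)
    }
    arr[, , k] <- frame
  }
  arr
}

scene_truth <- function(scene) {
  o <- scene$optics
  amp <- o$gain * scene$spot$C0 / (2 * pi * (o$sigma_psf^2 + 2 * scene$spot$D))
  list(true_D = scene$spot$D,
       x0 = scene$spot$x0,
       t0 = scene$spot$t0,
       clutter_D = vapply(scene$clutter, function(cl) cl$D, numeric(1)),
       noise_sigma = scene$noise_sigma,
       peak_amplitude = amp,
       snr = if (scene$noise_sigma > 0) amp / scene$noise_sigma else Inf,
       seed = scene$seed)
}

#' Render a scene with the analytic (closed-form) image model
#'
#' Each frame is the sum of the analytic Gaussian intensity profiles of all
#' spots, the background field, and i.i.d. Gaussian noise. Deterministic
#' given the scene's seed.
#'
#' @param scene A [scene_spec()].
#' @return List with `seq` (an [image_sequence()]) and `truth` (ground-truth
#'   sidecar: `true_D`, `x0`, `t0`, `noise_sigma`, `peak_amplitude`, `snr`,
#'   `seed`).
#' @export
#' @examples
#' out <- render_analytic(scene_spec(T = 50, noise_sigma = 1))
#' out$truth$snr
render_analytic <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  arr <- noiseless_frames(scene)
  if (scene$noise_sigma > 0) {
    set.seed(scene$seed)
    arr <- arr + stats::rnorm(length(arr), sd = scene$noise_sigma)
  }
  list(seq = image_sequence(arr, scene$frame_interval), truth = scene_truth(scene))
}

#' Render a scene with a Brownian-particle Monte Carlo model
#'
#' An image-formation oracle independent of the closed form: the main
#' spot's `C0` molecules are represented by `n_particles` random walkers
#' starting at `x0`, each taking per-frame Gaussian steps of per-axis
#' variance `2 D` and rendered as a Gaussian PSF carrying mass
#' `C0 / n_particles`. By the law of large numbers the particle frames
#' converge to the analytic render as `n_particles` (or seed replicates)
#' grow. Clutter spots with `D > 0` get their own walkers; static clutter
#' and the background are rendered analytically. Deterministic given `seed`.
#'
#' @param scene A [scene_spec()].
#' @param n_particles Walkers for the main spot, `>= 1`.
#' @param return_positions Logical; also return the main-spot walker
#'   positions (an `n_particles x 2 x T` array, elapsed frames 1..T).
#' @return List with `seq`, `truth`, and optionally `positions`.
#' @export
render_particles <- function(scene, n_particles = 1000, return_positions = FALSE) {
  stopifnot(inherits(scene, "scene_spec"), n_particles >= 1)
  d <- scene$image_dims
  o <- scene$optics
  set.seed(scene$seed)
  bg <- background_field(d, scene$background)
  arr <- array(0, dim = c(d, scene$T))

  walk_spot <- function(sp, n) {
    # cumulative Brownian steps: per-axis displacement variance 2*D per frame
    nsteps <- scene$T - sp$t0 + 1L
    if (nsteps < 1) return(NULL)
    dy <- matrix(stats::rnorm(n * nsteps, sd = sqrt(2 * sp$D)), n, nsteps)
    dx <- matrix(stats::rnorm(n * nsteps, sd = sqrt(2 * sp$D)), n, nsteps)
    if (nsteps > 1) for (j in 2:nsteps) {
      dy[, j] <- dy[, j] + dy[, j - 1]
      dx[, j] <- dx[, j] + dx[, j - 1]
    }
    list(y = sp$x0[1] + dy, x = sp$x0[2] + dx)
  }
  render_walkers <- function(arr, sp, pos, n) {
    mass <- o$gain * (sp$C0 / n) / (2 * pi * o$sigma_psf^2)
    ry <- seq_len(d[1]); rx <- seq_len(d[2])
    for (k in seq.int(sp$t0, scene$T)) {
      e <- k - sp$t0 + 1L
      py <- if (is.matrix(pos$y)) pos$y[, e] else pos$y[e]
      px <- if (is.matrix(pos$x)) pos$x[, e] else pos$x[e]
      Gy <- exp(-outer(ry, py, "-")^2 / (2 * o$sigma_psf^2))  # My x n
      Gx <- exp(-outer(rx, px, "-")^2 / (2 * o$sigma_psf^2))  # Mx x n
      arr[, , k] <- arr[, , k] + mass * (Gy %*% t(Gx))
    }
    arr
  }

  main <- list(D = scene$spot$D, C0 = scene$spot$C0, x0 = scene$spot$x0,
               t0 = scene$spot$t0)
  pos <- if (main$D > 0) walk_spot(main, n_particles) else
    list(y = matrix(main$x0[1], n_particles, scene$T - main$t0 + 1L),
         x = matrix(main$x0[2], n_particles, scene$T - main$t0 + 1L))
  arr <- render_walkers(arr, main, pos, n_particles)

  for (cl in scene$clutter) {
    if (is.null(cl$t0)) cl$t0 <- 1
    if (cl$D > 0) {
      cpos <- walk_spot(cl, n_particles)
      arr <- render_walkers(arr, cl, cpos, n_particles)
    } else {
      for (k in seq.int(cl$t0, scene$T))
        arr[, , k] <- arr[, , k] +
          spot_profile(d, k - cl$t0 + 1, 0, cl$C0, cl$x0, o$sigma_psf, o$gain)
    }
  }
  arr <- arr + as.vector(bg)
  if (scene$noise_sigma > 0)
    arr <- arr + stats::rnorm(length(arr), sd = scene$noise_sigma)

  out <- list(seq = image_sequence(arr, scene$frame_interval),
              truth = scene_truth(scene))
  if (return_positions) {
    T_eff <- scene$T - main$t0 + 1L
    positions <- array(NA_real_, dim = c(n_particles, 2, T_eff))
    positions[, 1, ] <- pos$y
    positions[, 2, ] <- pos$x
    out$positions <- positions
  }
  out
}

#' Clone a scene across signal-to-noise ratios
#'
#' SNR is defined as the main spot's peak noiseless amplitude at its first
#' post-fusion frame (above background) divided by the noise sd; each
#' returned scene has `noise_sigma = peak_amplitude / snr`.
#'
#' @param base A [scene_spec()].
#' @param snr_values Positive SNR values.
#' @return List of `scene_spec`s, one per SNR (named by SNR).
#' @export
snr_sweep <- function(base, snr_values) {
  stopifnot(inherits(base, "scene_spec"), all(snr_values > 0))
  o <- base$optics
  amp <- o$gain * base$spot$C0 / (2 * pi * (o$sigma_psf^2 + 2 * base$spot$D))
  out <- lapply(snr_values, function(s) {
    sc <- base
    sc$noise_sigma <- amp / s
    sc
  })
  names(out) <- as.character(snr_values)
  out
}

#' Six-scene robustness battery
#'
#' Emits the six-case suite used to probe robustness to spot position, ROI
#' size and shape, clutter, and noise: (a) off-center spot in a small
#' window at low SNR; (b) centered spot, medium window; (c) off-center spot
#' in a rectangular window; (d) large window with one static clutter spot;
#' (e) large window with one static and one diffusing neighbour; (f)
#' centered spot, medium window, high SNR. ROI dimensions and the true `D`
#' are parameters with defaults, not fixed constants.
#'
#' @param D True diffusion coefficient (pixel^2/frame).
#' @param T Frames per sequence.
#' @param C0 Released molecule count per spot.
#' @param seed Base RNG seed; scene i uses `seed + i`.
#' @param sizes Optional list of six `c(H, W)` window sizes.
#' @return Named list of six [scene_spec()]s.
#' @export
scenario_suite <- function(D = 0.5, T = 300, C0 = 500, seed = 1L,
                           sizes = NULL) {
  if (is.null(sizes))
    sizes <- list(c(15, 15), c(21, 21), c(21, 41), c(41, 41), c(41, 41),
                  c(31, 31))
  stopifnot(length(sizes) == 6)
  o <- optics_params(1.3, 1)
  amp <- o$gain * C0 / (2 * pi * (o$sigma_psf^2 + 2 * D))
  off <- function(dims, dr, dc) (dims + 1) / 2 + c(dr, dc)
  mk <- function(i, dims, x0, snr, clutter = list()) {
    scene_spec(image_dims = dims, T = T,
               spot = diffusion_params(D, C0, x0, t0 = 1),
               optics = o, clutter = clutter,
               noise_sigma = amp / snr, seed = seed + i)
  }
  list(
    a_offcenter_small_lowsnr = mk(1, sizes[[1]], off(sizes[[1]], 2, -2), snr = 2),
    b_centered_medium        = mk(2, sizes[[2]], off(sizes[[2]], 0, 0),  snr = 8),
    c_offcenter_rect         = mk(3, sizes[[3]], off(sizes[[3]], 1, -6), snr = 8),
    d_clutter_static         = mk(4, sizes[[4]], off(sizes[[4]], -3, 3), snr = 8,
      clutter = list(list(D = 0, C0 = C0 / 2,
                          x0 = off(sizes[[4]], 10, -10)))),
    e_clutter_mixed          = mk(5, sizes[[5]], off(sizes[[5]], 3, -3), snr = 8,
      clutter = list(list(D = 0,     C0 = C0 / 2, x0 = off(sizes[[5]], -12, 12)),
                     list(D = D / 2, C0 = C0 / 2, x0 = off(sizes[[5]], 12, 12)))),
    f_centered_highsnr       = mk(6, sizes[[6]], off(sizes[[6]], 0, 0),  snr = 16)
  )
}
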