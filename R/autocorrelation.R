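#' ROI time series: the unit of analysis
#'
#' A cropped sub-stack around one spot, stored as an `My x Mx x T` array
#' (rows, columns, frames), together with its spatial origin in the parent
#' image, the spot's reference (fusion) frame `t0`, and the frame interval
#' as optional metadata.
#'
#' @param data Numeric `My x Mx x T` array of intensities (a.u.). A matrix is
#'   accepted for a single-frame series.
#' @param origin Integer length-2 `c(row, col)` of the ROI's top-left pixel in
#'   the parent image (1-based). Defaults to `c(1, 1)`.
#' @param t0 Reference frame index within the series (1-based), in `[1, T]`.
#' @param frame_interval Seconds per frame (metadata only).
#'
#' @return An object of class `roi_series`.
#' @export
roi_series <- function(data, origin = c(1L, 1L), t0 = 1L, frame_interval = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (d[3] < 1) stop("series must contain at least one frame", call. = FALSE)
  if (t0 < 1 || t0 > d[3])
    stop("'t0' must lie within [1, T]", call. = FALSE)
  structure(list(data = data, origin = as.integer(origin), t0 = as.integer(t0),
                 frame_interval = frame_interval),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ROI series: %d x %d px, %d frames (origin %d,%d; t0 = %d)\n",
              d[1], d[2], d[3], x$origin[1], x$origin[2], x$t0))
  invisible(x)
}

#' @export
dim.roi_series <- function(x) dim(x$data)

new_autocorr_curve <- function(lags, values, variant, roi_dims, T,
                               t_ref = 1) {
  stopifnot(length(lags) == length(values), !is.unsorted(lags, strictly = TRUE))
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 variant = variant, roi_dims = as.integer(roi_dims),
                 T = as.integer(T), t_ref = t_ref),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf("Autocorrelation curve (%s variant): %d lags in [%g, %g], ROI %d x %d, T = %d\n",
              x$variant, length(x$lags), min(x$lags), max(x$lags),
              x$roi_dims[1], x$roi_dims[2], x$T))
  invisible(x)
}

#' @export
as.data.frame.autocorr_curve <- function(x, ...) {
  data.frame(lag_frames = x$lags, value = x$values)
}

#' @export
plot.autocorr_curve <- function(x, ..., add = FALSE, type = "l") {
  if (add) graphics::lines(x$lags, x$values, ...)
  else graphics::plot(x$lags, x$values, type = type,
                      xlab = "temporal lag (frames)",
                      ylab = expression(G(tau) ~ (a.u.^2)), ...)
  invisible(x)
}

#' Write an autocorrelation curve to CSV
#'
#' Two columns (`lag_frames`, `value`) preceded by `#` header comments
#' recording the variant, ROI dimensions and series length.
#'
#' @param curve An `autocorr_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_autocorr_csv <- function(curve, path) {
  stopifnot(inherits(curve, "autocorr_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# variant: %s", curve$variant),
               sprintf("# roi_dims: %d x %d", curve$roi_dims[1], curve$roi_dims[2]),
               sprintf("# T: %d", curve$T),
               sprintf("# t_ref: %g", curve$t_ref)), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Read an autocorrelation curve written by [write_autocorr_csv()]
#'
#' @param path CSV file path.
#' @return An `autocorr_curve`.
#' @export
read_autocorr_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(key) sub(sprintf("^# %s: *", key), "", hdr[grepl(paste0("^# ", key, ":"), hdr)])
  df <- utils::read.csv(path, comment.char = "#")
  dims <- as.integer(strsplit(field("roi_dims"), " x ")[[1]])
  T <- field("T")
  T <- if (identical(T, "NA")) NA_integer_ else as.integer(T)
  new_autocorr_curve(df$lag_frames, df$value, variant = field("variant"),
                     roi_dims = dims, T = T,
                     t_ref = as.numeric(field("t_ref")))
}

# Separable Gaussian smoothing with edge-replicate padding; kernel
# normalized to unit sum (mass-preserving, exact for constant images).
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- ceiling(6 * sigma)  # wide support: truncation below lattice precision
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  m <- mat[pad_idx(nrow(mat)), , drop = FALSE]
  m <- apply(m, 2, function(col) stats::convolve(col, k, type = "filter"))
  m <- m[, pad_idx(ncol(mat)), drop = FALSE]
  t(apply(m, 1, function(row) stats::convolve(row, k, type = "filter")))
}

#' Empirical nonstationary temporal autocorrelation of an ROI series
#'
#' The imaged spot is a transient, decaying signal: the process is not
#' stationary in time, so the autocorrelation is anchored at a reference
#' frame rather than averaged over a sliding time origin. For each lag
#' `tau`, the estimator is the spatial average over the ROI of the product
#' of the reference frame with the frame `tau` later:
#' \deqn{\hat G(\tau) = \frac{1}{M_x M_y} \sum_{x \in \Omega}
#'   j(x, t_\mathrm{ref})\, j(x, t_\mathrm{ref} + \tau),}
#' where `j = i` for the `"uniform"` variant (isolated spot over a uniform
#' background) and `j = i - m` for the `"fluctuation"` variant, with `m` the
#' scalar spatiotemporal mean of the series (used when nonuniform background
#' or neighbouring spots make the mean non-negligible). By default the
#' reference frame is the first frame of the (truncated) series, i.e. the
#' first post-fusion frame, where the spot is sharpest.
#'
#' Negative fluctuation values are kept as-is; the ABC distance handles
#' signed curves.
#'
#' @param roi A [roi_series()] (assumed already truncated so that frame 1 is
#'   the first post-fusion frame; see [truncate_series()]).
#' @param max_lag Largest lag (frames). Default `floor(T/4)`, capped at
#'   `T - t_ref`. Must satisfy `t_ref + max_lag <= T`.
#' @param variant `"uniform"` or `"fluctuation"`.
#' @param tau_min Smallest lag, `>= 0`; default 1 (the zero-lag value is
#'   dominated by the noise variance and excluded from fitting, as in
#'   standard FCS/TICS practice).
#' @param t_ref Reference frame index (1-based), default 1.
#' @param ref_smooth Gaussian bandwidth (pixels) used to smooth the
#'   reference frame before correlating; default 2. Because the reference
#'   frame multiplies every lagged frame, its pixel noise does not average
#'   out over time; matched-filter smoothing suppresses it by roughly
#'   `4 pi ref_smooth^2`-fold while the closed-form models absorb the
#'   smoothing exactly (a Gaussian convolved with a Gaussian), simply
#'   widening the reference profile by `ref_smooth^2`. Set 0 to disable; use
#'   the same value in [model_g1()]/[model_g2()] and [abc_config()].
#' @param n_ref Number of consecutive reference frames
#'   (`t_ref, ..., t_ref + n_ref - 1`) whose single-reference curves are
#'   averaged; default 1 (the canonical estimator). With noisy data each lag
#'   of a single-reference curve rests on one frame pair, so its noise never
#'   averages out; `n_ref = 8` (the analysis default in [estimate_spot()])
#'   reduces the per-lag noise by about `1/sqrt(n_ref)`. The closed-form
#'   models accept the same `n_ref` and average exactly the same way.
#'
#' @return An `autocorr_curve`.
#' @export
#' @examples
#' p <- diffusion_params(D = 0.5, C0 = 300, x0 = c(16, 16))
#' o <- optics_params(1.3, gain = 2)
#' frames <- sapply(1:120, function(t) render_frame(c(31, 31), t, p, o),
#'                  simplify = "array")
#' g <- empirical_autocorr(roi_series(frames), max_lag = 30)
empirical_autocorr <- function(roi, max_lag = NULL,
                               variant = c("uniform", "fluctuation"),
                               tau_min = 1L, t_ref = 1L, ref_smooth = 2,
                               n_ref = 1L) {
  stopifnot(inherits(roi, "roi_series"))
  variant <- match.arg(variant)
  d <- dim(roi$data)
  T <- d[3]
  if (T < 2) stop("series must contain at least two frames", call. = FALSE)
  stopifnot(n_ref >= 1)
  t_last <- t_ref + n_ref - 1L
  if (is.null(max_lag)) max_lag <- min(floor(T / 4), T - t_last)
  if (max_lag >= T)
    stop("'max_lag' must be smaller than the number of frames", call. = FALSE)
  if (t_last + max_lag > T)
    stop("reference frames plus 'max_lag' exceed the series length", call. = FALSE)
  if (tau_min < 0 || tau_min > max_lag)
    stop("'tau_min' must lie in [0, max_lag]", call. = FALSE)
  x <- roi$data
  if (variant == "fluctuation") x <- x - mean(x)
  A <- d[1] * d[2]
  lags <- seq.int(tau_min, max_lag)
  vals <- numeric(length(lags))
  for (tr in seq.int(t_ref, t_last)) {
    ref <- gauss_smooth(x[, , tr], ref_smooth)
    vals <- vals + vapply(lags, function(tau) sum(ref * x[, , tr + tau]) / A,
                          numeric(1))
  }
  vals <- vals / n_ref
  out <- new_autocorr_curve(lags, vals, variant = variant, roi_dims = d[1:2],
                            T = T, t_ref = t_ref)
  out$ref_smooth <- ref_smooth
  out$n_ref <- as.integer(n_ref)
  out
}

check_theta <- function(theta) {
  if (is.list(theta)) theta <- c(D = theta$D, a = theta$a)
  if (is.null(names(theta))) names(theta) <- c("D", "a")
  if (length(theta) != 2 || any(!is.finite(theta)) || any(theta <= 0))
    stop("'theta' must be two strictly positive finite values (D, a)",
         call. = FALSE)
  theta
}

#' Closed-form autocorrelation model G1 (uniform background)
#'
#' For an isolated spot over a uniform background, substituting the Gaussian
#' intensity profile into the reference-frame autocorrelation and replacing
#' the ROI pixel sum by a plane integral gives
#' \deqn{G_1(\tau) = \frac{a}{M_x M_y\, (\sigma_e^2 + D (2 t_\mathrm{ref} + \tau))},}
#' with `a = gain^2 C0^2 / (4 pi)` an amplitude nuisance folding the lumped
#' gain, the released molecule count and the PSF normalization into one
#' scalar, and `sigma_e^2 = sigma_psf^2 + ref_smooth^2 / 2` the effective
#' squared width combining the PSF bandwidth (a fixed instrument constant,
#' not a fitted parameter) with the reference-frame smoothing used by
#' [empirical_autocorr()]. The ROI size enters only as the multiplicative factor
#' `1/(Mx My)`; the curve is strictly decreasing in `tau` for `D > 0`, and
#' its inverse `1/G1` is exactly affine in `tau` — the basis of the
#' linearized fit returned by [inverse_g1_line()].
#'
#' @param lags Numeric vector of temporal lags (frames), `>= 0`.
#' @param theta Named vector or list with elements `D` (pixel^2/frame) and
#'   `a` (a.u.), both `> 0`.
#' @param roi_dims Integer length-2 `c(My, Mx)`.
#' @param sigma_psf PSF bandwidth (pixels).
#' @param t_ref Elapsed time of the reference frame since fusion (frames);
#'   default 1 (first usable frame one frame interval after fusion, avoiding
#'   the delta singularity at the fusion instant).
#' @param ref_smooth Reference-frame smoothing bandwidth (pixels) matching
#'   the estimator's; default 2.
#' @param n_ref Number of averaged reference frames matching the
#'   estimator's; default 1 (for which `1/G1` is exactly affine in the lag).
#'
#' @return An `autocorr_curve` (variant `"uniform"`).
#' @export
#' @examples
#' g <- model_g1(1:50, c(D = 0.5, a = 1e4), roi_dims = c(31, 31))
model_g1 <- function(lags, theta, roi_dims, sigma_psf = 1.3, t_ref = 1,
                     ref_smooth = 2, n_ref = 1L) {
  theta <- check_theta(theta)
  stopifnot(length(roi_dims) == 2, all(roi_dims >= 1), sigma_psf > 0,
            ref_smooth >= 0, n_ref >= 1)
  A <- prod(roi_dims)
  s2e <- sigma_psf^2 + ref_smooth^2 / 2
  vals <- 0
  for (tr in seq.int(t_ref, t_ref + n_ref - 1))
    vals <- vals + theta[["a"]] / (A * (s2e + theta[["D"]] * (2 * tr + lags)))
  out <- new_autocorr_curve(lags, vals / n_ref, variant = "uniform",
                            roi_dims = roi_dims, T = NA_integer_,
                            t_ref = t_ref)
  out$ref_smooth <- ref_smooth
  out$n_ref <- as.integer(n_ref)
  out
}

#' Coefficients of the affine inverse of G1
#'
#' `1/G1(tau)` is affine in the lag:
#' `1/G1 = intercept + slope * tau` with
#' `slope = Mx My D / a` and `intercept = Mx My (sigma_e^2 + 2 D t_ref) / a`,
#' where `sigma_e^2 = sigma_psf^2 + ref_smooth^2 / 2`.
#' Given the fitted line, the diffusion coefficient follows from
#' `D = sigma_e^2 * slope / (intercept - 2 * t_ref * slope)` without
#' knowledge of the amplitude `a` — a fast diagnostic (and initializer)
#' complementing the full Bayesian fit.
#'
#' @inheritParams model_g1
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
inverse_g1_line <- function(theta, roi_dims, sigma_psf = 1.3, t_ref = 1,
                            ref_smooth = 2) {
  theta <- check_theta(theta)
  A <- prod(roi_dims)
  s2e <- sigma_psf^2 + ref_smooth^2 / 2
  c(slope = A * theta[["D"]] / theta[["a"]],
    intercept = A * (s2e + 2 * theta[["D"]] * t_ref) / theta[["a"]])
}

# In-ROI mass fraction of a centered Gaussian profile with per-axis
# variance v on an Mx x My window (erf product).
roi_mass_fraction <- function(v, roi_dims) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  erf(roi_dims[2] / (2 * sqrt(2 * v))) * erf(roi_dims[1] / (2 * sqrt(2 * v)))
}

#' Closed-form autocorrelation model G2 (nonuniform/cluttered background)
#'
#' When the spatiotemporal mean of the ROI signal is not negligible
#' (nonuniform background, neighbouring spots), the autocorrelation is
#' computed on mean-subtracted fluctuations. Carrying the scalar mean
#' through the closed form yields
#' \deqn{G_2(\tau; T) = G_1(\tau) - m(T)\,[\mu(t_\mathrm{ref}) +
#'   \mu(t_\mathrm{ref}+\tau)] + m(T)^2,}
#' where `mu(t) = sqrt(4 pi a) E(t) / (Mx My)` is the model ROI-mean of the
#' spot image at elapsed time `t`, `E(t)` the fraction of the spread
#' Gaussian's mass inside the ROI (erf product, centered spot), and
#' `m(T) = mean(mu(t), t = 1..T)` the spatiotemporal mean over the `T`
#' observed frames. The total observation time `T` enters only through these
#' correction terms: as `T` grows the spot's mass spreads out of the ROI,
#' `m(T) -> 0`, and `G2` converges to `G1` — the out-of-equilibrium
#' correction is minimal for long sequences.
#'
#' @inheritParams model_g1
#' @param T Total number of observed frames, `>= 2`.
#'
#' @return An `autocorr_curve` (variant `"fluctuation"`).
#' @export
#' @examples
#' g2 <- model_g2(1:50, c(D = 0.5, a = 1e4), c(31, 31), T = 300)
model_g2 <- function(lags, theta, roi_dims, T, sigma_psf = 1.3, t_ref = 1,
                     ref_smooth = 2, n_ref = 1L) {
  theta <- check_theta(theta)
  stopifnot(length(roi_dims) == 2, all(roi_dims >= 1), sigma_psf > 0,
            ref_smooth >= 0, n_ref >= 1)
  if (!is.numeric(T) || length(T) != 1 || T < 2)
    stop("'T' must be a single value >= 2", call. = FALSE)
  A <- prod(roi_dims)
  D <- theta[["D"]]; a <- theta[["a"]]
  s2e <- sigma_psf^2 + ref_smooth^2 / 2
  gC0 <- sqrt(4 * pi * a)
  mu <- function(t) gC0 * roi_mass_fraction(sigma_psf^2 + 2 * D * t, roi_dims) / A
  m <- mean(mu(seq(t_ref, by = 1, length.out = T)))
  vals <- 0
  for (tr in seq.int(t_ref, t_ref + n_ref - 1)) {
    g1 <- a / (A * (s2e + D * (2 * tr + lags)))
    # the smoothed reference profile is wider by ref_smooth^2 but keeps mass
    mu_ref <- gC0 * roi_mass_fraction(
      sigma_psf^2 + ref_smooth^2 + 2 * D * tr, roi_dims) / A
    vals <- vals + g1 - m * (mu_ref + mu(tr + lags)) + m^2
  }
  out <- new_autocorr_curve(lags, vals / n_ref, variant = "fluctuation",
                            roi_dims = roi_dims, T = T, t_ref = t_ref)
  out$ref_smooth <- ref_smooth
  out$n_ref <- as.integer(n_ref)
  out
}
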