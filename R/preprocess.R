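#' Preprocessing configuration
#'
#' Controls how a raw ROI series is turned into an analysis-ready series:
#' ROI size, the number of frames used for the median background estimate,
#' optional generalized Anscombe variance stabilization, and the number of
#' post-fusion frames retained for fitting.
#'
#' ROI sizes are expected odd in both dimensions so a detected spot can sit
#' on a center pixel; even sizes are accepted with the center falling on the
#' pixel grid's upper-left of the four central pixels (half-pixel
#' convention).
#'
#' @param roi_size Integer length-2 `c(My, Mx)` (pixels).
#' @param background_frames Frames used for the pixelwise median background,
#'   `>= 1`; default 20.
#' @param background_from Which frames feed the median: `"auto"` (default)
#'   uses the frames immediately before the detected fusion frame — for a
#'   fusion event they are spot-free by construction — falling back to
#'   `"last"` when no pre-fusion frames exist; `"last"` (the protocol for
#'   recordings that begin mid-event: the user keeps the end of the sequence
#'   free of other diffusing spots — note the late frames still hold the
#'   spot of interest's residual density, about `C0 / (4 pi D t_end)` per
#'   pixel, which biases the fit once it is not small against the
#'   background); `"first"`; or an explicit integer vector of frame
#'   indices.
#' @param background_smooth Smoothing of the median background image passed
#'   to [estimate_background()]: `"plane"` (default), `"quadratic"`, or
#'   `"none"`.
#' @param anscombe Logical; apply the generalized Anscombe transform before
#'   background estimation.
#' @param gain,sigma_read,offset Poisson-Gaussian noise-model parameters for
#'   the transform; `NULL` to estimate robustly from the darkest 10% of
#'   pixels (gain then defaults to 1).
#' @param T_fit Frames retained after the fusion frame, `>= 2`; 100 is
#'   adequate for the G1 model, 300 for G2.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(roi_size = c(31, 31), background_frames = 20L,
                              background_from = "auto",
                              background_smooth = "plane", anscombe = FALSE,
                              gain = NULL, sigma_read = NULL, offset = NULL,
                              T_fit = 100L) {
  stopifnot(length(roi_size) == 2, all(roi_size >= 3),
            background_frames >= 1, T_fit >= 2)
  if (any(roi_size %% 2 == 0))
    warning("even ROI size: spot center falls between pixels", call. = FALSE)
  structure(list(roi_size = as.integer(roi_size),
                 background_frames = as.integer(background_frames),
                 background_from = background_from,
                 background_smooth = background_smooth,
                 anscombe = isTRUE(anscombe), gain = gain,
                 sigma_read = sigma_read, offset = offset,
                 T_fit = as.integer(T_fit)),
            class = "preprocess_config")
}

#' Extract an ROI series from an image sequence
#'
#' Crops a `size` window centered at `center` from every frame. The ROI must
#' lie fully inside the image: crossing a border is an error, never padded.
#'
#' @param seq An [image_sequence()] or a raw `H x W x T` array.
#' @param center Integer length-2 `c(row, col)` of the ROI center (1-based).
#' @param size Integer length-2 `c(My, Mx)`.
#' @return A [roi_series()] with its `origin` recorded.
#' @export
extract_roi <- function(seq, center, size) {
  arr <- if (inherits(seq, "image_sequence")) seq$data else seq
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  stopifnot(is.array(arr), length(dim(arr)) == 3,
            length(center) == 2, length(size) == 2, all(size >= 1))
  d <- dim(arr)
  half <- (as.integer(size) - 1L) %/% 2L
  r0 <- as.integer(center[1]) - half[1]
  c0 <- as.integer(center[2]) - half[2]
  r1 <- r0 + as.integer(size[1]) - 1L
  c1 <- c0 + as.integer(size[2]) - 1L
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2])
    stop(sprintf(
      "ROI [%d:%d, %d:%d] crosses the %dx%d image border (no padding)",
      r0, r1, c0, c1, d[1], d[2]), call. = FALSE)
  fi <- if (inherits(seq, "image_sequence")) seq$frame_interval else NA_real_
  roi_series(arr[r0:r1, c0:c1, , drop = FALSE], origin = c(r0, c0),
             frame_interval = fi)
}

#' Detect the fusion frame inside an ROI series
#'
#' Returns the index of the frame in which the fluorescence intensity is
#' maximal. At fusion all molecules sit in the sharp initial spot, so the
#' brightest pixel is sharply maximal there and decays as the spot spreads;
#' the default `"peak"` statistic takes the maximum of a 3 x 3 box-averaged
#' frame (the averaging suppresses single-pixel noise). The `"total"`
#' statistic (summed ROI intensity) is also available, but note that as long
#' as the spreading spot stays inside the ROI its total is conserved, so
#' post-fusion frames nearly tie and noise decides among them. Ties resolve
#' to the earliest frame.
#'
#' @param roi A [roi_series()].
#' @param statistic `"peak"` (default) or `"total"`.
#' @return Integer frame index (1-based).
#' @export
detect_t0 <- function(roi, statistic = c("peak", "total")) {
  stopifnot(inherits(roi, "roi_series"))
  statistic <- match.arg(statistic)
  score <- if (statistic == "total") {
    apply(roi$data, 3, sum)
  } else {
    d <- dim(roi$data)
    apply(roi$data, 3, function(f) {
      if (d[1] < 3 || d[2] < 3) return(max(f))
      sm <- f[1:(d[1]-2), 1:(d[2]-2)] + f[2:(d[1]-1), 1:(d[2]-2)] + f[3:d[1], 1:(d[2]-2)] +
            f[1:(d[1]-2), 2:(d[2]-1)] + f[2:(d[1]-1), 2:(d[2]-1)] + f[3:d[1], 2:(d[2]-1)] +
            f[1:(d[1]-2), 3:d[2]]     + f[2:(d[1]-1), 3:d[2]]     + f[3:d[1], 3:d[2]]
      max(sm) / 9
    })
  }
  which.max(score)  # which.max takes the first maximum: earliest frame
}

#' Estimate a static background image
#'
#' Pixelwise temporal median over `n_frames` frames of the series (by
#' default the last frames, which the user keeps free of diffusing spots),
#' optionally projected onto a smooth low-order field.
#'
#' The raw pixelwise median retains a residual noise pattern of variance
#' about `(pi/2) sigma^2 / n_frames`. Because the same estimate is
#' subtracted from every frame, that pattern is correlated across frames and
#' contributes a lag-independent offset to the temporal autocorrelation,
#' flattening the decay and biasing the diffusion estimate downward. When
#' the background is spatially smooth at ROI scale (the usual case in TIRF),
#' projecting the median image onto a tilted plane (`smooth = "plane"`, the
#' default) or a full quadratic (`"quadratic"`) removes the pattern while
#' keeping the nonuniform trend; `smooth = "none"` returns the raw median.
#'
#' @param roi A [roi_series()].
#' @param n_frames Number of frames entering the median; default 20.
#' @param from `"last"`, `"first"`, or explicit frame indices.
#' @param smooth `"plane"` (default), `"quadratic"`, or `"none"`.
#' @return An `My x Mx` background matrix.
#' @export
estimate_background <- function(roi, n_frames = 20L, from = "last",
                                smooth = c("plane", "quadratic", "none")) {
  stopifnot(inherits(roi, "roi_series"))
  smooth <- match.arg(smooth)
  T <- dim(roi$data)[3]
  idx <- if (is.numeric(from)) {
    as.integer(from)
  } else if (identical(from, "last")) {
    seq.int(T - n_frames + 1L, T)
  } else if (identical(from, "first")) {
    seq_len(n_frames)
  } else stop("'from' must be \"last\", \"first\" or frame indices",
              call. = FALSE)
  if (any(idx < 1) || any(idx > T))
    stop("background frames fall outside the series (n_frames > T?)",
         call. = FALSE)
  med <- apply(roi$data[, , idx, drop = FALSE], c(1, 2), stats::median)
  if (smooth == "none") return(med)
  d <- dim(med)
  r <- rep(seq_len(d[1]), times = d[2]) - (d[1] + 1) / 2
  c_ <- rep(seq_len(d[2]), each = d[1]) - (d[2] + 1) / 2
  X <- if (smooth == "plane") cbind(1, r, c_)
       else cbind(1, r, c_, r * c_, r^2, c_^2)
  fit <- stats::lm.fit(X, as.vector(med))
  matrix(X %*% fit$coefficients, d[1], d[2])
}

#' Subtract a background image from every frame
#'
#' Values may go negative; no clipping is applied — the fluctuation
#' autocorrelation handles signed values.
#'
#' @param roi A [roi_series()].
#' @param background An `My x Mx` matrix.
#' @return A [roi_series()].
#' @export
subtract_background <- function(roi, background) {
  stopifnot(inherits(roi, "roi_series"), is.matrix(background))
  d <- dim(roi$data)
  if (!all(dim(background) == d[1:2]))
    stop("background dimensions do not match the ROI", call. = FALSE)
  out <- roi
  out$data <- roi$data - as.vector(background)  # recycles over frames
  out
}

#' Truncate a series to the post-fusion window
#'
#' Keeps frames `[t0, t0 + T_fit)`; the returned series has its reference
#' frame at index 1. If fewer than `T_fit` frames remain after `t0`, all
#' available frames are kept with a warning.
#'
#' @param roi A [roi_series()].
#' @param t0 Fusion frame index (1-based), within the series.
#' @param T_fit Number of frames to retain.
#' @return A [roi_series()].
#' @export
truncate_series <- function(roi, t0, T_fit) {
  stopifnot(inherits(roi, "roi_series"))
  T <- dim(roi$data)[3]
  if (t0 < 1 || t0 > T) stop("'t0' outside the series", call. = FALSE)
  avail <- T - t0 + 1L
  if (T_fit > avail) {
    warning(sprintf("only %d frames available after t0; keeping all", avail),
            call. = FALSE)
    T_fit <- avail
  }
  out <- roi
  out$data <- roi$data[, , seq.int(t0, t0 + T_fit - 1L), drop = FALSE]
  out$t0 <- 1L
  out
}

#' Generalized Anscombe variance-stabilizing transform
#'
#' For Poisson-Gaussian camera noise `x = gain * Poisson(lambda) +
#' N(offset, sigma_read^2)`, the transform
#' \deqn{f(x) = \frac{2}{g}\sqrt{g x + \tfrac{3}{8} g^2 + \sigma_r^2 - g\,o}}
#' produces approximately unit-variance Gaussian noise at all intensity
#' levels. Inputs below the domain floor of the square root are clamped to
#' the floor; the transform is monotone nondecreasing. With `gain = 1`,
#' `sigma_read = 0`, `offset = 0` it reduces to the classical Anscombe
#' transform `2 sqrt(x + 3/8)`.
#'
#' @param img Numeric array/matrix/vector of intensities.
#' @param gain Camera gain `> 0` (a.u. per photo-electron).
#' @param sigma_read Read-noise standard deviation (a.u.).
#' @param offset Camera baseline offset (a.u.).
#' @return Transformed data of the same shape.
#' @export
generalized_anscombe <- function(img, gain = 1, sigma_read = 0, offset = 0) {
  if (gain <= 0) stop("'gain' must be positive", call. = FALSE)
  arg <- gain * img + 0.375 * gain^2 + sigma_read^2 - gain * offset
  out <- (2 / gain) * sqrt(pmax(arg, 0))
  if (is.array(img)) array(out, dim = dim(img)) else out
}

#' Robust Poisson-Gaussian noise parameters from dark pixels
#'
#' When camera metadata are unavailable, takes the darkest 10% of pixels as
#' signal-free: `offset` is their median, `sigma_read` their median absolute
#' deviation (scaled to a Gaussian sd), and `gain` defaults to 1.
#'
#' @param x Numeric array of raw intensities.
#' @return List with `gain`, `sigma_read`, `offset`.
#' @export
estimate_noise_params <- function(x) {
  dark <- x[x <= stats::quantile(x, 0.10)]
  list(gain = 1,
       sigma_read = stats::mad(dark),
       offset = stats::median(dark))
}

#' Full preprocessing pipeline for one spot
#'
#' Extract the ROI, optionally variance-stabilize, detect the fusion frame,
#' estimate and subtract the static median background (by default from the
#' pre-fusion frames; see [preprocess_config()]), and truncate to the
#' post-fusion fitting window. The fusion frame is detected before
#' background subtraction — a time-constant background shifts every frame's
#' peak statistic equally and cannot move the detected frame. Deterministic:
#' identical inputs give an identical series.
#'
#' @param seq An [image_sequence()] or `H x W x T` array.
#' @param center Integer `c(row, col)` spot location.
#' @param config A [preprocess_config()].
#' @return A [roi_series()] ready for [empirical_autocorr()].
#' @export
preprocess_roi <- function(seq, center, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  roi <- extract_roi(seq, center, config$roi_size)
  if (config$anscombe) {
    np <- if (is.null(config$gain))
      estimate_noise_params(roi$data)
    else list(gain = config$gain,
              sigma_read = if (is.null(config$sigma_read)) 0 else config$sigma_read,
              offset = if (is.null(config$offset)) 0 else config$offset)
    roi$data <- generalized_anscombe(roi$data, np$gain, np$sigma_read, np$offset)
  }
  t0 <- detect_t0(roi)
  from <- config$background_from
  if (identical(from, "auto")) {
    from <- if (t0 > 1)
      seq.int(max(1L, t0 - config$background_frames), t0 - 1L)
    else "last"
  }
  bg <- estimate_background(roi, config$background_frames, from,
                            config$background_smooth)
  roi <- subtract_background(roi, bg)
  roi <- truncate_series(roi, t0, config$T_fit)
  roi
}
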