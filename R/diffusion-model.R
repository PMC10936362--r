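#' Diffusion parameters of a single fluorescent spot
#'
#' Bundles the physical parameters of one diffusing spot: the lateral
#' diffusion coefficient `D`, the initial number of molecules `C0` released
#' at the source, the continuous source position `x0`, and the fusion (or
#' release) frame index `t0`. All molecules are assumed concentrated at `x0`
#' at the instant of fusion (a delta initial condition for Fick's second
#' law), after which they diffuse freely in the membrane plane.
#'
#' Units: `D` is carried in pixel^2/frame throughout the package. Given a
#' pixel size `p` (micrometres) and a frame interval `dt` (seconds), the
#' conversion to physical units is `D_um2_per_s = D * p^2 / dt`; pixel size
#' and frame interval are optional metadata and never enter the estimation.
#'
#' @param D Diffusion coefficient (pixel^2/frame), `> 0`.
#' @param C0 Initial number of molecules at the source (dimensionless), `> 0`.
#' @param x0 Numeric length-2 source position `c(row, col)` in continuous
#'   pixel coordinates. Pixel centers sit at integer coordinates, 1-based.
#' @param t0 Fusion frame index (frames), `>= 0`.
#'
#' @return An object of class `diffusion_params`.
#' @seealso [optics_params()], [intensity()], [render_frame()]
#' @export
#' @examples
#' p <- diffusion_params(D = 0.5, C0 = 500, x0 = c(16, 16))
diffusion_params <- function(D, C0 = 1, x0 = c(0, 0), t0 = 0) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D))
  if (D <= 0) stop("'D' must be strictly positive", call. = FALSE)
  if (C0 <= 0) stop("'C0' must be strictly positive", call. = FALSE)
  stopifnot(length(x0) == 2, all(is.finite(x0)), t0 >= 0)
  structure(list(D = D, C0 = C0, x0 = as.numeric(x0), t0 = t0),
            class = "diffusion_params")
}

#' Optics parameters: PSF width and lumped gain
#'
#' The microscope's point spread function is approximated by an isotropic 2D
#' Gaussian of lateral bandwidth `sigma_psf` (pixels), normalized to unit
#' mass. All multiplicative instrument factors (photon collection
#' efficiency, molecular absorption coefficient, fluorophore quantum yield)
#' are folded into the single lumped proportionality factor `gain`
#' (arbitrary intensity units per molecule); they are never needed
#' individually.
#'
#' @param sigma_psf Isotropic lateral PSF bandwidth (pixels), `> 0`.
#' @param gain Lumped intensity-per-molecule factor (a.u.), `> 0`.
#'
#' @return An object of class `optics_params`.
#' @export
#' @examples
#' o <- optics_params(sigma_psf = 1.3, gain = 3)
optics_params <- function(sigma_psf = 1.3, gain = 1) {
  if (!is.numeric(sigma_psf) || length(sigma_psf) != 1 || sigma_psf <= 0)
    stop("'sigma_psf' must be a single positive number", call. = FALSE)
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0)
    stop("'gain' must be a single positive number", call. = FALSE)
  structure(list(sigma_psf = sigma_psf, gain = gain), class = "optics_params")
}

#' Concentration field of a spot diffusing from a point source
#'
#' Free-space solution of Fick's second law in 2D with a delta initial
#' condition of mass `C0` at `x0`:
#' \deqn{C(x, t) = \frac{C_0}{4 \pi D t}
#'   \exp\!\left(-\frac{\|x - x_0\|^2}{4 D t}\right).}
#' The field is strictly positive, radially symmetric about `x0`, and its
#' integral over the plane equals `C0` at every `t > 0` (mass conservation).
#'
#' @param x Numeric length-2 position `c(row, col)` in pixel coordinates, or
#'   an n x 2 matrix of positions.
#' @param t Elapsed time since fusion (frames), `> 0`.
#' @param p A [diffusion_params()] object.
#'
#' @return Concentration (molecules/pixel^2), one value per row of `x`.
#' @export
#' @examples
#' p <- diffusion_params(D = 0.5, C0 = 100, x0 = c(0, 0))
#' concentration(c(1, 0), t = 2, p = p)
concentration <- function(x, t, p) {
  stopifnot(inherits(p, "diffusion_params"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive number (the field is singular at t = 0)",
         call. = FALSE)
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2)
  r2 <- (x[, 1] - p$x0[1])^2 + (x[, 2] - p$x0[2])^2
  p$C0 / (4 * pi * p$D * t) * exp(-r2 / (4 * p$D * t))
}

#' Fluorescence intensity profile of a diffusing spot
#'
#' The imaged intensity is the concentration field convolved with the
#' Gaussian PSF and scaled by the lumped gain. Since both factors are
#' Gaussian the convolution is itself Gaussian with per-axis variance
#' `sigma_psf^2 + 2 D t`:
#' \deqn{i(x, t) = \mathrm{gain}\, C_0 \,
#'   \frac{1}{2\pi(\sigma^2 + 2 D t)}
#'   \exp\!\left(-\frac{\|x - x_0\|^2}{2(\sigma^2 + 2 D t)}\right).}
#' At `t = 0` the profile is the PSF itself scaled by `gain * C0`; its
#' integral over the plane is `gain * C0` at every `t` (the convolution
#' preserves mass), and the per-axis second moment about `x0` grows linearly
#' in time with slope `2 D`.
#'
#' @inheritParams concentration
#' @param t Elapsed time since fusion (frames), `>= 0`.
#' @param o An [optics_params()] object.
#'
#' @return Fluorescence intensity (a.u.), one value per row of `x`.
#' @export
#' @examples
#' p <- diffusion_params(D = 0.5, C0 = 100, x0 = c(0, 0))
#' o <- optics_params(sigma_psf = 1.3, gain = 2)
#' intensity(c(0, 0), t = 0, p, o)  # peak at fusion: gain*C0/(2*pi*sigma^2)
intensity <- function(x, t, p, o) {
  stopifnot(inherits(p, "diffusion_params"), inherits(o, "optics_params"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("'t' must be a single nonnegative number", call. = FALSE)
  x <- if (is.matrix(x)) x else matrix(x, ncol = 2)
  v <- o$sigma_psf^2 + 2 * p$D * t
  r2 <- (x[, 1] - p$x0[1])^2 + (x[, 2] - p$x0[2])^2
  o$gain * p$C0 / (2 * pi * v) * exp(-r2 / (2 * v))
}

#' Render one analytic frame on a pixel lattice
#'
#' Evaluates [intensity()] at every pixel center of an `My x Mx` lattice
#' (point evaluation, not area integration: for PSF widths of a pixel or
#' more the difference is negligible). Pixel `(r, c)` has its center at
#' continuous coordinates `(r, c)`, 1-based.
#'
#' @param dims Integer length-2 lattice size `c(My, Mx)` (rows, cols).
#' @param t Elapsed time since fusion (frames), `>= 0`.
#' @param p A [diffusion_params()] object (with `x0` in lattice coordinates).
#' @param o An [optics_params()] object.
#'
#' @return An `My x Mx` numeric matrix of intensities.
#' @export
#' @examples
#' p <- diffusion_params(D = 0.5, C0 = 100, x0 = c(16, 16))
#' img <- render_frame(c(31, 31), t = 1, p, optics_params())
#' which(img == max(img), arr.ind = TRUE)  # 16, 16
render_frame <- function(dims, t, p, o) {
  stopifnot(length(dims) == 2, all(dims >= 1))
  My <- as.integer(dims[1]); Mx <- as.integer(dims[2])
  v <- o$sigma_psf^2 + 2 * p$D * t
  # separable Gaussian: outer product of the two axis profiles
  gy <- exp(-((seq_len(My) - p$x0[1])^2) / (2 * v))
  gx <- exp(-((seq_len(Mx) - p$x0[2])^2) / (2 * v))
  (o$gain * p$C0 / (2 * pi * v)) * outer(gy, gx)
}
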