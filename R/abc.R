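#' Uniform prior specification for (D, a)
#'
#' Both parameters get independent uniform priors on positive intervals.
#' The default for the diffusion coefficient, `D` in `[0.01, 10]`
#' pixel^2/frame, spans the dynamics resolvable at typical TIRF frame rates;
#' it should be adapted to the biological process at hand. When `a_bounds`
#' is `NULL`, bounds for the amplitude nuisance are moment-matched at fit
#' time from the first observed curve value (see [default_a_bounds()]),
#' spanning four orders of magnitude around the matched guess.
#'
#' @param d_bounds Length-2 `c(low, high)` for `D` (pixel^2/frame),
#'   `0 < low < high`.
#' @param a_bounds Length-2 `c(low, high)` for `a` (a.u.), or `NULL` to
#'   moment-match from the observed curve at fit time.
#'
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(d_bounds = c(0.01, 10), a_bounds = NULL) {
  chk <- function(b, nm) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop(sprintf("'%s' must satisfy 0 < low < high", nm), call. = FALSE)
    as.numeric(b)
  }
  d_bounds <- chk(d_bounds, "d_bounds")
  if (!is.null(a_bounds)) a_bounds <- chk(a_bounds, "a_bounds")
  structure(list(d_bounds = d_bounds, a_bounds = a_bounds),
            class = "prior_spec")
}

#' Moment-matched amplitude prior bounds
#'
#' Inverts the G1 model at the first observed lag using the geometric
#' mid-point of the `D` prior, and spans four orders of magnitude (a factor
#' of 100 each way) around the matched amplitude.
#'
#' @param obs Observed `autocorr_curve`.
#' @param prior A [prior_spec()].
#' @param sigma_psf PSF bandwidth (pixels).
#' @param t_ref Elapsed reference time (frames).
#' @param ref_smooth Reference-frame smoothing bandwidth (pixels).
#' @return Length-2 numeric bounds for `a`.
#' @export
default_a_bounds <- function(obs, prior, sigma_psf = 1.3, t_ref = 1,
                             ref_smooth = 2) {
  stopifnot(inherits(obs, "autocorr_curve"), inherits(prior, "prior_spec"))
  d_mid <- sqrt(prod(prior$d_bounds))
  A <- prod(obs$roi_dims)
  g1 <- abs(obs$values[1])
  if (g1 == 0) g1 <- max(abs(obs$values), .Machine$double.eps)
  s2e <- sigma_psf^2 + ref_smooth^2 / 2
  a_guess <- g1 * A * (s2e + d_mid * (2 * t_ref + obs$lags[1]))
  a_guess * c(1e-2, 1e2)
}

#' ABC sampler configuration
#'
#' @param n_samples Number of prior draws, `>= 100`. Default 100000.
#' @param acceptance Either `list(mode = "quantile", value = q)` with
#'   `0 < q <= 1` (keep exactly `ceiling(q * n_samples)` smallest-distance
#'   samples; default `q = 0.01`, i.e. the best 1% — the cut-off is chosen so
#'   as to accept 1 to 5% of the samples), or `list(mode = "epsilon",
#'   value = eps)` (keep all samples with distance `<= eps`).
#' @param distance `"normalized"` (default) or `"raw"`. Both are squared
#'   Euclidean distances between curves; `"normalized"` first divides each
#'   curve (observed and simulated) by its own first-lag value, so the
#'   distance compares decay shapes. Both models are exactly proportional to
#'   the amplitude nuisance `a`, which therefore cancels under
#'   `"normalized"`: the shape identifies `D` alone. Under `"raw"` the
#'   distance is dominated by the amplitude, and at lags where
#'   `D tau >> sigma_psf^2` only the ratio `a/D` is constrained, leaving a
#'   ridge of near-equivalent `(D, a)` pairs; `"raw"` therefore needs a
#'   tight, process-informed prior to localize `D` and tends to sit slightly
#'   high along the ridge.
#' @param seed Integer RNG seed, for bit-reproducible runs.
#' @param model `"g1"` or `"g2"`.
#' @param lags Lag grid (frames) on which observed and simulated curves are
#'   compared.
#' @param sigma_psf PSF bandwidth (pixels) used by the models.
#' @param t_ref Elapsed reference time (frames).
#' @param ref_smooth Reference-frame smoothing bandwidth (pixels) matching
#'   the estimator's; default 2.
#' @param n_ref Number of averaged reference frames matching the
#'   estimator's; default 1.
#' @param n_bins Histogram bin count for the posterior of `D`, or `NULL` for
#'   Freedman-Diaconis binning over the prior interval.
#'
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(n_samples = 1e5,
                       acceptance = list(mode = "quantile", value = 0.01),
                       distance = c("normalized", "raw"), seed = 1L,
                       model = c("g1", "g2"), lags = 1:50,
                       sigma_psf = 1.3, t_ref = 1, ref_smooth = 2,
                       n_ref = 1L, n_bins = NULL) {
  model <- match.arg(model)
  if (n_samples < 100) stop("'n_samples' must be >= 100", call. = FALSE)
  if (!is.list(acceptance) || !acceptance$mode %in% c("quantile", "epsilon"))
    stop("'acceptance' must be list(mode = 'quantile'|'epsilon', value = ...)",
         call. = FALSE)
  if (acceptance$mode == "quantile" &&
      (acceptance$value <= 0 || acceptance$value > 1))
    stop("acceptance quantile must lie in (0, 1]", call. = FALSE)
  distance <- match.arg(distance)
  structure(list(n_samples = as.integer(n_samples), acceptance = acceptance,
                 distance = distance, seed = as.integer(seed), model = model,
                 lags = lags, sigma_psf = sigma_psf, t_ref = t_ref,
                 ref_smooth = ref_smooth, n_ref = as.integer(n_ref),
                 n_bins = n_bins),
            class = "abc_config")
}

#' Draw parameter samples from the prior
#'
#' Independent uniforms on the two intervals. Vectorized: `n` draws come
#' back as an `n x 2` matrix with columns `D`, `a`.
#'
#' @param prior A [prior_spec()] with non-`NULL` `a_bounds`.
#' @param n Number of draws.
#' @return `n x 2` numeric matrix (columns `D`, `a`).
#' @export
sample_prior <- function(prior, n = 1) {
  stopifnot(inherits(prior, "prior_spec"))
  if (is.null(prior$a_bounds))
    stop("'a_bounds' unset; supply them or use default_a_bounds()", call. = FALSE)
  cbind(D = stats::runif(n, prior$d_bounds[1], prior$d_bounds[2]),
        a = stats::runif(n, prior$a_bounds[1], prior$a_bounds[2]))
}

#' Simulate a model autocorrelation curve for one parameter draw
#'
#' Dispatches to [model_g1()] or [model_g2()] according to the configured
#' model; deterministic given `theta`.
#'
#' @param theta Named vector/list with `D` and `a`.
#' @param config An [abc_config()].
#' @param roi_dims Integer length-2 `c(My, Mx)`.
#' @param T Total observed frames (required for `"g2"`).
#' @return An `autocorr_curve`.
#' @export
simulate_curve <- function(theta, config, roi_dims, T = NA_integer_) {
  stopifnot(inherits(config, "abc_config"))
  switch(config$model,
    g1 = model_g1(config$lags, theta, roi_dims, config$sigma_psf,
                  config$t_ref, config$ref_smooth, config$n_ref),
    g2 = model_g2(config$lags, theta, roi_dims, T, config$sigma_psf,
                  config$t_ref, config$ref_smooth, config$n_ref),
    stop("unknown model: ", config$model, call. = FALSE))
}

#' Squared Euclidean distance between two curves
#'
#' Zero iff the curves are identical; its square root is a metric. The lag
#' grids must match exactly.
#'
#' @param obs,sim `autocorr_curve` objects on the same lag grid.
#' @return Nonnegative scalar.
#' @export
l2_distance <- function(obs, sim) {
  stopifnot(inherits(obs, "autocorr_curve"), inherits(sim, "autocorr_curve"))
  if (length(obs$lags) != length(sim$lags) || any(obs$lags != sim$lags))
    stop("lag grids of the two curves do not match", call. = FALSE)
  sum((obs$values - sim$values)^2)
}

# Batched model curves: n x L matrix, one row per theta.
# Identical algebra to model_g1()/model_g2(); batching cannot change values
# (samples are independent), which the test suite cross-checks.
batch_curves <- function(D, a, config, roi_dims, T) {
  A <- prod(roi_dims)
  s2 <- config$sigma_psf^2
  s2e <- s2 + config$ref_smooth^2 / 2
  t0 <- config$t_ref
  R <- config$n_ref
  lags <- config$lags
  refs <- seq.int(t0, t0 + R - 1)
  acc <- 0
  if (config$model == "g1") {
    for (tr in refs)
      acc <- acc + (a / A) / outer(D, lags, function(d, l) s2e + d * (2 * tr + l))
    return(acc / R)
  }
  gC0 <- sqrt(4 * pi * a)
  # m(T): mean over frames of the model ROI-mean; O(T) per sample, chunked
  n <- length(D)
  m <- numeric(n)
  tt <- seq(t0, by = 1, length.out = T)
  chunk <- max(1L, floor(2e6 / T))
  for (i in seq(1L, n, by = chunk)) {
    j <- i:min(n, i + chunk - 1L)
    v <- outer(2 * D[j], tt) + s2                     # |j| x T variances
    m[j] <- (gC0[j] / A) * rowMeans(roi_mass_fraction(v, roi_dims))
  }
  for (tr in refs) {
    g1 <- (a / A) / outer(D, lags, function(d, l) s2e + d * (2 * tr + l))
    mu_ref <- (gC0 / A) *
      roi_mass_fraction(s2 + config$ref_smooth^2 + 2 * D * tr, roi_dims)
    mu_lag <- (gC0 / A) * roi_mass_fraction(outer(2 * D, tr + lags) + s2,
                                            roi_dims)
    acc <- acc + g1 - m * (mu_ref + mu_lag) + m^2
  }
  acc / R
}

#' ABC rejection sampling of the diffusion coefficient
#'
#' The rejection sampler: draw `n_samples` parameter pairs from the prior,
#' simulate the model autocorrelation curve for each, compute the squared
#' Euclidean distance to the observed curve, and keep the draws passing the
#' 0-1 acceptance cut-off (either the best `quantile` fraction, or all
#' distances `<= epsilon`). Accepted draws are i.i.d. from the approximate
#' posterior; the MMSE estimate of `D` is their empirical mean and the MAP
#' estimate is the mode of the binned marginal (see
#' [posterior_histogram()]). All model evaluations are vectorized; the
#' batching does not affect the results.
#'
#' @param obs Observed `autocorr_curve` (its lag grid must equal
#'   `config$lags`).
#' @param prior A [prior_spec()]; `NULL` `a_bounds` are moment-matched from
#'   `obs` via [default_a_bounds()].
#' @param config An [abc_config()].
#' @param roi_dims Integer length-2 `c(My, Mx)`; defaults to the observed
#'   curve's ROI dimensions.
#' @param T Total observed frames (for the G2 model); defaults to the
#'   observed curve's `T`.
#'
#' @return An object of class `bayestics_fit` with elements `accepted`
#'   (data.frame of `D`, `a`, `dist`), `d_map`, `d_mmse`, `a_mmse`,
#'   `histogram`, `acceptance_rate`, `epsilon_realized`, `prior`, `config`.
#' @export
#' @examples
#' obs <- model_g1(1:40, c(D = 0.4, a = 2e3), c(31, 31))
#' fit <- abc_rejection(obs, prior_spec(),
#'                      abc_config(n_samples = 2000, lags = 1:40, seed = 7))
#' fit$d_mmse
abc_rejection <- function(obs, prior, config, roi_dims = obs$roi_dims,
                          T = obs$T) {
  stopifnot(inherits(obs, "autocorr_curve"), inherits(prior, "prior_spec"),
            inherits(config, "abc_config"))
  if (length(obs$lags) != length(config$lags) || any(obs$lags != config$lags))
    stop("observed curve's lag grid must equal config$lags", call. = FALSE)
  if (any(!is.finite(obs$values)))
    stop("observed curve contains non-finite values", call. = FALSE)
  if (config$model == "g2" && (is.na(T) || T < 2))
    stop("the G2 model needs the total observation time 'T'", call. = FALSE)
  # estimator settings recorded on the observed curve take precedence, so
  # the simulated curves always share the observation's conventions
  if (!is.null(obs$t_ref)) config$t_ref <- obs$t_ref
  if (!is.null(obs$ref_smooth)) config$ref_smooth <- obs$ref_smooth
  if (!is.null(obs$n_ref)) config$n_ref <- obs$n_ref
  if (is.null(prior$a_bounds))
    prior$a_bounds <- default_a_bounds(obs, prior, config$sigma_psf,
                                       config$t_ref, config$ref_smooth)

  set.seed(config$seed)
  theta <- sample_prior(prior, config$n_samples)
  curves <- batch_curves(theta[, "D"], theta[, "a"], config, roi_dims, T)
  obs_v <- obs$values
  if (config$distance == "normalized") {
    if (!is.finite(obs_v[1]) || obs_v[1] <= 0)
      stop("first-lag value of the observed curve is not positive; ",
           "use distance = 'raw'", call. = FALSE)
    obs_v <- obs_v / obs_v[1]
    first <- curves[, 1]
    curves <- curves / first
    bad <- !is.finite(first) | first <= 0
  } else bad <- logical(nrow(curves))
  dist <- rowSums(sweep(curves, 2, obs_v)^2)
  dist[bad | !is.finite(dist)] <- Inf

  acc <- config$acceptance
  if (acc$mode == "quantile") {
    k <- ceiling(acc$value * config$n_samples)
    keep <- order(dist)[seq_len(k)]
    eps <- max(dist[keep])
  } else {
    eps <- acc$value
    keep <- which(dist <= eps)
    if (length(keep) == 0)
      stop("no samples accepted at epsilon = ", format(eps),
           "; raise epsilon or use quantile acceptance", call. = FALSE)
  }
  accepted <- data.frame(D = theta[keep, "D"], a = theta[keep, "a"],
                         dist = dist[keep])
  hist <- posterior_histogram(accepted$D, n_bins = config$n_bins,
                              bounds = prior$d_bounds)
  structure(list(accepted = accepted,
                 d_map = hist$map,
                 d_mmse = mean(accepted$D),
                 a_mmse = mean(accepted$a),
                 histogram = hist,
                 acceptance_rate = length(keep) / config$n_samples,
                 epsilon_realized = eps,
                 prior = prior, config = config,
                 roi_dims = roi_dims, T = T),
            class = "bayestics_fit")
}

#' Binned marginal posterior of D and its mode
#'
#' Bins the accepted `D` samples over the prior interval. The default bin
#' width follows the Freedman-Diaconis rule computed from the accepted
#' samples (the posterior is usually far narrower than the prior); the MAP
#' estimate is the center of the most massive bin, with ties broken toward
#' the lowest `D`.
#'
#' @param d Accepted `D` samples (nonempty numeric).
#' @param n_bins Number of bins, or `NULL` for Freedman-Diaconis.
#' @param bounds Length-2 interval to bin over (the `D` prior bounds).
#' @return List with `mids`, `counts`, `density` (bin masses summing to 1),
#'   `breaks`, and `map`.
#' @export
posterior_histogram <- function(d, n_bins = NULL, bounds = range(d)) {
  stopifnot(length(d) > 0, all(is.finite(d)))
  if (diff(bounds) <= 0)
    bounds <- bounds + c(-0.5, 0.5) * max(1e-8, abs(bounds[1]) * 1e-8)
  if (is.null(n_bins)) {
    iqr <- stats::IQR(d)
    h <- 2 * iqr * length(d)^(-1/3)
    n_bins <- if (h <= 0) 30L else max(10L, min(1000L,
      ceiling(diff(bounds) / h)))
  }
  breaks <- seq(bounds[1], bounds[2], length.out = n_bins + 1)
  # clamp so samples equal to a bound land in an end bin
  idx <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(mids = mids, counts = counts, density = counts / sum(counts),
       breaks = breaks, map = mids[which.max(counts)])
}

#' @export
print.bayestics_fit <- function(x, ...) {
  cat("BayesTICS ABC fit (", x$config$model, " model)\n", sep = "")
  cat(sprintf("  accepted: %d / %d samples (rate %.4f, realized eps %.4g)\n",
              nrow(x$accepted), x$config$n_samples, x$acceptance_rate,
              x$epsilon_realized))
  cat(sprintf("  D (MAP)  = %.4f px^2/frame\n", x$d_map))
  cat(sprintf("  D (MMSE) = %.4f px^2/frame\n", x$d_mmse))
  cat(sprintf("  a (MMSE) = %.4g a.u.\n", x$a_mmse))
  invisible(x)
}

#' @export
summary.bayestics_fit <- function(object, ...) {
  q <- stats::quantile(object$accepted$D, c(0.025, 0.25, 0.5, 0.75, 0.975))
  out <- list(d_map = object$d_map, d_mmse = object$d_mmse,
              a_mmse = object$a_mmse, d_quantiles = q,
              acceptance_rate = object$acceptance_rate,
              epsilon_realized = object$epsilon_realized)
  class(out) <- "summary.bayestics_fit"
  out
}

#' @export
print.summary.bayestics_fit <- function(x, ...) {
  cat(sprintf("D: MAP %.4f, MMSE %.4f px^2/frame\n", x$d_map, x$d_mmse))
  print(round(x$d_quantiles, 4))
  invisible(x)
}

#' Plot the marginal posterior of D
#'
#' @param x A `bayestics_fit`.
#' @param true_d Optional ground-truth `D` to mark.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.bayestics_fit <- function(x, true_d = NULL, ...) {
  h <- x$histogram
  graphics::plot(h$mids, h$density, type = "h",
                 xlab = "D (pixel^2/frame)", ylab = "posterior mass", ...)
  graphics::abline(v = x$d_map, col = "firebrick", lty = 2)
  graphics::abline(v = x$d_mmse, col = "steelblue", lty = 3)
  if (!is.null(true_d)) graphics::abline(v = true_d, col = "gray40")
  invisible(x)
}
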