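#' Read a multi-page grayscale TIFF stack
#'
#' Reads 8/16-bit integer or 32-bit float grayscale TIFFs into an
#' [image_sequence()]. If a metadata sidecar written by
#' [write_image_sequence()] sits next to the file (`<path>.json`), the
#' original intensity range and frame interval are restored; otherwise
#' intensities are returned as stored (the TIFF library maps integer data to
#' `[0, 1]`; autocorrelation and ABC results are invariant to the overall
#' intensity scale up to the amplitude nuisance, so no rescaling is needed
#' for estimation).
#'
#' @param path TIFF file path.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # collapse any channel dim
  })
  arr <- simplify2array(pages)
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1L))
  fi <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$intensity_range))
      arr <- meta$intensity_range[1] + arr * diff(meta$intensity_range)
    if (!is.null(meta$frame_interval) && !is.na(meta$frame_interval))
      fi <- meta$frame_interval
  }
  image_sequence(arr, frame_interval = fi)
}

#' Write an image sequence as a multi-page 32-bit TIFF
#'
#' Intensities are affinely mapped to `[0, 1]` for storage; the original
#' range (and the frame interval) is recorded in a `<path>.json` sidecar so
#' [read_image_sequence()] restores the data at 32-bit float precision.
#'
#' @param seq An [image_sequence()] or `H x W x T` array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path) {
  arr <- if (inherits(seq, "image_sequence")) seq$data else seq
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  rng <- range(arr)
  scaled <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  pages <- lapply(seq_len(dim(arr)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  fi <- if (inherits(seq, "image_sequence")) seq$frame_interval else NA_real_
  jsonlite::write_json(list(intensity_range = rng, frame_interval = fi),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a spot/ROI list
#'
#' CSV needs columns `row`, `col` and optionally `size` (odd window side);
#' JSON an array of objects with the same fields.
#'
#' @param path CSV or JSON file path.
#' @return Data frame with columns `row`, `col`, `size` (`NA` when absent).
#' @export
read_roi_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  if (nrow(df) > 0 && !all(c("row", "col") %in% names(df)))
    stop("ROI list needs 'row' and 'col' columns", call. = FALSE)
  if (nrow(df) == 0)
    return(data.frame(row = integer(), col = integer(), size = integer()))
  if (is.null(df$size)) df$size <- rep(NA_integer_, nrow(df))
  df
}

#' Write ground truth or estimation results as JSON
#'
#' @param x A list (e.g. a ground-truth sidecar or per-ROI results).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a fit for reporting
#'
#' Flattens a [abc_rejection()] fit into a JSON-ready list: point estimates,
#' acceptance diagnostics, and a config echo (with the seed).
#'
#' @param fit A `bayestics_fit`.
#' @return A plain list.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "bayestics_fit"))
  list(d_map = fit$d_map, d_mmse = fit$d_mmse, a_mmse = fit$a_mmse,
       acceptance_rate = fit$acceptance_rate,
       epsilon_realized = fit$epsilon_realized,
       n_accepted = nrow(fit$accepted),
       d_bounds = fit$prior$d_bounds, a_bounds = fit$prior$a_bounds,
       config = list(n_samples = fit$config$n_samples,
                     acceptance_mode = fit$config$acceptance$mode,
                     acceptance_value = fit$config$acceptance$value,
                     model = fit$config$model,
                     lags = range(fit$config$lags),
                     sigma_psf = fit$config$sigma_psf,
                     t_ref = fit$config$t_ref,
                     seed = fit$config$seed))
}
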