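#' Mono-exponential ADC fit
#'
#' Fits the diffusion signal model `S(b) = S0 * exp(-b * ADC)` per voxel by
#' ordinary least squares in log-signal space: `ln S = ln S0 - b * ADC`.
#' With exactly two distinct b-values the solution is the exact two-point
#' inversion `ADC = ln(S1/S2) / (b2 - b1)`. Voxels with any non-positive
#' signal are masked (`NA` in both outputs).
#'
#' @param bvalues numeric vector of b-values (s/mm^2), at least 2 distinct.
#' @param signals numeric matrix of signals, one row per voxel and one column
#'   per b-value (a vector is treated as a single voxel).
#' @return list with numeric vectors `s0` and `adc` (mm^2/s) and the logical
#'   mask `fitted`.
#' @export
fit_adc <- function(bvalues, signals) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  b <- as.numeric(bvalues)
  if (length(unique(b)) < 2)
    stop_config("fit_adc needs at least 2 distinct b-values")
  stopifnot(ncol(signals) == length(b))
  ok <- apply(signals > 0 & is.finite(signals), 1L, all)
  n <- nrow(signals)
  s0 <- adc <- rep(NA_real_, n)
  if (any(ok)) {
    y <- log(signals[ok, , drop = FALSE])
    mb <- mean(b)
    sxx <- sum((b - mb)^2)
    slope <- as.numeric(y %*% (b - mb)) / sxx
    my <- rowMeans(y)
    adc[ok] <- -slope
    s0[ok] <- exp(my + adc[ok] * mb)
  }
  list(s0 = s0, adc = adc, fitted = ok)
}

#' Synthesize a computed high-b-value signal
#'
#' Extrapolates the fitted mono-exponential model to a target b-value
#' (default 1500 s/mm^2), the standard construction of a computed
#' high-b diffusion image when the acquisition lacks one. Negative fitted
#' ADC values (noise) are clamped to 0 at synthesis — the signal then equals
#' `s0` — and counted in the `"n_clamped"` attribute with a warning; the
#' fitted ADC map itself is left untouched so it stays diagnostic of noise.
#'
#' @param s0,adc fitted per-voxel values from [fit_adc()].
#' @param b_target target b-value (s/mm^2).
#' @return numeric vector of synthesized signals (`NA` where the fit was
#'   masked), with attribute `n_clamped`.
#' @export
synthesize_high_b <- function(s0, adc, b_target = 1500) {
  stopifnot(length(s0) == length(adc), b_target >= 0)
  neg <- is.finite(adc) & adc < 0
  if (any(neg))
    warning(sprintf("%d voxel(s) with negative fitted ADC clamped to 0",
                    sum(neg)))
  adc2 <- pmax(adc, 0)
  out <- s0 * exp(-b_target * adc2)
  attr(out, "n_clamped") <- sum(neg)
  out
}

#' Generate a DWI phantom
#'
#' A voxel grid with known per-voxel `S0` and ADC, and the corresponding
#' signal stack `S(b) = S0 * exp(-b * ADC)` plus optional Gaussian noise —
#' the round-trip fixture for [fit_adc()] / [synthesize_high_b()].
#'
#' @param shape integer vector of grid dimensions (e.g. `c(8, 8)`).
#' @param s0_range,adc_range uniform sampling intervals for the true `S0`
#'   (a.u.) and ADC (mm^2/s, positive).
#' @param bvalues b-values of the stack; at least 2 distinct.
#' @param noise_sd SD of additive Gaussian noise (a.u.).
#' @param seed integer seed.
#' @return object of class `dwi_phantom`: list `bvalues`, `signals`
#'   (voxels x b matrix), `truth_s0`, `truth_adc`, `shape`.
#' @export
generate_dwi_phantom <- function(shape = c(8, 8), s0_range = c(500, 1500),
                                 adc_range = c(5e-4, 2.5e-3),
                                 bvalues = c(0, 500, 1000),
                                 noise_sd = 0, seed = NULL) {
  if (length(unique(bvalues)) < 2)
    stop_config("phantom needs at least 2 distinct b-values (ADC not identifiable)")
  if (any(adc_range <= 0)) stop_config("adc_range must be positive")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- prod(shape)
  s0 <- runif(n, s0_range[1], s0_range[2])
  adc <- runif(n, adc_range[1], adc_range[2])
  signals <- s0 * exp(outer(-adc, bvalues))
  if (noise_sd > 0)
    signals <- signals + matrix(rnorm(length(signals), 0, noise_sd),
                                nrow = n)
  structure(list(bvalues = bvalues, signals = signals, truth_s0 = s0,
                 truth_adc = adc, shape = shape),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat(sprintf("DWI phantom: %s grid, b = {%s} s/mm^2\n",
              paste(x$shape, collapse = "x"),
              paste(x$bvalues, collapse = ", ")))
  invisible(x)
}

#' Volume I/O for voxel maps
#'
#' `write_volume()` / `read_volume()` store a voxel map in NIfTI format via
#' the RNifti package when available; `write_volume_text()` /
#' `read_volume_text()` provide an equivalent plain-text matrix round trip
#' used by the test-suite fixtures.
#'
#' @param x numeric vector of voxel values, `dim` reshaped from `shape`.
#' @param shape grid dimensions.
#' @param path file path.
#' @return `read_*` return the numeric array; `write_*` the path, invisibly.
#' @export
write_volume <- function(x, shape, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_config("write_volume requires the RNifti package")
  RNifti::writeNifti(array(x, dim = shape), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_config("read_volume requires the RNifti package")
  as.array(RNifti::readNifti(path))
}

#' @rdname write_volume
#' @export
write_volume_text <- function(x, shape, path) {
  writeLines(c(paste(shape, collapse = " "),
               paste(format(x, digits = 17), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume_text <- function(path) {
  ln <- readLines(path)
  shape <- as.integer(strsplit(ln[1], " ")[[1]])
  array(as.numeric(strsplit(ln[2], " +")[[1]]), dim = shape)
}
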