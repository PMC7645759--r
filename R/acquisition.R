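#' Construct a T1rho-weighted image sequence
#'
#' A complex 2D+time image stack for a single slice, the unknown of the
#' reconstruction problem. Dimensions are `(Ny, Nz, Nt)` with one frame per
#' spin-lock time (TSL).
#'
#' @param data Complex (or numeric) array of dimension `(Ny, Nz, Nt)`.
#' @param tsl Numeric vector of spin-lock times in ms, strictly increasing and
#'   positive, of length `Nt`.
#' @return An object of class `image_sequence` with elements `data` and `tsl`.
#' @export
image_sequence <- function(data, tsl) {
  data <- as_complex_array(data, 3L, "image data")
  tsl <- as.numeric(tsl)
  if (dim(data)[3] != length(tsl))
    stop("number of frames (", dim(data)[3], ") does not match length of tsl (",
         length(tsl), ")")
  if (any(tsl <= 0) || any(diff(tsl) <= 0))
    stop("tsl must be strictly increasing and positive")
  structure(list(data = data, tsl = tsl), class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_sequence> %d x %d voxels, %d TSLs (%s ms)\n",
              d[1], d[2], d[3], paste(x$tsl, collapse = "/")))
  invisible(x)
}

#' Construct a multi-coil k-space object
#'
#' Complex k-space samples of one slice stored in the centered (FFT-shifted)
#' convention, so the calibration region is a centered rectangle. Dimensions
#' are `(Ny, Nz, Nt, Nc)`.
#'
#' @param data Complex array `(Ny, Nz, Nt, Nc)`.
#' @param tsl Spin-lock time vector in ms (length `Nt`).
#' @param noise_sd Per-component Gaussian noise standard deviation used to
#'   generate the data, or `NA` if unknown/noiseless.
#' @return Object of class `multicoil_kspace`.
#' @export
multicoil_kspace <- function(data, tsl, noise_sd = NA_real_) {
  data <- as_complex_array(data, 4L, "k-space data")
  tsl <- as.numeric(tsl)
  if (dim(data)[3] != length(tsl))
    stop("number of k-space frames does not match length of tsl")
  if (any(tsl <= 0) || any(diff(tsl) <= 0))
    stop("tsl must be strictly increasing and positive")
  if (dim(data)[4] < 1) stop("coil count must be >= 1")
  structure(list(data = data, tsl = tsl, noise_sd = noise_sd),
            class = "multicoil_kspace")
}

#' @export
print.multicoil_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multicoil_kspace> %d x %d k-space, %d TSLs, %d coils\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Construct a coil profile
#'
#' Coil sensitivities plus the low-order phase map used for phase
#' compensation. On the support mask the sensitivities are normalized to unit
#' sum-of-squares magnitude, so that coil combination behaves as a left
#' inverse of coil weighting, and the phase map has unit magnitude.
#'
#' @param sensitivities Complex array `(Ny, Nz, Nc)`.
#' @param phase_map Complex unit-magnitude matrix `(Ny, Nz)`; default all 1.
#' @param support Logical matrix `(Ny, Nz)`; default all `TRUE`.
#' @return Object of class `coil_profile`.
#' @export
coil_profile <- function(sensitivities, phase_map = NULL, support = NULL) {
  sens <- as_complex_array(sensitivities, 3L, "sensitivities")
  d <- dim(sens)
  if (is.null(support)) support <- matrix(TRUE, d[1], d[2])
  if (is.null(phase_map)) phase_map <- matrix(1 + 0i, d[1], d[2])
  storage.mode(support) <- "logical"
  phase_map <- as_complex_array(phase_map, 2L, "phase map")
  if (!all(dim(support) == d[1:2]) || !all(dim(phase_map) == d[1:2]))
    stop("phase_map/support dimensions do not match sensitivities")
  sos <- apply(Mod(sens)^2, c(1, 2), sum)
  if (any(abs(sos[support] - 1) > 1e-6))
    stop("sensitivities are not sum-of-squares normalized on the support ",
         "(max deviation ", format(max(abs(sos[support] - 1))), ")")
  if (any(abs(Mod(phase_map[support]) - 1) > 1e-6))
    stop("phase_map must have unit magnitude on the support")
  structure(list(sensitivities = sens, phase_map = phase_map,
                 support = support), class = "coil_profile")
}

as_complex_array <- function(x, ndim, what) {
  if (is.null(dim(x)) && ndim == 2L && is.vector(x)) dim(x) <- c(length(x), 1)
  if (length(dim(x)) != ndim)
    stop(what, " must be a ", ndim, "-dimensional array")
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

check_geometry <- function(ny, nz, coils, mask = NULL, nt = NULL) {
  ds <- dim(coils$sensitivities)
  if (ds[1] != ny || ds[2] != nz)
    stop("coil profile grid (", ds[1], " x ", ds[2],
         ") does not match data grid (", ny, " x ", nz, ")")
  if (!is.null(mask)) {
    dm <- dim(mask$pattern)
    if (dm[1] != ny || dm[2] != nz || (!is.null(nt) && dm[3] != nt))
      stop("sampling mask dimensions (", paste(dm, collapse = " x "),
           ") do not match data (", ny, " x ", nz,
           if (!is.null(nt)) paste0(" x ", nt), ")")
  }
  invisible(TRUE)
}

# Raw-array operator cores (no class validation): the solver hot paths.
forward_raw <- function(x, sens, phase, pattern = NULL) {
  d <- dim(x); nc <- dim(sens)[3]
  y <- array(0i, c(d[1], d[2], d[3], nc))
  for (t in seq_len(d[3])) {
    xt <- phase * x[, , t]
    for (c in seq_len(nc)) {
      k <- fftshift2(fft2u(sens[, , c] * xt))
      if (!is.null(pattern)) k <- k * pattern[, , t]
      y[, , t, c] <- k
    }
  }
  y
}

adjoint_raw <- function(y, sens, phase, pattern = NULL) {
  d <- dim(y)
  x <- array(0i, d[1:3])
  cphase <- Conj(phase)
  for (t in seq_len(d[3])) {
    acc <- matrix(0i, d[1], d[2])
    for (c in seq_len(d[4])) {
      k <- y[, , t, c]
      if (!is.null(pattern)) k <- k * pattern[, , t]
      acc <- acc + Conj(sens[, , c]) * ifft2u(ifftshift2(k))
    }
    x[, , t] <- cphase * acc
  }
  x
}

#' Multi-coil Fourier forward operator
#'
#' Maps an image sequence to k-space: each frame is phase-weighted, multiplied
#' by the coil sensitivities, transformed by a unitary 2D FFT, and (optionally)
#' subsampled by the mask, `y = S F C x`. K-space is returned in the centered
#' convention.
#'
#' @param x An [image_sequence].
#' @param coils A [coil_profile] on the same grid.
#' @param mask Optional [sampling_mask]; when absent, returns `F C x`.
#' @return A [multicoil_kspace].
#' @seealso [mri_adjoint()]
#' @export
mri_forward <- function(x, coils, mask = NULL) {
  d <- dim(x$data)
  check_geometry(d[1], d[2], coils, mask, d[3])
  y <- forward_raw(x$data, coils$sensitivities, coils$phase_map,
                   if (is.null(mask)) NULL else mask$pattern)
  multicoil_kspace(y, x$tsl)
}

#' Multi-coil Fourier adjoint operator
#'
#' The exact adjoint of [mri_forward()]: `C* F* S* y`. With a mask present the
#' unsampled entries are zeroed first; coil images are inverse-transformed,
#' combined with conjugate sensitivities, and the conjugate phase map removes
#' the smooth image phase. With fully sampled, noiseless data and normalized
#' sensitivities this is the fully-sampled reference reconstruction.
#'
#' @param y A [multicoil_kspace].
#' @param coils A [coil_profile] on the same grid.
#' @param mask Optional [sampling_mask].
#' @return An [image_sequence].
#' @export
mri_adjoint <- function(y, coils, mask = NULL) {
  d <- dim(y$data)
  check_geometry(d[1], d[2], coils, mask, d[3])
  if (d[4] != dim(coils$sensitivities)[3])
    stop("coil count mismatch between k-space and coil profile")
  x <- adjoint_raw(y$data, coils$sensitivities, coils$phase_map,
                   if (is.null(mask)) NULL else mask$pattern)
  image_sequence(x, y$tsl)
}

#' Add complex Gaussian noise to k-space
#'
#' Independent zero-mean Gaussian noise of standard deviation `sd` is added to
#' the real and imaginary component of every stored sample. Deterministic
#' under `seed`.
#'
#' @param y A [multicoil_kspace].
#' @param sd Per-component noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @return A [multicoil_kspace] with `noise_sd` recorded.
#' @export
add_noise <- function(y, sd, seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(y)
  n <- length(y$data)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eta <- complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd))
  dim(eta) <- dim(y$data)
  multicoil_kspace(y$data + eta, y$tsl, noise_sd = sd)
}

# Low-resolution coil images from the windowed, zero-padded calibration block
# of the first TSL frame. Shared by sensitivity and phase estimation.
calib_lowres <- function(y, calib_extent) {
  d <- dim(y$data)
  ry <- calib_range(d[1], calib_extent[1])
  rz <- calib_range(d[2], calib_extent[2])
  hann <- function(k) if (k == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(k - 1)) / (k - 1))
  win <- outer(hann(calib_extent[1]), hann(calib_extent[2]))
  low <- array(0i, c(d[1], d[2], d[4]))
  for (c in seq_len(d[4])) {
    k <- matrix(0i, d[1], d[2])
    k[ry, rz] <- y$data[ry, rz, 1, c] * win
    low[, , c] <- ifft2u(ifftshift2(k))
  }
  low
}

#' Estimate coil sensitivities from the calibration region
#'
#' Autocalibrating estimate from the fully sampled central k-space block of
#' the first TSL: the windowed block is zero-padded and inverse-transformed to
#' low-resolution coil images, which are divided by their root-sum-of-squares
#' and referenced to the phase of the virtual (coil-sum) image so the smooth
#' image phase cancels from the sensitivities. The result is normalized to
#' unit sum-of-squares magnitude on the support, where the support is the set
#' of voxels whose root-sum-of-squares low-resolution image exceeds
#' `support_rel` times its maximum.
#'
#' @param y A [multicoil_kspace] whose central `calib_extent` block is sampled.
#' @param calib_extent Integer pair (rows, cols) of the calibration block.
#' @param support_rel Relative root-sum-of-squares threshold for the support.
#' @return A [coil_profile] including the estimated low-order phase map.
#' @export
estimate_sensitivities <- function(y, calib_extent = c(39, 19),
                                   support_rel = 0.05) {
  d <- dim(y$data)
  if (calib_extent[1] > d[1] || calib_extent[2] > d[2])
    stop("calibration extent larger than k-space grid")
  low <- calib_lowres(y, calib_extent)
  rss <- sqrt(apply(Mod(low)^2, c(1, 2), sum))
  support <- rss > support_rel * max(rss)
  vref <- apply(low, c(1, 2), sum)               # virtual coil carrying image phase
  phase_ref <- exp(1i * Arg(vref))
  sens <- array(0i, dim(low))
  for (c in seq_len(d[4]))
    sens[, , c] <- ifelse(support, low[, , c] / rss * Conj(phase_ref), 0i)
  # renormalize (exact SoS-1 on support)
  sos <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  for (c in seq_len(d[4]))
    sens[, , c] <- ifelse(support, sens[, , c] / sos, 0i)
  comb <- apply(Conj(sens) * low, c(1, 2), sum)  # coil-combined low-res image
  pm <- matrix(1 + 0i, d[1], d[2])
  pm[support] <- exp(1i * Arg(comb[support]))
  coil_profile(sens, phase_map = pm, support = support)
}

#' Estimate the low-order phase map from the calibration region
#'
#' Phase of the coil-combined low-resolution calibration image. Applying the
#' conjugate of this map to the coil-combined image yields a near-zero-phase
#' image for smooth-phase objects, which is the premise of complex-valued
#' relaxation fitting.
#'
#' @inheritParams estimate_sensitivities
#' @return Complex unit-magnitude matrix `(Ny, Nz)`.
#' @export
estimate_phase_map <- function(y, calib_extent = c(39, 19),
                               support_rel = 0.05) {
  estimate_sensitivities(y, calib_extent, support_rel)$phase_map
}
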