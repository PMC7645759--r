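#' Default spin-lock times (ms)
#'
#' The 10 TSLs of the knee protocol the phantom generator emulates:
#' 2/4/6/8/10/15/25/35/45/55 ms.
#' @return Numeric vector of length 10.
#' @export
default_tsl <- function() c(2, 4, 6, 8, 10, 15, 25, 35, 45, 55)

roi_names <- c("MFC", "MTC", "LFC", "LTC", "PC")

#' Generate ground-truth relaxation parameter maps
#'
#' Procedural piecewise-smooth phantom: five curved band-shaped "cartilage"
#' ROIs (labelled MFC, MTC, LFC, LTC, PC) placed on a smooth elliptical
#' background. Each ROI draws its relaxation parameters from configurable
#' uniform ranges; by default the femoral and patellar bands (MFC, LFC, PC)
#' are biexponential and the tibial bands (MTC, LTC) plus the background are
#' monoexponential with a long component. Mono voxels carry `f_s` of exactly 0
#' or 1, so one signal equation serves both models.
#'
#' @param ny,nz Grid size (>= 16 each).
#' @param seed Integer seed; maps are deterministic given the seed.
#' @param config Optional list overriding the defaults:
#'   `force_mono` (logical, make every voxel monoexponential),
#'   `biexp_rois` (integer labels of biexponential ROIs, default `c(1,3,5)`),
#'   `f_s_range`, `tau_s_range`, `tau_l_range`, `bg_tau_range` (uniform draw
#'   ranges, ms where applicable), `phase0` and `phase_ramp` (constant phase,
#'   rad, and linear phase ramp across the field of view, rad).
#' @return Object of class `ground_truth_maps` with matrices `c` (complex),
#'   `f_s`, `f_l`, `tau_s`, `tau_l`, logical `is_biexp`, and integer
#'   `roi_labels` (0 = background).
#' @export
make_ground_truth <- function(ny, nz, seed = 1L, config = list()) {
  if (ny < 16 || nz < 16) stop("grid must be at least 16 x 16")
  cfg <- utils::modifyList(list(
    force_mono = FALSE,
    biexp_rois = c(1L, 3L, 5L),
    f_s_range = c(0.25, 0.45),
    tau_s_range = c(3, 8),
    tau_l_range = c(40, 80),
    bg_tau_range = c(30, 60),
    phase0 = pi / 8,
    phase_ramp = c(0.3, 0.2)
  ), config)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  yy <- matrix(seq(-1, 1, length.out = ny), ny, nz)
  zz <- matrix(seq(-1, 1, length.out = nz), ny, nz, byrow = TRUE)
  object <- (yy / 0.92)^2 + (zz / 0.88)^2 <= 1

  # Curved cartilage-like bands: polar annular arcs jittered per seed.
  runif1 <- function(r) runif(1, r[1], r[2])
  arcs <- list(
    list(cy = -0.25, cz = 0.0, r = 0.52, w = 0.10, a0 = 50, a1 = 130),  # MFC
    list(cy = 0.42, cz = -0.30, r = 0.28, w = 0.09, a0 = 150, a1 = 260), # MTC
    list(cy = -0.25, cz = 0.0, r = 0.34, w = 0.09, a0 = 40, a1 = 140),  # LFC
    list(cy = 0.42, cz = 0.30, r = 0.28, w = 0.09, a0 = -80, a1 = 30),  # LTC
    list(cy = -0.62, cz = 0.0, r = 0.24, w = 0.09, a0 = 230, a1 = 310)  # PC
  )
  roi <- matrix(0L, ny, nz)
  for (k in seq_along(arcs)) {
    a <- arcs[[k]]
    r <- a$r * (1 + runif(1, -0.05, 0.05))
    ang0 <- (a$a0 + runif(1, -8, 8)) * pi / 180
    ang1 <- (a$a1 + runif(1, -8, 8)) * pi / 180
    dy <- yy - a$cy; dz <- zz - a$cz
    rad <- sqrt(dy^2 + dz^2)
    th <- atan2(dz, dy)
    th <- th + 2 * pi * (th < ang0 - pi)  # unwrap near the arc start
    band <- abs(rad - r) <= a$w & th >= ang0 & th <= ang1 & object
    roi[band & roi == 0L] <- k
  }

  f_s <- matrix(0, ny, nz); tau_s <- matrix(4, ny, nz)
  tau_l <- matrix(runif1(cfg$bg_tau_range), ny, nz)
  is_biexp <- matrix(FALSE, ny, nz)
  for (k in 1:5) {
    sel <- roi == k
    if (!any(sel)) next
    if (!cfg$force_mono && k %in% cfg$biexp_rois) {
      f_s[sel] <- runif1(cfg$f_s_range)
      tau_s[sel] <- runif1(cfg$tau_s_range)
      tau_l[sel] <- runif1(cfg$tau_l_range)
      is_biexp[sel] <- TRUE
    } else {
      tau_l[sel] <- runif1(cfg$bg_tau_range)
    }
  }
  f_l <- 1 - f_s

  # Smooth complex amplitude: tapered object with gentle shading and a
  # low-order phase, zero outside the object.
  mag <- exp(-((yy / 1.15)^2 + (zz / 1.1)^2)) * (1 + 0.15 * yy - 0.1 * zz)
  mag[!object] <- 0
  phase <- cfg$phase0 + cfg$phase_ramp[1] * yy + cfg$phase_ramp[2] * zz
  cmap <- mag * exp(1i * phase)
  structure(list(c = cmap, f_s = f_s, f_l = f_l, tau_s = tau_s,
                 tau_l = tau_l, is_biexp = is_biexp, roi_labels = roi),
            class = "ground_truth_maps")
}

#' Synthesize a T1rho-weighted image sequence from ground-truth maps
#'
#' Per voxel the complex signal decays as
#' `x(t) = c (f_s exp(-t/tau_s) + f_l exp(-t/tau_l))`; monoexponential voxels
#' are the special cases `f_s = 0` or `f_s = 1`.
#'
#' @param maps A [make_ground_truth()] result.
#' @param tsl Spin-lock times in ms (positive, increasing).
#' @return An [image_sequence].
#' @export
synthesize_sequence <- function(maps, tsl = default_tsl()) {
  if (any(maps$tau_s <= 0) || any(maps$tau_l <= 0))
    stop("relaxation times must be positive")
  d <- dim(maps$c)
  x <- array(0i, c(d[1], d[2], length(tsl)))
  for (t in seq_along(tsl))
    x[, , t] <- maps$c * (maps$f_s * exp(-tsl[t] / maps$tau_s) +
                          maps$f_l * exp(-tsl[t] / maps$tau_l))
  image_sequence(x, tsl)
}

#' Generate smooth synthetic coil profiles
#'
#' `nc` Gaussian-bump sensitivity magnitudes centered around the field of
#' view periphery with smooth per-coil linear phases, normalized to unit
#' sum-of-squares magnitude everywhere (support = full grid, unit phase map).
#'
#' @param ny,nz Grid size.
#' @param nc Number of coils.
#' @param seed Integer seed for the coil geometry jitter.
#' @return A [coil_profile].
#' @export
make_coil_profiles <- function(ny, nz, nc, seed = 1L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1000L)
  yy <- matrix(seq(-1, 1, length.out = ny), ny, nz)
  zz <- matrix(seq(-1, 1, length.out = nz), ny, nz, byrow = TRUE)
  sens <- array(0i, c(ny, nz, nc))
  for (c in seq_len(nc)) {
    ang <- 2 * pi * (c - 1) / nc + runif(1, -0.15, 0.15)
    cy <- 1.25 * cos(ang); cz <- 1.25 * sin(ang)
    width <- 0.9 + runif(1, -0.1, 0.1)
    mag <- 0.15 + exp(-((yy - cy)^2 + (zz - cz)^2) / width^2)
    ph <- runif(1, -pi, pi) + 0.5 * runif(1, -1, 1) * yy + 0.5 * runif(1, -1, 1) * zz
    sens[, , c] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  for (c in seq_len(nc)) sens[, , c] <- sens[, , c] / sos
  coil_profile(sens)
}

#' Noise level giving a target image-domain SNR
#'
#' Per-component k-space noise standard deviation such that the first-TSL
#' image SNR (RMS signal magnitude over the object divided by RMS complex
#' noise magnitude) equals `snr_db`. With the unitary FFT and sum-of-squares
#' normalized coils, per-component noise maps to the combined image unchanged.
#'
#' @param x The noiseless [image_sequence].
#' @param snr_db Target SNR in dB (default 30).
#' @return Noise standard deviation per real/imaginary component.
#' @export
noise_sd_for_snr <- function(x, snr_db = 30) {
  first <- x$data[, , 1]
  sig <- Mod(first)[Mod(first) > 0]
  rms <- sqrt(mean(sig^2))
  rms / (sqrt(2) * 10^(snr_db / 20))
}

#' Generate a complete synthetic dataset
#'
#' Composes [make_ground_truth()], [synthesize_sequence()],
#' [make_coil_profiles()], [mri_forward()] and [add_noise()], plus a
#' [poisson_disk_mask()] at the requested acceleration factor. The returned
#' k-space is fully sampled (the mask is returned separately for retrospective
#' undersampling).
#'
#' @param ny,nz Grid size.
#' @param tsl Spin-lock times in ms (default the 10-TSL protocol).
#' @param nc Number of coils (a 15-channel knee array is typical).
#' @param af Acceleration factor for the generated mask.
#' @param noise_sd Per-component k-space noise SD; `NULL` calibrates it to a
#'   30 dB first-TSL image SNR, 0 gives noiseless data.
#' @param seed Integer seed controlling maps, coils, mask and noise.
#' @param config Ground-truth configuration passed to [make_ground_truth()].
#' @return List with elements `kspace` (fully sampled [multicoil_kspace]),
#'   `mask`, `maps`, `coils` and `truth` (the noiseless [image_sequence]).
#' @export
make_dataset <- function(ny, nz, tsl = default_tsl(), nc = 15, af = 2,
                         noise_sd = NULL, seed = 1L, config = list()) {
  maps <- make_ground_truth(ny, nz, seed = seed, config = config)
  truth <- synthesize_sequence(maps, tsl)
  coils <- make_coil_profiles(ny, nz, nc, seed = seed)
  y <- mri_forward(truth, coils)
  if (is.null(noise_sd)) noise_sd <- noise_sd_for_snr(truth, 30)
  if (noise_sd > 0) y <- add_noise(y, noise_sd, seed = seed + 2000L)
  mask <- poisson_disk_mask(ny, nz, length(tsl), af, seed = seed + 3000L)
  list(kspace = y, mask = mask, maps = maps, coils = coils, truth = truth)
}
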