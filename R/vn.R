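# ---- complex <-> 2-channel helpers -----------------------------------------

c2r <- function(x) {
  d <- dim(x)
  out <- array(0, c(d, 2))
  out[, , , 1] <- Re(x); out[, , , 2] <- Im(x)
  out
}

r2c <- function(xr) {
  d <- dim(xr)[1:3]
  re <- xr[, , , 1, drop = FALSE]; dim(re) <- d
  im <- xr[, , , 2, drop = FALSE]; dim(im) <- d
  complex(real = re, imaginary = im) |> array(d)
}

# Cross-correlation of a 2-channel real field with one kernel (ky,kz,kt,2):
# out[n] = sum_{d,ch} x[n+d, ch] k[d, ch], zero padded (compiled kernel).
vn_corr <- function(xr, kern) {
  d <- dim(xr)[1:3]
  array(vn_corr_cpp(as.numeric(xr), d, as.numeric(kern), dim(kern)[1:3]), d)
}

# Exact transpose of vn_corr: maps a single-channel response back to 2 channels.
vn_corr_t <- function(resp, kern) {
  d <- dim(resp)
  array(vn_corr_t_cpp(as.numeric(resp), d, as.numeric(kern), dim(kern)[1:3]),
        c(d, 2))
}

# Gradient of <up, vn_corr(xr, k)> with respect to the kernel.
vn_kernel_grad <- function(xr, up, kd) {
  array(vn_kernel_grad_cpp(as.numeric(xr), dim(up), as.numeric(up), kd[1:3]), kd)
}

# ---- learned pointwise activation -------------------------------------------

#' Evaluate a learned radial-basis activation
#'
#' The learned activations are weighted sums of Gaussian radial basis
#' functions on fixed, evenly spaced knots spanning a symmetric range; inputs
#' outside the range are clamped so the boundary basis values apply.
#'
#' @param u Numeric array of filter responses.
#' @param weights Knot weight vector.
#' @param knots Knot centers (fixed, evenly spaced, symmetric).
#' @return Array of activation values, same shape as `u`.
#' @export
activation_apply <- function(u, weights, knots) {
  out <- rbf_eval_cpp(as.numeric(u), weights, knots)
  if (!is.null(dim(u))) dim(out) <- dim(u)
  out
}

vn_knots <- function(n_knots = 31, range = 1) seq(-range, range, length.out = n_knots)

# ---- parameters -------------------------------------------------------------

#' Configuration presets for the variational network
#'
#' The `"full"` preset records the full-scale reference configuration
#' (M = 10 layers, N_k = 24 filters of size 11x11 for the spatial variant and
#' 11x11x3 for the spatio-temporal one, 50 ADAM epochs at learning rate 1e-3
#' with batch size 40/20), practical only with accelerator hardware. The
#' `"desk"` preset is the package's CPU-scale configuration used
#' throughout the tests: 24x24x6 images, M = 5 layers, N_k = 8 filters of
#' size 5x5 (or 5x5x3), 30 epochs, batch 8, 64 training slices.
#'
#' @param preset `"desk"` or `"full"`.
#' @param variant `"S"` (spatial filters) or `"ST"` (spatio-temporal).
#' @return List of configuration values.
#' @export
vn_preset <- function(preset = c("desk", "full"), variant = c("S", "ST")) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  if (preset == "full") {
    list(preset = "full", variant = variant, M = 10, n_filters = 24,
         ksize = 11, kt = if (variant == "ST") 3 else 1, n_knots = 31,
         knot_range = 1, epochs = 50, learning_rate = 1e-3,
         batch_size = if (variant == "S") 40 else 20, n_train = 3072)
  } else {
    list(preset = "desk", variant = variant, M = 5, n_filters = 8,
         ksize = 5, kt = if (variant == "ST") 3 else 1, n_knots = 31,
         knot_range = 1, epochs = 30, learning_rate = 1e-3,
         batch_size = 8, n_train = 64, ny = 24, nz = 24, nt = 6, nc = 4)
  }
}

#' Initialize variational-network parameters
#'
#' Random small convolution filters, activation weights initialized to a
#' least-squares radial-basis fit of a gentle linear function (so early layers
#' act as weak smoothers rather than the zero map), and unit step sizes.
#'
#' @param config A [vn_preset()] list (or one with the same fields).
#' @param seed Integer seed.
#' @return Object of class `vn_params` with per-layer `kernels`
#'   `(k, k, kt, 2, N_k)`, `w` `(N_k, n_knots)` and `alpha`.
#' @export
vn_init_params <- function(config, seed = 1L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  knots <- vn_knots(config$n_knots, config$knot_range)
  sigma <- knots[2] - knots[1]
  ugrid <- seq(-config$knot_range, config$knot_range, length.out = 201)
  phi <- exp(-(outer(ugrid, knots, "-"))^2 / (2 * sigma^2))
  w_lin <- qr.solve(crossprod(phi) + 1e-8 * diag(length(knots)),
                    crossprod(phi, 0.05 * ugrid))
  kd <- c(config$ksize, config$ksize, config$kt, 2)
  layers <- lapply(seq_len(config$M), function(m) {
    kernels <- array(rnorm(prod(kd) * config$n_filters,
                           sd = 0.1 / sqrt(prod(kd))),
                     c(kd, config$n_filters))
    w <- matrix(rep(as.numeric(w_lin), each = config$n_filters),
                config$n_filters, length(knots))
    list(kernels = kernels, w = w, alpha = 1)
  })
  structure(list(layers = layers, knots = knots, variant = config$variant,
                 config = config), class = "vn_params")
}

#' @export
print.vn_params <- function(x, ...) {
  kd <- dim(x$layers[[1]]$kernels)
  cat(sprintf("<vn_params> VN-%s, %d layers, %d filters of %dx%dx%d, %d knots\n",
              x$variant, length(x$layers), kd[5], kd[1], kd[2], kd[3],
              length(x$knots)))
  invisible(x)
}

# ---- forward ----------------------------------------------------------------

vn_layer_core <- function(x, ys, coils, mask, layer, knots, tsl) {
  xr <- c2r(x)
  d <- dim(x)
  nf <- dim(layer$kernels)[5]
  reg <- array(0, c(d, 2))
  us <- vector("list", nf)
  for (i in seq_len(nf)) {
    kern <- layer$kernels[, , , , i, drop = FALSE]
    dim(kern) <- dim(layer$kernels)[1:4]
    u <- vn_corr(xr, kern)
    us[[i]] <- u
    a <- activation_apply(u, layer$w[i, ], knots)
    reg <- reg + vn_corr_t(a, kern)
  }
  res <- ys - forward_raw(x, coils$sensitivities, coils$phase_map, mask$pattern)
  g <- adjoint_raw(res, coils$sensitivities, coils$phase_map, mask$pattern)
  list(x_next = x - r2c(reg) + layer$alpha * g, u = us, g = g)
}

#' Apply one variational-network layer
#'
#' One unrolled gradient-descent-like step
#' `x_{m+1} = x_m - sum_i K*_i Phi'_i(K_i x_m) + alpha C* F* S* (y_S - S F C x_m)`:
#' learned zero-padded convolutions over the real/imaginary channels, learned
#' pointwise activations, and a data-consistency gradient step. (The data
#' term is applied with the standard descent sign, which moves the iterate
#' toward data consistency.)
#'
#' @param x An [image_sequence] (current iterate).
#' @param y A [multicoil_kspace] (zero-filled measurements).
#' @param coils A [coil_profile].
#' @param mask A [sampling_mask].
#' @param layer One layer of a [vn_init_params()] object.
#' @param knots Activation knot vector.
#' @return The next iterate as an [image_sequence].
#' @export
vn_layer <- function(x, y, coils, mask, layer, knots = vn_knots()) {
  out <- vn_layer_core(x$data, zero_fill(y, mask), coils, mask, layer, knots,
                       x$tsl)
  image_sequence(out$x_next, x$tsl)
}

zero_fill <- function(y, mask) {
  ys <- y$data
  for (t in seq_len(dim(ys)[3])) for (c in seq_len(dim(ys)[4]))
    ys[, , t, c] <- ys[, , t, c] * mask$pattern[, , t]
  ys
}

#' Variational-network reconstruction
#'
#' Applies the M learned layers starting from the zero-filled adjoint
#' `x_1 = C* F* S* y_S`. The input is scaled by the peak magnitude of the
#' zero-filled adjoint so activations operate on a fixed range, and scaled
#' back on output; the map is deterministic.
#'
#' @param y A [multicoil_kspace].
#' @param coils A [coil_profile].
#' @param mask A [sampling_mask].
#' @param params A [vn_init_params()] / [train_vn()] parameter object.
#' @return An [image_sequence].
#' @export
vn_forward <- function(y, coils, mask, params) {
  ys <- zero_fill(y, mask)
  x <- mri_adjoint(multicoil_kspace(ys, y$tsl), coils, mask)$data
  s <- max(Mod(x))
  if (s == 0) return(image_sequence(x, y$tsl))
  xn <- x / s
  ysn <- ys / s
  for (layer in params$layers)
    xn <- vn_layer_core(xn, ysn, coils, mask, layer, params$knots, y$tsl)$x_next
  image_sequence(xn * s, y$tsl)
}

# ---- backward ---------------------------------------------------------------

# Forward pass with caches, then reverse-mode gradients of
# L = sum |x_{M+1} - x_ref|^2 with respect to all layer parameters.
vn_loss_grad <- function(sample, params, coils = sample$coils,
                         mask = sample$mask) {
  tsl <- sample$y$tsl
  ys <- zero_fill(sample$y, mask)
  x <- mri_adjoint(multicoil_kspace(ys, tsl), coils, mask)$data
  s <- max(Mod(x))
  if (s == 0) s <- 1
  xn <- x / s
  ysn <- ys / s
  xref <- sample$x_ref$data / s
  M <- length(params$layers)
  cache <- vector("list", M)
  xs <- vector("list", M + 1)
  xs[[1]] <- xn
  for (m in seq_len(M)) {
    st <- vn_layer_core(xs[[m]], ysn, coils, mask, params$layers[[m]],
                        params$knots, tsl)
    cache[[m]] <- st
    xs[[m + 1]] <- st$x_next
  }
  diffc <- xs[[M + 1]] - xref
  loss <- sum(Mod(diffc)^2) * s^2
  G <- 2 * c2r(diffc)                      # d L_norm / d x_{M+1}
  A <- function(v) forward_raw(v, coils$sensitivities, coils$phase_map,
                               mask$pattern)
  At <- function(k) adjoint_raw(k, coils$sensitivities, coils$phase_map,
                                mask$pattern)
  grads <- vector("list", M)
  knots <- params$knots
  for (m in rev(seq_len(M))) {
    layer <- params$layers[[m]]
    st <- cache[[m]]
    xr_m <- c2r(xs[[m]])
    nf <- dim(layer$kernels)[5]
    kd <- dim(layer$kernels)[1:4]
    g_alpha <- sum(G * c2r(st$g))
    Gc <- r2c(G)
    Gx <- G - layer$alpha * c2r(At(A(Gc)))   # identity + data-consistency path
    gk <- array(0, dim(layer$kernels))
    gw <- matrix(0, nf, length(knots))
    Greg <- -G
    for (i in seq_len(nf)) {
      kern <- layer$kernels[, , , , i, drop = FALSE]; dim(kern) <- kd
      u <- st$u[[i]]
      a_bar <- vn_corr(Greg, kern)           # adjoint of the transposed conv
      act <- rbf_backward_cpp(as.numeric(u), layer$w[i, ], knots,
                              as.numeric(a_bar))
      gw[i, ] <- act$gw
      u_bar <- array(act$u_bar, dim(u))
      gk[, , , , i] <- vn_kernel_grad(Greg, array(act$value, dim(u)), kd) +
        vn_kernel_grad(xr_m, u_bar, kd)
      Gx <- Gx + vn_corr_t(u_bar, kern)
    }
    grads[[m]] <- list(kernels = gk * s^2, w = gw * s^2, alpha = g_alpha * s^2)
    G <- Gx
  }
  list(loss = loss, grads = grads)
}

# ---- training ---------------------------------------------------------------

#' Build a synthetic training/validation set for the variational network
#'
#' Small phantom slices at the desk scale: each slice draws its own ground
#' truth, coil profiles, Poisson-disk mask and k-space noise. Half the slices
#' are noiseless and half carry 30 dB k-space noise, giving a mixed
#' noiseless/noisy training corpus.
#'
#' @param n_slices Number of slices.
#' @param ny,nz,nt,nc Geometry (defaults from the desk preset).
#' @param af Acceleration factor of the per-slice masks.
#' @param seed Integer seed.
#' @return List of samples, each with `y` (full k-space), `coils`, `mask`,
#'   `x_ref` (ground-truth image sequence).
#' @export
make_vn_training_set <- function(n_slices, ny = 24, nz = 24, nt = 6, nc = 4,
                                 af = 4, seed = 1L) {
  tsl <- default_tsl()[seq_len(nt)]
  lapply(seq_len(n_slices), function(j) {
    ds <- make_dataset(ny, nz, tsl = tsl, nc = nc, af = af,
                       noise_sd = if (j %% 2 == 0) 0 else NULL,
                       seed = seed * 10000L + j)
    list(y = ds$kspace, coils = ds$coils, mask = ds$mask, x_ref = ds$truth)
  })
}

#' Train the variational network
#'
#' Minimizes the summed squared complex reconstruction error
#' `sum_j ||x_{M,j} - x_ref,j||_2^2` over all layer parameters (filters,
#' activation knot weights, step sizes) with ADAM, using reverse-mode
#' gradients of the unrolled network. A random 10% of the slices is held out
#' as a validation set whose loss is recorded per epoch; step sizes are
#' projected to be nonnegative after each update. Training aborts with an
#' error if the loss becomes non-finite.
#'
#' @param training_set List of samples as from [make_vn_training_set()]
#'   (fields `y`, `coils`, `mask`, `x_ref`).
#' @param config A [vn_preset()]-style configuration (fields `epochs`,
#'   `learning_rate`, `batch_size`, and the architecture fields).
#' @param seed Integer seed (initialization, split and shuffling).
#' @param verbose Print per-epoch losses.
#' @return List with `params` (trained [vn_init_params()] object), `loss`
#'   (per-epoch mean training loss) and `val_loss`.
#' @export
train_vn <- function(training_set, config = vn_preset("desk", "S"), seed = 1L,
                     verbose = FALSE) {
  if (length(training_set) == 0) stop("training set is empty")
  if (config$epochs < 1) stop("epochs must be >= 1")
  if (config$learning_rate <= 0) stop("learning_rate must be > 0")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- vn_init_params(config, seed = seed)
  n <- length(training_set)
  n_val <- max(0L, floor(0.1 * n))
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  # ADAM state mirrors the parameter structure
  zero_like <- function(p) lapply(p$layers, function(l)
    list(kernels = array(0, dim(l$kernels)),
         w = matrix(0, nrow(l$w), ncol(l$w)), alpha = 0))
  m1 <- zero_like(params); m2 <- zero_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0L
  loss_trace <- numeric(0); val_trace <- numeric(0)

  sample_loss <- function(s) {
    out <- vn_forward(s$y, s$coils, s$mask, params)
    sum(Mod(out$data - s$x_ref$data)^2)
  }

  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      acc <- zero_like(params)
      bl <- 0
      for (j in batch) {
        bg <- vn_loss_grad(training_set[[j]], params)
        bl <- bl + bg$loss
        for (m in seq_along(acc)) {
          acc[[m]]$kernels <- acc[[m]]$kernels + bg$grads[[m]]$kernels
          acc[[m]]$w <- acc[[m]]$w + bg$grads[[m]]$w
          acc[[m]]$alpha <- acc[[m]]$alpha + bg$grads[[m]]$alpha
        }
      }
      if (!is.finite(bl)) stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + bl
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (m in seq_along(params$layers)) {
        for (fld in c("kernels", "w", "alpha")) {
          g <- acc[[m]][[fld]] / length(batch)
          m1[[m]][[fld]] <- b1 * m1[[m]][[fld]] + (1 - b1) * g
          m2[[m]][[fld]] <- b2 * m2[[m]][[fld]] + (1 - b2) * g^2
          params$layers[[m]][[fld]] <- params$layers[[m]][[fld]] -
            lr * corr * m1[[m]][[fld]] / (sqrt(m2[[m]][[fld]]) + eps)
        }
        params$layers[[m]]$alpha <- max(params$layers[[m]]$alpha, 0)
      }
    }
    loss_trace[ep] <- ep_loss / length(tr_idx)
    val_trace[ep] <- if (n_val > 0)
      mean(vapply(training_set[val_idx], sample_loss, numeric(1))) else NA_real_
    if (verbose)
      message(sprintf("epoch %3d  train %.5g  val %.5g", ep, loss_trace[ep],
                      val_trace[ep]))
  }
  list(params = params, loss = loss_trace, val_loss = val_trace)
}
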