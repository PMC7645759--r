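tiny_vn_cfg <- list(preset = "desk", variant = "S", M = 2, n_filters = 2,
                    ksize = 3, kt = 1, n_knots = 31, knot_range = 1,
                    epochs = 1, learning_rate = 1e-3, batch_size = 1)

tiny_vn_sample <- function(seed = 1) {
  ny <- 8; nz <- 8; nt <- 2; tsl <- c(2, 4)
  maps <- make_ground_truth(16, 16, seed = seed)
  truth <- synthesize_sequence(maps, tsl)
  x <- image_sequence(truth$data[1:ny, 1:nz, , drop = FALSE], tsl)
  coils <- make_coil_profiles(ny, nz, 2, seed = seed)
  y <- add_noise(mri_forward(x, coils), 0.005, seed = seed + 1)
  mask <- poisson_disk_mask(ny, nz, nt, af = 1.5, seed = seed + 2)
  list(y = y, coils = coils, mask = mask, x_ref = x)
}

test_that("learned activations evaluate the radial-basis expansion", {
  k <- t1rhomap:::vn_knots(31, 1.1)
  u <- seq(-1.3, 1.3, length.out = 500)
  expect_true(all(activation_apply(u, rep(0, 31), k) == 0))
  # least-squares fit of the identity on [-1, 1]: small uniform error
  sigma <- k[2] - k[1]
  ug <- seq(-1, 1, length.out = 501)
  phi <- exp(-(outer(ug, k, "-"))^2 / (2 * sigma^2))
  w_lin <- qr.solve(crossprod(phi) + 1e-12 * diag(31), crossprod(phi, ug))
  uu <- seq(-1, 1, length.out = 301)
  expect_lt(max(abs(activation_apply(uu, as.numeric(w_lin), k) - uu)), 1e-2)
  # odd weight patterns give odd functions
  w_odd <- sin(seq(-2, 2, length.out = 31))
  expect_equal(activation_apply(uu, w_odd, k),
               -activation_apply(-uu, w_odd, k), tolerance = 1e-8)
})

test_that("VN convolutions and their transposes are exact adjoint pairs", {
  set.seed(51)
  for (kd in list(c(3, 3, 1), c(5, 5, 3))) {
    kern <- array(rnorm(prod(kd) * 2), c(kd, 2))
    xr <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    resp <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    lhs <- sum(t1rhomap:::vn_corr(xr, kern) * resp)
    rhs <- sum(xr * t1rhomap:::vn_corr_t(resp, kern))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  }
})

test_that("degenerate layers act as the identity", {
  s <- tiny_vn_sample(61)
  knots <- t1rhomap:::vn_knots(31, 1)
  zero_layer <- list(kernels = array(0, c(3, 3, 1, 2, 2)),
                     w = matrix(0, 2, 31), alpha = 0)
  x <- mri_adjoint(s$y, s$coils, s$mask)
  out <- vn_layer(x, s$y, s$coils, s$mask, zero_layer, knots)
  expect_equal(out$data, x$data)
  # zero filters with a unit data step: the residual vanishes at the adjoint
  # of fully sampled data under normalized coils
  full <- sampling_mask(array(1, dim(s$mask$pattern)), s$mask$calib_extent)
  xf <- mri_adjoint(s$y, s$coils, full)
  dc_layer <- list(kernels = array(0, c(3, 3, 1, 2, 2)),
                   w = matrix(0, 2, 31), alpha = 1)
  out2 <- vn_layer(xf, s$y, s$coils, full, dc_layer, knots)
  expect_lt(max(Mod(out2$data - xf$data)), 1e-10 * max(Mod(xf$data)))
})

test_that("the network with all-zero parameters returns the zero-filled adjoint", {
  s <- tiny_vn_sample(62)
  params <- vn_init_params(tiny_vn_cfg, seed = 3)
  for (m in seq_along(params$layers)) {
    params$layers[[m]]$kernels[] <- 0
    params$layers[[m]]$w[] <- 0
    params$layers[[m]]$alpha <- 0
  }
  out <- vn_forward(s$y, s$coils, s$mask, params)
  zf <- mri_adjoint(s$y, s$coils, s$mask)
  expect_equal(out$data, zf$data, tolerance = 1e-12)
})

test_that("reconstruction is deterministic and bounded for finite parameters", {
  s <- tiny_vn_sample(63)
  set.seed(64)
  params <- vn_init_params(tiny_vn_cfg, seed = 4)
  for (m in seq_along(params$layers)) {  # exaggerate the parameters
    params$layers[[m]]$kernels <- params$layers[[m]]$kernels * 50
    params$layers[[m]]$w <- params$layers[[m]]$w + rnorm(length(params$layers[[m]]$w))
  }
  o1 <- vn_forward(s$y, s$coils, s$mask, params)
  o2 <- vn_forward(s$y, s$coils, s$mask, params)
  expect_identical(o1$data, o2$data)
  expect_true(all(is.finite(Mod(o1$data))))
})

test_that("reverse-mode gradients agree with finite differences", {
  s <- tiny_vn_sample(65)
  params <- vn_init_params(tiny_vn_cfg, seed = 5)
  bg <- t1rhomap:::vn_loss_grad(s, params)
  loss_of <- function(p) {
    out <- vn_forward(s$y, s$coils, s$mask, p)
    sum(Mod(out$data - s$x_ref$data)^2)
  }
  eps <- 1e-5
  fds <- ans <- c()
  set.seed(66)
  for (m in 1:2) {
    for (fld in c("kernels", "w")) {
      for (j in 1:6) {
        idx <- sample(length(params$layers[[m]][[fld]]), 1)
        p2 <- params; p2$layers[[m]][[fld]][idx] <- p2$layers[[m]][[fld]][idx] + eps
        p3 <- params; p3$layers[[m]][[fld]][idx] <- p3$layers[[m]][[fld]][idx] - eps
        fds <- c(fds, (loss_of(p2) - loss_of(p3)) / (2 * eps))
        ans <- c(ans, bg$grads[[m]][[fld]][idx])
      }
    }
    p2 <- params; p2$layers[[m]]$alpha <- p2$layers[[m]]$alpha + eps
    p3 <- params; p3$layers[[m]]$alpha <- p3$layers[[m]]$alpha - eps
    fds <- c(fds, (loss_of(p2) - loss_of(p3)) / (2 * eps))
    ans <- c(ans, bg$grads[[m]]$alpha)
  }
  expect_lt(sqrt(sum((fds - ans)^2) / sum(ans^2)), 1e-4)
})

test_that("the full-scale preset records the reference configuration", {
  ps <- vn_preset("full", "S")
  expect_equal(ps$M, 10)
  expect_equal(ps$n_filters, 24)
  expect_equal(ps$ksize, 11)
  expect_equal(ps$kt, 1)
  expect_equal(ps$epochs, 50)
  expect_equal(ps$learning_rate, 1e-3)
  expect_equal(ps$batch_size, 40)
  pst <- vn_preset("full", "ST")
  expect_equal(pst$kt, 3)
  expect_equal(pst$batch_size, 20)
})

test_that("training rejects invalid configurations and empty sets", {
  cfg0 <- tiny_vn_cfg; cfg0$epochs <- 0
  expect_error(train_vn(list(tiny_vn_sample(67)), cfg0), "epochs")
  expect_error(train_vn(list(), tiny_vn_cfg), "empty")
  cfg_lr <- tiny_vn_cfg; cfg_lr$learning_rate <- 0
  expect_error(train_vn(list(tiny_vn_sample(67)), cfg_lr), "learning_rate")
})

test_that("desk-scale training halves the loss", {
  fit <- get_desk_vn()
  n <- length(fit$loss)
  expect_gte(1 - fit$loss[n] / fit$loss[1], 0.5)
  expect_true(all(is.finite(fit$loss)))
  expect_true(all(vapply(fit$params$layers, function(l) l$alpha >= 0, logical(1))))
})
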