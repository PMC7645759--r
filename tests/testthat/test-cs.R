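test_that("finite-difference transforms match hand values and kill constants", {
  a <- array(0i, c(3, 3, 3))
  a[] <- 5 + 2i
  expect_true(all(sfd(a) == 0))
  # y-differences of the row [1, 3, 6] with zero boundary
  b <- array(0i, c(3, 1, 1)); b[, 1, 1] <- c(1, 3, 6)
  expect_equal(as.vector(Re(sfd(b)[, 1, 1, 1])), c(2, 3, 0))
  # affine-in-time, constant-in-space sequences are in the STFD kernel
  lin <- array(0i, c(4, 4, 3))
  for (t in 1:3) lin[, , t] <- 2 * t + 1
  expect_true(all(stfd(lin) == 0))
  # temporal profile [1, 2, 4]: second difference 1 at the interior point
  tp <- array(0i, c(1, 1, 3)); tp[1, 1, ] <- c(1, 2, 4)
  expect_equal(as.vector(Re(stfd(tp)[1, 1, , 3])), c(0, 1, 0))
  expect_error(stfd(array(0i, c(4, 4, 2))), "at least 3")
})

test_that("transform adjoints are exact transposes", {
  x <- rand_cplx(c(6, 6, 4), 31)
  u <- rand_cplx(c(6, 6, 4, 2), 32)
  lhs <- sum(Conj(sfd(x)) * u)
  rhs <- sum(Conj(x) * sfd_adjoint(u))
  expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-12)
  v <- rand_cplx(c(6, 6, 4, 3), 33)
  lhs <- sum(Conj(stfd(x)) * v)
  rhs <- sum(Conj(x) * stfd_adjoint(v))
  expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-12)
})

test_that("the beta rule scales with the zero-filled adjoint peak", {
  ny <- 8; nz <- 8; nt <- 2
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  full <- sampling_mask(array(1, c(ny, nz, nt)), c(2, 2))
  x <- array(0i, c(ny, nz, nt)); x[3, 5, 1] <- 3.5   # adjoint peak 3.5
  y <- mri_forward(image_sequence(x, c(2, 4)), one, full)
  expect_equal(lambda_from_beta(0, y, one, full), 0)
  expect_equal(lambda_from_beta(0.01, y, one, full), 0.035, tolerance = 1e-10)
  y10 <- multicoil_kspace(10 * y$data, y$tsl)
  expect_equal(lambda_from_beta(0.01, y10, one, full),
               10 * lambda_from_beta(0.01, y, one, full), tolerance = 1e-10)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(cs_config("SFD"), "exactly one")
  expect_error(cs_config("SFD", lambda = 1, beta = 1), "exactly one")
  expect_error(cs_config("SFD", lambda = -1), ">= 0")
  expect_error(cs_config("SFD", lambda = 1, tol = 0), "tol")
})

test_that("unregularized full-sampling problems stop at the adjoint solution", {
  ny <- 16; nz <- 16; nt <- 4
  tsl <- default_tsl()[1:4]
  maps <- make_ground_truth(ny, nz, seed = 4)
  x <- synthesize_sequence(maps, tsl)
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  y <- mri_forward(x, one)
  full <- sampling_mask(array(1, c(ny, nz, nt)), c(5, 5))
  r <- cs_reconstruct(y, one, full, cs_config("SFD", lambda = 0))
  expect_equal(r$iterations, 1L)
  expect_true(r$converged)
  expect_lt(nrmse(r$x, x), 1e-10)
})

test_that("the solver cost trace is monotone and strong regularization shrinks", {
  ny <- 16; nz <- 16; nt <- 4
  tsl <- default_tsl()[1:4]
  x <- synthesize_sequence(make_ground_truth(ny, nz, seed = 4), tsl)
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  y <- add_noise(mri_forward(x, one), 0.01, seed = 5)
  mask <- poisson_disk_mask(ny, nz, nt, af = 2.5, seed = 6)
  rec <- cs_reconstruct(y, one, mask, cs_config("SFD", beta = 0.02))
  expect_true(all(diff(rec$cost) <= 1e-9 * abs(rec$cost[-length(rec$cost)]) + 1e-12))
  expect_true(rec$converged)
  zf <- mri_adjoint(y, one, mask)
  big <- cs_reconstruct(y, one, mask,
                        cs_config("SFD", lambda = 10 * max(Mod(zf$data))))
  expect_lt(sum(Mod(sfd(big$x$data))), sum(Mod(sfd(zf$data))))
})

test_that("the beta search grid has the 12.3285 log geometry and tuning beats the endpoints", {
  g <- beta_grid()
  expect_length(g, 12)
  expect_equal(g[1], 1e-6)
  expect_equal(g[12], 1e6)
  expect_equal(unique(round(g[-1] / g[-12], 4)), 12.3285, tolerance = 5e-4)
  # tuning on one noisy undersampled pair improves on both grid endpoints
  ny <- 12; nz <- 12; nt <- 4
  tsl <- default_tsl()[1:4]
  x <- synthesize_sequence(make_ground_truth(16, 16, seed = 7), tsl)
  x <- image_sequence(x$data[1:ny, 1:nz, , drop = FALSE], tsl)
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  y <- add_noise(mri_forward(x, one), 0.02, seed = 8)
  mask <- poisson_disk_mask(ny, nz, nt, af = 4, seed = 9)
  pair <- list(list(y = y, coils = one, mask = mask, x_ref = x))
  tuned <- tune_beta(pair, "SFD", max_iter = 40)
  err_at <- function(b) {
    r <- cs_reconstruct(y, one, mask, cs_config("SFD", beta = b, max_iter = 40))
    sum(Mod(r$x$data - x$data)^2)
  }
  expect_lte(min(tuned$evaluations$error), err_at(1e-6) + 1e-9)
  expect_lte(min(tuned$evaluations$error), err_at(1e6) + 1e-9)
  expect_error(tune_beta(list(), "SFD"), "empty")
})
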