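test_that("forward/adjoint satisfy the dot-product identity and are linear", {
  ny <- 8; nz <- 8; nt <- 2; nc <- 2
  coils <- rand_coils(ny, nz, nc, 11)
  mask <- rand_mask(ny, nz, nt, 12)
  x <- image_sequence(rand_cplx(c(ny, nz, nt), 13), c(2, 4))
  y <- multicoil_kspace(rand_cplx(c(ny, nz, nt, nc), 14), c(2, 4))
  for (m in list(NULL, mask)) {
    fx <- mri_forward(x, coils, m)
    ay <- mri_adjoint(y, coils, m)
    lhs <- sum(Conj(fx$data) * y$data)
    rhs <- sum(Conj(x$data) * ay$data)
    expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-10)
  }
  # linearity: operator(a x + b z) = a op(x) + b op(z)
  z <- image_sequence(rand_cplx(c(ny, nz, nt), 15), c(2, 4))
  a <- 0.7 - 0.2i; b <- -1.3 + 0.4i
  comb <- image_sequence(a * x$data + b * z$data, c(2, 4))
  lhs <- mri_forward(comb, coils, mask)$data
  rhs <- a * mri_forward(x, coils, mask)$data + b * mri_forward(z, coils, mask)$data
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-12)
})

test_that("zero input produces zero output for both operators", {
  coils <- rand_coils(8, 8, 2, 21)
  x0 <- image_sequence(array(0i, c(8, 8, 2)), c(2, 4))
  y0 <- multicoil_kspace(array(0i, c(8, 8, 2, 2)), c(2, 4))
  expect_true(all(mri_forward(x0, coils)$data == 0))
  expect_true(all(mri_adjoint(y0, coils)$data == 0))
})

test_that("unitary convention: round trips are exact and energy is preserved", {
  ny <- 8; nz <- 8; nt <- 2
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  x <- image_sequence(rand_cplx(c(ny, nz, nt), 31), c(2, 4))
  y <- mri_forward(x, one)
  expect_lt(Mod(cplx <- sqrt(sum(Mod(y$data)^2)) - sqrt(sum(Mod(x$data)^2))), 1e-10)
  rt <- mri_adjoint(y, one)
  expect_lt(max(Mod(rt$data - x$data)) / max(Mod(x$data)), 1e-10)
  # C*C = identity on support for normalized multi-coil profiles
  coils <- rand_coils(ny, nz, 3, 32)
  rt2 <- mri_adjoint(mri_forward(x, coils), coils)
  expect_lt(max(Mod(rt2$data - x$data)) / max(Mod(x$data)), 1e-10)
})

test_that("shape mismatches raise errors", {
  coils <- rand_coils(8, 8, 2, 41)
  x_bad <- image_sequence(rand_cplx(c(6, 8, 2), 42), c(2, 4))
  expect_error(mri_forward(x_bad, coils), "grid")
  mask_bad <- rand_mask(8, 8, 3, 43)
  x <- image_sequence(rand_cplx(c(8, 8, 2), 44), c(2, 4))
  expect_error(mri_forward(x, coils, mask_bad), "mask")
  y_bad <- multicoil_kspace(rand_cplx(c(8, 8, 2, 3), 45), c(2, 4))
  expect_error(mri_adjoint(y_bad, coils), "coil count")
})

test_that("sensitivity estimation recovers known smooth coil profiles", {
  ny <- 32; nz <- 32; nc <- 4
  maps <- make_ground_truth(ny, nz, seed = 3)
  x <- synthesize_sequence(maps)
  coils <- make_coil_profiles(ny, nz, nc, seed = 3)
  y <- mri_forward(x, coils)
  est <- estimate_sensitivities(y, c(15, 15))
  sup <- est$support & Mod(maps$c) > 0
  ip <- abs(apply(Conj(est$sensitivities) * coils$sensitivities, c(1, 2), sum))
  expect_gt(median(ip[sup]), 0.95)
  # single uniform coil: constant sensitivity magnitude on the support
  one <- coil_profile(array(1 + 0i, c(ny, nz, 1)))
  y1 <- mri_forward(x, one)
  est1 <- estimate_sensitivities(y1, c(15, 15))
  mags <- Mod(est1$sensitivities[, , 1][est1$support])
  expect_lt(max(abs(mags - 1)), 1e-6)
  # the protocol's 39 x 19 block is accepted on a 128 x 64 grid
  y128 <- multicoil_kspace(rand_cplx(c(128, 64, 1, 1), 5), 2)
  expect_no_error(estimate_sensitivities(y128, c(39, 19)))
  expect_error(estimate_sensitivities(y1, c(64, 15)), "larger than")
})

test_that("phase compensation yields near-zero-phase reconstructions", {
  ny <- 32; nz <- 32
  coils <- make_coil_profiles(ny, nz, 4, seed = 7)
  # constant global phase pi/4: compensated calibration image has zero phase
  maps <- make_ground_truth(ny, nz, seed = 7,
                            config = list(phase0 = pi / 4, phase_ramp = c(0, 0)))
  x <- synthesize_sequence(maps)
  y <- mri_forward(x, coils)
  est <- estimate_sensitivities(y, c(15, 15))
  low <- t1rhomap:::calib_lowres(y, c(15, 15))
  comb <- apply(Conj(est$sensitivities) * low, c(1, 2), sum)
  comp <- Conj(est$phase_map) * comb
  expect_lt(max(abs(Arg(comp[est$support]))), 1e-6)
  # real-valued phantom with real coils: phase map is identically one
  mapsR <- make_ground_truth(ny, nz, seed = 7,
                             config = list(phase0 = 0, phase_ramp = c(0, 0)))
  sensR <- array(0i, c(ny, nz, 2)); sensR[, , 1] <- 0.6; sensR[, , 2] <- 0.8
  yR <- mri_forward(synthesize_sequence(mapsR), coil_profile(sensR))
  estR <- estimate_sensitivities(yR, c(15, 15))
  expect_lt(max(Mod(estR$phase_map[estR$support] - 1)), 1e-9)
  # linear phase ramp: compensated full reconstruction has small residual phase
  mapsL <- make_ground_truth(ny, nz, seed = 7,
                             config = list(phase0 = 0.3, phase_ramp = c(0.5, 0.4)))
  xL <- synthesize_sequence(mapsL)
  yL <- mri_forward(xL, coils)
  estL <- estimate_sensitivities(yL, c(15, 15))
  rec <- mri_adjoint(yL, estL)
  sup <- estL$support & Mod(mapsL$c) > 0
  expect_lt(median(abs(Arg(rec$data[, , 1])[sup])), 0.05)
})

test_that("k-space noise injection is deterministic with the stated SD", {
  y <- multicoil_kspace(array(0i, c(50, 50, 10, 4)), default_tsl())
  expect_identical(add_noise(y, 0), y)
  n1 <- add_noise(y, 1, seed = 5)
  n2 <- add_noise(y, 1, seed = 5)
  expect_identical(n1$data, n2$data)
  expect_lt(abs(sd(Re(n1$data)) - 1), 0.01)
  expect_lt(abs(sd(Im(n1$data)) - 1), 0.01)
  expect_error(add_noise(y, -1), ">= 0")
})
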