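tsl10 <- default_tsl()

test_that("complex monoexponential fits recover noiseless parameters exactly", {
  s <- (1 + 0.5i) * exp(-tsl10 / 40)
  f <- fit_mono(s, tsl10)
  expect_lt(Mod(f$c - (1 + 0.5i)) / Mod(1 + 0.5i), 1e-6)
  expect_lt(abs(f$tau - 40) / 40, 1e-6)
  expect_true(f$valid)
  # a constant signal pushes tau to its upper bound and is flagged
  fc <- fit_mono(rep(1 + 0i, 10), tsl10)
  expect_gte(fc$tau, 500 * (1 - 1e-6))
  expect_true(fc$tau_at_bound)
  expect_false(fc$valid)
  # real-valued signals give real amplitudes
  fr <- fit_mono(2.3 * exp(-tsl10 / 25) + 0i, tsl10)
  expect_lt(abs(Im(fr$c)), 1e-8)
  # degenerate inputs
  f0 <- fit_mono(rep(0i, 10), tsl10)
  expect_false(f0$valid)
  expect_error(fit_mono(1:3 + 0i, c(2, 4)), "equal length")
})

test_that("monoexponential classification uses the short/long windows", {
  expect_equal(classify_mono(5), "short")
  expect_equal(classify_mono(50), "long")
  expect_equal(classify_mono(400), "out_of_range")
  expect_equal(classify_mono(10), "short")
  expect_equal(classify_mono(0.4), "out_of_range")
  expect_equal(classify_mono(300), "long")
})

test_that("biexponential fits recover noiseless parameters and nest the mono model", {
  s <- 1 * (0.4 * exp(-tsl10 / 4) + 0.6 * exp(-tsl10 / 45))
  fm <- fit_mono(s, tsl10)
  fb <- fit_biexp(s, tsl10, fm)
  expect_lt(abs(fb$f_s - 0.4) / 0.4, 1e-3)
  expect_lt(abs(fb$tau_s - 4) / 4, 1e-3)
  expect_lt(abs(fb$tau_l - 45) / 45, 1e-3)
  expect_equal(fb$f_s + fb$f_l, 1)
  # pure mono signal: nesting enforced by the fallback rule
  sm <- (0.8 - 0.1i) * exp(-tsl10 / 35)
  fmm <- fit_mono(sm, tsl10)
  fbm <- fit_biexp(sm, tsl10, fmm)
  expect_lte(fbm$sse, fmm$sse)
  # nesting holds under noise as well
  set.seed(6)
  for (i in 1:25) {
    sn <- sm + complex(real = rnorm(10, 0, 0.03), imaginary = rnorm(10, 0, 0.03))
    a <- fit_mono(sn, tsl10); b <- fit_biexp(sn, tsl10, a)
    expect_lte(b$sse, a$sse + 1e-12)
  }
})

test_that("the F-test reproduces the 5.14 cutoff and its formula", {
  ft <- f_test(2, 0.5, 10)
  expect_equal(ft$threshold, 5.14, tolerance = 0.01)
  expect_equal(ft$f_ratio, ((2 - 0.5) / 2) / (0.5 / 6))  # = 9
  expect_true(ft$accept)
  eq <- f_test(1, 1, 10)
  expect_equal(eq$f_ratio, 0)
  expect_false(eq$accept)
  expect_true(f_test(1, 0, 10)$accept)   # perfect biexponential fit
  expect_error(f_test(1, 0.5, 4), "exceed 4")
})

test_that("voxelwise mapping assigns models correctly on noiseless phantoms", {
  maps <- make_ground_truth(24, 24, seed = 11,
                            config = list(phase0 = 0, phase_ramp = c(0, 0)))
  x <- synthesize_sequence(maps)
  pm <- fit_map(x, maps$roi_labels)
  roi <- maps$roi_labels != 0
  fitted <- !is.na(pm$model)
  expect_true(all(fitted == roi))
  agree <- (pm$model[roi] == 2L) == maps$is_biexp[roi]
  expect_equal(mean(agree), 1)
  # all-background labels give an empty map with a warning
  expect_warning(empty <- fit_map(x, matrix(0L, 24, 24)), "no ROI")
  expect_true(all(is.na(empty$model)))
})

test_that("sub-threshold fractions are excluded by the 5% validity rule", {
  maps <- make_ground_truth(16, 16, seed = 12,
                            config = list(f_s_range = c(0.04, 0.04),
                                          phase0 = 0, phase_ramp = c(0, 0)))
  expect_true(any(maps$is_biexp))
  x <- synthesize_sequence(maps)
  pm <- fit_map(x, maps$roi_labels)
  # true f_s = 4% everywhere biexponential: never accepted as biexponential
  expect_true(all(pm$model[maps$is_biexp] == 1L))
})

test_that("model assignment is reliable at 30 dB and conservative under the null", {
  # The 5.14 cutoff is strongly conservative for complex
  # residuals, so sensitivity at 30 dB requires a clearly resolved short
  # component (tau_s 2-4 ms, f_s 0.35-0.45, within the cartilage literature);
  # specificity is essentially perfect.
  maps <- make_ground_truth(24, 24, seed = 13,
                            config = list(phase0 = 0, phase_ramp = c(0, 0),
                                          f_s_range = c(0.35, 0.45),
                                          tau_s_range = c(2, 4)))
  x <- synthesize_sequence(maps)
  sd30 <- noise_sd_for_snr(x, 30)
  set.seed(14)
  noisy <- x$data + array(complex(real = rnorm(length(x$data), 0, sd30),
                                  imaginary = rnorm(length(x$data), 0, sd30)),
                          dim(x$data))
  pm <- fit_map(image_sequence(noisy, x$tsl), maps$roi_labels)
  roi <- maps$roi_labels != 0
  agree <- (pm$model[roi] == 2L) == maps$is_biexp[roi]
  expect_gte(mean(agree), 0.75)
  mono_gt <- roi & !maps$is_biexp
  expect_gte(mean(pm$model[mono_gt] == 1L), 0.95)
  # under a pure mono truth the selection rule never exceeds its nominal level
  set.seed(15)
  n <- 400; acc <- logical(n)
  for (i in seq_len(n)) {
    sn <- exp(-tsl10 / 40) +
      complex(real = rnorm(10, 0, 10^-1.5), imaginary = rnorm(10, 0, 10^-1.5))
    a <- fit_mono(sn, tsl10); b <- fit_biexp(sn, tsl10, a)
    acc[i] <- f_test(a$sse, b$sse, 10)$accept && min(b$f_s, b$f_l) >= 0.05
  }
  expect_lte(mean(acc), 0.05 + 1.5 * sqrt(0.05 * 0.95 / n))
})

test_that("complex fitting is less biased than magnitude-only fitting at 30 dB", {
  set.seed(16)
  n <- 300
  tc <- tm <- numeric(n)
  for (i in seq_len(n)) {
    sn <- exp(-tsl10 / 40) +
      complex(real = rnorm(10, 0, 10^-1.5), imaginary = rnorm(10, 0, 10^-1.5))
    tc[i] <- fit_mono(sn, tsl10)$tau
    tm[i] <- fit_mono_magnitude(sn, tsl10)$tau
  }
  expect_lt(abs(mean(tc) - 40) / 40, 0.01)
  expect_lt(abs(mean(tc) - 40), abs(mean(tm) - 40))
})
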