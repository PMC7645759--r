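# Shared fixtures and oracles, all generated in code.

rand_cplx <- function(dims, seed) {
  set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
}

# random sum-of-squares-normalized coil profile with random unit phase map
rand_coils <- function(ny, nz, nc, seed) {
  sens <- rand_cplx(c(ny, nz, nc), seed)
  sos <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  for (c in seq_len(nc)) sens[, , c] <- sens[, , c] / sos
  set.seed(seed + 1)
  coil_profile(sens, exp(1i * matrix(rnorm(ny * nz), ny, nz)))
}

rand_mask <- function(ny, nz, nt, seed, calib = c(4, 4)) {
  set.seed(seed)
  pat <- array(rbinom(ny * nz * nt, 1, 0.5), c(ny, nz, nt))
  ry <- t1rhomap:::calib_range(ny, calib[1])
  rz <- t1rhomap:::calib_range(nz, calib[2])
  pat[ry, rz, ] <- 1
  sampling_mask(pat, calib)
}

# Plain (non-accelerated) proximal-gradient reference for the CS problem on a
# single-coil instance: independent long-run oracle for the solver objective.
ista_oracle <- function(y, coils, mask, lambda, n_iter, inner_iter = 20) {
  tsl <- y$tsl
  nt <- length(tsl)
  A <- function(v) mri_forward(image_sequence(v, tsl), coils, mask)$data
  At <- function(k) mri_adjoint(multicoil_kspace(k, tsl), coils, mask)$data
  ys <- y$data
  for (t in seq_len(nt)) ys[, , t, 1] <- ys[, , t, 1] * mask$pattern[, , t]
  L <- 2 * 1.05                      # ||A||^2 <= 1 for unitary/normalized ops
  sigma <- 0.99 / 8                  # ||SFD||^2 <= 8
  mu <- lambda / L
  x <- At(ys)
  z <- sfd(x) * 0
  for (i in seq_len(n_iter)) {
    v <- x - 2 * At(A(x) - ys) / L
    for (k in seq_len(inner_iter)) {
      z <- z + sigma * sfd(v - sfd_adjoint(z))
      m <- Mod(z)
      z <- z * pmin(1, mu / pmax(m, 1e-300))
    }
    x <- v - sfd_adjoint(z)
  }
  obj <- sum(Mod(A(x) - ys)^2) + lambda * sum(Mod(sfd(x)))
  list(x = x, objective = obj)
}

# Desk-scale VN-S training is expensive; run it once per session and share it
# between the training test and the acceptance trend checks.
.vn_cache <- new.env()
get_desk_vn <- function() {
  if (is.null(.vn_cache$fit)) {
    cfg <- vn_preset("desk", "S")
    tset <- make_vn_training_set(cfg$n_train, af = 4, seed = 1)
    .vn_cache$fit <- train_vn(tset, cfg, seed = 1)
  }
  .vn_cache$fit
}
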