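#' Spatial finite differences (SFD), order 1
#'
#' First-order forward differences along y and along z of each TSL frame,
#' stacked along a fourth dimension. Differences at the trailing boundary are
#' zero, so the operator and [sfd_adjoint()] are exact transposes.
#'
#' @param x An [image_sequence] or complex array `(Ny, Nz, Nt)`.
#' @return Complex array `(Ny, Nz, Nt, 2)` of difference coefficients.
#' @export
sfd <- function(x) {
  a <- if (inherits(x, "image_sequence")) x$data else x
  if (!is.complex(a)) storage.mode(a) <- "complex"
  d <- dim(a)
  array(sfd_cpp(a, d), c(d, 2))
}

#' Adjoint of [sfd()]
#' @param u Complex array `(Ny, Nz, Nt, 2)`.
#' @return Complex array `(Ny, Nz, Nt)`.
#' @export
sfd_adjoint <- function(u) {
  if (!is.complex(u)) storage.mode(u) <- "complex"
  d <- dim(u)[1:3]
  array(sfd_adj_cpp(u, d), d)
}

#' Spatio-temporal finite differences (STFD)
#'
#' [sfd()] coefficients plus second-order temporal differences
#' `x(t-1) - 2 x(t) + x(t+1)` at interior TSL indices (zero at the temporal
#' boundaries), stacked as a third coefficient channel.
#'
#' @inheritParams sfd
#' @return Complex array `(Ny, Nz, Nt, 3)`.
#' @export
stfd <- function(x) {
  a <- if (inherits(x, "image_sequence")) x$data else x
  if (!is.complex(a)) storage.mode(a) <- "complex"
  d <- dim(a)
  if (d[3] < 3) stop("STFD needs at least 3 TSL frames")
  array(c(sfd_cpp(a, d), tdiff2_cpp(a, d)), c(d, 3))
}

#' Adjoint of [stfd()]
#' @param u Complex array `(Ny, Nz, Nt, 3)`.
#' @return Complex array `(Ny, Nz, Nt)`.
#' @export
stfd_adjoint <- function(u) {
  if (!is.complex(u)) storage.mode(u) <- "complex"
  d <- dim(u)[1:3]
  n <- prod(d)
  array(sfd_adj_cpp(u[seq_len(2 * n)], d) +
          tdiff2_adj_cpp(u[2 * n + seq_len(n)], d), d)
}

apply_transform <- function(a, transform) {
  switch(transform, SFD = sfd(a), STFD = stfd(a),
         stop("unknown transform: ", transform))
}

apply_transform_adjoint <- function(u, transform) {
  switch(transform, SFD = sfd_adjoint(u), STFD = stfd_adjoint(u),
         stop("unknown transform: ", transform))
}

#' Compressed-sensing reconstruction configuration
#'
#' @param transform Sparsifying transform, `"STFD"` or `"SFD"`.
#' @param lambda Regularization parameter; exactly one of `lambda`/`beta`.
#' @param beta Scale-free regularization coefficient; the effective lambda is
#'   `beta * max |C* F* S* y|` ([lambda_from_beta()]).
#' @param tol Relative-change stopping tolerance (default 1e-5).
#' @param max_iter Outer iteration cap (default 600).
#' @param inner_iter Dual sub-iterations of the transform prox (default 20).
#' @return A `cs_config` list.
#' @export
cs_config <- function(transform = c("STFD", "SFD"), lambda = NULL, beta = NULL,
                      tol = 1e-5, max_iter = 600, inner_iter = 20) {
  transform <- match.arg(transform)
  if (is.null(lambda) == is.null(beta))
    stop("exactly one of lambda or beta must be set")
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (!is.null(beta) && beta < 0) stop("beta must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(transform = transform, lambda = lambda, beta = beta,
                 tol = tol, max_iter = max_iter, inner_iter = inner_iter),
            class = "cs_config")
}

#' Regularization parameter from the zero-filled adjoint
#'
#' `lambda = beta * max |C* F* S* y|`: beta times the largest magnitude of
#' the zero-filled adjoint reconstruction, making the regularization strength
#' scale-free in the data.
#'
#' @param beta Coefficient (>= 0).
#' @param y A [multicoil_kspace] (zero-filled or full).
#' @param coils A [coil_profile].
#' @param mask A [sampling_mask].
#' @return The scalar lambda.
#' @export
lambda_from_beta <- function(beta, y, coils, mask) {
  if (beta < 0) stop("beta must be >= 0")
  beta * max(Mod(mri_adjoint(y, coils, mask)$data))
}

# largest eigenvalue of the composed normal operator by power iteration
power_norm <- function(apply_normal, dims, iters = 20, seed = 7L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
  lam <- 1
  for (i in seq_len(iters)) {
    w <- apply_normal(v)
    lam <- cplx_norm(w) / cplx_norm(v)
    v <- w / cplx_norm(w)
  }
  lam
}

# prox of mu * ||T . ||_1 at v by projected dual ascent, warm-started
# (fused C++ loop; see src/cs_ops.cpp)
prox_l1_transform <- function(v, mu, transform, sigma, inner_iter, z = NULL) {
  d <- dim(v)
  nchan <- if (transform == "SFD") 2L else 3L
  if (is.null(z)) z <- complex(nchan * prod(d))
  out <- prox_l1_dual_cpp(v, z, mu, sigma, inner_iter, d, nchan)
  list(x = array(out$x, d), z = out$z)
}

#' l1-regularized CS reconstruction by monotone FISTA
#'
#' Approximately minimizes `||y_S - S F C x||_2^2 + lambda ||T x||_1` with a
#' monotone accelerated proximal-gradient scheme (FISTA with a monotone
#' safeguard and restart). The non-separable transform prox is computed by a
#' warm-started projected dual-ascent inner loop; the gradient step size comes
#' from a power-iteration Lipschitz estimate with a 1.05 safety factor.
#' Iterations start at the zero-filled adjoint and stop when the relative
#' iterate change drops below `tol` or at `max_iter` (flagged, not an error).
#' The recorded cost trace is non-increasing by construction.
#'
#' @param y A [multicoil_kspace]; unsampled entries are zero-filled.
#' @param coils A [coil_profile].
#' @param mask A [sampling_mask].
#' @param cfg A [cs_config()].
#' @return List with `x` ([image_sequence]), `cost` (trace), `lambda`,
#'   `iterations`, `converged`.
#' @export
cs_reconstruct <- function(y, coils, mask, cfg = cs_config(beta = 0.01)) {
  stopifnot(inherits(cfg, "cs_config"))
  lambda <- cfg$lambda %||% lambda_from_beta(cfg$beta, y, coils, mask)
  if (lambda < 0) stop("lambda must be >= 0")
  d <- dim(y$data)[1:3]
  A <- function(x) forward_raw(x, coils$sensitivities, coils$phase_map,
                               mask$pattern)
  At <- function(k) adjoint_raw(k, coils$sensitivities, coils$phase_map,
                                mask$pattern)

  ys <- y$data
  for (t in seq_len(d[3])) for (c in seq_len(dim(y$data)[4]))
    ys[, , t, c] <- ys[, , t, c] * mask$pattern[, , t]

  L <- 2 * power_norm(function(v) At(A(v)), d) * 1.05
  sigmaT <- 0.99 / power_norm(function(v)
    apply_transform_adjoint(apply_transform(v, cfg$transform), cfg$transform), d)

  cost <- function(x) {
    r <- A(x) - ys
    sum(Re(r)^2 + Im(r)^2) + lambda * l1_norm_cpp(apply_transform(x, cfg$transform))
  }
  prox_step <- function(xx, z) {
    g <- 2 * At(A(xx) - ys)
    v <- xx - g / L
    if (lambda == 0) return(list(x = v, z = z))
    prox_l1_transform(v, lambda / L, cfg$transform, sigmaT, cfg$inner_iter, z)
  }

  x <- At(ys)
  fx <- cost(x)
  xv <- x            # extrapolation point
  tk <- 1
  zdual <- NULL
  trace <- fx
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    st <- prox_step(xv, zdual)
    zdual <- st$z
    fz <- cost(st$x)
    if (fz <= fx) {
      x_new <- st$x; f_new <- fz
    } else {
      # monotone safeguard: restart momentum, plain step from the incumbent
      tk <- 1
      st <- prox_step(x, zdual)
      zdual <- st$z
      fz <- cost(st$x)
      if (fz <= fx) { x_new <- st$x; f_new <- fz } else { x_new <- x; f_new <- fx }
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    xv <- x_new + (tk / t_next) * (st$x - x_new) + ((tk - 1) / t_next) * (x_new - x)
    rel <- cplx_norm(x_new - x) / max(cplx_norm(x_new), .Machine$double.eps)
    x <- x_new; fx <- f_new; tk <- t_next
    trace <- c(trace, fx)
    if (rel < cfg$tol) { converged <- TRUE; break }
  }
  list(x = image_sequence(x, y$tsl), cost = trace, lambda = lambda,
       iterations = iter, converged = converged)
}

#' The 12-point logarithmic beta search grid
#'
#' Twelve log-spaced coefficients between 1e-6 and 1e6; the consecutive ratio
#' is `10^(12/11) = 12.3285`.
#' @return Numeric vector of length 12.
#' @export
beta_grid <- function() 10^seq(-6, 6, length.out = 12)

#' Tune the CS regularization coefficient beta on training data
#'
#' Minimizes the summed squared reconstruction error
#' `sum_j ||x_hat(beta, j) - x_ref(j)||_2^2` over the 12-point log grid
#' ([beta_grid()]), then refines with 12 bisection steps in log space between
#' the best grid point's neighbors. Returns the best beta among all evaluated
#' points.
#'
#' @param training_pairs Nonempty list; each element a list with `y`
#'   ([multicoil_kspace]), `coils`, `mask`, and `x_ref` ([image_sequence]).
#' @param transform `"STFD"` or `"SFD"`.
#' @param max_iter Outer iteration cap for the tuning reconstructions.
#' @param refine Number of bisection refinement steps (default 12).
#' @return List with `beta`, `lambda_rule` description, and the evaluated
#'   `log10_beta`/`error` table.
#' @export
tune_beta <- function(training_pairs, transform = c("STFD", "SFD"),
                      max_iter = 100, refine = 12) {
  transform <- match.arg(transform)
  if (length(training_pairs) == 0) stop("training set is empty")
  evals <- new.env()
  err_of <- function(lb) {
    key <- sprintf("%.12g", lb)
    if (!is.null(evals[[key]])) return(evals[[key]])
    cfg <- cs_config(transform = transform, beta = 10^lb, max_iter = max_iter)
    e <- sum(vapply(training_pairs, function(p) {
      rec <- cs_reconstruct(p$y, p$coils, p$mask, cfg)
      sum(Mod(rec$x$data - p$x_ref$data)^2)
    }, numeric(1)))
    evals[[key]] <- e
    e
  }
  grid <- seq(-6, 6, length.out = 12)
  errs <- vapply(grid, err_of, numeric(1))
  b <- which.min(errs)
  lo <- grid[max(b - 1, 1)]; hi <- grid[min(b + 1, 12)]
  best <- grid[b]
  for (i in seq_len(refine)) {
    mid <- if ((best - lo) >= (hi - best)) (lo + best) / 2 else (best + hi) / 2
    em <- err_of(mid)
    if (em < err_of(best)) {
      if (mid < best) hi <- best else lo <- best
      best <- mid
    } else {
      if (mid < best) lo <- mid else hi <- mid
    }
  }
  keys <- ls(evals)
  tab <- data.frame(log10_beta = as.numeric(keys),
                    error = vapply(keys, function(k) evals[[k]], numeric(1)))
  tab <- tab[order(tab$log10_beta), ]
  best_all <- tab$log10_beta[which.min(tab$error)]
  list(beta = 10^best_all, evaluations = tab,
       lambda_rule = "lambda = beta * max|C*F*S*y|")
}
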