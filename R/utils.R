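#' @useDynLib t1rhomap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qf pf rnorm runif median sd oneway.test optimize
NULL

# Unitary 2D FFT over a matrix: adjoint equals inverse.
fft2u <- function(x) stats::fft(x) / sqrt(length(x))

ifft2u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Swap halves so DC sits at floor(n/2) (0-based) in each dimension.
# Index permutations are cached per grid size (hot path under FFT loops).
.shift_cache <- new.env(parent = emptyenv())
shift_idx <- function(n) {
  key <- as.character(n)
  got <- .shift_cache[[key]]
  if (is.null(got)) {
    inv <- c(seq_len(ceiling(n / 2)) + floor(n / 2), seq_len(floor(n / 2)))
    got <- list(fwd = order(inv), inv = inv)
    .shift_cache[[key]] <- got
  }
  got
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[shift_idx(d[1])$fwd, shift_idx(d[2])$fwd, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[shift_idx(d[1])$inv, shift_idx(d[2])$inv, drop = FALSE]
}

# 1-based index range of a centered calibration block of size k in a grid of
# size n. The block contains the DC index floor(n/2) (0-based): for n = 128,
# k = 39 this is rows 46..84 (0-based 45..83); for n = 64, k = 19, 24..42.
calib_range <- function(n, k) {
  if (k > n) stop("calibration extent (", k, ") exceeds grid size (", n, ")")
  start0 <- floor(n / 2) - floor((k - 1) / 2)
  (start0 + 1):(start0 + k)
}

cplx_norm <- function(x) sqrt(sum(Mod(x)^2))

cplx_inner <- function(a, b) sum(Conj(a) * b)

`%||%` <- function(a, b) if (is.null(a)) b else a
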