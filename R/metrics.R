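#' Normalized root mean squared error
#'
#' `||x_hat - x_ref||_2 / ||x_ref||_2` over the full complex sequence.
#'
#' @param x_hat,x_ref [image_sequence] objects or complex arrays of equal shape.
#' @return The nRMSE (scale-free in the reference).
#' @export
nrmse <- function(x_hat, x_ref) {
  a <- if (inherits(x_hat, "image_sequence")) x_hat$data else x_hat
  b <- if (inherits(x_ref, "image_sequence")) x_ref$data else x_ref
  if (!all(dim(a) == dim(b))) stop("shapes differ")
  nb <- cplx_norm(b)
  if (nb == 0) stop("reference has zero norm")
  cplx_norm(a - b) / nb
}

#' Normalized absolute deviation of a parameter pair
#'
#' `|p - p_ref| / ((p + p_ref)/2)`. Defined for positive parameters
#' (relaxation times and fractions); symmetric in its arguments and bounded
#' by 2.
#'
#' @param p,p_ref Parameter values (vectors allowed, positive sums required).
#' @return The NAD value(s).
#' @export
nad <- function(p, p_ref) {
  s <- p + p_ref
  if (any(s <= 0)) stop("nad requires p + p_ref > 0")
  abs(p - p_ref) / (s / 2)
}

param_matrix <- function(maps, parameter) {
  ok <- c("tau", "f_s", "f_l", "tau_s", "tau_l")
  if (!parameter %in% ok)
    stop("parameter must be one of: ", paste(ok, collapse = ", "))
  maps[[parameter]]
}

# Voxels usable for a given parameter: mono tau needs a fit; biexponential
# parameters additionally need the voxel accepted as biexponential (F-test
# and 5% fraction rule), applied two-sidedly when comparing two maps.
valid_voxels <- function(maps, parameter) {
  v <- !is.na(maps$model)
  if (parameter != "tau") v <- v & !is.na(maps$model) & maps$model == 2L
  v & !is.na(param_matrix(maps, parameter))
}

#' Median normalized absolute deviation over an ROI
#'
#' Median of per-voxel [nad()] values between two parameter maps, restricted
#' to voxels of the requested ROI that are valid in both maps. For
#' biexponential parameters both maps must accept the voxel as biexponential
#' (F-test and minimum-fraction rule); an MNAD of 0.1 reads as a 10% median
#' deviation.
#'
#' @param maps,ref_maps [fit_map()] results on aligned grids.
#' @param parameter One of `"tau"`, `"f_s"`, `"f_l"`, `"tau_s"`, `"tau_l"`.
#' @param roi ROI label(s) to restrict to; `NULL` uses all nonzero labels.
#' @return The MNAD, or `NA` (with a warning) if no common valid voxels exist.
#' @export
mnad <- function(maps, ref_maps, parameter = "tau", roi = NULL) {
  sel <- valid_voxels(maps, parameter) & valid_voxels(ref_maps, parameter)
  lab <- maps$roi_labels
  sel <- sel & (if (is.null(roi)) lab != 0 else lab %in% roi)
  if (!any(sel)) {
    warning("no common valid voxels for parameter ", parameter)
    return(NA_real_)
  }
  p <- param_matrix(maps, parameter)[sel]
  pr <- param_matrix(ref_maps, parameter)[sel]
  median(nad(p, pr))
}

#' ROI mean of a parameter map
#'
#' Arithmetic mean over the valid voxels of an ROI, the central-tendency
#' summary used when voxelwise comparison across subjects is impossible.
#'
#' @inheritParams mnad
#' @param maps A [fit_map()] result.
#' @return The ROI mean.
#' @export
roi_mean <- function(maps, parameter = "tau", roi = NULL) {
  v <- roi_values(maps, parameter, roi)
  mean(v)
}

#' ROI standard deviation of a parameter map
#'
#' Population standard deviation (1/N normalization) over the valid voxels of
#' an ROI, the variability summary paired with [roi_mean()].
#'
#' @inheritParams mnad
#' @param maps A [fit_map()] result.
#' @return The ROI standard deviation.
#' @export
roi_sd <- function(maps, parameter = "tau", roi = NULL) {
  v <- roi_values(maps, parameter, roi)
  sqrt(mean((v - mean(v))^2))
}

roi_values <- function(maps, parameter, roi) {
  sel <- valid_voxels(maps, parameter)
  lab <- maps$roi_labels
  sel <- sel & (if (is.null(roi)) lab != 0 else lab %in% roi)
  if (!any(sel)) stop("no valid voxels in the requested ROI")
  param_matrix(maps, parameter)[sel]
}

#' Repeatability coefficient of variation of two scans
#'
#' `CV = SD / M` of a pair of repeated-scan ROI means, with the population
#' (1/N) standard deviation convention, so `cv_repeat(c(90, 110)) = 0.1`.
#'
#' @param scan_means Numeric pair of ROI means from two scans.
#' @return The coefficient of variation (scale invariant).
#' @export
cv_repeat <- function(scan_means) {
  if (length(scan_means) != 2) stop("cv_repeat expects exactly two scan means")
  m <- mean(scan_means)
  if (m <= 0) stop("cv requires a positive mean")
  sqrt(mean((scan_means - m)^2)) / m
}

#' Balanced one-way ANOVA across methods
#'
#' Standard balanced one-way ANOVA (equal group variances assumed) testing
#' whether differences between per-method ROI means exceed chance.
#'
#' @param groups List of >= 2 equal-length numeric vectors (length >= 2).
#' @return List with `f_statistic` and `p_value`.
#' @export
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  sizes <- lengths(groups)
  if (length(unique(sizes)) != 1 || sizes[1] < 2)
    stop("groups must be balanced with at least two observations each")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), sizes))
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(f_statistic = unname(ft$statistic), p_value = unname(ft$p.value))
}
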