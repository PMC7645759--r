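experiment_methods <- c("CS-S", "CS-ST", "VN-S", "VN-ST", "REF", "ZF")

#' Default experiment configuration
#'
#' Desk-scale defaults for [run_experiment()]: 48 x 32 x 10 slices, 4 coils,
#' 6 training and 4 testing slices (a roughly 4:3 train:test split, half
#' noiseless and half noisy), acceleration
#' factors 2/4/6, CS methods plus the zero-filled and fully-sampled
#' references. Phantoms for the experiment are generated with zero object
#' phase so the ground truth is directly comparable to the phase-compensated
#' reconstructions.
#'
#' @param ... Named overrides of any configuration field.
#' @return Configuration list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    ny = 48, nz = 32, tsl = default_tsl(), nc = 4,
    n_train = 6, n_test = 4,
    af_list = c(2, 4, 6),
    methods = c("CS-S", "CS-ST", "ZF", "REF"),
    tune_af = NULL,            # default: middle of af_list
    cs_max_iter = 200, tune_max_iter = 40,
    vn_epochs = 12, vn_filters = 8, vn_layers = 5, vn_ksize = 5,
    fit_biexp = FALSE,
    gt_config = list(phase0 = 0, phase_ramp = c(0, 0)),
    seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Run the end-to-end accelerated-mapping experiment on synthetic data
#'
#' Reproduces the study design at desk scale: generates train/test synthetic
#' datasets, tunes the CS regularization coefficient beta per transform on
#' the training group, optionally trains the variational-network variants on
#' the same group, reconstructs the test group at each acceleration factor
#' with each method, fits relaxation maps over the ROIs, and tabulates
#' reconstruction (nRMSE) and mapping (MNAD) errors per method and AF.
#' Accelerated maps are scored against the maps fitted on the fully-sampled
#' reference reconstruction; image nRMSE is reported both against the ground
#' truth and against the reference. Fully reproducible from the
#' configuration seed.
#'
#' @param config An [experiment_config()].
#' @return List with `config`, tuned `beta` per transform, `vn` training
#'   results (if any), `per_slice` results and a `summary` table aggregated
#'   over test slices.
#' @export
run_experiment <- function(config = experiment_config()) {
  bad <- setdiff(config$methods, experiment_methods)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(experiment_methods, collapse = ", "))
  seed <- config$seed
  tune_af <- config$tune_af %||% config$af_list[ceiling(length(config$af_list) / 2)]
  nt <- length(config$tsl)

  gen_slice <- function(j, base_seed, af) {
    make_dataset(config$ny, config$nz, tsl = config$tsl, nc = config$nc,
                 af = af, noise_sd = if (j %% 2 == 0) 0 else NULL,
                 seed = base_seed + j, config = config$gt_config)
  }
  train <- lapply(seq_len(config$n_train), gen_slice, base_seed = seed * 100L,
                  af = tune_af)
  test <- lapply(seq_len(config$n_test), gen_slice, base_seed = seed * 100L + 50L,
                 af = tune_af)

  # estimated coil profiles (calibration-region autocalibration), per slice
  calib <- default_calib_extent(config$ny, config$nz)
  for (i in seq_along(train))
    train[[i]]$coils_est <- estimate_sensitivities(train[[i]]$kspace, calib)
  for (i in seq_along(test))
    test[[i]]$coils_est <- estimate_sensitivities(test[[i]]$kspace, calib)

  cs_methods <- intersect(config$methods, c("CS-S", "CS-ST"))
  betas <- list()
  for (m in cs_methods) {
    tf <- if (m == "CS-S") "SFD" else "STFD"
    pairs <- lapply(train, function(d)
      list(y = d$kspace, coils = d$coils_est, mask = d$mask, x_ref = d$truth))
    betas[[tf]] <- tune_beta(pairs, tf, max_iter = config$tune_max_iter)$beta
  }

  vn_methods <- intersect(config$methods, c("VN-S", "VN-ST"))
  vn_fits <- list()
  for (m in vn_methods) {
    variant <- if (m == "VN-S") "S" else "ST"
    vcfg <- vn_preset("desk", variant)
    vcfg$M <- config$vn_layers; vcfg$n_filters <- config$vn_filters
    vcfg$ksize <- config$vn_ksize; vcfg$epochs <- config$vn_epochs
    tset <- lapply(train, function(d)
      list(y = d$kspace, coils = d$coils_est, mask = d$mask, x_ref = d$truth))
    vn_fits[[m]] <- train_vn(tset, vcfg, seed = seed + 77L)
  }

  reconstruct <- function(d, method, af, mask) {
    switch(method,
      "ZF" = mri_adjoint(d$kspace, d$coils_est, mask),
      "CS-S" = cs_reconstruct(d$kspace, d$coils_est, mask,
                              cs_config("SFD", beta = betas[["SFD"]],
                                        max_iter = config$cs_max_iter))$x,
      "CS-ST" = cs_reconstruct(d$kspace, d$coils_est, mask,
                               cs_config("STFD", beta = betas[["STFD"]],
                                         max_iter = config$cs_max_iter))$x,
      "VN-S" = vn_forward(d$kspace, d$coils_est, mask, vn_fits[["VN-S"]]$params),
      "VN-ST" = vn_forward(d$kspace, d$coils_est, mask, vn_fits[["VN-ST"]]$params),
      stop("unhandled method ", method))
  }

  rows <- list()
  acc_methods <- setdiff(config$methods, "REF")
  for (i in seq_along(test)) {
    d <- test[[i]]
    ref <- mri_adjoint(d$kspace, d$coils_est)
    ref_maps <- fit_map(ref, d$maps$roi_labels,
                        fit_biexp_model = config$fit_biexp)
    if ("REF" %in% config$methods) {
      row <- data.frame(
        slice = i, af = 1, method = "REF",
        nrmse_gt = nrmse(ref, d$truth), nrmse_ref = 0, mnad_tau = 0)
      if (config$fit_biexp)
        for (p in c("f_s", "tau_s", "tau_l")) row[[paste0("mnad_", p)]] <- 0
      rows[[length(rows) + 1]] <- row
    }
    for (af in if (length(acc_methods)) config$af_list else numeric(0)) {
      mask <- poisson_disk_mask(config$ny, config$nz, nt, af,
                                seed = seed * 1000L + i * 37L + round(af))
      for (m in acc_methods) {
        rec <- reconstruct(d, m, af, mask)
        maps <- fit_map(rec, d$maps$roi_labels,
                        fit_biexp_model = config$fit_biexp)
        row <- data.frame(
          slice = i, af = af, method = m,
          nrmse_gt = nrmse(rec, d$truth),
          nrmse_ref = nrmse(rec, ref),
          mnad_tau = mnad(maps, ref_maps, "tau"))
        if (config$fit_biexp)
          for (p in c("f_s", "tau_s", "tau_l"))
            row[[paste0("mnad_", p)]] <-
              suppressWarnings(mnad(maps, ref_maps, p))
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  per_slice <- do.call(rbind, rows)
  agg_cols <- setdiff(names(per_slice), c("slice", "af", "method"))
  summary <- stats::aggregate(per_slice[agg_cols],
                              by = list(method = per_slice$method,
                                        af = per_slice$af),
                              FUN = mean, na.rm = TRUE)
  summary <- summary[order(summary$method, summary$af), ]
  list(config = config, beta = betas, vn = vn_fits,
       per_slice = per_slice, summary = summary)
}

bundle_version <- "1"

#' Save a results bundle to disk
#'
#' Writes a directory containing a JSON manifest (with a format version), a
#' serialized payload holding every component bit-exactly (including complex
#' arrays), and CSV copies of any top-level data frames. ROI label matrices
#' can additionally be exported as NIfTI with [write_labels_nifti()].
#'
#' @param bundle A list (for example a [run_experiment()] result).
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    saveRDS(bundle, file.path(path, "payload.rds"), version = 3)
    TRUE
  }, error = function(e) stop("failed writing bundle payload at ", path, ": ",
                              conditionMessage(e)))
  for (nm in names(bundle))
    if (is.data.frame(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
  manifest <- list(format = "t1rhomap-bundle", version = bundle_version,
                   components = names(bundle))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a results bundle
#'
#' @param path Directory written by [save_bundle()].
#' @return The bundle list.
#' @export
load_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("no bundle manifest found at ", path)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "t1rhomap-bundle"))
    stop("not a t1rhomap bundle: ", path)
  if (!identical(as.character(manifest$version), bundle_version))
    stop("bundle version ", manifest$version, " not supported (expected ",
         bundle_version, ")")
  pf <- file.path(path, "payload.rds")
  if (!file.exists(pf)) stop("bundle payload missing at ", path)
  readRDS(pf)
}

#' Export a label or parameter matrix as NIfTI
#'
#' @param m Numeric/integer matrix (e.g. ROI labels or a parameter map; NAs
#'   are written as 0).
#' @param path Output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(m, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  m[is.na(m)] <- 0
  arr <- array(as.numeric(m), c(dim(m), 1))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
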