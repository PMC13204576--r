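#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' One image volume and one mask volume per patient (slices stacked along
#' the third axis), written as uncompressed `.nii`, with a
#' `manifest.csv` listing `patient_id, image_path, mask_path, slice_count`.
#' Intensities are stored as float64, so [load_cohort()] round-trips the
#' cohort exactly.
#'
#' @param cohort a `slice_cohort` (or list of `slice_sample`s).
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pids <- vapply(cohort, function(s) s$patient_id, character(1))
  rows <- NULL
  for (pid in unique(pids)) {
    idx <- which(pids == pid)
    idx <- idx[order(vapply(cohort[idx], function(s) s$slice_index, numeric(1)))]
    img <- simplify2array(lapply(cohort[idx], `[[`, "image"))
    msk <- simplify2array(lapply(cohort[idx], function(s) s$mask * 1.0))
    ipath <- file.path(dir, paste0(pid, "_image.nii"))
    mpath <- file.path(dir, paste0(pid, "_mask.nii"))
    RNifti::writeNifti(img, ipath, datatype = "double")
    RNifti::writeNifti(msk, mpath, datatype = "double")
    rows <- rbind(rows, data.frame(patient_id = pid, image_path = basename(ipath),
                                   mask_path = basename(mpath),
                                   slice_count = length(idx),
                                   stringsAsFactors = FALSE))
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(rows, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load one NIfTI volume (and optional mask) as a list of slices
#'
#' Axial slices are extracted along `axis` (default the last/third axis) in
#' index order; intensities are passed through unmodified.
#'
#' @param path NIfTI image volume.
#' @param mask_path optional NIfTI mask volume of identical dimensions.
#' @param patient_id patient identifier; defaults to the filename stem.
#' @param axis slice axis (1-3).
#' @return list of `slice_sample`s (mask all-`NULL`-free: absent masks give
#'   `mask = NULL`).
#' @export
load_volume <- function(path, mask_path = NULL, patient_id = NULL, axis = 3L) {
  img <- as.array(RNifti::readNifti(path))
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  msk <- NULL
  if (!is.null(mask_path)) {
    msk <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(msk)) == 2) dim(msk) <- c(dim(msk), 1L)
    if (!all(dim(msk) == dim(img)))
      stop_input("volume/mask dimension mismatch: ",
                 paste(dim(img), collapse = "x"), " vs ",
                 paste(dim(msk), collapse = "x"))
  }
  n <- dim(img)[axis]
  take <- function(a, i) {
    m <- switch(axis, a[i, , ], a[, i, ], a[, , i])
    matrix(m, dim(a)[-axis][1], dim(a)[-axis][2])
  }
  lapply(seq_len(n), function(i) {
    structure(list(image = take(img, i),
                   mask = if (is.null(msk)) NULL else {
                     mm <- take(msk, i)
                     matrix(as.integer(mm != 0), nrow(mm), ncol(mm))
                   },
                   brain = NULL, patient_id = patient_id, slice_index = i,
                   role = "train"),
              class = "slice_sample")
  })
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @param require_masks error if any patient lacks a mask volume.
#' @return a `slice_cohort`.
#' @export
load_cohort <- function(dir, require_masks = TRUE) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop_input("no manifest.csv in ", dir)
  rows <- read.csv(manifest, stringsAsFactors = FALSE)
  cohort <- list()
  for (r in seq_len(nrow(rows))) {
    mp <- file.path(dir, rows$mask_path[r])
    if (!file.exists(mp)) {
      if (require_masks) stop_input("missing mask volume for patient ",
                                    rows$patient_id[r])
      mp <- NULL
    }
    cohort <- c(cohort, load_volume(file.path(dir, rows$image_path[r]),
                                    mask_path = mp,
                                    patient_id = rows$patient_id[r]))
  }
  structure(cohort, class = "slice_cohort")
}

#' Save a fitted model to a JSON checkpoint
#'
#' Parameters, running batch-norm statistics, both configuration blocks
#' and the loss history are stored with full numeric precision; the
#' checkpoint is self-describing and [load_model()] reproduces predictions
#' exactly.
#'
#' @param fit a [cheb_gcn()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  ser_bn <- function(bn) if (is.null(bn)) NULL else
    lapply(bn[c("gamma", "beta", "run_mean", "run_var")], as.numeric)
  payload <- list(
    package = "strokegraph",
    format = 1L,
    model_cfg = unclass(fit$model_cfg),
    train_cfg = unclass(fit$train_cfg),
    normalization = fit$normalization,
    loss_history = fit$loss_history,
    n_graphs = fit$n_graphs, n_nodes = fit$n_nodes,
    class_weights = fit$class_weights,
    params = lapply(fit$params, function(p) list(
      theta = lapply(p$theta, function(m) list(dim = dim(m), data = as.numeric(m))),
      bias = as.numeric(p$bias),
      bn1 = ser_bn(p$bn1), bn2 = ser_bn(p$bn2),
      order = p$order, din = p$din, dout = p$dout))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return a `cheb_gcn` object usable with [predict.cheb_gcn()].
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$package, "strokegraph")) stop_input("not a strokegraph checkpoint")
  num <- function(x) as.numeric(unlist(x))
  int <- function(x) as.integer(unlist(x))
  mc <- j$model_cfg
  model_cfg <- model_config(n_blocks = int(mc$n_blocks), dims = int(mc$dims),
                            cheb_orders = int(mc$cheb_orders),
                            leaky_relu_slope = num(mc$leaky_relu_slope),
                            dropout_rate = num(mc$dropout_rate),
                            double_batchnorm = isTRUE(unlist(mc$double_batchnorm)))
  tcj <- j$train_cfg
  train_cfg <- train_config(learning_rate = num(tcj$learning_rate),
                            rho = num(tcj$rho),
                            eps = num(tcj$eps), weight_decay = num(tcj$weight_decay),
                            epochs = int(tcj$epochs),
                            class_weights = isTRUE(unlist(tcj$class_weights)),
                            shuffle = isTRUE(unlist(tcj$shuffle)),
                            bn_momentum = num(tcj$bn_momentum),
                            seed = int(tcj$seed))
  des_bn <- function(bn) if (is.null(bn)) NULL else
    list(gamma = num(bn$gamma), beta = num(bn$beta),
         run_mean = num(bn$run_mean), run_var = num(bn$run_var))
  params <- lapply(j$params, function(pj) {
    theta <- lapply(pj$theta, function(t)
      matrix(num(t$data), int(t$dim)[1], int(t$dim)[2]))
    list(theta = theta, bias = num(pj$bias),
         bn1 = des_bn(pj$bn1), bn2 = des_bn(pj$bn2),
         order = int(pj$order), din = int(pj$din), dout = int(pj$dout))
  })
  structure(list(params = params, model_cfg = model_cfg, train_cfg = train_cfg,
                 normalization = unlist(j$normalization),
                 loss_history = num(j$loss_history),
                 n_graphs = int(j$n_graphs), n_nodes = int(j$n_nodes),
                 class_weights = num(j$class_weights), call = NULL),
            class = "cheb_gcn")
}
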