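#' Graph-construction configuration
#'
#' @param n_zones requested SLIC superpixel count (default 100).
#' @param compactness SLIC compactness.
#' @param sigma Gaussian edge bandwidth (`NULL` = scale-adaptive, see
#'   [build_region_graph()]).
#' @param label_threshold lesion-fraction threshold for node labels.
#' @param feature_mode node feature mode, see [region_features()]; the
#'   default `"mean16"` feeds the region mean intensity (replicated to the
#'   16-wide first layer); `"hist16"` selects the richer intensity
#'   histogram.
#' @param smooth_sigma SLIC pre-smoothing, see [slic_superpixels()].
#' @return object of class `graph_config`.
#' @export
graph_config <- function(n_zones = 100L, compactness = 0.1, sigma = NULL,
                         label_threshold = 0.5, feature_mode = "mean16",
                         smooth_sigma = 1) {
  structure(list(n_zones = as.integer(n_zones), compactness = compactness,
                 sigma = sigma, label_threshold = label_threshold,
                 feature_mode = feature_mode, smooth_sigma = smooth_sigma),
            class = "graph_config")
}

#' Turn a raw slice into a labelled region graph
#'
#' Runs the standard chain: Hounsfield clipping, normalization to `[0, 1]`,
#' size standardization, SLIC superpixels, region-adjacency graph with
#' Gaussian edge weights and mask-derived node labels.
#'
#' @param sample a `slice_sample`.
#' @param pre_cfg a [preprocess_config()].
#' @param graph_cfg a [graph_config()].
#' @return a `region_graph` carrying the sample's provenance.
#' @export
graphify_sample <- function(sample, pre_cfg = preprocess_config(),
                            graph_cfg = graph_config()) {
  img <- clip_hounsfield(sample$image, pre_cfg)
  img <- normalize_intensity(img, pre_cfg)
  std <- standardize_size(img, sample$mask, pre_cfg$target_size)
  spmap <- slic_superpixels(std$image, n_zones = graph_cfg$n_zones,
                            compactness = graph_cfg$compactness,
                            smooth_sigma = graph_cfg$smooth_sigma)
  build_region_graph(spmap, std$image, std$mask,
                     sigma = graph_cfg$sigma,
                     label_threshold = graph_cfg$label_threshold,
                     feature_mode = graph_cfg$feature_mode,
                     patient_id = sample$patient_id,
                     slice_index = sample$slice_index)
}

#' Patient-level k-fold assignment
#'
#' Randomly partitions patients (not slices) into `k` folds whose sizes
#' differ by at most one, so no patient's slices can appear on both sides
#' of any train/test split.
#'
#' @param patient_ids character vector (may contain repeats; the unique set
#'   is partitioned).
#' @param k number of folds.
#' @param seed integer seed; the assignment is deterministic given
#'   `(patient_ids, k, seed)`.
#' @return object of class `fold_assignment`: named integer vector mapping
#'   each patient id to a fold in `1..k`, with attribute `k`.
#' @export
patient_kfold <- function(patient_ids, k = 10L, seed = 1L) {
  ids <- sort(unique(as.character(patient_ids)))
  if (k > length(ids))
    stop_input("k (", k, ") exceeds the number of patients (", length(ids), ")")
  if (k < 2) stop_input("k must be >= 2")
  with_local_seed(seed, {
    perm <- sample(ids)
    folds <- rep(seq_len(k), length.out = length(ids))
    out <- folds[order(match(ids, perm))]
    names(out) <- ids
    structure(out, k = as.integer(k), class = "fold_assignment")
  })
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("fold_assignment:", length(x), "patients in", attr(x, "k"), "folds; sizes",
      paste(tabulate(x, attr(x, "k")), collapse = ", "), "\n")
  invisible(x)
}

#' Patient-level cross-validation of the full segmentation pipeline
#'
#' For each fold: training patients' slices are graphified (plus
#' `n_augment` rotated/flipped copies per training slice), a [cheb_gcn()]
#' is trained, and the held-out patients' slices are segmented and scored
#' at the pixel level. Augmented copies are deterministic per slice and
#' cached across folds; they are only ever used in folds where their
#' patient is in the training split.
#'
#' @param cohort a `slice_cohort` (or list of `slice_sample`s).
#' @param k folds (default 10).
#' @param model_cfg,train_cfg model and training configuration.
#' @param pre_cfg,graph_cfg preprocessing and graph configuration.
#' @param augment augment training slices.
#' @param n_augment augmented copies per training slice.
#' @param seed seed for fold assignment and augmentation draws.
#' @param aggregation metric aggregation, see [metrics_report()].
#' @param keep_predictions retain predicted masks (memory-heavy).
#' @param verbose progress messages.
#' @return object of class `strokegraph_cv`: `folds` (the
#'   [patient_kfold()] assignment), `models` (per-fold `cheb_gcn`s),
#'   `metrics` (one [metrics_report()] row per fold), `node_probs` /
#'   `node_labels` (pooled held-out node-level scores, for ROC),
#'   `per_slice` (per-slice DSC data frame), and optionally `predictions`.
#' @export
cross_validate <- function(cohort, k = 10L,
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           pre_cfg = preprocess_config(),
                           graph_cfg = graph_config(),
                           augment = TRUE, n_augment = 1L,
                           seed = train_cfg$seed,
                           aggregation = "global-pooled",
                           keep_predictions = FALSE,
                           verbose = FALSE) {
  pids <- vapply(cohort, function(s) s$patient_id, character(1))
  folds <- patient_kfold(pids, k = k, seed = seed)

  if (verbose) message("graphifying ", length(cohort), " slices ...")
  base_graphs <- lapply(cohort, graphify_sample, pre_cfg = pre_cfg,
                        graph_cfg = graph_cfg)
  aug_cache <- vector("list", length(cohort))

  metrics <- NULL
  models <- vector("list", k)
  node_probs <- numeric(0)
  node_labels <- integer(0)
  per_slice <- NULL
  predictions <- if (keep_predictions) vector("list", length(cohort)) else NULL

  for (f in seq_len(k)) {
    test_pat <- names(folds)[folds == f]
    is_test <- pids %in% test_pat
    train_idx <- which(!is_test)
    test_idx <- which(is_test)

    train_graphs <- base_graphs[train_idx]
    if (augment && n_augment > 0) {
      for (i in train_idx) {
        if (is.null(aug_cache[[i]])) {
          s <- cohort[[i]]
          s$role <- "train"
          aug_cache[[i]] <- lapply(seq_len(n_augment), function(a) {
            graphify_sample(augment_sample(s, pre_cfg,
                                           seed = derive_seed(seed, i, a)),
                            pre_cfg = pre_cfg, graph_cfg = graph_cfg)
          })
        }
        train_graphs <- c(train_graphs, aug_cache[[i]])
      }
    }
    if (verbose) message("fold ", f, ": training on ", length(train_graphs),
                         " graphs, testing on ", length(test_idx), " slices")
    tc <- train_cfg
    tc$seed <- derive_seed(seed, 1000L + f)
    fit <- cheb_gcn(train_graphs, model_cfg = model_cfg, train_cfg = tc)
    models[[f]] <- fit

    preds <- list(); truths <- list(); slice_rows <- NULL
    for (i in test_idx) {
      g <- base_graphs[[i]]
      probs <- predict(fit, g, type = "prob")
      cls <- as.integer(probs[, 2] >= 0.5)
      pm <- nodes_to_mask(g$spmap, cls)
      tm <- standardize_size(cohort[[i]]$image, cohort[[i]]$mask,
                             pre_cfg$target_size)$mask
      preds[[length(preds) + 1L]] <- pm
      truths[[length(truths) + 1L]] <- tm
      node_probs <- c(node_probs, probs[, 2])
      node_labels <- c(node_labels, g$labels)
      slice_rows <- rbind(slice_rows, data.frame(
        fold = f, patient_id = g$patient_id, slice_index = g$slice_index,
        dsc = dsc(pm, tm), stringsAsFactors = FALSE))
      if (keep_predictions) predictions[[i]] <- pm
    }
    metrics <- rbind(metrics,
                     metrics_report(preds, truths, aggregation = aggregation,
                                    fold_id = f))
    per_slice <- rbind(per_slice, slice_rows)
  }
  structure(list(folds = folds, models = models, metrics = metrics,
                 node_probs = node_probs, node_labels = node_labels,
                 per_slice = per_slice, predictions = predictions,
                 k = as.integer(k), seed = seed,
                 pre_cfg = pre_cfg, graph_cfg = graph_cfg),
            class = "strokegraph_cv")
}

#' @export
print.strokegraph_cv <- function(x, ...) {
  cat("strokegraph_cv:", x$k, "patient-level folds\n")
  m <- colMeans(x$metrics[, c("dsc", "jaccard", "sensitivity", "precision", "accuracy")])
  cat(sprintf("  mean fold metrics: DSC %.3f  Jaccard %.3f  Sens %.3f  Prec %.3f  Acc %.3f\n",
              m["dsc"], m["jaccard"], m["sensitivity"], m["precision"], m["accuracy"]))
  invisible(x)
}

#' Noise-robustness sweep over SNR levels
#'
#' Re-runs the full pipeline (noise injection on the raw HU image, then
#' clipping, normalization, SLIC, graph construction, prediction with the
#' fold model that held the slice out) for every SNR in `snr_grid`, and
#' reports pooled segmentation metrics per SNR. A clean (no-noise)
#' reference row is included with `snr_db = Inf`.
#'
#' @param cv a fitted [cross_validate()] result.
#' @param cohort the same cohort the CV was run on.
#' @param snr_grid SNR levels in dB (default `-4:5`).
#' @param seed seed for the noise draws.
#' @param include_clean include the clean reference row.
#' @param aggregation metric aggregation.
#' @return data frame of class `snr_sweep`: one row per SNR (plus clean),
#'   columns `snr_db`, the five metrics, `n_slices`.
#' @export
robustness_sweep <- function(cv, cohort, snr_grid = -4:5, seed = 1L,
                             include_clean = TRUE,
                             aggregation = "global-pooled") {
  if (length(snr_grid) == 0 && !include_clean) stop_input("empty SNR grid")
  pids <- vapply(cohort, function(s) s$patient_id, character(1))
  levels <- c(if (include_clean) Inf, snr_grid)
  out <- NULL
  for (snr in levels) {
    preds <- list(); truths <- list()
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      f <- cv$folds[[s$patient_id]]
      img <- if (is.finite(snr))
        add_awgn(s$image, snr, seed = derive_seed(seed, i, round(100 * snr)))
      else s$image
      noisy <- s; noisy$image <- img
      g <- graphify_sample(noisy, pre_cfg = cv$pre_cfg, graph_cfg = cv$graph_cfg)
      pm <- predict(cv$models[[f]], g, type = "mask")
      tm <- standardize_size(s$image, s$mask, cv$pre_cfg$target_size)$mask
      preds[[length(preds) + 1L]] <- pm
      truths[[length(truths) + 1L]] <- tm
    }
    rep <- metrics_report(preds, truths, aggregation = aggregation)
    rep$snr_db <- snr
    out <- rbind(out, rep)
  }
  out <- out[, c("snr_db", "dsc", "jaccard", "sensitivity", "precision",
                 "accuracy", "n_slices", "aggregation")]
  class(out) <- c("snr_sweep", "data.frame")
  out
}

#' @export
print.snr_sweep <- function(x, ...) {
  cat("SNR robustness sweep (", x$aggregation[1], " metrics, ",
      x$n_slices[1], " slices)\n", sep = "")
  df <- as.data.frame(x)
  df$snr_db <- ifelse(is.infinite(df$snr_db), "clean", format(df$snr_db))
  print(df[, c("snr_db", "dsc", "jaccard", "sensitivity", "precision", "accuracy")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
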