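#' Full pipeline configuration
#'
#' Bundles the preprocessing, graph, model, training and evaluation blocks
#' plus paths and the master seed into one serializable object. Defaults
#' reproduce the pipeline's chosen operating point: 100 SLIC zones,
#' 5 Chebyshev blocks of width 16, Adadelta + cross-entropy with weight
#' decay 6e-4 and dropout 0.3, 150 epochs, 10 patient-level folds, SNR
#' grid -4..5 dB.
#'
#' @param preprocess a [preprocess_config()].
#' @param graph a [graph_config()].
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param eval list with `k`, `snr_grid`, `aggregation`, `augment`,
#'   `n_augment`.
#' @param paths list with `data` (cohort directory) and `out` (artifact
#'   directory).
#' @param seed master seed for folds, augmentation and noise.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            graph = graph_config(),
                            model = model_config(),
                            train = train_config(),
                            eval = list(k = 10L, snr_grid = -4:5,
                                        aggregation = "global-pooled",
                                        augment = TRUE, n_augment = 1L,
                                        sweep = FALSE),
                            paths = list(data = "cohort", out = "artifacts"),
                            seed = 1L) {
  structure(list(preprocess = preprocess, graph = graph, model = model,
                 train = train, eval = eval, paths = paths,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  payload <- list(preprocess = unclass(cfg$preprocess),
                  graph = unclass(cfg$graph),
                  model = unclass(cfg$model),
                  train = unclass(cfg$train),
                  eval = cfg$eval, paths = cfg$paths, seed = cfg$seed)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' Values omitted from the file keep their defaults; the write/read pair
#' round-trips a configuration exactly.
#'
#' @param path `.yaml` path written by [write_pipeline_config()] (or by
#'   hand).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, ctor) {
    if (is.null(block)) return(ctor())
    # NULL-valued fields (e.g. sigma) are dropped by YAML; restore defaults
    args <- block[!vapply(block, is.null, logical(1))]
    do.call(ctor, args)
  }
  pre <- take(y$preprocess, function(hu_low = 0, hu_high = 150,
                                     target_size = c(256L, 256L), bit_depth = 8L,
                                     rotation_range = c(-20, 20), hflip = TRUE)
    preprocess_config(hu_low, hu_high, target_size, bit_depth, rotation_range, hflip))
  grf <- take(y$graph, function(n_zones = 100L, compactness = 0.1, sigma = NULL,
                                label_threshold = 0.5, feature_mode = "mean16",
                                smooth_sigma = 1)
    graph_config(n_zones, compactness, sigma, label_threshold, feature_mode,
                 smooth_sigma))
  mdl <- take(y$model, model_config)
  trn <- take(y$train, function(optimizer = "adadelta", loss = "cross_entropy",
                                learning_rate = 1.0, rho = 0.9, eps = 1e-6,
                                weight_decay = 6e-4, epochs = 150L,
                                class_weights = FALSE, shuffle = TRUE,
                                bn_momentum = 0.1, seed = 1L)
    train_config(optimizer, loss, learning_rate, rho, eps, weight_decay,
                 epochs, class_weights, shuffle, bn_momentum, seed))
  ev <- y$eval
  if (is.null(ev)) ev <- list()
  ev_def <- list(k = 10L, snr_grid = -4:5, aggregation = "global-pooled",
                 augment = TRUE, n_augment = 1L, sweep = FALSE)
  for (nm in names(ev_def)) if (is.null(ev[[nm]])) ev[[nm]] <- ev_def[[nm]]
  paths <- y$paths
  if (is.null(paths)) paths <- list(data = "cohort", out = "artifacts")
  pipeline_config(preprocess = pre, graph = grf, model = mdl, train = trn,
                  eval = ev, paths = paths,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}
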