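#' Gaussian edge weight
#'
#' The weight between two adjacent regions at spatial distance `d` is
#' `exp(-d^2 / (2 sigma^2))`: 1 at zero distance, strictly decreasing in
#' `d`, always in `(0, 1]`.
#'
#' @param d nonnegative distance(s) in pixels.
#' @param sigma Gaussian bandwidth, `> 0`.
#' @return weight(s) in `(0, 1]`.
#' @export
gaussian_edge_weight <- function(d, sigma) {
  if (any(sigma <= 0)) stop_input("sigma must be positive")
  if (any(d < 0)) stop_input("d must be nonnegative")
  exp(-d^2 / (2 * sigma^2))
}

#' Per-region node features
#'
#' The default `"mean16"` is the scalar region mean intensity replicated 16
#' times, so the mean-only signal can feed a 16-wide first layer; `"mean"`
#' gives the bare mean; `"hist16"` computes a 16-bin normalized intensity
#' histogram over `[0, 1]` per region (each row sums to 1) -- richer on
#' clean images, but brittle under additive noise.
#'
#' @param spmap a `superpixel_map`.
#' @param image numeric matrix in `[0, 1]`, same shape as `spmap$labels`.
#' @param mode feature mode.
#' @param n_bins histogram bins for `"hist16"`-style features.
#' @return `n_regions x F` feature matrix.
#' @export
region_features <- function(spmap, image, mode = c("mean16", "mean", "hist16"),
                            n_bins = 16L) {
  mode <- match.arg(mode)
  if (!all(dim(spmap$labels) == dim(image))) stop_input("spmap/image shape mismatch")
  n <- spmap$n_regions
  lab <- as.vector(spmap$labels)
  if (mode == "mean" || mode == "mean16") {
    m <- rowsum(as.vector(image), lab)[, 1] / spmap$region_size
    X <- if (mode == "mean") matrix(m, n, 1) else matrix(m, n, 16)
  } else {
    v <- pmin(pmax(as.vector(image), 0), 1)
    bin <- pmin(floor(v * n_bins) + 1L, n_bins)
    counts <- matrix(0, n, n_bins)
    tab <- tabulate((bin - 1L) * n + lab, nbins = n * n_bins)
    counts[] <- tab
    X <- counts / spmap$region_size
  }
  unname(X)
}

# unique 4-connected region adjacency pairs (i < j) from a label matrix
region_adjacency_pairs <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  a <- c(labels[-nr, ], labels[, -nc])
  b <- c(labels[-1, ], labels[, -1])
  keep <- a != b
  p <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  unique(p)
}

#' Build a region-adjacency graph from a superpixel map
#'
#' Nodes are superpixels; two nodes are linked iff their regions share a
#' pixel boundary (4-connectivity), with weight
#' `exp(-d^2/(2 sigma^2))` where `d` is the Euclidean distance between
#' region centroids. Non-neighbouring regions get weight 0 and the diagonal
#' is 0. If a lesion mask is supplied, node `i` is labelled 1 iff the
#' lesion-pixel fraction of region `i` is at least `label_threshold`.
#'
#' @param spmap a `superpixel_map` derived from `image`.
#' @param image normalized image in `[0, 1]`.
#' @param mask optional binary lesion mask, same shape.
#' @param sigma Gaussian bandwidth; default (`NULL`) is the mean
#'   centroid distance over adjacent region pairs, which keeps weights in a
#'   usable range across zone counts.
#' @param label_threshold lesion-fraction threshold for node labels.
#' @param feature_mode passed to [region_features()].
#' @param patient_id,slice_index provenance carried on the graph.
#' @return an object of class `region_graph` with fields `A` (N x N
#'   symmetric weight matrix), `X` (N x F features), `labels` (0/1 vector or
#'   `NULL`), `lesion_fraction` (per-region), `sigma`, `centroids`, `spmap`,
#'   `n`, `patient_id`, `slice_index`.
#' @export
build_region_graph <- function(spmap, image, mask = NULL, sigma = NULL,
                               label_threshold = 0.5,
                               feature_mode = "mean16",
                               patient_id = NA_character_,
                               slice_index = NA_integer_) {
  if (!inherits(spmap, "superpixel_map")) stop_input("spmap must be a superpixel_map")
  if (!all(dim(spmap$labels) == dim(image))) stop_input("spmap/image shape mismatch")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image))) stop_input("spmap/mask shape mismatch")
    check_binary_mask(mask)
  }
  n <- spmap$n_regions
  pairs <- region_adjacency_pairs(spmap$labels)
  d <- sqrt(rowSums((spmap$centroids[pairs[, 1], , drop = FALSE] -
                     spmap$centroids[pairs[, 2], , drop = FALSE])^2))
  if (is.null(sigma)) sigma <- if (length(d)) mean(d) else 1
  w <- gaussian_edge_weight(d, sigma)
  A <- matrix(0, n, n)
  A[pairs] <- w
  A[pairs[, 2:1, drop = FALSE]] <- w
  labels <- NULL; lfrac <- NULL
  if (!is.null(mask)) {
    lfrac <- node_lesion_fraction(spmap, mask)
    labels <- as.integer(lfrac >= label_threshold)
  }
  X <- region_features(spmap, image, mode = feature_mode)
  structure(list(A = A, X = X, labels = labels, lesion_fraction = lfrac,
                 sigma = sigma, centroids = spmap$centroids, spmap = spmap,
                 n = n, patient_id = patient_id, slice_index = slice_index),
            class = "region_graph")
}

# per-region lesion-pixel fraction
node_lesion_fraction <- function(spmap, mask) {
  rowsum(as.vector(mask), as.vector(spmap$labels))[, 1] / spmap$region_size
}

#' Node labels from a pixel mask
#'
#' @param spmap a `superpixel_map`.
#' @param mask binary mask, same shape as `spmap$labels`.
#' @param threshold lesion-fraction threshold (default majority, 0.5).
#' @return integer 0/1 vector of length `n_regions`. Raising the threshold
#'   never increases the number of lesion nodes.
#' @export
node_labels_from_mask <- function(spmap, mask, threshold = 0.5) {
  if (!all(dim(mask) == dim(spmap$labels))) stop_input("spmap/mask shape mismatch")
  check_binary_mask(mask)
  as.integer(node_lesion_fraction(spmap, mask) >= threshold)
}

#' Project node predictions back to a pixel mask
#'
#' Every pixel inherits the prediction of its region. Composed with
#' [node_labels_from_mask()], this is the identity on masks that are unions
#' of whole regions.
#'
#' @param spmap a `superpixel_map`.
#' @param node_predictions 0/1 vector of length `n_regions`.
#' @return binary integer matrix, same shape as `spmap$labels`.
#' @export
nodes_to_mask <- function(spmap, node_predictions) {
  if (length(node_predictions) != spmap$n_regions)
    stop_input("predictions length (", length(node_predictions),
               ") != number of regions (", spmap$n_regions, ")")
  if (!all(node_predictions %in% c(0, 1)))
    stop_input("node_predictions must be binary (0/1)")
  matrix(as.integer(node_predictions)[spmap$labels],
         nrow(spmap$labels), ncol(spmap$labels))
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", x$n, "nodes,", sum(x$A > 0) / 2, "edges, sigma =",
      signif(x$sigma, 4), "\n")
  if (!is.null(x$labels))
    cat("  lesion nodes:", sum(x$labels), "/", x$n, "\n")
  if (!is.na(x$patient_id))
    cat("  provenance:", x$patient_id, "slice", x$slice_index, "\n")
  invisible(x)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Serialize a region graph to plain text
#'
#' Writes two files: `<prefix>_nodes.csv` with columns
#' `node_id, f1..fF, label` (label −1 when absent) and `<prefix>_edges.txt`
#' with lines `i j weight` (1-based ids, `i < j`, one line per undirected
#' edge) preceded by a header line `n sigma patient_id slice_index`.
#' Numbers are written with 17 significant digits so that
#' [read_region_graph()] round-trips `A`, `X`, `labels` and `sigma`
#' bit-exactly. The pixel-level superpixel map is not serialized; a re-read
#' graph has `spmap = NULL` and cannot be projected back to masks.
#'
#' @param graph a `region_graph`.
#' @param prefix path prefix for the two files.
#' @return the two file paths, invisibly.
#' @export
write_region_graph <- function(graph, prefix) {
  nodes_f <- paste0(prefix, "_nodes.csv")
  edges_f <- paste0(prefix, "_edges.txt")
  X <- graph$X
  df <- data.frame(node_id = seq_len(graph$n))
  for (j in seq_len(ncol(X))) df[[paste0("f", j)]] <- fmt_full(X[, j])
  df$label <- if (is.null(graph$labels)) -1L else graph$labels
  write.csv(df, nodes_f, row.names = FALSE, quote = FALSE)
  up <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  con <- file(edges_f, "w")
  on.exit(close(con))
  writeLines(paste("#", graph$n, fmt_full(graph$sigma),
                   graph$patient_id, graph$slice_index), con)
  if (nrow(up))
    writeLines(paste(up[, 1], up[, 2], fmt_full(graph$A[up])), con)
  invisible(c(nodes = nodes_f, edges = edges_f))
}

#' Read a region graph written by [write_region_graph()]
#'
#' @param prefix path prefix used when writing.
#' @return a `region_graph` (with `spmap = NULL` and `centroids = NULL`).
#' @export
read_region_graph <- function(prefix) {
  nodes_f <- paste0(prefix, "_nodes.csv")
  edges_f <- paste0(prefix, "_edges.txt")
  df <- read.csv(nodes_f, colClasses = "character")
  n <- nrow(df)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  X <- matrix(as.numeric(as.matrix(df[, fcols, drop = FALSE])), n, length(fcols))
  labels <- as.integer(df$label)
  if (all(labels == -1L)) labels <- NULL
  lines <- readLines(edges_f)
  hdr <- strsplit(sub("^# ", "", lines[1]), "\\s+")[[1]]
  A <- matrix(0, n, n)
  if (length(lines) > 1) {
    e <- do.call(rbind, strsplit(trimws(lines[-1]), "\\s+"))
    i <- as.integer(e[, 1]); j <- as.integer(e[, 2]); w <- as.numeric(e[, 3])
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  structure(list(A = A, X = X, labels = labels, lesion_fraction = NULL,
                 sigma = as.numeric(hdr[2]), centroids = NULL, spmap = NULL,
                 n = n, patient_id = hdr[3],
                 slice_index = as.integer(hdr[4])),
            class = "region_graph")
}
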