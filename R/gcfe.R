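# Gershgorin circle feature extraction. Every eigenvalue of a square matrix
# lies in at least one disk centered at a diagonal entry with radius equal
# to that row's absolute off-diagonal sum; the radii and centers of the
# modified weighted Laplacian summarise an epoch's spectrum in O(N^2)
# without an eigendecomposition.

#' Gershgorin disk radii of a square matrix
#'
#' `r_i = sum_{j != i} |L_ij|`, the absolute off-diagonal row sums.
#'
#' @param L Square numeric matrix.
#' @return Non-negative numeric vector of length `nrow(L)`.
#' @export
gershgorin_radii <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("'L' must be square", call. = FALSE)
  rowSums(abs(L)) - abs(diag(L))
}

#' Gershgorin disk centers of a square matrix
#'
#' `c_i = L_ii`, the diagonal. For the modified weighted Laplacian these
#' are the integer node degrees of the visibility graph.
#'
#' @param L Square numeric matrix.
#' @return Numeric vector of length `nrow(L)`.
#' @export
gershgorin_centers <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("'L' must be square", call. = FALSE)
  diag(L)
}

#' Concatenate radii and centers into the 2N feature vector
#'
#' Ordering is fixed: all radii in node order, then all centers in node
#' order.
#'
#' @param r Radius vector.
#' @param c_ Center vector of the same length.
#' @return Numeric vector of length `2 * length(r)`.
#' @export
assemble_feature_vector <- function(r, c_) {
  if (length(r) != length(c_)) {
    stop("radii and centers must have equal length", call. = FALSE)
  }
  c(r, c_)
}

#' Extract Gershgorin circle features from one epoch
#'
#' Runs the full per-epoch pipeline: visibility graph (WVG or WDPVG) ->
#' modified weighted Laplacian -> disk radii and centers. The result is
#' deterministic; identical epochs give bit-identical features.
#'
#' @param q Numeric vector of epoch samples (typically normalized to
#'   `[0, 1]`).
#' @param graph `"wvg"` or `"wdpvg"`.
#' @param reflection Reflection operator for the dual-perspective graph;
#'   see [reflect_epoch()].
#' @return A `gcfe_features` object: list with `radii`, `centers`,
#'   `vector` (length `2N`, radii then centers), `n`, and `graph`.
#' @examples
#' f <- extract_features(c(0.6, 0.4, 0.1, 0.5, 0.7))
#' round(f$radii, 3)  # 0.258 0.650 0.700 0.683 0.325
#' f$centers          # 3 4 2 4 3
#' @export
extract_features <- function(q, graph = c("wvg", "wdpvg"),
                             reflection = c("midline", "negate")) {
  graph <- match.arg(graph)
  g <- switch(graph,
              wvg = build_wvg(q),
              wdpvg = build_wdpvg(q, match.arg(reflection)))
  L <- graph_matrices(g)$L
  r <- gershgorin_radii(L)
  ce <- gershgorin_centers(L)
  structure(list(radii = r, centers = ce,
                 vector = assemble_feature_vector(r, ce),
                 n = g$n_nodes, graph = graph),
            class = "gcfe_features")
}

#' @export
print.gcfe_features <- function(x, digits = 3, ...) {
  cat(sprintf("<gcfe_features> %s, N = %d (%d features)\n",
              x$graph, x$n, 2L * x$n))
  cat("  radii:  ", paste(round(x$radii, digits), collapse = " "), "\n")
  cat("  centers:", paste(round(x$centers, digits), collapse = " "), "\n")
  invisible(x)
}

#' Plot Gershgorin disks of an epoch
#'
#' Draws the inclusion disks in the complex plane (all centers are real for
#' the symmetric Laplacian); every eigenvalue lies inside the union.
#'
#' @param x A `gcfe_features` object.
#' @param ... Passed to `plot`.
#' @return `x`, invisibly.
#' @importFrom graphics lines points
#' @export
plot.gcfe_features <- function(x, ...) {
  xs <- range(x$centers - x$radii, x$centers + x$radii)
  ys <- max(x$radii)
  plot(NA, xlim = xs, ylim = c(-ys, ys), asp = 1,
       xlab = "Re", ylab = "Im",
       main = sprintf("Gershgorin disks (%s, N = %d)", x$graph, x$n), ...)
  th <- seq(0, 2 * pi, length.out = 120)
  for (i in seq_len(x$n)) {
    lines(x$centers[i] + x$radii[i] * cos(th), x$radii[i] * sin(th),
          col = grDevices::adjustcolor("steelblue", 0.7))
  }
  points(x$centers, rep(0, x$n), pch = 19, cex = 0.6)
  invisible(x)
}

#' Extract features for every epoch in a set
#'
#' @param epochs An `epoch_set` (see [segment_epochs()]) or numeric matrix
#'   with one epoch per row; all epochs share the same length `N`.
#' @param graph `"wvg"` or `"wdpvg"`.
#' @param reflection See [reflect_epoch()].
#' @param N Declared epoch length, only consulted when `epochs` has zero
#'   rows (to size the empty result).
#' @return A data frame with columns `r1..rN`, `c1..cN` and, when the
#'   epoch set carries labels, a final integer `label` column. Row `k` is
#'   `extract_features(epochs[k, ])$vector`.
#' @examples
#' es <- segment_epochs(runif(168), 56)
#' dim(extract_features_batch(es))  # 3 x 112
#' @export
extract_features_batch <- function(epochs, graph = c("wvg", "wdpvg"),
                                   reflection = c("midline", "negate"),
                                   N = NULL) {
  graph <- match.arg(graph)
  reflection <- match.arg(reflection)
  m <- if (inherits(epochs, "epoch_set")) unclass(epochs) else as.matrix(epochs)
  if (nrow(m) == 0L) {
    if (is.null(N)) stop("empty epoch collection with no declared N",
                         call. = FALSE)
    nm <- c(paste0("r", seq_len(N)), paste0("c", seq_len(N)))
    out <- as.data.frame(matrix(numeric(0), 0L, 2L * N,
                                dimnames = list(NULL, nm)))
    return(out)
  }
  N <- ncol(m)
  feats <- t(vapply(seq_len(nrow(m)), function(k) {
    extract_features(m[k, ], graph = graph, reflection = reflection)$vector
  }, numeric(2L * N)))
  out <- as.data.frame(feats)
  names(out) <- c(paste0("r", seq_len(N)), paste0("c", seq_len(N)))
  lab <- attr(epochs, "label")
  if (!is.null(lab)) out$label <- as.integer(lab)
  out
}

#' Write a feature table as CSV
#'
#' @param features Data frame from [extract_features_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
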