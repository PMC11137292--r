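# Natural-visibility criterion and weighted graph construction.
#
# Two samples (x, q[x]) and (y, q[y]) are mutually visible when the straight
# line joining them passes strictly above every intermediate sample. The
# equivalent slope form used by the fast builder: y is visible from x iff
# slope(x, y) exceeds the running maximum of slope(x, z) over x < z < y.
# A collinear intermediate point blocks visibility (strict inequality).

WEIGHT_EPS <- 1e-8

#' Test visibility between two samples of an epoch
#'
#' Returns `TRUE` when every intermediate sample lies strictly below the
#' line through `(x, q[x])` and `(y, q[y])`; adjacent samples are always
#' visible. Collinear intermediate points block visibility.
#'
#' @param q Numeric vector of epoch samples.
#' @param x,y 1-based node indices with `x < y`.
#' @return Logical scalar.
#' @examples
#' is_visible(c(0.6, 0.4, 0.1, 0.5, 0.7), 3, 5)  # FALSE: node 4 blocks
#' @export
is_visible <- function(q, x, y) {
  n <- length(q)
  x <- as.integer(x); y <- as.integer(y)
  if (is.na(x) || is.na(y) || x < 1L || y > n || x >= y) {
    stop("need node indices 1 <= x < y <= length(q)", call. = FALSE)
  }
  if (y == x + 1L) return(TRUE)
  z <- (x + 1L):(y - 1L)
  all(q[z] < q[y] + (q[x] - q[y]) * (y - z) / (y - x))
}

#' Weight of a visibility edge
#'
#' The absolute slope between the two samples, with time measured in
#' sample-index units, plus a floor of `1e-8` so equal-valued samples still
#' carry a positive weight: `|q[i] - q[j]| / |i - j| + 1e-8`.
#'
#' @param q Numeric vector of epoch samples.
#' @param i,j Distinct 1-based node indices.
#' @return Positive edge weight.
#' @export
edge_weight <- function(q, i, j) {
  n <- length(q)
  if (i == j) stop("edge weight undefined for i == j", call. = FALSE)
  if (i < 1L || j < 1L || i > n || j > n) {
    stop("node index out of range", call. = FALSE)
  }
  abs(q[i] - q[j]) / abs(i - j) + WEIGHT_EPS
}

# Fast O(N^2) edge enumeration: for each left endpoint i, node j > i is
# visible iff slope(i, j) strictly exceeds every slope(i, z), x < z < j.
# Returns a 3-column matrix (i, j, w) with i < j.
visibility_edges <- function(q) {
  n <- length(q)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    slopes <- (q[js] - q[i]) / (js - i)
    m <- length(js)
    vis <- logical(m)
    vis[1L] <- TRUE                       # adjacent pair, vacuous
    if (m > 1L) {
      run <- cummax(slopes[-m])           # max over z <= j-1
      vis[-1L] <- slopes[-1L] > run
    }
    jv <- js[vis]
    out[[i]] <- cbind(i = rep.int(i, length(jv)), j = jv,
                      w = abs(q[jv] - q[i]) / (jv - i) + WEIGHT_EPS)
  }
  do.call(rbind, out)
}

new_visibility_graph <- function(n, edges, kind) {
  structure(list(n_nodes = as.integer(n),
                 edges = data.frame(i = as.integer(edges[, 1L]),
                                    j = as.integer(edges[, 2L]),
                                    w = as.numeric(edges[, 3L])),
                 kind = kind),
            class = "visibility_graph")
}

#' Build the weighted visibility graph (WVG) of an epoch
#'
#' Nodes are the samples in time order; an undirected edge joins every
#' mutually visible pair, weighted by [edge_weight()]. All `N - 1` adjacent
#' pairs are present, so the graph is connected.
#'
#' @param q Numeric vector of epoch samples (length >= 2), typically
#'   normalized to `[0, 1]`.
#' @return A `visibility_graph`: list with `n_nodes`, `edges` (data frame
#'   `i`, `j`, `w` with `i < j`) and `kind = "wvg"`.
#' @examples
#' g <- build_wvg(c(0.6, 0.4, 0.1, 0.5, 0.7))
#' g$edges
#' @export
build_wvg <- function(q) {
  q <- as_samples(q)
  if (length(q) < 2L) stop("epoch needs at least 2 samples", call. = FALSE)
  new_visibility_graph(length(q), visibility_edges(q), "wvg")
}

#' Reflect an epoch about its amplitude midline
#'
#' Returns `max(q) + min(q) - q`, mirroring the signal about the midpoint
#' of its own range so the result stays inside `[min(q), max(q)]`; the map
#' is an involution and a constant epoch is a fixed point. `method =
#' "negate"` gives plain sign inversion instead; both are affine, so the
#' visibility structure of the reflected signal is identical either way.
#'
#' @param q Numeric vector of epoch samples.
#' @param method `"midline"` (default) or `"negate"`.
#' @return Reflected numeric vector of the same length.
#' @export
reflect_epoch <- function(q, method = c("midline", "negate")) {
  method <- match.arg(method)
  q <- as_samples(q)
  switch(method,
         midline = max(q) + min(q) - q,
         negate = -q)
}

#' Build the weighted dual-perspective visibility graph (WDPVG)
#'
#' The edge-set union of the WVG of `q` and the WVG of the reflected
#' signal, capturing visibility from above and below the curve. An edge
#' present in both graphs appears once: the weight depends only on
#' `|q[i] - q[j]|`, which reflection preserves, so both copies agree.
#'
#' @inheritParams build_wvg
#' @param reflection Reflection operator passed to [reflect_epoch()].
#' @return A `visibility_graph` with `kind = "wdpvg"`.
#' @export
build_wdpvg <- function(q, reflection = c("midline", "negate")) {
  reflection <- match.arg(reflection)
  q <- as_samples(q)
  if (length(q) < 2L) stop("epoch needs at least 2 samples", call. = FALSE)
  e1 <- visibility_edges(q)
  e2 <- visibility_edges(reflect_epoch(q, reflection))
  both <- rbind(e1, e2)
  key <- both[, 1L] * (length(q) + 1L) + both[, 2L]
  uniq <- both[!duplicated(key), , drop = FALSE]
  uniq <- uniq[order(uniq[, 1L], uniq[, 2L]), , drop = FALSE]
  new_visibility_graph(length(q), uniq, "wdpvg")
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat(sprintf("<visibility_graph:%s> %d nodes, %d edges\n",
              x$kind, x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Write a visibility graph as a weighted edge list
#'
#' Three-column delimited text (`i`, `j`, `w`), full precision, suitable
#' for standard graph tooling.
#'
#' @param g A `visibility_graph`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, sep = "\t") {
  df <- g$edges
  df$w <- sprintf("%.17g", df$w)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
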