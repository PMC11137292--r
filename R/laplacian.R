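# Matrix representations of a visibility graph. The Laplacian used here is
# deliberately a hybrid: D holds UNWEIGHTED node degrees while A is the
# WEIGHTED adjacency. For epochs normalized to [0,1] every edge weight is at
# most 1 + 1e-8, so each diagonal entry (an integer degree) dominates its
# absolute off-diagonal row sum up to the epsilon inflation, making the
# matrix (near-)strictly diagonally dominant with non-negative diagonal.

#' Weighted adjacency matrix of a visibility graph
#'
#' @param g A `visibility_graph`.
#' @return Symmetric `N x N` matrix with edge weights off the diagonal and
#'   zeros elsewhere.
#' @export
weighted_adjacency <- function(g) {
  stopifnot(inherits(g, "visibility_graph"))
  n <- g$n_nodes
  A <- matrix(0, n, n)
  A[cbind(g$edges$i, g$edges$j)] <- g$edges$w
  A[cbind(g$edges$j, g$edges$i)] <- g$edges$w
  A
}

#' Unweighted (binary) adjacency matrix of a visibility graph
#'
#' @param g A `visibility_graph`.
#' @return Symmetric 0/1 `N x N` matrix with zero diagonal.
#' @export
unweighted_adjacency <- function(g) {
  stopifnot(inherits(g, "visibility_graph"))
  n <- g$n_nodes
  S <- matrix(0, n, n)
  S[cbind(g$edges$i, g$edges$j)] <- 1
  S[cbind(g$edges$j, g$edges$i)] <- 1
  S
}

#' Degree matrix from a binary adjacency matrix
#'
#' @param S Square 0/1 symmetric matrix with zero diagonal.
#' @return Diagonal matrix of row sums (node degrees).
#' @export
degree_matrix <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("'S' must be square", call. = FALSE)
  diag(rowSums(S), nrow = nrow(S))
}

#' Modified weighted Laplacian
#'
#' `L = D - A` with `D` the unweighted-degree diagonal and `A` the weighted
#' adjacency. Note this is not the standard weighted Laplacian (whose
#' diagonal would carry weighted degrees): mixing integer degrees with
#' fractional weights is what guarantees diagonal dominance for normalized
#' epochs and separates the Gershgorin centers (integers) from the radii.
#'
#' @param D Diagonal degree matrix.
#' @param A Weighted adjacency matrix of the same dimension.
#' @return Symmetric `N x N` Laplacian.
#' @export
mwl_matrix <- function(D, A) {
  D <- as.matrix(D); A <- as.matrix(A)
  if (!all(dim(D) == dim(A)) || nrow(D) != ncol(D)) {
    stop("'D' and 'A' must be square matrices of equal dimension",
         call. = FALSE)
  }
  D - A
}

#' All four matrix representations of a visibility graph
#'
#' Convenience constructor returning the weighted adjacency `A`, binary
#' adjacency `S`, degree matrix `D`, and modified weighted Laplacian `L`
#' in one pass.
#'
#' @param g A `visibility_graph`.
#' @return A list with components `A`, `S`, `D`, `L`.
#' @examples
#' gm <- graph_matrices(build_wvg(c(0.6, 0.4, 0.1, 0.5, 0.7)))
#' diag(gm$L)  # unweighted degrees 3 4 2 4 3
#' @export
graph_matrices <- function(g) {
  A <- weighted_adjacency(g)
  S <- unweighted_adjacency(g)
  D <- degree_matrix(S)
  list(A = A, S = S, D = D, L = mwl_matrix(D, A))
}

#' Write a matrix as delimited text at full precision
#'
#' Values are serialised with 17 significant digits so that
#' [read_matrix_txt()] round-trips them bit-exactly.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(m, path, sep = "\t") {
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Read a matrix written by [write_matrix_txt()]
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return Numeric matrix.
#' @export
read_matrix_txt <- function(path, sep = "\t") {
  rows <- strsplit(readLines(path), sep, fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}
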