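# Independent O(N^3) visibility oracle: evaluates the line-of-sight
# inequality directly for every pair and every intermediate sample. Kept
# deliberately naive so it shares no code path with the package's
# running-maximum slope builder.
oracle_edges <- function(q) {
  n <- length(q)
  rows <- list()
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      ok <- TRUE
      if (y > x + 1L) {
        for (z in (x + 1L):(y - 1L)) {
          line_at_z <- q[y] + (q[x] - q[y]) * (y - z) / (y - x)
          if (!(q[z] < line_at_z)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) rows[[length(rows) + 1L]] <- c(x, y)
    }
  }
  do.call(rbind, rows)
}

# Canonical string key for an (i, j) edge set, for order-free comparison.
edge_set_key <- function(e) {
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  paste(e[, 1L], e[, 2L], sep = "-", collapse = ";")
}

graph_edge_key <- function(g) {
  edge_set_key(as.matrix(g$edges[, c("i", "j")]))
}

# Worked five-sample series used throughout: the epoch whose printed
# radii/centers anchor the golden tests.
worked_q <- c(0.6, 0.4, 0.1, 0.5, 0.7)
worked_radii <- c(0.258, 0.650, 0.700, 0.683, 0.325)
worked_centers <- c(3, 4, 2, 4, 3)
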