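test_that("pairwise visibility matches the line-of-sight rule", {
  q <- worked_q
  expect_false(is_visible(q, 3, 5))   # node 4 rises above the 3-5 line
  expect_true(is_visible(q, 1, 4))
  expect_true(is_visible(q, 1, 5))
  expect_false(is_visible(q, 1, 3))   # node 2 blocks
  # an interior sample at exactly the line's height blocks (strict rule)
  expect_false(is_visible(c(0, 1, 0), 1, 3))
  expect_false(is_visible(c(0, 0.5, 1), 1, 3))  # collinear blocks too
  expect_error(is_visible(q, 4, 2), "x < y")
  expect_error(is_visible(q, 0, 3), "x < y")
})

test_that("edge weights are absolute slopes plus the 1e-8 floor", {
  q <- worked_q
  expect_equal(edge_weight(q, 1, 4), 0.1 / 3 + 1e-8)
  expect_equal(edge_weight(q, 2, 3), 0.3 + 1e-8)
  expect_identical(edge_weight(c(0.4, 0.4), 1, 2), 1e-8)
  expect_equal(edge_weight(q, 4, 1), edge_weight(q, 1, 4))  # symmetric
  expect_error(edge_weight(q, 2, 2), "i == j")
})

test_that("the worked five-sample WVG has the printed edge set", {
  g <- build_wvg(worked_q)
  expect_s3_class(g, "visibility_graph")
  want <- rbind(c(1, 2), c(1, 4), c(1, 5), c(2, 3),
                c(2, 4), c(2, 5), c(3, 4), c(4, 5))
  expect_equal(graph_edge_key(g), edge_set_key(want))
  # weights agree with direct evaluation
  for (k in seq_len(nrow(g$edges))) {
    expect_equal(g$edges$w[k],
                 edge_weight(worked_q, g$edges$i[k], g$edges$j[k]))
  }
})

test_that("degenerate epochs produce the expected chains", {
  g <- build_wvg(c(0, 1, 0))
  expect_equal(graph_edge_key(g), edge_set_key(rbind(c(1, 2), c(2, 3))))
  g2 <- build_wvg(c(0.3, 0.8))
  expect_equal(nrow(g2$edges), 1L)
  expect_error(build_wvg(0.5), "at least 2")
  # constant epoch: visibility chain with all weights at the floor
  gc_ <- build_wvg(rep(0, 6))
  expect_equal(nrow(gc_$edges), 5L)
  expect_true(all(gc_$edges$w == 1e-8))
})

test_that("reflection is a midline involution and negate is offered", {
  expect_equal(reflect_epoch(c(0, 1, 0)), c(1, 0, 1))
  expect_equal(reflect_epoch(rep(0.4, 5)), rep(0.4, 5))
  set.seed(2)
  q <- runif(40)
  expect_equal(reflect_epoch(reflect_epoch(q)), q)
  expect_true(all(reflect_epoch(q) >= min(q) & reflect_epoch(q) <= max(q)))
  expect_equal(reflect_epoch(q, method = "negate"), -q)
})

test_that("the dual-perspective graph is the union of both orientations", {
  g <- build_wdpvg(c(0, 1, 0))
  expect_equal(graph_edge_key(g),
               edge_set_key(rbind(c(1, 2), c(1, 3), c(2, 3))))
  set.seed(3)
  for (rep in 1:10) {
    q <- runif(sample(5:20, 1))
    wd <- build_wdpvg(q)
    e1 <- oracle_edges(q)
    e2 <- oracle_edges(reflect_epoch(q))
    union_ <- unique(rbind(e1, e2))
    expect_equal(graph_edge_key(wd), edge_set_key(union_))
    # superset of the plain WVG, duplicates kept once with the slope weight
    expect_true(all(
      paste(e1[, 1], e1[, 2]) %in% paste(wd$edges$i, wd$edges$j)))
    expect_true(!anyDuplicated(paste(wd$edges$i, wd$edges$j)))
  }
})

test_that("dual-perspective graphs are reflection invariant", {
  set.seed(4)
  for (rep in 1:10) {
    q <- runif(sample(5:24, 1))
    a <- build_wdpvg(q)
    b <- build_wdpvg(reflect_epoch(q))
    expect_equal(graph_edge_key(a), graph_edge_key(b))
    expect_equal(a$edges$w, b$edges$w, tolerance = 1e-12)
  }
})

test_that("time reversal relabels nodes i -> N+1-i with equal weights", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:24, 1)
    q <- runif(n)
    g1 <- build_wvg(q)
    g2 <- build_wvg(rev(q))
    remap <- cbind(pmin(n + 1 - g2$edges$i, n + 1 - g2$edges$j),
                   pmax(n + 1 - g2$edges$i, n + 1 - g2$edges$j))
    expect_equal(graph_edge_key(g1), edge_set_key(remap))
    o <- order(remap[, 1], remap[, 2])
    expect_equal(g1$edges$w, g2$edges$w[o], tolerance = 1e-12)
  }
})

test_that("visibility is invariant under positive affine maps of q", {
  set.seed(6)
  for (rep in 1:10) {
    q <- runif(sample(5:24, 1))
    a <- runif(1, 0.2, 5)
    b <- rnorm(1)
    g1 <- build_wvg(q)
    g2 <- build_wvg(a * q + b)
    expect_equal(graph_edge_key(g1), graph_edge_key(g2))
    # weights scale by a (modulo the additive epsilon)
    expect_equal(g2$edges$w - 1e-8, a * (g1$edges$w - 1e-8),
                 tolerance = 1e-9)
  }
})

test_that("visibility graphs are connected with interior degree >= 2", {
  set.seed(8)
  for (rep in 1:10) {
    q <- runif(sample(4:32, 1))
    S <- unweighted_adjacency(build_wvg(q))
    deg <- rowSums(S)
    expect_true(all(deg >= 1))
    expect_true(all(deg[c(-1, -length(q))] >= 2))
    # adjacent pairs always present => path exists => connected
    expect_true(all(S[cbind(seq_len(length(q) - 1), seq_len(length(q) - 1) + 1)] == 1))
  }
})

test_that("edge lists export as three-column delimited text", {
  g <- build_wvg(worked_q)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("i", "j", "w"))
  expect_equal(back$w, g$edges$w, tolerance = 1e-15)
})
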