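test_that("a straight cylinder skeletonizes to one chain", {
  d <- c(21L, 21L, 40L)
  seg <- binary_mask(cylinder_mask(d, 3))
  sg <- skeletonize(seg)
  expect_equal(igraph::vcount(sg$graph), 2)
  expect_equal(igraph::ecount(sg$graph), 1)
  # thinning erodes the end caps by about one radius at each end
  len <- igraph::E(sg$graph)$length[1]
  expect_gte(len, 40 - 2 * (3 + 1))
  expect_lte(len, 40)
  # node radii reflect the tube radius
  expect_true(all(abs(igraph::V(sg$graph)$radius - 3) <= 1.2))
})

test_that("a Y tube yields one bifurcation and three endpoints", {
  seg <- binary_mask(y_tube_mask())
  sg <- skeletonize(seg)
  deg <- igraph::degree(sg$graph)
  expect_equal(sum(deg >= 3), 1)
  expect_equal(sum(deg == 1), 3)
  expect_equal(igraph::ecount(sg$graph), 3)
})

test_that("degenerate masks are handled", {
  sv <- array(FALSE, c(5L, 5L, 5L)); sv[3, 3, 3] <- TRUE
  sg <- skeletonize(binary_mask(sv))
  expect_equal(igraph::vcount(sg$graph), 1)
  expect_equal(igraph::ecount(sg$graph), 0)
  expect_error(skeletonize(binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("the root is the top endpoint unless a hint overrides it", {
  d <- c(15L, 15L, 30L)
  seg <- binary_mask(cylinder_mask(d, 2))
  sg <- skeletonize(seg)
  root <- find_root(seg, sg)
  expect_equal(igraph::V(sg$graph)$z[root],
               max(igraph::V(sg$graph)$z))
  hinted <- find_root(seg, sg, hint = c(1, 1, 1))
  expect_equal(igraph::V(sg$graph)$z[hinted],
               min(igraph::V(sg$graph)$z))
})

test_that("DFS orientation turns paths and trees into rooted DAGs", {
  sg <- graph_fixture(rbind(c(1, 2), c(2, 3)))
  ag <- direct_graph(sg, 1)
  expect_true(igraph::is_dag(ag$graph))
  expect_equal(ag$n_leaf, 1)
  expect_equal(unname(ag$path_counts), 1)
  # balanced binary tree of 7 nodes: 4 leaves, one path each
  tree7 <- graph_fixture(rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5),
                               c(3, 6), c(3, 7)))
  ag7 <- direct_graph(tree7, 1)
  expect_equal(ag7$n_leaf, 4)
  expect_true(all(ag7$path_counts == 1))
  expect_equal(complexity(ag7), 0)
  expect_error(direct_graph(tree7, 99), "root")
})

test_that("path counts match brute-force enumeration on small graphs", {
  count_paths_brute <- function(dg, root, leaf) {
    length(igraph::all_simple_paths(dg$graph, from = root, to = leaf,
                                    mode = "out"))
  }
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    tr <- igraph::sample_tree(n, directed = FALSE)
    extra <- sample(0:3, 1)
    g <- tr
    for (e in seq_len(extra)) {
      uv <- sample(n, 2)
      # simple paths do not distinguish parallel edges; keep the graph simple
      if (igraph::get_edge_ids(g, uv) == 0) g <- igraph::add_edges(g, uv)
    }
    sg <- as_skeleton_graph(g)
    ag <- direct_graph(sg, 1)
    for (i in seq_along(ag$leaves)) {
      brute <- count_paths_brute(ag, ag$root, ag$leaves[i])
      expect_equal(unname(ag$path_counts[i]), brute)
    }
  }
})

test_that("hand-computed complexities are reproduced", {
  # 4-cycle rooted anywhere: one leaf reachable by two routes, 1 - 1/2,
  # whatever the DFS order
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 1), directed = FALSE)
  ag <- direct_graph(as_skeleton_graph(g), 1)
  expect_equal(ag$n_leaf, 1)
  expect_equal(unname(ag$path_counts), 2)
  expect_equal(complexity(ag), 0.5)
  # triple edge to one node plus a plain leaf: path counts (3, 1), 1 - 2/4
  g2 <- igraph::make_graph(c(1, 2, 1, 2, 1, 2, 1, 3), directed = FALSE)
  ag2 <- direct_graph(as_skeleton_graph(g2), 1)
  expect_equal(sort(unname(ag2$path_counts)), c(1, 3))
  expect_equal(complexity(ag2), 0.5)
  # isolated root
  g3 <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(complexity(direct_graph(as_skeleton_graph(g3), 1)), 0)
})

test_that("complexity is 0 exactly on trees and bounded in [0,1]", {
  set.seed(32)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    tr <- igraph::sample_tree(n, directed = FALSE)
    ag <- direct_graph(as_skeleton_graph(tr), 1)
    expect_identical(complexity(ag), 0)
  }
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    g <- igraph::sample_tree(n, directed = FALSE)
    for (e in seq_len(sample(1:4, 1)))
      g <- igraph::add_edges(g, sample(n, 2))
    cx <- complexity(direct_graph(as_skeleton_graph(g), 1))
    expect_gte(cx, 0); expect_lte(cx, 1)
  }
})

test_that("adding a parallel route never decreases complexity", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    g <- igraph::sample_tree(n, directed = FALSE)
    cx0 <- complexity(direct_graph(as_skeleton_graph(g), 1))
    # connect two distinct existing nodes: one more route to some leaf side
    uv <- sample(2:n, 2)
    g2 <- igraph::add_edges(g, uv)
    cx1 <- complexity(direct_graph(as_skeleton_graph(g2), 1))
    expect_gte(cx1, cx0)
  }
})

test_that("the objective honours the empty-mask convention", {
  E <- bridged_map(1500)
  search <- threshold_search(750, 5000, 50, 0.15)
  expect_equal(f_complex(E, max(E$data) + 1, search), -0.15)
  # a clean tree at a mid threshold has complexity zero
  search0 <- threshold_search(750, 5000, 50, 0)
  expect_equal(f_complex(E, 1600, search0), 0)
  # below the bridge value the cycle pushes the objective above zero
  expect_gt(f_complex(E, 900, search0), 0)
})

test_that("bisection tracks a brute-force threshold scan", {
  set.seed(34)
  tol <- 40
  for (rep in 1:12) {
    bval <- runif(1, 1000, 1800)
    E <- bridged_map(bval)
    search <- threshold_search(800, 2400, tol, 0)
    opt <- optimize_threshold(E, search)
    # oracle: linear scan at tol/10 for the smallest feasible threshold
    grid <- seq(800, 2400, by = tol / 10)
    fs <- vapply(grid, function(th) f_complex(E, th, search), numeric(1))
    oracle <- grid[which(fs <= 0)[1]]
    expect_lte(abs(opt$threshold - oracle), tol)
    expect_false(opt$floor)
  }
})

test_that("bisection boundary conventions hold", {
  E <- bridged_map(1500)
  # budget met on the whole interval: floor with a warning
  expect_warning(
    lo <- optimize_threshold(E, threshold_search(1900, 2400, 50, 0)),
    "floor")
  expect_equal(lo$threshold, 1900)
  # budget violated on the whole interval: bracket error
  expect_error(
    optimize_threshold(E, threshold_search(500, 1200, 50, 0)),
    "bracket")
})

test_that("the feasible segmentation never outgrows the permissive one", {
  E <- bridged_map(1400)
  search <- threshold_search(800, 2400, 40, 0)
  opt <- optimize_threshold(E, search)
  n_opt <- sum(threshold_segment(E, opt$threshold)$data)
  n_min <- sum(threshold_segment(E, search$th_min)$data)
  expect_lte(n_opt, n_min)
})
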