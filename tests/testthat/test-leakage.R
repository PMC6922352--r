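test_that("cycle detection matches the cycle space of hand-built graphs", {
  # tree: no cycles
  tr <- igraph::sample_tree(9, directed = FALSE)
  ag <- direct_graph(as_skeleton_graph(tr), 1)
  expect_length(find_cycle_nodes(ag), 0)
  # one square cycle
  sq <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 1), directed = FALSE)
  cyc <- find_cycle_nodes(direct_graph(as_skeleton_graph(sq), 1))
  expect_length(cyc, 1)
  expect_setequal(cyc[[1]], 1:4)
  # two edge-disjoint cycles sharing one node
  g2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4, 4, 5, 5, 3),
                           directed = FALSE)
  cyc2 <- find_cycle_nodes(direct_graph(as_skeleton_graph(g2), 1))
  expect_length(cyc2, 2)
  expect_setequal(sort(unique(unlist(cyc2))), 1:5)
})

test_that("pruning removes the lowest-appearance cycle node", {
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 1), directed = FALSE)
  igraph::V(g)$evalue <- c(900, 800, 100, 850)
  ag <- direct_graph(as_skeleton_graph(g), 1)
  rec <- prune_cycles(ag)
  expect_equal(nrow(rec$nodes), 1)
  expect_equal(rec$nodes$evalue, 100)
  expect_equal(complexity(rec$graph), 0)
  expect_equal(rec$complexity_before, 0.5)
  expect_equal(rec$complexity_after, 0)
})

test_that("a tree passes through pruning unchanged", {
  tr <- igraph::sample_tree(12, directed = FALSE)
  igraph::V(tr)$evalue <- runif(12, 100, 1000)
  ag <- direct_graph(as_skeleton_graph(tr), 1)
  rec <- prune_cycles(ag)
  expect_equal(nrow(rec$nodes), 0)
  expect_length(rec$chains, 0)
  expect_equal(igraph::vcount(rec$graph$graph), 12)
})

test_that("nested cycles sharing their weakest node clear in one removal", {
  # two triangles glued along 1-3; node 3 is the unique minimum of both
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 1, 4, 4, 3), directed = FALSE)
  igraph::V(g)$evalue <- c(900, 800, 50, 850)
  ag <- direct_graph(as_skeleton_graph(g), 1)
  rec <- prune_cycles(ag)
  expect_equal(rec$nodes$evalue, 50)
  expect_equal(complexity(rec$graph), 0)
})

test_that("inverse skeletonization rebuilds a tube segment from its chain", {
  d <- c(15L, 15L, 40L)
  seg <- binary_mask(cylinder_mask(d, 2))
  sg <- skeletonize(seg)
  chain <- igraph::E(sg$graph)$chain[[1]]
  mid <- chain[chain %in% which(array(rep(rep(seq_len(d[3]) %in% 15:25,
                                              each = d[1] * d[2]), 1), d))]
  rec <- structure(list(nodes = data.frame(vox = integer(0),
                                           evalue = numeric(0),
                                           radius = numeric(0)),
                        chains = list(mid)), class = "prune_record")
  art <- inverse_skeletonize(rec, seg)
  truth_seg <- cylinder_mask(d, 2) &
    array(rep(rep(seq_len(d[3]) %in% 15:25, each = d[1] * d[2]), 1), d)
  dice <- 2 * sum(art$data & truth_seg) / (sum(art$data) + sum(truth_seg))
  expect_gt(dice, 0.8)
  expect_true(all(seg$data[art$data]))  # artifact never leaves the mask
  # empty record: empty mask
  rec0 <- structure(list(nodes = data.frame(vox = integer(0)),
                         chains = list()), class = "prune_record")
  expect_equal(sum(inverse_skeletonize(rec0, seg)$data), 0)
})

test_that("leakage removal deletes a bridging blob and keeps the tree", {
  d <- c(41L, 41L, 60L)
  ym <- y_tube_mask(d)
  # bridge between the two branches, fat in the middle
  bridge <- capsule_vox(d, c(12, 21, 12), c(30, 21, 12), 2.5)
  seg <- binary_mask(ym | bridge)
  # appearance: high on the true tube centerlines, low on the bridge
  a <- array(0, d)
  a[ym] <- 3000
  a[bridge & !ym] <- 400
  E <- scalar_volume(array(a, d))
  class(E) <- c("appearance_map", class(E))
  pre <- skeletonize(seg, E = E, split_chains = TRUE, close_gaps = TRUE)
  agp <- direct_graph(pre, find_root(seg, pre, hint = c(21, 21, 58)))
  expect_gt(complexity(agp), 0)
  lr <- remove_leakage(seg, E, root_hint = c(21, 21, 58))
  expect_equal(complexity(lr$graph), 0)
  expect_true(all(seg$data[lr$mask$data])) # output within input
  # most of the bridge is gone, the tube centerline survives
  blob <- bridge & !ym
  expect_gt(sum(blob & !lr$mask$data) / sum(blob), 0.7)
  tube_core <- y_tube_mask(d, r_stem = 1, r_branch = 0.8)
  expect_gt(mean(lr$mask$data[tube_core]), 0.95)
  # a clean mask passes through untouched
  clean <- binary_mask(ym)
  lr2 <- remove_leakage(clean, E, root_hint = c(21, 21, 58))
  expect_identical(lr2$mask$data, clean$data)
  expect_equal(sum(lr2$artifact$data), 0)
})

test_that("removal is idempotent at the graph level", {
  d <- c(41L, 41L, 60L)
  ym <- y_tube_mask(d)
  bridge <- capsule_vox(d, c(12, 21, 12), c(30, 21, 12), 2.5)
  seg <- binary_mask(ym | bridge)
  a <- array(0, d); a[ym] <- 3000; a[bridge & !ym] <- 400
  E <- scalar_volume(array(a, d))
  class(E) <- c("appearance_map", class(E))
  lr1 <- remove_leakage(seg, E, root_hint = c(21, 21, 58))
  lr2 <- remove_leakage(lr1$mask, E, root_hint = c(21, 21, 58))
  expect_equal(complexity(lr2$graph), 0)
  # the second pass finds nothing new to prune
  expect_equal(nrow(lr2$record$nodes), 0)
  expect_identical(lr2$mask$data, lr1$mask$data)
})
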