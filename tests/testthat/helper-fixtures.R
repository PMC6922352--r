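# Fixtures are built in code: small geometric masks and volumes shared by
# the module tests.

# solid cylinder along z, radius r, spanning the full k extent
cylinder_mask <- function(d, r, center = (d[1:2] + 1) / 2) {
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if ((i - center[1])^2 + (j - center[2])^2 <= r^2) out[i, j, ] <- TRUE
  out
}

# voxels within radius r of the segment p0-p1
capsule_vox <- function(d, p0, p1, r) {
  out <- array(FALSE, d)
  v <- p1 - p0
  L2 <- sum(v^2)
  co <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                              k = seq_len(d[3])))
  t <- if (L2 == 0) rep(0, nrow(co)) else
    pmin(pmax(((co[, 1] - p0[1]) * v[1] + (co[, 2] - p0[2]) * v[2] +
                 (co[, 3] - p0[3]) * v[3]) / L2, 0), 1)
  d2 <- (co[, 1] - (p0[1] + t * v[1]))^2 + (co[, 2] - (p0[2] + t * v[2]))^2 +
    (co[, 3] - (p0[3] + t * v[3]))^2
  out[co[d2 <= r^2, , drop = FALSE]] <- TRUE
  out
}

# digital line: rounded points along the segment, 26-connected
line_vox <- function(d, p0, p1) {
  n <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2))))
  ts <- seq(0, 1, length.out = n)
  pts <- unique(round(cbind(p0[1] + ts * (p1[1] - p0[1]),
                            p0[2] + ts * (p1[2] - p0[2]),
                            p0[3] + ts * (p1[3] - p0[3]))))
  pts[, 1] + (pts[, 2] - 1) * d[1] + (pts[, 3] - 1) * d[1] * d[2]
}

# Y-shaped solid tube mask: stem down the middle, two branches
y_tube_mask <- function(d = c(41L, 41L, 60L), r_stem = 3, r_branch = 2.5) {
  m <- capsule_vox(d, c(21, 21, 58), c(21, 21, 30), r_stem) |
    capsule_vox(d, c(21, 21, 30), c(10, 21, 8), r_branch) |
    capsule_vox(d, c(21, 21, 30), c(32, 21, 8), r_branch)
  m
}

# synthetic appearance map with a controllable bridge: a Y of high-value
# lines plus a bridge line whose value decides whether thresholding yields
# a cycle. Returns the map and the bridge value.
bridged_map <- function(bridge_value, d = c(25L, 25L, 25L),
                        tree_value = 2000) {
  a <- array(0, d)
  a[line_vox(d, c(13, 13, 24), c(13, 13, 13))] <- tree_value
  a[line_vox(d, c(13, 13, 13), c(5, 13, 3))] <- tree_value
  a[line_vox(d, c(13, 13, 13), c(21, 13, 3))] <- tree_value
  bridge <- line_vox(d, c(6, 13, 5), c(20, 13, 5))
  a[bridge] <- pmax(a[bridge], bridge_value)
  E <- scalar_volume(a)
  class(E) <- c("appearance_map", class(E))
  E
}

# hand-built skeleton graph from an edge list (rows from-to), positions
# optional; wraps as_skeleton_graph
graph_fixture <- function(edges, n = max(edges), z = NULL) {
  g <- igraph::make_graph(as.vector(t(edges)), n = n, directed = FALSE)
  if (!is.null(z)) igraph::V(g)$z <- z
  as_skeleton_graph(g)
}
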