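# Leakage removal. Segmentation artifacts that bridge two branches show up
# as cycles in the skeleton graph. Each cycle is cleared by removing its
# lowest-appearance node (leakage tissue responds weakly to the tubular
# filter) together with its incident edges. The removed skeleton subset
# is turned back into a volume by inverse skeletonization -- a union of
# balls with the local distance-transform radius -- and subtracted from the
# segmentation.

#' Independent cycles of an airway graph
#'
#' Returns the node sets of a cycle basis of the underlying undirected
#' graph (one fundamental cycle per non-tree edge of a spanning tree). The
#' list is empty exactly when the directed complexity is zero.
#'
#' @param ag An `airway_graph` from [direct_graph()].
#' @return List of integer vectors of vertex indices.
#' @export
find_cycle_nodes <- function(ag) {
  g <- igraph::as_undirected(ag$graph, mode = "each")
  nv <- igraph::vcount(g)
  if (nv == 0L || igraph::ecount(g) == 0L) return(list())
  # spanning forest via BFS from the root
  bfs <- igraph::bfs(g, root = ag$root, father = TRUE, unreachable = TRUE)
  father <- as.integer(bfs$father)
  tree_edges <- integer(0)
  for (v in seq_len(nv)) {
    if (!is.na(father[v]) && father[v] > 0L) {
      eid <- igraph::get_edge_ids(g, c(father[v], v))
      tree_edges <- c(tree_edges, eid[eid > 0L][1])
    }
  }
  tg <- igraph::subgraph_from_edges(g, tree_edges, delete.vertices = FALSE)
  nontree <- setdiff(seq_len(igraph::ecount(g)), tree_edges)
  # parallel edges: get_edge_ids returns one id; any further copies of a
  # tree edge are non-tree edges and close a 2-cycle
  cycles <- list()
  for (e in nontree) {
    uv <- as.integer(igraph::ends(g, e, names = FALSE))
    if (uv[1] == uv[2]) { cycles[[length(cycles) + 1L]] <- uv[1]; next }
    path <- igraph::shortest_paths(tg, from = uv[1], to = uv[2],
                                   output = "vpath")$vpath[[1]]
    cycles[[length(cycles) + 1L]] <- unique(c(as.integer(path), uv))
  }
  cycles
}

#' Prune graph cycles by increasing appearance value
#'
#' Repeats until the directed complexity is zero: take a cycle, sort its
#' nodes by increasing appearance value (ties: lower degree first, then
#' lexicographic position), remove the lowest one with its incident edges,
#' and re-derive the directed graph. Nodes that lose their connection to
#' the root drop out of the graph (their volume is kept; only removed
#' cycle nodes and edges count as artifact skeleton). The root itself is
#' never removed.
#'
#' @param ag An `airway_graph` with node E-values (skeletonize with `E`).
#'   An optional logical vertex attribute `protected` (e.g. nodes inside
#'   the coarse-scale-confirmed segmentation) demotes those nodes in the
#'   removal order: they are only removed when a cycle has no unprotected
#'   node left.
#' @return A `prune_record`: data frames of removed nodes and edges (with
#'   voxel chains), complexity before/after, and the pruned `airway_graph`.
#' @export
prune_cycles <- function(ag) {
  comp0 <- complexity(ag)
  removed_nodes <- list(); removed_edges <- list()
  guard <- igraph::vcount(ag$graph) + 1L
  cur <- ag
  while (complexity(cur) > 0 && guard > 0L) {
    guard <- guard - 1L
    cycles <- find_cycle_nodes(cur)
    if (length(cycles) == 0L) break
    cand <- setdiff(unique(unlist(cycles)), cur$root)
    if (length(cand) == 0L)
      stop("structural error: cycle through the root only")
    ev <- igraph::V(cur$graph)$evalue[cand]
    ev[is.na(ev)] <- -Inf # mid-chain nodes without a sampled value go first
    dg <- igraph::degree(cur$graph)[cand]
    pos <- igraph::V(cur$graph)$vox[cand]
    prot <- igraph::V(cur$graph)$protected[cand]
    if (is.null(prot)) prot <- rep(FALSE, length(cand))
    prot[is.na(prot)] <- FALSE
    pick <- cand[order(prot, ev, dg, pos)][1]
    cur <- drop_node(
      cur, pick,
      note_node = function(n)
        removed_nodes[[length(removed_nodes) + 1L]] <<- n,
      note_edge = function(e)
        removed_edges[[length(removed_edges) + 1L]] <<- e)
  }
  if (complexity(cur) > 0)
    stop("structural error: could not reduce complexity to zero")
  structure(list(
    nodes = if (length(removed_nodes)) do.call(rbind.data.frame, removed_nodes)
            else data.frame(vox = integer(0), evalue = numeric(0),
                            radius = numeric(0)),
    chains = removed_edges,
    complexity_before = comp0,
    complexity_after = complexity(cur),
    graph = cur), class = "prune_record")
}

# remove one vertex (plus incident edges and newly unreachable vertices)
# and rebuild the directed graph from the same root
drop_node <- function(ag, v, note_node, note_edge) {
  g <- igraph::as_undirected(ag$graph, mode = "each")
  vs <- igraph::V(g)
  record_node <- function(u)
    note_node(data.frame(vox = vs$vox[u], evalue = vs$evalue[u],
                         radius = vs$radius[u]))
  record_edges_of <- function(u) {
    for (e in igraph::incident(g, u)) {
      ch <- igraph::edge_attr(g, "chain", e)[[1]]
      note_edge(ch)
    }
  }
  record_node(v)
  record_edges_of(v)
  keepmask <- rep(TRUE, igraph::vcount(g)); keepmask[v] <- FALSE
  g2 <- igraph::delete_vertices(g, v)
  root2 <- cumsum(keepmask)[ag$root]
  # subtrees cut off from the root drop out of the graph (direct_graph
  # excludes unreachable components) but their volume is kept: only the
  # removed cycle nodes and their incident edges are artifact skeleton
  sg <- structure(list(graph = g2, dim = ag$dim, spacing = ag$spacing,
                       origin = ag$origin), class = "skeleton_graph")
  direct_graph(sg, root2)
}

#' Inverse skeletonization of a prune record
#'
#' Reconstructs the artifact volume: a union of Euclidean balls centred on
#' every removed skeleton voxel, each with the local distance-transform
#' radius of the segmentation (floored at 1 voxel), intersected with the
#' segmentation.
#'
#' @param record A `prune_record` from [prune_cycles()].
#' @param seg The [binary_mask()] the graph was skeletonized from.
#' @return A [binary_mask()] of the artifact volume (subset of `seg`).
#' @export
inverse_skeletonize <- function(record, seg) {
  d <- dim(seg$data)
  vox <- unique(c(record$nodes$vox, unlist(record$chains)))
  skeleton_volume(vox, seg)
}

# balls with local distance-field radii around a set of skeleton voxels.
# Skeleton voxels inside the mask use the mask's own distance-field value;
# voxels lying in a closed seam (outside the mask, where the gap-closed
# skeleton can run) get just enough radius to reach past the seam walls.
skeleton_volume <- function(vox, seg, seam_reach = FALSE) {
  d <- dim(seg$data)
  if (length(vox) == 0L)
    return(binary_mask(array(FALSE, d), seg$spacing, seg$origin))
  edt <- cpp_edt_feature(as.vector(!seg$data), d, c(1, 1, 1))$dist
  radii <- pmax(edt[vox], 1)
  if (seam_reach) {
    # half-voxel margin so balls at the inscribed radius also take the
    # discrete surface shell, plus reach across closed seams
    to_mask <- cpp_edt_feature(as.vector(seg$data), d, c(1, 1, 1))$dist
    radii <- pmax(radii + 0.5, to_mask[vox] + 1.5)
  }
  art <- array(cpp_paint_balls(as.integer(vox), radii, d), d)
  binary_mask(art & seg$data, seg$spacing, seg$origin)
}

# skeleton voxels of the surviving graph (nodes plus edge chains)
kept_skeleton_voxels <- function(ag) {
  g <- ag$graph
  ch <- igraph::edge_attr(g, "chain")
  unique(c(igraph::V(g)$vox, unlist(ch)))
}

#' Remove leakage from a segmentation
#'
#' Full chain: skeletonize, root, direct, prune cycles by increasing
#' appearance until the graph is a tree, inverse-skeletonize the pruned
#' subset and subtract it from the segmentation. The pruned graph (which
#' has complexity zero by construction) is the anatomical graph of the
#' cleaned segmentation. Voxels that the surviving tree's own inverse
#' skeletonization claims are kept: they belong to the airway even when a
#' removed artifact chain passes nearby.
#'
#' @param seg Non-empty [binary_mask()].
#' @param E `appearance_map` used for node values.
#' @param root_hint Optional voxel triple for [find_root()].
#' @param protect Optional [binary_mask()] of volume confirmed at a
#'   coarser scale (typically `SegUp^1`): skeleton nodes inside it are
#'   demoted in the removal order and its voxels are never subtracted.
#'   Coarse-confirmed anatomy responds weakly to the fine-scale filter for
#'   scale reasons, not for lack of airway evidence, so its faint
#'   appearance must not mark it as leakage.
#' @param max_pass Maximum number of prune-subtract-reskeletonize passes.
#'   Pruning can detach a region from the root graph-wise while its volume
#'   (kept on purpose) still carries a cycle; a further pass rediscovers
#'   and prunes it.
#' @return List with `mask` (cleaned segmentation), `artifact` (removed
#'   volume), `record` (the first pass's `prune_record`) and `graph` (the
#'   last pruned `airway_graph`, complexity 0 by construction).
#' @export
remove_leakage <- function(seg, E, root_hint = NULL, protect = NULL,
                           max_pass = 1) {
  d <- dim(seg$data)
  empty_rec <- function(ag)
    structure(list(nodes = data.frame(vox = integer(0),
                                      evalue = numeric(0),
                                      radius = numeric(0)),
                   chains = list(), complexity_before = 0,
                   complexity_after = 0, graph = ag),
              class = "prune_record")
  out <- seg
  artifact <- array(FALSE, d)
  first <- NULL
  graph <- NULL
  for (pass in seq_len(max_pass)) {
    sg <- skeletonize(out, E = E, split_chains = TRUE, close_gaps = TRUE)
    if (igraph::vcount(sg$graph) == 0L) break
    if (!is.null(protect))
      igraph::V(sg$graph)$protected <- protect$data[igraph::V(sg$graph)$vox]
    root <- find_root(out, sg, hint = root_hint)
    ag <- direct_graph(sg, root)
    if (complexity(ag) == 0) {
      if (is.null(first)) first <- empty_rec(ag)
      graph <- ag
      break
    }
    rec <- prune_cycles(ag)
    if (is.null(first)) first <- rec
    graph <- rec$graph
    remvox <- unique(c(rec$nodes$vox, unlist(rec$chains)))
    art <- skeleton_volume(remvox, out, seam_reach = TRUE)
    keep <- skeleton_volume(kept_skeleton_voxels(rec$graph), out)
    cut <- art$data & !keep$data
    if (!is.null(protect)) cut <- cut & !protect$data
    if (!any(cut)) break # nothing cuttable: stop rather than loop
    artifact <- artifact | cut
    out <- binary_mask(out$data & !cut, seg$spacing, seg$origin)
    if (!any(out$data)) break
  }
  list(mask = out,
       artifact = binary_mask(artifact, seg$spacing, seg$origin),
       record = first, graph = graph)
}
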