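# Structural analysis. A segmentation is reduced to its centerline skeleton,
# encoded as a graph (nodes = branching points and endpoints, edges =
# centerline chains), directed from the trachea entry by depth-first search,
# and scored by a complexity statistic:
#
#   Complexity = 1 - N_leaf / sum_i #paths(root -> leaf_i)   in [0, 1]
#
# A directed graph derived from a tree has exactly one root path per leaf,
# hence complexity 0; every cycle adds root paths and pushes the statistic
# towards 1. The optimal binarization threshold is the smallest threshold
# whose segmentation stays within a complexity budget (MxComplexity), found
# by bisection.

#' Threshold search settings
#'
#' Bundles the bisection search interval (appearance units), the stopping
#' tolerance on the bracket width, and the complexity budget `MxComplexity`
#' in `[0, 1)` (the maximum tolerated deviation from a tree).
#'
#' @param th_min,th_max Search interval ends, `th_min < th_max`.
#' @param tol Bracket-width stopping tolerance, appearance units.
#' @param max_complexity Complexity budget in `[0, 1)`.
#' @return A `threshold_search` object.
#' @export
threshold_search <- function(th_min = 750, th_max = 975, tol = 50,
                             max_complexity = 0) {
  if (!(th_min < th_max)) stop("th_min must be strictly below th_max")
  if (tol <= 0) stop("tol must be positive")
  if (max_complexity < 0 || max_complexity >= 1)
    stop("max_complexity must lie in [0, 1)")
  structure(list(th_min = th_min, th_max = th_max, tol = tol,
                 max_complexity = max_complexity),
            class = "threshold_search")
}

# two-voxel morphological closing: heals the tunnels and seams left by
# cross-scale mask unions without bridging solid structures
close_mask <- function(data) {
  d <- dim(data)
  dil <- cpp_dilate1(cpp_dilate1(as.vector(data), d), d)
  ero <- cpp_dilate1(cpp_dilate1(as.vector(!array(dil, d)), d), d)
  !array(ero, d) | data
}

vox_coords <- function(idx, d) {
  idx0 <- idx - 1L
  cbind(i = idx0 %% d[1] + 1L,
        j = (idx0 %/% d[1]) %% d[2] + 1L,
        k = idx0 %/% (d[1] * d[2]) + 1L)
}

# appearance value of a skeleton voxel: maximum over its 5x5x5
# neighbourhood, so a centerline that runs a couple of voxels off the
# response ridge (as thinning of a thick or gap-closed mass can leave it)
# still reports the ridge value
sample_evalue <- function(vox, E, d) {
  if (is.null(E)) return(rep(NA_real_, length(vox)))
  co <- vox_coords(vox, d)
  out <- rep(-Inf, length(vox))
  for (dk in -2:2) for (dj in -2:2) for (di in -2:2) {
    i <- pmin(pmax(co[, 1] + di, 1L), d[1])
    j <- pmin(pmax(co[, 2] + dj, 1L), d[2])
    k <- pmin(pmax(co[, 3] + dk, 1L), d[3])
    out <- pmax(out, E$data[cbind(i, j, k)])
  }
  out
}

chain_length_mm <- function(chain, d, spacing) {
  if (length(chain) < 2L) return(0)
  xyz <- vox_coords(chain, d)
  steps <- diff(xyz) * rep(spacing, each = nrow(xyz) - 1L)
  sum(sqrt(rowSums(steps^2)))
}

#' Skeletonize a segmentation into a graph
#'
#' Thins the mask to a 1-voxel-wide 26-connected centerline
#' (topology-preserving sequential thinning, boundary-first in
#' distance-transform order), then converts it to a graph: 26-adjacent
#' junction voxels are merged into single branching nodes, endpoints become
#' leaf nodes, and the degree-2 voxel chains between nodes become edges.
#' Each node carries its voxel position, local radius (Euclidean
#' distance-transform value of the mask) and the appearance value at its
#' voxel; each edge carries its voxel chain and length in mm. Short
#' low-radius terminal spurs, a thinning artifact, are pruned.
#'
#' @param seg Non-empty [binary_mask()].
#' @param E Optional appearance map to sample node E-values from.
#' @param split_chains Insert a mid-chain node on every long edge. This does
#'   not change the complexity statistic but gives the leakage pruning
#'   candidate nodes inside long chains (used by [remove_leakage()]).
#' @param spur_voxels,spur_radius Prune terminal chains with fewer than
#'   `spur_voxels` voxels whose tip radius is below `spur_radius`.
#' @param close_gaps Apply a one-voxel morphological closing before
#'   thinning. Voxel-scale tunnels and seams (e.g. where a fine-scale mask
#'   meets a blocky un-pooled coarse mask) each register as a skeleton
#'   cycle in grid-based thinning, while subvoxel distance-field
#'   skeletonizers are naturally robust to them; enable the closing for
#'   masks assembled by unions across scales (see [remove_leakage()]),
#'   leave it off when the cycles themselves are the signal being measured
#'   (threshold optimization on single-scale maps).
#' @return A `skeleton_graph`: an undirected igraph plus grid metadata.
#' @export
skeletonize <- function(seg, E = NULL, split_chains = FALSE,
                        spur_voxels = 3, spur_radius = 1.5,
                        close_gaps = FALSE) {
  if (!is_mask(seg)) stop("seg must be a binary_mask")
  d <- dim(seg$data)
  if (!any(seg$data)) stop("degenerate input: empty segmentation")
  thin_in <- if (close_gaps) close_mask(seg$data) else seg$data
  edt <- cpp_edt_feature(as.vector(!thin_in), d, c(1, 1, 1))$dist
  if (all(thin_in)) edt <- rep(max(d) / 2, prod(d)) # mask fills the grid
  skel <- array(cpp_thin(as.vector(thin_in), d, edt), d)
  g <- skeleton_to_graph(skel, d, seg$spacing, edt, E)
  g <- prune_spurs(g, spur_voxels, spur_radius)
  if (split_chains) g <- split_long_chains(g, edt, E)
  structure(list(graph = g, dim = d, spacing = seg$spacing,
                 origin = seg$origin), class = "skeleton_graph")
}

skeleton_to_graph <- function(skel, d, spacing, edt, E) {
  vox <- which(skel)
  n <- length(vox)
  idx_map <- integer(prod(d)); idx_map[vox] <- seq_len(n)
  ev <- cpp_voxel_edges(as.vector(skel), d)
  ei <- idx_map[ev[, 1]]; ej <- idx_map[ev[, 2]]
  deg <- tabulate(c(ei, ej), nbins = n)
  nbr <- vector("list", n)
  if (length(ei)) {
    af <- c(ei, ej); at <- c(ej, ei)
    o <- order(af)
    spl <- split(at[o], af[o])
    nbr[as.integer(names(spl))] <- spl
  }
  is_node <- deg != 2L
  # components made only of degree-2 voxels (pure cycles): anchor the
  # smallest voxel index so the cycle still appears in the graph
  comp <- cpp_label_components(as.vector(skel), d, 26L)[vox]
  for (cc in unique(comp)) {
    sel <- which(comp == cc)
    if (!any(is_node[sel])) is_node[sel[which.min(vox[sel])]] <- TRUE
  }
  # merge 26-adjacent junction voxels (deg >= 3) into one branching node;
  # thick junctions otherwise yield spurious small cycles
  junction <- is_node & deg >= 3L
  super_of <- integer(n)
  n_super <- 0L
  if (any(junction)) {
    sel <- junction[ei] & junction[ej]
    jg <- igraph::make_graph(as.vector(rbind(ei[sel], ej[sel])), n = n,
                             directed = FALSE)
    memb <- igraph::components(jg)$membership
    jcomps <- split(which(junction), memb[junction])
    for (grp in jcomps) {
      n_super <- n_super + 1L
      super_of[grp] <- n_super
    }
  }
  singles <- which(is_node & !junction)
  for (v in singles) { n_super <- n_super + 1L; super_of[v] <- n_super }
  # representative voxel per supernode: maximum radius, then smallest index
  rep_vox <- integer(n_super)
  for (s in seq_len(n_super)) {
    mem <- which(super_of == s)
    r <- edt[vox[mem]]
    mem <- mem[order(-r, vox[mem])]
    rep_vox[s] <- vox[mem[1]]
  }
  efrom <- integer(0); eto <- integer(0); chains <- list()
  add_edge <- function(a, b, chain) {
    efrom <<- c(efrom, a); eto <<- c(eto, b)
    chains[[length(chains) + 1L]] <<- chain
  }
  # direct node-node adjacencies across supernodes, one edge per pair
  seen_pairs <- character(0)
  node_ids <- which(is_node)
  for (u in node_ids) {
    for (w in nbr[[u]]) {
      if (!is_node[w]) next
      su <- super_of[u]; sw <- super_of[w]
      if (su == sw) next
      key <- paste(min(su, sw), max(su, sw))
      if (key %in% seen_pairs) next
      seen_pairs <- c(seen_pairs, key)
      add_edge(su, sw, vox[c(u, w)])
    }
  }
  # chains through degree-2 voxels
  visited <- logical(n)
  for (u in node_ids) {
    for (w in nbr[[u]]) {
      if (is_node[w] || visited[w]) next
      chain <- c(u, w)
      prev <- u; cur <- w
      repeat {
        visited[cur] <- TRUE
        nxt <- setdiff(nbr[[cur]], prev)
        if (length(nxt) == 0L) break
        nxt <- nxt[1]
        chain <- c(chain, nxt)
        if (is_node[nxt]) break
        prev <- cur; cur <- nxt
      }
      endv <- chain[length(chain)]
      if (!is_node[endv]) next
      su <- super_of[u]; se <- super_of[endv]
      if (su == se) {
        # chain returning to its own node: a minimal cycle; keep it visible
        # by anchoring its midpoint as a node (two parallel edges)
        interior <- chain[-c(1, length(chain))]
        if (length(interior) < 2L) next # too short to carry volume
        midpos <- ceiling(length(interior) / 2)
        mid <- interior[midpos]
        n_super <- n_super + 1L
        rep_vox <- c(rep_vox, vox[mid])
        cut <- which(chain == interior[midpos])[1]
        add_edge(su, n_super, vox[chain[1:cut]])
        add_edge(n_super, se, vox[chain[cut:length(chain)]])
      } else {
        add_edge(su, se, vox[chain])
      }
    }
  }
  xyz <- vox_coords(rep_vox, d)
  g <- igraph::make_empty_graph(n = n_super, directed = FALSE)
  igraph::V(g)$name <- as.character(rep_vox)
  igraph::V(g)$vox <- rep_vox
  igraph::V(g)$x <- xyz[, 1]; igraph::V(g)$y <- xyz[, 2]; igraph::V(g)$z <- xyz[, 3]
  igraph::V(g)$radius <- edt[rep_vox]
  igraph::V(g)$evalue <- sample_evalue(rep_vox, E, d)
  if (length(efrom)) {
    g <- igraph::add_edges(g, rbind(efrom, eto))
    igraph::E(g)$chain <- chains
    igraph::E(g)$length <- vapply(chains, chain_length_mm, numeric(1),
                                  d = d, spacing = spacing)
  }
  igraph::graph_attr(g, "dim") <- d
  igraph::graph_attr(g, "spacing") <- spacing
  g
}

prune_spurs <- function(g, spur_voxels, spur_radius) {
  repeat {
    deg <- igraph::degree(g)
    drop <- integer(0)
    for (v in which(deg == 1L)) {
      e <- igraph::incident(g, v)
      ch <- igraph::edge_attr(g, "chain", e)[[1]]
      if (length(ch) >= spur_voxels + 2L) next
      if (igraph::V(g)$radius[v] >= spur_radius) next
      other <- setdiff(as.integer(igraph::ends(g, e, names = FALSE)), v)
      if (length(other) && deg[other] > 2L) drop <- c(drop, v)
    }
    if (length(drop) == 0L) break
    g <- igraph::delete_vertices(g, drop)
  }
  dissolve_degree2(g)
}

# merge chains across nodes that became degree-2 after spur pruning
dissolve_degree2 <- function(g) {
  d <- igraph::graph_attr(g, "dim")
  sp <- igraph::graph_attr(g, "spacing")
  repeat {
    deg <- igraph::degree(g)
    cand <- which(deg == 2L)
    merged <- FALSE
    for (v in cand) {
      es <- igraph::incident(g, v)
      if (length(es) != 2L) next # degree 2 via a self-loop: leave alone
      ends1 <- as.integer(igraph::ends(g, es[1], names = FALSE))
      ends2 <- as.integer(igraph::ends(g, es[2], names = FALSE))
      a <- setdiff(ends1, v); b <- setdiff(ends2, v)
      if (length(a) != 1L || length(b) != 1L) next
      if (a == b) next # merging would hide this cycle in a self-loop
      vv <- igraph::V(g)$vox[v]
      ch1 <- igraph::edge_attr(g, "chain", es[1])[[1]]
      ch2 <- igraph::edge_attr(g, "chain", es[2])[[1]]
      if (ch1[length(ch1)] != vv) ch1 <- rev(ch1)
      if (ch2[1] != vv) ch2 <- rev(ch2)
      newchain <- c(ch1, ch2[-1])
      g <- igraph::delete_edges(g, es)
      g <- igraph::add_edges(g, c(a, b))
      eid <- igraph::ecount(g)
      g <- igraph::set_edge_attr(g, "chain", eid, list(newchain))
      g <- igraph::set_edge_attr(g, "length", eid,
                                 chain_length_mm(newchain, d, sp))
      g <- igraph::delete_vertices(g, v)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_long_chains <- function(g, edt = NULL, E = NULL) {
  d <- igraph::graph_attr(g, "dim")
  sp <- igraph::graph_attr(g, "spacing")
  chains <- igraph::edge_attr(g, "chain")
  if (is.null(chains)) return(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  to_split <- which(vapply(chains, length, integer(1)) >= 5L)
  if (length(to_split) == 0L) return(g)
  newv_vox <- integer(0); newe <- list()
  for (t in to_split) {
    ch <- chains[[t]]
    cut <- ceiling(length(ch) / 2)
    newv_vox <- c(newv_vox, ch[cut])
    newe[[length(newe) + 1L]] <- list(a = ends[t, 1], chain = ch[1:cut])
    newe[[length(newe) + 1L]] <- list(b = ends[t, 2],
                                      chain = ch[cut:length(ch)])
  }
  nv0 <- igraph::vcount(g)
  xyz <- vox_coords(newv_vox, d)
  g <- igraph::add_vertices(g, length(newv_vox),
    name = paste0("m", newv_vox), vox = newv_vox,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = if (!is.null(edt)) edt[newv_vox] else NA_real_,
    evalue = sample_evalue(newv_vox, E, d))
  edge_vec <- integer(0); echains <- list(); elens <- numeric(0)
  for (s in seq_along(to_split)) {
    mid <- nv0 + s
    e1 <- newe[[2 * s - 1L]]; e2 <- newe[[2 * s]]
    edge_vec <- c(edge_vec, e1$a, mid, mid, e2$b)
    echains <- c(echains, list(e1$chain), list(e2$chain))
    elens <- c(elens, chain_length_mm(e1$chain, d, sp),
               chain_length_mm(e2$chain, d, sp))
  }
  g <- igraph::delete_edges(g, to_split)
  ne0 <- igraph::ecount(g)
  g <- igraph::add_edges(g, edge_vec)
  ids <- ne0 + seq_along(echains)
  g <- igraph::set_edge_attr(g, "chain", ids, echains)
  g <- igraph::set_edge_attr(g, "length", ids, elens)
  g
}

#' Wrap an igraph as a skeleton graph
#'
#' Mainly useful for constructing small graphs by hand (tests, examples).
#' Vertex attributes `vox`, `x`, `y`, `z`, `radius`, `evalue` and edge
#' attributes `chain`, `length` are filled with defaults when missing.
#'
#' @param graph An undirected igraph.
#' @param dim Grid extents the node positions refer to.
#' @param spacing,origin Grid metadata.
#' @return A `skeleton_graph`.
#' @export
as_skeleton_graph <- function(graph, dim = c(64L, 64L, 64L),
                              spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(igraph::is_igraph(graph), !igraph::is_directed(graph))
  nv <- igraph::vcount(graph)
  va <- igraph::vertex_attr_names(graph)
  if (!"x" %in% va) igraph::V(graph)$x <- seq_len(nv)
  if (!"y" %in% va) igraph::V(graph)$y <- rep(1, nv)
  if (!"z" %in% va) igraph::V(graph)$z <- rep(1, nv)
  if (!"vox" %in% va)
    igraph::V(graph)$vox <- (igraph::V(graph)$z - 1) * dim[1] * dim[2] +
      (igraph::V(graph)$y - 1) * dim[1] + igraph::V(graph)$x
  if (!"radius" %in% va) igraph::V(graph)$radius <- rep(1, nv)
  if (!"evalue" %in% va) igraph::V(graph)$evalue <- rep(NA_real_, nv)
  ea <- igraph::edge_attr_names(graph)
  ne <- igraph::ecount(graph)
  if (!"chain" %in% ea && ne > 0) {
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    igraph::E(graph)$chain <- lapply(seq_len(ne), function(e)
      igraph::V(graph)$vox[ends[e, ]])
  }
  if (!"length" %in% ea && ne > 0) igraph::E(graph)$length <- rep(1, ne)
  igraph::graph_attr(graph, "dim") <- dim
  igraph::graph_attr(graph, "spacing") <- spacing
  structure(list(graph = graph, dim = dim, spacing = spacing,
                 origin = origin), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges on a %s grid\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Locate the airway root (trachea entry)
#'
#' Picks the endpoint node closest to the centroid of the largest airway
#' cross-section on the top axial slab of the mask. An explicit `hint`
#' (voxel triple) wins over the automatic rule: the endpoint nearest the
#' hint is chosen (useful for phantoms where the true entry is known).
#'
#' @param seg The [binary_mask()] the graph came from.
#' @param sg A `skeleton_graph` from [skeletonize()].
#' @param hint Optional voxel (i, j, k) near the root.
#' @param slab Number of top axial slices searched for endpoints.
#' @return Vertex index (integer) of the root node in `sg$graph`.
#' @export
find_root <- function(seg, sg, hint = NULL, slab = 3L) {
  g <- sg$graph
  nv <- igraph::vcount(g)
  if (nv == 0L) stop("empty graph: no root can be chosen")
  px <- igraph::V(g)$x; py <- igraph::V(g)$y; pz <- igraph::V(g)$z
  deg <- igraph::degree(g)
  endpoints <- which(deg <= 1L)
  if (length(endpoints) == 0L) endpoints <- seq_len(nv)
  if (!is.null(hint)) {
    d2 <- (px[endpoints] - hint[1])^2 + (py[endpoints] - hint[2])^2 +
      (pz[endpoints] - hint[3])^2
    return(endpoints[which.min(d2)])
  }
  d <- dim(seg$data)
  ktop <- max(which(apply(seg$data, 3, any)))
  top <- seg$data[, , ktop, drop = FALSE]
  lab <- array(cpp_label_components(as.vector(top), c(d[1], d[2], 1L), 26L),
               dim(top))
  big <- which.max(tabulate(lab))
  sel <- which(lab == big, arr.ind = TRUE)
  cen <- c(mean(sel[, 1]), mean(sel[, 2]), ktop)
  near_top <- endpoints[pz[endpoints] >= ktop - slab + 1L]
  if (length(near_top) == 0L) {
    near_top <- endpoints[pz[endpoints] == max(pz[endpoints])]
  }
  d2 <- (px[near_top] - cen[1])^2 + (py[near_top] - cen[2])^2 +
    (pz[near_top] - cen[3])^2
  near_top[which.min(d2)]
}

#' Direct a skeleton graph from its root
#'
#' Runs a depth-first search from the root and orients every edge from the
#' endpoint discovered earlier towards the one discovered later. Orienting
#' by a fixed vertex ordering makes the result acyclic, so root-to-leaf
#' path counts are finite even in the presence of (undirected) cycles.
#' Components not reachable from the root are excluded and reported.
#'
#' @param sg A `skeleton_graph`.
#' @param root Root vertex index, e.g. from [find_root()].
#' @return An `airway_graph`: directed igraph, root, leaf set, per-leaf
#'   root-path counts and the number of excluded (unreachable) nodes.
#' @export
direct_graph <- function(sg, root) {
  g <- sg$graph
  nv <- igraph::vcount(g)
  if (root < 1L || root > nv) stop("root vertex not in graph")
  loops <- igraph::which_loop(g)
  if (any(loops)) g <- igraph::delete_edges(g, which(loops))
  dfs <- igraph::dfs(g, root = root, order = TRUE, dist = FALSE,
                     unreachable = FALSE)
  ordv <- as.integer(dfs$order)
  ordv <- ordv[!is.na(ordv)]
  disc <- rep(NA_integer_, nv)
  disc[ordv] <- seq_along(ordv)
  reach <- !is.na(disc)
  excluded <- sum(!reach)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  keep_e <- reach[ends[, 1]] & reach[ends[, 2]]
  sub <- igraph::subgraph_from_edges(g, which(keep_e), delete.vertices = FALSE)
  sub <- igraph::delete_vertices(sub, which(!reach))
  # vertex ids shift after deletion; recompute discovery on the subgraph
  map <- cumsum(reach)
  newroot <- map[root]
  ends2 <- igraph::ends(sub, igraph::E(sub), names = FALSE)
  disc2 <- disc[reach]
  flip <- disc2[ends2[, 1]] > disc2[ends2[, 2]]
  from <- ifelse(flip, ends2[, 2], ends2[, 1])
  to <- ifelse(flip, ends2[, 1], ends2[, 2])
  dg <- igraph::make_empty_graph(n = igraph::vcount(sub), directed = TRUE)
  for (a in igraph::vertex_attr_names(sub))
    dg <- igraph::set_vertex_attr(dg, a, value = igraph::vertex_attr(sub, a))
  if (length(from)) {
    dg <- igraph::add_edges(dg, rbind(from, to))
    for (a in igraph::edge_attr_names(sub))
      dg <- igraph::set_edge_attr(dg, a, value = igraph::edge_attr(sub, a))
  }
  pc <- dag_path_counts(dg, newroot)
  leaves <- which(igraph::degree(dg, mode = "out") == 0L)
  structure(list(graph = dg, root = newroot, leaves = leaves,
                 path_counts = pc[leaves], n_leaf = length(leaves),
                 excluded_nodes = excluded, dim = sg$dim,
                 spacing = sg$spacing, origin = sg$origin),
            class = "airway_graph")
}

# number of distinct root->v directed paths, by dynamic programming in
# topological order (finite because DFS-orientation gives a DAG)
dag_path_counts <- function(dg, root) {
  nv <- igraph::vcount(dg)
  counts <- numeric(nv)
  if (nv == 0L) return(counts)
  counts[root] <- 1
  topo <- as.integer(igraph::topo_sort(dg))
  ends <- igraph::ends(dg, igraph::E(dg), names = FALSE)
  if (nrow(ends) == 0L) return(counts)
  for (v in topo) {
    if (v == root) next
    ine <- which(ends[, 2] == v)
    if (length(ine)) counts[v] <- sum(counts[ends[ine, 1]])
  }
  counts
}

#' @export
print.airway_graph <- function(x, ...) {
  cat(sprintf("<airway_graph> %d nodes, %d edges, %d leaves, complexity %.4f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_leaf,
              complexity(x)))
  invisible(x)
}

#' Complexity of a directed airway graph
#'
#' `Complexity = 1 - N_leaf / sum_i #paths(root -> leaf_i)`, in `[0, 1]`.
#' Zero exactly when every leaf is reached by a single root path (the graph
#' is a tree); each additional root path, i.e. each cycle in the underlying
#' segmentation, moves the value towards 1. A graph with no leaves (an
#' isolated root) has complexity 0.
#'
#' @param dg An `airway_graph` from [direct_graph()].
#' @return Scalar in `[0, 1]`.
#' @export
complexity <- function(dg) {
  if (!inherits(dg, "airway_graph")) stop("expected an airway_graph")
  if (dg$n_leaf == 0L) return(0)
  1 - dg$n_leaf / sum(dg$path_counts)
}

# Complexity of the whole segmentation graph: every component is oriented
# by one DFS sweep (the root component from the chosen root, the others
# from their first-discovered vertex), path counts accumulate by dynamic
# programming in discovery order, and leaves/paths aggregate over the
# forest. Zero exactly when every component is a tree; root choice within
# a component only modulates the magnitude, never the zero set.
forest_complexity <- function(sg, root) {
  g <- sg$graph
  nv <- igraph::vcount(g)
  if (nv == 0L) return(0)
  loops <- igraph::which_loop(g)
  if (any(loops)) g <- igraph::delete_edges(g, which(loops))
  dfs <- igraph::dfs(g, root = root, order = TRUE, unreachable = TRUE)
  ordv <- as.integer(dfs$order)
  disc <- integer(nv); disc[ordv] <- seq_len(nv)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  if (nrow(ends) == 0L) return(0) # isolated vertices only: a forest
  flip <- disc[ends[, 1]] > disc[ends[, 2]]
  from <- ifelse(flip, ends[, 2], ends[, 1])
  to <- ifelse(flip, ends[, 1], ends[, 2])
  counts <- numeric(nv)
  counts[setdiff(seq_len(nv), unique(to))] <- 1 # per-component DFS starts
  o <- order(disc[from])
  for (e in o) counts[to[e]] <- counts[to[e]] + counts[from[e]]
  is_leaf <- !(seq_len(nv) %in% from)
  n_leaf <- sum(is_leaf)
  if (n_leaf == 0L) return(0)
  1 - n_leaf / sum(counts[is_leaf])
}

# threshold -> (complexity, graph) for one appearance map; shared by
# f_complex and the pipeline so both see the same graph. scope "all"
# scores the whole segmentation (every component; used during threshold
# optimization), scope "root" only the root's component (the airway tree
# output).
segmentation_complexity <- function(E, th, roi = NULL, root_hint = NULL,
                                    split_chains = FALSE,
                                    scope = c("all", "root")) {
  scope <- match.arg(scope)
  data <- E$data
  if (!is.null(roi)) data <- data * roi$data
  segdata <- data > th
  if (!any(segdata)) return(list(complexity = 0, empty = TRUE, graph = NULL))
  seg <- binary_mask(segdata, E$spacing, E$origin)
  sg <- skeletonize(seg, E = E, split_chains = split_chains)
  if (igraph::vcount(sg$graph) == 0L)
    return(list(complexity = 0, empty = TRUE, graph = NULL))
  root <- find_root(seg, sg, hint = root_hint)
  if (scope == "all") {
    list(complexity = forest_complexity(sg, root), empty = FALSE,
         graph = NULL, seg = seg)
  } else {
    ag <- direct_graph(sg, root)
    list(complexity = complexity(ag), empty = FALSE, graph = ag, seg = seg)
  }
}

#' Complexity objective for threshold optimization
#'
#' `F_Complex(th) = Complexity(Seg_th) - MxComplexity`, bounded in
#' `[-MxComplexity, 1 - MxComplexity]`. An empty segmentation is trivially
#' tree-consistent and returns `-MxComplexity`, which keeps the bisection
#' bracket well defined at high thresholds.
#'
#' @param E An `appearance_map`.
#' @param th Threshold, appearance units.
#' @param search A [threshold_search()] (supplies `MxComplexity`).
#' @param roi Optional [binary_mask()]; the map is zeroed outside it before
#'   thresholding (per-branch refinement).
#' @param root_hint Optional voxel triple for [find_root()].
#' @return Scalar objective value.
#' @export
f_complex <- function(E, th, search = threshold_search(), roi = NULL,
                      root_hint = NULL) {
  sc <- segmentation_complexity(E, th, roi = roi, root_hint = root_hint)
  sc$complexity - search$max_complexity
}

#' Optimal threshold by bisection
#'
#' Approximates `ThOpt = min{ Th : F_Complex(Th) <= 0 }` by bisection on
#' `[th_min, th_max]`: the midpoint replaces the bracket end with the same
#' objective sign, and the search stops when the bracket is narrower than
#' `tol` (or the objective hits 0 exactly). The upper end of the final
#' bracket is returned, so the reported threshold always satisfies the
#' complexity budget. If the budget is already met at `th_min` the floor is
#' returned with a warning; if it is violated on the whole interval the
#' bracket is invalid and an error reports both endpoint values.
#'
#' @inheritParams f_complex
#' @param search A [threshold_search()].
#' @return List with `threshold`, logical `floor` (lower end already
#'   feasible), and `trace`, a data frame of evaluated thresholds and
#'   objective values.
#' @export
optimize_threshold <- function(E, search = threshold_search(), roi = NULL,
                               root_hint = NULL) {
  stopifnot(inherits(search, "threshold_search"))
  evals <- list()
  f <- function(th) {
    val <- f_complex(E, th, search, roi = roi, root_hint = root_hint)
    evals[[length(evals) + 1L]] <<- c(threshold = th, objective = val)
    val
  }
  a <- search$th_min; b <- search$th_max
  fa <- f(a)
  if (fa <= 0) {
    warning("complexity budget already met at th_min; threshold floor reached")
    return(list(threshold = a, floor = TRUE, trace = trace_df(evals)))
  }
  fb <- f(b)
  if (fb > 0)
    stop(sprintf(paste0("bisection bracket invalid: F_Complex > 0 on the ",
                        "whole interval (F(%.6g) = %.4f, F(%.6g) = %.4f)"),
                 a, fa, b, fb))
  while (b - a > search$tol) {
    mid <- (a + b) / 2
    fm <- f(mid)
    if (fm <= 0) b <- mid else a <- mid
  }
  list(threshold = b, floor = FALSE, trace = trace_df(evals))
}

trace_df <- function(evals) {
  do.call(rbind.data.frame, c(lapply(evals, as.list),
                              list(make.row.names = FALSE)))
}

#' Learn a bisection interval from calibration maps
#'
#' Scans a threshold grid over one or more appearance maps and returns the
#' widest interval whose ends have the opposite objective signs on every
#' map: `th_min` is the largest grid value with `F_Complex > 0` everywhere,
#' `th_max` the smallest with `F_Complex <= 0` everywhere. Useful when the
#' intensity scale of the input differs from clinical CT (e.g. phantoms).
#'
#' @param maps A list of `appearance_map`s (or a single one).
#' @param grid Numeric vector of candidate thresholds.
#' @param max_complexity Complexity budget for the objective.
#' @param tol Stopping tolerance stored in the result.
#' @param root_hints Optional list of per-map root hints.
#' @return A [threshold_search()] spanning the learned interval.
#' @export
calibrate_search <- function(maps, grid, max_complexity = 0, tol = 50,
                             root_hints = NULL) {
  if (inherits(maps, "appearance_map")) maps <- list(maps)
  search <- threshold_search(min(grid), max(grid) + tol, tol, max_complexity)
  vals <- sapply(seq_along(maps), function(m)
    vapply(grid, function(th)
      f_complex(maps[[m]], th, search, root_hint = root_hints[[m]]),
      numeric(1)))
  vals <- matrix(vals, nrow = length(grid))
  pos <- apply(vals > 0, 1, all)
  nonpos <- apply(vals <= 0, 1, all)
  if (!any(pos) || !any(nonpos))
    stop("calibration grid contains no valid sign-changing interval")
  th_min <- max(grid[pos]); th_max <- min(grid[nonpos])
  if (!(th_min < th_max))
    stop("calibration produced a crossed interval; widen the grid")
  threshold_search(th_min, th_max, tol, max_complexity)
}
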