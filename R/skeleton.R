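#' Homotopic 3D skeletonization
#'
#' Thins the foreground to a one-voxel-thick centerline skeleton by
#' sequential deletion of simple points (topological numbers T26 = T6 = 1)
#' in six directional subiterations, preserving curve endpoints. The
#' skeleton is a subset of the foreground, preserves its connected-component
#' count and its cycles, and is one voxel thick except at junctions.
#'
#' @param bin A [binary_volume()] with non-empty foreground.
#' @return A [binary_volume()] containing the skeleton voxels.
#' @export
skeletonize <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$mask)) abort("cannot skeletonize an empty foreground")
  skel <- cpp_thin(as.vector(bin$mask), dim(bin$mask))
  binary_volume(array(skel, dim(bin$mask)), bin$voxel_size, bin$origin)
}

#' Per-voxel radius field from the Euclidean distance transform
#'
#' Distance from each foreground voxel centre to the estimated material
#' boundary, in micrometres: the exact Euclidean distance to the nearest
#' background voxel centre minus half a voxel (the boundary surface lies
#' between voxel centres), floored at `voxel_size / 2` so an isolated voxel
#' carries a half-voxel radius. The volume border counts as background.
#' Background voxels are 0.
#'
#' @param bin A [binary_volume()].
#' @return A 3D numeric array (um) with the dimensions of the mask.
#' @export
radius_map <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  d2 <- cpp_edt_sq(as.vector(bin$mask), dim(bin$mask), TRUE)
  r <- pmax(sqrt(d2) - 0.5, 0.5) * bin$voxel_size
  r[!as.vector(bin$mask)] <- 0
  array(r, dim(bin$mask))
}

#' Build a spatial graph from a skeleton
#'
#' Classifies skeleton voxels by their number of 26-neighbors within the
#' skeleton (1 = endpoint, 2 = path, >= 3 = junction), merges 26-connected
#' junction voxel clusters into single nodes at their centroids, and walks
#' maximal path runs into segment polylines. Every polyline point carries
#' its radius from the radius field; a node's radius is the field value at
#' its nearest skeleton voxel. Pure cycles without a junction are anchored
#' at their lexicographically smallest voxel and emitted as flagged
#' self-loops. Optional Laplacian smoothing relaxes interior polyline
#' points (off by default; the voxel chain is reported as-is).
#'
#' @param skeleton A [binary_volume()] holding skeleton voxels (from
#'   [skeletonize()]).
#' @param radii Radius field array from [radius_map()] (um), or `NULL` to
#'   assign the half-voxel floor everywhere.
#' @param voxel_size Voxel edge in um (defaults to the skeleton's).
#' @param smooth_iterations Laplacian smoothing sweeps applied to interior
#'   polyline points (0 = none).
#' @param smooth_lambda Relaxation factor per sweep in (0, 1].
#' @return A [spatial_graph()].
#' @export
build_spatial_graph <- function(skeleton, radii = NULL,
                                voxel_size = skeleton$voxel_size,
                                smooth_iterations = 0, smooth_lambda = 0.5) {
  stopifnot(inherits(skeleton, "binary_volume"))
  mask <- skeleton$mask
  dims <- dim(mask)
  origin <- skeleton$origin
  if (!any(mask)) abort("empty skeleton")
  if (is.null(radii)) {
    radii <- array(0, dims)
    radii[mask] <- voxel_size / 2
  }
  deg_all <- array(cpp_neighbor_count(as.vector(mask), dims), dims)
  branch_ct <- array(cpp_branch_count(as.vector(mask), dims), dims)

  lin_idx <- which(mask)                     # linear indices of skeleton voxels
  center_of <- function(lin) {
    ai <- arrayInd(lin, dims)
    voxel_centers(ai, voxel_size, origin)[1, ]
  }
  # 26-neighbor linear indices of a voxel, restricted to the skeleton,
  # face steps before edge steps before corner steps (then by index) so
  # tracing prefers the tightest connection through voxel-chain staircases
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[order(rowSums(abs(offs))), , drop = FALSE]
  nbrs <- function(lin) {
    ai <- arrayInd(lin, dims)[1, ]
    cand <- sweep(offs, 2, ai, "+")
    ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
      cand[, 1] <= dims[1] & cand[, 2] <= dims[2] & cand[, 3] <= dims[3]
    cand <- cand[ok, , drop = FALSE]
    step <- rowSums(abs(offs))[ok]
    li <- cand[, 1] + dims[1] * (cand[, 2] - 1 + dims[2] * (cand[, 3] - 1))
    keep <- mask[li]
    li[keep][order(step[keep], li[keep])]
  }

  # classification: junctions are voxels whose skeleton neighbors fall into
  # >= 3 connected components (this keeps junction clusters tight where raw
  # neighbor counts inflate along staircase chains), or voxels with >= 3
  # neighbors that all touch each other (a planar crossing like an in-plane
  # "+", where the four arms are pairwise 26-adjacent around the center);
  # endpoints are strict one-neighbor tips; everything else is walkable path
  is_junction <- array(FALSE, dims)
  is_junction[lin_idx[branch_ct[lin_idx] >= 3 |
                        (deg_all[lin_idx] >= 3 &
                           branch_ct[lin_idx] == 1)]] <- TRUE
  is_endpoint <- array(FALSE, dims)
  is_endpoint[lin_idx[deg_all[lin_idx] == 1]] <- TRUE
  is_isolated <- array(FALSE, dims)
  is_isolated[lin_idx[deg_all[lin_idx] == 0]] <- TRUE

  # --- nodes -----------------------------------------------------------------
  node_coord <- list(); node_radius <- numeric()
  node_at <- array(0L, dims)   # node id claimed by junction/endpoint voxels

  jl <- cpp_label(as.vector(is_junction), dims, 26L)
  n_clusters <- max(jl)
  cluster_members <- vector("list", n_clusters)
  if (n_clusters > 0) {
    jv <- which(jl > 0)
    cluster_members <- split(jv, jl[jv])
  }
  next_id <- 0L
  new_node <- function(coord, radius) {
    next_id <<- next_id + 1L
    node_coord[[next_id]] <<- coord
    node_radius[next_id] <<- radius
    next_id
  }
  for (k in seq_len(n_clusters)) {
    mem <- sort(cluster_members[[k]])
    ctr <- colMeans(voxel_centers(arrayInd(mem, dims), voxel_size, origin))
    mem_xyz <- voxel_centers(arrayInd(mem, dims), voxel_size, origin)
    nearest <- mem[which.min(rowSums(sweep(mem_xyz, 2, ctr)^2))]
    id <- new_node(ctr, radii[nearest])
    node_at[mem] <- id
  }
  ep <- sort(lin_idx[is_endpoint[lin_idx] | is_isolated[lin_idx]])
  for (v in ep) node_at[v] <- new_node(center_of(v), radii[v])

  # --- segments --------------------------------------------------------------
  visited <- array(FALSE, dims)  # consumed path voxels
  seg_start <- integer(); seg_end <- integer()
  seg_poly <- list(); seg_radii <- list()
  add_segment <- function(a, b, poly, pr) {
    seg_start[length(seg_start) + 1L] <<- a
    seg_end[length(seg_end) + 1L] <<- b
    seg_poly[[length(seg_poly) + 1L]] <<- poly
    seg_radii[[length(seg_radii) + 1L]] <<- pr
  }

  trace_from <- function(start_node, entry_voxel, first_path_voxel) {
    # walk along path voxels until a node-claimed voxel or a dead end
    pts <- list(node_coord[[start_node]])
    prs <- node_radius[start_node]
    cur <- first_path_voxel
    prev <- entry_voxel
    repeat {
      visited[cur] <<- TRUE
      pts[[length(pts) + 1L]] <- center_of(cur)
      prs <- c(prs, radii[cur])
      nb <- setdiff(nbrs(cur), prev)
      claimed <- nb[node_at[nb] > 0L]
      # terminate into a different node as soon as one is touched; the
      # start node only closes the segment (a genuine loop) when the walk
      # has nowhere else to go, since branch voxels near a junction may
      # brush the start cluster diagonally
      claimed_other <- claimed[node_at[claimed] != start_node]
      if (length(claimed_other) > 0) {
        end_node <- node_at[claimed_other[1]]
        pts[[length(pts) + 1L]] <- node_coord[[end_node]]
        prs <- c(prs, node_radius[end_node])
        return(list(end = end_node, poly = do.call(rbind, pts), pr = prs))
      }
      nxt <- nb[!visited[nb] & node_at[nb] == 0L]
      if (length(nxt) == 0) {
        if (length(claimed) > 0) {     # close the loop into the start node
          pts[[length(pts) + 1L]] <- node_coord[[start_node]]
          prs <- c(prs, node_radius[start_node])
          return(list(end = start_node, poly = do.call(rbind, pts),
                      pr = prs))
        }
        # dead end inside a path run: close defensively at a new node
        end_node <- new_node(center_of(cur), radii[cur])
        node_at[cur] <<- end_node
        return(list(end = end_node, poly = do.call(rbind, pts), pr = prs))
      }
      prev <- cur
      cur <- nxt[1]
    }
  }

  # segments leaving junction clusters
  if (n_clusters > 0) {
    seen_pair <- character()
    for (k in seq_len(n_clusters)) {
      mem <- sort(cluster_members[[k]])
      id_a <- node_at[mem[1]]
      for (m in mem) {
        for (p in nbrs(m)) {
          if (is_junction[p]) {
            id_b <- node_at[p]
            if (id_b == id_a) next
            key <- paste(sort(c(id_a, id_b)), collapse = "_")
            if (key %in% seen_pair) next   # direct cluster-cluster contact
            seen_pair <- c(seen_pair, key)
            add_segment(id_a, id_b,
                        rbind(node_coord[[id_a]], node_coord[[id_b]]),
                        c(node_radius[id_a], node_radius[id_b]))
          } else if (is_endpoint[p]) {
            id_b <- node_at[p]
            add_segment(id_a, id_b,
                        rbind(node_coord[[id_a]], node_coord[[id_b]]),
                        c(node_radius[id_a], node_radius[id_b]))
            visited[p] <- TRUE
          } else if (!visited[p]) {
            tr <- trace_from(id_a, m, p)
            add_segment(id_a, tr$end, tr$poly, tr$pr)
          }
        }
      }
    }
  }
  # chains starting at endpoint voxels (no junction at this end)
  for (v in ep) {
    if (deg_all[v] == 0) next                      # isolated: node only
    nb <- nbrs(v)
    p <- nb[1]
    if (node_at[p] > 0L) {
      # two adjacent endpoint voxels form a direct two-voxel segment
      if (is_endpoint[p] && v < p && !visited[v]) {
        add_segment(node_at[v], node_at[p],
                    rbind(node_coord[[node_at[v]]],
                          node_coord[[node_at[p]]]),
                    c(node_radius[node_at[v]], node_radius[node_at[p]]))
        visited[v] <- TRUE
        visited[p] <- TRUE
      }
      next
    }
    if (!visited[p]) {
      tr <- trace_from(node_at[v], v, p)
      add_segment(node_at[v], tr$end, tr$poly, tr$pr)
    }
  }
  # pure cycles: remaining unvisited path voxels
  remaining <- array(FALSE, dims)
  pv <- lin_idx[deg_all[lin_idx] >= 2 & branch_ct[lin_idx] <= 2 &
                  node_at[lin_idx] == 0L]
  remaining[pv[!visited[pv]]] <- TRUE
  if (any(remaining)) {
    cl <- cpp_label(as.vector(remaining), dims, 26L)
    for (k in seq_len(max(cl))) {
      vox <- which(cl == k)
      anchor <- min(vox)
      id <- new_node(center_of(anchor), radii[anchor])
      node_at[anchor] <- id
      visited[anchor] <- TRUE
      nb <- nbrs(anchor)
      nb <- nb[remaining[nb] & !visited[nb]]
      if (length(nb) == 0) next
      tr <- trace_from(id, anchor, nb[1])
      add_segment(id, tr$end, tr$poly, tr$pr)
    }
  }

  nodes <- tibble(
    node_id = seq_len(next_id),
    x = vapply(node_coord, `[`, 0, 1),
    y = vapply(node_coord, `[`, 0, 2),
    z = vapply(node_coord, `[`, 0, 3),
    radius = node_radius
  )
  segments <- tibble(
    segment_id = seq_along(seg_start),
    start_node = seg_start,
    end_node = seg_end,
    polyline = seg_poly,
    point_radii = seg_radii
  )
  g <- spatial_graph(nodes, segments, validate = FALSE)
  if (smooth_iterations > 0) {
    g <- smooth_polylines(g, smooth_iterations, smooth_lambda)
  }
  g
}

#' Prune skeleton spurs and dissolve pass-through nodes
#'
#' Removes leaf segments (one free end) shorter than `min_length` -- the
#' short side branches that thinning leaves where truncated trabeculae
#' erode to a nub -- collapses redundant parallel connections (two skeleton
#' paths between the same node pair where a beam splits around a pore and
#' rejoins; the shorter path is kept when the longer is under three chord
#' lengths), drops self-loops shorter than twice `min_length`, and then
#' dissolves nodes of valence 2 by splicing their two incident segments
#' into one polyline, repeating until stable. All are standard
#' spatial-graph cleaning steps after skeletonization.
#'
#' @param graph A [spatial_graph()].
#' @param min_length Chord length (um) below which a leaf segment is a
#   spur. The default, 3 voxels at the reference 3 um resolution,
#'   approximates one beam diameter plus the cap retraction inherent to
#'   medial-axis thinning.
#' @param dissolve Splice out valence-2 nodes after pruning.
#' @return A cleaned [spatial_graph()].
#' @export
prune_spurs <- function(graph, min_length = 7.5, dissolve = TRUE) {
  stopifnot(inherits(graph, "spatial_graph"))
  nodes <- graph$nodes
  segs <- graph$segments
  repeat {
    changed <- FALSE
    inc <- c(segs$start_node, segs$end_node)
    val <- table(factor(inc, levels = nodes$node_id))
    leaf_nodes <- nodes$node_id[val == 1]
    if (length(leaf_nodes) > 0 && nrow(segs) > 0) {
      chord <- vapply(segs$polyline, chord_length, 0)
      other_val <- function(s) {
        # valence of the non-leaf end (a spur must branch off a junction)
        ends <- c(segs$start_node[s], segs$end_node[s])
        max(val[as.character(ends)])
      }
      is_spur <- (segs$start_node %in% leaf_nodes |
                    segs$end_node %in% leaf_nodes) &
        !(segs$start_node %in% leaf_nodes & segs$end_node %in% leaf_nodes) &
        chord < min_length &
        vapply(seq_len(nrow(segs)), other_val, 0) >= 3
      if (any(is_spur)) {
        drop_nodes <- intersect(
          leaf_nodes,
          c(segs$start_node[is_spur], segs$end_node[is_spur])
        )
        segs <- segs[!is_spur, , drop = FALSE]
        nodes <- nodes[!nodes$node_id %in% drop_nodes, , drop = FALSE]
        changed <- TRUE
      }
    }
    # short self-loops are split-and-rejoin artifacts, not trabeculae
    if (nrow(segs) > 0) {
      loops <- segs$start_node == segs$end_node
      short_loop <- loops &
        vapply(segs$polyline, curved_length, 0) < 2 * min_length
      if (any(short_loop)) {
        segs <- segs[!short_loop, , drop = FALSE]
        changed <- TRUE
      }
    }
    # collapse redundant parallel paths between one node pair
    if (nrow(segs) > 1) {
      nl <- segs$start_node != segs$end_node
      key <- paste(pmin(segs$start_node, segs$end_node),
                   pmax(segs$start_node, segs$end_node))
      drop <- logical(nrow(segs))
      for (k in unique(key[nl])) {
        idx <- which(key == k & nl & !drop)
        if (length(idx) < 2) next
        lc <- chord_length(segs$polyline[[idx[1]]])
        lt <- vapply(segs$polyline[idx], curved_length, 0)
        redundant <- idx[lt < 3 * max(lc, min_length)]
        if (length(redundant) >= 2) {
          keep_one <- redundant[which.min(lt[match(redundant, idx)])]
          drop[setdiff(redundant, keep_one)] <- TRUE
        }
      }
      if (any(drop)) {
        segs <- segs[!drop, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (dissolve && nrow(segs) > 1) {
      inc <- c(segs$start_node, segs$end_node)
      val <- table(factor(inc, levels = nodes$node_id))
      loops <- segs$start_node == segs$end_node
      pass <- nodes$node_id[val == 2]
      pass <- setdiff(pass, c(segs$start_node[loops], segs$end_node[loops]))
      for (nd in pass) {
        at <- which(segs$start_node == nd | segs$end_node == nd)
        if (length(at) != 2) next
        s1 <- at[1]; s2 <- at[2]
        p1 <- segs$polyline[[s1]]; r1 <- segs$point_radii[[s1]]
        p2 <- segs$polyline[[s2]]; r2 <- segs$point_radii[[s2]]
        if (segs$start_node[s1] == nd) {       # orient s1 to end at nd
          p1 <- p1[nrow(p1):1, , drop = FALSE]; r1 <- rev(r1)
          a <- segs$end_node[s1]
        } else a <- segs$start_node[s1]
        if (segs$end_node[s2] == nd) {         # orient s2 to start at nd
          p2 <- p2[nrow(p2):1, , drop = FALSE]; r2 <- rev(r2)
          b <- segs$start_node[s2]
        } else b <- segs$end_node[s2]
        segs$polyline[[s1]] <- rbind(p1, p2[-1, , drop = FALSE])
        segs$point_radii[[s1]] <- c(r1, r2[-1])
        segs$start_node[s1] <- a
        segs$end_node[s1] <- b
        segs <- segs[-s2, , drop = FALSE]
        nodes <- nodes[nodes$node_id != nd, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  segs$is_loop <- segs$start_node == segs$end_node
  spatial_graph(nodes, segs, validate = FALSE, tol = graph$tol)
}

#' Laplacian smoothing of segment polylines
#'
#' Relaxes interior polyline points toward the midpoint of their neighbors;
#' endpoints stay fixed on their nodes, so graph topology and chord lengths
#' are untouched while the voxel-chain staircase (which inflates curved
#' length) is damped.
#'
#' @param graph A [spatial_graph()].
#' @param iterations Number of sweeps.
#' @param lambda Relaxation factor in (0, 1].
#' @return A [spatial_graph()].
#' @export
smooth_polylines <- function(graph, iterations = 2, lambda = 0.5) {
  stopifnot(inherits(graph, "spatial_graph"))
  segs <- graph$segments
  for (i in seq_len(nrow(segs))) {
    pl <- segs$polyline[[i]]
    n <- nrow(pl)
    if (n < 3) next
    for (it in seq_len(iterations)) {
      mid <- (pl[1:(n - 2), , drop = FALSE] + pl[3:n, , drop = FALSE]) / 2
      pl[2:(n - 1), ] <- (1 - lambda) * pl[2:(n - 1), , drop = FALSE] +
        lambda * mid
    }
    segs$polyline[[i]] <- pl
  }
  spatial_graph(graph$nodes, segs, validate = FALSE, tol = graph$tol)
}
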