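# Fixture builders and independent brute-force oracles used across tests.

# graph with one central node and incident segments along given unit
# directions (chord length `len`), all radii `r`
star_graph <- function(dirs, len = 10, r = 2, center = c(0, 0, 0)) {
  k <- nrow(dirs)
  nodes <- tibble::tibble(
    node_id = seq_len(k + 1),
    x = c(center[1], center[1] + len * dirs[, 1]),
    y = c(center[2], center[2] + len * dirs[, 2]),
    z = c(center[3], center[3] + len * dirs[, 3]),
    radius = r
  )
  segs <- tibble::tibble(
    segment_id = seq_len(k),
    start_node = 1L,
    end_node = seq_len(k) + 1L,
    polyline = lapply(seq_len(k), function(i) {
      rbind(center, center + len * dirs[i, ])
    }),
    point_radii = rep(list(c(r, r)), k)
  )
  spatial_graph(nodes, segs, validate = FALSE)
}

# "+" fixture: one 4-valent node at origin, four leaves in the x-y plane
plus_graph <- function(len = 5, r = 1.5) {
  star_graph(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
             len = len, r = r)
}

# random connected-ish graph: n_seg segments among n_node random nodes,
# polylines jittered so curved length exceeds the chord
random_graph <- function(n_node = 10, n_seg = 15, seed = 1) {
  set.seed(seed)
  coords <- matrix(runif(3 * n_node, 0, 50), ncol = 3)
  nodes <- tibble::tibble(
    node_id = seq_len(n_node),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = runif(n_node, 1, 3)
  )
  a <- sample.int(n_node, n_seg, replace = TRUE)
  b <- sample.int(n_node, n_seg, replace = TRUE)
  # drop self-pairs and repeated unordered pairs: duplicate chords meet at
  # exactly 0 degrees, where any arccos formulation is ill-conditioned and
  # oracle comparisons at tight absolute tolerance are meaningless
  keep <- a != b & !duplicated(paste(pmin(a, b), pmax(a, b)))
  a <- a[keep]; b <- b[keep]
  segs <- tibble::tibble(
    segment_id = seq_along(a),
    start_node = a, end_node = b,
    polyline = lapply(seq_along(a), function(i) {
      p0 <- coords[a[i], ]; p1 <- coords[b[i], ]
      mid <- (p0 + p1) / 2 + runif(3, -1, 1)
      rbind(p0, mid, p1)
    }),
    point_radii = lapply(seq_along(a), function(i) runif(3, 1, 3))
  )
  spatial_graph(nodes, segs, validate = FALSE)
}

# Brute-force pairwise angles at a node: law of cosines on endpoint
# coordinates, explicit double loop. Independent of the package's
# dot-product path.
oracle_node_angles <- function(graph, node_id) {
  segs <- graph$segments
  nd <- graph$nodes
  p0 <- unlist(nd[nd$node_id == node_id, c("x", "y", "z")])
  ends <- list()
  for (i in seq_len(nrow(segs))) {
    for (e in 1:2) {
      this_end <- c(segs$start_node[i], segs$end_node[i])[e]
      other <- c(segs$start_node[i], segs$end_node[i])[3 - e]
      if (this_end == node_id) {
        q <- unlist(nd[nd$node_id == other, c("x", "y", "z")])
        if (sqrt(sum((q - p0)^2)) > 1e-6) ends[[length(ends) + 1]] <- q
      }
    }
  }
  out <- numeric(0)
  if (length(ends) >= 2) {
    for (i in 1:(length(ends) - 1)) {
      for (j in (i + 1):length(ends)) {
        A <- ends[[i]]; B <- ends[[j]]
        a2 <- sum((A - p0)^2); b2 <- sum((B - p0)^2)
        c2 <- sum((A - B)^2)
        cosv <- (a2 + b2 - c2) / (2 * sqrt(a2) * sqrt(b2))
        out <- c(out, acos(min(1, max(-1, cosv))) * 180 / pi)
      }
    }
  }
  out
}

# brute-force 3D flood fill (R implementation, queue-based) for tiny masks
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k] || lab[i, j, k] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j, k))
    lab[i, j, k] <- nxt
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  lab
}

# brute-force nearest-background distance (voxels) for tiny masks
oracle_bg_distance <- function(mask, at) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0) return(Inf)
  min(sqrt(colSums((t(bg) - at)^2)))
}

# dense semicircular polyline of radius r in the x-y plane
semicircle_polyline <- function(r = 1, n = 1000) {
  t <- seq(0, pi, length.out = n)
  cbind(r * cos(t), r * sin(t), 0)
}

# solid geometric masks
solid_ball <- function(n, center, r) {
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  arr <- array(FALSE, c(n, n, n))
  arr[idx[rowSums(sweep(idx, 2, center)^2) <= r^2, , drop = FALSE]] <- TRUE
  arr
}

solid_cylinder_z <- function(nx, ny, nz, cx, cy, r, z0, z1) {
  arr <- array(FALSE, c(nx, ny, nz))
  for (z in z0:z1) {
    for (x in 1:nx) for (y in 1:ny) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) arr[x, y, z] <- TRUE
    }
  }
  arr
}

solid_torus <- function(n, nz, R, tube_r) {
  arr <- array(FALSE, c(n, n, nz))
  cx <- (n + 1) / 2; cz <- (nz + 1) / 2
  for (x in 1:n) for (y in 1:n) for (z in 1:nz) {
    rho <- sqrt((x - cx)^2 + (y - cx)^2)
    if ((rho - R)^2 + (z - cz)^2 <= tube_r^2) arr[x, y, z] <- TRUE
  }
  arr
}

# 26-neighbor counts as an array (internal compiled helper)
cpp_neighbor_count_wrap <- function(mask) {
  array(trabecula:::cpp_neighbor_count(as.vector(mask), dim(mask)),
        dim(mask))
}

# graph cycle rank (independent igraph route)
cycle_rank <- function(graph) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = graph$segments$start_node,
               to = graph$segments$end_node),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node_id)
  )
  igraph::ecount(ig) - igraph::vcount(ig) + igraph::components(ig)$no
}
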