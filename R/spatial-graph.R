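#' Spatial graph of trabecular centerlines
#'
#' The product of skeletonization: `nodes` is a tibble with one row per
#' trabecular intersection or free end (`node_id`, physical coordinates
#' `x`, `y`, `z` in um, `radius` in um); `segments` is a tibble with one row
#' per trabecula (`segment_id`, `start_node`, `end_node`, plus list-columns
#' `polyline` -- an n x 3 matrix of um coordinates whose first and last rows
#' coincide with the endpoint node coordinates -- and `point_radii`, one
#' radius per polyline row). Self-loops (`start_node == end_node`) are
#' permitted and flagged in the logical `is_loop` column.
#'
#' @param nodes Tibble/data frame with columns `node_id`, `x`, `y`, `z`,
#'   `radius`.
#' @param segments Tibble/data frame with columns `segment_id`,
#'   `start_node`, `end_node`, `polyline`, `point_radii`.
#' @param validate Check the class invariants (endpoint coincidence within
#'   the coordinate tolerance, positive radii, resolvable node references).
#' @param tol Coordinate tolerance in um used by validation and merging.
#' @return An object of class `spatial_graph`.
#' @export
spatial_graph <- function(nodes, segments, validate = TRUE, tol = 1e-6) {
  nodes <- as_tibble(nodes)
  segments <- as_tibble(segments)
  if (nrow(segments) > 0 && !"is_loop" %in% names(segments)) {
    segments$is_loop <- segments$start_node == segments$end_node
  }
  if (nrow(segments) == 0) {
    segments <- tibble(
      segment_id = integer(), start_node = integer(), end_node = integer(),
      polyline = list(), point_radii = list(), is_loop = logical()
    )
  }
  if (nrow(nodes) == 0) {
    nodes <- tibble(
      node_id = integer(), x = numeric(), y = numeric(), z = numeric(),
      radius = numeric()
    )
  }
  g <- structure(list(nodes = nodes, segments = segments, tol = tol),
                 class = "spatial_graph")
  if (validate) validate_spatial_graph(g)
  g
}

validate_spatial_graph <- function(g) {
  nodes <- g$nodes
  segs <- g$segments
  tol <- g$tol %||% 1e-6
  if (anyDuplicated(nodes$node_id)) abort("duplicate node_id values")
  radii_absent <- isTRUE(attr(g, "radii_absent"))
  if (!radii_absent && nrow(nodes) > 0 && any(!is.na(nodes$radius) &
                                              nodes$radius <= 0)) {
    abort("all node radii must be > 0")
  }
  if (nrow(segs) == 0) return(invisible(g))
  if (!all(segs$start_node %in% nodes$node_id) ||
      !all(segs$end_node %in% nodes$node_id)) {
    abort("segment references a non-existent node")
  }
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(coords) <- as.character(nodes$node_id)
  for (i in seq_len(nrow(segs))) {
    pl <- segs$polyline[[i]]
    if (!is.matrix(pl) || ncol(pl) != 3 || nrow(pl) < 2) {
      abort(sprintf("segment %d: polyline must be an n x 3 matrix, n >= 2",
                    segs$segment_id[i]))
    }
    pr <- segs$point_radii[[i]]
    if (length(pr) != nrow(pl)) {
      abort(sprintf("segment %d: point_radii length != polyline rows",
                    segs$segment_id[i]))
    }
    if (!radii_absent && any(!is.na(pr) & pr <= 0)) {
      abort(sprintf("segment %d: all point radii must be > 0",
                    segs$segment_id[i]))
    }
    a <- coords[as.character(segs$start_node[i]), ]
    b <- coords[as.character(segs$end_node[i]), ]
    if (max(abs(pl[1, ] - a)) > tol || max(abs(pl[nrow(pl), ] - b)) > tol) {
      abort(sprintf(
        "segment %d: polyline ends do not coincide with endpoint nodes",
        segs$segment_id[i]
      ))
    }
  }
  invisible(g)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf(
    "<spatial_graph> %d nodes, %d segments (%d self-loops)\n",
    nrow(x$nodes), nrow(x$segments), sum(x$segments$is_loop)
  ))
  invisible(x)
}

#' Merge duplicate nodes and segments
#'
#' Nodes whose coordinates coincide within the tolerance are merged (the
#' smallest `node_id` survives, incident segments are re-pointed at it and
#' their polyline ends snapped to its coordinate); segments with the same
#' unordered endpoint pair and identical polylines (up to reversal, within
#' tolerance) are reduced to one. Idempotent and independent of segment
#' ordering; node and segment counts never increase.
#'
#' @param graph A [spatial_graph()].
#' @param tol Coordinate tolerance in um.
#' @return A cleaned [spatial_graph()].
#' @export
deduplicate <- function(graph, tol = 1e-6) {
  stopifnot(inherits(graph, "spatial_graph"))
  nodes <- dplyr::arrange(graph$nodes, .data$node_id)
  segs <- dplyr::arrange(graph$segments, .data$segment_id)
  if (nrow(nodes) > 1) {
    coords <- as.matrix(nodes[, c("x", "y", "z")])
    # union-find over pairs within tolerance (graphs are small enough for
    # the quadratic sweep; pairs are found via a sorted first-axis window)
    n <- nrow(coords)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ord <- order(coords[, 1])
    for (a in seq_len(n - 1)) {
      i <- ord[a]
      for (b in (a + 1):n) {
        j <- ord[b]
        if (coords[j, 1] - coords[i, 1] > tol) break
        if (max(abs(coords[j, ] - coords[i, ])) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    rep_idx <- vapply(seq_len(n), find, 1L)
    keep <- rep_idx == seq_len(n)
    remap <- setNames(nodes$node_id[rep_idx], as.character(nodes$node_id))
    nodes <- nodes[keep, , drop = FALSE]
    if (nrow(segs) > 0) {
      segs$start_node <- unname(remap[as.character(segs$start_node)])
      segs$end_node <- unname(remap[as.character(segs$end_node)])
      coords2 <- as.matrix(nodes[, c("x", "y", "z")])
      rownames(coords2) <- as.character(nodes$node_id)
      for (i in seq_len(nrow(segs))) {
        pl <- segs$polyline[[i]]
        pl[1, ] <- coords2[as.character(segs$start_node[i]), ]
        pl[nrow(pl), ] <- coords2[as.character(segs$end_node[i]), ]
        segs$polyline[[i]] <- pl
      }
      segs$is_loop <- segs$start_node == segs$end_node
    }
  }
  if (nrow(segs) > 1) {
    key <- vapply(seq_len(nrow(segs)), function(i) {
      paste(sort(c(segs$start_node[i], segs$end_node[i])), collapse = "_")
    }, "")
    drop <- logical(nrow(segs))
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 2) next
      for (a in seq_along(idx)[-1]) {
        i <- idx[a]
        if (drop[i]) next
        for (b in seq_len(a - 1)) {
          j <- idx[b]
          if (drop[j]) next
          pi <- segs$polyline[[i]]; pj <- segs$polyline[[j]]
          if (nrow(pi) != nrow(pj)) next
          same_fwd <- max(abs(pi - pj)) <= tol
          same_rev <- max(abs(pi - pj[nrow(pj):1, , drop = FALSE])) <= tol
          if (same_fwd || same_rev) { drop[i] <- TRUE; break }
        }
      }
    }
    segs <- segs[!drop, , drop = FALSE]
  }
  spatial_graph(nodes, segs, validate = FALSE, tol = graph$tol %||% tol)
}

# unit chord directions away from `node_id` for each incidence of the node;
# returns a list of unit vectors (NULL for zero-chord incidences)
node_directions <- function(graph, node_id, chord_tol = 1e-6) {
  segs <- graph$segments
  dirs <- list()
  dropped <- 0L
  coords <- as.matrix(graph$nodes[, c("x", "y", "z")])
  rownames(coords) <- as.character(graph$nodes$node_id)
  p0 <- coords[as.character(node_id), ]
  for (i in seq_len(nrow(segs))) {
    ends <- c(segs$start_node[i], segs$end_node[i])
    for (e in which(ends == node_id)) {
      other <- ends[3 - e]
      p1 <- coords[as.character(other), ]
      v <- p1 - p0
      nv <- sqrt(sum(v^2))
      if (nv < chord_tol) {
        dropped <- dropped + 1L
      } else {
        dirs[[length(dirs) + 1L]] <- v / nv
      }
    }
  }
  structure(dirs, dropped = dropped)
}
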