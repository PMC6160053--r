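#' Read an Avizo SpatialGraph ASCII export
#'
#' Parses the AmiraMesh/Avizo ASCII SpatialGraph dialect: `define VERTEX /
#' EDGE / POINT` counts, declarations binding data blocks (`@1` ...) to
#' `VertexCoordinates`, `EdgeConnectivity`, `NumEdgePoints`,
#' `EdgePointCoordinates` and a point `thickness` (or `Radius`) attribute.
#' Vertex indices in the file are 0-based and become 1-based node ids.
#' The thickness attribute is interpreted as a radius by default; pass
#' `thickness_is = "diameter"` to halve it. If the attribute is missing the
#' graph loads with all radii `NA` and the attribute `radii_absent` set.
#' Duplicated edges are parsed as-is; cleaning is explicit via
#' [deduplicate()].
#'
#' @param path Path to the `.am` ASCII file.
#' @param thickness_is `"radius"` (default) or `"diameter"`.
#' @return A [spatial_graph()].
#' @export
read_avizo_spatialgraph <- function(path,
                                    thickness_is = c("radius", "diameter")) {
  thickness_is <- match.arg(thickness_is)
  if (!file.exists(path)) abort(paste0("no file at ", path))
  lines <- readLines(path, warn = FALSE)
  fail <- function(lineno, msg) {
    abort(sprintf("malformed SpatialGraph file (line %d): %s", lineno, msg))
  }
  counts <- c(VERTEX = NA_integer_, EDGE = NA_integer_, POINT = NA_integer_)
  decls <- list()  # "@k" -> list(section, name, width)
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^define +", ln)) {
      parts <- strsplit(ln, " +")[[1]]
      if (length(parts) < 3) fail(i, "bad define")
      counts[parts[2]] <- as.integer(parts[3])
    } else if (grepl("^(VERTEX|EDGE|POINT) *\\{", ln)) {
      sec <- sub(" .*", "", ln)
      m <- regmatches(ln, regexec(
        "\\{ *([A-Za-z]+)(\\[([0-9]+)\\])? +([A-Za-z]+) *\\} *@([0-9]+)", ln
      ))[[1]]
      if (length(m) == 0) fail(i, "bad declaration")
      decls[[paste0("@", m[6])]] <- list(
        section = sec, name = m[5],
        width = if (m[4] == "") 1L else as.integer(m[4])
      )
    } else if (grepl("^@[0-9]+$", ln)) {
      data_start <- i
      break
    }
  }
  if (anyNA(counts[c("VERTEX", "EDGE", "POINT")])) {
    fail(1L, "missing define VERTEX/EDGE/POINT")
  }
  if (is.na(data_start)) fail(length(lines), "no data blocks found")
  # read data blocks
  blocks <- list()
  i <- data_start
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^@[0-9]+$", ln)) {
      tag <- ln
      d <- decls[[tag]]
      if (is.null(d)) fail(i, paste0("data block ", tag, " never declared"))
      need <- counts[d$section] * d$width
      vals <- numeric(0)
      j <- i + 1L
      while (j <= length(lines) && length(vals) < need) {
        lj <- trimws(lines[j])
        if (grepl("^@[0-9]+$", lj)) break
        if (nzchar(lj)) {
          vals <- c(vals, as.numeric(strsplit(lj, "[ \t,]+")[[1]]))
        }
        j <- j + 1L
      }
      if (length(vals) < need || anyNA(vals)) {
        fail(j - 1L, sprintf("block %s truncated: expected %d values, got %d",
                             tag, need, length(vals)))
      }
      blocks[[tag]] <- matrix(vals[seq_len(need)], ncol = d$width,
                              byrow = TRUE)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  get_block <- function(name, section) {
    for (tag in names(decls)) {
      d <- decls[[tag]]
      if (d$section == section && tolower(d$name) == tolower(name)) {
        return(blocks[[tag]])
      }
    }
    NULL
  }
  vc <- get_block("VertexCoordinates", "VERTEX")
  ec <- get_block("EdgeConnectivity", "EDGE")
  np <- get_block("NumEdgePoints", "EDGE")
  pc <- get_block("EdgePointCoordinates", "POINT")
  if (is.null(vc) || is.null(ec) || is.null(np) || is.null(pc)) {
    fail(data_start, "missing VERTEX/EDGE/POINT core attributes")
  }
  th <- get_block("thickness", "POINT") %||% get_block("Radius", "POINT")
  radii_absent <- is.null(th)
  pr <- if (radii_absent) rep(NA_real_, nrow(pc)) else as.numeric(th)
  if (!radii_absent && thickness_is == "diameter") pr <- pr / 2
  if (sum(np) != nrow(pc)) {
    fail(data_start, "NumEdgePoints does not sum to the POINT count")
  }
  nodes <- tibble(
    node_id = seq_len(nrow(vc)),
    x = vc[, 1], y = vc[, 2], z = vc[, 3],
    radius = NA_real_
  )
  offs <- cumsum(c(0, np[, 1]))
  polylines <- lapply(seq_len(nrow(ec)), function(k) {
    pc[(offs[k] + 1):offs[k + 1], , drop = FALSE]
  })
  pradii <- lapply(seq_len(nrow(ec)), function(k) {
    pr[(offs[k] + 1):offs[k + 1]]
  })
  # node radius: thickness at the first incident polyline end
  if (!radii_absent) {
    for (k in seq_len(nrow(ec))) {
      a <- ec[k, 1] + 1L; b <- ec[k, 2] + 1L
      if (is.na(nodes$radius[a])) nodes$radius[a] <- pradii[[k]][1]
      if (is.na(nodes$radius[b])) {
        nodes$radius[b] <- pradii[[k]][length(pradii[[k]])]
      }
    }
  }
  segments <- tibble(
    segment_id = seq_len(nrow(ec)),
    start_node = as.integer(ec[, 1] + 1L),
    end_node = as.integer(ec[, 2] + 1L),
    polyline = polylines,
    point_radii = pradii
  )
  g <- spatial_graph(nodes, segments, validate = FALSE)
  attr(g, "radii_absent") <- radii_absent
  g
}

#' Write / read a spatial graph (CSV or JSON)
#'
#' The JSON format stores nodes and segments losslessly
#' (full-precision coordinates). The CSV format is one file with a `record`
#' column: `"node"` rows carry `node_id`, coordinates and radius; `"point"`
#' rows carry `segment_id`, `start_node`, `end_node`, `point_index`,
#' coordinates and radius, one row per polyline point. Both round-trip:
#' `read_graph(write_graph(g, p))` equals `g` within coordinate tolerance.
#'
#' @param graph A [spatial_graph()].
#' @param path Output path.
#' @param format `"json"`, `"csv"`, or `NULL` to infer from the extension.
#' @return `path` invisibly (writer); a [spatial_graph()] (reader).
#' @export
write_graph <- function(graph, path, format = NULL) {
  stopifnot(inherits(graph, "spatial_graph"))
  format <- graph_format(path, format)
  if (format == "json") {
    segs <- graph$segments
    obj <- list(
      nodes = graph$nodes,
      segments = lapply(seq_len(nrow(segs)), function(i) {
        list(
          segment_id = segs$segment_id[i],
          start_node = segs$start_node[i],
          end_node = segs$end_node[i],
          polyline = unname(segs$polyline[[i]]),
          point_radii = segs$point_radii[[i]]
        )
      })
    )
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  } else {
    nodes <- graph$nodes
    node_rows <- tibble(
      record = "node", node_id = nodes$node_id,
      segment_id = NA_integer_, start_node = NA_integer_,
      end_node = NA_integer_, point_index = NA_integer_,
      x = nodes$x, y = nodes$y, z = nodes$z, radius = nodes$radius
    )
    segs <- graph$segments
    pt_rows <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      pl <- segs$polyline[[i]]
      tibble(
        record = "point", node_id = NA_integer_,
        segment_id = segs$segment_id[i],
        start_node = segs$start_node[i], end_node = segs$end_node[i],
        point_index = seq_len(nrow(pl)),
        x = pl[, 1], y = pl[, 2], z = pl[, 3],
        radius = segs$point_radii[[i]]
      )
    })
    utils::write.csv(rbind(node_rows, pt_rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = NULL) {
  format <- graph_format(path, format)
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    num_col <- function(x) {
      vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    }
    nodes <- tibble(
      node_id = as.integer(num_col(obj$nodes$node_id)),
      x = num_col(obj$nodes$x), y = num_col(obj$nodes$y),
      z = num_col(obj$nodes$z),
      radius = num_col(obj$nodes$radius)
    )
    if (length(obj$segments) == 0) {
      return(spatial_graph(nodes, NULL, validate = FALSE))
    }
    segs <- obj$segments
    segments <- tibble(
      segment_id = vapply(segs, function(s) as.integer(s$segment_id), 1L),
      start_node = vapply(segs, function(s) as.integer(s$start_node), 1L),
      end_node = vapply(segs, function(s) as.integer(s$end_node), 1L),
      polyline = lapply(segs, function(s) {
        do.call(rbind, lapply(s$polyline, num_col))
      }),
      point_radii = lapply(segs, function(s) num_col(s$point_radii))
    )
    spatial_graph(nodes, segments, validate = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    nd <- df[df$record == "node", , drop = FALSE]
    nodes <- tibble(node_id = as.integer(nd$node_id), x = nd$x, y = nd$y,
                    z = nd$z, radius = nd$radius)
    pt <- df[df$record == "point", , drop = FALSE]
    if (nrow(pt) == 0) return(spatial_graph(nodes, NULL, validate = FALSE))
    pt <- pt[order(pt$segment_id, pt$point_index), , drop = FALSE]
    by_seg <- unname(split(pt, pt$segment_id))
    segments <- tibble(
      segment_id = vapply(by_seg, function(d) as.integer(d$segment_id[1]),
                          1L),
      start_node = vapply(by_seg, function(d) as.integer(d$start_node[1]), 1L),
      end_node = vapply(by_seg, function(d) as.integer(d$end_node[1]), 1L),
      polyline = lapply(by_seg, function(d) cbind(d$x, d$y, d$z)),
      point_radii = lapply(by_seg, function(d) d$radius)
    )
    segments <- segments[order(segments$segment_id), , drop = FALSE]
    spatial_graph(nodes, segments, validate = FALSE)
  }
}

graph_format <- function(path, format) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      json = "json",
      csv = "csv",
      abort(paste0("cannot infer graph format from extension '", ext, "'"))
    )
  }
  match.arg(format, c("json", "csv"))
}
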