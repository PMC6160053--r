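#' Per-segment geometric descriptors
#'
#' @description
#' Low-level descriptor functions operate on a single polyline (an n x 3
#' matrix of um coordinates); [segment_table()] applies them to every
#' segment of a spatial graph and returns a tidy table.
#'
#' `chord_length()` is the straight-line distance between the first and
#' last polyline points (the two nodes). `curved_length()` is the summed
#' consecutive point distance along the centerline. `tortuosity()` is their
#' ratio, curved over chord; it is `NA` ("absent") when the chord is
#' shorter than `chord_tol`, as for closed loops, and such segments are
#' excluded from tortuosity summaries.
#'
#' @param polyline n x 3 numeric matrix of polyline coordinates (um),
#'   n >= 2.
#' @param chord_tol Chord length (um) below which tortuosity and
#'   orientation are undefined.
#' @return A single numeric value (um, or dimensionless for tortuosity).
#' @examples
#' pl <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
#' chord_length(pl)   # 5
#' curved_length(pl)  # 7
#' tortuosity(pl)     # 1.4
#' @export
chord_length <- function(polyline) {
  check_polyline(polyline)
  sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
}

#' @rdname chord_length
#' @export
curved_length <- function(polyline) {
  check_polyline(polyline)
  d <- diff(polyline)
  sum(sqrt(rowSums(d^2)))
}

#' @rdname chord_length
#' @export
tortuosity <- function(polyline, chord_tol = 1e-6) {
  lc <- chord_length(polyline)
  if (lc < chord_tol) return(NA_real_)
  curved_length(polyline) / lc
}

check_polyline <- function(polyline) {
  if (!is.matrix(polyline) || ncol(polyline) != 3 || nrow(polyline) < 2) {
    abort("degenerate polyline: need an n x 3 matrix with n >= 2")
  }
  invisible(polyline)
}

#' Mean segment radius
#'
#' The radius of a trabecula is the arithmetic mean of all point radii
#' describing the segment.
#'
#' @param point_radii Numeric vector of per-point radii (um).
#' @return Mean radius in um.
#' @export
segment_mean_radius <- function(point_radii) {
  if (length(point_radii) == 0) abort("point radii absent")
  mean(point_radii)
}

#' Radius of gyration of a circular cross-section
#'
#' For a circular cross-section of diameter `d_t`, `g_r = d_t / 4`.
#'
#' @param d_t Trabecular diameter (um).
#' @return Radius of gyration (um).
#' @export
radius_of_gyration <- function(d_t) d_t / 4

#' Slenderness ratio
#'
#' Ratio of trabecular length to radius of gyration, `R_S = L / g_r`.
#' The pipeline uses the curved length for `L` (the physical beam length).
#'
#' @param L Trabecular length (um).
#' @param g_r Radius of gyration (um), `> 0`.
#' @return Dimensionless slenderness ratio.
#' @export
slenderness_ratio <- function(L, g_r) {
  if (any(g_r <= 0)) abort("radius of gyration must be > 0")
  L / g_r
}

#' Direction of a segment at one of its nodes
#'
#' Unit vector from the node coordinate to the segment's other endpoint
#' (chord-based direction; the local polyline tangent is available via
#' `mode = "tangent"`). `NA` for zero-chord loops.
#'
#' @param graph A [spatial_graph()].
#' @param segment_id,node_id Segment and one of its endpoint nodes.
#' @param mode `"chord"` (default) or `"tangent"` (first polyline step away
#'   from the node).
#' @param chord_tol Chord tolerance (um).
#' @return Length-3 unit vector, or `NA` vector if undefined.
#' @export
segment_direction_at_node <- function(graph, segment_id, node_id,
                                      mode = c("chord", "tangent"),
                                      chord_tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "spatial_graph"))
  i <- match(segment_id, graph$segments$segment_id)
  if (is.na(i)) abort("no such segment")
  s <- graph$segments[i, ]
  if (node_id != s$start_node && node_id != s$end_node) {
    abort("node is not an endpoint of this segment")
  }
  pl <- s$polyline[[1]]
  at_start <- node_id == s$start_node
  v <- if (mode == "chord") {
    if (at_start) pl[nrow(pl), ] - pl[1, ] else pl[1, ] - pl[nrow(pl), ]
  } else {
    if (at_start) pl[2, ] - pl[1, ] else pl[nrow(pl) - 1, ] - pl[nrow(pl), ]
  }
  nv <- sqrt(sum(v^2))
  if (nv < chord_tol) return(c(NA_real_, NA_real_, NA_real_))
  v / nv
}

#' Inter-trabecular angles at a node
#'
#' The angle between the direction vectors of every unordered pair of
#' segments meeting at the node, computed as the arccosine of the
#' normalized dot product, in degrees. For a node of valence n with all
#' directions defined the list has length n(n-1)/2. Pairs involving an
#' undefined (zero-chord) direction are omitted and counted in the
#' `dropped_pairs` attribute.
#'
#' @param graph A [spatial_graph()].
#' @param node_id Node identifier.
#' @param chord_tol Chord tolerance (um).
#' @return Numeric vector of angles in degrees (empty for valence < 2).
#' @examples
#' # three coplanar chords at full rotational symmetry meet at 120 degrees
#' @export
inter_trabecular_angles <- function(graph, node_id, chord_tol = 1e-6) {
  dirs <- node_directions(graph, node_id, chord_tol)
  pairwise_angles(dirs, attr(dirs, "dropped"))
}

pairwise_angles <- function(dirs, n_undefined = 0) {
  k <- length(dirs)
  total_dirs <- k + n_undefined
  out <- numeric(0)
  if (k >= 2) {
    m <- do.call(rbind, dirs)
    dots <- tcrossprod(m)
    ij <- which(upper.tri(dots), arr.ind = TRUE)
    out <- acos(pmin(pmax(dots[ij], -1), 1)) * 180 / pi
  }
  dropped <- total_dirs * (total_dirs - 1) / 2 - k * (k - 1) / 2
  structure(out, dropped_pairs = dropped)
}

#' Orientation angles theta and phi of a segment chord
#'
#' `theta()` is the angle between the chord and the z-axis folded into
#' `[0, 90]` degrees (`acos(|z . d|)`): 0 means perpendicular to the plate
#' surface, 90 means lying in the x-y plane. `phi()` is the azimuth of the
#' chord's x-y projection in `[0, 360)` degrees, counterclockwise from +x,
#' after orienting the chord to non-negative z; it is `NA` for a purely
#' vertical chord (undefined azimuth) and both are `NA` for a zero chord.
#'
#' @param polyline n x 3 polyline matrix (um).
#' @param chord_tol Chord tolerance (um).
#' @return Angle in degrees, or `NA`.
#' @export
theta <- function(polyline, chord_tol = 1e-6) {
  v <- polyline[nrow(polyline), ] - polyline[1, ]
  nv <- sqrt(sum(v^2))
  if (nv < chord_tol) return(NA_real_)
  acos(min(1, abs(v[3]) / nv)) * 180 / pi
}

#' @rdname theta
#' @export
phi <- function(polyline, chord_tol = 1e-6) {
  v <- polyline[nrow(polyline), ] - polyline[1, ]
  nv <- sqrt(sum(v^2))
  if (nv < chord_tol) return(NA_real_)
  if (v[3] < 0) v <- -v                      # orient chord to non-negative z
  h <- sqrt(v[1]^2 + v[2]^2)
  if (h < chord_tol) return(NA_real_)        # purely vertical
  a <- atan2(v[2], v[1]) * 180 / pi
  a <- a %% 360
  if (a >= 360) a <- 0       # guard the floating-point wrap at exactly 360
  a
}

#' Segment descriptor table
#'
#' One row per segment with the eight trabecular descriptors: chord length,
#' curved length, tortuosity (NA for zero-chord loops), mean radius,
#' diameter, radius of gyration, slenderness ratio (curved length over
#' radius of gyration), theta and phi.
#'
#' @param graph A [spatial_graph()].
#' @param chord_tol Chord tolerance (um) below which tortuosity and
#'   orientation are reported as `NA`.
#' @return A tibble with one row per segment.
#' @export
segment_table <- function(graph, chord_tol = 1e-6) {
  stopifnot(inherits(graph, "spatial_graph"))
  segs <- graph$segments
  n <- nrow(segs)
  lc <- vapply(segs$polyline, chord_length, 0)
  lt <- vapply(segs$polyline, curved_length, 0)
  tau <- ifelse(lc >= chord_tol, lt / lc, NA_real_)
  r <- vapply(segs$point_radii, segment_mean_radius, 0)
  d_t <- 2 * r
  g_r <- radius_of_gyration(d_t)
  tibble(
    segment_id = segs$segment_id,
    start_node = segs$start_node,
    end_node = segs$end_node,
    chord_length = lc,
    curved_length = lt,
    tortuosity = tau,
    mean_radius = r,
    diameter = d_t,
    radius_of_gyration = g_r,
    slenderness = ifelse(g_r > 0, lt / g_r, NA_real_),
    theta = vapply(segs$polyline, theta, 0, chord_tol = chord_tol),
    phi = vapply(segs$polyline, phi, 0, chord_tol = chord_tol),
    is_loop = segs$is_loop
  )
}

#' Node descriptor table
#'
#' One row per node: valence (the node configuration; self-loops count
#' twice), node radius, the list of pairwise inter-trabecular angles, their
#' per-node mean and standard deviation, and the number of pairs dropped
#' because a direction was undefined (zero chord).
#'
#' @param graph A [spatial_graph()].
#' @param chord_tol Chord tolerance (um).
#' @return A tibble with one row per node; `ita` is a list-column.
#' @export
node_table <- function(graph, chord_tol = 1e-6) {
  stopifnot(inherits(graph, "spatial_graph"))
  segs <- graph$segments
  nodes <- graph$nodes
  # incidence list: each segment endpoint contributes one (node, direction)
  dir_of <- function(pl, rev) {
    v <- if (rev) pl[1, ] - pl[nrow(pl), ] else pl[nrow(pl), ] - pl[1, ]
    nv <- sqrt(sum(v^2))
    if (nv < chord_tol) rep(NA_real_, 3) else v / nv
  }
  inc_node <- c(segs$start_node, segs$end_node)
  inc_dir <- c(
    lapply(segs$polyline, dir_of, rev = FALSE),
    lapply(segs$polyline, dir_of, rev = TRUE)
  )
  by_node <- split(seq_along(inc_node), inc_node)
  valence <- mean_ita <- sd_ita <- dropped <- rep(NA_real_, nrow(nodes))
  itas <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    idx <- by_node[[as.character(nodes$node_id[i])]]
    valence[i] <- length(idx)
    dirs <- inc_dir[idx]
    def <- dirs[!vapply(dirs, function(d) anyNA(d), TRUE)]
    ang <- pairwise_angles(def, length(dirs) - length(def))
    itas[[i]] <- as.numeric(ang)
    dropped[i] <- attr(ang, "dropped_pairs")
    mean_ita[i] <- if (length(ang) > 0) mean(ang) else NA_real_
    sd_ita[i] <- if (length(ang) > 1) stats::sd(ang) else NA_real_
  }
  valence[is.na(valence)] <- 0
  tibble(
    node_id = nodes$node_id,
    valence = as.integer(valence),
    node_radius = nodes$radius,
    ita = itas,
    mean_ita = mean_ita,
    sd_ita = sd_ita,
    dropped_pairs = as.integer(dropped)
  )
}

#' Node-configuration table
#'
#' Counts and percentages of nodes by valence class (2N, 3N, ...), with the
#' pooled inter-trabecular-angle mean, standard deviation and histogram
#' mode per class. Free ends (valence < 2) carry no angle and are excluded
#' from the table and its denominator, matching the usual reporting of
#' intersection nodes only.
#'
#' @param graph A [spatial_graph()] or a [node_table()] tibble.
#' @param ita_bin Histogram bin width (degrees) for the mode estimate; bins
#'   are anchored at 0 and the mode is the midpoint of the tallest bin.
#' @param chord_tol Chord tolerance (um), used if a graph is supplied.
#' @return A tibble with one row per valence class, fractions in percent
#'   summing to 100.
#' @export
node_configuration_table <- function(graph, ita_bin = 5, chord_tol = 1e-6) {
  nt <- if (inherits(graph, "spatial_graph")) {
    node_table(graph, chord_tol)
  } else {
    graph
  }
  nt <- nt[nt$valence >= 2, , drop = FALSE]
  if (nrow(nt) == 0) {
    return(tibble(
      valence = integer(), n = integer(), fraction_pct = numeric(),
      mean_ita = numeric(), sd_ita = numeric(), mode_ita = numeric()
    ))
  }
  total <- nrow(nt)
  dplyr::summarise(
    dplyr::group_by(nt, .data$valence),
    n = dplyr::n(),
    fraction_pct = 100 * dplyr::n() / total,
    mean_ita = {
      a <- unlist(.data$ita)
      if (length(a)) mean(a) else NA_real_
    },
    sd_ita = {
      a <- unlist(.data$ita)
      if (length(a) > 1) stats::sd(a) else NA_real_
    },
    mode_ita = hist_mode(unlist(.data$ita), ita_bin),
    .groups = "drop"
  )
}

# midpoint of tallest histogram bin, bins of `width` degrees anchored at 0;
# earliest bin wins ties (deterministic)
hist_mode <- function(x, width = 5) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  idx <- floor(pmin(x, 180 - 1e-9) / width)   # fold exact 180 into last bin
  tab <- table(idx)
  best <- as.numeric(names(tab)[which.max(tab)])
  best * width + width / 2
}

#' Median / MAD descriptor summary
#'
#' Summarizes descriptor columns as median, unscaled median absolute
#' deviation, minimum, maximum and N (the layout of standard trabecular
#' measurement tables). `NA` values (absent tortuosity or orientation of
#' zero-chord segments) are dropped per variable, so N differs between
#' variables.
#'
#' @param segments A [segment_table()] tibble (or any data frame).
#' @param nodes Optionally a [node_table()] tibble; adds node radius and
#'   per-node mean ITA rows.
#' @param variables Columns of `segments` to summarize.
#' @return A tibble with columns `variable`, `median`, `mad`, `min`,
#'   `max`, `n`.
#' @export
summarize_descriptors <- function(segments,
                                  nodes = NULL,
                                  variables = c(
                                    "chord_length", "curved_length",
                                    "tortuosity", "mean_radius",
                                    "slenderness", "theta", "phi"
                                  )) {
  one <- function(name, x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble(variable = name, median = NA_real_, mad = NA_real_,
                    min = NA_real_, max = NA_real_, n = 0L))
    }
    tibble(
      variable = name, median = median(x), mad = mad_raw(x),
      min = min(x), max = max(x), n = length(x)
    )
  }
  out <- dplyr::bind_rows(lapply(intersect(variables, names(segments)),
                                 function(v) one(v, segments[[v]])))
  if (!is.null(nodes)) {
    out <- dplyr::bind_rows(
      out,
      one("node_radius", nodes$node_radius[nodes$valence >= 2]),
      one("mean_ita", nodes$mean_ita[nodes$valence >= 2])
    )
  }
  out
}
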