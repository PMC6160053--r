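#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis chain with its standard default:
#' segmentation band 76--172, small-spot threshold 1000 voxels at
#' 26-connectivity, 3 um voxels, two Laplacian polyline-smoothing sweeps
#' (damping the voxel-chain staircase that otherwise inflates curved
#' length), spur pruning at 3 voxels, sub-voxel radius refinement on,
#' subsampled comparisons at n = 300 and 10000 iterations.
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default. Serializes to JSON via [write_config()] / [read_config()].
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `trab_config` list.
#' @export
trab_config <- function(...) {
  defaults <- list(
    voxel_size = 3,
    band = c(76, 172),
    min_size_vox = 1000,
    connectivity = 26,
    denoise = TRUE,
    denoise_size = 3,
    denoise_neighborhood = 26,
    chord_tol = 1e-6,
    smooth_iterations = 2,
    spur_voxels = 3,
    refine_radii = TRUE,
    subsample_n = 300,
    iterations = 10000,
    seed = 1,
    E = 1,
    n_coeff = 4,
    phi_bins = 36,
    ita_bin = 5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "trab_config")
}

#' @param config A `trab_config`.
#' @param path JSON file path.
#' @rdname trab_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trab_config"))
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname trab_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(trab_config, obj)
}

#' Run the full trabecular analysis pipeline
#'
#' Executes the stage chain for one or more plate regions: preprocessing
#' (for intensity volumes), skeletonization and graph construction (for
#' binary volumes), duplicate removal, descriptor extraction, mechanics,
#' distribution statistics (Shapiro-Wilk, skewness/kurtosis on theta;
#' chi-squared uniformity and rose sectors on phi) and, when two or more
#' regions are supplied, the battery of pairwise subsampled Wilcoxon
#' comparisons (chord length, curved length, radius, tortuosity, node
#' radius, slenderness, per-node mean ITA, theta, phi, plus the
#' within-region chord-vs-curved comparison). Every stage's parameters and
#' seeds are recorded in the bundle. A stage failure aborts with the region
#' and stage name.
#'
#' @param inputs A single input or named list of inputs, each a
#'   [voxel_volume()], [binary_volume()] or [spatial_graph()].
#' @param config A [trab_config()].
#' @return A `trab_report` bundle: `regions` (per-region tables), a
#'   `comparisons` tibble, `config` and metadata.
#' @export
run_pipeline <- function(inputs, config = trab_config()) {
  stopifnot(inherits(config, "trab_config"))
  if (inherits(inputs, c("voxel_volume", "binary_volume", "spatial_graph",
                         "trab_network"))) {
    inputs <- list(region1 = inputs)
  }
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- paste0("region", seq_along(inputs))
  }
  stage <- function(region, name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for region '%s': %s",
                    name, region, conditionMessage(e)))
    })
  }
  regions <- lapply(names(inputs), function(rn) {
    input <- inputs[[rn]]
    if (inherits(input, "trab_network")) input <- input$graph
    bin <- NULL
    if (inherits(input, "voxel_volume")) {
      bin <- stage(rn, "preprocess", preprocess_volume(
        input, band = config$band, min_size_vox = config$min_size_vox,
        connectivity = config$connectivity, denoise = config$denoise,
        denoise_size = config$denoise_size,
        denoise_neighborhood = config$denoise_neighborhood
      ))
      input <- bin
    }
    if (inherits(input, "binary_volume")) {
      bin <- input
      skel <- stage(rn, "skeletonize", skeletonize(bin))
      rmap <- stage(rn, "radius_map", radius_map(bin))
      graph <- stage(rn, "build_graph", build_spatial_graph(
        skel, rmap, smooth_iterations = config$smooth_iterations
      ))
      graph <- stage(rn, "deduplicate", deduplicate(graph))
      if (config$spur_voxels > 0) {
        graph <- stage(rn, "prune_spurs", prune_spurs(
          graph, min_length = config$spur_voxels * config$voxel_size
        ))
      }
      if (isTRUE(config$refine_radii)) {
        graph <- stage(rn, "refine_radii", refine_segment_radii(graph, bin))
      }
    } else if (inherits(input, "spatial_graph")) {
      graph <- stage(rn, "deduplicate", deduplicate(input))
    } else {
      abort(sprintf("unsupported input type for region '%s'", rn))
    }
    segs <- stage(rn, "descriptors",
                  segment_table(graph, chord_tol = config$chord_tol))
    nods <- stage(rn, "descriptors",
                  node_table(graph, chord_tol = config$chord_tol))
    mech <- stage(rn, "mechanics",
                  per_segment_buckling(segs, E = config$E,
                                       n_coeff = config$n_coeff))
    theta_v <- segs$theta[!is.na(segs$theta)]
    phi_v <- segs$phi[!is.na(segs$phi)]
    dist_tests <- list()
    if (length(theta_v) >= 3 && diff(range(theta_v)) > 0) {
      dist_tests$theta_normality <- shapiro_wilk(theta_v,
                                                 seed = config$seed)
    }
    dist_tests$theta_moments <- tibble(
      skewness = moment_skewness(theta_v),
      kurtosis = moment_kurtosis(theta_v),
      n = length(theta_v)
    )
    if (length(phi_v) >= config$phi_bins) {
      dist_tests$phi_uniformity <- chi_square_uniformity(phi_v,
                                                         config$phi_bins)
    }
    list(
      name = rn,
      n_foreground = if (is.null(bin)) NA_integer_ else sum(bin$mask),
      graph = graph,
      segments = segs,
      nodes = nods,
      mechanics = mech,
      summary = summarize_descriptors(segs, nods),
      node_configuration = node_configuration_table(
        nods, ita_bin = config$ita_bin
      ),
      distribution_tests = dist_tests,
      rose = rose_bins(phi_v, config$phi_bins)
    )
  })
  names(regions) <- names(inputs)

  comparisons <- compare_regions(regions, config)
  structure(
    list(regions = regions, comparisons = comparisons, config = config,
         meta = list(
           package_version = as.character(utils::packageVersion("trabecula")),
           seed = config$seed,
           config_hash = config_hash(config)
         )),
    class = "trab_report"
  )
}

compare_regions <- function(regions, config) {
  vars <- c("chord_length", "curved_length", "mean_radius", "tortuosity",
            "slenderness", "theta", "phi")
  rows <- list()
  seed_k <- config$seed
  add <- function(g1, g2, variable, x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) return()
    seed_k <<- seed_k + 1L
    cmp <- suppressWarnings(subsampled_wilcoxon(
      x, y, n = config$subsample_n, iterations = config$iterations,
      seed = seed_k, labels = c(g1, g2)
    ))
    rows[[length(rows) + 1L]] <<- tibble(
      group1 = g1, group2 = g2, variable = variable,
      mean_p = cmp$mean_p, n = cmp$n, iterations = cmp$iterations,
      seed = seed_k
    )
  }
  for (rn in names(regions)) {
    r <- regions[[rn]]
    add(rn, rn, "chord_vs_curved", r$segments$chord_length,
        r$segments$curved_length)
  }
  rns <- names(regions)
  if (length(rns) >= 2) {
    for (i in seq_len(length(rns) - 1)) {
      for (j in (i + 1):length(rns)) {
        a <- regions[[rns[i]]]; b <- regions[[rns[j]]]
        for (v in vars) add(rns[i], rns[j], v, a$segments[[v]],
                            b$segments[[v]])
        add(rns[i], rns[j], "node_radius",
            a$nodes$node_radius[a$nodes$valence >= 2],
            b$nodes$node_radius[b$nodes$valence >= 2])
        add(rns[i], rns[j], "mean_ita", a$nodes$mean_ita, b$nodes$mean_ita)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(group1 = character(), group2 = character(),
                  variable = character(), mean_p = numeric(), n = integer(),
                  iterations = integer(), seed = integer()))
  }
  dplyr::bind_rows(rows)
}

# small deterministic polynomial hash of the serialized config (31-bit
# arithmetic, exactly representable in doubles), for provenance stamping
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render a pipeline report
#'
#' Formats a `trab_report` bundle as deterministic plain text (summary
#' table in median/MAD layout, node-configuration table with 2N..kN
#' columns, distribution tests, pairwise comparisons) and optionally
#' writes the text, a JSON version of all tables, and per-region
#' descriptor CSVs sufficient to regenerate the histogram and rose-diagram
#' figures.
#'
#' @param bundle A `trab_report` from [run_pipeline()].
#' @param path Optional text file path.
#' @param json_path Optional JSON file path.
#' @param csv_dir Optional directory for per-region segment/node CSVs and
#'   rose-sector counts.
#' @return The text report as a character vector, invisibly if `path` is
#'   given.
#' @export
render_report <- function(bundle, path = NULL, json_path = NULL,
                          csv_dir = NULL) {
  stopifnot(inherits(bundle, "trab_report"))
  fmt <- function(x, d = 2) {
    ifelse(is.na(x), "n/a", formatC(x, format = "f", digits = d))
  }
  out <- c(
    "# Trabecular architecture report",
    sprintf("# config %s | seed %d | trabecula %s",
            bundle$meta$config_hash, bundle$meta$seed,
            bundle$meta$package_version),
    ""
  )
  for (rn in names(bundle$regions)) {
    r <- bundle$regions[[rn]]
    out <- c(out, sprintf("## region: %s", rn), "")
    if (nrow(r$summary) == 0 || all(r$summary$n == 0)) {
      out <- c(out, "no data", "")
    } else {
      out <- c(out, "variable            median     mad     min     max       N")
      for (i in seq_len(nrow(r$summary))) {
        s <- r$summary[i, ]
        out <- c(out, sprintf("%-18s %8s %7s %7s %7s %7d",
                              s$variable, fmt(s$median), fmt(s$mad),
                              fmt(s$min), fmt(s$max), s$n))
      }
      out <- c(out, "")
    }
    nc <- r$node_configuration
    if (nrow(nc) == 0) {
      out <- c(out, "node configuration: no data", "")
    } else {
      cls <- sprintf("%dN", nc$valence)
      out <- c(out,
        paste0("node conf      total  ", paste(sprintf("%8s", cls),
                                               collapse = "")),
        paste0("N            ", sprintf("%7d", sum(nc$n)), "  ",
               paste(sprintf("%8d", nc$n), collapse = "")),
        paste0("fraction (%) ", sprintf("%7s", "100.00"), "  ",
               paste(sprintf("%8s", fmt(nc$fraction_pct)), collapse = "")),
        paste0("mean ITA     ", sprintf("%7s", ""), "  ",
               paste(sprintf("%8s", fmt(nc$mean_ita)), collapse = "")),
        paste0("sd ITA       ", sprintf("%7s", ""), "  ",
               paste(sprintf("%8s", fmt(nc$sd_ita)), collapse = "")),
        paste0("mode ITA     ", sprintf("%7s", ""), "  ",
               paste(sprintf("%8s", fmt(nc$mode_ita)), collapse = "")),
        ""
      )
    }
    dt <- r$distribution_tests
    if (!is.null(dt$theta_normality)) {
      out <- c(out, sprintf(
        "theta normality (Shapiro-Wilk): W = %.3f, p = %.3g, N = %d",
        dt$theta_normality$statistic, dt$theta_normality$p_value,
        dt$theta_normality$n
      ))
    }
    out <- c(out, sprintf(
      "theta moments: skewness = %.3f, kurtosis = %.3f, N = %d",
      dt$theta_moments$skewness, dt$theta_moments$kurtosis,
      dt$theta_moments$n
    ))
    if (!is.null(dt$phi_uniformity)) {
      out <- c(out, sprintf(
        "phi uniformity (chi-squared): X2(%d) = %.2f, p = %.3g, N = %d",
        dt$phi_uniformity$df, dt$phi_uniformity$statistic,
        dt$phi_uniformity$p_value, dt$phi_uniformity$n
      ))
    }
    out <- c(out, "")
  }
  cmp <- bundle$comparisons
  if (nrow(cmp) > 0) {
    out <- c(out, "## pairwise comparisons (subsampled Wilcoxon, mean p)", "")
    for (i in seq_len(nrow(cmp))) {
      out <- c(out, sprintf(
        "%s vs %s / %-16s mean p = %.4g (n = %d, iterations = %d)",
        cmp$group1[i], cmp$group2[i], cmp$variable[i], cmp$mean_p[i],
        cmp$n[i], cmp$iterations[i]
      ))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  if (!is.null(json_path)) {
    obj <- list(
      meta = bundle$meta,
      config = unclass(bundle$config),
      regions = lapply(bundle$regions, function(r) {
        list(summary = r$summary, node_configuration = r$node_configuration,
             distribution_tests = r$distribution_tests, rose = r$rose)
      }),
      comparisons = bundle$comparisons
    )
    jsonlite::write_json(obj, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    for (rn in names(bundle$regions)) {
      r <- bundle$regions[[rn]]
      utils::write.csv(r$segments[, setdiff(names(r$segments),
                                            c("polyline", "point_radii"))],
                       file.path(csv_dir, paste0(rn, "_segments.csv")),
                       row.names = FALSE)
      nd <- r$nodes
      nd$ita <- vapply(nd$ita, function(a) paste(signif(a, 8),
                                                 collapse = ";"), "")
      utils::write.csv(nd, file.path(csv_dir, paste0(rn, "_nodes.csv")),
                       row.names = FALSE)
      utils::write.csv(r$rose, file.path(csv_dir, paste0(rn, "_rose.csv")),
                       row.names = FALSE)
    }
  }
  if (is.null(path)) out else invisible(out)
}

#' @export
print.trab_report <- function(x, ...) {
  cat(sprintf("<trab_report> %d region(s): %s; %d comparison(s)\n",
              length(x$regions), paste(names(x$regions), collapse = ", "),
              nrow(x$comparisons)))
  invisible(x)
}
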