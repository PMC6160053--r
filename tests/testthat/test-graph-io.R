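avizo_minimal <- function(path, dup_edge = FALSE, truncate = FALSE,
                          thickness = TRUE) {
  n_edge <- if (dup_edge) 2 else 1
  lines <- c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    sprintf("define VERTEX %d", 2),
    sprintf("define EDGE %d", n_edge),
    sprintf("define POINT %d", 3 * n_edge),
    "",
    "Parameters { ContentType \"HxSpatialGraph\" }",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    if (thickness) "POINT { float thickness } @5" else NULL,
    "",
    "@1",
    "0 0 0",
    "10 0 0",
    "",
    "@2",
    rep("0 1", n_edge),
    "",
    "@3",
    rep("3", n_edge),
    "",
    "@4",
    rep(c("0 0 0", "5 1 0", "10 0 0"), n_edge),
    if (thickness) c("", "@5", rep(c("1.5", "2.0", "1.5"), n_edge)) else NULL
  )
  if (truncate) lines <- lines[1:(length(lines) - 2)]
  writeLines(lines, path)
  path
}

test_that("a minimal Avizo SpatialGraph file parses losslessly", {
  p <- withr::local_tempfile(fileext = ".am")
  avizo_minimal(p)
  g <- read_avizo_spatialgraph(p)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$segments), 1)
  pl <- g$segments$polyline[[1]]
  expect_equal(nrow(pl), 3)
  expect_equal(pl[2, ], c(5, 1, 0))
  expect_equal(g$segments$point_radii[[1]], c(1.5, 2.0, 1.5))
  # 0-based vertex ids became 1-based node ids
  expect_equal(g$segments$start_node, 1L)
  expect_equal(g$segments$end_node, 2L)
  # thickness as diameter halves the radii
  gd <- read_avizo_spatialgraph(p, thickness_is = "diameter")
  expect_equal(gd$segments$point_radii[[1]], c(0.75, 1.0, 0.75))
})

test_that("duplicated edges parse as-is and clean via deduplicate", {
  p <- withr::local_tempfile(fileext = ".am")
  avizo_minimal(p, dup_edge = TRUE)
  g <- read_avizo_spatialgraph(p)
  expect_equal(nrow(g$segments), 2)
  expect_equal(nrow(deduplicate(g)$segments), 1)
})

test_that("truncated files fail with a line number", {
  p <- withr::local_tempfile(fileext = ".am")
  avizo_minimal(p, truncate = TRUE)
  expect_error(read_avizo_spatialgraph(p), "line [0-9]+")
})

test_that("a file without thickness loads with radii flagged absent", {
  p <- withr::local_tempfile(fileext = ".am")
  avizo_minimal(p, thickness = FALSE)
  g <- read_avizo_spatialgraph(p)
  expect_true(attr(g, "radii_absent"))
  expect_true(all(is.na(g$segments$point_radii[[1]])))
})

test_that("JSON and CSV graph formats round-trip", {
  g <- plus_graph()
  for (ext in c(".json", ".csv")) {
    p <- withr::local_tempfile(fileext = ext)
    write_graph(g, p)
    g2 <- read_graph(p)
    expect_equal(g2$nodes$x, g$nodes$x)
    expect_equal(g2$nodes$radius, g$nodes$radius)
    expect_equal(nrow(g2$segments), nrow(g$segments))
    for (i in seq_len(nrow(g$segments))) {
      expect_equal(g2$segments$polyline[[i]], unname(g$segments$polyline[[i]]),
                   tolerance = 1e-9)
      expect_equal(g2$segments$point_radii[[i]], g$segments$point_radii[[i]])
    }
  }
})

test_that("cross-format round-trip preserves the graph", {
  g <- random_graph(6, 9, seed = 3)
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_graph(g, pj)
  write_graph(read_graph(pj), pc)
  g2 <- read_graph(pc)
  st1 <- segment_table(g)
  st2 <- segment_table(g2)
  expect_equal(st2$chord_length, st1$chord_length, tolerance = 1e-9)
  expect_equal(st2$curved_length, st1$curved_length, tolerance = 1e-9)
})

test_that("an empty graph writes and reads back as empty", {
  g <- spatial_graph(NULL, NULL, validate = FALSE)
  for (ext in c(".json", ".csv")) {
    p <- withr::local_tempfile(fileext = ext)
    write_graph(g, p)
    g2 <- read_graph(p)
    expect_equal(nrow(g2$nodes), 0)
    expect_equal(nrow(g2$segments), 0)
  }
})
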