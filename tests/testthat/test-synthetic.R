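test_that("generation is bit-reproducible for a fixed seed and spec", {
  a <- generate_network(seed = 21)
  b <- generate_network(seed = 21)
  expect_identical(a$truth$segments, b$truth$segments)
  expect_identical(a$graph$nodes, b$graph$nodes)
  c <- generate_network(seed = 22)
  expect_false(identical(a$graph$nodes, c$graph$nodes))
})

test_that("zero tortuosity target yields exactly straight segments", {
  nw <- generate_network(network_spec(tortuosity = 1), seed = 5)
  st <- segment_table(nw$graph)
  expect_true(all(abs(st$tortuosity[!is.na(st$tortuosity)] - 1) < 1e-12))
})

test_that("a pure 3N mix saturates every interior node at valence 3", {
  nw <- generate_network(network_spec(valence_mix = c("3" = 1)), seed = 5)
  tn <- nw$truth$nodes
  expect_true(any(tn$interior))
  expect_true(all(tn$valence[tn$interior] == 3L))
})

test_that("default spec hits its emulation targets on the raw graph", {
  nw <- generate_network(seed = 17)
  st <- segment_table(nw$graph)
  spec <- nw$spec
  expect_lt(abs(median(st$chord_length) / spec$median_chord - 1), 0.10)
  expect_lt(abs(median(st$mean_radius) / spec$radius_median - 1), 0.10)
  expect_lt(abs(median(st$tortuosity, na.rm = TRUE) - spec$tortuosity),
            0.02)
  # graph tables agree with the recorded ground truth record-for-record
  expect_equal(st$chord_length, nw$truth$segments$chord_length,
               tolerance = 1e-9)
  expect_equal(st$tortuosity, nw$truth$segments$tortuosity,
               tolerance = 1e-9)
  nt <- node_table(nw$graph)
  expect_equal(nt$valence, nw$truth$nodes$valence)
  # theta mode near horizontal, as for isotropic orientations
  expect_gt(median(st$theta, na.rm = TRUE), 50)
  expect_lt(median(st$theta, na.rm = TRUE), 70)
})

test_that("valence mix is recovered exactly from the un-voxelized graph", {
  nw <- generate_network(seed = 23)
  nt <- node_table(nw$graph)
  tab_rec <- node_configuration_table(nt)
  tn <- nw$truth$nodes
  v <- tn$valence[tn$valence >= 2]
  for (k in tab_rec$valence) {
    expect_equal(tab_rec$n[tab_rec$valence == k], sum(v == k))
  }
})

test_that("voxelization rasterizes capsules at the stated radius", {
  # a straight beam of radius 4.5 um at 3 um voxels, axis through voxel
  # centers: the distance-transform radius at mid-segment is within one
  # voxel of the true radius
  pl <- rbind(c(13.5, 13.5, 6), c(13.5, 13.5, 36))
  nodes <- tibble::tibble(node_id = 1:2, x = 13.5, y = 13.5, z = c(6, 36),
                          radius = 4.5)
  segs <- tibble::tibble(segment_id = 1L, start_node = 1L, end_node = 2L,
                         polyline = list(pl),
                         point_radii = list(c(4.5, 4.5)))
  g <- spatial_graph(nodes, segs, validate = FALSE)
  bin <- voxelize_network(g, voxel_size = 3, bounds_um = c(30, 30, 42))
  rm <- radius_map(bin)
  mid <- rm[5, 5, 7]
  expect_lt(abs(mid - 4.5), 3)
  # brute-force check: foreground is exactly centers within r of the axis
  idx <- which(bin$mask, arr.ind = TRUE)
  ctr <- (idx - 0.5) * 3
  d_axis <- sqrt((ctr[, 1] - 13.5)^2 + (ctr[, 2] - 13.5)^2)
  expect_true(all(d_axis <= 4.5 + 1e-9 |
                    ctr[, 3] < 6 | ctr[, 3] > 36))
})

test_that("empty graphs and crossing segments voxelize sensibly", {
  empty <- spatial_graph(NULL, NULL, validate = FALSE)
  bin <- voxelize_network(empty, voxel_size = 3, bounds_um = 9)
  expect_false(any(bin$mask))
  # two crossing segments fuse into one connected component
  nodes <- tibble::tibble(node_id = 1:4, x = c(3, 27, 15, 15),
                          y = c(15, 15, 3, 27), z = 15, radius = 3)
  segs <- tibble::tibble(
    segment_id = 1:2, start_node = c(1L, 3L), end_node = c(2L, 4L),
    polyline = list(rbind(c(3, 15, 15), c(27, 15, 15)),
                    rbind(c(15, 3, 15), c(15, 27, 15))),
    point_radii = list(c(3, 3), c(3, 3))
  )
  g <- spatial_graph(nodes, segs, validate = FALSE)
  b2 <- voxelize_network(g, voxel_size = 3, bounds_um = 30)
  expect_equal(max(oracle_label(b2$mask, 26)), 1)
  expect_error(voxelize_network(g, voxel_size = 3, bounds_um = 20),
               "outside")
  expect_warning(
    voxelize_network(
      spatial_graph(nodes, dplyr::mutate(segs,
        point_radii = list(c(1, 1), c(1, 1))), validate = FALSE),
      voxel_size = 3, bounds_um = 30
    ),
    "half a voxel"
  )
})

test_that("recovery report is all-zero when truth is fed back directly", {
  nw <- generate_network(seed = 24)
  st <- segment_table(nw$graph)
  nt <- node_table(nw$graph)
  rep <- recovery_report(nw, st, nt)
  expect_true(all(abs(rep$delta) < 1e-9))
  expect_true(all(rep$pass))
})

test_that("recovery report flags an injected radius fault", {
  nw <- generate_network(seed = 24)
  st <- segment_table(nw$graph)
  st$mean_radius <- st$mean_radius / 2
  rep <- recovery_report(nw, st, node_table(nw$graph))
  expect_false(rep$pass[rep$metric == "median_radius"])
  expect_true(all(rep$pass[rep$metric != "median_radius"]))
})
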