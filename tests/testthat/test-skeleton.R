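test_that("a solid cylinder thins to a single endpoint-to-endpoint path", {
  mask <- solid_cylinder_z(21, 21, 28, 11, 11, 4, 5, 24)
  bin <- binary_volume(mask, 1)
  sk <- skeletonize(bin)
  expect_true(all(which(sk$mask) %in% which(mask)))
  deg <- cpp_neighbor_count_wrap(sk$mask)
  dd <- deg[which(sk$mask)]
  expect_equal(sum(dd == 1), 2)            # exactly two endpoints
  expect_true(all(dd <= 2))                # one-voxel-thick path
  # component count preserved
  expect_equal(max(oracle_label(sk$mask, 26)), max(oracle_label(mask, 26)))
})

test_that("a solid torus thins to a single cycle (cycle rank 1)", {
  mask <- solid_torus(30, 9, 9, 2.05)
  bin <- binary_volume(mask, 1)
  sk <- skeletonize(bin)
  g <- build_spatial_graph(sk, radius_map(bin))
  expect_gte(nrow(g$nodes), 1)
  expect_equal(cycle_rank(g), 1)
  expect_true(any(g$segments$is_loop) || nrow(g$nodes) > 1)
})

test_that("an isolated voxel is its own skeleton", {
  mask <- array(FALSE, c(5, 5, 5)); mask[3, 3, 3] <- TRUE
  sk <- skeletonize(binary_volume(mask, 1))
  expect_equal(sk$mask, mask)
  expect_error(skeletonize(binary_volume(array(FALSE, c(3, 3, 3)), 1)),
               "empty")
})

test_that("radius map matches brute-force background distances", {
  n <- 13
  mask <- solid_ball(n, c(7, 7, 7), 5)
  bin <- binary_volume(mask, 3)
  rm <- radius_map(bin)
  # ball center: radius 5 voxels within one voxel, in um
  expect_lt(abs(rm[7, 7, 7] - 5 * 3), 3)
  d_oracle <- oracle_bg_distance(mask, c(7, 7, 7))
  expect_equal(rm[7, 7, 7], (d_oracle - 0.5) * 3, tolerance = 1e-12)
  expect_true(all(rm[mask] >= 1.5))
  expect_true(all(rm[!mask] == 0))
})

test_that("single-voxel foreground takes the half-voxel floor", {
  mask <- array(FALSE, c(5, 5, 5)); mask[3, 3, 3] <- TRUE
  rm <- radius_map(binary_volume(mask, 3))
  expect_equal(rm[3, 3, 3], 1.5)
})

test_that("an all-foreground volume grows toward the volume center", {
  mask <- array(TRUE, c(9, 9, 9))
  rm <- radius_map(binary_volume(mask, 1))
  expect_gt(rm[5, 5, 5], rm[2, 5, 5])
  expect_gt(rm[5, 5, 5], rm[5, 5, 8])
  # brute-force oracle with virtual background just outside the grid
  expect_equal(rm[5, 5, 5], 5 - 0.5)       # 5 voxels to coord 0 or 10
})

test_that("a plus-shaped skeleton becomes one 4-valent node and 4 spokes", {
  mask <- array(FALSE, c(9, 9, 3))
  mask[2:8, 5, 2] <- TRUE
  mask[5, 2:8, 2] <- TRUE
  g <- build_spatial_graph(binary_volume(mask, 1))
  nt <- node_table(g)
  expect_equal(sort(nt$valence), c(1, 1, 1, 1, 4))
  expect_equal(nrow(g$segments), 4)
})

test_that("cylinder graph has 2 nodes, 1 segment, plausible length", {
  mask <- solid_cylinder_z(21, 21, 28, 11, 11, 4, 5, 24)
  bin <- binary_volume(mask, 1)
  g <- build_spatial_graph(skeletonize(bin), radius_map(bin))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$segments), 1)
  len <- curved_length(g$segments$polyline[[1]])
  expect_gt(len, 10)                       # caps retract by about the radius
  expect_lte(len, 20)
})

test_that("deduplicate merges coincident nodes and repeated segments", {
  g <- plus_graph()
  # duplicate one segment verbatim
  segs <- g$segments
  dup <- segs[1, ]
  dup$segment_id <- 99L
  g2 <- spatial_graph(g$nodes, rbind(segs, dup), validate = FALSE)
  out <- deduplicate(g2)
  expect_equal(nrow(out$segments), 4)
  # reversed polyline duplicates are also caught
  rev_dup <- segs[2, ]
  rev_dup$segment_id <- 98L
  rev_dup$polyline[[1]] <- rev_dup$polyline[[1]][2:1, ]
  rev_dup$start_node <- segs$end_node[2]
  rev_dup$end_node <- segs$start_node[2]
  out2 <- deduplicate(spatial_graph(g$nodes, rbind(segs, rev_dup),
                                    validate = FALSE))
  expect_equal(nrow(out2$segments), 4)
  # coincident nodes merge with union of incidences
  nodes <- g$nodes
  extra <- nodes[1, ]
  extra$node_id <- 50L
  segs3 <- segs
  segs3$start_node[1] <- 50L
  g3 <- spatial_graph(rbind(nodes, extra), segs3, validate = FALSE)
  out3 <- deduplicate(g3)
  expect_equal(nrow(out3$nodes), 5)
  nt <- node_table(out3)
  expect_equal(max(nt$valence), 4)
  # idempotence
  expect_equal(deduplicate(out3)$segments$segment_id,
               out3$segments$segment_id)
})

test_that("deduplicate is independent of segment ordering", {
  g <- random_graph(8, 12, seed = 4)
  segs <- g$segments
  shuffled <- segs[rev(seq_len(nrow(segs))), ]
  a <- deduplicate(spatial_graph(g$nodes, segs, validate = FALSE))
  b <- deduplicate(spatial_graph(g$nodes, shuffled, validate = FALSE))
  expect_equal(sort(a$segments$segment_id), sort(b$segments$segment_id))
})

test_that("spur pruning removes short leaves and splices through nodes", {
  # a long run split by a 3N node carrying one tiny spur
  nodes <- tibble::tibble(
    node_id = 1:4,
    x = c(0, 10, 20, 10), y = c(0, 0, 0, 2), z = 0, radius = 1.5
  )
  seg <- function(id, a, b, pl) tibble::tibble(
    segment_id = id, start_node = a, end_node = b,
    polyline = list(pl), point_radii = list(rep(1.5, nrow(pl)))
  )
  segs <- rbind(
    seg(1L, 1L, 2L, rbind(c(0, 0, 0), c(10, 0, 0))),
    seg(2L, 2L, 3L, rbind(c(10, 0, 0), c(20, 0, 0))),
    seg(3L, 2L, 4L, rbind(c(10, 0, 0), c(10, 2, 0)))  # 2 um spur
  )
  g <- spatial_graph(nodes, segs, validate = FALSE)
  out <- prune_spurs(g, min_length = 4.5)
  expect_equal(nrow(out$segments), 1)      # spur gone, run spliced
  expect_equal(chord_length(out$segments$polyline[[1]]), 20)
  # a long leaf is not a spur
  out2 <- prune_spurs(g, min_length = 1)
  expect_equal(nrow(out2$segments), 3)
})

test_that("polyline smoothing shortens staircases but keeps endpoints", {
  zigzag <- cbind(0:10, rep(c(0, 1), length.out = 11), 0)
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 10), y = c(0, 0),
                          z = 0, radius = 1)
  nodes$y[2] <- zigzag[11, 2]
  segs <- tibble::tibble(segment_id = 1L, start_node = 1L, end_node = 2L,
                         polyline = list(zigzag),
                         point_radii = list(rep(1, 11)))
  g <- spatial_graph(nodes, segs, validate = FALSE)
  sm <- smooth_polylines(g, iterations = 3)
  expect_lt(curved_length(sm$segments$polyline[[1]]),
            curved_length(zigzag))
  expect_equal(sm$segments$polyline[[1]][1, ], zigzag[1, ])
  expect_equal(sm$segments$polyline[[1]][11, ], zigzag[11, ])
})
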