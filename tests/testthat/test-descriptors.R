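test_that("length descriptors follow their geometric definitions", {
  expect_equal(chord_length(rbind(c(0, 0, 0), c(0, 0, 10))), 10)
  expect_equal(chord_length(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 5)
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(chord_length(loop), 0)
  expect_equal(curved_length(rbind(c(0, 0, 0), c(0, 0, 10))), 10)
  expect_equal(curved_length(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 7)
  expect_error(chord_length(matrix(c(0, 0, 0), 1)), "degenerate")
})

test_that("a dense semicircle has curved length pi and tortuosity pi/2", {
  pl <- semicircle_polyline(1, 1000)
  expect_equal(curved_length(pl), pi, tolerance = 1e-4)
  expect_equal(chord_length(pl), 2, tolerance = 1e-12)
  expect_equal(tortuosity(pl), pi / 2, tolerance = 1e-4)
})

test_that("tortuosity is 1 for straight segments, absent for loops", {
  straight <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 0, 0), c(9, 0, 0))
  expect_identical(tortuosity(straight), 1)
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_true(is.na(tortuosity(loop)))
})

test_that("radius, gyration and slenderness arithmetic", {
  expect_equal(segment_mean_radius(c(1.5, 2.5)), 2)
  expect_equal(segment_mean_radius(c(1, 2, 3, 4)), 2.5)
  expect_equal(radius_of_gyration(4), 1)
  expect_equal(radius_of_gyration(0), 0)
  expect_equal(radius_of_gyration(2 * 2.33), 1.165)
  expect_equal(slenderness_ratio(16, 1), 16)
  expect_equal(slenderness_ratio(0, 1), 0)
  # straight segment, L 17.55 and r 2.33 gives roughly the reported 15
  expect_equal(slenderness_ratio(17.55, radius_of_gyration(2 * 2.33)),
               17.55 / 1.165, tolerance = 1e-12)
  expect_gt(slenderness_ratio(17.55, 1.165), 15)
  expect_lt(slenderness_ratio(17.55, 1.165), 15.5)
  expect_error(slenderness_ratio(10, 0), "> 0")
})

test_that("segment direction at a node is the outward unit chord", {
  g <- star_graph(rbind(c(0, 0, 1)), len = 5)
  expect_equal(segment_direction_at_node(g, 1, 1), c(0, 0, 1))
  expect_equal(segment_direction_at_node(g, 1, 2), c(0, 0, -1))
  expect_error(segment_direction_at_node(g, 1, 99), "endpoint|exist")
})

test_that("ideal node geometries give their textbook angles", {
  # coplanar 3N with full rotational symmetry: all pairwise angles 120
  ang <- c(90, 210, 330) * pi / 180
  dirs <- cbind(cos(ang), sin(ang), 0)
  g3 <- star_graph(dirs)
  ita3 <- inter_trabecular_angles(g3, 1)
  expect_equal(length(ita3), 3)
  expect_equal(as.numeric(ita3), rep(120, 3), tolerance = 1e-6)
  # regular tetrahedron: all six pairwise angles 109.47
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  g4 <- star_graph(tet)
  ita4 <- inter_trabecular_angles(g4, 1)
  expect_equal(length(ita4), 6)
  expect_equal(as.numeric(ita4), rep(109.4712206, 6), tolerance = 1e-6)
  expect_equal(round(mean(ita4), 1), 109.5)
  # collinear opposite directions meet at 180
  g2 <- star_graph(rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(as.numeric(inter_trabecular_angles(g2, 1)), 180)
})

test_that("pairwise angle lists have length n(n-1)/2 and drop zero chords", {
  g <- plus_graph()
  expect_equal(length(inter_trabecular_angles(g, 1)), 4 * 3 / 2)
  expect_equal(length(inter_trabecular_angles(g, 2)), 0)  # valence 1
})

test_that("node configuration table reports counts, fractions and modes", {
  g <- plus_graph()
  tab <- node_configuration_table(g)
  # leaves are excluded; the single 4N node remains
  expect_equal(tab$valence, 4L)
  expect_equal(tab$n, 1L)
  expect_equal(tab$fraction_pct, 100)
  expect_equal(tab$mode_ita, 92.5)   # 90-degree angles fall in bin [90, 95)
  empty <- node_configuration_table(
    spatial_graph(NULL, NULL, validate = FALSE)
  )
  expect_equal(nrow(empty), 0)
})

test_that("theta and phi implement the plate orientation conventions", {
  seg <- function(v) rbind(c(0, 0, 0), v)
  expect_equal(theta(seg(c(0, 0, 1))), 0)
  expect_equal(theta(seg(c(1, 0, 0))), 90)
  expect_equal(theta(seg(c(1, 0, 1))), 45)
  expect_equal(theta(seg(c(0, 0, -1))), 0)      # folded into [0, 90]
  expect_equal(phi(seg(c(1, 0, 0))), 0)
  expect_equal(phi(seg(c(0, 1, 0))), 90)
  expect_true(is.na(phi(seg(c(0, 0, 1)))))
  # chord sign fixed by orienting to non-negative z
  expect_equal(phi(seg(c(-1, 0, -1))), 0)
  expect_true(is.na(theta(seg(c(0, 0, 0)))))
})

test_that("theta/phi reconstruct the oriented chord within 1e-9", {
  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    if (v[3] < 0) v <- -v                  # orientation convention
    pl <- rbind(c(0, 0, 0), v)
    th <- theta(pl) * pi / 180
    ph <- phi(pl)
    if (is.na(ph)) next
    ph <- ph * pi / 180
    rec <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    expect_lt(max(abs(rec - v)), 1e-9)
  }
})

test_that("curved length never falls below chord length on random graphs", {
  for (s in 1:10) {
    g <- random_graph(8, 14, seed = s)
    st <- segment_table(g)
    expect_true(all(st$curved_length >= st$chord_length - 1e-9))
  }
})

test_that("angle lists match the law-of-cosines oracle on random graphs", {
  for (s in 1:20) {
    g <- random_graph(7, 12, seed = s)
    for (nid in g$nodes$node_id) {
      got <- sort(as.numeric(inter_trabecular_angles(g, nid)))
      want <- sort(oracle_node_angles(g, nid))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("pairwise counts satisfy the valence combinatorics", {
  for (s in 1:10) {
    g <- random_graph(8, 16, seed = 100 + s)
    nt <- node_table(g)
    ok <- vapply(seq_len(nrow(nt)), function(i) {
      length(nt$ita[[i]]) + nt$dropped_pairs[i] ==
        nt$valence[i] * (nt$valence[i] - 1) / 2
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("angles are invariant under rigid motions", {
  g <- random_graph(8, 14, seed = 42)
  base <- lapply(g$nodes$node_id, function(n) {
    sort(as.numeric(inter_trabecular_angles(g, n)))
  })
  set.seed(9)
  for (rep in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Rx
    shift <- runif(3, -20, 20)
    nodes <- g$nodes
    xyz <- t(R %*% t(as.matrix(nodes[, c("x", "y", "z")]))) +
      matrix(shift, nrow(nodes), 3, byrow = TRUE)
    nodes$x <- xyz[, 1]; nodes$y <- xyz[, 2]; nodes$z <- xyz[, 3]
    segs <- g$segments
    segs$polyline <- lapply(segs$polyline, function(p) {
      t(R %*% t(p)) + matrix(shift, nrow(p), 3, byrow = TRUE)
    })
    gt <- spatial_graph(nodes, segs, validate = FALSE)
    moved <- lapply(gt$nodes$node_id, function(n) {
      sort(as.numeric(inter_trabecular_angles(gt, n)))
    })
    for (i in seq_along(base)) {
      expect_equal(moved[[i]], base[[i]], tolerance = 1e-9)
    }
  }
})

test_that("summaries report median, unscaled MAD, min, max and N", {
  st <- tibble::tibble(chord_length = c(1, 2, 3))
  s <- summarize_descriptors(st, variables = "chord_length")
  expect_equal(s$median, 2)
  expect_equal(s$mad, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$n, 3L)
  s1 <- summarize_descriptors(tibble::tibble(chord_length = 5),
                              variables = "chord_length")
  expect_equal(s1$mad, 0)
  sc <- summarize_descriptors(tibble::tibble(chord_length = rep(1.5, 7)),
                              variables = "chord_length")
  expect_equal(sc$median, 1.5)
  expect_equal(sc$mad, 0)
})

test_that("segment_table excludes loops from orientation, not from radii", {
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 5), y = 0, z = 0,
                          radius = 2)
  loop_pl <- rbind(c(0, 0, 0), c(1, 1, 0), c(0, 2, 0), c(0, 0, 0))
  segs <- tibble::tibble(
    segment_id = 1:2, start_node = c(1L, 1L), end_node = c(2L, 1L),
    polyline = list(rbind(c(0, 0, 0), c(5, 0, 0)), loop_pl),
    point_radii = list(c(2, 2), rep(2, 4))
  )
  st <- segment_table(spatial_graph(nodes, segs, validate = FALSE))
  expect_true(is.na(st$tortuosity[2]))
  expect_true(is.na(st$theta[2]))
  expect_true(is.na(st$phi[2]))
  expect_equal(st$mean_radius[2], 2)
  expect_gt(st$curved_length[2], 0)
  s <- summarize_descriptors(st)
  expect_equal(s$n[s$variable == "tortuosity"], 1L)
  expect_equal(s$n[s$variable == "curved_length"], 2L)
})
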