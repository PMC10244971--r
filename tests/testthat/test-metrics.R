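test_that("monolayer length sums the L1 centroid chain", {
  tis <- make_l1_row(n = 5, size = 6)
  ml <- monolayer_length(tis)
  expect_equal(ml$length_um, 24, tolerance = 1e-9)   # 4 gaps x 6 µm
  expect_false(ml$break_detected)
  expect_length(ml$chain, 5)
})

test_that("monolayer length approaches the arc length on a semicircle", {
  R <- 40; n <- 24
  ang <- seq(pi, 0, length.out = n)
  nodes <- NULL; off <- 0L
  for (i in seq_len(n)) {
    cen <- R * c(cos(ang[i]), sin(ang[i]))
    ni <- make_rect_cell(w = 2, h = 2, cell_id = i, origin = cen - 1,
                         id_offset = off, nc = 0)
    off <- max(ni$node_id)
    nodes <- rbind(nodes, ni)
  }
  tis <- build_tissue(nodes, cells_frame(seq_len(n), layer = "L1"))
  # adhere consecutive cells explicitly (abstract fixture)
  adh <- t(vapply(seq_len(n - 1), function(i)
    c(tis$cells[[as.character(i)]]$wall[1], tis$cells[[as.character(i + 1)]]$wall[1]),
    integer(2)))
  tis$adhesion <- cbind(pmin(adh[, 1], adh[, 2]), pmax(adh[, 1], adh[, 2]))
  ml <- monolayer_length(tis)
  expect_equal(ml$length_um, pi * R, tolerance = 0.01 * pi * R)
  expect_false(ml$break_detected)
})

test_that("an expelled L1 cell breaks the monolayer chain", {
  tis <- make_l1_row(n = 5, size = 6)
  # push the middle cell a full diameter below the layer line and let its
  # neighbours bond directly across the hole
  rows <- samsce:::node_rows(tis, c(tis$cells[["3"]]$wall, tis$cells[["3"]]$cyto))
  tis$pos[rows, 2] <- tis$pos[rows, 2] - 6
  w2 <- tis$cells[["2"]]$wall[1]; w4 <- tis$cells[["4"]]$wall[1]
  tis$adhesion <- rbind(tis$adhesion, c(min(w2, w4), max(w2, w4)))
  tis$adhesion <- tis$adhesion[order(tis$adhesion[, 1], tis$adhesion[, 2]), ]
  ml <- monolayer_length(tis)
  expect_true(ml$break_detected)
})

test_that("relative curvature is 2 for a semicircular cap and 0 when flat", {
  # tissue whose L1 outer wall samples a semicircle of radius R
  semicircle_tissue <- function(R) {
    n <- 12
    ang <- seq(pi, 0, length.out = n + 1)
    nodes <- NULL; off <- 0L
    for (i in seq_len(n)) {
      a0 <- ang[i]; a1 <- ang[i + 1]
      outer0 <- R * c(cos(a0), sin(a0)); outer1 <- R * c(cos(a1), sin(a1))
      inner1 <- 0.8 * outer1; inner0 <- 0.8 * outer0
      ring <- rbind(outer0, outer1, inner1, inner0)
      ni <- data.frame(node_id = off + 1:5, cell_id = i,
                       role = c(rep("wall", 4), "cytoplasm"),
                       ring_index = c(1:4, NA),
                       x = c(ring[, 1], mean(ring[, 1])),
                       y = c(ring[, 2], mean(ring[, 2])), is_boundary = FALSE)
      off <- off + 5L
      nodes <- rbind(nodes, ni)
    }
    build_tissue(nodes, cells_frame(seq_len(n), layer = "L1"))
  }
  for (R in c(10, 57)) {                       # scale invariance
    tis <- semicircle_tissue(R)
    expect_equal(relative_curvature(tis), 2.0, tolerance = 0.02)
  }
  # rigid translation invariance
  tis <- semicircle_tissue(20)
  tis$pos <- sweep(tis$pos, 2, c(13, -7), "+")
  expect_equal(relative_curvature(tis), 2.0, tolerance = 0.02)
  # flat top surface: curvature ~ 0
  flat <- make_l1_row(n = 6, size = 6)
  expect_lt(abs(relative_curvature(flat, cap_fraction = 0)), 0.05)
})

test_that("relative curvature matches chord geometry on a 90-degree arc", {
  # arc subtending 90 degrees whose chord is the tissue width:
  # after width-1 rescaling 1/R = 2 sin(45 deg)
  R <- 30; n <- 12
  ang <- seq(3 * pi / 4, pi / 4, length.out = n + 1)
  nodes <- NULL; off <- 0L
  for (i in seq_len(n)) {
    a0 <- ang[i]; a1 <- ang[i + 1]
    ring <- rbind(R * c(cos(a0), sin(a0)), R * c(cos(a1), sin(a1)),
                  0.9 * R * c(cos(a1), sin(a1)), 0.9 * R * c(cos(a0), sin(a0)))
    ni <- data.frame(node_id = off + 1:4, cell_id = i, role = "wall",
                     ring_index = 1:4, x = ring[, 1], y = ring[, 2],
                     is_boundary = FALSE)
    off <- off + 4L
    nodes <- rbind(nodes, ni)
  }
  tis <- build_tissue(nodes, cells_frame(seq_len(n), layer = "L1"))
  expect_equal(relative_curvature(tis, cap_fraction = 0), 2 * sin(pi / 4),
               tolerance = 0.03)
})

test_that("aspect ratio uses principal-axis extents", {
  # near-regular ring: ratio ~ 1
  tis <- make_round_cell(nw = 20)
  expect_equal(aspect_ratio(1L, tis), 1, tolerance = 0.05)
  # 2 x 1 rectangle: exactly 2, and rotation invariant
  rect <- make_rect_cell(w = 2, h = 1, per_side = 3)
  P <- as.matrix(rect[rect$role == "wall", c("x", "y")])
  expect_equal(aspect_ratio(P), 2, tolerance = 1e-9)
  th <- 0.61
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(aspect_ratio(P %*% Rm), 2, tolerance = 1e-9)
  # ellipse a=3, b=1 sampled at 40 nodes: ratio 3
  ang <- 2 * pi * (0:39) / 40
  E <- cbind(3 * cos(ang), sin(ang))
  expect_equal(aspect_ratio(E), 3, tolerance = 0.1)
  expect_error(aspect_ratio(cbind(0:3, 0)), "degenerate")
})

test_that("percent periclinal classifies division planes against the radial", {
  log1 <- data.frame(mode = "in_plane", layer = "apical_corpus",
                     normal_x = c(0, 0, 0, 1), normal_y = c(1, 1, 1, 0),
                     radial_x = 0, radial_y = 1)
  expect_equal(percent_periclinal(log1, "apical_corpus"), 75)
  # exact 45-degree ties count as anticlinal
  s2 <- 1 / sqrt(2)
  log2 <- data.frame(mode = "in_plane", layer = "apical_corpus",
                     normal_x = s2, normal_y = s2, radial_x = 0, radial_y = 1)
  expect_equal(percent_periclinal(log2, "apical_corpus"), 0)
  # empty region flagged
  expect_warning(pp <- percent_periclinal(log1, "basal_corpus"), "undefined")
  expect_true(is.na(pp))
  # uniformly random plane angles: 50% within a binomial interval
  n <- 4000
  a <- vapply(seq_len(n), function(k)
    stream_uniform(5, 1, 1, k) * pi / 2, numeric(1))
  log3 <- data.frame(mode = "in_plane", layer = "apical_corpus",
                     normal_x = sin(a), normal_y = cos(a),
                     radial_x = 0, radial_y = 1)
  expect_lt(abs(percent_periclinal(log3, "apical_corpus") - 50),
            300 * sqrt(0.25 / n))
})

test_that("Voronoi adjacency matches brute-force Delaunay on random points", {
  # oracle: i~j iff some circumcircle through i,j and a third point is empty
  delaunay_oracle <- function(P) {
    n <- nrow(P)
    pairs <- matrix(integer(0), 0, 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        ax <- P[i, 1] - P[k, 1]; ay <- P[i, 2] - P[k, 2]
        bx <- P[j, 1] - P[k, 1]; by <- P[j, 2] - P[k, 2]
        d <- 2 * (ax * by - ay * bx)
        if (abs(d) < 1e-12) next
        ux <- (by * (ax^2 + ay^2) - ay * (bx^2 + by^2)) / d
        uy <- (ax * (bx^2 + by^2) - bx * (ax^2 + ay^2)) / d
        cen <- c(ux + P[k, 1], uy + P[k, 2])
        r2 <- sum((P[i, ] - cen)^2)
        d2 <- rowSums(sweep(P, 2, cen)^2)
        if (all(d2[-c(i, j, k)] > r2 - 1e-9)) { ok <- TRUE; break }
      }
      if (ok) pairs <- rbind(pairs, c(i, j))
    }
    pairs
  }
  set.seed(11)
  P <- cbind(runif(9) * 10, runif(9) * 10)
  nb <- voronoi_neighbors(P)
  got <- cbind(nb$i, nb$j)
  want <- delaunay_oracle(P)
  expect_equal(got[order(got[, 1], got[, 2]), ],
               want[order(want[, 1], want[, 2]), ])
})

test_that("the adhesion graph prunes lattice degeneracies and long edges", {
  # 3 cells in a triangle: complete graph K3
  tri <- rbind(c(0, 0), c(4, 0), c(2, 3))
  g3 <- adhesion_graph(tri)
  expect_equal(igraph::ecount(g3), 3)
  # 3x3 unit lattice: diagonal (cocircular) ridges are degenerate, interior
  # cell keeps degree 4
  latt <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  gl <- adhesion_graph(latt, alpha = 1.5)
  centre <- which(latt[, 1] == 1 & latt[, 2] == 1)
  expect_equal(igraph::degree(gl)[centre], 4)
  # generated tissue: connected, with edges pruned to near neighbours
  tis <- small_tissue(relax_steps = 100L)
  gt <- adhesion_graph(tis)
  expect_true(igraph::is_connected(gt))
  cc <- cell_centroids(tis)
  el <- igraph::as_edgelist(gt, names = FALSE)
  d <- sqrt(rowSums((cbind(cc$x, cc$y)[el[, 1], ] - cbind(cc$x, cc$y)[el[, 2], ])^2))
  expect_true(all(d <= 2 * mean_cell_diameter(tis) + 1e-9))
})

test_that("centralities respect symmetry and the large-beta limit", {
  C5 <- igraph::make_ring(5)
  ct <- centralities(C5, beta = 1)
  expect_equal(ct$pagerank, rep(0.2, 5), tolerance = 1e-9)
  expect_equal(sum(ct$pagerank), 1, tolerance = 1e-9)
  expect_lt(diff(range(ct$rspb)), 1e-9)
  expect_lt(diff(range(ct$rspbn)), 1e-9)
  K3 <- igraph::make_full_graph(3)
  expect_equal(centralities(K3)$pagerank, rep(1 / 3, 3), tolerance = 1e-9)
  # path graph, large beta: RSPB ordering matches classical shortest-path
  # betweenness (independent oracle), centre node maximal
  P5 <- igraph::make_graph(~ 1 - 2 - 3 - 4 - 5)
  ct5 <- centralities(P5, beta = 8)
  bw <- igraph::betweenness(P5)
  expect_equal(order(ct5$rspb), order(bw))
  expect_equal(which.max(ct5$rspb), 3L)
  expect_equal(which.max(ct5$rspbn), 3L)
  # disconnected input: per-component with a warning
  g2 <- igraph::disjoint_union(igraph::make_ring(4), igraph::make_ring(3))
  expect_warning(cd <- centralities(g2), "disconnected")
  expect_true(all(is.finite(cd$rspb)))
})
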