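test_that("cycle length is a bounded decreasing function of WUS", {
  gp <- growth_params()
  expect_equal(cycle_length_hours(0, gp), gp$h_max)
  expect_equal(cycle_length_hours(10, gp), gp$h_min)
  w <- seq(0, 2, by = 0.1)
  expect_true(all(diff(cycle_length_hours(w, gp)) <= 0))
})

test_that("a full cycle inserts the configured cytoplasm nodes and flags division", {
  gp <- growth_params(nodes_per_cycle = 4L, inplane_terminal_area = 1e6)
  tis <- make_round_cell(nc = 3)
  tis$cells[["1"]]$wus <- 0                    # slowest cycle: h_max hours
  n0 <- length(tis$cells[["1"]]$cyto)
  tis <- advance_cycle(tis, 1L, dt_hours = gp$h_max, gp = gp)
  expect_equal(tis$cells[["1"]]$cp, 1)
  expect_equal(length(tis$cells[["1"]]$cyto), n0 + 4L)
  expect_silent(validate_tissue(tis))
  # doubling the cycle rate (halving length via WUS) halves time to division
  t1 <- make_round_cell(nc = 3); t1$cells[["1"]]$wus <- 0
  gp2 <- growth_params(h_min = 10, h_max = 40, wus_slope = 20,
                       inplane_terminal_area = 1e6)
  t2 <- make_round_cell(nc = 3); t2$cells[["1"]]$wus <- 1   # 40 - 20 = 20 h
  steps_to_divide <- function(tis, gp) {
    n <- 0
    while (tis$cells[["1"]]$cp < 1) {
      tis <- advance_cycle(tis, 1L, dt_hours = 1, gp = gp); n <- n + 1
    }
    n
  }
  expect_equal(steps_to_divide(t1, gp2), 2 * steps_to_divide(t2, gp2))
})

test_that("terminal area stops cytoplasm insertion but not the cycle", {
  gp <- growth_params(nodes_per_cycle = 4L, inplane_terminal_area = 1)
  tis <- make_round_cell(nc = 3)
  tis$cells[["1"]]$target_area <- 1            # already past terminal size
  n0 <- length(tis$cells[["1"]]$cyto)
  tis <- advance_cycle(tis, 1L, dt_hours = 1000, gp = gp)
  expect_equal(length(tis$cells[["1"]]$cyto), n0)
  expect_equal(tis$cells[["1"]]$cp, 1)
})

test_that("over-stretched wall edges are bisected at their midpoints", {
  tis <- make_rect_cell(nc = 1) |> build_tissue(cells_frame(1L))
  # rest-length edges: nothing happens
  t0 <- insert_wall_nodes(tis, 1L, threshold = 0.5, l_eq = 1)
  expect_equal(length(t0$cells[["1"]]$wall), 4L)
  # exactly one edge stretched to 2.2 l_eq: one node at its midpoint
  pent <- data.frame(node_id = 1:6, cell_id = 1L,
                     role = c(rep("wall", 5), "cytoplasm"),
                     ring_index = c(1:5, NA),
                     x = c(0, 2.2, 2.2, 1, 0, 1), y = c(0, 0, 1, 1.2, 1, 0.6),
                     is_boundary = FALSE)
  t1 <- build_tissue(pent, cells_frame(1L))
  t1 <- insert_wall_nodes(t1, 1L, threshold = 0.5, l_eq = 1)
  expect_equal(length(t1$cells[["1"]]$wall), 6L)
  new_id <- setdiff(t1$cells[["1"]]$wall, 1:5)
  expect_equal(unname(t1$pos[samsce:::node_rows(t1, new_id), ]), c(1.1, 0),
               tolerance = 1e-12)
  expect_equal(t1$cells[["1"]]$wall[1:3], c(1L, new_id, 2L))  # ring order kept
  expect_silent(validate_tissue(t1))
  # repeated application reaches a fixed point on an inflated ring
  t2 <- tis
  t2$pos[t2$role == 0L, ] <- t2$pos[t2$role == 0L, ] * 4
  t2 <- insert_wall_nodes(t2, 1L, threshold = 0.5, l_eq = 1)
  t3 <- insert_wall_nodes(t2, 1L, threshold = 0.5, l_eq = 1)
  expect_identical(length(t3$cells[["1"]]$wall), length(t2$cells[["1"]]$wall))
})

test_that("polarization sampling recovers the calibrated frequencies", {
  gp <- growth_params()
  draw_freq <- function(layer, zone, n) {
    tis <- make_round_cell(layer = layer)
    tis$cells[["1"]]$zone <- zone
    tis$seed <- 2024L
    hits <- 0
    for (k in seq_len(n)) {
      tis <- sample_polarization(tis, 1L, gp, variant = "p3d")
      if (tis$cells[["1"]]$polarization == "out_of_plane") hits <- hits + 1
    }
    hits / n
  }
  n <- 5000
  for (case in list(list("L1", "central", 0.474),
                    list("apical_corpus", "peripheral", 0.290),
                    list("basal_corpus", "central", 0.105))) {
    p0 <- case[[3]]
    f <- draw_freq(case[[1]], case[[2]], n)
    expect_lt(abs(f - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  # the 2D variant never polarizes out of the plane
  tis <- make_round_cell(layer = "L1")
  for (k in 1:200) {
    tis <- sample_polarization(tis, 1L, gp, variant = "2d")
    expect_false(tis$cells[["1"]]$polarization == "out_of_plane")
  }
})

test_that("polarization translates into wall stiffness and target area", {
  gp <- growth_params()
  p <- potential_params()
  tis <- make_round_cell()
  tis$apex <- c(0, 30)                          # radial direction is -y here
  tis$cells[["1"]]$polarization <- "out_of_plane"
  tis <- apply_polarization(tis, 1L, gp, p)
  cl <- tis$cells[["1"]]
  expect_true(all(cl$edge_k == p$extensibility$k))   # uniform walls
  expect_equal(cl$target_area, 0.75 * gp$inplane_terminal_area)
  tis$cells[["1"]]$polarization <- "in_plane_anticlinal"
  tis <- apply_polarization(tis, 1L, gp, p)
  cl <- tis$cells[["1"]]
  expect_equal(cl$target_area, gp$inplane_terminal_area)
  soft <- cl$edge_k < p$extensibility$k
  expect_gt(sum(soft), 0); expect_lt(sum(soft), length(soft))
  # softened edges run along the preferred (radial = vertical) axis
  rows <- samsce:::node_rows(tis, cl$wall)
  P <- tis$pos[rows, ]
  m <- nrow(P); ed <- P[c(2:m, 1), ] - P
  ca <- abs(ed[, 2]) / sqrt(rowSums(ed^2))
  expect_true(all(ca[soft] > cos(pi / 4)))
})

test_that("an anticlinally polarized cell elongates along the radial axis", {
  gp <- growth_params(anisotropy_factor = 0.1)
  p <- potential_params()
  tis <- make_round_cell()
  tis$apex <- c(0, 30)
  tis$cells[["1"]]$polarization <- "in_plane_anticlinal"
  tis <- apply_polarization(tis, 1L, gp, p)
  tis <- relax_tissue(tis, p, nsteps = 10000)
  P <- cell_polygon(1L, tis)
  pc <- sweep(P, 2, colMeans(P))
  ax <- eigen(crossprod(pc), symmetric = TRUE)$vectors[, 1]
  ang <- acos(min(1, abs(ax[2])))               # angle to the vertical/radial
  expect_lt(ang, pi / 6)                        # within 30 degrees
  expect_gt(aspect_ratio(1L, tis), 1.05)
})

test_that("division planes follow the layer-specific rules", {
  gp <- growth_params()
  p <- potential_params()
  # tunica: anticlinal, normal near the layer tangent (horizontal here)
  tis <- make_round_cell(layer = "L1")
  tis$apex <- c(0, 30)                          # radial = vertical
  tis$cells[["1"]]$cp <- 1
  pl <- choose_division_plane(tis, 1L, gp, p)
  expect_lt(acos(min(1, abs(pl$normal[1]))), 15 * pi / 180)
  # basal corpus with all weight periclinal: normal along the radial axis
  gp0 <- growth_params(anti_base = 0, anti_wus = 0, peri_base = 1, peri_ck = 0)
  tb <- make_round_cell(layer = "basal_corpus")
  tb$apex <- c(0, 30)
  tb$cells[["1"]]$cp <- 1
  pl <- choose_division_plane(tb, 1L, gp0, p)
  expect_lt(acos(min(1, abs(pl$normal[2]))), 1e-6)
  # apical corpus: perpendicular to the maximal-tension direction
  ta <- make_round_cell(layer = "apical_corpus")
  ta$apex <- c(0, 30)
  rows <- which(ta$role == 0L)
  ta$pos[rows, 1] <- ta$pos[rows, 1] * 1.6      # pre-stretched along x
  ta$cells[["1"]]$cp <- 1
  pl <- choose_division_plane(ta, 1L, gp, p)
  expect_lt(acos(min(1, abs(pl$normal[1]))), 15 * pi / 180)
  # boundary cells never divide; tiny cells defer
  tbnd <- make_round_cell(layer = "boundary_cell")
  expect_error(choose_division_plane(tbnd, 1L, gp, p), "never divide")
  tsm <- make_round_cell(r0 = 0.5)
  tsm$cells[["1"]]$cp <- 1
  expect_warning(pl2 <- choose_division_plane(tsm, 1L, gp, p), "deferred")
  expect_null(pl2)
})

test_that("in-plane division adds one cell and splits area evenly", {
  gp <- growth_params()
  p <- potential_params()
  tis <- make_round_cell(nw = 24, nc = 6)
  tis$apex <- c(0, 30)
  a0 <- abs(polygon_area(cell_polygon(1L, tis)))
  plane <- list(point = c(0, 0), normal = c(1, 0))
  tis2 <- execute_division(tis, 1L, plane, gp, p, variant = "p3d")
  expect_length(tis2$cells, 2)
  expect_null(tis2$cells[["1"]])                # mother id retired
  ids <- names(tis2$cells)
  areas <- vapply(ids, function(i)
    abs(polygon_area(cell_polygon(as.integer(i), tis2))), numeric(1))
  expect_equal(unname(areas[1] / sum(areas)), 0.5, tolerance = 0.01)
  expect_silent(validate_tissue(tis2))
  for (i in ids) {
    expect_equal(tis2$cells[[i]]$cp, 0)
    expect_equal(tis2$cells[[i]]$parent, 1L)    # lineage
    expect_gt(length(tis2$cells[[i]]$cyto), 0)
  }
  # the two fresh wall chains adhere to each other
  expect_gt(nrow(tis2$adhesion), 0)
  expect_equal(nrow(tis2$division_log), 1)
  expect_equal(tis2$division_log$mode, "in_plane")
})

test_that("out-of-plane division keeps the cell and sheds cytoplasm", {
  gp <- growth_params(outplane_area_factor = 0.75)
  p <- potential_params()
  tis <- make_round_cell(nc = 8, layer = "apical_corpus")
  tis$apex <- c(0, 30)
  tis$cells[["1"]]$polarization <- "out_of_plane"
  tis$cells[["1"]]$cp <- 1
  tis2 <- execute_division(tis, 1L, NULL, gp, p, variant = "p3d")
  expect_length(tis2$cells, 1)                  # cell count unchanged
  expect_equal(length(tis2$cells[["1"]]$cyto), 6L)   # round(0.75 * 8)
  expect_equal(tis2$cells[["1"]]$cp, 0)
  expect_equal(tis2$division_log$mode, "out_of_plane")
  expect_silent(validate_tissue(tis2))
})

test_that("L1 daughters inherit the clonal layer label", {
  gp <- growth_params()
  p <- potential_params()
  tis <- make_round_cell(nw = 24, nc = 4, layer = "L1")
  tis$apex <- c(0, 30)
  plane <- choose_division_plane(tis, 1L, gp, p)
  tis2 <- execute_division(tis, 1L, plane, gp, p, variant = "2d")
  expect_true(all(vapply(tis2$cells, `[[`, character(1), "layer") == "L1"))
})
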