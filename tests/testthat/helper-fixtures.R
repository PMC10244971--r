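# Fixtures are built in code; nothing is read from disk.

# one axis-aligned rectangular cell with nodes at the corners (and optionally
# subdivided edges), plus nc cytoplasm nodes near the centre
make_rect_cell <- function(w = 1, h = 1, nc = 1, per_side = 1, origin = c(0, 0),
                           cell_id = 1L, layer = "apical_corpus",
                           id_offset = 0L, clockwise = FALSE) {
  corners <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  ring <- matrix(numeric(0), 0, 2)
  for (k in 1:4) {
    p0 <- corners[k, ]; p1 <- corners[if (k == 4) 1 else k + 1, ]
    tt <- (seq_len(per_side) - 1) / per_side
    ring <- rbind(ring, t(vapply(tt, function(f) p0 + f * (p1 - p0), numeric(2))))
  }
  if (clockwise) ring <- ring[rev(seq_len(nrow(ring))), ]
  ring <- sweep(ring, 2, origin, "+")
  cen <- origin + c(w, h) / 2
  cy <- t(vapply(seq_len(nc), function(q)
    cen + 0.15 * min(w, h) * c(cos(2.4 * q), sin(2.4 * q)), numeric(2)))
  m <- nrow(ring)
  nodes <- data.frame(
    node_id = id_offset + seq_len(m + nc), cell_id = cell_id,
    role = c(rep("wall", m), rep("cytoplasm", nc)),
    ring_index = c(seq_len(m), rep(NA_integer_, nc)),
    x = c(ring[, 1], cy[, 1]), y = c(ring[, 2], cy[, 2]),
    is_boundary = FALSE)
  nodes
}

cells_frame <- function(ids, layer = "apical_corpus", wus = 0, ck = 0, cp = 0) {
  data.frame(cell_id = ids, layer = layer, zone = "central",
             polarization = "in_plane_anticlinal", wus = wus, ck = ck,
             cycle_progress = cp)
}

# two abutting unit-square cells sharing the x = 1 wall line
make_two_cell_tissue <- function(per_side = 3, gap = 0.1) {
  n1 <- make_rect_cell(per_side = per_side, cell_id = 1L)
  n2 <- make_rect_cell(per_side = per_side, cell_id = 2L,
                       origin = c(1 + gap, 0), id_offset = max(n1$node_id))
  build_tissue(rbind(n1, n2), cells_frame(1:2))
}

# one round nearly-relaxed cell
make_round_cell <- function(r0 = 3, nw = 18, nc = 6, layer = "apical_corpus") {
  ang <- 2 * pi * (seq_len(nw) - 1) / nw
  ring <- cbind(r0 * cos(ang), r0 * sin(ang))
  cy <- cbind(0.3 * r0 * cos(2.4 * seq_len(nc)), 0.3 * r0 * sin(2.4 * seq_len(nc)))
  nodes <- data.frame(
    node_id = seq_len(nw + nc), cell_id = 1L,
    role = c(rep("wall", nw), rep("cytoplasm", nc)),
    ring_index = c(seq_len(nw), rep(NA_integer_, nc)),
    x = c(ring[, 1], cy[, 1]), y = c(ring[, 2], cy[, 2]), is_boundary = FALSE)
  build_tissue(nodes, cells_frame(1L, layer = layer))
}

# a row of touching square cells along the x axis, all L1, with adhesion
make_l1_row <- function(n = 5, size = 6, gap = 0.2) {
  nodes <- NULL; off <- 0L
  for (i in seq_len(n)) {
    ni <- make_rect_cell(w = size - gap, h = size - gap, per_side = 4,
                         cell_id = i, origin = c((i - 1) * size, 0),
                         id_offset = off)
    off <- max(ni$node_id)
    nodes <- rbind(nodes, ni)
  }
  tis <- build_tissue(nodes, cells_frame(seq_len(n), layer = "L1"))
  refresh_adhesion(tis, cutoff = 1.0)
}

# small generated tissue for integration-style tests
small_tissue <- function(seed = 7, variant = "p3d", gp = growth_params(),
                         relax_steps = 200L) {
  suppressWarnings(generate_initial_tissue(
    n_columns = 5, corpus_rows = 1, seed = seed, variant = variant, gp = gp,
    relax_steps = relax_steps))
}

# central finite-difference gradient of a scalar field f(x) for 2-vectors
fd_grad <- function(f, x, h = 1e-6) {
  vapply(1:2, function(k) {
    e <- c(0, 0); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
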