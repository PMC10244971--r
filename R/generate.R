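# Synthetic initial tissue: a dome section with single-cell L1 and L2
# monolayers over a corpus block, flanked by non-dividing boundary-cell
# columns, standing on a bottom row with 10x damping. The construction is
# a documented stand-in for experimentally derived initial conditions and
# is validated by a relaxation smoke test (no ring self-intersection after
# mechanics-only relaxation).

#' Generate a dome-section initial tissue
#'
#' Builds `n_columns` interior cell columns plus one boundary column on
#' each flank. Rows, bottom to top: one bottom corpus row (damping x10),
#' `corpus_rows` corpus rows, then the L2 and L1 monolayers. The top
#' follows an elliptical dome profile. Every cell is a closed wall ring
#' with interior cytoplasm nodes; layers, zones, signal concentrations,
#' polarizations and boundary flags are assigned, and adhesion is paired.
#' Deterministic given `seed`.
#'
#' @param n_columns interior columns (>= 5).
#' @param corpus_rows corpus rows between the bottom row and L2.
#' @param cell_size nominal cell edge length (µm).
#' @param seed integer seed driving all of the tissue's random streams.
#' @param variant `"p3d"` or `"2d"` (controls the polarization draw).
#' @param params,gp,sp mechanical, growth and signalling parameter sets.
#' @param dome_rise apex rise as a fraction of the tissue half-width.
#' @param cyto_per_cell initial cytoplasm nodes per cell.
#' @param wall_margin inset of each cell's wall from the shared cell
#'   boundary (µm); adhesion spans the resulting gap.
#' @param relax_steps mechanics-only relaxation steps applied before the
#'   tissue is returned, so simulations start near mechanical equilibrium.
#' @param cell_aspect width/height ratio of the generated cells; the mild
#'   default widening compensates the lateral confinement of the flank
#'   columns so that relaxed corpus cells start mechanically isotropic.
#' @return an `sce_tissue`.
#' @export
generate_initial_tissue <- function(n_columns = 9, corpus_rows = 2,
                                    cell_size = 6, seed = 1L,
                                    variant = "p3d",
                                    params = potential_params(),
                                    gp = growth_params(),
                                    sp = signal_params(),
                                    dome_rise = 0.15, cyto_per_cell = 6,
                                    wall_margin = 0.25, relax_steps = 500L,
                                    cell_aspect = 1.15) {
  if (n_columns < 5) stop("need at least 5 interior columns")
  n_rows <- corpus_rows + 3L
  if (cell_size < 4 * params$extensibility$l_eq)
    stop("geometry too small: cells cannot fit wall rings at this l_eq")
  d <- cell_size
  ncol_tot <- n_columns + 2L
  width <- ncol_tot * d
  Xw <- width / 2
  H0 <- n_rows * d / cell_aspect
  A <- dome_rise * Xw
  hfun <- function(x) H0 + A * sqrt(pmax(0, 1 - (x / (1.02 * Xw))^2))
  xedges <- seq(-Xw, Xw, length.out = ncol_tot + 1)

  nodes <- list(); cells <- list()
  next_node <- 1L; next_cell <- 1L
  for (c_i in seq_len(ncol_tot)) {
    xl <- xedges[c_i]; xr <- xedges[c_i + 1]
    flank <- c_i == 1L || c_i == ncol_tot
    for (r_i in seq_len(n_rows)) {
      f0 <- (r_i - 1) / n_rows; f1 <- r_i / n_rows
      corners <- rbind(c(xl, f0 * hfun(xl)), c(xr, f0 * hfun(xr)),
                       c(xr, f1 * hfun(xr)), c(xl, f1 * hfun(xl)))
      cen <- colMeans(corners)
      shrink <- sapply(1:4, function(k) {
        v <- corners[k, ] - cen
        corners[k, ] - wall_margin * v / sqrt(sum(v * v)) * sqrt(2)
      })
      corners <- t(shrink)
      # wall nodes: subdivide each side at roughly the spring rest length
      ring <- matrix(numeric(0), 0, 2)
      for (k in 1:4) {
        p0 <- corners[k, ]; p1 <- corners[if (k == 4) 1 else k + 1, ]
        nseg <- max(1L, round(sqrt(sum((p1 - p0)^2)) / params$extensibility$l_eq))
        tt <- (seq_len(nseg) - 1) / nseg
        ring <- rbind(ring, t(vapply(tt, function(f) p0 + f * (p1 - p0), numeric(2))))
      }
      layer <- if (flank) "boundary_cell"
               else if (r_i == n_rows) "L1"
               else if (r_i == n_rows - 1L) "L2"
               else "basal_corpus"
      id <- next_cell; next_cell <- next_cell + 1L
      m <- nrow(ring)
      wall_ids <- next_node + seq_len(m) - 1L
      next_node <- next_node + m
      # cytoplasm: deterministic sunflower pattern with per-cell jitter
      ccen <- polygon_centroid(ring)
      rmax <- 0.3 * d
      cyto <- t(vapply(seq_len(cyto_per_cell), function(q) {
        u1 <- stream_uniform(seed, id, rng_purpose[["jitter"]], 2L * q - 2L)
        u2 <- stream_uniform(seed, id, rng_purpose[["jitter"]], 2L * q - 1L)
        ang <- 2.399963 * q + 2 * pi * 0.1 * (u1 - 0.5)
        rad <- rmax * sqrt((q - 0.5) / cyto_per_cell) * (0.9 + 0.2 * u2)
        ccen + rad * c(cos(ang), sin(ang))
      }, numeric(2)))
      cyto_ids <- next_node + seq_len(cyto_per_cell) - 1L
      next_node <- as.integer(next_node + cyto_per_cell)
      cp0 <- if (flank) 0 else
        0.9 * stream_uniform(seed, id, rng_purpose[["phase"]], 0L)
      nodes[[length(nodes) + 1L]] <- list(
        pos = rbind(ring, cyto),
        role = c(rep(0L, m), rep(1L, cyto_per_cell)),
        ring = c(seq_len(m), rep(NA_integer_, cyto_per_cell)),
        ids = c(wall_ids, cyto_ids), cell = id)
      cl <- new_cell(id, wall = wall_ids, cyto = cyto_ids, layer = layer,
                     cp = cp0, bottom = (r_i == 1L && !flank))
      cl$counters[["jitter"]] <- as.integer(2 * cyto_per_cell)
      cl$counters[["phase"]] <- 1L
      cells[[as.character(id)]] <- cl
    }
  }
  pos <- do.call(rbind, lapply(nodes, `[[`, "pos"))
  tis <- new_tissue(
    pos = pos,
    role = unlist(lapply(nodes, `[[`, "role")),
    node_cell = unlist(lapply(nodes, function(n) rep(n$cell, nrow(n$pos)))),
    ring_index = unlist(lapply(nodes, `[[`, "ring")),
    is_boundary = rep(FALSE, nrow(pos)),
    node_id = unlist(lapply(nodes, `[[`, "ids")),
    cells = cells,
    apex = c(0, hfun(0)), base_y = 0, time_h = 0, seed = seed)
  tis <- relabel_regions(tis, gp)
  tis <- place_signal_centres(tis, sp)
  tis <- assign_concentrations(tis, sp)
  for (id in sort(as.integer(names(tis$cells)))) {
    tis <- sample_polarization(tis, id, gp, variant)
    tis <- apply_polarization(tis, id, gp, params)
  }
  tis <- identify_boundary_nodes(tis)
  tis <- refresh_adhesion(tis, params$adhesion$cutoff, params$adhesion$max_partners)
  if (relax_steps > 0) {
    tis <- relax_tissue(tis, params, nsteps = relax_steps)
    tis$time_h <- 0                      # relaxation is part of construction
    tis <- update_apex(tis)
    tis <- identify_boundary_nodes(tis)
  }
  validate_tissue(tis)
  tis
}
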