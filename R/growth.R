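# Cell-cycle progression, growth by node insertion, growth-direction
# polarization (in-plane anticlinal/periclinal, and out-of-plane in the
# P3D variant) and division-plane placement/execution.
#
# WUS shortens the cell cycle; cycle progress adds cytoplasm nodes at
# evenly spaced progress fractions (turgor then inflates the cell and wall
# nodes are inserted into over-stretched edges). At progress 1 a cell
# divides: tunica cells always anticlinally, apical-corpus cells
# perpendicular to the principal direction of wall tension, basal-corpus
# cells stochastically with WUS/CK-weighted anticlinal/periclinal odds.
# Out-of-plane polarized cells (P3D) divide out of the section: the
# unrepresented daughter leaves the plane and the mother footprint keeps a
# reduced cytoplasm content.

#' Growth and division parameters
#'
#' The out-of-plane probability table holds the calibrated per-stratum
#' frequencies (percent/100) of out-of-plane growth polarization:
#' central-zone tunica 0.474, apical corpus 0.178, basal corpus 0.105;
#' peripheral-zone tunica 0.434, apical corpus 0.290, basal corpus 0.182.
#' Cycle-length and in-plane bias maps are package placeholders (the
#' calibrated maps are not published with the main text): cycle_hours =
#' clamp(h_max - wus_slope * wus, h_min, h_max), anticlinal weight
#' `anti_base + anti_wus * wus`, periclinal weight `peri_base + peri_ck * ck`.
#'
#' @param h_min,h_max,wus_slope cell-cycle length map (hours).
#' @param nodes_per_cycle cytoplasm nodes added over one full cycle.
#' @param wall_strain_threshold relative extension above which a wall edge
#'   is bisected.
#' @param inplane_terminal_area terminal section area of in-plane cells (µm²).
#' @param outplane_area_factor fraction of the in-plane terminal area given
#'   to out-of-plane cells (their major axis leaves the section).
#' @param anisotropy_factor stiffness multiplier (<1) softening wall edges
#'   parallel to the preferred expansion axis.
#' @param anti_base,anti_wus,peri_base,peri_ck in-plane orientation bias map.
#' @param periclinal_table 2 x 3 matrix of out-of-plane probabilities,
#'   rows central/peripheral, columns tunica/apical_corpus/basal_corpus.
#' @param zone_radius_cells central-zone half-width in mean cell diameters
#'   (the eight-cell-diameter window across the apex).
#' @param apical_fraction fraction of the corpus depth labelled apical.
#' @param min_division_area area (µm²) below which division is deferred.
#' @return list of class `sce_growth_params`.
#' @export
growth_params <- function(h_min = 20, h_max = 60, wus_slope = 40,
                          nodes_per_cycle = 6L, wall_strain_threshold = 0.5,
                          inplane_terminal_area = 45,
                          outplane_area_factor = 0.75,
                          anisotropy_factor = 0.3,
                          anti_base = 0.5, anti_wus = 1,
                          peri_base = 0.5, peri_ck = 1,
                          periclinal_table = NULL,
                          zone_radius_cells = 4, apical_fraction = 0.5,
                          min_division_area = 4) {
  if (is.null(periclinal_table)) {
    periclinal_table <- matrix(
      c(0.474, 0.178, 0.105,
        0.434, 0.290, 0.182), nrow = 2, byrow = TRUE,
      dimnames = list(c("central", "peripheral"),
                      c("tunica", "apical_corpus", "basal_corpus")))
  }
  stopifnot(outplane_area_factor > 0, outplane_area_factor < 1,
            all(periclinal_table >= 0), all(periclinal_table <= 1),
            h_min > 0, h_max >= h_min, nodes_per_cycle >= 1,
            wall_strain_threshold > 0)
  structure(list(h_min = h_min, h_max = h_max, wus_slope = wus_slope,
                 nodes_per_cycle = as.integer(nodes_per_cycle),
                 wall_strain_threshold = wall_strain_threshold,
                 inplane_terminal_area = inplane_terminal_area,
                 outplane_area_factor = outplane_area_factor,
                 anisotropy_factor = anisotropy_factor,
                 anti_base = anti_base, anti_wus = anti_wus,
                 peri_base = peri_base, peri_ck = peri_ck,
                 periclinal_table = periclinal_table,
                 zone_radius_cells = zone_radius_cells,
                 apical_fraction = apical_fraction,
                 min_division_area = min_division_area),
            class = "sce_growth_params")
}

#' WUS-dependent cell-cycle length
#' @param wus WUS concentration (a.u.).
#' @param gp an `sce_growth_params`.
#' @return cycle length in hours, monotone non-increasing in `wus` and
#'   bounded in `[h_min, h_max]`.
#' @export
cycle_length_hours <- function(wus, gp) {
  pmin(gp$h_max, pmax(gp$h_min, gp$h_max - gp$wus_slope * wus))
}

layer_group <- function(layer) {
  switch(layer, L1 = "tunica", L2 = "tunica",
         apical_corpus = "apical_corpus", basal_corpus = "basal_corpus",
         NA_character_)
}

radial_dir <- function(tissue, centroid) {
  v <- centroid - tissue$apex
  n <- sqrt(sum(v * v))
  if (n < 1e-9) c(0, -1) else v / n
}

draw <- function(tissue, cl, purpose) {
  k <- cl$counters[[purpose]]
  u <- stream_uniform(tissue$seed, cl$id, rng_purpose[[purpose]], k)
  cl$counters[[purpose]] <- k + 1L
  list(u = u, cell = cl)
}

#' Advance a cell's cycle and insert cytoplasm nodes
#'
#' Progress advances by `dt_hours / cycle_length(wus)`. Whenever progress
#' crosses a multiple of `1/nodes_per_cycle` a cytoplasm node is inserted
#' near the centroid with a small deterministic jitter from the cell's
#' stream, unless the cell has already reached its terminal area. Progress
#' is capped at 1, which flags the cell for division.
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id cell to advance.
#' @param dt_hours elapsed time (h), > 0.
#' @param gp an `sce_growth_params`.
#' @return the updated tissue.
#' @export
advance_cycle <- function(tissue, cell_id, dt_hours, gp) {
  stopifnot(dt_hours > 0)
  cl <- tissue$cells[[as.character(cell_id)]]
  if (cl$layer == "boundary_cell") return(tissue)     # non-dividing flanks
  cp0 <- cl$cp
  cp1 <- min(1, cp0 + dt_hours / cycle_length_hours(cl$wus, gp))
  k0 <- floor(cp0 * gp$nodes_per_cycle + 1e-12)
  k1 <- floor(cp1 * gp$nodes_per_cycle + 1e-12)
  n_ins <- max(0L, min(k1, gp$nodes_per_cycle) - k0)
  if (n_ins > 0) {
    poly <- tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE]
    area <- abs(polygon_area(poly))
    target <- if (!is.null(cl$target_area)) cl$target_area else gp$inplane_terminal_area
    if (area < target) {
      cen <- polygon_centroid(poly)
      r0 <- 0.25 * sqrt(area / pi)
      for (q in seq_len(n_ins)) {
        d1 <- draw(tissue, cl, "jitter"); cl <- d1$cell
        d2 <- draw(tissue, cl, "jitter"); cl <- d2$cell
        ang <- 2 * pi * d1$u
        rad <- r0 * sqrt(d2$u)
        res <- add_nodes(tissue, matrix(cen + rad * c(cos(ang), sin(ang)), 1, 2),
                         role = 1L, cell = cl$id)
        tissue <- res$tissue
        cl$cyto <- c(cl$cyto, res$ids)
      }
    }
  }
  cl$cp <- cp1
  tissue$cells[[as.character(cell_id)]] <- cl
  tissue
}

#' Bisect over-stretched wall edges
#'
#' Any wall edge longer than `(1 + threshold) * l_eq` gains a node at its
#' midpoint; ring order is preserved and spring rest lengths are unchanged.
#' Repeated application terminates because each split halves the edge.
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id cell whose ring is checked.
#' @param threshold relative extension trigger, > 0.
#' @param l_eq wall spring rest length (µm).
#' @return the updated tissue.
#' @export
insert_wall_nodes <- function(tissue, cell_id, threshold, l_eq) {
  stopifnot(threshold > 0)
  cl <- tissue$cells[[as.character(cell_id)]]
  repeat {
    rows <- node_rows(tissue, cl$wall)
    P <- tissue$pos[rows, , drop = FALSE]
    m <- nrow(P)
    nxt <- c(2:m, 1)
    len <- sqrt(rowSums((P[nxt, , drop = FALSE] - P)^2))
    over <- which(len > (1 + threshold) * l_eq & len > 2 * 0.4 * l_eq)
    if (!length(over)) break
    new_wall <- integer(0)
    for (i in seq_len(m)) {
      new_wall <- c(new_wall, cl$wall[i])
      if (i %in% over) {
        mid <- (P[i, ] + P[nxt[i], ]) / 2
        res <- add_nodes(tissue, matrix(mid, 1, 2), role = 0L, cell = cl$id)
        tissue <- res$tissue
        new_wall <- c(new_wall, res$ids)
      }
    }
    cl$wall <- new_wall
    cl$edge_k <- NULL                                 # re-derived from polarization
    tissue$cells[[as.character(cell_id)]] <- cl
    tissue <- set_ring_indices(tissue, cl)
  }
  tissue$cells[[as.character(cell_id)]] <- cl
  tissue
}

set_ring_indices <- function(tissue, cl) {
  rows <- node_rows(tissue, cl$wall)
  tissue$ring_index[rows] <- seq_along(rows)
  tissue
}

#' Sample a cell's growth-direction polarization
#'
#' In the P3D variant a cell first draws out-of-plane with the probability
#' its zone/layer stratum has in the calibrated table; otherwise (and
#' always in 2D, where the table is forced to zero) the in-plane direction
#' is drawn anticlinal vs periclinal with WUS/CK-weighted odds. Applied at
#' initialization and to both daughters of every division.
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id cell to sample.
#' @param gp an `sce_growth_params`.
#' @param variant `"p3d"` or `"2d"`.
#' @return the tissue with the cell's `polarization` set.
#' @export
sample_polarization <- function(tissue, cell_id, gp, variant = "p3d") {
  cl <- tissue$cells[[as.character(cell_id)]]
  if (cl$layer == "boundary_cell") {
    cl$polarization <- "in_plane_anticlinal"
    tissue$cells[[as.character(cell_id)]] <- cl
    return(tissue)
  }
  grp <- layer_group(cl$layer)
  if (is.na(grp) || !cl$zone %in% rownames(gp$periclinal_table))
    stop("cell ", cell_id, " lacks zone/layer labels for polarization")
  p_out <- if (identical(variant, "2d")) 0 else gp$periclinal_table[cl$zone, grp]
  d1 <- draw(tissue, cl, "polarization"); cl <- d1$cell
  if (d1$u < p_out) {
    cl$polarization <- "out_of_plane"
  } else {
    w_anti <- max(0, gp$anti_base + gp$anti_wus * cl$wus)
    w_peri <- max(0, gp$peri_base + gp$peri_ck * cl$ck)
    if (w_anti + w_peri == 0) { w_anti <- 1; w_peri <- 1 }
    d2 <- draw(tissue, cl, "inplane"); cl <- d2$cell
    cl$polarization <- if (d2$u < w_anti / (w_anti + w_peri))
      "in_plane_anticlinal" else "in_plane_periclinal"
  }
  tissue$cells[[as.character(cell_id)]] <- cl
  tissue
}

#' Translate polarization into wall mechanical parameters
#'
#' Out-of-plane cells get uniform wall-edge stiffness and a target area
#' reduced by `outplane_area_factor` (only their minor axis stays in the
#' section). In-plane cells get reduced stiffness on the wall edges roughly
#' parallel (within 45 degrees) to the preferred expansion axis — radial
#' (apex-to-centroid) for anticlinal, tangential for periclinal — so the
#' cell elongates that way.
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id cell to update.
#' @param gp an `sce_growth_params`.
#' @param params an `sce_params` (base wall stiffness).
#' @return the tissue with the cell's `edge_k` and `target_area` set.
#' @export
apply_polarization <- function(tissue, cell_id, gp, params) {
  cl <- tissue$cells[[as.character(cell_id)]]
  rows <- node_rows(tissue, cl$wall)
  P <- tissue$pos[rows, , drop = FALSE]
  m <- nrow(P)
  k0 <- params$extensibility$k
  if (cl$polarization == "out_of_plane") {
    cl$edge_k <- rep(k0, m)
    cl$target_area <- gp$outplane_area_factor * gp$inplane_terminal_area
  } else if (cl$layer == "boundary_cell") {
    cl$edge_k <- rep(k0, m)
    cl$target_area <- gp$inplane_terminal_area
  } else {
    cen <- polygon_centroid(P)
    u <- radial_dir(tissue, cen)
    axis <- if (cl$polarization == "in_plane_anticlinal") u else c(-u[2], u[1])
    nxt <- c(2:m, 1)
    ed <- P[nxt, , drop = FALSE] - P
    len <- sqrt(rowSums(ed^2))
    len[len == 0] <- 1
    ca <- abs((ed[, 1] * axis[1] + ed[, 2] * axis[2]) / len)
    cl$edge_k <- ifelse(ca > cos(pi / 4), k0 * gp$anisotropy_factor, k0)
    cl$target_area <- gp$inplane_terminal_area
  }
  tissue$cells[[as.character(cell_id)]] <- cl
  tissue$rev <- (if (is.null(tissue$rev)) 0L else tissue$rev) + 1L
  tissue
}

# principal direction of wall tension: eigenvector of sum_e t_e d d^T
wall_tension_axis <- function(tissue, cl, params) {
  rows <- node_rows(tissue, cl$wall)
  P <- tissue$pos[rows, , drop = FALSE]
  m <- nrow(P)
  nxt <- c(2:m, 1)
  ed <- P[nxt, , drop = FALSE] - P
  len <- sqrt(rowSums(ed^2))
  kk <- if (!is.null(cl$edge_k) && length(cl$edge_k) == m) cl$edge_k
        else rep(params$extensibility$k, m)
  tens <- kk * (len - params$extensibility$l_eq)
  d <- ed / ifelse(len == 0, 1, len)
  S <- matrix(0, 2, 2)
  for (e in seq_len(m)) S <- S + tens[e] * (d[e, ] %o% d[e, ])
  ei <- eigen(S, symmetric = TRUE)
  ei$vectors[, 1]                                     # largest eigenvalue
}

#' Choose a division plane for a cell flagged to divide
#'
#' Tunica (L1/L2) cells divide anticlinally, preserving the monolayer;
#' apical-corpus cells divide through the centroid perpendicular to the
#' principal direction of wall tension (mechanical cue); basal-corpus
#' cells sample anticlinal vs periclinal with WUS/CK-parametrized weights.
#' Boundary cells never divide. Cells below the minimum area defer.
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id the dividing cell.
#' @param gp an `sce_growth_params`.
#' @param params an `sce_params` (for wall tension).
#' @return list with `point` (centroid), `normal` (unit 2-vector) and the
#'   updated tissue (stream counters may advance), or `NULL` if deferred.
#' @export
choose_division_plane <- function(tissue, cell_id, gp, params) {
  cl <- tissue$cells[[as.character(cell_id)]]
  if (cl$layer == "boundary_cell") stop("boundary cells never divide")
  poly <- tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE]
  if (abs(polygon_area(poly)) < gp$min_division_area) {
    warning("division deferred: cell ", cell_id, " below minimum area")
    return(NULL)
  }
  cen <- polygon_centroid(poly)
  u <- radial_dir(tissue, cen)
  tang <- c(-u[2], u[1])
  if (cl$layer %in% c("L1", "L2")) {
    normal <- tang                                    # anticlinal insertion
  } else if (cl$layer == "apical_corpus") {
    normal <- wall_tension_axis(tissue, cl, params)
  } else {                                            # basal corpus: stochastic
    w_anti <- max(0, gp$anti_base + gp$anti_wus * cl$wus)
    w_peri <- max(0, gp$peri_base + gp$peri_ck * cl$ck)
    if (w_anti + w_peri == 0) { w_anti <- 1; w_peri <- 1 }
    d <- draw(tissue, cl, "plane"); cl <- d$cell
    tissue$cells[[as.character(cell_id)]] <- cl
    normal <- if (d$u < w_peri / (w_anti + w_peri)) u else tang
  }
  list(point = cen, normal = normal / sqrt(sum(normal^2)), tissue = tissue)
}

ring_plane_crossings <- function(P, point, normal) {
  s <- (P[, 1] - point[1]) * normal[1] + (P[, 2] - point[2]) * normal[2]
  if (any(abs(s) < 1e-9)) s <- s + 1e-7                # nudge off exact hits
  m <- nrow(P)
  nxt <- c(2:m, 1)
  cross <- which(s * s[nxt] < 0)
  list(s = s, cross = cross, nxt = nxt)
}

#' Execute a division
#'
#' In-plane: the wall ring is split at the two plane crossings; each
#' daughter receives its own chain of new wall nodes along the plane
#' (coincident chains, mutually adhered), the cytoplasm nodes are
#' partitioned by side, cycle progress resets and polarization is
#' resampled for both daughters. Out-of-plane: no new cell appears in the
#' section; the mother's cytoplasm content is cut to `outplane_area_factor`
#' and its cycle restarts (the second daughter leaves the plane).
#'
#' @param tissue an `sce_tissue`.
#' @param cell_id the dividing cell.
#' @param plane list with `point` and unit `normal` (ignored out-of-plane).
#' @param gp an `sce_growth_params`.
#' @param params an `sce_params`.
#' @param variant `"p3d"` or `"2d"` (for the daughters' polarization draw).
#' @return the updated tissue (cell count +1 in-plane, unchanged
#'   out-of-plane); `NULL` plane defers.
#' @export
execute_division <- function(tissue, cell_id, plane, gp, params,
                             variant = "p3d") {
  cl <- tissue$cells[[as.character(cell_id)]]
  if (cl$polarization == "out_of_plane") {
    keep_n <- max(1L, as.integer(round(gp$outplane_area_factor * length(cl$cyto))))
    if (keep_n < length(cl$cyto)) {
      cen <- cell_centroid(tissue, cl$id)
      d2 <- rowSums((tissue$pos[node_rows(tissue, cl$cyto), , drop = FALSE] -
                       matrix(cen, length(cl$cyto), 2, byrow = TRUE))^2)
      keep <- cl$cyto[order(d2)][seq_len(keep_n)]
      drop_rows <- node_rows(tissue, setdiff(cl$cyto, keep))
      cl$cyto <- keep
      tissue$cells[[as.character(cell_id)]] <- cl
      tissue <- compact_tissue(tissue, setdiff(seq_len(nrow(tissue$pos)), drop_rows))
    }
    cl <- tissue$cells[[as.character(cell_id)]]
    cl$cp <- 0
    tissue$cells[[as.character(cell_id)]] <- cl
    tissue <- sample_polarization(tissue, cell_id, gp, variant)
    tissue <- apply_polarization(tissue, cell_id, gp, params)
    tissue <- log_division(tissue, cl, daughters = cell_id,
                           mode = "out_of_plane", normal = c(NA, NA))
    return(tissue)
  }
  if (is.null(plane)) return(tissue)
  rows <- node_rows(tissue, cl$wall)
  P <- tissue$pos[rows, , drop = FALSE]
  cr <- ring_plane_crossings(P, plane$point, plane$normal)
  if (length(cr$cross) != 2) {
    # fallback: split across the ring's short axis
    pc <- sweep(P, 2, colMeans(P))
    ax <- eigen(crossprod(pc) / nrow(P), symmetric = TRUE)$vectors[, 1]
    plane$normal <- ax / sqrt(sum(ax^2))
    cr <- ring_plane_crossings(P, plane$point, plane$normal)
    if (length(cr$cross) != 2) {
      warning("division deferred: plane does not cross cell ", cell_id,
              " in exactly two edges")
      cl$cp <- 0.95
      tissue$cells[[as.character(cell_id)]] <- cl
      return(tissue)
    }
  }
  i <- cr$cross[1]; j <- cr$cross[2]
  m <- nrow(P)
  ti <- cr$s[i] / (cr$s[i] - cr$s[cr$nxt[i]])
  tj <- cr$s[j] / (cr$s[j] - cr$s[cr$nxt[j]])
  qi <- P[i, ] + ti * (P[cr$nxt[i], ] - P[i, ])
  qj <- P[j, ] + tj * (P[cr$nxt[j], ] - P[j, ])
  l_eq <- params$extensibility$l_eq
  n_int <- max(0L, as.integer(round(sqrt(sum((qj - qi)^2)) / l_eq)) - 1L)
  tfrac <- if (n_int > 0) seq_len(n_int) / (n_int + 1) else numeric(0)
  chain_ji <- t(vapply(tfrac, function(f) qj + f * (qi - qj), numeric(2)))
  if (n_int == 0) chain_ji <- matrix(0, 0, 2)
  eps <- 0.05
  side_u <- sign(cr$s[i + 1])                         # side of nodes i+1..j
  idx_u <- (i + 1):j
  idx_v <- c(if (j < m) (j + 1):m else integer(0), 1:i)

  make_side <- function(side_sign, wall_old_idx, first_q, mats) {
    off <- eps * side_sign * plane$normal
    id <- tissue$next_cell_id
    tissue$next_cell_id <<- id + 1L
    dg <- new_cell(id, wall = integer(0), cyto = integer(0),
                   layer = cl$layer, zone = cl$zone,
                   wus = cl$wus, ck = cl$ck, cp = 0,
                   bottom = cl$bottom, parent = cl$id)
    old_ids <- cl$wall[wall_old_idx]
    # reassign retained wall nodes to the daughter
    tissue$node_cell[node_rows(tissue, old_ids)] <<- id
    if (identical(first_q, "u")) {
      newp <- rbind(qj + off, chain_ji + matrix(off, max(n_int, 0), 2, byrow = TRUE),
                    qi + off)
    } else {
      newp <- rbind(qi + off,
                    chain_ji[rev(seq_len(nrow(chain_ji))), , drop = FALSE] +
                      matrix(off, max(n_int, 0), 2, byrow = TRUE),
                    qj + off)
    }
    res <- add_nodes(tissue, newp, role = 0L, cell = id)
    tissue <<- res$tissue
    dg$wall <- c(old_ids, res$ids)
    dg$chain <- res$ids
    tissue$cells[[as.character(id)]] <<- dg
    tissue <<- set_ring_indices(tissue, dg)
    dg
  }
  du <- make_side(side_u, idx_u, "u")
  dv <- make_side(-side_u, idx_v, "v")

  # partition cytoplasm by plane side; guarantee one node per daughter
  if (length(cl$cyto)) {
    cp_pos <- tissue$pos[node_rows(tissue, cl$cyto), , drop = FALSE]
    sc <- (cp_pos[, 1] - plane$point[1]) * plane$normal[1] +
          (cp_pos[, 2] - plane$point[2]) * plane$normal[2]
    cu <- cl$cyto[sign(sc) == side_u]
    cv <- setdiff(cl$cyto, cu)
  } else cu <- cv <- integer(0)
  for (dd in list(list(d = du, cy = cu), list(d = dv, cy = cv))) {
    dg <- tissue$cells[[as.character(dd$d$id)]]
    dg$cyto <- dd$cy
    if (length(dd$cy))
      tissue$node_cell[node_rows(tissue, dd$cy)] <- dg$id
    tissue$cells[[as.character(dg$id)]] <- dg
    if (!length(dd$cy)) {
      cen <- cell_centroid(tissue, dg$id)
      res <- add_nodes(tissue, matrix(cen, 1, 2), role = 1L, cell = dg$id)
      tissue <- res$tissue
      dg <- tissue$cells[[as.character(dg$id)]]
      dg$cyto <- res$ids
      tissue$cells[[as.character(dg$id)]] <- dg
    }
  }
  # adhere the two coincident chains to each other
  chu <- tissue$cells[[as.character(du$id)]]$chain
  chv <- rev(tissue$cells[[as.character(dv$id)]]$chain)
  newp <- cbind(pmin(chu, chv), pmax(chu, chv))
  tissue$adhesion <- rbind(tissue$adhesion, newp)

  tissue$cells[[as.character(cell_id)]] <- NULL       # mother id retired
  a_m <- abs(polygon_area(P))
  a_u <- abs(polygon_area(cell_polygon(du$id, tissue)))
  if (a_u < 0.35 * a_m || a_u > 0.65 * a_m)
    warning("asymmetric division of cell ", cell_id, ": daughter fraction ",
            round(a_u / a_m, 2))
  tissue <- sample_polarization(tissue, du$id, gp, variant)
  tissue <- sample_polarization(tissue, dv$id, gp, variant)
  tissue <- apply_polarization(tissue, du$id, gp, params)
  tissue <- apply_polarization(tissue, dv$id, gp, params)
  log_division(tissue, cl, daughters = c(du$id, dv$id), mode = "in_plane",
               normal = plane$normal)
}

log_division <- function(tissue, mother, daughters, mode, normal) {
  cen <- if (mode == "in_plane") {
    colMeans(do.call(rbind, lapply(daughters, function(i) cell_centroid(tissue, i))))
  } else cell_centroid(tissue, daughters[1])
  u <- radial_dir(tissue, cen)
  rec <- data.frame(time_h = tissue$time_h, mother = mother$id,
                    daughter1 = daughters[1],
                    daughter2 = if (length(daughters) > 1) daughters[2] else NA_integer_,
                    layer = mother$layer, zone = mother$zone, mode = mode,
                    normal_x = normal[1], normal_y = normal[2],
                    radial_x = u[1], radial_y = u[2])
  tissue$division_log <- rbind(tissue$division_log, rec)
  tissue
}

#' Recompute positional region labels
#'
#' Zone: central when the centroid is within `zone_radius_cells` mean cell
#' diameters of the apex axis (the eight-cell-diameter window), else
#' peripheral. Corpus cells split positionally into apical (upper
#' `apical_fraction` of the corpus depth range) and basal; L1/L2 labels are
#' clonal and never change; bottom-row cells stay basal.
#'
#' @param tissue an `sce_tissue`.
#' @param gp an `sce_growth_params`.
#' @return the relabelled tissue.
#' @export
relabel_regions <- function(tissue, gp) {
  d <- mean_cell_diameter(tissue)
  cc <- cell_centroids(tissue)
  rownames(cc) <- as.character(cc$cell_id)
  corpus <- Filter(function(cl)
    cl$layer %in% c("apical_corpus", "basal_corpus"), tissue$cells)
  if (length(corpus)) {
    ys <- cc[as.character(vapply(corpus, `[[`, integer(1), "id")), "y"]
    ylim <- range(ys)
    ycut <- ylim[1] + (1 - gp$apical_fraction) * (ylim[2] - ylim[1])
  }
  for (nm in names(tissue$cells)) {
    cl <- tissue$cells[[nm]]
    cen <- unlist(cc[as.character(cl$id), c("x", "y")])
    cl$zone <- if (abs(cen[1] - tissue$apex[1]) <= gp$zone_radius_cells * d)
      "central" else "peripheral"
    if (cl$layer %in% c("apical_corpus", "basal_corpus")) {
      cl$layer <- if (isTRUE(cl$bottom)) "basal_corpus"
                  else if (cen[2] >= ycut) "apical_corpus" else "basal_corpus"
    }
    tissue$cells[[nm]] <- cl
  }
  tissue
}
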