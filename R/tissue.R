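# Tissue state: cells as closed rings of wall nodes plus cytoplasm nodes.
#
# Node bookkeeping uses persistent integer node ids. Positions live in a
# single n x 2 matrix; `id2row` maps a persistent id to its current row.
# Cells are stored in a named list keyed by cell id and reference nodes by
# persistent id, so rows can be compacted after divisions without touching
# cell records.

node_rows <- function(tissue, ids) tissue$id2row[ids]

new_tissue <- function(pos, role, node_cell, ring_index, is_boundary, node_id,
                       cells, adhesion = NULL, wus_centre = NULL, ck_centre = NULL,
                       apex = NULL, base_y = 0, time_h = 0, seed = 1L) {
  n <- nrow(pos)
  node_id <- as.integer(node_id)
  role <- as.integer(role)
  node_cell <- as.integer(node_cell)
  ring_index <- as.integer(ring_index)
  id2row <- integer(max(node_id, 0L))
  id2row[node_id] <- seq_len(n)
  structure(list(
    pos = pos, role = role, node_cell = node_cell, ring_index = ring_index,
    is_boundary = is_boundary, node_id = node_id, id2row = id2row,
    cells = cells,
    adhesion = if (is.null(adhesion)) matrix(integer(0), 0, 2) else adhesion,
    wus_centre = wus_centre, ck_centre = ck_centre,
    apex = apex, base_y = base_y, time_h = time_h, seed = as.integer(seed),
    next_node_id = as.integer(max(node_id, 0L) + 1L),
    next_cell_id = as.integer(max(c(0L, vapply(cells, `[[`, integer(1), "id"))) + 1L),
    division_log = data.frame()
  ), class = "sce_tissue")
}

new_cell <- function(id, wall, cyto, layer = "apical_corpus", zone = "central",
                     polarization = "in_plane_anticlinal", wus = 0, ck = 0,
                     cp = 0, bottom = FALSE, parent = NA_integer_) {
  list(id = as.integer(id), wall = as.integer(wall), cyto = as.integer(cyto),
       layer = layer, zone = zone, polarization = polarization,
       wus = wus, ck = ck, cp = cp, bottom = bottom, parent = as.integer(parent),
       edge_k = NULL,
       counters = setNames(integer(length(rng_purpose)), names(rng_purpose)))
}

.layers <- c("L1", "L2", "apical_corpus", "basal_corpus", "boundary_cell")
.polarizations <- c("in_plane_anticlinal", "in_plane_periclinal", "out_of_plane")

#' Assemble a tissue from node and cell tables
#'
#' Builds a validated tissue from a nodes table and a list of cell
#' descriptions. This is the low-level constructor; most users will call
#' [generate_initial_tissue()] instead.
#'
#' @param nodes data frame with columns `node_id`, `cell_id`, `role`
#'   (`"wall"` or `"cytoplasm"`), `ring_index` (NA for cytoplasm nodes),
#'   `x`, `y`, `is_boundary`.
#' @param cells data frame with columns `cell_id`, `layer`, `zone`,
#'   `polarization`, `wus`, `ck`, `cycle_progress` (optional extras kept).
#' @param wus_centre,ck_centre optional 2-vectors, the WUS/CK signal centres.
#' @param apex optional 2-vector; defaults to the highest wall node.
#' @param time_h simulated time in hours.
#' @param seed integer seed owned by the tissue's random streams.
#' @return an object of class `sce_tissue`.
#' @export
build_tissue <- function(nodes, cells, wus_centre = NULL, ck_centre = NULL,
                         apex = NULL, time_h = 0, seed = 1L) {
  stopifnot(is.data.frame(nodes), is.data.frame(cells))
  need <- c("node_id", "cell_id", "role", "ring_index", "x", "y")
  if (!all(need %in% names(nodes)))
    stop("nodes table must have columns: ", paste(need, collapse = ", "))
  if (!"is_boundary" %in% names(nodes)) nodes$is_boundary <- FALSE
  if (anyDuplicated(nodes$node_id)) stop("topology error: duplicated node ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    stop("topology error: non-finite node positions")

  cell_list <- list()
  for (i in seq_len(nrow(cells))) {
    ci <- cells$cell_id[i]
    sub <- nodes[nodes$cell_id == ci, , drop = FALSE]
    wall <- sub[sub$role == "wall", , drop = FALSE]
    cyto <- sub[sub$role == "cytoplasm", , drop = FALSE]
    if (nrow(wall) < 3)
      stop("topology error: cell ", ci, " has fewer than 3 wall nodes")
    if (anyDuplicated(wall$ring_index) || any(is.na(wall$ring_index)))
      stop("topology error: cell ", ci, " wall ring indices invalid")
    if (any(!is.na(cyto$ring_index)))
      stop("topology error: cytoplasm node with a ring index in cell ", ci)
    wall <- wall[order(wall$ring_index), , drop = FALSE]
    cell_list[[as.character(ci)]] <- new_cell(
      id = ci, wall = wall$node_id, cyto = cyto$node_id,
      layer = if ("layer" %in% names(cells)) as.character(cells$layer[i]) else "apical_corpus",
      zone = if ("zone" %in% names(cells)) as.character(cells$zone[i]) else "central",
      polarization = if ("polarization" %in% names(cells)) as.character(cells$polarization[i]) else "in_plane_anticlinal",
      wus = if ("wus" %in% names(cells)) cells$wus[i] else 0,
      ck = if ("ck" %in% names(cells)) cells$ck[i] else 0,
      cp = if ("cycle_progress" %in% names(cells)) cells$cycle_progress[i] else 0,
      bottom = if ("bottom" %in% names(cells)) isTRUE(cells$bottom[i]) else FALSE)
  }
  claimed <- unlist(lapply(cell_list, function(cl) c(cl$wall, cl$cyto)))
  if (!setequal(claimed, nodes$node_id) || anyDuplicated(claimed))
    stop("topology error: node/cell references inconsistent")

  ord <- order(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  tis <- new_tissue(
    pos = cbind(nodes$x, nodes$y),
    role = ifelse(nodes$role == "wall", 0L, 1L),
    node_cell = as.integer(nodes$cell_id),
    ring_index = as.integer(nodes$ring_index),
    is_boundary = as.logical(nodes$is_boundary),
    node_id = as.integer(nodes$node_id),
    cells = cell_list,
    wus_centre = wus_centre, ck_centre = ck_centre,
    apex = apex, base_y = min(nodes$y), time_h = time_h, seed = seed)
  if (is.null(apex)) {
    wrows <- tis$role == 0L
    tis$apex <- tis$pos[which(wrows)[which.max(tis$pos[wrows, 2])], ]
  }
  validate_tissue(tis)
  tis
}

#' Check all tissue invariants
#'
#' Verifies ring integrity, reference consistency, adhesion symmetry and
#' per-cell invariants (cycle progress in \[0,1\], zero cytokinin in the
#' tunica). Called by the constructors and, in test mode, after every
#' simulation event.
#'
#' @param tissue an `sce_tissue`.
#' @return the tissue, invisibly; stops with a topology error otherwise.
#' @export
validate_tissue <- function(tissue) {
  if (!all(is.finite(tissue$pos))) stop("topology error: non-finite positions")
  seen <- integer(0)
  for (cl in tissue$cells) {
    rows <- node_rows(tissue, c(cl$wall, cl$cyto))
    if (anyNA(rows) || any(rows == 0))
      stop("topology error: cell ", cl$id, " references missing nodes")
    if (any(tissue$role[node_rows(tissue, cl$wall)] != 0L))
      stop("topology error: cell ", cl$id, " wall ring lists a non-wall node")
    if (length(cl$cyto) &&
        any(tissue$role[node_rows(tissue, cl$cyto)] != 1L))
      stop("topology error: cell ", cl$id, " cytoplasm set lists a wall node")
    if (length(cl$wall) < 3)
      stop("topology error: cell ", cl$id, " open or degenerate wall ring")
    if (any(tissue$node_cell[rows] != cl$id))
      stop("topology error: node ownership mismatch in cell ", cl$id)
    if (cl$cp < 0 || cl$cp > 1 + 1e-12)
      stop("invariant violation: cycle progress outside [0,1] in cell ", cl$id)
    if (cl$layer %in% c("L1", "L2") && cl$ck != 0)
      stop("invariant violation: nonzero CK in tunica cell ", cl$id)
    if (!cl$layer %in% .layers) stop("unknown layer label in cell ", cl$id)
    seen <- c(seen, cl$wall, cl$cyto)
  }
  if (length(seen) != nrow(tissue$pos) || anyDuplicated(seen))
    stop("topology error: node/cell references inconsistent")
  if (nrow(tissue$adhesion)) {
    ca <- tissue$node_cell[node_rows(tissue, tissue$adhesion[, 1])]
    cb <- tissue$node_cell[node_rows(tissue, tissue$adhesion[, 2])]
    if (any(ca == cb))
      stop("invariant violation: adhesion pair within a single cell")
    if (any(tissue$adhesion[, 1] >= tissue$adhesion[, 2]))
      stop("invariant violation: adhesion pairs not stored canonically")
  }
  invisible(tissue)
}

#' Ordered polygon of a cell's wall ring
#'
#' Returns the wall-node coordinates in ring order, re-oriented
#' counter-clockwise (positive signed area). Transient self-intersection
#' during a simulation is allowed: it sets the `self_intersecting` attribute
#' rather than failing.
#'
#' @param cell_id integer cell id.
#' @param tissue an `sce_tissue`.
#' @return an m x 2 matrix with attribute `self_intersecting`.
#' @export
cell_polygon <- function(cell_id, tissue) {
  cl <- tissue$cells[[as.character(cell_id)]]
  if (is.null(cl)) stop("no such cell: ", cell_id)
  pts <- tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE]
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  attr(pts, "self_intersecting") <- polygon_self_intersects(pts)
  pts
}

#' Signed area of a polygon (shoelace formula)
#' @param pts m x 2 matrix of vertices in order.
#' @return signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# O(m^2) segment-crossing test over non-adjacent ring edges
polygon_self_intersects <- function(pts) {
  m <- nrow(pts)
  if (m < 4) return(FALSE)
  a <- pts; b <- pts[c(2:m, 1), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1]-p3[1])*(p1[2]-p3[2]) - (p4[2]-p3[2])*(p1[1]-p3[1])
    d2 <- (p4[1]-p3[1])*(p2[2]-p3[2]) - (p4[2]-p3[2])*(p2[1]-p3[1])
    d3 <- (p2[1]-p1[1])*(p3[2]-p1[2]) - (p2[2]-p1[2])*(p3[1]-p1[1])
    d4 <- (p2[1]-p1[1])*(p4[2]-p1[2]) - (p2[2]-p1[2])*(p4[1]-p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(m - 2)) {
    jmax <- if (i == 1) m - 1 else m
    for (j in (i + 2):jmax) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

cell_centroid <- function(tissue, cell_id) {
  cl <- tissue$cells[[as.character(cell_id)]]
  polygon_centroid(tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE])
}

#' Centroids of all cells
#' @param tissue an `sce_tissue`.
#' @return data frame with `cell_id`, `x`, `y`.
#' @export
cell_centroids <- function(tissue) {
  ids <- sort(vapply(tissue$cells, `[[`, integer(1), "id"))
  cc <- t(vapply(ids, function(i) cell_centroid(tissue, i), numeric(2)))
  data.frame(cell_id = ids, x = cc[, 1], y = cc[, 2])
}

#' Recompute cell-cell adhesion pairings
#'
#' Pairs wall nodes of distinct cells lying within `cutoff` of each other.
#' Each wall node adheres to at most `max_partners` nodes per neighbouring
#' cell; candidate pairs are accepted greedily by ascending distance. Pairs
#' are stored canonically (smaller id first), so the pairing is symmetric.
#'
#' @param tissue an `sce_tissue`.
#' @param cutoff adhesion search radius (µm), > 0.
#' @param max_partners maximum partners per node per neighbouring cell.
#' @return the tissue with its `adhesion` pair set replaced.
#' @export
refresh_adhesion <- function(tissue, cutoff, max_partners = 1L) {
  stopifnot(cutoff > 0)
  wall <- which(tissue$role == 0L)
  if (length(wall) < 2) { tissue$adhesion <- matrix(integer(0), 0, 2); return(tissue) }
  cand <- grid_pairs_cpp(tissue$pos[wall, , drop = FALSE],
                         tissue$node_cell[wall], cutoff)
  if (nrow(cand$pairs) == 0) { tissue$adhesion <- matrix(integer(0), 0, 2); return(tissue) }
  i <- wall[cand$pairs[, 1]]; j <- wall[cand$pairs[, 2]]
  keep <- greedy_pairs_cpp(tissue$node_id[i], tissue$node_id[j],
                           tissue$node_cell[i], tissue$node_cell[j],
                           cand$dist, as.integer(max_partners))
  ia <- tissue$node_id[i[keep]]; ib <- tissue$node_id[j[keep]]
  pair <- cbind(pmin(ia, ib), pmax(ia, ib))
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  tissue$adhesion <- pair
  tissue
}

# Drop dead rows and rebuild id2row; cell records are untouched because they
# reference persistent ids.
compact_tissue <- function(tissue, keep_rows) {
  tissue$pos <- tissue$pos[keep_rows, , drop = FALSE]
  tissue$role <- tissue$role[keep_rows]
  tissue$node_cell <- tissue$node_cell[keep_rows]
  tissue$ring_index <- tissue$ring_index[keep_rows]
  tissue$is_boundary <- tissue$is_boundary[keep_rows]
  tissue$node_id <- tissue$node_id[keep_rows]
  id2row <- integer(tissue$next_node_id - 1L)
  id2row[tissue$node_id] <- seq_along(tissue$node_id)
  tissue$id2row <- id2row
  if (nrow(tissue$adhesion)) {
    ok <- tissue$id2row[tissue$adhesion[, 1]] > 0 &
          tissue$id2row[tissue$adhesion[, 2]] > 0
    tissue$adhesion <- tissue$adhesion[ok, , drop = FALSE]
  }
  tissue$rev <- (if (is.null(tissue$rev)) 0L else tissue$rev) + 1L
  tissue
}

add_nodes <- function(tissue, pos, role, cell, ring_index = NA_integer_,
                      is_boundary = FALSE) {
  n_new <- nrow(pos)
  ids <- tissue$next_node_id + seq_len(n_new) - 1L
  tissue$pos <- rbind(tissue$pos, pos)
  tissue$role <- c(tissue$role, rep_len(role, n_new))
  tissue$node_cell <- c(tissue$node_cell, rep_len(as.integer(cell), n_new))
  tissue$ring_index <- c(tissue$ring_index, rep_len(as.integer(ring_index), n_new))
  tissue$is_boundary <- c(tissue$is_boundary, rep_len(is_boundary, n_new))
  tissue$node_id <- c(tissue$node_id, ids)
  old_len <- length(tissue$id2row)
  tissue$id2row <- c(tissue$id2row, integer(max(ids) - old_len))
  tissue$id2row[ids] <- nrow(tissue$pos) - n_new + seq_len(n_new)
  tissue$next_node_id <- tissue$next_node_id + n_new
  tissue$rev <- (if (is.null(tissue$rev)) 0L else tissue$rev) + 1L
  list(tissue = tissue, ids = ids)
}

#' @export
print.sce_tissue <- function(x, ...) {
  cat("<sce_tissue> ", length(x$cells), " cells, ", nrow(x$pos), " nodes (",
      sum(x$role == 0L), " wall / ", sum(x$role == 1L), " cytoplasm), t = ",
      format(x$time_h, digits = 4), " h\n", sep = "")
  lay <- table(vapply(x$cells, `[[`, character(1), "layer"))
  cat("  layers: ", paste(names(lay), as.integer(lay), sep = ":", collapse = "  "),
      "\n  adhesion pairs: ", nrow(x$adhesion), "\n", sep = "")
  invisible(x)
}
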