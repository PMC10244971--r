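# Tissue-structure readouts: monolayer length, relative curvature, cell
# aspect ratio, percent-periclinal division frequency, the Voronoi
# adhesion-neighbour graph and its centralities (PageRank and the
# randomized-shortest-path betweenness family).

l1_cell_graph <- function(tissue) {
  l1 <- sort(vapply(Filter(function(cl) cl$layer == "L1", tissue$cells),
                    `[[`, integer(1), "id"))
  if (length(l1) < 2) stop("need at least 2 L1 cells")
  edges <- matrix(integer(0), 0, 2)
  if (nrow(tissue$adhesion)) {
    ca <- tissue$node_cell[node_rows(tissue, tissue$adhesion[, 1])]
    cb <- tissue$node_cell[node_rows(tissue, tissue$adhesion[, 2])]
    keep <- ca %in% l1 & cb %in% l1
    if (any(keep)) {
      e <- unique(cbind(pmin(ca[keep], cb[keep]), pmax(ca[keep], cb[keep])))
      edges <- e[e[, 1] != e[, 2], , drop = FALSE]
    }
  }
  list(cells = l1, edges = edges)
}

#' Epidermal monolayer length
#'
#' Orders the L1 cells into an adjacency chain from the left to the right
#' tissue edge (shortest path through the adhesion graph restricted to L1)
#' and sums consecutive centroid distances. The chain length evolves
#' continuously while the monolayer is intact; `break_detected` is set when
#' the L1 cells do not form a single chain visiting every L1 cell (for
#' example after a cell is expelled into L2 and the chain reroutes around
#' it). Jump detection between snapshots is applied by the driver on the
#' resulting series.
#'
#' @param tissue an `sce_tissue` with current adhesion pairs.
#' @return list with `length_um`, `break_detected` and the ordered
#'   `chain` of cell ids.
#' @export
monolayer_length <- function(tissue) {
  g <- l1_cell_graph(tissue)
  cc <- cell_centroids(tissue)
  cc <- cc[match(g$cells, cc$cell_id), ]
  idx <- setNames(seq_along(g$cells), g$cells)
  ed <- cbind(idx[as.character(g$edges[, 1])], idx[as.character(g$edges[, 2])])
  # prune corner shortcuts: drop an edge when a third in-layer L1 cell sits
  # between its endpoints and is adjacent to both, so the healthy chain
  # visits every cell; an expelled cell (off the layer line) is not between
  # and the chain skipping it is a real break
  if (nrow(ed) > 1) {
    d_l1 <- mean_l1_diameter(tissue)
    adj <- lapply(seq_along(g$cells), function(v)
      unique(c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1])))
    keep <- vapply(seq_len(nrow(ed)), function(e) {
      a <- ed[e, 1]; b <- ed[e, 2]
      mids <- intersect(adj[[a]], adj[[b]])
      mids <- setdiff(mids, c(a, b))
      for (c3 in mids) {
        between <- cc$x[c3] > min(cc$x[a], cc$x[b]) &&
                   cc$x[c3] < max(cc$x[a], cc$x[b])
        on_layer <- abs(cc$y[c3] - (cc$y[a] + cc$y[b]) / 2) < 0.75 * d_l1
        if (between && on_layer) return(FALSE)
      }
      TRUE
    }, logical(1))
    ed <- ed[keep, , drop = FALSE]
  }
  gr <- igraph::make_empty_graph(n = length(g$cells), directed = FALSE)
  if (nrow(ed)) gr <- igraph::add_edges(gr, t(ed))
  from <- which.min(cc$x); to <- which.max(cc$x)
  chain_len <- function(v) {
    p <- cc[v, c("x", "y")]
    sum(sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2)))
  }
  sp <- suppressWarnings(igraph::shortest_paths(gr, from, to)$vpath[[1]])
  if (length(sp) == 0) {
    # no left-right path: take the longest chain inside the biggest component
    comp <- igraph::components(gr)
    big <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(gr, big)
    dm <- igraph::distances(sub)
    dm[!is.finite(dm)] <- -1
    ends <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    v <- big[as.integer(igraph::shortest_paths(sub, ends[1], ends[2])$vpath[[1]])]
    return(list(length_um = chain_len(v), break_detected = TRUE, chain = g$cells[v]))
  }
  v <- as.integer(sp)
  broken <- length(v) < length(g$cells)
  list(length_um = chain_len(v), break_detected = broken, chain = g$cells[v])
}

# least-squares (Kasa) circle fit; returns centre and radius
fit_circle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  list(centre = sol[1:2], radius = sqrt(r2))
}

#' Relative curvature of the apical surface
#'
#' Collects the outward wall nodes of L1 cells in the apical cap (above
#' the configurable height fraction of the tissue), rescales the
#' coordinates so that the horizontal extent is 1, fits a circle by least
#' squares and returns `1/R`. Scale- and translation-invariant by
#' construction: a semicircular cap gives 2 (width 1 implies radius 1/2)
#' and a flat top gives 0.
#'
#' @param tissue an `sce_tissue`.
#' @param cap_fraction height fraction above which surface nodes are used.
#' @return dimensionless curvature `1/R` of the width-normalized surface.
#' @export
relative_curvature <- function(tissue, cap_fraction = 0.5) {
  pts <- apical_surface_nodes(tissue, cap_fraction)
  if (nrow(pts) < 5) stop("fewer than 5 apical surface nodes")
  w <- diff(range(tissue$pos[tissue$role == 0L, 1]))   # full tissue width -> 1
  if (w <= 0) stop("degenerate apical surface")
  pts <- pts / w
  fit <- fit_circle(pts)
  if (is.null(fit) || fit$radius > 1e6) return(0)
  1 / fit$radius
}

# Outer-face wall nodes of the L1 cells in the apical cap: per cell, the
# nodes in the top band of the cell's own height (the face turned away from
# the tissue interior), restricted to the cap above the height cut.
apical_surface_nodes <- function(tissue, cap_fraction = 0.5) {
  wall <- tissue$pos[tissue$role == 0L, , drop = FALSE]
  ylim <- range(wall[, 2])
  ycut <- ylim[1] + cap_fraction * (ylim[2] - ylim[1])
  l1 <- Filter(function(cl) cl$layer == "L1", tissue$cells)
  if (!length(l1)) stop("tissue has no L1 surface")
  out <- matrix(numeric(0), 0, 2)
  for (cl in l1) {
    rows <- node_rows(tissue, cl$wall)
    P <- tissue$pos[rows, , drop = FALSE]
    yr <- range(P[, 2])
    keep <- P[, 2] >= yr[1] + 0.85 * (yr[2] - yr[1]) & P[, 2] >= ycut
    out <- rbind(out, P[keep, , drop = FALSE])
  }
  out
}

#' Cell aspect ratio
#'
#' Ratio of the cell's extent along its principal (longest) axis to the
#' extent in the perpendicular direction, computed from the wall-node
#' positions; always >= 1 and rotation invariant.
#'
#' @param cell_id cell id, or an m x 2 matrix of ring coordinates.
#' @param tissue an `sce_tissue` (ignored when a matrix is given).
#' @return aspect ratio >= 1.
#' @export
aspect_ratio <- function(cell_id, tissue = NULL) {
  P <- if (is.matrix(cell_id)) cell_id
       else tissue$pos[node_rows(tissue, tissue$cells[[as.character(cell_id)]]$wall),
                       , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 wall nodes")
  pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(pc) / nrow(P), symmetric = TRUE)$vectors
  proj <- pc %*% ev
  ext <- apply(proj, 2, function(z) diff(range(z)))
  if (min(ext) <= 1e-12) stop("degenerate cell: zero minor extent")
  max(ext) / min(ext)
}

#' Percent periclinal divisions in a region
#'
#' A division is periclinal when its plane is closer to parallel with the
#' local L1 surface tangent than perpendicular to it, i.e. when the plane
#' normal is within 45 degrees of the local radial (apex-to-centroid)
#' direction; ties at exactly 45 degrees count as anticlinal.
#'
#' @param division_log data frame as kept by the simulation driver
#'   (columns `layer`, `zone`, `mode`, `normal_x/y`, `radial_x/y`).
#' @param region optional layer name (e.g. `"apical_corpus"`) restricting
#'   the log; `NULL` uses all in-plane divisions.
#' @return percentage in `[0, 100]`, or `NA` (flagged by a warning) when
#'   the region has no divisions.
#' @export
percent_periclinal <- function(division_log, region = NULL) {
  dl <- division_log[division_log$mode == "in_plane", , drop = FALSE]
  if (!is.null(region)) dl <- dl[dl$layer == region, , drop = FALSE]
  if (!nrow(dl)) {
    warning("no in-plane divisions in region; percent periclinal undefined")
    return(NA_real_)
  }
  ct <- abs(dl$normal_x * dl$radial_x + dl$normal_y * dl$radial_y)
  ct <- pmin(1, ct)
  peri <- acos(ct) < pi / 4                  # strict: 45-degree ties anticlinal
  100 * sum(peri) / length(peri)
}

#' Cell adhesion-neighbour graph from a Voronoi tessellation
#'
#' Nodes are cells; edges join centroid pairs sharing a Voronoi ridge.
#' Edges longer than `alpha` (default twice the mean cell diameter) are
#' pruned: they arise across concavities of the tissue outline where the
#' shared ridge lies outside the tissue. Degenerate zero-length ridges
#' (cocircular centroids, e.g. exact lattices) are dropped.
#'
#' @param tissue an `sce_tissue`, or an n x 2 matrix of points.
#' @param alpha pruning distance (µm); `NULL` uses 2 x mean cell diameter
#'   (or no pruning for a bare point matrix).
#' @return an undirected simple `igraph` graph with vertex attribute
#'   `cell_id` and coordinates `x`, `y`.
#' @export
adhesion_graph <- function(tissue, alpha = NULL) {
  if (is.matrix(tissue)) {
    pts <- tissue
    ids <- seq_len(nrow(pts))
    if (is.null(alpha)) alpha <- Inf
  } else {
    cc <- cell_centroids(tissue)
    pts <- cbind(cc$x, cc$y)
    ids <- cc$cell_id
    if (is.null(alpha)) alpha <- 2 * mean_cell_diameter(tissue)
  }
  if (nrow(pts) < 3) stop("need at least 3 cells")
  nb <- voronoi_neighbors(pts)
  if (nrow(nb)) {
    d <- sqrt(rowSums((pts[nb$i, , drop = FALSE] - pts[nb$j, , drop = FALSE])^2))
    nb <- nb[d <= alpha, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = nrow(pts), directed = FALSE)
  if (nrow(nb)) g <- igraph::add_edges(g, t(as.matrix(nb[, c("i", "j")])))
  g <- igraph::simplify(g)
  igraph::V(g)$cell_id <- ids
  igraph::V(g)$x <- pts[, 1]
  igraph::V(g)$y <- pts[, 2]
  g
}

# Fundamental matrix of the randomized-shortest-path framework: reference
# random walk on the graph, Gibbs-Boltzmann reweighted by exp(-beta * cost)
rsp_Z <- function(g, beta) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  if (any(deg == 0)) stop("isolated vertex in centrality graph")
  P_ref <- A / deg
  W <- P_ref * exp(-beta)                    # unit edge costs
  Z <- solve(diag(nrow(A)) - W)
  if (any(Z <= 0)) Z[Z <= 0] <- .Machine$double.xmin
  Z
}

rsp_betweenness <- function(Z) {
  n <- nrow(Z)
  bet <- numeric(n)
  for (t in seq_len(n)) {
    # expected visits n_j(s,t) = Z_sj Z_jt / Z_st - Z_tj Z_jt / Z_tt + [j==t]
    N <- Z * outer(1 / Z[, t], Z[, t])
    const <- Z[t, ] * Z[, t] / Z[t, t]
    N <- sweep(N, 2, const)
    N[, t] <- N[, t] + 1
    N[t, ] <- 0                              # exclude s == t
    bet <- bet + colSums(N)
  }
  bet
}

rsp_net_betweenness <- function(Z, g, beta) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(A)
  W <- (A / deg) * exp(-beta)
  n <- nrow(Z)
  el <- igraph::as_edgelist(g, names = FALSE)
  ei <- c(el[, 1], el[, 2]); ej <- c(el[, 2], el[, 1])   # both directions
  wij <- W[cbind(ei, ej)]
  nE <- nrow(el)
  netsum <- numeric(nE)                      # per-edge |net flow| over pairs
  for (t in seq_len(n)) {
    Zt <- Z - outer(Z[, t], Z[t, ]) / Z[t, t]
    Zt[, t] <- Z[, t] / Z[t, t]              # hitting-path column
    for (s in seq_len(n)) {
      if (s == t) next
      if (Zt[s, t] < 1e-300) next
      eta <- Zt[s, ei] * wij * Zt[ej, t] / Zt[s, t]
      eta[ei == t] <- 0                      # target is absorbing: no outflow
      netsum <- netsum + abs(eta[seq_len(nE)] - eta[nE + seq_len(nE)])
    }
  }
  bet <- numeric(n)
  for (e in seq_len(nE)) {
    bet[el[e, 1]] <- bet[el[e, 1]] + netsum[e] / 2
    bet[el[e, 2]] <- bet[el[e, 2]] + netsum[e] / 2
  }
  bet
}

#' Graph centralities of the cell adjacency network
#'
#' PageRank (damped random-walk centrality, normalized to sum 1) plus the
#' randomized-shortest-path betweenness (RSPB) and net betweenness (RSPBN)
#' at inverse temperature `beta`: expected (net) visit counts over the
#' Gibbs-Boltzmann distribution on source-target paths, interpolating
#' between random-walk betweenness (small `beta`) and shortest-path
#' betweenness (large `beta`).
#'
#' @param graph connected undirected `igraph` graph (per-component
#'   computation with a warning otherwise).
#' @param beta inverse temperature of the RSP family.
#' @param damping PageRank damping factor.
#' @return data frame with `cell_id` (when present), `pagerank`, `rspb`,
#'   `rspbn`; attribute `beta` records the temperature used.
#' @export
centralities <- function(graph, beta = 1.0, damping = 0.85) {
  n <- igraph::vcount(graph)
  pr <- igraph::page_rank(graph, damping = damping)$vector
  rspb <- rspbn <- rep(NA_real_, n)
  comp <- igraph::components(graph)
  if (comp$no > 1) warning("graph is disconnected; centralities per component")
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    if (length(vs) < 2) { rspb[vs] <- 0; rspbn[vs] <- 0; next }
    sub <- igraph::induced_subgraph(graph, vs)
    Z <- rsp_Z(sub, beta)
    rspb[vs] <- rsp_betweenness(Z)
    rspbn[vs] <- rsp_net_betweenness(Z, sub, beta)
  }
  out <- data.frame(pagerank = as.numeric(pr), rspb = rspb, rspbn = rspbn)
  if (!is.null(igraph::V(graph)$cell_id))
    out <- cbind(cell_id = igraph::V(graph)$cell_id, out)
  attr(out, "beta") <- beta
  out
}
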