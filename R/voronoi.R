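# Planar Voronoi adjacency by half-plane clipping.
#
# For each generator point, its Voronoi cell is obtained by clipping a
# large bounding box with the perpendicular-bisector half-plane of every
# other generator (nearest first, so far generators rarely contribute).
# Two generators are adjacent when the bisector between them contributes
# an edge (ridge) of positive length to the clipped cell. O(n^2) with tiny
# constants; exact enough for tissues of a few hundred cells, and
# degenerate cocircular configurations simply produce zero-length ridges,
# which are dropped.

# clip convex polygon (verts, edge labels) by half-plane a.x <= b
clip_halfplane <- function(verts, labels, a, b, label) {
  m <- nrow(verts)
  if (m == 0) return(list(verts = verts, labels = labels))
  s <- verts %*% a - b
  keep_any <- any(s <= 1e-12)
  if (!keep_any) return(list(verts = verts[0, , drop = FALSE], labels = integer(0)))
  out_v <- matrix(numeric(0), 0, 2)
  out_l <- integer(0)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    inside_i <- s[i] <= 1e-12
    inside_j <- s[j] <= 1e-12
    if (inside_i) {
      out_v <- rbind(out_v, verts[i, ])
      out_l <- c(out_l, labels[i])
    }
    if (inside_i != inside_j) {
      t <- s[i] / (s[i] - s[j])
      q <- verts[i, ] + t * (verts[j, ] - verts[i, ])
      out_v <- rbind(out_v, q)
      # edge entering the excluded side starts the new bisector edge;
      # edge re-entering keeps the old edge's label
      out_l <- c(out_l, if (inside_i) label else labels[i])
    }
  }
  list(verts = out_v, labels = out_l)
}

#' Voronoi neighbour pairs of a planar point set
#'
#' @param pts n x 2 matrix of generator points (n >= 3).
#' @param min_ridge ridges shorter than this are treated as degenerate
#'   (cocircular point sets) and not reported.
#' @return data frame with columns `i`, `j` (1-based indices, i < j) and
#'   `ridge_length`.
#' @export
voronoi_neighbors <- function(pts, min_ridge = 1e-9) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (abs(max(pts[, 1]) - min(pts[, 1])) < 1e-12 &&
      abs(max(pts[, 2]) - min(pts[, 2])) < 1e-12)
    stop("degenerate point set")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  lo <- c(min(pts[, 1]), min(pts[, 2])) - 3 * span
  hi <- c(max(pts[, 1]), max(pts[, 2])) + 3 * span
  box <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]), c(hi[1], hi[2]), c(lo[1], hi[2]))
  edges <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    verts <- box
    labels <- rep(0L, 4)                    # box edges carry label 0
    d2 <- rowSums((pts - matrix(pts[i, ], n, 2, byrow = TRUE))^2)
    for (j in order(d2)) {
      if (j == i) next
      mid <- (pts[i, ] + pts[j, ]) / 2
      a <- pts[j, ] - pts[i, ]
      cl <- clip_halfplane(verts, labels, a, sum(a * mid), j)
      verts <- cl$verts; labels <- cl$labels
      if (nrow(verts) == 0) break
    }
    m <- nrow(verts)
    if (m == 0) next
    nxt <- c(2:m, 1)
    len <- sqrt(rowSums((verts[nxt, , drop = FALSE] - verts)^2))
    for (e in seq_len(m)) {
      j <- labels[e]
      if (j > 0 && len[e] > min_ridge) {
        key <- paste0(min(i, j), "|", max(i, j))
        old <- mget(key, envir = edges, ifnotfound = 0)[[1]]
        assign(key, max(old, len[e]), envir = edges)
      }
    }
  }
  keys <- ls(edges)
  if (!length(keys))
    return(data.frame(i = integer(0), j = integer(0), ridge_length = numeric(0)))
  ij <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    ridge_length = vapply(keys, get, numeric(1), envir = edges,
                                          USE.NAMES = FALSE))
  out[order(out$i, out$j), ]
}
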