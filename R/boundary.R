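# Tunica boundary tension.
#
# The meristem behaves like a pressurized shell: the tension the removed
# surrounding tissue exerted on the simulated section is reintroduced as a
# force of total magnitude |F| = (r_ex / 2) * w * P0 (µm^2 * MPa = µN),
# shared equally over the flagged outward-facing tunica nodes at the left
# and right edges of the section, directed to restore the experimentally
# observed curvature radius r_ex.

#' Boundary force magnitude from shell pressure
#'
#' `(r_ex / 2) * w * p0`, with µm²·MPa giving µN directly.
#'
#' @param r_ex radius of curvature of the epidermal surface (µm).
#' @param w mean out-of-plane cell width (µm).
#' @param p0 shell pressure (MPa).
#' @return total boundary force magnitude (µN).
#' @export
magnitude_from_pressure <- function(r_ex, w, p0) {
  if (p0 == 0) return(0)
  if (r_ex <= 0 || w <= 0 || p0 < 0)
    stop("domain error: boundary-force inputs must be positive")
  (r_ex / 2) * w * p0
}

#' Named boundary-tension conditions
#'
#' The calibrated pressure range maps to total magnitudes of 190 µN (low)
#' and 280 µN (high); "average" is their midpoint 235 µN, "2x" is the
#' doubled-maximum stress test 560 µN, and "free" applies no force.
#'
#' @param label one of `"free"`, `"low"`, `"average"`, `"high"`, `"2x"`.
#' @return total magnitude (µN).
#' @export
condition_magnitude <- function(label) {
  tbl <- c(free = 0, low = 190, average = 235, high = 280, "2x" = 560)
  if (!label %in% names(tbl))
    stop("config error: unknown boundary condition '", label, "'")
  unname(tbl[label])
}

#' Boundary-tension specification
#'
#' Either a named condition (rounded calibrated magnitudes) or an explicit
#' pressure (used unrounded through the shell formula).
#'
#' @param condition condition label, see [condition_magnitude()]; ignored
#'   when `pressure_mpa` is given.
#' @param pressure_mpa shell pressure (MPa), optional.
#' @param r_ex_um target radius of curvature (µm).
#' @param w_um mean out-of-plane cell width (µm).
#' @param direction_blend weight in \[0,1\] mixing the radial-correction
#'   component into the tangential pull (see [apply_boundary_force()]).
#'   This direction construction is a documented modelling choice.
#' @return list of class `sce_boundary_spec` with the resolved
#'   `total_magnitude`.
#' @export
boundary_force_spec <- function(condition = "average", pressure_mpa = NULL,
                                r_ex_um = 80.1, w_um = 7.09,
                                direction_blend = 0.5) {
  total <- if (!is.null(pressure_mpa)) {
    magnitude_from_pressure(r_ex_um, w_um, pressure_mpa)
  } else condition_magnitude(condition)
  structure(list(r_ex = r_ex_um, w = w_um,
                 p0 = if (is.null(pressure_mpa)) NA_real_ else pressure_mpa,
                 condition_label = if (is.null(pressure_mpa)) condition else NA_character_,
                 total_magnitude = total, direction_blend = direction_blend),
            class = "sce_boundary_spec")
}

#' Flag the outward-facing tunica edge nodes
#'
#' Boundary nodes are wall nodes of L1/L2 cells whose centroid lies within
#' the left or right edge band of the tunica and that sit on the outer side
#' of their cell (largest horizontal distance from the apex axis). They are
#' re-identified after every division.
#'
#' @param tissue an `sce_tissue`.
#' @param band_um width of the edge bands; default 1.5 mean cell diameters.
#' @return the tissue with its `is_boundary` flags replaced.
#' @export
identify_boundary_nodes <- function(tissue, band_um = NULL) {
  if (is.null(band_um)) band_um <- 1.5 * mean_cell_diameter(tissue)
  tissue$is_boundary <- rep(FALSE, nrow(tissue$pos))
  tun <- Filter(function(cl) cl$layer %in% c("L1", "L2"), tissue$cells)
  if (!length(tun)) return(tissue)
  cx <- vapply(tun, function(cl) cell_centroid(tissue, cl$id)[1], numeric(1))
  apex_x <- tissue$apex[1]
  xmin <- min(cx); xmax <- max(cx)
  for (k in seq_along(tun)) {
    if (cx[k] > xmin + band_um && cx[k] < xmax - band_um) next
    cl <- tun[[k]]
    rows <- node_rows(tissue, cl$wall)
    dx <- tissue$pos[rows, 1] - apex_x
    if (sign(cx[k] - apex_x) != 0) dx <- dx * sign(cx[k] - apex_x)
    thr <- stats::quantile(dx, 2 / 3, names = FALSE)
    tissue$is_boundary[rows[dx >= thr & dx > 0]] <- TRUE
  }
  tissue
}

#' Per-node boundary force field
#'
#' Each flagged node receives magnitude `total / n_boundary_nodes` along a
#' unit direction built from the circle of radius `r_ex` anchored at the
#' current apex: a tangential component oriented away from the apex
#' (generating in-plane tension) blended with a radial correction
#' proportional to the node's signed distance from the circle (restoring
#' the target curvature). The blend weight is `spec$direction_blend`; with
#' nodes exactly on the circle the pull is purely tangential.
#'
#' @param tissue an `sce_tissue` with current `is_boundary` flags.
#' @param spec an `sce_boundary_spec`.
#' @return list with `field` (n x 2 matrix, µN), `nodes` (flagged rows) and
#'   `magnitude_per_node`; the per-node magnitudes sum to the total exactly.
#' @export
apply_boundary_force <- function(tissue, spec) {
  n <- nrow(tissue$pos)
  field <- matrix(0, n, 2)
  rows <- which(tissue$is_boundary)
  if (spec$total_magnitude == 0)
    return(list(field = field, nodes = rows, magnitude_per_node = 0))
  if (!length(rows))
    stop("boundary force requested but no boundary nodes are flagged")
  centre <- tissue$apex - c(0, spec$r_ex)
  per <- spec$total_magnitude / length(rows)
  for (i in rows) {
    p <- tissue$pos[i, ]
    rv <- p - centre
    rn <- sqrt(sum(rv * rv))
    rhat <- if (rn > 0) rv / rn else c(0, 1)
    tang <- c(-rhat[2], rhat[1])                       # counter-clockwise
    if (p[1] > tissue$apex[1]) tang <- -tang           # away from the apex
    s <- rn - spec$r_ex                                # signed gap to circle
    v <- (1 - spec$direction_blend) * tang +
      spec$direction_blend * (-s / spec$w) * rhat
    vn <- sqrt(sum(v * v))
    if (vn == 0) v <- tang else v <- v / vn
    field[i, ] <- per * v
  }
  list(field = field, nodes = rows, magnitude_per_node = per)
}
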