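# Mechanics: parameter container, pair-list construction, force assembly
# and overdamped time stepping.
#
# The equations of motion are first-order (viscosity dominated): for a wall
# node, eta * dW/dt = -grad of (turgor + extensibility + bending + volume
# exclusion + adhesion) + F_boundary; for a cytoplasm node, eta * dC/dt =
# -grad of (cytoplasmic pressure + turgor). eta is a per-cell damping
# coefficient, multiplied by 10 in the bottom tissue layer, which anchors
# the section to the stiffer differentiated tissue below the meristem.

#' Mechanical parameter set
#'
#' Coefficients of the six interaction potentials plus damping and
#' neighbour-search settings. The shipped defaults are the package's own
#' calibration, chosen so that a generated cell relaxes to a round profile
#' 5-7 µm across and the tissue is stable at the default 0.4 s step; they
#' are not literature values. Units: energies µN·µm, lengths µm, stiffness
#' µN/µm, damping µN·s/µm.
#'
#' Each Morse block should satisfy `U/xi == V/gamma` so the pair force is
#' continuous through zero separation; validation warns otherwise.
#'
#' @param turgor,pressure,volume_exclusion Morse blocks: lists with `U`,
#'   `V`, `xi`, `gamma`. Turgor acts wall vs own-cytoplasm, pressure
#'   cytoplasm vs own-cytoplasm, volume exclusion wall vs other-cell wall.
#' @param extensibility wall spring: list with `k`, `l_eq`.
#' @param adhesion cell-cell adhesion spring: list with `k`, `l_eq`,
#'   `cutoff` (pair search radius), `max_partners` (per node per neighbour
#'   cell) and `refresh_steps` (re-pairing cadence in steps).
#' @param bending microfibril bending: list with `k_bend`, `theta_eq`.
#' @param eta_base damping coefficient per cell.
#' @param eta_bottom_multiplier damping multiplier for bottom-layer cells.
#' @param cutoff_um volume-exclusion interaction cutoff; default
#'   `3 * max(xi, gamma)` of the volume-exclusion Morse block.
#' @param dt_seconds integration step (s) of represented time.
#' @return a validated list of class `sce_params`.
#' @export
potential_params <- function(
    turgor = list(U = 240, V = 120, xi = 1.2, gamma = 0.6),
    pressure = list(U = 120, V = 60, xi = 1.0, gamma = 0.5),
    volume_exclusion = list(U = 240, V = 120, xi = 1.2, gamma = 0.6),
    extensibility = list(k = 600, l_eq = 1.0),
    adhesion = list(k = 240, l_eq = 0.5, cutoff = 1.6, max_partners = 1L,
                    refresh_steps = 25L),
    bending = list(k_bend = 10, theta_eq = pi),
    eta_base = 2000, eta_bottom_multiplier = 10,
    cutoff_um = NULL, dt_seconds = 0.4) {
  p <- list(turgor = turgor, pressure = pressure,
            volume_exclusion = volume_exclusion,
            extensibility = extensibility, adhesion = adhesion,
            bending = bending, eta_base = eta_base,
            eta_bottom_multiplier = eta_bottom_multiplier,
            cutoff_um = if (is.null(cutoff_um))
              3 * max(volume_exclusion$xi, volume_exclusion$gamma) else cutoff_um,
            dt_seconds = dt_seconds)
  class(p) <- "sce_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  for (nm in c("turgor", "pressure", "volume_exclusion")) {
    m <- p[[nm]]
    stopifnot(m$U > 0, m$V > 0, m$xi > 0, m$gamma > 0)
    if (abs(m$U / m$xi - m$V / m$gamma) > 1e-9 * (m$U / m$xi))
      warning(nm, " Morse block has U/xi != V/gamma: force is discontinuous ",
              "at zero separation", call. = FALSE)
  }
  stopifnot(p$extensibility$k > 0, p$extensibility$l_eq > 0,
            p$adhesion$k > 0, p$adhesion$l_eq >= 0, p$adhesion$cutoff > 0,
            p$bending$k_bend >= 0, p$eta_base > 0, p$cutoff_um > 0,
            p$dt_seconds > 0)
  invisible(p)
}

morse_vec <- function(m) c(m$U, m$V, m$xi, m$gamma)

# Per-node damping (per-cell eta; x multiplier in the bottom layer)
node_eta <- function(tissue, params) {
  eta <- numeric(nrow(tissue$pos))
  for (cl in tissue$cells) {
    e <- params$eta_base * if (isTRUE(cl$bottom)) params$eta_bottom_multiplier else 1
    eta[node_rows(tissue, c(cl$wall, cl$cyto))] <- e
  }
  eta
}

# 0-based interaction index lists for the kernel. The intra-cell part
# (turgor, pressure, springs, bending) changes only at topology events and
# is cached; the volume-exclusion and adhesion parts are refreshed every
# neighbour-refresh block.
intracell_pairs <- function(tissue, params) {
  ti <- tj <- pi_ <- pj <- ei <- ej <- bp <- bc <- bq <- integer(0)
  ek <- numeric(0)
  for (id in sort(as.integer(names(tissue$cells)))) {
    cl <- tissue$cells[[as.character(id)]]
    w <- node_rows(tissue, cl$wall) - 1L
    cy <- node_rows(tissue, cl$cyto) - 1L
    nw <- length(w)
    if (length(cy)) {
      ti <- c(ti, rep(w, each = length(cy)))
      tj <- c(tj, rep(cy, times = nw))
      if (length(cy) >= 2) {
        cmb <- utils::combn(cy, 2)
        pi_ <- c(pi_, cmb[1, ]); pj <- c(pj, cmb[2, ])
      }
    }
    nxt <- c(2:nw, 1)
    ei <- c(ei, w); ej <- c(ej, w[nxt])
    kk <- if (!is.null(cl$edge_k) && length(cl$edge_k) == nw) cl$edge_k
          else rep(params$extensibility$k, nw)
    ek <- c(ek, kk)
    prv <- c(nw, 1:(nw - 1))
    bp <- c(bp, w[prv]); bc <- c(bc, w); bq <- c(bq, w[nxt])
  }
  list(turg_i = as.integer(ti), turg_j = as.integer(tj),
       pres_i = as.integer(pi_), pres_j = as.integer(pj),
       ext_i = as.integer(ei), ext_j = as.integer(ej), ext_k = ek,
       bend_p = as.integer(bp), bend_c = as.integer(bc),
       bend_q = as.integer(bq),
       stamp = pair_stamp(tissue))
}

# cache key: bumped by node insertion/removal and polarization updates
pair_stamp <- function(tissue) {
  c(nrow(tissue$pos), length(tissue$cells), tissue$next_node_id,
    tissue$next_cell_id, if (is.null(tissue$rev)) 0L else tissue$rev)
}

build_pairs <- function(tissue, params, intra = NULL) {
  if (is.null(intra) || !identical(intra$stamp, pair_stamp(tissue)))
    intra <- intracell_pairs(tissue, params)
  intra <- intra[c("turg_i", "turg_j", "pres_i", "pres_j", "ext_i", "ext_j",
                   "ext_k", "bend_p", "bend_c", "bend_q", "stamp")]
  wall <- which(tissue$role == 0L)
  vi <- vj <- integer(0)
  if (length(wall) >= 2) {
    cand <- grid_pairs_cpp(tissue$pos[wall, , drop = FALSE],
                           tissue$node_cell[wall], params$cutoff_um)
    if (nrow(cand$pairs)) {
      vi <- wall[cand$pairs[, 1]] - 1L
      vj <- wall[cand$pairs[, 2]] - 1L
    }
  }
  ai <- aj <- integer(0)
  if (nrow(tissue$adhesion)) {
    ai <- node_rows(tissue, tissue$adhesion[, 1]) - 1L
    aj <- node_rows(tissue, tissue$adhesion[, 2]) - 1L
  }
  c(intra,
    list(ved_i = as.integer(vi), ved_j = as.integer(vj),
         adh_i = as.integer(ai), adh_j = as.integer(aj),
         adh_k = rep(params$adhesion$k, length(ai))))
}

#' Assemble the force field on every node
#'
#' Evaluates all interaction forces exactly as the equations of motion
#' assign them: wall nodes feel turgor (vs their own cytoplasm nodes), wall
#' extensibility springs (ring neighbours), microfibril bending (ring
#' triplets), volume exclusion (wall nodes of other cells within the
#' cutoff), adhesion springs (current partners) and any boundary force;
#' cytoplasm nodes feel cytoplasmic pressure (own cytoplasm) and turgor
#' (own wall).
#'
#' @param tissue an `sce_tissue`; adhesion pairs should be current
#'   (see [refresh_adhesion()]).
#' @param params an `sce_params` set.
#' @param boundary_force optional n x 2 matrix (or object from
#'   [apply_boundary_force()]) added to flagged nodes.
#' @param breakdown if `TRUE`, keep the per-term force matrices.
#' @return list with `force` (n x 2, µN), `energy` (total potential,
#'   µN·µm) and, when `breakdown = TRUE`, one matrix per term.
#' @export
assemble_forces <- function(tissue, params, boundary_force = NULL,
                            breakdown = FALSE) {
  pairs <- build_pairs(tissue, params)
  out <- sce_forces_cpp(tissue$pos, pairs,
                        morse_vec(params$turgor), morse_vec(params$pressure),
                        morse_vec(params$volume_exclusion),
                        params$extensibility$l_eq, params$adhesion$l_eq,
                        params$bending$k_bend, params$bending$theta_eq,
                        breakdown)
  if (!is.null(boundary_force)) {
    bf <- if (is.list(boundary_force)) boundary_force$field else boundary_force
    out$force <- out$force + bf
    if (breakdown) out$boundary <- bf
  }
  out
}

#' Advance the tissue by overdamped forward-Euler steps
#'
#' Positions update as `x <- x + (F / eta) * dt`; damping is per cell, ten
#' times larger in the bottom layer. The interaction pair lists and the
#' boundary force are held fixed across the `nsteps` of one call, so keep
#' calls short (the driver uses the adhesion refresh cadence). Non-finite
#' positions abort with the offending node.
#'
#' @param tissue an `sce_tissue`.
#' @param params an `sce_params`.
#' @param dt step length in seconds, > 0.
#' @param nsteps number of steps to take with frozen neighbour lists.
#' @param boundary_force optional n x 2 matrix or [apply_boundary_force()]
#'   result.
#' @param track_energy if `TRUE`, attach the per-step total potential
#'   energy as attribute `energy` of the returned tissue.
#' @return the advanced tissue (time moved by `nsteps * dt`).
#' @export
step <- function(tissue, params, dt = params$dt_seconds, nsteps = 1L,
                 boundary_force = NULL, track_energy = FALSE, pairs = NULL) {
  stopifnot(dt > 0, nsteps >= 1)
  if (is.null(pairs)) pairs <- build_pairs(tissue, params)
  fext <- matrix(0, nrow(tissue$pos), 2)
  if (!is.null(boundary_force)) {
    bf <- if (is.list(boundary_force)) boundary_force$field else boundary_force
    fext <- fext + bf
  }
  res <- sce_integrate_cpp(tissue$pos, node_eta(tissue, params), pairs,
                           morse_vec(params$turgor), morse_vec(params$pressure),
                           morse_vec(params$volume_exclusion),
                           params$extensibility$l_eq, params$adhesion$l_eq,
                           params$bending$k_bend, params$bending$theta_eq,
                           fext, as.integer(nsteps), dt, track_energy)
  tissue$pos <- res$pos
  tissue$time_h <- tissue$time_h + nsteps * dt / 3600
  if (track_energy) attr(tissue, "energy") <- res$energy
  tissue
}

#' Total potential energy of the tissue
#' @inheritParams assemble_forces
#' @return scalar energy (µN·µm).
#' @export
tissue_energy <- function(tissue, params) {
  assemble_forces(tissue, params)$energy
}

#' Relax a tissue with mechanics only
#'
#' Pure gradient flow: no growth, no boundary force. Adhesion pairings and
#' volume-exclusion neighbour lists are refreshed every
#' `params$adhesion$refresh_steps` steps.
#'
#' @inheritParams step
#' @param nsteps total steps.
#' @return the relaxed tissue.
#' @export
relax_tissue <- function(tissue, params, nsteps = 1000L,
                         dt = params$dt_seconds) {
  block <- max(1L, as.integer(params$adhesion$refresh_steps))
  done <- 0L
  intra <- NULL
  while (done < nsteps) {
    tissue <- refresh_adhesion(tissue, params$adhesion$cutoff,
                               params$adhesion$max_partners)
    pairs <- build_pairs(tissue, params, intra)
    intra <- pairs
    k <- min(block, nsteps - done)
    tissue <- step(tissue, params, dt = dt, nsteps = k, pairs = pairs)
    done <- done + k
  }
  tissue
}
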