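# WUSCHEL / cytokinin signal gradients.
#
# Concentrations are static exponential gradients around point "signal
# centres" on the apex axis: [WUS] = wus0 exp(-mu_wus * r_wus), likewise
# for CK, evaluated at each cell's centroid. Tunica layers (L1, L2) keep
# CK at zero: they lack its receptors. The gradients do not evolve
# dynamically; they are re-evaluated on the current geometry at each
# snapshot, and the centres are re-placed when the apex has moved by more
# than one mean cell diameter.

#' Signal gradient parameters
#'
#' Peak concentrations, decay rates and the signal-centre depths below the
#' apex (in multiples of the mean cell diameter). The numeric defaults are
#' package placeholders: the calibrated values live outside this package,
#' so these are chosen to give a WUS gradient spanning the central zone and
#' a deeper, flatter CK domain, and are flagged as such in the
#' configuration.
#'
#' @param wus0,ck0 peak concentrations (a.u.).
#' @param mu_wus,mu_ck decay rates (1/µm), non-negative.
#' @param wus_depth_cells,ck_depth_cells centre depths below the apex in
#'   mean cell diameters; the WUS centre sits shallower than the CK centre.
#' @return list of class `sce_signal_params`.
#' @export
signal_params <- function(wus0 = 1, ck0 = 1, mu_wus = 0.10, mu_ck = 0.06,
                          wus_depth_cells = 2, ck_depth_cells = 3.5) {
  stopifnot(wus0 >= 0, ck0 >= 0, mu_wus >= 0, mu_ck >= 0)
  structure(list(wus0 = wus0, ck0 = ck0, mu_wus = mu_wus, mu_ck = mu_ck,
                 wus_depth_cells = wus_depth_cells,
                 ck_depth_cells = ck_depth_cells),
            class = "sce_signal_params")
}

#' Mean cell diameter of the tissue
#'
#' Mean over cells of the equal-area circle diameter `2*sqrt(area/pi)`;
#' the tissue's intrinsic length unit for zone rules and centre depths.
#'
#' @param tissue an `sce_tissue`.
#' @return mean diameter (µm).
#' @export
mean_cell_diameter <- function(tissue) {
  a <- vapply(tissue$cells, function(cl)
    abs(polygon_area(tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE])),
    numeric(1))
  mean(2 * sqrt(a / pi))
}

#' Place the WUS and CK signal centres
#'
#' Centres sit on the vertical apex axis at the configured depths below the
#' apex, expressed in multiples of the current mean cell diameter, so their
#' position is determined by the cell sizes the mechanics produced.
#'
#' @param tissue an `sce_tissue`.
#' @param params an `sce_signal_params`.
#' @return the tissue with `wus_centre` and `ck_centre` set.
#' @export
place_signal_centres <- function(tissue, params) {
  d <- mean_cell_diameter(tissue)
  apex <- tissue$apex
  tissue$wus_centre <- c(apex[1], apex[2] - params$wus_depth_cells * d)
  tissue$ck_centre <- c(apex[1], apex[2] - params$ck_depth_cells * d)
  lim <- range(tissue$pos[, 2])
  if (tissue$ck_centre[2] < lim[1] || tissue$wus_centre[2] > lim[2])
    warning("signal centre placed outside the tissue extent")
  tissue
}

#' Assign WUS and CK concentrations to every cell
#'
#' Exponential decay with distance from each centre to the cell centroid;
#' CK is forced to zero in L1 and L2. Idempotent on a static tissue.
#'
#' @param tissue an `sce_tissue` with signal centres placed.
#' @param params an `sce_signal_params`.
#' @return the tissue with per-cell `wus` and `ck` updated.
#' @export
assign_concentrations <- function(tissue, params) {
  if (is.null(tissue$wus_centre) || is.null(tissue$ck_centre))
    tissue <- place_signal_centres(tissue, params)
  for (nm in names(tissue$cells)) {
    cl <- tissue$cells[[nm]]
    cen <- cell_centroid(tissue, cl$id)
    rw <- sqrt(sum((cen - tissue$wus_centre)^2))
    rc <- sqrt(sum((cen - tissue$ck_centre)^2))
    cl$wus <- params$wus0 * exp(-params$mu_wus * rw)
    cl$ck <- if (cl$layer %in% c("L1", "L2")) 0
             else params$ck0 * exp(-params$mu_ck * rc)
    tissue$cells[[nm]] <- cl
  }
  tissue
}
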