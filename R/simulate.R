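# Simulation driver and experiment runner.
#
# Main loop, per mechanics block (the adhesion refresh cadence): re-pair
# adhesion, rebuild the boundary force on the current geometry, integrate
# the overdamped dynamics, advance cell cycles (inserting cytoplasm
# nodes), split over-stretched wall edges, and execute any pending
# divisions. At each snapshot interval the signal gradients are refreshed
# on the current geometry and the tissue-structure metrics are recorded.

#' Simulation configuration
#'
#' @param variant `"2d"` or `"p3d"`. The 2D variant is exactly the P3D
#'   variant with all out-of-plane probabilities forced to zero.
#' @param boundary a boundary condition label (see [condition_magnitude()])
#'   or an `sce_boundary_spec`.
#' @param duration_hours simulated duration (h).
#' @param snapshot_interval_hours metric sampling interval (h).
#' @param seed integer seed for the run's random streams.
#' @param params,growth,signaling parameter sets; defaults are the package
#'   defaults of [potential_params()], [growth_params()], [signal_params()].
#' @param check_invariants validate the tissue after every topology event
#'   (slower; used by the test suite).
#' @return list of class `sce_config`.
#' @export
sim_config <- function(variant = "p3d", boundary = "average",
                       duration_hours = 40, snapshot_interval_hours = 0.5,
                       seed = 1L, params = potential_params(),
                       growth = growth_params(), signaling = signal_params(),
                       check_invariants = FALSE) {
  stopifnot(variant %in% c("2d", "p3d"), duration_hours >= 0,
            snapshot_interval_hours > 0)
  if (is.character(boundary)) boundary <- boundary_force_spec(boundary)
  structure(list(variant = variant, boundary = boundary,
                 duration_hours = duration_hours,
                 snapshot_interval_hours = snapshot_interval_hours,
                 seed = as.integer(seed), params = params, growth = growth,
                 signaling = signaling,
                 check_invariants = isTRUE(check_invariants)),
            class = "sce_config")
}

update_apex <- function(tissue) {
  wrows <- which(tissue$role == 0L)
  tissue$apex <- tissue$pos[wrows[which.max(tissue$pos[wrows, 2])], ]
  tissue
}

region_mean_ar <- function(tissue, layer) {
  ids <- vapply(Filter(function(cl) cl$layer == layer, tissue$cells),
                `[[`, integer(1), "id")
  if (!length(ids)) return(NA_real_)
  mean(vapply(ids, function(i)
    tryCatch(aspect_ratio(i, tissue), error = function(e) NA_real_),
    numeric(1)), na.rm = TRUE)
}

snapshot_metrics <- function(tissue) {
  ml <- tryCatch(monolayer_length(tissue),
                 error = function(e) list(length_um = NA_real_, break_detected = TRUE))
  rc <- tryCatch(relative_curvature(tissue), error = function(e) NA_real_)
  data.frame(
    time_h = tissue$time_h, n_cells = length(tissue$cells),
    monolayer_length = ml$length_um, break_detected = ml$break_detected,
    relative_curvature = rc,
    ar_L1 = region_mean_ar(tissue, "L1"),
    ar_L2 = region_mean_ar(tissue, "L2"),
    ar_apical_corpus = region_mean_ar(tissue, "apical_corpus"),
    ar_basal_corpus = region_mean_ar(tissue, "basal_corpus"))
}

#' Run one simulation
#'
#' @param config an `sce_config`.
#' @param tissue an initial `sce_tissue`, e.g. from
#'   [generate_initial_tissue()]; its seed is replaced by `config$seed`.
#' @param snapshot_dir optional directory; when given, a snapshot is
#'   written at every metric interval.
#' @return list of class `sce_sim` with the final `tissue`, the `metrics`
#'   series (one row per snapshot, with monolayer jump detection applied),
#'   the `division_log`, the resolved `config` and a `halted` flag (set
#'   when an instability stopped the run; the last valid state is kept).
#' @export
run_simulation <- function(config, tissue, snapshot_dir = NULL) {
  params <- config$params; gp <- config$growth; sp <- config$signaling
  tissue$seed <- config$seed
  dt <- params$dt_seconds
  block <- max(1L, as.integer(params$adhesion$refresh_steps))
  block_h <- block * dt / 3600
  n_blocks <- ceiling(config$duration_hours / block_h)
  snap_every <- max(1L, round(config$snapshot_interval_hours / block_h))

  tissue <- update_apex(tissue)
  tissue <- place_signal_centres(tissue, sp)
  tissue <- assign_concentrations(tissue, sp)
  tissue <- identify_boundary_nodes(tissue)
  tissue <- refresh_adhesion(tissue, params$adhesion$cutoff,
                             params$adhesion$max_partners)
  metrics <- snapshot_metrics(tissue)
  if (!is.null(snapshot_dir))
    write_snapshot(tissue, file.path(snapshot_dir, "t0000"))
  centre_apex <- tissue$apex
  halted <- FALSE
  intra <- NULL

  if (config$duration_hours > 0) for (b in seq_len(n_blocks)) {
    res <- tryCatch({
      tis <- refresh_adhesion(tissue, params$adhesion$cutoff,
                              params$adhesion$max_partners)
      bf <- apply_boundary_force(tis, config$boundary)
      pairs <- build_pairs(tis, params, intra)
      intra <- pairs
      tis <- step(tis, params, dt = dt, nsteps = block, boundary_force = bf,
                  pairs = pairs)
      tis <- update_apex(tis)
      for (id in sort(as.integer(names(tis$cells))))
        tis <- advance_cycle(tis, id, block_h, gp)
      for (id in sort(as.integer(names(tis$cells))))
        tis <- insert_wall_nodes(tis, id, gp$wall_strain_threshold,
                                 params$extensibility$l_eq)
      ready <- Filter(function(cl) cl$cp >= 1 && cl$layer != "boundary_cell",
                      tis$cells)
      if (length(ready)) {
        for (cl in ready) {
          if (is.null(tis$cells[[as.character(cl$id)]])) next
          if (tis$cells[[as.character(cl$id)]]$polarization == "out_of_plane") {
            tis <- execute_division(tis, cl$id, NULL, gp, params, config$variant)
          } else {
            pl <- choose_division_plane(tis, cl$id, gp, params)
            if (is.null(pl)) next
            tis <- pl$tissue
            pl$tissue <- NULL
            tis <- execute_division(tis, cl$id, pl, gp, params, config$variant)
          }
        }
        tis <- relabel_regions(tis, gp)
        tis <- identify_boundary_nodes(tis)
        tis <- refresh_adhesion(tis, params$adhesion$cutoff,
                                params$adhesion$max_partners)
        if (config$check_invariants) validate_tissue(tis)
      }
      tis
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("simulation halted at t=", format(tissue$time_h, digits = 4),
              " h: ", conditionMessage(res))
      halted <- TRUE
      break
    }
    tissue <- res
    if (b %% snap_every == 0 || b == n_blocks) {
      moved <- sqrt(sum((tissue$apex - centre_apex)^2))
      if (moved > mean_cell_diameter(tissue)) {
        tissue <- place_signal_centres(tissue, sp)
        centre_apex <- tissue$apex
      }
      tissue <- assign_concentrations(tissue, sp)
      metrics <- rbind(metrics, snapshot_metrics(tissue))
      if (!is.null(snapshot_dir))
        write_snapshot(tissue, file.path(snapshot_dir,
                                         sprintf("t%04d", nrow(metrics) - 1)))
    }
  }
  # monolayer jump detection on the recorded series
  if (nrow(metrics) > 1) {
    d_l1 <- mean_l1_diameter(tissue)
    jump <- c(FALSE, abs(diff(metrics$monolayer_length)) > 2 * d_l1)
    jump[is.na(jump)] <- FALSE
    metrics$break_detected <- metrics$break_detected | jump
  }
  structure(list(tissue = tissue, metrics = metrics,
                 division_log = tissue$division_log, config = config,
                 halted = halted),
            class = "sce_sim")
}

mean_l1_diameter <- function(tissue) {
  l1 <- Filter(function(cl) cl$layer == "L1", tissue$cells)
  if (!length(l1)) return(mean_cell_diameter(tissue))
  a <- vapply(l1, function(cl)
    abs(polygon_area(tissue$pos[node_rows(tissue, cl$wall), , drop = FALSE])),
    numeric(1))
  mean(2 * sqrt(a / pi))
}

#' @export
print.sce_sim <- function(x, ...) {
  cat("<sce_sim> ", x$config$variant, " variant, boundary total ",
      x$config$boundary$total_magnitude, " µN, ",
      format(max(x$metrics$time_h), digits = 4), " h simulated\n", sep = "")
  cat("  cells ", x$metrics$n_cells[1], " -> ", length(x$tissue$cells),
      "; divisions: ",
      if (nrow(x$division_log)) sum(x$division_log$mode == "in_plane") else 0,
      " in-plane, ",
      if (nrow(x$division_log)) sum(x$division_log$mode == "out_of_plane") else 0,
      " out-of-plane\n", sep = "")
  cat("  monolayer break detected: ", any(x$metrics$break_detected),
      if (x$halted) "; run halted early" else "", "\n", sep = "")
  invisible(x)
}

#' Run an experiment over model/boundary arms
#'
#' Runs `replicates` simulations per arm with seeds derived from
#' `base_seed` via the counter-based splitting scheme, and summarises the
#' paper-style readouts per arm: monolayer disruption fraction, final mean
#' aspect ratios per region, relative-curvature mean and variance at the
#' final time, and pooled apical-corpus percent-periclinal frequency.
#' Failed replicates are recorded, not fatal.
#'
#' @param arms list of `list(variant=, boundary=)` pairs.
#' @param replicates replicates per arm (>= 1).
#' @param base_seed integer experiment seed.
#' @param tissue_args arguments for [generate_initial_tissue()] (scale knobs).
#' @param config_args arguments for [sim_config()] besides variant/boundary/seed.
#' @return list with per-run `runs` and per-arm `summary` data frames.
#' @export
run_experiment <- function(arms, replicates = 3, base_seed = 1L,
                           tissue_args = list(), config_args = list()) {
  stopifnot(replicates >= 1)
  runs <- list(); k <- 0L
  for (a in seq_along(arms)) {
    arm <- arms[[a]]
    for (r in seq_len(replicates)) {
      k <- k + 1L
      seed_r <- derive_seed(base_seed, 1000L * a + r)
      cfg <- do.call(sim_config, c(list(variant = arm$variant,
                                        boundary = arm$boundary,
                                        seed = seed_r), config_args))
      res <- tryCatch({
        tis <- do.call(generate_initial_tissue,
                       c(list(seed = seed_r, variant = arm$variant,
                              params = cfg$params, gp = cfg$growth,
                              sp = cfg$signaling), tissue_args))
        run_simulation(cfg, tis)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        runs[[k]] <- data.frame(arm = a, variant = arm$variant,
                                boundary = as.character(arm$boundary),
                                replicate = r, seed = seed_r, failed = TRUE,
                                disrupted = NA, final_curvature = NA_real_,
                                pct_periclinal_ac = NA_real_,
                                ar_L1 = NA_real_, ar_L2 = NA_real_)
        next
      }
      fin <- res$metrics[nrow(res$metrics), ]
      pp <- suppressWarnings(percent_periclinal(res$division_log, "apical_corpus"))
      runs[[k]] <- data.frame(arm = a, variant = arm$variant,
                              boundary = as.character(arm$boundary),
                              replicate = r, seed = seed_r, failed = FALSE,
                              disrupted = any(res$metrics$break_detected),
                              final_curvature = fin$relative_curvature,
                              pct_periclinal_ac = pp,
                              ar_L1 = fin$ar_L1, ar_L2 = fin$ar_L2)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$arm), function(g) {
    ok <- g[!g$failed, , drop = FALSE]
    data.frame(arm = g$arm[1], variant = g$variant[1], boundary = g$boundary[1],
               n_ok = nrow(ok),
               disruption_fraction = mean(ok$disrupted),
               curvature_mean = mean(ok$final_curvature, na.rm = TRUE),
               curvature_var = stats::var(ok$final_curvature),
               pct_periclinal_ac = mean(ok$pct_periclinal_ac, na.rm = TRUE),
               ar_L1 = mean(ok$ar_L1, na.rm = TRUE),
               ar_L2 = mean(ok$ar_L2, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}
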