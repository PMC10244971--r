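# Snapshot input/output and configuration files.
#
# A snapshot is a directory holding two delimited-text tables -- nodes.tsv
# (node_id, cell_id, role, ring_index, x, y, is_boundary) and cells.tsv
# (cell_id, layer, zone, polarization, wus, ck, cycle_progress, bottom,
# parent) -- plus meta.json with the schema version, simulated time,
# signal centres, apex, seed, adhesion pairs and the per-cell stream
# counters. Numeric columns are written with 17 significant digits so the
# round trip is exact to at least 15. Unknown ("foreign") columns in
# either table survive a read/write cycle untouched.

SNAPSHOT_SCHEMA <- "samsce-snapshot-1"

num17 <- function(x) sprintf("%.17g", x)

#' Write a tissue snapshot
#' @param tissue an `sce_tissue`.
#' @param path snapshot directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(tissue, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nd <- data.frame(
    node_id = tissue$node_id, cell_id = tissue$node_cell,
    role = ifelse(tissue$role == 0L, "wall", "cytoplasm"),
    ring_index = tissue$ring_index,
    x = num17(tissue$pos[, 1]), y = num17(tissue$pos[, 2]),
    is_boundary = tissue$is_boundary)
  ex <- attr(tissue, "extra_node_cols")
  if (!is.null(ex)) nd <- merge(nd, ex, by = "node_id", all.x = TRUE, sort = FALSE)
  nd <- nd[order(nd$node_id), ]
  ids <- sort(as.integer(names(tissue$cells)))
  cl <- lapply(ids, function(i) tissue$cells[[as.character(i)]])
  cd <- data.frame(
    cell_id = ids,
    layer = vapply(cl, `[[`, character(1), "layer"),
    zone = vapply(cl, `[[`, character(1), "zone"),
    polarization = vapply(cl, `[[`, character(1), "polarization"),
    wus = num17(vapply(cl, `[[`, numeric(1), "wus")),
    ck = num17(vapply(cl, `[[`, numeric(1), "ck")),
    cycle_progress = num17(vapply(cl, `[[`, numeric(1), "cp")),
    bottom = vapply(cl, function(x) isTRUE(x$bottom), logical(1)),
    parent = vapply(cl, `[[`, integer(1), "parent"))
  ex <- attr(tissue, "extra_cell_cols")
  if (!is.null(ex)) cd <- merge(cd, ex, by = "cell_id", all.x = TRUE, sort = FALSE)
  write.table(nd, file.path(path, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cd, file.path(path, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(schema = SNAPSHOT_SCHEMA, time_h = tissue$time_h,
               seed = tissue$seed,
               wus_centre = tissue$wus_centre, ck_centre = tissue$ck_centre,
               apex = tissue$apex, base_y = tissue$base_y,
               adhesion = if (nrow(tissue$adhesion))
                 apply(tissue$adhesion, 1, identity, simplify = FALSE) else list(),
               counters = setNames(lapply(cl, function(x) as.list(x$counters)),
                                   ids))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a tissue snapshot
#' @param path snapshot directory written by [write_snapshot()].
#' @return an `sce_tissue`.
#' @export
read_snapshot <- function(path) {
  fn <- file.path(path, "meta.json")
  if (!file.exists(fn)) stop("not a snapshot directory: ", path)
  meta <- jsonlite::read_json(fn, simplifyVector = TRUE)
  if (!identical(meta$schema, SNAPSHOT_SCHEMA))
    stop("snapshot schema mismatch: found '", meta$schema, "', expected '",
         SNAPSHOT_SCHEMA, "'")
  nd <- tryCatch(
    read.delim(file.path(path, "nodes.tsv"), stringsAsFactors = FALSE),
    error = function(e) stop("parse error in nodes.tsv: ", conditionMessage(e)))
  cd <- tryCatch(
    read.delim(file.path(path, "cells.tsv"), stringsAsFactors = FALSE),
    error = function(e) stop("parse error in cells.tsv: ", conditionMessage(e)))
  core_n <- c("node_id", "cell_id", "role", "ring_index", "x", "y", "is_boundary")
  core_c <- c("cell_id", "layer", "zone", "polarization", "wus", "ck",
              "cycle_progress", "bottom", "parent")
  miss <- setdiff(core_n, names(nd))
  if (length(miss)) stop("nodes.tsv is missing column(s): ",
                         paste(miss, collapse = ", "),
                         " (line 1: truncated or foreign file?)")
  tis <- build_tissue(nd[core_n], cd[intersect(core_c, names(cd))],
                      wus_centre = unlist(meta$wus_centre),
                      ck_centre = unlist(meta$ck_centre),
                      apex = unlist(meta$apex), time_h = meta$time_h,
                      seed = meta$seed)
  tis$base_y <- meta$base_y
  if ("bottom" %in% names(cd)) for (i in seq_len(nrow(cd))) {
    key <- as.character(cd$cell_id[i])
    tis$cells[[key]]$bottom <- isTRUE(cd$bottom[i])
    if ("parent" %in% names(cd)) tis$cells[[key]]$parent <- cd$parent[i]
  }
  if (length(meta$adhesion)) {
    adh <- meta$adhesion
    if (is.list(adh)) adh <- do.call(rbind, lapply(adh, as.integer))
    adh <- matrix(as.integer(adh), ncol = 2)
    tis$adhesion <- adh[order(adh[, 1], adh[, 2]), , drop = FALSE]
  }
  if (length(meta$counters)) for (key in names(meta$counters)) {
    if (!is.null(tis$cells[[key]]))
      tis$cells[[key]]$counters[names(meta$counters[[key]])] <-
        as.integer(unlist(meta$counters[[key]]))
  }
  extra_n <- setdiff(names(nd), core_n)
  if (length(extra_n))
    attr(tis, "extra_node_cols") <- nd[c("node_id", extra_n)]
  extra_c <- setdiff(names(cd), core_c)
  if (length(extra_c))
    attr(tis, "extra_cell_cols") <- cd[c("cell_id", extra_c)]
  validate_tissue(tis)
  tis
}

#' Read a simulation configuration from YAML
#'
#' Recognised blocks: top-level `variant`, `duration_hours`,
#' `snapshot_interval_hours`, `seed`; `boundary` (either `condition` or
#' `pressure_mpa` with `r_ex_um`, `w_um`, plus `direction_blend`);
#' `mechanics` (`dt_seconds`, `cutoff_um`, `adhesion_refresh_steps`, and
#' one sub-table per potential); `signaling`; `growth`. Unspecified
#' entries keep the package defaults.
#'
#' @param path YAML file.
#' @return an `sce_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  mech <- y$mechanics
  pp_args <- list()
  for (nm in c("turgor", "pressure", "volume_exclusion", "extensibility",
               "adhesion", "bending"))
    if (!is.null(mech[[nm]])) pp_args[[nm]] <-
      utils::modifyList(formals(potential_params)[[nm]] |> eval(), mech[[nm]])
  for (nm in c("eta_base", "eta_bottom_multiplier", "cutoff_um", "dt_seconds"))
    if (!is.null(mech[[nm]])) pp_args[[nm]] <- mech[[nm]]
  if (!is.null(mech$adhesion_refresh_steps)) {
    pp_args$adhesion <- utils::modifyList(
      pp_args$adhesion %||% eval(formals(potential_params)$adhesion),
      list(refresh_steps = mech$adhesion_refresh_steps))
  }
  params <- do.call(potential_params, pp_args)
  gp <- do.call(growth_params, y$growth %||% list())
  sp <- do.call(signal_params, y$signaling %||% list())
  bnd <- y$boundary
  boundary <- if (is.null(bnd)) "average"
    else do.call(boundary_force_spec, bnd)
  sim_config(variant = y$variant %||% "p3d", boundary = boundary,
             duration_hours = y$duration_hours %||% 40,
             snapshot_interval_hours = y$snapshot_interval_hours %||% 0.5,
             seed = y$seed %||% 1L, params = params, growth = gp,
             signaling = sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
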