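test_that("the generator builds a labelled, well-formed dome section", {
  tis <- suppressWarnings(generate_initial_tissue(
    n_columns = 9, corpus_rows = 2, seed = 4, relax_steps = 0L))
  lay <- vapply(tis$cells, `[[`, character(1), "layer")
  expect_equal(sum(lay == "L1"), 9)
  expect_equal(sum(lay == "L2"), 9)
  expect_equal(sum(lay == "boundary_cell"), 2 * 5)   # two flank columns
  expect_gt(sum(lay %in% c("apical_corpus", "basal_corpus")), 0)
  expect_silent(validate_tissue(tis))
  # L1 and L2 each form a single 9-cell adjacency chain
  tis <- refresh_adhesion(tis, potential_params()$adhesion$cutoff)
  ml <- monolayer_length(tis)
  expect_length(ml$chain, 9)
  expect_false(ml$break_detected)
  # bottom row is damped 10x
  bottoms <- Filter(function(cl) isTRUE(cl$bottom), tis$cells)
  expect_gt(length(bottoms), 0)
  eta <- samsce:::node_eta(tis, potential_params())
  r1 <- samsce:::node_rows(tis, bottoms[[1]]$wall[1])
  expect_equal(eta[r1], potential_params()$eta_base * 10)
  expect_error(generate_initial_tissue(n_columns = 3), "at least 5")
})

test_that("the generator is deterministic and relaxes cleanly", {
  a <- small_tissue(seed = 12, relax_steps = 300L)
  b <- small_tissue(seed = 12, relax_steps = 300L)
  expect_identical(a$pos, b$pos)
  expect_identical(a$adhesion, b$adhesion)
  expect_identical(vapply(a$cells, `[[`, character(1), "polarization"),
                   vapply(b$cells, `[[`, character(1), "polarization"))
  # relaxation smoke test: no wall ring self-intersects
  si <- vapply(names(a$cells), function(i)
    attr(cell_polygon(as.integer(i), a), "self_intersecting"), logical(1))
  expect_false(any(si))
})

test_that("zero-duration runs return the initial metrics only", {
  tis <- small_tissue(relax_steps = 50L)
  cfg <- sim_config(variant = "p3d", boundary = "free", duration_hours = 0,
                    seed = 3)
  sim <- run_simulation(cfg, tis)
  expect_equal(nrow(sim$metrics), 1)
  expect_equal(sim$metrics$time_h, tis$time_h)
  expect_equal(nrow(sim$division_log), 0)
})

test_that("identical configuration and seed reproduce a run exactly", {
  tis <- small_tissue(seed = 8, relax_steps = 100L)
  cfg <- sim_config(variant = "p3d", boundary = "average",
                    duration_hours = 0.3, snapshot_interval_hours = 0.1,
                    seed = 8)
  s1 <- run_simulation(cfg, tis)
  s2 <- run_simulation(cfg, tis)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$tissue$pos, s2$tissue$pos)
})

test_that("boundary tension changes the trajectory", {
  tis <- small_tissue(seed = 8, relax_steps = 100L)
  free <- run_simulation(sim_config(variant = "p3d", boundary = "free",
                                    duration_hours = 0.2, seed = 8), tis)
  avg <- run_simulation(sim_config(variant = "p3d", boundary = "average",
                                   duration_hours = 0.2, seed = 8), tis)
  expect_false(identical(free$tissue$pos, avg$tissue$pos))
  expect_false(isTRUE(all.equal(free$metrics$monolayer_length[-1],
                                avg$metrics$monolayer_length[-1])))
})

test_that("experiments fan out over arms and replicates deterministically", {
  arms <- list(list(variant = "2d", boundary = "free"),
               list(variant = "p3d", boundary = "free"))
  ex <- run_experiment(arms, replicates = 2, base_seed = 5,
                       tissue_args = list(n_columns = 5, corpus_rows = 1,
                                          relax_steps = 50L),
                       config_args = list(duration_hours = 0.1,
                                          snapshot_interval_hours = 0.05))
  expect_equal(nrow(ex$runs), 4)
  expect_equal(nrow(ex$summary), 2)
  expect_true(all(!ex$runs$failed))
  # disruption fraction is the share of replicates with any detected break
  g <- ex$runs[ex$runs$arm == 1, ]
  expect_equal(ex$summary$disruption_fraction[1], mean(g$disrupted))
  ex2 <- run_experiment(arms, replicates = 2, base_seed = 5,
                        tissue_args = list(n_columns = 5, corpus_rows = 1,
                                           relax_steps = 50L),
                        config_args = list(duration_hours = 0.1,
                                           snapshot_interval_hours = 0.05))
  expect_identical(ex$runs, ex2$runs)
})
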