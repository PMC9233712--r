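test_that("the Metropolis acceptance rule has the prescribed statistics", {
  # energy-lowering moves are always accepted
  expect_true(all(extrudr:::cpp_accept_rule(rep(-0.1, 1000), 0.05)))
  # energy-raising moves are accepted with probability p_accept
  set.seed(99)
  n <- 1e5
  acc <- extrudr:::cpp_accept_rule(rep(0.1, n), 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(acc) - 0.05), 3 * se)
})

test_that("trial displacements are bounded by delta_max per coordinate", {
  m <- build_initial_tissue(30, seed = 5)
  st <- simulation_state(m)
  set.seed(7)
  p <- model_params()
  for (i in 1:200) {
    before <- st$mesh$vertices
    st <- metropolis_step(st, p)
    moved <- abs(st$mesh$vertices - before)
    expect_lte(max(moved), p$delta_max + 1e-12)
    expect_lte(sum(rowSums(moved) > 0), 1)  # at most one vertex per step
  }
  expect_equal(st$iteration, 200L)
  expect_equal(st$accepted + st$rejected, 200)
})

test_that("ramp updates follow their closed forms", {
  m <- square_mesh()
  m$tracked <- TRUE
  p <- model_params(iterations_per_sts = 10L)

  sch <- rate_schedule("contractility", rate = 1e-4, ramp_start_sts = 1,
                       total_sts = 5)
  g0 <- m$contractility
  m1 <- m
  for (it in 0:999) m1 <- apply_ramps(m1, sch, it, p)
  # iterations 10..999 update (ramp starts at sts 1 = iteration 10)
  expect_equal(m1$contractility, g0 * (1 + 1e-4)^990, tolerance = 1e-12)

  sch_r <- rate_schedule("resting_area", rate = 3.5e-4, ramp_start_sts = 1,
                         total_sts = 5)
  m2 <- m
  for (it in 10:1009) m2 <- apply_ramps(m2, sch_r, it, p)
  expect_equal(m2$resting_area, (1 - 3.5e-4)^1000, tolerance = 1e-12)
  expect_equal(ramp_factor(3.5e-4, 1000, "resting_area"), 0.7047,
               tolerance = 1e-3)

  # control never changes parameters; pre-ramp iterations don't either
  m3 <- apply_ramps(m, rate_schedule("control"), 1e7, p)
  expect_identical(m3$contractility, m$contractility)
  m4 <- apply_ramps(m, sch, 3, p)
  expect_identical(m4$contractility, m$contractility)

  expect_error(rate_schedule("contractility", rate = -1),
               class = "extrudr_parameter_error")
})

test_that("rate rescaling preserves the per-sts ramp factor", {
  c_small <- scale_rate(7.5e-7, "contractility", 130000, 13000)
  expect_equal((1 + c_small)^13000, (1 + 7.5e-7)^130000, tolerance = 1e-9)
  r_small <- scale_rate(3.5e-4, "resting_area", 130000, 13000)
  expect_equal((1 - r_small)^13000, (1 - 3.5e-4)^130000, tolerance = 1e-9)
})

test_that("T1 rewires a short central edge and swaps adjacencies", {
  p_always <- model_params(p_accept = 1)  # accept any admissible rewiring

  q <- quartet_mesh(gap = 0.15)
  adj0 <- face_adjacency(q)
  # before: left(3) and right(4) are neighbours; top(1) and bottom(2) not
  expect_true(any(adj0[, 1] == 3 & adj0[, 2] == 4))
  expect_false(any(adj0[, 1] == 1 & adj0[, 2] == 2))

  res <- t1_transitions(q, p_always)
  expect_equal(res$n_rewired, 1)
  expect_length(res$mesh$faces, 4)
  expect_equal(nrow(validate_mesh(res$mesh)), 0)
  adj1 <- face_adjacency(res$mesh)
  expect_true(any(adj1[, 1] == 1 & adj1[, 2] == 2))
  expect_false(any(adj1[, 1] == 3 & adj1[, 2] == 4))
  # the reopened junction has the configured length
  e <- mesh_edges(res$mesh)
  len <- sqrt(rowSums((res$mesh$vertices[e$v1, ] - res$mesh$vertices[e$v2, ])^2))
  expect_true(any(abs(len - p_always$t1_new_length) < 1e-9))

  # an edge longer than d_min is not eligible
  q2 <- quartet_mesh(gap = 0.25)
  expect_equal(t1_transitions(q2, p_always)$n_rewired, 0)
})

test_that("T1 sweeps conserve face count and disk topology in full runs", {
  cfg <- sim_config("small", n_cells = 60L, iterations_per_sts = 2000L,
                    total_sts = 6L, ramp_start_sts = 2L,
                    min_boundary_distance = 1L, initial_area_ratio = 1)
  m <- config_tissue(cfg, seed = 3)
  sim <- run_simulation(m, config_params(cfg),
                        rate_schedule("resting_area",
                                      rate = scale_rate(3.5e-4, "resting_area",
                                                        130000, 2000),
                                      ramp_start_sts = 2, total_sts = 6),
                        seed = 3)
  fm <- sim$final_mesh
  expect_length(fm$faces, 60)
  expect_equal(nrow(validate_mesh(fm)), 0)
  e <- mesh_edges(fm)
  expect_identical(nrow(fm$vertices) - nrow(e) + length(fm$faces), 1L)
})

test_that("energy bookkeeping closes over a full run", {
  cfg <- sim_config("small", n_cells = 60L, iterations_per_sts = 5000L,
                    total_sts = 4L, ramp_start_sts = 2L,
                    min_boundary_distance = 1L)
  m <- config_tissue(cfg, seed = 1)
  sim <- run_simulation(m, config_params(cfg),
                        rate_schedule("control", ramp_start_sts = 2,
                                      total_sts = 4),
                        seed = 1)
  expect_equal(sim$energy$initial + sim$energy$delta_sum, sim$energy$final,
               tolerance = 1e-6)
})

test_that("with a vanishing acceptance probability energy never increases", {
  cfg <- sim_config("small", n_cells = 50L, iterations_per_sts = 4000L,
                    total_sts = 3L, ramp_start_sts = 1L, p_accept = 1e-12,
                    min_boundary_distance = 1L)
  m <- config_tissue(cfg, seed = 2)
  sim <- run_simulation(m, config_params(cfg),
                        rate_schedule("control", ramp_start_sts = 1,
                                      total_sts = 3),
                        seed = 2)
  expect_lte(sim$energy$final, sim$energy$initial)
  expect_lte(sim$energy$delta_sum, 0)
})

test_that("simulations are deterministic per seed and sized as configured", {
  cfg <- sim_config("small", n_cells = 40L, iterations_per_sts = 1000L,
                    total_sts = 3L, ramp_start_sts = 1L,
                    min_boundary_distance = 1L)
  m <- config_tissue(cfg, seed = 4)
  sch <- rate_schedule("contractility", rate = 1e-5, ramp_start_sts = 1,
                       total_sts = 3)
  s1 <- run_simulation(m, config_params(cfg), sch, seed = 10)
  s2 <- run_simulation(m, config_params(cfg), sch, seed = 10)
  expect_identical(s1$observables, s2$observables)
  expect_identical(s1$final_mesh$vertices, s2$final_mesh$vertices)
  s3 <- run_simulation(m, config_params(cfg), sch, seed = 11)
  expect_false(identical(s1$final_mesh$vertices, s3$final_mesh$vertices))

  # one record per tracked cell per sts, including the initial state
  expect_equal(nrow(s1$observables), (3 + 1) * sum(m$tracked))
  expect_true(all(s1$observables$circularity > 0 &
                    s1$observables$circularity <= 1))
})
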