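lv1 <- c(pial = 1, inner_skull = 1, outer_skull = 1, scalp = 1)
lv2 <- c(pial = 2, inner_skull = 2, outer_skull = 1, scalp = 1)

test_that("the undeflated operator annihilates constants", {
  for (method in c("LC", "LG")) {
    model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
    sys <- assemble_system(model, method, use_isa = FALSE)
    M <- headbem:::bem_operator(sys, deflated = FALSE)
    expect_lt(max(abs(M %*% rep(1, sys$nv))) / mean(abs(diag(M))), 1e-8)
  }
})

test_that("LC and LG systems share dimensions and vertex maps", {
  model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  lc <- assemble_system(model, "LC", use_isa = FALSE)
  lg <- assemble_system(model, "LG", use_isa = FALSE)
  expect_identical(dim(lc$B), dim(lg$B))
  expect_identical(lc$vmap, lg$vmap)
})

test_that("solving is linear in the sources", {
  model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  sys <- assemble_system(model, "LC", use_isa = TRUE)
  s1 <- source_space(matrix(c(0, 0, 0.03), 1), matrix(c(1e-8, 0, 0), 1))
  s2 <- source_space(matrix(c(0.02, 0, -0.01), 1), matrix(c(0, 5e-9, 5e-9), 1))
  both <- source_space(rbind(s1$positions, s2$positions),
                       rbind(s1$moments, s2$moments))
  g <- bem_source_terms(sys, both)
  expect_equal(solve_potentials(sys, matrix(0, sys$nv, 2)),
               matrix(0, sys$nv, 2))
  phi <- solve_potentials(sys, g)
  # scaling a moment scales the potential column
  s1b <- source_space(s1$positions, 3.5 * s1$moments)
  phi1b <- solve_potentials(sys, bem_source_terms(sys, s1b))
  expect_equal(phi1b[, 1], 3.5 * phi[, 1], tolerance = 1e-12)
  # superposition of joint and individual solves
  joint <- source_space(s1$positions + 0, (s1$moments + 0))
  sum_src <- source_space(matrix(c(0, 0, 0.03), 1),
                          matrix(c(1e-8, 5e-9, 5e-9), 1))
  phi_sum <- solve_potentials(sys, bem_source_terms(sys, sum_src))
  s3 <- source_space(matrix(c(0, 0, 0.03), 1), matrix(c(0, 5e-9, 5e-9), 1))
  phi3 <- solve_potentials(sys, bem_source_terms(sys, s3))
  expect_equal(phi_sum[, 1], phi[, 1] + phi3[, 1], tolerance = 1e-12)
})

test_that("transfer matrix reproduces direct solves", {
  model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  for (isa in c(FALSE, TRUE)) {
    sys <- assemble_system(model, "LC", use_isa = isa)
    set.seed(11)
    S <- matrix(rnorm(5 * sys$nv), 5, sys$nv)
    Tm <- transfer_matrix(sys, S)
    src <- build_source_space(20, c(10, 60), "random", seed = 4)
    g <- bem_source_terms(sys, src)
    direct <- S %*% solve_potentials(sys, g)
    via_T <- Tm %*% g
    expect_lt(max(abs(direct - via_T)) / max(abs(direct)), 1e-10)
  }
  sys <- assemble_system(model, "LC", use_isa = FALSE)
  expect_identical(dim(transfer_matrix(sys, matrix(0, 0, sys$nv))),
                   c(0L, sys$nv))
})

test_that("an undeflated system refuses to solve, naming deflation", {
  model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  sys <- assemble_system(model, "LC", use_isa = FALSE, deflation = "none")
  src <- dipole(c(0, 0, 0.03), c(1e-8, 0, 0))
  expect_error(solve_potentials(sys, bem_source_terms(sys, src)), "deflation")
})

test_that("dimension mismatches are reported with the expected count", {
  model <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  sys <- assemble_system(model, "LC", use_isa = FALSE)
  expect_error(solve_potentials(sys, matrix(0, 10, 1)),
               as.character(sys$nv))
  expect_error(transfer_matrix(sys, matrix(0, 2, 10)),
               as.character(sys$nv))
})

test_that("zero-jump surfaces are inert for EEG and MEG topographies", {
  base <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv2)
  with_blob <- head_model(c(
    list(blob = boundary_surface(build_icosphere(1, 30, c(10, 0, 0), "blob"),
                                 0.33, 0.33)),
    base$surfaces), K = 50)
  src <- build_source_space(10, c(10, 60), "random", seed = 5)
  arrays <- build_sensor_arrays(base)
  sys0 <- assemble_system(base, "LC", use_isa = TRUE)
  sys1 <- assemble_system(with_blob, "LC", use_isa = TRUE)
  L0 <- eeg_leadfield(base, sys0, src, arrays$electrodes)
  L1 <- eeg_leadfield(with_blob, sys1, src, arrays$electrodes)
  expect_lt(max(abs(L0$matrix - L1$matrix)) / max(abs(L0$matrix)), 1e-10)
  M0 <- meg_leadfield(base, sys0, src, arrays$magnetometers)
  M1 <- meg_leadfield(with_blob, sys1, src, arrays$magnetometers)
  expect_lt(max(abs(M0$matrix - M1$matrix)) / max(abs(M0$matrix)), 1e-10)
})

test_that("a 3-S model equals the 4-C model with CSF set to brain", {
  m4 <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv2)
  m4$surfaces$pial$sigma_out <- 0.33       # CSF -> brain: pial jump vanishes
  m4$surfaces$inner_skull$sigma_in <- 0.33
  m3 <- build_layered_sphere_model("3S", K = 50,
                                   mesh_levels = lv2[-1])
  src <- build_source_space(10, c(10, 60), "random", seed = 5)
  arrays <- build_sensor_arrays(m3)
  s4 <- assemble_system(m4, "LC", use_isa = TRUE)
  s3 <- assemble_system(m3, "LC", use_isa = TRUE)
  L4 <- eeg_leadfield(m4, s4, src, arrays$electrodes)
  L3 <- eeg_leadfield(m3, s3, src, arrays$electrodes)
  expect_lt(max(abs(L4$matrix - L3$matrix)) / max(abs(L3$matrix)), 1e-8)
})

test_that("conductivity updates reuse the assembly and match fresh ones", {
  m50 <- build_layered_sphere_model("4C", K = 50, mesh_levels = lv1)
  m20 <- build_layered_sphere_model("4C", K = 20, mesh_levels = lv1)
  sys <- assemble_system(m50, "LC", use_isa = TRUE)
  src <- dipole(c(0, 0.02, 0.03), c(1e-8, 0, 1e-8))
  arrays <- build_sensor_arrays(m50)
  L_upd <- eeg_leadfield(m20, sys, src, arrays$electrodes)
  sys20 <- assemble_system(m20, "LC", use_isa = TRUE)
  L_fresh <- eeg_leadfield(m20, sys20, src, arrays$electrodes)
  expect_equal(L_upd$matrix, L_fresh$matrix, tolerance = 1e-12)
  bad <- build_layered_sphere_model("4C", K = 20, mesh_levels = lv2)
  expect_error(bem_update_conductivities(sys, bad), "differ")
})
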