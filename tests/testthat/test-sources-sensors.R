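test_that("infinite-medium dipole potential matches its closed form", {
  d <- dipole(c(0, 0, 0), c(0, 0, 1e-8))
  # perpendicular offset: zero potential
  expect_equal(dipole_potential_infinite(d, matrix(c(0.01, 0, 0), 1), 0.33)[1, 1], 0)
  # on-axis value and sigma scaling
  p <- matrix(c(0, 0, 0.01), 1)
  v1 <- dipole_potential_infinite(d, p, 0.33)[1, 1]
  expect_equal(v1, 1e-8 * 0.01 / (4 * pi * 0.33 * 0.01^3), tolerance = 1e-12)
  expect_equal(v1, 2.4115e-5, tolerance = 1e-4)
  expect_equal(dipole_potential_infinite(d, p, 0.66)[1, 1], v1 / 2)
  expect_error(dipole_potential_infinite(d, matrix(c(0, 0, 0), 1), 0.33),
               "singular")
  expect_error(dipole_potential_infinite(d, p, 0), "positive")
})

test_that("primary magnetic field follows Biot-Savart", {
  d <- dipole(c(0, 0, 0), c(0, 0, 1e-8))
  # parallel offset: zero field
  expect_equal(dipole_primary_field(d, matrix(c(0, 0, 0.05), 1))[, 1],
               c(0, 0, 0))
  # right angle: |B| = mu0 p / (4 pi r^2)
  B <- dipole_primary_field(d, matrix(c(0.02, 0, 0), 1))[, 1]
  expect_equal(sqrt(sum(B^2)), 4e-7 * pi * 1e-8 / (4 * pi * 0.02^2),
               tolerance = 1e-12)
  # antisymmetry under moment reversal
  dneg <- dipole(c(0, 0, 0), c(0, 0, -1e-8))
  pts <- matrix(rnorm(9, sd = 0.1), 3)
  expect_equal(dipole_primary_field(dneg, pts), -dipole_primary_field(d, pts))
})

test_that("source spaces are deterministic and respect the depth rule", {
  s1 <- build_source_space(200, c(0, 76.5), "random", seed = 9)
  s2 <- build_source_space(200, c(0, 76.5), "random", seed = 9)
  expect_identical(s1, s2)
  s3 <- build_source_space(200, c(0, 76.5), "random", seed = 10)
  expect_false(identical(s1$moments, s3$moments))
  expect_equal(nrow(s1$positions), 200L)
  depth_mm <- 78 - sqrt(rowSums(s1$positions^2)) * 1000
  expect_true(all(depth_mm >= 1.5 - 1e-9))
  expect_error(build_source_space(10, c(0, 77.5), "random", seed = 1),
               "infeasible")
  # radial mode: moment parallel to position
  sr <- build_source_space(50, c(10, 70), "radial", seed = 2)
  cosang <- rowSums(sr$positions * sr$moments) /
    (sqrt(rowSums(sr$positions^2)) * sqrt(rowSums(sr$moments^2)))
  expect_equal(cosang, rep(1, 50), tolerance = 1e-12)
  # tangential mode: moment perpendicular to position
  st <- build_source_space(50, c(10, 70), "tangential", seed = 2)
  expect_lt(max(abs(rowSums(st$positions * st$moments))) /
              (1e-8 * max(sqrt(rowSums(st$positions^2)))), 1e-10)
  expect_equal(unname(sqrt(rowSums(st$moments^2))), rep(1e-8, 50))
})

test_that("sensor arrays have the paper's counts and geometric invariants", {
  model <- build_layered_sphere_model("4C", K = 50,
                                      mesh_levels = c(pial = 1, inner_skull = 1,
                                                      outer_skull = 1, scalp = 2))
  arrays <- build_sensor_arrays(model)
  expect_equal(nrow(arrays$electrodes$positions), 256L)
  expect_equal(nrow(arrays$magnetometers$centers), 102L)
  # electrodes lie exactly on the scalp mesh (barycentric points)
  scalp <- model$surfaces$scalp$mesh
  W <- arrays$electrodes$weights
  expect_equal(unname(rowSums(W)), rep(1, 256), tolerance = 1e-9)
  rec <- W %*% headbem:::mesh_vertices_m(scalp)
  expect_lt(max(sqrt(rowSums((rec - arrays$electrodes$positions)^2))), 1e-6)
  # magnetometers: weights 1/4, integration points in the coil plane
  expect_equal(arrays$magnetometers$int_weights, rep(0.25, 4))
  for (ch in c(1, 50, 102)) {
    ip <- arrays$magnetometers$int_points[(4 * ch - 3):(4 * ch), ]
    off <- sweep(ip, 2, arrays$magnetometers$centers[ch, ])
    expect_lt(max(abs(off %*% arrays$magnetometers$normals[ch, ])), 1e-12)
  }
  expect_error(build_sensor_arrays(model, helmet_radius = 80), "helmet")
})

test_that("electrode interpolation is exact for affine fields", {
  model <- build_layered_sphere_model("4C", K = 50,
                                      mesh_levels = c(pial = 1, inner_skull = 1,
                                                      outer_skull = 1, scalp = 2))
  arrays <- build_sensor_arrays(model)
  scalp_v <- headbem:::mesh_vertices_m(model$surfaces$scalp$mesh)
  a <- c(2.5, -1, 4)
  nodal <- scalp_v %*% a + 7
  interp <- electrode_potentials(nodal, arrays$electrodes)
  truth <- arrays$electrodes$positions %*% a + 7
  expect_equal(as.vector(interp), as.vector(truth), tolerance = 1e-12)
  expect_error(electrode_potentials(nodal[-1, , drop = FALSE],
                                    arrays$electrodes), "scalp vertex")
})

test_that("magnetometer readings integrate the normal field", {
  model <- build_layered_sphere_model("4C", K = 50,
                                      mesh_levels = c(pial = 1, inner_skull = 1,
                                                      outer_skull = 1, scalp = 1))
  mags <- build_sensor_arrays(model)$magnetometers
  np <- nrow(mags$int_points)
  # uniform field: reading is B0 . normal
  B0 <- c(1e-13, -2e-13, 5e-13)
  field <- matrix(rep(B0, np), ncol = 1)
  rd <- magnetometer_readings(field, mags)
  expect_equal(rd[, 1], as.vector(mags$normals %*% B0), tolerance = 1e-15)
  expect_equal(magnetometer_readings(matrix(0, 3 * np, 2), mags),
               matrix(0, 102, 2))
  expect_error(magnetometer_readings(matrix(0, 7, 1), mags), "rows")
  # distant dipole: 2x2 Gauss vs dense 20x20 grid average within 0.1%
  d <- dipole(c(0, 0.03, 0.02), c(1e-8, 0, 1e-8))
  rd2 <- magnetometer_readings(dipole_primary_field(d, mags$int_points), mags)
  ch <- 7
  ctr <- mags$centers[ch, ]; nrm <- mags$normals[ch, ]
  ref <- c(0, 0, 1); if (abs(nrm[3]) > 0.9) ref <- c(1, 0, 0)
  t1 <- ref - sum(ref * nrm) * nrm; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2], nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  g <- seq(-mags$side / 2, mags$side / 2, length.out = 20)
  grid <- as.matrix(expand.grid(g, g))
  pts <- sweep(grid[, 1] %o% t1 + grid[, 2] %o% t2, 2, ctr, "+")
  Bg <- dipole_primary_field(d, pts)
  dense <- mean(colSums(matrix(Bg[, 1], 3) * nrm))
  expect_equal(rd2[ch, 1], dense, tolerance = 1e-3)
})
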