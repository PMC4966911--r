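test_that("layered series reduces to the homogeneous closed form", {
  src <- source_space(rbind(c(0, 0, 0.04), c(0, 0.06, 0.03), c(0, 0, 0)),
                      rbind(c(1e-8, 0, 1e-8), c(1e-8, -3e-9, 1e-8),
                            c(0, 1e-8, 0)))
  pts <- headbem:::fibonacci_cap(80) * 0.08
  closed <- homogeneous_sphere_potential(0.08, 0.33, src, pts)
  series <- multilayer_sphere_potential(layered_sphere_spec(0.08, 0.33),
                                        src, pts)
  expect_lt(max(abs(series - closed)) / max(abs(closed)), 1e-9)
  # degenerate layering with equal conductivities
  series3 <- multilayer_sphere_potential(
    layered_sphere_spec(c(0.07, 0.075, 0.08), rep(0.33, 3)), src, pts)
  expect_lt(max(abs(series3 - closed)) / max(abs(closed)), 1e-9)
})

test_that("radial-dipole potentials are axisymmetric", {
  axis <- c(0, 0, 1)
  src <- dipole(0.05 * axis, 1e-8 * axis)
  spec <- layered_sphere_spec(c(0.078, 0.081, 0.087, 0.092),
                              c(0.33, 1.79, 0.0066, 0.33))
  theta <- acos(0.42)
  phis <- seq(0, 2 * pi, length.out = 17)
  circle <- 0.092 * cbind(sin(theta) * cos(phis), sin(theta) * sin(phis),
                          cos(theta))
  v <- multilayer_sphere_potential(spec, src, circle)
  expect_lt(diff(range(v)) / max(abs(v)), 1e-10)
})

test_that("oracle potentials obey the global conductivity scaling law", {
  src <- source_space(matrix(c(0, 0.05, 0.04), 1), matrix(c(1e-8, 0, 2e-9), 1))
  pts <- headbem:::fibonacci_cap(40) * 0.092
  spec1 <- layered_sphere_spec(c(0.078, 0.081, 0.087, 0.092),
                               c(0.33, 1.79, 0.0066, 0.33))
  spec2 <- layered_sphere_spec(spec1$radii, 2 * spec1$conductivities)
  v1 <- multilayer_sphere_potential(spec1, src, pts)
  v2 <- multilayer_sphere_potential(spec2, src, pts)
  expect_equal(v2, v1 / 2, tolerance = 1e-10)
})

test_that("series truncation converges monotonically for eccentric dipoles", {
  spec <- layered_sphere_spec(c(0.078, 0.081, 0.087, 0.092),
                              c(0.33, 1.79, 0.0066, 0.33))
  ecc <- 0.95
  src <- dipole(c(0, 0, ecc * 0.078), c(1e-8, 0, 0))
  pts <- matrix(c(0, 0.03, 0.0869), 1)
  full <- multilayer_sphere_potential(spec, src, pts, tol = 1e-12)[1, 1]
  errs <- vapply(c(20, 40, 80, 160), function(nm) {
    v <- tryCatch(multilayer_sphere_potential(spec, src, pts, tol = 0,
                                              nmax = nm),
                  error = function(e) NA_real_)
    abs(v - full)
  }, 0)
  errs <- errs[!is.na(errs)]
  expect_true(all(diff(errs) < 0))
  # truncation cap raises a diagnostic error
  expect_error(multilayer_sphere_potential(spec, src, pts, tol = 0, nmax = 5),
               "converge")
  expect_error(multilayer_sphere_potential(spec, dipole(c(0, 0, 0.1),
                                                        c(1e-8, 0, 0)), pts),
               "innermost")
})

test_that("Sarvas field has the classical spherical-conductor properties", {
  ctr <- c(0, 0, 0)
  pts <- headbem:::fibonacci_cap(30, zmin = 0) * 0.13
  # exactly radial moment: zero external field
  pos <- c(0, 0.02, 0.05)
  radial <- dipole(pos, 1e-8 * pos / sqrt(sum(pos^2)))
  expect_equal(max(abs(sarvas_field(radial, ctr, pts))), 0)
  tang <- dipole(pos, 1e-8 * c(1, 0, 0) -
                   1e-8 * sum(c(1, 0, 0) * pos / sum(pos^2)) * pos)
  B <- sarvas_field(tang, ctr, pts)
  Bp <- dipole_primary_field(tang, pts)
  rhat <- pts / sqrt(rowSums(pts^2))
  br <- vapply(seq_len(nrow(pts)), function(i)
    sum(B[(3 * i - 2):(3 * i), 1] * rhat[i, ]), 0)
  bpr <- vapply(seq_len(nrow(pts)), function(i)
    sum(Bp[(3 * i - 2):(3 * i), 1] * rhat[i, ]), 0)
  expect_lt(max(abs(br - bpr)), 1e-12 * max(abs(br)))
})

test_that("fine-mesh Geselowitz integration approaches the Sarvas field", {
  # analytic boundary potentials fed through the volume-current quadrature;
  # nominal radii keep the vertices exactly on the potential's boundaries
  model <- build_layered_sphere_model("4C", K = 50,
                                      mesh_levels = c(pial = 5, inner_skull = 5,
                                                      outer_skull = 5, scalp = 5))
  spec <- layered_sphere_spec(c(0.078, 0.081, 0.087, 0.092),
                              c(0.33, 1.79, 0.33 / 50, 0.33))
  src <- source_space(matrix(c(0, 0.03, 0.05), 1), matrix(c(1e-8, 0, 0), 1))
  phi <- do.call(rbind, lapply(model$surfaces, function(s)
    multilayer_sphere_potential(spec, src, headbem:::mesh_vertices_m(s$mesh))))
  fp <- rbind(c(0.08, 0.02, 0.09), c(-0.02, 0.1, 0.07), c(0, -0.08, 0.1))
  Btot <- geselowitz_volume_field(model, phi, fp) +
    dipole_primary_field(src, fp)
  Bs <- sarvas_field(src, c(0, 0, 0), fp)
  expect_lt(sqrt(sum((Btot - Bs)^2) / sum(Bs^2)), 0.005)
})
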