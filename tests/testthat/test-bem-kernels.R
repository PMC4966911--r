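test_that("solid angles satisfy the Gauss identities", {
  m <- build_icosphere(2, 80)
  pin <- rbind(c(0, 0, 0), c(10, -25, 30), c(-50, 10, 5))
  om <- solid_angles(m, pin)
  expect_equal(rowSums(om), rep(4 * pi, 3), tolerance = 1e-9)
  pout <- rbind(c(120, 0, 0), c(-90, 90, 40))
  expect_lt(max(abs(rowSums(solid_angles(m, pout)))), 1e-9)
  expect_error(solid_angles(m, m$vertices[5, ]), "singular")
})

test_that("cube-corner solid angles recover the octant angle from inside", {
  # as an interior point approaches a cube corner, the non-incident faces
  # subtend exactly the corner's interior (octant) angle pi/2, so the faces
  # incident to the corner account for the remaining 4*pi - pi/2
  cu <- cube_mesh(2)
  corner <- c(1, 1, 1)
  incident <- which(apply(cu$faces, 1, function(f)
    any(apply(cu$vertices[f, ], 1, function(v) all(abs(v - corner) < 1e-12)))))
  expect_gte(length(incident), 3L)
  sums <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    p <- corner * (1 - eps)
    sum(solid_angles(cu, p)[1, incident])
  }, 0)
  expect_lt(abs(sums[3] - (4 * pi - pi / 2)), 1e-4)
  expect_true(all(diff(abs(sums - (4 * pi - pi / 2))) < 0))
  octant <- sum(solid_angles(cu, corner * (1 - 1e-6))[1, -incident])
  expect_equal(octant, pi / 2, tolerance = 1e-5)
})

test_that("linear collocation weights obey partition of unity", {
  m <- build_icosphere(2, 40)
  pts <- rbind(c(3, 8, -5), c(-20, 4, 9), c(90, -10, 20))
  W <- linear_collocation_weights(m, pts)
  om <- solid_angles(m, pts)
  # per-triangle sums equal the triangle solid angle: check via global sum and
  # per-face reconstruction on a single-face mesh
  expect_equal(rowSums(W), rowSums(om), tolerance = 1e-10)
  tri <- m$vertices[m$faces[17, ], ]
  W1 <- headbem:::cpp_dl_collocation(tri, matrix(0:2, 1), pts, rep(-1L, 3))
  expect_equal(rowSums(W1), headbem:::cpp_solid_angles(tri, matrix(0:2, 1), pts)[, 1],
               tolerance = 1e-12)
})

test_that("analytic double-layer weights match dense quadrature", {
  set.seed(42)
  for (rep in 1:5) {
    tri <- matrix(rnorm(9), 3, 3)
    # keep the observation point a triangle-diameter away
    p <- colMeans(tri) + rnorm(3, sd = 2) + c(0, 0, 2)
    W <- headbem:::cpp_dl_collocation(tri, matrix(0:2, 1),
                                      matrix(p, 1), -1L)[1, ]
    Wq <- dl_weights_quadrature(tri[1, ], tri[2, ], tri[3, ], p, depth = 5)
    expect_equal(W, Wq, tolerance = 1e-8)
  }
})

test_that("far-field double-layer weights vanish", {
  m <- build_icosphere(1, 10)
  W <- linear_collocation_weights(m, matrix(c(5000, 0, 0), 1))
  expect_lt(max(abs(W)), 1e-5)   # individual weights decay like area/d^2
  expect_lt(abs(sum(W)), 1e-12)  # total solid angle of a closed surface: 0
})

test_that("in-plane exterior observation points give zero weights", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  p <- c(2, 2, 0)   # coplanar, outside the triangle
  W <- headbem:::cpp_dl_collocation(tri, matrix(0:2, 1), matrix(p, 1), -1L)
  expect_equal(as.vector(W), c(0, 0, 0))
})

test_that("Galerkin and collocation assemblies agree on smooth blocks", {
  # rows on one sphere, columns on a well-separated other: the Galerkin block
  # must equal the mass-matrix-weighted average of collocation rows as the
  # row mesh refines; at fixed mesh they already agree to quadrature accuracy
  ma <- build_icosphere(2, 20)
  mb <- build_icosphere(1, 60)
  Va <- headbem:::mesh_vertices_m(ma); Vb <- headbem:::mesh_vertices_m(mb)
  G <- headbem:::cpp_dl_galerkin(Va, ma$faces - 1L, Vb, mb$faces - 1L,
                                 FALSE, 0L)
  N <- as.matrix(headbem:::mass_matrix(Va, ma$faces))
  C <- headbem:::cpp_dl_collocation(Vb, mb$faces - 1L, Va,
                                    rep(-1L, nrow(Va)))
  expect_lt(max(abs(G - N %*% C)) / max(abs(G)), 0.02)
  # row sums: weighted interior solid angle of the enclosing sphere, to
  # outer-quadrature accuracy (the assembler restores them exactly)
  expect_lt(max(abs(rowSums(G) - 4 * pi * rowSums(N))) /
              max(4 * pi * rowSums(N)), 1e-4)
})
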