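#' @useDynLib headbem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif setNames
#' @importFrom rlang .data
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
NULL

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Closed oriented triangle surface
#'
#' The geometric atom of all conductivity boundaries: a triangulated closed
#' 2-manifold with consistently outward-oriented faces. Vertex coordinates are
#' in millimetres; field computations convert to SI metres internally.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices; consistent
#'   counter-clockwise order seen from outside.
#' @param name label for the surface.
#' @param normals optional n x 3 matrix of outward unit vertex normals of the
#'   smooth surface the mesh discretises; generators attach analytic normals,
#'   otherwise area-weighted face-normal averages are used when needed.
#' @param orient if `TRUE` (default), flip all faces when the signed volume is
#'   negative, with a warning.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, name = "surface", normals = NULL,
                     orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have three columns")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  areas <- face_areas(vertices, faces)
  if (any(areas <= 1e-12 * max(areas)))
    stop("mesh contains degenerate (zero-area) faces")
  m <- structure(list(vertices = vertices, faces = faces, name = name,
                      normals = normals),
                 class = "tri_mesh", unit = "mm")
  if (orient && signed_volume(m) < 0) {
    warning("mesh '", name, "' had inward orientation; flipping faces")
    m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces, mean TSL %.3f mm>\n",
              x$name, nrow(x$vertices), nrow(x$faces), mean_edge_length(x)))
  invisible(x)
}

# --- internal mesh helpers (all in mm) --------------------------------------

face_corner <- function(vertices, faces, k) vertices[faces[, k], , drop = FALSE]

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_cross <- function(vertices, faces) {
  v1 <- face_corner(vertices, faces, 1L)
  cross3(face_corner(vertices, faces, 2L) - v1,
         face_corner(vertices, faces, 3L) - v1)
}

face_areas <- function(vertices, faces) {
  cr <- face_cross(vertices, faces)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh$vertices, mesh$faces)
  cr / sqrt(rowSums(cr^2))
}

# Area-weighted outward vertex normals; used when no analytic normals stored.
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  cr <- face_cross(mesh$vertices, mesh$faces)  # 2*area-weighted face normals
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    n[, 1] <- n[, 1] + tapply_sum(cr[, 1], idx, nrow(n))
    n[, 2] <- n[, 2] + tapply_sum(cr[, 2], idx, nrow(n))
    n[, 3] <- n[, 3] + tapply_sum(cr[, 3], idx, nrow(n))
  }
  n / sqrt(rowSums(n^2))
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Signed volume enclosed by a triangle mesh
#'
#' Positive for closed meshes with outward-oriented faces.
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v1 <- face_corner(mesh$vertices, mesh$faces, 1L)
  v2 <- face_corner(mesh$vertices, mesh$faces, 2L)
  v3 <- face_corner(mesh$vertices, mesh$faces, 3L)
  sum(rowSums(cross3(v2, v3) * v1)) / 6
}

# Directed edge list (m*3 x 2); a closed orientable mesh has every undirected
# edge exactly twice, once per direction.
directed_edges <- function(faces) {
  rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
}

unique_edges <- function(faces) {
  e <- directed_edges(faces)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(key), , drop = FALSE]
}

is_closed_mesh <- function(mesh) {
  e <- directed_edges(mesh$faces)
  key_u <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_u)
  if (any(cnt != 2L)) return(FALSE)
  # orientation consistency: each directed edge must appear exactly once
  key_d <- paste(e[, 1], e[, 2])
  !anyDuplicated(key_d)
}

mean_edge_length <- function(mesh) {
  e <- unique_edges(mesh$faces)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

mesh_vertices_m <- function(mesh) mesh$vertices / 1000  # the one mm -> m point

# inscribed radius: minimum distance from `center` to any face plane (mm)
mesh_inradius <- function(mesh, center = colMeans(mesh$vertices)) {
  n <- face_normals(mesh)
  v1 <- sweep(face_corner(mesh$vertices, mesh$faces, 1L), 2, center)
  min(abs(rowSums(n * v1)))
}

#' Mesh statistics
#'
#' Summary used for meshing guidance: mesh density is expressed as the mean
#' triangle-side length (TSL) over unique edges.
#'
#' @param mesh a [tri_mesh()].
#' @return a one-row tibble with `vertex_count`, `face_count`, `mean_tsl` (mm),
#'   `total_area` (mm^2), `signed_volume` (mm^3), `is_closed`, `is_outward`.
#' @export
mesh_statistics <- function(mesh) {
  vol <- signed_volume(mesh)
  tibble::tibble(
    name = mesh$name,
    vertex_count = nrow(mesh$vertices),
    face_count = nrow(mesh$faces),
    mean_tsl = mean_edge_length(mesh),
    total_area = sum(face_areas(mesh$vertices, mesh$faces)),
    signed_volume = vol,
    is_closed = is_closed_mesh(mesh),
    is_outward = vol > 0)
}

# --- icosphere --------------------------------------------------------------

icosahedron_vertices <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v / sqrt(1 + p^2)
}

icosahedron_faces <- function() {
  matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
    ncol = 3, byrow = TRUE)
}

#' Generate an icosphere surface
#'
#' Recursive icosahedron subdivision with projection onto the sphere, giving
#' quasi-uniform triangulations at controlled mean triangle-side length. The
#' generated mesh carries exact radial vertex normals.
#'
#' @param level non-negative integer subdivision level; the mesh has
#'   `10 * 4^level + 2` vertices and TSL roughly halves per level.
#' @param radius sphere radius in mm.
#' @param center sphere centre (mm), default origin.
#' @param name surface label.
#' @return a [tri_mesh()].
#' @export
build_icosphere <- function(level, radius, center = c(0, 0, 0),
                            name = sprintf("icosphere%d", level)) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stop("subdivision level must be a non-negative integer")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  v <- icosahedron_vertices()
  f <- icosahedron_faces()
  if (level > 0) for (i in seq_len(level)) {
    edges <- unique_edges(f)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- setNames(nrow(v) + seq_len(nrow(mid)), key)
    v <- rbind(v, mid)
    ek <- function(a, b) midx[paste(pmin(a, b), pmax(a, b))]
    m12 <- ek(f[, 1], f[, 2]); m23 <- ek(f[, 2], f[, 3]); m31 <- ek(f[, 3], f[, 1])
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  verts <- sweep(v * radius, 2, center, "+")
  tri_mesh(verts, f, name = name, normals = v, orient = FALSE)
}

# --- band-limited random sphere perturbation --------------------------------

# Random band-limited function on the sphere: sum over degrees 1..max_degree of
# associated-Legendre / Fourier terms with N(0, 1/(n+1)) coefficients.
random_band_limited <- function(max_degree, seed) {
  coef <- with_seed(seed, {
    lapply(seq_len(max_degree), function(n) {
      list(a = rnorm(n + 1, sd = 1 / (n + 1)),  # cos(m*phi), m = 0..n
           b = rnorm(n + 1, sd = 1 / (n + 1)))  # sin(m*phi)
    })
  })
  function(dirs) {
    ct <- pmin(1, pmax(-1, dirs[, 3]))
    phi <- atan2(dirs[, 2], dirs[, 1])
    val <- numeric(nrow(dirs))
    for (n in seq_len(max_degree)) {
      P <- t(pracma::legendre(n, ct))          # npts x (n+1), m = 0..n
      # mild order normalisation keeps high-m terms comparable in size
      nrm <- exp(-0.5 * (lgamma(n + (0:n) + 1) - lgamma(n - (0:n) + 1)))
      for (m in 0:n) {
        cf <- coef[[n]]
        val <- val + P[, m + 1] * nrm[m + 1] *
          (cf$a[m + 1] * cos(m * phi) + cf$b[m + 1] * sin(m * phi))
      }
    }
    val
  }
}

#' Radially perturb a sphere-topology mesh
#'
#' Scales every vertex radius by `1 + f(theta, phi)` about the vertex
#' centroid, with `f`
#' a random band-limited smooth function scaled so `max |f| = amplitude` over
#' the mesh vertices. Because the perturbed surface remains a radial graph it
#' is free of self-intersections by construction. Used to break spherical
#' symmetry so that MEG becomes sensitive to conductivities. Analytic normals
#' of the perturbed smooth surface are attached.
#'
#' @param mesh a sphere-topology [tri_mesh()].
#' @param amplitude maximum relative radial displacement; must be `< 0.3`.
#' @param max_degree maximum spherical-harmonic degree of the perturbation.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a perturbed [tri_mesh()].
#' @export
perturb_sphere <- function(mesh, amplitude, max_degree = 6L, seed = 1L) {
  if (!is.numeric(amplitude) || amplitude < 0 || amplitude >= 0.3)
    stop("amplitude must be in [0, 0.3); larger values risk self-intersection")
  if (amplitude == 0) return(mesh)
  ctr <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, ctr)
  r0 <- sqrt(rowSums(rel^2))
  dirs <- rel / r0
  f_raw <- random_band_limited(max_degree, seed)
  scl <- amplitude / max(abs(f_raw(dirs)))
  r_new <- r0 * (1 + scl * f_raw(dirs))
  verts <- sweep(dirs * r_new, 2, ctr, "+")
  # normals of the smooth surface P(u) = g(u) u via tangent finite differences
  rbar <- mean(r0)
  nrm <- perturbed_normals(dirs, function(u) rbar * (1 + scl * f_raw(u)))
  tri_mesh(verts, mesh$faces, name = paste0(mesh$name, "_pert"),
           normals = nrm, orient = FALSE)
}

# Normal of surface P(u) = g(u) * u at unit directions u, by central
# differences of P along two tangents of the unit sphere (pole-free).
perturbed_normals <- function(dirs, gfun) {
  h <- 1e-5
  a <- cbind(-dirs[, 2], dirs[, 1], 0)
  deg <- sqrt(rowSums(a^2)) < 1e-6     # dirs near +-z: pick x tangent
  a[deg, ] <- rep(c(1, 0, 0), each = sum(deg))
  t1 <- a / sqrt(rowSums(a^2))
  t2 <- cross3(dirs, t1)
  pt <- function(u) gfun(u / sqrt(rowSums(u^2))) * u / sqrt(rowSums(u^2))
  d1 <- (pt(dirs + h * t1) - pt(dirs - h * t1)) / (2 * h)
  d2 <- (pt(dirs + h * t2) - pt(dirs - h * t2)) / (2 * h)
  n <- cross3(d1, d2)
  n <- n / sqrt(rowSums(n^2))
  # orient outward
  s <- sign(rowSums(n * dirs))
  n * s
}
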