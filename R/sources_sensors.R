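# Dipole primary fields, source spaces, and sensor arrays. Positions of
# dipoles and sensors are SI metres; constructors accept mm where stated.

MU0 <- 4e-7 * pi  # vacuum permeability, T m / A

#' Current dipole
#'
#' @param position 3-vector, metres.
#' @param moment 3-vector, ampere-metres.
#' @return object of class `source_space` holding one dipole.
#' @export
dipole <- function(position, moment) {
  source_space(matrix(position, 1, 3), matrix(moment, 1, 3))
}

#' Source space of current dipoles
#'
#' @param positions n x 3 matrix (m).
#' @param moments n x 3 matrix (A m).
#' @return object of class `source_space`.
#' @export
source_space <- function(positions, moments) {
  positions <- as.matrix(positions); moments <- as.matrix(moments)
  stopifnot(ncol(positions) == 3L, ncol(moments) == 3L,
            nrow(positions) == nrow(moments))
  structure(list(positions = positions, moments = moments),
            class = "source_space", unit = "m")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space: %d dipoles>\n", nrow(x$positions)))
  invisible(x)
}

n_sources <- function(sources) nrow(sources$positions)

#' Infinite-medium dipole potential
#'
#' `phi(r) = p . (r - r0) / (4 pi sigma |r - r0|^3)` for each dipole.
#'
#' @param sources a [source_space()].
#' @param points m x 3 matrix of field points (m).
#' @param sigma conductivity of the (infinite homogeneous) medium, S/m.
#' @return m x n matrix of potentials (V), one column per dipole.
#' @export
dipole_potential_infinite <- function(sources, points, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  points <- as.matrix(points)
  out <- matrix(0, nrow(points), n_sources(sources))
  for (s in seq_len(n_sources(sources))) {
    d <- sweep(points, 2, sources$positions[s, ])
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-12)) stop("singular evaluation: field point at dipole position")
    out[, s] <- (d %*% sources$moments[s, ]) / (4 * pi * sigma * r^3)
  }
  out
}

#' Primary (infinite-medium) magnetic field of dipoles
#'
#' Biot-Savart field of the primary current alone:
#' `B(r) = mu0/(4 pi) p x (r - r0) / |r - r0|^3`.
#'
#' @param sources a [source_space()].
#' @param points m x 3 matrix (m).
#' @return `3 m x n` matrix (T); rows are x,y,z triplets per point.
#' @export
dipole_primary_field <- function(sources, points) {
  points <- as.matrix(points)
  np <- nrow(points)
  out <- matrix(0, 3 * np, n_sources(sources))
  for (s in seq_len(n_sources(sources))) {
    d <- sweep(points, 2, sources$positions[s, ])
    r <- sqrt(rowSums(d^2))
    if (any(r < 1e-12)) stop("singular evaluation: field point at dipole position")
    p <- sources$moments[s, ]
    cr <- cbind(p[2] * d[, 3] - p[3] * d[, 2],
                p[3] * d[, 1] - p[1] * d[, 3],
                p[1] * d[, 2] - p[2] * d[, 1])
    out[, s] <- as.vector(t(cr * (MU0 / (4 * pi) / r^3)))
  }
  out
}

# Quasi-uniform directions on a z-band of the unit sphere (Fibonacci lattice).
fibonacci_cap <- function(n, zmin = -1, zmax = 1) {
  i <- seq_len(n) - 0.5
  z <- zmax - (zmax - zmin) * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Build a dipole source space inside a spherical brain surrogate
#'
#' Dipole positions are quasi-uniform in the ball shell `radius_range` (volume
#' -uniform radii on a Fibonacci direction lattice); all dipoles stay at least
#' `min_depth` below the pial surface. Moments have magnitude
#' `moment` and radial, tangential, or seeded random orientation.
#'
#' @param n number of dipoles.
#' @param radius_range length-2 vector (mm): min and max distance from centre.
#' @param orientation_mode `"radial"`, `"tangential"`, or `"random"`.
#' @param seed integer; orientations (and tangential azimuths) are
#'   deterministic given the seed.
#' @param min_depth minimum distance to the pial surface (mm), default 1.5.
#' @param pial_radius pial sphere radius (mm) used for the depth check.
#' @param center sphere centre (mm).
#' @param moment dipole magnitude (A m), default 10 nA m.
#' @return a [source_space()] (positions in metres).
#' @export
build_source_space <- function(n, radius_range = c(0, 76.5),
                               orientation_mode = c("random", "radial", "tangential"),
                               seed = 1L, min_depth = 1.5, pial_radius = 78,
                               center = c(0, 0, 0), moment = 1e-8) {
  orientation_mode <- match.arg(orientation_mode)
  if (radius_range[2] > pial_radius - min_depth + 1e-9)
    stop("infeasible radius range: dipoles would be within ", min_depth,
         " mm of the pial surface")
  if (radius_range[1] < 0 || diff(radius_range) < 0) stop("bad radius range")
  u <- (seq_len(n) - 0.5) / n
  r <- (radius_range[1]^3 + u * (radius_range[2]^3 - radius_range[1]^3))^(1 / 3)
  dirs <- fibonacci_cap(n)
  pos_mm <- sweep(dirs * r, 2, center, "+")
  ori <- with_seed(seed, switch(orientation_mode,
    random = {
      m <- matrix(rnorm(3 * n), n, 3)
      m / sqrt(rowSums(m^2))
    },
    radial = dirs,
    tangential = {
      az <- runif(n, 0, 2 * pi)
      ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
      swap <- abs(dirs[, 3]) > 0.9
      ref[swap, ] <- rep(c(1, 0, 0), each = sum(swap))
      t1 <- cross3(ref, dirs); t1 <- t1 / sqrt(rowSums(t1^2))
      t2 <- cross3(dirs, t1)
      t1 * cos(az) + t2 * sin(az)
    }))
  source_space(pos_mm / 1000, ori * moment)
}

# --- electrode array --------------------------------------------------------

# Möller-Trumbore ray/triangle intersection of a ray from `orig` along `dir`
# against all faces; returns hit point and barycentric weights of the closest
# forward hit, or NULL.
ray_mesh_hit <- function(mesh, orig, dir) {
  v1 <- face_corner(mesh$vertices, mesh$faces, 1L)
  e1 <- face_corner(mesh$vertices, mesh$faces, 2L) - v1
  e2 <- face_corner(mesh$vertices, mesh$faces, 3L) - v1
  dirm <- matrix(dir, nrow(v1), 3, byrow = TRUE)
  pv <- cross3(dirm, e2)
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  tv <- sweep(v1, 2, orig, "-") * -1
  u <- rowSums(tv * pv) / det
  qv <- cross3(tv, e1)
  v <- rowSums(qv * dirm) / det
  tt <- rowSums(e2 * qv) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > 0
  if (!any(hit)) return(NULL)
  f <- which(hit)[which.max(tt[hit])]   # outermost crossing
  list(face = f, t = tt[f], bary = c(1 - u[f] - v[f], u[f], v[f]),
       point = orig + tt[f] * dir)
}

#' EEG electrode array snapped to the scalp surface
#'
#' @param positions n x 3 matrix of points exactly on the scalp mesh (m).
#' @param weights n x n_scalp_vertices interpolation matrix (rows sum to 1).
#' @param names channel names.
#' @return object of class `electrode_array`.
#' @export
electrode_array <- function(positions, weights, names = NULL) {
  if (is.null(names)) names <- sprintf("EEG%03d", seq_len(nrow(positions)))
  structure(list(positions = positions, weights = weights, names = names),
            class = "electrode_array")
}

#' Magnetometer array
#'
#' Square pickup coils with 2 x 2 Gauss-Legendre integration points; readings
#' are the average normal field over the coil (tesla).
#'
#' @param centers n x 3 coil centres (m).
#' @param normals n x 3 unit coil normals.
#' @param side coil side length (m), default 21 mm.
#' @param names channel names.
#' @return object of class `magnetometer_array` with fields `int_points`
#'   (`4 n x 3`) and `int_weights` (all 1/4).
#' @export
magnetometer_array <- function(centers, normals, side = 0.021, names = NULL) {
  n <- nrow(centers)
  if (is.null(names)) names <- sprintf("MEG%03d", seq_len(n))
  ref <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  swap <- abs(normals[, 3]) > 0.9
  ref[swap, ] <- rep(c(1, 0, 0), each = sum(swap))
  t1 <- cross3(ref, normals); t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cross3(normals, t1)
  g <- side / 2 / sqrt(3)   # 2-point Gauss node on [-side/2, side/2]
  offs <- rbind(c(-g, -g), c(g, -g), c(-g, g), c(g, g))
  pts <- matrix(0, 4 * n, 3)
  for (k in 1:4)
    pts[seq(k, 4 * n, by = 4), ] <- centers + offs[k, 1] * t1 + offs[k, 2] * t2
  structure(list(centers = centers, normals = normals, side = side,
                 int_points = pts, int_weights = rep(0.25, 4), names = names),
            class = "magnetometer_array")
}

#' Build default electrode and magnetometer arrays for a head model
#'
#' Electrodes are a deterministic Fibonacci lattice over the upper scalp
#' (directions with `z > -0.25 * scalp radius`), snapped onto the scalp mesh
#' by radial ray casting; magnetometers sit on an upper helmet cap with
#' radial coil normals.
#'
#' @param model a [head_model()]; the last surface is taken as the scalp.
#' @param n_electrodes,n_magnetometers channel counts (default 256 / 102).
#' @param helmet_radius helmet sphere radius (mm); must exceed the maximum
#'   scalp radius.
#' @param seed reserved for randomised layouts; the default lattice is
#'   deterministic.
#' @return list with elements `electrodes` ([electrode_array()]) and
#'   `magnetometers` ([magnetometer_array()]).
#' @export
build_sensor_arrays <- function(model, n_electrodes = 256, n_magnetometers = 102,
                                helmet_radius = 120, seed = 1L) {
  scalp <- model$surfaces[[length(model$surfaces)]]$mesh
  ctr_mm <- colMeans(scalp$vertices)
  rel <- sweep(scalp$vertices, 2, ctr_mm)
  rmax <- max(sqrt(rowSums(rel^2)))
  if (helmet_radius <= rmax)
    stop("helmet radius (", helmet_radius, " mm) must exceed the scalp radius (",
         round(rmax, 1), " mm)")
  dirs <- fibonacci_cap(n_electrodes, zmin = -0.25, zmax = 1)
  W <- matrix(0, n_electrodes, nrow(scalp$vertices))
  pos <- matrix(0, n_electrodes, 3)
  for (i in seq_len(n_electrodes)) {
    hit <- ray_mesh_hit(scalp, ctr_mm, dirs[i, ])
    if (is.null(hit)) stop("electrode ray missed the scalp surface")
    W[i, scalp$faces[hit$face, ]] <- hit$bary
    pos[i, ] <- hit$point / 1000
  }
  mdirs <- fibonacci_cap(n_magnetometers, zmin = -0.15, zmax = 1)
  centers <- (sweep(mdirs * helmet_radius, 2, ctr_mm, "+")) / 1000
  list(electrodes = electrode_array(pos, W),
       magnetometers = magnetometer_array(centers, mdirs))
}

#' Interpolate scalp potentials to electrode positions
#'
#' Linear (barycentric) interpolation with the BEM hat basis within the
#' triangle containing each electrode; weights sum to one, so affine fields
#' are reproduced exactly.
#'
#' @param surface_potentials n_scalp_vertices x n_sources matrix (V).
#' @param electrodes an [electrode_array()].
#' @return n_channels x n_sources matrix (V).
#' @export
electrode_potentials <- function(surface_potentials, electrodes) {
  surface_potentials <- as.matrix(surface_potentials)
  if (nrow(surface_potentials) != ncol(electrodes$weights))
    stop("expected ", ncol(electrodes$weights), " scalp vertex values")
  electrodes$weights %*% surface_potentials
}

#' Integrate pointwise fields into magnetometer readings
#'
#' @param field `3 m x n_sources` matrix of field vectors at the array's
#'   integration points (layout as [dipole_primary_field()]).
#' @param array a [magnetometer_array()].
#' @return n_channels x n_sources matrix of average normal fields (T).
#' @export
magnetometer_readings <- function(field, array) {
  field <- as.matrix(field)
  np <- nrow(array$int_points)
  if (nrow(field) != 3 * np)
    stop("field must have ", 3 * np, " rows (3 per integration point)")
  R <- magnetometer_projection(array)
  R %*% field
}

# channels x (3 * n_int_points) projection: picks B . normal averaged over
# each channel's integration points.
magnetometer_projection <- function(array) {
  n <- nrow(array$centers)
  np <- nrow(array$int_points)
  R <- matrix(0, n, 3 * np)
  for (ch in seq_len(n)) {
    for (k in 1:4) {
      ip <- (ch - 1) * 4 + k
      R[ch, (3 * ip - 2):(3 * ip)] <- array$int_weights[k] * array$normals[ch, ]
    }
  }
  R
}
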