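# Discretisation and solution of the surface-integral equation for the
# potential with linear basis functions, by collocation (LC) or Galerkin (LG)
# weighting, with deflation and the isolated source approach (ISA).
#
# Conventions. The double-layer matrix B holds integrals
#   B[i, (l,j)] = int_{S_l} lambda_j(r') (r' - r_i) . dS' / |r' - r_i|^3
# (solid-angle convention: the row sum over a closed surface is 4*pi at
# interior points, 0 outside; on the own surface the vertex/face jump is
# included, so the row sum is exactly 4*pi there as well). These integrals
# are scale invariant, so meshes are passed in metres for uniformity only.
# The operator is
#   M = 4*pi*diag(sigma_in(row)) %*% N  -  B %*% diag(jump(col)),
# with N the (per-surface) mass matrix for LG and the identity for LC, and
# jump = sigma_in - sigma_out. M annihilates the constant vector exactly;
# deflation adds a rank-one term pinning the mean potential on the outermost
# surface to zero. The right-hand side per dipole is the infinite-medium term
#   g(r) = p . (r - r0) / |r - r0|^3
# sampled at vertices (LC) or hat-weighted by quadrature (LG).

#' Assemble a BEM system for a head model
#'
#' Discretises the boundary-integral equation for all surfaces of `model`
#' with linear basis functions and collocation (`"LC"`) or Galerkin (`"LG"`)
#' weighting. With `use_isa`, the isolated source approach is prepared: the
#' sub-model consisting of the isolation surface and everything inside it is
#' solved first with zero outside conductivity, and the full problem is then
#' solved with a modified right-hand side, which avoids the numerical
#' cancellation caused by the poorly conducting skull.
#'
#' @param model a validated [head_model()].
#' @param method `"LC"` (linear collocation) or `"LG"` (linear Galerkin).
#' @param use_isa logical; isolate the high-contrast skull (default `TRUE`
#'   when the isolation surface exists in the model).
#' @param isolation_surface surface name, default `"inner_skull"`.
#' @param deflation `"outer"` (rank-one correction pinning the mean outermost
#'   -surface potential to zero) or `"none"` (system left singular; solving
#'   raises an error directing to deflation).
#' @param galerkin_refine recursive outer-subdivision depth for near-singular
#'   Galerkin blocks (default 2).
#' @return an object of class `bem_system`.
#' @export
assemble_system <- function(model, method = c("LC", "LG"), use_isa = TRUE,
                            isolation_surface = "inner_skull",
                            deflation = c("outer", "none"),
                            galerkin_refine = 2L) {
  method <- match.arg(method)
  deflation <- match.arg(deflation)
  ns <- length(model$surfaces)
  nvs <- vapply(model$surfaces, function(s) nrow(s$mesh$vertices), 0L)
  offs <- cumsum(c(0L, nvs))[seq_len(ns)]
  vmap <- lapply(seq_len(ns), function(k) offs[k] + seq_len(nvs[k]))
  names(vmap) <- surface_names(model)
  nv <- sum(nvs)

  Vm <- lapply(model$surfaces, function(s) mesh_vertices_m(s$mesh))
  F0 <- lapply(model$surfaces, function(s) s$mesh$faces - 1L)

  B <- matrix(0, nv, nv)
  for (k in seq_len(ns)) for (l in seq_len(ns)) {
    if (method == "LC") {
      own <- if (k == l) seq_len(nvs[k]) - 1L else rep(-1L, nvs[k])
      blk <- cpp_dl_collocation(Vm[[l]], F0[[l]], Vm[[k]], as.integer(own))
      if (k == l) {
        auto <- 4 * pi - rowSums(blk)
        blk <- blk + diag(auto, nvs[k])
      }
    } else {
      blk <- cpp_dl_galerkin(Vm[[k]], F0[[k]], Vm[[l]], F0[[l]],
                             same_mesh = (k == l),
                             refine_depth = as.integer(galerkin_refine))
    }
    B[vmap[[k]], vmap[[l]]] <- blk
  }

  N <- NULL
  quad <- NULL
  if (method == "LG") {
    N <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(nv, nv))
    quad <- vector("list", ns)
    for (k in seq_len(ns)) {
      mesh <- model$surfaces[[k]]$mesh
      N[vmap[[k]], vmap[[k]]] <- mass_matrix(Vm[[k]], mesh$faces)
      quad[[k]] <- galerkin_quad_map(Vm[[k]], mesh$faces, vmap[[k]], nv)
    }
    # Galerkin analogue of the auto solid angle: the exact hat-weighted
    # block row sums are known (4*pi * mass row sum when the row surface is
    # on or inside the column surface, else 0); spreading the quadrature
    # deficit uniformly over each block restores the exact constant null
    # space that the adaptive outer quadrature perturbs at the 1e-4 level.
    for (k in seq_len(ns)) {
      n1 <- 4 * pi * Matrix::rowSums(N[vmap[[k]], vmap[[k]]])
      for (l in seq_len(ns)) {
        inside_l <- k == l ||
          point_in_mesh(model$surfaces[[l]]$mesh,
                        model$surfaces[[k]]$mesh$vertices[1, ])
        target <- if (inside_l) n1 else 0
        blk <- B[vmap[[k]], vmap[[l]], drop = FALSE]
        B[vmap[[k]], vmap[[l]]] <- blk + (target - rowSums(blk)) / ncol(blk)
      }
    }
  }

  iso <- NULL
  if (use_isa) {
    if (!isolation_surface %in% surface_names(model))
      stop("isolation surface '", isolation_surface, "' not in model")
    iso_i <- match(isolation_surface, surface_names(model))
    iso_mesh <- model$surfaces[[iso_i]]$mesh
    inner <- vapply(seq_len(ns), function(k) {
      k == iso_i || point_in_mesh(iso_mesh, model$surfaces[[k]]$mesh$vertices[1, ])
    }, TRUE)
    idx <- unlist(vmap[inner], use.names = FALSE)
    iso <- list(surface = isolation_surface, surface_index = iso_i,
                inner_surfaces = which(inner), idx = idx,
                iso_cols = vmap[[iso_i]],
                iso_local = match(vmap[[iso_i]], idx))
  }

  structure(list(model = model, method = method, vmap = vmap, nv = nv,
                 B = B, N = N, quad = quad, iso = iso, deflation = deflation,
                 env = new.env(parent = emptyenv())),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("<bem_system: %s, %d vertices, %d surfaces, ISA %s, deflation %s>\n",
              x$method, x$nv, length(x$model$surfaces),
              if (is.null(x$iso)) "off" else paste0("on (", x$iso$surface, ")"),
              x$deflation))
  invisible(x)
}

# exact per-surface mass matrix of linear hat functions (A/6 diag, A/12 off)
mass_matrix <- function(Vm, faces) {
  A <- face_areas(Vm, faces)
  i <- c(faces[, 1], faces[, 2], faces[, 3],
         faces[, 1], faces[, 2], faces[, 1], faces[, 3], faces[, 2], faces[, 3])
  j <- c(faces[, 1], faces[, 2], faces[, 3],
         faces[, 2], faces[, 1], faces[, 3], faces[, 1], faces[, 3], faces[, 2])
  x <- c(rep(A / 6, 3), rep(A / 12, 6))
  Matrix::sparseMatrix(i = i, j = j, x = x)
}

# quadrature points (7-point rule) and the sparse map from point values to
# hat-weighted vertex rows, for Galerkin right-hand sides
galerkin_quad_map <- function(Vm, faces, rows_global, nv) {
  qb <- rbind(c(1, 1, 1) / 3,
              c(0.059715871789770, 0.470142064105115, 0.470142064105115),
              c(0.470142064105115, 0.059715871789770, 0.470142064105115),
              c(0.470142064105115, 0.470142064105115, 0.059715871789770),
              c(0.797426985353087, 0.101286507323456, 0.101286507323456),
              c(0.101286507323456, 0.797426985353087, 0.101286507323456),
              c(0.101286507323456, 0.101286507323456, 0.797426985353087))
  qw <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  nf <- nrow(faces)
  A <- face_areas(Vm, faces)
  v1 <- Vm[faces[, 1], , drop = FALSE]
  v2 <- Vm[faces[, 2], , drop = FALSE]
  v3 <- Vm[faces[, 3], , drop = FALSE]
  Q <- matrix(0, 7 * nf, 3)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (q in 1:7) {
    rows <- seq(q, 7 * nf, by = 7)
    Q[rows, ] <- qb[q, 1] * v1 + qb[q, 2] * v2 + qb[q, 3] * v3
    for (k in 1:3) {
      ii <- c(ii, rows_global[faces[, k]])
      jj <- c(jj, rows)
      xx <- c(xx, qw[q] * A * qb[q, k])
    }
  }
  list(Q = Q,
       P = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, 7 * nf)))
}

# infinite-medium dipole source term g(r) = p . (r - r0) / |r - r0|^3
dipole_g <- function(sources, points) {
  out <- matrix(0, nrow(points), n_sources(sources))
  for (s in seq_len(n_sources(sources))) {
    d <- sweep(points, 2, sources$positions[s, ])
    r3 <- sqrt(rowSums(d^2))^3
    out[, s] <- (d %*% sources$moments[s, ]) / r3
  }
  out
}

#' Source terms for a BEM system
#'
#' Builds the right-hand-side matrix (vertices x sources) of the discretised
#' potential equation for a set of dipoles: nodal samples of the
#' infinite-medium term for LC, hat-weighted quadrature integrals for LG.
#'
#' @param system a [assemble_system()] result.
#' @param sources a [source_space()].
#' @return `nv x n_sources` matrix.
#' @export
bem_source_terms <- function(system, sources) {
  if (system$method == "LC") {
    pts <- do.call(rbind, lapply(system$model$surfaces,
                                 function(s) mesh_vertices_m(s$mesh)))
    dipole_g(sources, pts)
  } else {
    out <- matrix(0, system$nv, n_sources(sources))
    for (k in seq_along(system$quad)) {
      qk <- system$quad[[k]]
      out <- out + as.matrix(qk$P %*% dipole_g(sources, qk$Q))
    }
    out
  }
}

# per-vertex sigma_in / jump vectors in global ordering
row_sigma_in <- function(system, surfaces = seq_along(system$model$surfaces),
                         sigma_out_zero = integer(0)) {
  unlist(lapply(surfaces, function(k)
    rep(system$model$surfaces[[k]]$sigma_in,
        length(system$vmap[[k]]))), use.names = FALSE)
}

col_jump <- function(system, surfaces = seq_along(system$model$surfaces),
                     sigma_out_zero = integer(0)) {
  unlist(lapply(surfaces, function(k) {
    s <- system$model$surfaces[[k]]
    so <- if (k %in% sigma_out_zero) 0 else s$sigma_out
    rep(s$sigma_in - so, length(system$vmap[[k]]))
  }), use.names = FALSE)
}

# Build the (optionally deflated) operator. which = "full" or "iso".
bem_operator <- function(system, which = "full", deflated = TRUE) {
  if (which == "full") {
    surfs <- seq_along(system$model$surfaces)
    rows <- seq_len(system$nv)
    zero_out <- integer(0)
    defl_surf <- length(system$model$surfaces)   # outermost
  } else {
    surfs <- system$iso$inner_surfaces
    rows <- system$iso$idx
    zero_out <- system$iso$surface_index
    defl_surf <- system$iso$surface_index
  }
  sin_r <- row_sigma_in(system, surfs)
  jmp_c <- col_jump(system, surfs, sigma_out_zero = zero_out)
  Bsub <- system$B[rows, rows, drop = FALSE]
  M <- -sweep(Bsub, 2, jmp_c, "*")
  if (system$method == "LC") {
    diag(M) <- diag(M) + 4 * pi * sin_r
  } else {
    M <- M + 4 * pi * as.matrix(Matrix::Diagonal(x = sin_r) %*%
                                  system$N[rows, rows, drop = FALSE])
  }
  if (deflated) {
    if (system$deflation == "none")
      return(structure(M, deflated = FALSE))
    dv <- system$vmap[[defl_surf]]
    w <- numeric(length(rows))
    w[match(dv, rows)] <- 1 / length(dv)
    s <- mean(abs(diag(M)))
    M <- M + s * outer(rep(1, length(rows)), w)
    attr(M, "deflated") <- TRUE
  }
  M
}

# conductivity fingerprint for factorisation caching
sigma_key <- function(system, which) {
  sig <- unlist(lapply(system$model$surfaces,
                       function(s) c(s$sigma_in, s$sigma_out)))
  paste(which, system$deflation, paste(signif(sig, 12), collapse = ","))
}

# cached LU solve M x = rhs (and for the transposed system); one cached
# factorisation per (sub-system, transpose) slot, keyed by the
# conductivities, so sweeps never hold more than a few LUs in memory and
# cache hits never rebuild the dense operator
bem_solve <- function(system, rhs, which = "full", transpose = FALSE) {
  slot <- paste0("lu_", which, if (transpose) "_t")
  key <- sigma_key(system, which)
  cached <- system$env[[slot]]
  if (is.null(cached) || !identical(cached$key, key)) {
    system$env[[slot]] <- NULL   # free the previous factorisation first
    M <- bem_operator(system, which)
    if (!isTRUE(attr(M, "deflated")))
      stop("BEM operator is singular without deflation; assemble the system ",
           "with deflation = \"outer\"")
    if (transpose) M <- t(M)
    cached <- list(key = key, lu = Matrix::lu(M))
    rm(M)
    system$env[[slot]] <- cached
  }
  as.matrix(Matrix::solve(cached$lu, rhs))
}

#' Solve boundary potentials for given source terms
#'
#' Solves the assembled (deflated, optionally ISA-split) system for nodal
#' potentials on all boundary surfaces, one column per source. The
#' factorisation is cached and reused across calls with the same
#' conductivities.
#'
#' @param system a [assemble_system()] result.
#' @param source_terms `nv x n_sources` matrix from [bem_source_terms()].
#' @return `nv x n_sources` matrix of potentials (V).
#' @export
solve_potentials <- function(system, source_terms) {
  source_terms <- as.matrix(source_terms)
  if (nrow(source_terms) != system$nv)
    stop("source_terms must have ", system$nv, " rows (total vertex count)")
  if (ncol(source_terms) == 0L) return(matrix(0, system$nv, 0))
  if (is.null(system$iso))
    return(bem_solve(system, source_terms))
  iso <- system$iso
  phi0 <- bem_solve(system, source_terms[iso$idx, , drop = FALSE], which = "iso")
  sigma_sk <- system$model$surfaces[[iso$surface_index]]$sigma_out
  gt <- -sigma_sk * (system$B[, iso$iso_cols, drop = FALSE] %*%
                       phi0[iso$iso_local, , drop = FALSE])
  phi <- bem_solve(system, gt)
  phi[iso$idx, ] <- phi[iso$idx, ] + phi0
  phi
}

#' Transfer matrix from source terms to sensor readings
#'
#' Returns `T` (channels x vertices) such that `T %*% source_terms` equals
#' `sensor_weights %*% solve_potentials(system, source_terms)` for any source
#' set; the channel-side formulation factorises the system once regardless of
#' the number of sources.
#'
#' @param system a [assemble_system()] result.
#' @param sensor_weights channels x nv matrix (e.g. zero-padded electrode
#'   interpolation weights).
#' @return channels x nv matrix.
#' @export
transfer_matrix <- function(system, sensor_weights) {
  S <- as.matrix(sensor_weights)
  if (ncol(S) != system$nv)
    stop("sensor_weights must have ", system$nv, " columns")
  if (nrow(S) == 0L) return(matrix(0, 0, system$nv))
  SM <- t(bem_solve(system, t(S), transpose = TRUE))
  if (is.null(system$iso)) return(SM)
  iso <- system$iso
  sigma_sk <- system$model$surfaces[[iso$surface_index]]$sigma_out
  Y <- S[, iso$idx, drop = FALSE]
  Y[, iso$iso_local] <- Y[, iso$iso_local, drop = FALSE] -
    sigma_sk * (SM %*% system$B[, iso$iso_cols, drop = FALSE])
  Z <- t(bem_solve(system, t(Y), which = "iso", transpose = TRUE))
  out <- matrix(0, nrow(S), system$nv)
  out[, iso$idx] <- Z
  out
}

#' Swap conductivities of an assembled system
#'
#' Reuses the geometry-dependent double-layer matrices with the
#' conductivities of `model`, which must have identical surfaces (name and
#' vertex count). Used by conductivity sweeps, where only the skull
#' resistivity ratio changes.
#'
#' @param system a [assemble_system()] result.
#' @param model a [head_model()] with the same geometry.
#' @return a `bem_system` sharing the assembly with `system`.
#' @export
bem_update_conductivities <- function(system, model) {
  old <- system$model
  if (!identical(surface_names(old), surface_names(model)))
    stop("model surfaces differ from the assembled system")
  for (k in seq_along(old$surfaces)) {
    if (!identical(dim(old$surfaces[[k]]$mesh$vertices),
                   dim(model$surfaces[[k]]$mesh$vertices)))
      stop("mesh of surface '", surface_names(old)[k], "' differs")
  }
  system$model <- model
  system
}

#' Signed solid angles of mesh faces at field points
#'
#' Closed-form (van Oosterom-Strackee) signed solid angle of every face at
#' every point; the sum over a closed outward-oriented mesh is `4 pi` at
#' interior points and `0` outside.
#'
#' @param mesh a [tri_mesh()].
#' @param points n x 3 matrix (mm, like the mesh).
#' @return n x n_faces matrix (steradians).
#' @export
solid_angles <- function(mesh, points) {
  points <- matrix(points, ncol = 3)
  d2 <- point_face_min_dist2(mesh, points)
  if (any(d2 < (1e-6)^2))
    stop("singular evaluation: point lies on the surface")
  cpp_solid_angles(mesh$vertices, mesh$faces - 1L, points)
}

# squared distance from each point to the nearest face vertex (cheap guard)
point_face_min_dist2 <- function(mesh, points) {
  v <- mesh$vertices
  apply(points, 1, function(p) min(rowSums(sweep(v, 2, p)^2)))
}

#' Analytic double-layer weights of linear basis functions
#'
#' For each field point, the closed-form integrals
#' `int lambda_j (r' - p) . dS' / |r' - p|^3` over all faces, accumulated per
#' vertex basis function. For every triangle the three linear-basis weights
#' sum to the triangle's solid angle (partition of unity).
#'
#' @param mesh a [tri_mesh()].
#' @param points n x 3 matrix (mm).
#' @return n x n_vertices matrix.
#' @export
linear_collocation_weights <- function(mesh, points) {
  points <- matrix(points, ncol = 3)
  cpp_dl_collocation(mesh$vertices, mesh$faces - 1L, points,
                     rep(-1L, nrow(points)))
}
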