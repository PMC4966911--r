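# Geselowitz volume-current magnetic field and full EEG/MEG leadfields.
#
# The volume-current contribution is
#   B_v(r) = mu0/(4 pi) sum_l (sigma_out - sigma_in)_l
#            int_{S_l} phi(r') dS' x (r - r') / |r - r'|^3,
# evaluated with per-triangle quadrature of the linear potential and
# linearly interpolated vertex normals (curved-panel correction). Each
# surface operator is projected to annihilate constant potentials exactly,
# matching the closed-surface identity of the continuous integral.

#' Leadfield (topography matrix)
#'
#' @param matrix channels x sources matrix of sensor signals per unit source.
#' @param modality `"EEG"` or `"MEG"`.
#' @param channels channel names.
#' @param sources the [source_space()] used.
#' @return object of class `leadfield`.
#' @export
leadfield <- function(matrix, modality, channels = NULL, sources = NULL) {
  if (any(!is.finite(matrix))) stop("leadfield contains non-finite entries")
  structure(list(matrix = matrix, modality = modality,
                 channels = channels, sources = sources),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield %s: %d channels x %d sources>\n",
              x$modality, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# Per-surface Geselowitz operators at fixed field points, cached on the
# system environment (geometry only; conductivity jumps applied at use).
geselowitz_operators <- function(system, points_m, nquad = 3L) {
  fp <- c(nrow(points_m), sum(points_m), sum(points_m^2), nquad)
  cached <- system$env$ges
  if (!is.null(cached) && isTRUE(all.equal(cached$fp, fp))) return(cached$ops)
  ops <- lapply(system$model$surfaces, function(s) {
    G <- cpp_geselowitz(mesh_vertices_m(s$mesh), s$mesh$faces - 1L,
                        vertex_normals(s$mesh), points_m, 3L)
    # exact inertness of constant potentials on a closed surface
    nv <- ncol(G)
    G - tcrossprod(G %*% rep(1, nv), rep(1 / nv, nv))
  })
  system$env$ges <- list(fp = fp, ops = ops)
  ops
}

#' Volume-current magnetic field from boundary potentials
#'
#' Evaluates the surface-integral (Geselowitz) term of the magnetic field
#' from nodal boundary potentials, summed over all conductivity boundaries.
#'
#' @param model a [head_model()].
#' @param nodal_potentials total-vertex-count x n_sources matrix (V), stacked
#'   in surface order.
#' @param field_points n x 3 matrix (m), strictly outside the outermost
#'   surface.
#' @return `3 n x n_sources` matrix (T), rows are x,y,z triplets per point.
#' @export
geselowitz_volume_field <- function(model, nodal_potentials, field_points) {
  field_points <- as.matrix(field_points)
  scalp <- model$surfaces[[length(model$surfaces)]]$mesh
  inside <- vapply(seq_len(nrow(field_points)), function(i)
    point_in_mesh(scalp, field_points[i, ] * 1000), TRUE)
  if (any(inside))
    stop("field points must lie strictly outside the conductor")
  nodal_potentials <- as.matrix(nodal_potentials)
  nvs <- vapply(model$surfaces, function(s) nrow(s$mesh$vertices), 0L)
  if (nrow(nodal_potentials) != sum(nvs))
    stop("expected ", sum(nvs), " potential rows")
  offs <- cumsum(c(0L, nvs))
  out <- matrix(0, 3 * nrow(field_points), ncol(nodal_potentials))
  for (l in seq_along(model$surfaces)) {
    s <- model$surfaces[[l]]
    jump_out <- s$sigma_out - s$sigma_in
    if (jump_out == 0) next
    G <- cpp_geselowitz(mesh_vertices_m(s$mesh), s$mesh$faces - 1L,
                        vertex_normals(s$mesh), field_points, 3L)
    nv <- ncol(G)
    G <- G - tcrossprod(G %*% rep(1, nv), rep(1 / nv, nv))
    phi_l <- nodal_potentials[(offs[l] + 1):offs[l + 1], , drop = FALSE]
    out <- out + (MU0 / (4 * pi)) * jump_out * (G %*% phi_l)
  }
  out
}

# zero-padded sensor weight matrix over all system vertices (scalp block)
electrode_system_weights <- function(system, electrodes) {
  scalp_k <- length(system$model$surfaces)
  W <- matrix(0, nrow(electrodes$weights), system$nv)
  W[, system$vmap[[scalp_k]]] <- as.matrix(electrodes$weights)
  W
}

avg_reference <- function(L) sweep(L, 2, colMeans(L))

#' EEG leadfield of a head model
#'
#' Solves the BEM for every dipole and interpolates the scalp potential to
#' the electrodes; topographies are average-referenced. The conductivities
#' of `model` are applied to the assembled `system` (geometry must match),
#' so conductivity sweeps reuse one assembly.
#'
#' @param model a [head_model()].
#' @param system a [assemble_system()] result for the same geometry.
#' @param sources a [source_space()].
#' @param electrodes an [electrode_array()] snapped to the model's scalp.
#' @param via `"transfer"` factorises the channel-side (transposed) system —
#'   best when sweeping many conductivities; `"direct"` solves the nodal
#'   potentials and shares its factorisation with [meg_leadfield()].
#' @return a [leadfield()] (V per unit dipole moment), channels x sources.
#' @export
eeg_leadfield <- function(model, system, sources, electrodes,
                          via = c("transfer", "direct")) {
  via <- match.arg(via)
  system <- bem_update_conductivities(system, model)
  W <- electrode_system_weights(system, electrodes)
  L <- if (via == "transfer") {
    transfer_matrix(system, W) %*% bem_source_terms(system, sources)
  } else {
    W %*% solve_potentials(system, bem_source_terms(system, sources))
  }
  leadfield(avg_reference(L), "EEG", electrodes$names, sources)
}

#' MEG magnetometer leadfield of a head model
#'
#' Primary (Biot-Savart) plus volume-current (Geselowitz) field, integrated
#' over the pickup coils.
#'
#' @param model a [head_model()].
#' @param system a [assemble_system()] result for the same geometry.
#' @param sources a [source_space()].
#' @param magnetometers a [magnetometer_array()].
#' @return a [leadfield()] (T per unit dipole moment), channels x sources.
#' @export
meg_leadfield <- function(model, system, sources, magnetometers) {
  system <- bem_update_conductivities(system, model)
  phi <- solve_potentials(system, bem_source_terms(system, sources))
  pts <- magnetometers$int_points
  ops <- geselowitz_operators(system, pts)
  field <- dipole_primary_field(sources, pts)
  for (l in seq_along(system$model$surfaces)) {
    s <- system$model$surfaces[[l]]
    jump_out <- s$sigma_out - s$sigma_in
    if (jump_out == 0) next
    phi_l <- phi[system$vmap[[l]], , drop = FALSE]
    field <- field + (MU0 / (4 * pi)) * jump_out * (ops[[l]] %*% phi_l)
  }
  leadfield(as.matrix(magnetometer_readings(field, magnetometers)),
            "MEG", magnetometers$names, sources)
}
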