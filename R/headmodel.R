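# Piecewise-homogeneous, isotropic volume-conductor models assembled from
# closed boundary surfaces. Topology (nested or not) is carried entirely by
# the per-surface (sigma_in, sigma_out) pairs; no containment tree is needed
# by the solver.

SIGMA_SOFT <- 0.33   # brain and scalp conductivity, S/m
SIGMA_CSF  <- 1.79   # cerebrospinal fluid, S/m

#' Conductivity boundary surface
#'
#' @param mesh a [tri_mesh()].
#' @param sigma_in conductivity just inside the surface (S/m).
#' @param sigma_out conductivity just outside (S/m); 0 for the outermost
#'   surface (air).
#' @param name compartment boundary label.
#' @return object of class `boundary_surface`; the conductivity jump
#'   `sigma_in - sigma_out` scales all of the surface's coupling terms.
#' @export
boundary_surface <- function(mesh, sigma_in, sigma_out, name = mesh$name) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (sigma_in < 0 || sigma_out < 0) stop("conductivities must be non-negative")
  structure(list(mesh = mesh, sigma_in = sigma_in, sigma_out = sigma_out,
                 name = name),
            class = "boundary_surface")
}

#' Head conductor model
#'
#' An ordered set of boundary surfaces with inside/outside conductivities,
#' optionally parameterised by the soft-tissue-to-skull resistivity ratio K
#' (`sigma_skull = 0.33 / K`).
#'
#' @param surfaces list of [boundary_surface()] objects.
#' @param K skull resistivity ratio associated with the model, or `NA`.
#' @return object of class `head_model`.
#' @export
head_model <- function(surfaces, K = NA_real_) {
  stopifnot(length(surfaces) >= 1L,
            all(vapply(surfaces, inherits, TRUE, "boundary_surface")))
  names(surfaces) <- vapply(surfaces, `[[`, "", "name")
  structure(list(surfaces = surfaces, K = K), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model: %d surfaces, K = %s>\n", length(x$surfaces),
              format(x$K)))
  for (s in x$surfaces)
    cat(sprintf("  %-14s %5d vertices  sigma_in %.4g  sigma_out %.4g\n",
                s$name, nrow(s$mesh$vertices), s$sigma_in, s$sigma_out))
  invisible(x)
}

surface_names <- function(model) names(model$surfaces)

model_jumps <- function(model)
  vapply(model$surfaces, function(s) s$sigma_in - s$sigma_out, 0)

#' Layered-sphere head model
#'
#' Concentric-sphere surrogate of a four-compartment (brain, CSF, skull,
#' scalp; `kind = "4C"`) or three-shell (`kind = "3S"`, CSF volume labelled
#' as brain) head. Conductivities: brain and scalp 0.33 S/m, CSF 1.79 S/m,
#' skull `0.33 / K`. Default radii 78/81/87/92 mm give a 3 mm CSF layer,
#' 6 mm skull and 5 mm scalp.
#'
#' @param kind `"4C"` or `"3S"`.
#' @param K skull resistivity ratio (> 0).
#' @param radii named numeric vector (mm) with `pial`, `inner_skull`,
#'   `outer_skull`, `scalp`, strictly increasing; `pial` is ignored for
#'   `kind = "3S"`.
#' @param center sphere centre (mm).
#' @param mesh_levels named integer vector of icosphere subdivision levels per
#'   surface (same names as `radii`).
#' @param brain_scale factor multiplying the brain conductivity; supports the
#'   alternative CSF compensation that raises brain conductivity in a 3-S
#'   model (default 1).
#' @return a [head_model()].
#' @export
build_layered_sphere_model <- function(kind = c("4C", "3S"), K = 50,
                                       radii = c(pial = 78, inner_skull = 81,
                                                 outer_skull = 87, scalp = 92),
                                       center = c(0, 0, 0),
                                       mesh_levels = c(pial = 3, inner_skull = 3,
                                                       outer_skull = 2, scalp = 2),
                                       brain_scale = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(K) || K <= 0) stop("K must be positive")
  need <- if (kind == "4C") c("pial", "inner_skull", "outer_skull", "scalp")
          else c("inner_skull", "outer_skull", "scalp")
  if (!all(need %in% names(radii))) stop("radii must name ", paste(need, collapse = ", "))
  r <- radii[need]
  if (any(diff(r) <= 0)) stop("invalid geometry: radii must be strictly increasing")
  sig_brain <- SIGMA_SOFT * brain_scale
  sig_skull <- SIGMA_SOFT / K
  lv <- mesh_levels[need]
  mk <- function(nm) build_icosphere(lv[[nm]], r[[nm]], center, name = nm)
  surfaces <- if (kind == "4C") list(
    boundary_surface(mk("pial"), sig_brain, SIGMA_CSF),
    boundary_surface(mk("inner_skull"), SIGMA_CSF, sig_skull),
    boundary_surface(mk("outer_skull"), sig_skull, SIGMA_SOFT),
    boundary_surface(mk("scalp"), SIGMA_SOFT, 0)
  ) else list(
    boundary_surface(mk("inner_skull"), sig_brain, sig_skull),
    boundary_surface(mk("outer_skull"), sig_skull, SIGMA_SOFT),
    boundary_surface(mk("scalp"), SIGMA_SOFT, 0)
  )
  head_model(surfaces, K = K)
}

#' Non-nested multi-body test model
#'
#' A four-compartment sphere model whose brain consists of three disjoint
#' bodies immersed in the CSF-conductivity space inside the inner skull: a
#' cerebrum surrogate (20 mm sphere at z = +40 mm) and two 30 mm blobs at
#' x = -35 and +35 mm. Mirrors the non-nested five-sub-volume topology that
#' arises when the cerebellum is meshed as a separate brain body.
#'
#' @param K skull resistivity ratio.
#' @param blob_sigma_in conductivity inside the blobs (default brain).
#' @param mesh_level icosphere level for the brain bodies.
#' @return a [head_model()] with six surfaces.
#' @export
build_nonnested_test_model <- function(K = 50, blob_sigma_in = SIGMA_SOFT,
                                       mesh_level = 2) {
  outer <- build_layered_sphere_model("3S", K = K,
                                      mesh_levels = c(inner_skull = mesh_level + 1,
                                                      outer_skull = mesh_level,
                                                      scalp = mesh_level))
  # reuse skull/scalp; replace the brain: inner skull now borders CSF inside
  inner_skull <- outer$surfaces$inner_skull
  inner_skull$sigma_in <- SIGMA_CSF
  bodies <- list(
    boundary_surface(build_icosphere(mesh_level, 20, c(0, 0, 40), "cerebrum"),
                     SIGMA_SOFT, SIGMA_CSF),
    boundary_surface(build_icosphere(mesh_level, 30, c(-35, 0, 0), "blob_left"),
                     blob_sigma_in, SIGMA_CSF),
    boundary_surface(build_icosphere(mesh_level, 30, c(35, 0, 0), "blob_right"),
                     blob_sigma_in, SIGMA_CSF))
  head_model(c(bodies, list(inner_skull, outer$surfaces$outer_skull,
                            outer$surfaces$scalp)), K = K)
}

# --- containment and validation --------------------------------------------

# Is point p (mm) inside mesh? Winding via summed signed solid angles.
point_in_mesh <- function(mesh, p) {
  om <- sum(cpp_solid_angles(mesh$vertices, mesh$faces - 1L,
                             matrix(p, 1, 3)))
  om > 2 * pi   # 4*pi inside, 0 outside
}

# surface i strictly inside surface j (tested on a representative vertex)
containment_matrix <- function(model) {
  n <- length(model$surfaces)
  inside <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    inside[i, j] <- point_in_mesh(model$surfaces[[j]]$mesh,
                                  model$surfaces[[i]]$mesh$vertices[1, ])
  dimnames(inside) <- list(surface_names(model), surface_names(model))
  inside
}

# Spot-check intersection of two closed surfaces: vertices of one falling on
# both sides of the other (and vice versa) flag an intersection.
surfaces_intersect <- function(mesh_a, mesh_b, n_sample = 40L) {
  split_check <- function(ma, mb) {
    idx <- unique(round(seq(1, nrow(ma$vertices), length.out = n_sample)))
    om <- rowSums(cpp_solid_angles(mb$vertices, mb$faces - 1L,
                                   ma$vertices[idx, , drop = FALSE]))
    ins <- om > 2 * pi
    any(ins) && !all(ins)
  }
  split_check(mesh_a, mesh_b) || split_check(mesh_b, mesh_a)
}

#' Validate a head model
#'
#' Checks closedness and orientation of every surface, that the outermost
#' surfaces border a non-conductor, conductivity consistency across shared
#' compartments (each surface's outside conductivity must match the inside
#' conductivity of its immediate enclosing surface), and spot-checks pairwise
#' surface intersections.
#'
#' @param model a [head_model()].
#' @param strict raise an error on the first failed check instead of
#'   reporting it.
#' @return a tibble with columns `check`, `surface`, `ok`, `detail`.
#' @export
validate_model <- function(model, strict = FALSE) {
  rows <- list()
  add <- function(check, surface, ok, detail = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(check = check, surface = surface,
                                                ok = ok, detail = detail)
    if (strict && !ok)
      stop("model validation failed: ", check, " for surface '", surface,
           "' ", detail)
  }
  n <- length(model$surfaces)
  for (s in model$surfaces) {
    st <- mesh_statistics(s$mesh)
    add("closed", s$name, st$is_closed)
    add("outward", s$name, st$is_outward)
  }
  inside <- containment_matrix(model)
  for (i in seq_len(n)) {
    s <- model$surfaces[[i]]
    enclosing <- which(inside[i, ])
    if (length(enclosing) == 0L) {
      add("outermost borders nonconductor", s$name, s$sigma_out == 0,
          if (s$sigma_out != 0) "outermost surface must border nonconductor" else "")
    } else {
      # immediate parent: enclosing surface that is inside all other enclosers
      parent <- enclosing[which.max(rowSums(inside[enclosing, enclosing, drop = FALSE]))]
      ps <- model$surfaces[[parent]]
      add("conductivity consistent", s$name,
          isTRUE(all.equal(s$sigma_out, ps$sigma_in)),
          sprintf("sigma_out %.4g vs enclosing '%s' sigma_in %.4g",
                  s$sigma_out, ps$name, ps$sigma_in))
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    mi <- model$surfaces[[i]]$mesh; mj <- model$surfaces[[j]]$mesh
    bad <- surfaces_intersect(mi, mj)
    add("no intersection", paste(model$surfaces[[i]]$name,
                                 model$surfaces[[j]]$name, sep = "/"), !bad)
  }
  dplyr::bind_rows(rows)
}
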