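# Topography comparison metrics (RE, CC), conductivity sweeps over the skull
# resistivity ratio K, selection of optimal (K_opt) and equivalent (K_equi)
# ratios, and expected-error aggregation.

#' Relative error between two topographies
#'
#' `RE = |d_ref - d_test| / |d_ref|` (Euclidean norms): sensitive to both
#' shape and amplitude differences.
#'
#' @param d_ref,d_test channel vectors.
#' @return non-negative scalar; `NA` with a warning if `|d_ref| = 0`.
#' @export
relative_error <- function(d_ref, d_test) {
  nref <- sqrt(sum(d_ref^2))
  if (nref == 0) {
    warning("reference topography has zero norm; RE undefined")
    return(NA_real_)
  }
  sqrt(sum((d_ref - d_test)^2)) / nref
}

#' Correlation coefficient between two topographies
#'
#' Centred cosine similarity: identically shaped topographies have CC = 1
#' regardless of overall amplitude.
#'
#' @param d_ref,d_test channel vectors.
#' @return scalar in `[-1, 1]`; `NA` with a warning for a constant vector.
#' @export
correlation_coefficient <- function(d_ref, d_test) {
  a <- d_ref - mean(d_ref)
  b <- d_test - mean(d_test)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("constant topography; CC undefined")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

percentile_summary <- function(x, prefix) {
  q <- quantile(x, c(0.16, 0.5, 0.84), na.rm = TRUE, names = FALSE)
  setNames(list(q[2], q[1], q[3]),
           paste0(c("median_", "p16_", "p84_"), prefix))
}

#' Compare two leadfields source by source
#'
#' Column-wise RE and CC between matched topographies plus their median and
#' 16th/84th percentiles (the non-parametric analogue of the standard
#' deviation).
#'
#' @param L_ref,L_test [leadfield()] objects (or plain matrices) with
#'   identical channel and source sets.
#' @return object of class `metric_summary`: list with per-source `re`, `cc`
#'   and a one-row `summary` tibble.
#' @export
compare_leadfields <- function(L_ref, L_test) {
  A <- if (inherits(L_ref, "leadfield")) L_ref$matrix else as.matrix(L_ref)
  B <- if (inherits(L_test, "leadfield")) L_test$matrix else as.matrix(L_test)
  if (!all(dim(A) == dim(B)))
    stop("leadfields have mismatched channels or sources")
  re <- vapply(seq_len(ncol(A)), function(j) relative_error(A[, j], B[, j]), 0)
  cc <- vapply(seq_len(ncol(A)), function(j)
    correlation_coefficient(A[, j], B[, j]), 0)
  structure(list(re = re, cc = cc,
                 summary = tibble::as_tibble(c(percentile_summary(re, "re"),
                                               percentile_summary(cc, "cc")))),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("<metric_summary over %d sources: median RE %.4f, median CC %.5f>\n",
              length(x$re), x$summary$median_re, x$summary$median_cc))
  invisible(x)
}

#' Per-source metric tibble
#' @param x a `metric_summary`.
#' @param ... unused.
#' @return tibble with columns `source`, `re`, `cc`.
#' @export
as_tibble.metric_summary <- function(x, ...) {
  tibble::tibble(source = seq_along(x$re), re = x$re, cc = x$cc)
}

# --- study geometry ---------------------------------------------------------

#' Sphere-surrogate study geometry specification
#'
#' Defines the fixed geometry of a conductivity study: sphere radii, mesh
#' density (icosphere level) per surface for the reference and test models,
#' and an optional shared radial perturbation that breaks spherical symmetry.
#'
#' @param radii named radii in mm (`pial`, `inner_skull`, `outer_skull`,
#'   `scalp`).
#' @param ref_levels,test_levels named icosphere levels per surface.
#' @param perturb `NULL`, or `list(amplitude =, max_degree =, seed =)`
#'   applied radially to all surfaces with one shared band-limited field.
#' @param center sphere centre (mm).
#' @return object of class `study_geometry`.
#' @export
sphere_geometry <- function(radii = c(pial = 78, inner_skull = 81,
                                      outer_skull = 87, scalp = 92),
                            ref_levels = c(pial = 4, inner_skull = 4,
                                           outer_skull = 3, scalp = 3),
                            test_levels = ref_levels,
                            perturb = NULL, center = c(0, 0, 0)) {
  structure(list(radii = radii, ref_levels = ref_levels,
                 test_levels = test_levels, perturb = perturb,
                 center = center),
            class = "study_geometry")
}

#' Radially perturb all surfaces of a head model with one shared field
#'
#' All surfaces are displaced with the same band-limited relative radial
#' field (normalised on a fixed direction lattice), which preserves their
#' mutual distances relative to the local radius and hence non-intersection.
#'
#' @param model a concentric-sphere [head_model()].
#' @param amplitude maximum relative displacement (`< 0.3`).
#' @param max_degree maximum spherical-harmonic degree.
#' @param seed integer seed.
#' @return the perturbed [head_model()].
#' @export
perturb_model <- function(model, amplitude, max_degree = 6L, seed = 1L) {
  if (amplitude < 0 || amplitude >= 0.3) stop("amplitude must be in [0, 0.3)")
  if (amplitude == 0) return(model)
  f_raw <- random_band_limited(max_degree, seed)
  scl <- amplitude / max(abs(f_raw(fibonacci_cap(2000))))
  ctr <- colMeans(model$surfaces[[length(model$surfaces)]]$mesh$vertices)
  model$surfaces <- lapply(model$surfaces, function(s) {
    mesh <- s$mesh
    rel <- sweep(mesh$vertices, 2, ctr)
    r0 <- sqrt(rowSums(rel^2))
    dirs <- rel / r0
    verts <- sweep(dirs * (r0 * (1 + scl * f_raw(dirs))), 2, ctr, "+")
    rbar <- mean(r0)
    nrm <- perturbed_normals(dirs, function(u) rbar * (1 + scl * f_raw(u)))
    s$mesh <- tri_mesh(verts, mesh$faces, name = mesh$name, normals = nrm,
                       orient = FALSE)
    s
  })
  model
}

build_study_model <- function(kind, K, geometry, which = c("ref", "test"),
                              brain_scale = 1) {
  which <- match.arg(which)
  levels <- if (which == "ref") geometry$ref_levels else geometry$test_levels
  m <- build_layered_sphere_model(kind, K = K, radii = geometry$radii,
                                  center = geometry$center,
                                  mesh_levels = levels,
                                  brain_scale = brain_scale)
  if (!is.null(geometry$perturb))
    m <- perturb_model(m, geometry$perturb$amplitude,
                       geometry$perturb$max_degree %||% 6L,
                       geometry$perturb$seed %||% 1L)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# largest source radius keeping min_depth below the (possibly perturbed) pial
source_radius_limit <- function(models, min_depth = 1.5) {
  rmin <- min(vapply(models, function(m) {
    pial <- m$surfaces[[1]]$mesh
    rel <- sweep(pial$vertices, 2, colMeans(pial$vertices))
    min(sqrt(rowSums(rel^2)))
  }, 0))
  rmin - min_depth
}

# --- conductivity sweep -----------------------------------------------------

#' Sweep the skull resistivity ratio in reference and test models
#'
#' Computes reference leadfields at every `K_ref` (reference mesh levels,
#' `ref_method`) and test leadfields at every `K_test` (test kind, mesh
#' levels and method) on fixed geometry, sources and sensors, and compares
#' them source by source. When the reference and test specifications agree,
#' the assembled system is shared and the sweep diagonal is exactly zero.
#'
#' @param geometry a [sphere_geometry()].
#' @param modality `"EEG"` or `"MEG"`.
#' @param K_ref,K_test skull resistivity ratio grids.
#' @param test_kind `"4C"` or `"3S"`; the reference is `ref_kind` (default
#'   four-compartment).
#' @param ref_kind reference model kind.
#' @param ref_method,test_method `"LG"` / `"LC"` BEM weighting.
#' @param n_sources number of dipoles; positions are quasi-uniform in the
#'   brain with at least `min_depth` mm below the pial surface.
#' @param orientation dipole orientation mode (see [build_source_space()]).
#' @param source_seed,sensor_seed seeds for sources and sensor layouts.
#' @param n_electrodes,n_magnetometers,helmet_radius sensor configuration.
#' @param min_depth minimum dipole depth (mm).
#' @param use_isa isolate the skull in all solves (default `TRUE`).
#' @param test_brain_scale brain-conductivity factor for the test model
#'   (supports brain-conductivity compensation; default 1).
#' @param verbose print progress.
#' @return a `sweep_result` tibble: one row per (K_ref, K_test) with summary
#'   columns and per-source `re`/`cc` list columns.
#' @export
conductivity_sweep <- function(geometry = sphere_geometry(),
                               modality = c("EEG", "MEG"),
                               K_ref = seq(20, 80, by = 10),
                               K_test = seq(20, 170, by = 10),
                               test_kind = c("3S", "4C"), ref_kind = "4C",
                               ref_method = "LG", test_method = ref_method,
                               n_sources = 200,
                               orientation = "random",
                               source_seed = 1L, sensor_seed = 1L,
                               n_electrodes = 256, n_magnetometers = 102,
                               helmet_radius = 120, min_depth = 1.5,
                               use_isa = TRUE, test_brain_scale = 1,
                               verbose = FALSE) {
  modality <- match.arg(modality)
  test_kind <- match.arg(test_kind)
  say <- function(...) if (verbose) message(sprintf(...))

  ref_model0 <- build_study_model(ref_kind, K_ref[1], geometry, "ref")
  same_spec <- identical(test_kind, ref_kind) &&
    identical(test_method, ref_method) && test_brain_scale == 1 &&
    identical(geometry$test_levels, geometry$ref_levels)
  test_model0 <- if (same_spec) ref_model0
    else build_study_model(test_kind, K_test[1], geometry, "test",
                           brain_scale = test_brain_scale)

  rmax <- source_radius_limit(list(ref_model0, test_model0), min_depth)
  sources <- build_source_space(n_sources, radius_range = c(0, rmax),
                                orientation_mode = orientation,
                                seed = source_seed, min_depth = min_depth,
                                pial_radius = rmax + min_depth,
                                center = geometry$center)
  arrays <- build_sensor_arrays(ref_model0, n_electrodes = n_electrodes,
                                n_magnetometers = n_magnetometers,
                                helmet_radius = helmet_radius,
                                seed = sensor_seed)

  say("assembling reference system (%s, %d vertices)", ref_method,
      sum(vapply(ref_model0$surfaces, function(s) nrow(s$mesh$vertices), 0L)))
  ref_sys <- assemble_system(ref_model0, method = ref_method,
                             use_isa = use_isa)
  test_sys <- if (same_spec) ref_sys else {
    say("assembling test system (%s)", test_method)
    assemble_system(test_model0, method = test_method, use_isa = use_isa)
  }

  compute_lf <- function(sys, model) {
    if (modality == "EEG") {
      el <- snap_electrodes(arrays$electrodes, model)
      eeg_leadfield(model, sys, sources, el)
    } else {
      meg_leadfield(model, sys, sources, arrays$magnetometers)
    }
  }

  if (same_spec) {
    # identical reference and test specification: one leadfield per unique K
    all_K <- unique(c(K_ref, K_test))
    lf_by_K <- lapply(all_K, function(K) {
      say("leadfield, K = %g", K)
      compute_lf(ref_sys, build_study_model(ref_kind, K, geometry, "ref"))
    })
    ref_lfs <- lf_by_K[match(K_ref, all_K)]
    test_lfs <- lf_by_K[match(K_test, all_K)]
  } else {
    ref_lfs <- lapply(K_ref, function(K) {
      say("reference leadfield, K_ref = %g", K)
      compute_lf(ref_sys, build_study_model(ref_kind, K, geometry, "ref"))
    })
    test_lfs <- lapply(K_test, function(K) {
      say("test leadfield, K_test = %g", K)
      compute_lf(test_sys, build_study_model(test_kind, K, geometry, "test",
                                             brain_scale = test_brain_scale))
    })
  }

  rows <- list()
  for (i in seq_along(K_ref)) for (j in seq_along(K_test)) {
    ms <- compare_leadfields(ref_lfs[[i]], test_lfs[[j]])
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(K_ref = K_ref[i], K_test = K_test[j]),
      ms$summary,
      tibble::tibble(re = list(ms$re), cc = list(ms$cc)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "modality") <- modality
  attr(out, "test_kind") <- test_kind
  attr(out, "ref_kind") <- ref_kind
  class(out) <- c("sweep_result", class(out))
  out
}

# re-snap an electrode array onto (a possibly different mesh of) the same
# scalp surface, keeping the physical electrode directions fixed
snap_electrodes <- function(electrodes, model) {
  scalp <- model$surfaces[[length(model$surfaces)]]$mesh
  ctr <- colMeans(scalp$vertices)
  pos_mm <- electrodes$positions * 1000
  dirs <- sweep(pos_mm, 2, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- nrow(pos_mm)
  W <- matrix(0, n, nrow(scalp$vertices))
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    hit <- ray_mesh_hit(scalp, ctr, dirs[i, ])
    if (is.null(hit)) stop("electrode ray missed the scalp surface")
    W[i, scalp$faces[hit$face, ]] <- hit$bary
    pos[i, ] <- hit$point / 1000
  }
  electrode_array(pos, W, electrodes$names)
}

sweep_rows_from_lfs <- function(K_ref, K_test, ref_lfs, test_lfs, modality,
                                ref_kind, test_kind) {
  rows <- list()
  for (i in seq_along(K_ref)) for (j in seq_along(K_test)) {
    ms <- compare_leadfields(ref_lfs[[i]], test_lfs[[j]])
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(K_ref = K_ref[i], K_test = K_test[j]),
      ms$summary,
      tibble::tibble(re = list(ms$re), cc = list(ms$cc)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "modality") <- modality
  attr(out, "test_kind") <- test_kind
  attr(out, "ref_kind") <- ref_kind
  class(out) <- c("sweep_result", class(out))
  out
}

#' Skull-conductivity compensation study
#'
#' The full conductivity analysis on fixed geometry: reference
#' four-compartment leadfields over the plausible skull resistivity range,
#' compared against (a) four-compartment test models on the same grid (for
#' the optimal ratio K_opt) and (b) three-shell models over an extended grid
#' (for the equivalent ratio K_equi that compensates the omission of CSF).
#' The reference system is assembled once and every reference leadfield is
#' shared between the two sweeps.
#'
#' @param geometry a [sphere_geometry()]; reference and 4-C test models use
#'   `ref_levels`, the 3-S models the matching subset.
#' @param K_ref reference grid (default 20 to 80 by 10).
#' @param K_test_4c,K_test_3s test grids (defaults 20:80 and 20:170 by 10).
#' @param method BEM weighting for all models (default `"LG"`).
#' @param n_sources,orientation,source_seed,sensor_seed,n_electrodes,helmet_radius
#'   source/sensor configuration as in [conductivity_sweep()].
#' @param use_isa isolated source approach (default `TRUE`).
#' @param verbose print progress.
#' @return list with sweeps `sw4`, `sw3`, selections `opt4`, `opt3`
#'   (`K_opt = opt4$K_best`, `K_equi = opt3$K_best`), per-K_ref
#'   `factors`, and `uncompensated` / `compensated` per-source expected
#'   errors of the 3-S model.
#' @export
compensation_study <- function(geometry = sphere_geometry(),
                               K_ref = seq(20, 80, by = 10),
                               K_test_4c = K_ref,
                               K_test_3s = seq(20, 170, by = 10),
                               method = "LG", n_sources = 200,
                               orientation = "random",
                               source_seed = 1L, sensor_seed = 1L,
                               n_electrodes = 256, helmet_radius = 120,
                               use_isa = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ref0 <- build_study_model("4C", K_ref[1], geometry, "ref")
  g3 <- geometry
  g3$test_levels <- geometry$ref_levels
  test0 <- build_study_model("3S", K_test_3s[1], g3, "test")
  rmax <- source_radius_limit(list(ref0), 1.5)
  sources <- build_source_space(n_sources, c(0, rmax), orientation,
                                seed = source_seed, pial_radius = rmax + 1.5,
                                center = geometry$center)
  arrays <- build_sensor_arrays(ref0, n_electrodes = n_electrodes,
                                n_magnetometers = 12,
                                helmet_radius = helmet_radius,
                                seed = sensor_seed)
  lf_of <- function(sys, kind, K, geom) {
    model <- build_study_model(kind, K, geom, if (kind == "4C") "ref" else "test")
    el <- snap_electrodes(arrays$electrodes, model)
    eeg_leadfield(model, sys, sources, el)
  }
  say("assembling reference %s system", method)
  ref_sys <- assemble_system(ref0, method = method, use_isa = use_isa)
  all_K4 <- unique(c(K_ref, K_test_4c))
  lf4 <- lapply(all_K4, function(K) {
    say("4-C leadfield, K = %g", K)
    lf_of(ref_sys, "4C", K, geometry)
  })
  rm(ref_sys); gc(FALSE)
  say("assembling 3-S %s system", method)
  test_sys <- assemble_system(test0, method = method, use_isa = use_isa)
  lf3 <- lapply(K_test_3s, function(K) {
    say("3-S leadfield, K = %g", K)
    lf_of(test_sys, "3S", K, g3)
  })
  rm(test_sys); gc(FALSE)
  ref_lfs <- lf4[match(K_ref, all_K4)]
  sw4 <- sweep_rows_from_lfs(K_ref, K_test_4c, ref_lfs,
                             lf4[match(K_test_4c, all_K4)], "EEG", "4C", "4C")
  sw3 <- sweep_rows_from_lfs(K_ref, K_test_3s, ref_lfs, lf3, "EEG", "4C", "3S")
  opt4 <- select_optimal_k(sw4)
  opt3 <- select_optimal_k(sw3)
  list(sw4 = sw4, sw3 = sw3, opt4 = opt4, opt3 = opt3,
       K_opt = opt4$K_best, K_equi = opt3$K_best,
       factors = compensation_factors(sw3),
       uncompensated = expected_error_per_source(sw3, "matched"),
       compensated = expected_error_per_source(sw3, opt3$K_best))
}

#' Expected metrics over the reference-conductivity range
#'
#' For each `K_test`, the expectation of the summary metrics over the K_ref
#' grid (unweighted mean, mirroring a flat prior on the plausible skull
#' conductivity range).
#'
#' @param sweep a `sweep_result`.
#' @return tibble with `K_test`, `expected_re`, `expected_cc`.
#' @export
sweep_expected <- function(sweep) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(sweep), .data$K_test),
                   expected_re = mean(.data$median_re),
                   expected_cc = mean(.data$median_cc), .groups = "drop")
}

#' Select the optimal skull resistivity ratio from a sweep
#'
#' Minimum-expected-RE rule with CC tie-break: the expectation of the median
#' RE over the K_ref grid is minimised; all `K_test` values within `window`
#' RE of that minimum are candidates, and the candidate with the best
#' expected CC wins.
#'
#' @param sweep a `sweep_result` covering the K_ref range of interest.
#' @param window candidate window in RE units (default 0.01, i.e. one
#'   percentage point).
#' @return list with `K_best`, `expected_re`, `expected_cc`, and the
#'   per-K_test `table`.
#' @export
select_optimal_k <- function(sweep, window = 0.01) {
  if (nrow(tibble::as_tibble(sweep)) == 0) stop("empty sweep")
  tab <- sweep_expected(sweep)
  cand <- tab[tab$expected_re <= min(tab$expected_re) + window, ]
  best <- cand[which.max(cand$expected_cc), ]
  list(K_best = best$K_test, expected_re = best$expected_re,
       expected_cc = best$expected_cc, table = tab)
}

#' Per-source expected error at a fixed test conductivity
#'
#' Mean of the per-source RE and CC over all reference models (the K_ref
#' grid) at one `K_test`, summarised like [compare_leadfields()].
#'
#' @param sweep a `sweep_result`.
#' @param K_test fixed test ratio present in the sweep, or `"matched"` to
#'   take the uncompensated diagonal `K_test = K_ref`.
#' @return a `metric_summary`.
#' @export
expected_error_per_source <- function(sweep, K_test = "matched") {
  tb <- tibble::as_tibble(sweep)
  rows <- if (identical(K_test, "matched")) tb[tb$K_test == tb$K_ref, ]
          else tb[tb$K_test == K_test, ]
  if (nrow(rows) == 0) stop("no sweep rows for the requested K_test")
  re <- rowMeans(do.call(cbind, rows$re))
  cc <- rowMeans(do.call(cbind, rows$cc))
  structure(list(re = re, cc = cc,
                 summary = tibble::as_tibble(c(percentile_summary(re, "re"),
                                               percentile_summary(cc, "cc")))),
            class = "metric_summary")
}

#' Expected-error study across meshing and weighting choices
#'
#' Runs a conductivity sweep with a single fixed `K_test` for each requested
#' test configuration (mesh levels and BEM method) and reports the expected
#' (mean over K_ref) per-source errors, combining numerical error with
#' conductivity uncertainty and, for three-shell models, the omission of CSF.
#'
#' @param geometry a [sphere_geometry()]; `test_levels` is overridden per
#'   configuration.
#' @param modality `"EEG"` or `"MEG"`.
#' @param K_test_fixed fixed test-model ratio (e.g. from
#'   [select_optimal_k()]).
#' @param test_kind `"4C"` or `"3S"`.
#' @param configs list of `list(levels =, method =)` test configurations.
#' @param K_ref reference grid.
#' @param ... passed to [conductivity_sweep()].
#' @return tibble with one row per configuration and the expected-error
#'   summary columns.
#' @export
expected_error_study <- function(geometry, modality, K_test_fixed,
                                 test_kind = "3S",
                                 configs = list(list(levels = NULL,
                                                     method = "LC")),
                                 K_ref = seq(20, 80, by = 10), ...) {
  rows <- lapply(configs, function(cfg) {
    g <- geometry
    if (!is.null(cfg$levels)) g$test_levels <- cfg$levels
    sw <- conductivity_sweep(g, modality = modality, K_ref = K_ref,
                             K_test = K_test_fixed, test_kind = test_kind,
                             test_method = cfg$method, ...)
    ms <- expected_error_per_source(sw, K_test_fixed)
    dplyr::bind_cols(tibble::tibble(method = cfg$method,
                                    levels = paste(if (is.null(cfg$levels))
                                      g$test_levels else cfg$levels,
                                      collapse = "/"),
                                    K_test = K_test_fixed),
                     ms$summary,
                     tibble::tibble(mean_re = mean(ms$re),
                                    mean_cc = mean(ms$cc)))
  })
  dplyr::bind_rows(rows)
}

#' Best test ratio and compensation factor per reference ratio
#'
#' For each `K_ref`, the `K_test` minimising the median RE, the corresponding
#' compensation factor `K_test / K_ref`, and the CC-optimal factor.
#'
#' @param sweep a `sweep_result`.
#' @return tibble with `K_ref`, `K_best_re`, `factor_re`, `best_re`,
#'   `K_best_cc`, `factor_cc`.
#' @export
compensation_factors <- function(sweep) {
  tb <- tibble::as_tibble(sweep)
  dplyr::summarise(dplyr::group_by(tb, .data$K_ref),
                   K_best_re = .data$K_test[which.min(.data$median_re)],
                   factor_re = .data$K_best_re / .data$K_ref[1],
                   best_re = min(.data$median_re),
                   K_best_cc = .data$K_test[which.max(.data$median_cc)],
                   factor_cc = .data$K_best_cc / .data$K_ref[1],
                   .groups = "drop")
}

#' Mean RE over sources and reference ratios
#'
#' Grand mean of the per-source relative errors over all K_ref, either for a
#' fixed `K_test` (compensated model) or along the diagonal `K_test = K_ref`
#' (uncompensated model).
#'
#' @param sweep a `sweep_result`.
#' @param K_test numeric value, or `"matched"` for the diagonal.
#' @return scalar mean RE.
#' @export
sweep_mean_re <- function(sweep, K_test = "matched") {
  ms <- expected_error_per_source(sweep, K_test)
  mean(ms$re)
}
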