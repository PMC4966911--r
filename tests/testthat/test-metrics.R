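test_that("RE and CC metrics behave per definition", {
  d <- c(1, -2, 3, 0.5)
  expect_equal(relative_error(d, d), 0)
  expect_equal(relative_error(d, 0 * d), 1)
  expect_equal(relative_error(d, 2 * d), 1)
  expect_warning(re0 <- relative_error(c(0, 0), c(1, 1)), "zero norm")
  expect_true(is.na(re0))
  expect_equal(correlation_coefficient(d, 3.7 * d), 1)
  expect_equal(correlation_coefficient(d, -d), -1)
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)   # centred orthogonal
  expect_equal(correlation_coefficient(a, b), 0)
  expect_warning(cc0 <- correlation_coefficient(rep(2, 4), d), "constant")
  expect_true(is.na(cc0))
  # invariance to common positive rescaling of both leadfields
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(relative_error(5 * x, 5 * y), relative_error(x, y))
  expect_equal(correlation_coefficient(2 * x, 9 * y),
               correlation_coefficient(x, y))
})

test_that("compare_leadfields equals brute-force per-column computation", {
  set.seed(7)
  A <- matrix(rnorm(20), 5, 4)
  B <- A + matrix(rnorm(20, sd = 0.3), 5, 4)
  ms <- compare_leadfields(A, B)
  re_bf <- sapply(1:4, function(j)
    sqrt(sum((A[, j] - B[, j])^2)) / sqrt(sum(A[, j]^2)))
  cc_bf <- sapply(1:4, function(j) {
    a <- A[, j] - mean(A[, j]); b <- B[, j] - mean(B[, j])
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_equal(ms$re, re_bf)
  expect_equal(ms$cc, cc_bf)
  expect_equal(ms$summary$median_re, median(re_bf))
  expect_equal(ms$summary$p16_re, unname(quantile(re_bf, 0.16)))
  expect_equal(ms$summary$p84_cc, unname(quantile(cc_bf, 0.84)))
  ms2 <- compare_leadfields(A, A)
  expect_equal(ms2$summary$median_re, 0)
  expect_equal(ms2$summary$median_cc, 1)
  ms3 <- compare_leadfields(A, 0.5 * A)
  expect_equal(ms3$summary$median_re, 0.5)
  expect_equal(ms3$summary$median_cc, 1)
  expect_error(compare_leadfields(A, B[, 1:3]), "mismatch")
  tb <- tibble::as_tibble(ms)
  expect_named(tb, c("source", "re", "cc"))
})

# hand-built sweep_result rows for the selection rules
fake_sweep <- function(K_test, expected_re, expected_cc, K_ref = c(20, 50, 80)) {
  rows <- list()
  for (i in seq_along(K_ref)) for (j in seq_along(K_test)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      K_ref = K_ref[i], K_test = K_test[j],
      median_re = expected_re[j], p16_re = expected_re[j], p84_re = expected_re[j],
      median_cc = expected_cc[j], p16_cc = expected_cc[j], p84_cc = expected_cc[j],
      re = list(rep(expected_re[j], 4)), cc = list(rep(expected_cc[j], 4)))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

test_that("optimal-K selection follows the min-RE rule with CC tie-break", {
  # one strictly dominating K_test
  sw <- fake_sweep(c(40, 50, 60), c(0.30, 0.10, 0.25), c(0.99, 0.995, 0.99))
  expect_equal(select_optimal_k(sw)$K_best, 50)
  # constructed tie within 1 percentage point: CC decides
  sw2 <- fake_sweep(c(90, 100), c(0.200, 0.205), c(0.990, 0.994))
  expect_equal(select_optimal_k(sw2)$K_best, 100)
  # outside the window the better-RE candidate wins despite worse CC
  sw3 <- fake_sweep(c(90, 100), c(0.200, 0.215), c(0.990, 0.994))
  expect_equal(select_optimal_k(sw3)$K_best, 90)
  # invariance to K_test grid order
  sw4 <- fake_sweep(c(100, 90), c(0.205, 0.200), c(0.994, 0.990))
  expect_equal(select_optimal_k(sw4)$K_best, 100)
  expect_error(select_optimal_k(fake_sweep(numeric(0), numeric(0),
                                           numeric(0))), "empty")
})

test_that("expected-error aggregation takes means over the K_ref grid", {
  sw <- fake_sweep(c(50, 100), c(0.4, 0.2), c(0.98, 0.99))
  ms <- expected_error_per_source(sw, 100)
  expect_equal(unique(ms$re), 0.2)
  tab <- sweep_expected(sw)
  expect_equal(tab$expected_re, c(0.4, 0.2))
  # mean >= min over K_ref for every source, by construction of the mean
  expect_true(all(ms$re >= apply(do.call(cbind,
    dplyr::filter(tibble::as_tibble(sw), K_test == 100)$re), 1, min) - 1e-15))
  expect_error(expected_error_per_source(sw, 77), "no sweep rows")
})

test_that("a tiny real sweep has an exactly zero diagonal", {
  g <- sphere_geometry(ref_levels = c(pial = 1, inner_skull = 1,
                                      outer_skull = 1, scalp = 1))
  sw <- conductivity_sweep(g, modality = "EEG", K_ref = c(30, 60),
                           K_test = c(30, 60), test_kind = "4C",
                           ref_method = "LC", n_sources = 6,
                           n_electrodes = 32, n_magnetometers = 17)
  tb <- tibble::as_tibble(sw)
  diag_rows <- tb[tb$K_ref == tb$K_test, ]
  expect_equal(diag_rows$median_re, c(0, 0))
  expect_equal(diag_rows$median_cc, c(1, 1))
  off <- tb[tb$K_ref != tb$K_test, ]
  expect_true(all(off$median_re > 0))
  # EEG RE grows with conductivity mismatch
  expect_true(all(off$median_re > max(diag_rows$median_re)))
})

test_that("compensation factors pick the per-K_ref RE minimiser", {
  sw <- fake_sweep(c(40, 50, 60), c(0.3, 0.1, 0.25), c(0.99, 0.995, 0.999))
  cf <- compensation_factors(sw)
  expect_equal(cf$K_best_re, rep(50, 3))
  expect_equal(cf$factor_re, 50 / c(20, 50, 80))
  expect_equal(cf$K_best_cc, rep(60, 3))
})
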