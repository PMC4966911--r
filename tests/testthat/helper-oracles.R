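# Brute-force quadrature oracles used to validate the analytic BEM kernels.

# axis-aligned cube mesh with outward-oriented faces
cube_mesh <- function(side = 2, center = c(0, 0, 0)) {
  s <- side / 2
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = -s
    c(5, 6, 7), c(6, 8, 7),      # z = +s
    c(1, 2, 5), c(2, 6, 5),      # y = -s
    c(3, 7, 4), c(4, 7, 8),      # y = +s
    c(1, 5, 3), c(3, 5, 7),      # x = -s
    c(2, 4, 6), c(4, 8, 6))      # x = +s
  tri_mesh(v, f, name = "cube", orient = TRUE)
}

# dense fixed-subdivision quadrature of int_T lambda_i (r'-p).n dS / |r'-p|^3
dl_weights_quadrature <- function(v1, v2, v3, p, depth = 4) {
  qb <- rbind(c(1, 1, 1) / 3,
              c(0.059715871789770, 0.470142064105115, 0.470142064105115),
              c(0.470142064105115, 0.059715871789770, 0.470142064105115),
              c(0.470142064105115, 0.470142064105115, 0.059715871789770),
              c(0.797426985353087, 0.101286507323456, 0.101286507323456),
              c(0.101286507323456, 0.797426985353087, 0.101286507323456),
              c(0.101286507323456, 0.101286507323456, 0.797426985353087))
  qw <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  n <- c((v2 - v1)[2] * (v3 - v1)[3] - (v2 - v1)[3] * (v3 - v1)[2],
         (v2 - v1)[3] * (v3 - v1)[1] - (v2 - v1)[1] * (v3 - v1)[3],
         (v2 - v1)[1] * (v3 - v1)[2] - (v2 - v1)[2] * (v3 - v1)[1])
  area2 <- sqrt(sum(n^2))
  n <- n / area2
  # recursive barycentric subdivision
  tris <- list(diag(3))
  for (d in seq_len(depth)) {
    tris <- unlist(lapply(tris, function(tr) {
      m12 <- (tr[1, ] + tr[2, ]) / 2; m23 <- (tr[2, ] + tr[3, ]) / 2
      m31 <- (tr[3, ] + tr[1, ]) / 2
      list(rbind(tr[1, ], m12, m31), rbind(m12, tr[2, ], m23),
           rbind(m31, m23, tr[3, ]), rbind(m12, m23, m31))
    }), recursive = FALSE)
  }
  w <- c(0, 0, 0)
  V <- rbind(v1, v2, v3)
  for (tr in tris) {
    for (q in 1:7) {
      lam <- qb[q, ] %*% tr          # barycentric wrt the full triangle
      pos <- as.vector(lam %*% V)
      d <- pos - p
      kern <- sum(d * n) / sum(d^2)^1.5
      w <- w + qw[q] * (area2 / 2 / 4^depth) * as.vector(lam) * kern
    }
  }
  w
}
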