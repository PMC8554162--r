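# Independent brute-force oracles for the constrained fits: full SVD of the
# centered coordinates, kept separate from the implementation under test.

oracle_sign <- function(v, tol = 1e-12) {
  for (x in v) if (abs(x) > tol) return(if (x < 0) -v else v)
  v
}

oracle_plane_normal <- function(p) {
  s <- svd(sweep(p, 2, colMeans(p)))
  oracle_sign(s$v[, 3])
}

oracle_line_dir <- function(p) {
  s <- svd(sweep(p, 2, colMeans(p)))
  oracle_sign(s$v[, 1])
}

oracle_line2d_e <- function(p) {
  # TLS on (x, -y): coefficient vector (a, b) = right singular vector of the
  # smallest singular value; direction e = (b, a)
  q <- cbind(p[, 1] - mean(p[, 1]), -(p[, 2] - mean(p[, 2])))
  ab <- svd(q)$v[, 2]
  oracle_sign(c(ab[2], ab[1]))
}
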