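# Shared numerical helpers.

# Moore-Penrose pseudoinverse via SVD. Singular values below `tol` times the
# largest are truncated; the same rank tolerance is used everywhere the
# inverse solution needs a pseudoinverse so that estimates and their
# standardization stay consistent.
pinvTol <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (!length(A)) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Draw `n` sub-seeds from a master seed without disturbing caller RNG state.
spawnSeeds <- function(seed, n) {
  withSeed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}
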