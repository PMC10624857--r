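# Shared fixtures and small generators for property-style tests.

# random symmetric positive definite matrix via A'A + eps*I
random_spd <- function(m, jitter = 0.5) {
  A <- matrix(rnorm(m * m), m)
  crossprod(A) + jitter * diag(m)
}

# random (P, G, a) with P = G + E so that P - G is positive definite,
# mirroring how phenotypic covariance decomposes in a trial
random_pga <- function(m) {
  G <- random_spd(m)
  E <- random_spd(m)
  list(P = G + E, G = G, a = rnorm(m))
}

# 4-trait ground truth used by the simulation-recovery tests: unequal
# variances, mixed-sign genetic correlations, moderate heritabilities
recovery_truth <- function() {
  sds <- c(4, 1.5, 6, 0.8)
  Rg <- matrix(c(1, 0.5, -0.3, 0.2,
                 0.5, 1, 0.1, -0.4,
                 -0.3, 0.1, 1, 0.3,
                 0.2, -0.4, 0.3, 1), 4)
  G <- diag(sds) %*% Rg %*% diag(sds)
  E <- diag(c(5, 2, 8, 1)^2) * 0.8
  dimnames(G) <- dimnames(E) <- list(paste0("t", 1:4), paste0("t", 1:4))
  list(G = G, E = E, mu = c(100, 20, 50, 5))
}

expect_vector_equal <- function(actual, expected, tol = 1e-8) {
  expect_equal(unname(as.numeric(actual)), unname(as.numeric(expected)),
               tolerance = tol)
}
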