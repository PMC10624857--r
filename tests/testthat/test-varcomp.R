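test_that("expected mean squares recover variance components on a hand-worked trial", {
  # 2 genotypes x 2 reps, replicate means 12 and 14; hand sums of squares:
  # SS_g = 16, SS_rep = 4, SS_tot = 20, SS_e = 0 => MS_g = 16, MS_e = 0
  tr <- rcbd_trial(genotype = c("A", "B", "A", "B"),
                   replicate = c("r1", "r1", "r2", "r2"),
                   values = matrix(c(10, 14, 12, 16), ncol = 1,
                                   dimnames = list(NULL, "y")))
  for (basis in c("plot", "mean")) {
    vc <- estimate_components(tr, basis = basis)
    expect_equal(unname(vc$anova$MS_genotype), 16)
    expect_equal(unname(vc$anova$MS_error), 0)
    expect_equal(unname(vc$sigma2_g), 8)
    expect_equal(unname(vc$sigma2_e), 0)
    expect_equal(unname(vc$h2_broad), 1)
  }
})

test_that("univariate mean squares agree with an aov() oracle on random trials", {
  set.seed(42)
  truth <- recovery_truth()
  sim <- simulate_rcbd_trial(simulation_spec(truth$G, truth$E, truth$mu,
                                             n_genotypes = 12, n_reps = 3,
                                             rep_effect_sd = 2, seed = 7))
  tr <- sim$trial
  vc <- estimate_components(tr)
  for (j in seq_along(tr$trait_names)) {
    df <- data.frame(y = tr$values[, j], g = tr$genotype, r = tr$replicate)
    ms <- summary(aov(y ~ g + r, data = df))[[1]][, "Mean Sq"]
    expect_equal(unname(vc$anova$MS_genotype[j]), ms[1], tolerance = 1e-10)
    expect_equal(unname(vc$anova$MS_error[j]), ms[3], tolerance = 1e-10)
    expect_equal(unname(vc$sigma2_g[j]), (ms[1] - ms[3]) / 3, tolerance = 1e-10)
  }
})

test_that("constant trial yields zero components and flagged heritability", {
  tr <- rcbd_trial(rep(c("A", "B", "C"), 2), rep(1:2, each = 3),
                   matrix(5, nrow = 6, ncol = 2))
  expect_warning(vc <- estimate_components(tr), "heritability undefined")
  expect_vector_equal(vc$sigma2_g, c(0, 0))
  expect_vector_equal(vc$sigma2_e, c(0, 0))
  expect_true(all(is.na(vc$h2_broad)))
})

test_that("sum-of-squares identity and symmetry hold on simulated trials", {
  set.seed(11)
  truth <- recovery_truth()
  for (seed in 1:3) {
    sim <- simulate_rcbd_trial(simulation_spec(truth$G, truth$E, truth$mu,
                                               n_genotypes = 15, n_reps = 4,
                                               rep_effect_sd = 1, seed = seed))
    vc <- estimate_components(sim$trial)
    with(vc$anova, expect_equal(SS_total, SS_genotype + SS_replicate + SS_error,
                                tolerance = 1e-8))
    expect_identical(vc$G, t(vc$G))
    expect_identical(vc$P, t(vc$P))
    expect_vector_equal(diag(vc$G), vc$sigma2_g)
    expect_vector_equal(diag(vc$P), vc$sigma2_p)
    # setting j = k in the cross-product path reproduces the variance path
    expect_equal(diag(vc$E), vc$sigma2_e, tolerance = 1e-12)
  }
})

test_that("noiseless trial gives cov_g = covariance of genotype means, sigma2_e = 0", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)      # genotype values, replicated exactly
  tr <- rcbd_trial(rep(1:10, each = 2), rep(1:2, times = 10),
                   X[rep(1:10, each = 2), ])
  vc <- estimate_components(tr)
  expect_vector_equal(vc$sigma2_e, c(0, 0), tol = 1e-12)
  expect_equal(unname(vc$G), unname(cov(X)), tolerance = 1e-10)
})

test_that("mean-basis phenotypic variance never exceeds plot-basis", {
  set.seed(5)
  truth <- recovery_truth()
  sim <- simulate_rcbd_trial(simulation_spec(truth$G, truth$E, truth$mu,
                                             n_genotypes = 30, n_reps = 3,
                                             seed = 9))
  vp <- estimate_components(sim$trial, basis = "plot")
  vm <- estimate_components(sim$trial, basis = "mean")
  expect_true(all(vm$sigma2_p <= vp$sigma2_p + 1e-12))
  expect_identical(vp$G, vm$G)  # basis only affects P
})

test_that("unbalanced designs and undersized trials are rejected with diagnostics", {
  expect_error(rcbd_trial(c("A", "B", "A"), c(1, 1, 2),
                          matrix(1:3, ncol = 1)),
               "unbalanced.*genotype B.*replicate 2")
  expect_error(rcbd_trial(c("A", "B"), c(1, 1), matrix(1:2, ncol = 1)),
               "at least 2 replicates")
  expect_error(rcbd_trial(c("A", "A"), c(1, 2), matrix(1:2, ncol = 1)),
               "at least 2 genotypes")
  expect_error(rcbd_trial(c("A", "B", "A", "B"), c(1, 1, 2, 2),
                          matrix(c(1, NA, 3, 4), ncol = 1)),
               "missing")
})

test_that("negative genotypic components are reported raw with warning, clamped on request", {
  # genotype differences tiny relative to noise => MS_g < MS_e possible
  set.seed(123)
  G <- matrix(1e-6, 1, 1); E <- matrix(4, 1, 1)
  found <- FALSE
  for (seed in 1:20) {
    sim <- simulate_rcbd_trial(simulation_spec(G, E, 0, n_genotypes = 5,
                                               n_reps = 2, seed = seed))
    vc <- suppressWarnings(estimate_components(sim$trial))
    if (vc$sigma2_g < 0) {
      found <- TRUE
      expect_warning(estimate_components(sim$trial), "negative genotypic variance")
      vcc <- suppressWarnings(estimate_components(sim$trial, clamp = TRUE))
      expect_equal(unname(vcc$sigma2_g), 0)
      break
    }
  }
  expect_true(found)
})

test_that("correlation matrices standardize covariances and flag zero-variance traits", {
  # hand case: r_g(1,2) = 0.5/sqrt(2) on the worked 2-trait matrices
  vc <- list(G = matrix(c(2, 0.5, 0.5, 1), 2), P = matrix(c(4, 1, 1, 2), 2))
  cp <- correlation_matrices(vc)
  expect_equal(cp$r_g[1, 2], 0.5 / sqrt(2), tolerance = 1e-10)
  expect_equal(cp$r_p[1, 2], 1 / sqrt(8), tolerance = 1e-10)
  expect_vector_equal(diag(cp$r_g), c(1, 1))

  # diagonal G -> identity correlations
  cp2 <- correlation_matrices(list(G = diag(c(2, 3)), P = diag(c(4, 5))))
  expect_equal(unname(cp2$r_g), diag(2))

  # zero-variance trait flagged NA, not zeroed
  vc3 <- list(G = matrix(c(0, 0, 0, 1), 2), P = diag(2))
  cp3 <- correlation_matrices(vc3)
  expect_true(all(is.na(cp3$r_g[1, ])))
  expect_equal(cp3$r_g[2, 2], 1)
})

test_that("genetic correlations from a simulated trial recover the generator's", {
  truth <- recovery_truth()
  r_true <- cov2cor(truth$G)[1, 2]
  ests <- vapply(1:12, function(seed) {
    sim <- simulate_rcbd_trial(simulation_spec(truth$G, truth$E, truth$mu,
                                               n_genotypes = 150, n_reps = 3,
                                               seed = 100 + seed))
    correlation_matrices(estimate_components(sim$trial))$r_g[1, 2]
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - r_true), 3 * se + 0.02)
})

test_that("genotype means average replicates and preserve order of appearance", {
  tr <- rcbd_trial(c("B", "A", "B", "A"), c(1, 1, 2, 2),
                   matrix(c(10, 20, 12, 24), ncol = 1,
                          dimnames = list(NULL, "y")))
  pm <- genotype_means(tr)
  expect_identical(pm$genotype_ids, c("B", "A"))
  expect_vector_equal(pm$X[, 1], c(11, 22))

  # simulation bookkeeping: means = mu + g_i + mean rep effect + mean error
  truth <- recovery_truth()
  sim <- simulate_rcbd_trial(simulation_spec(truth$G, truth$E, truth$mu,
                                             n_genotypes = 8, n_reps = 3,
                                             rep_effect_sd = 2, seed = 21))
  pm2 <- genotype_means(sim$trial)
  Y <- sim$trial$values
  g_exp <- sim$truth$genotype_effects[rep(1:8, each = 3), ]
  r_exp <- sim$truth$rep_effects[rep(1:3, times = 8), ]
  errors <- Y - matrix(truth$mu, 24, 4, byrow = TRUE) - g_exp - r_exp
  manual <- matrix(truth$mu, 8, 4, byrow = TRUE) +
    sim$truth$genotype_effects +
    matrix(colMeans(sim$truth$rep_effects), 8, 4, byrow = TRUE) +
    rowsum(errors, sim$trial$genotype, reorder = FALSE) / 3
  expect_equal(unname(pm2$X), unname(manual), tolerance = 1e-10)
})
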