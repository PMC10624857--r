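#' Specify a multi-trait RCBD trial simulation
#'
#' Defines the ground truth for a simulated balanced RCBD trial: a genetic
#' covariance matrix for the genotype effects, an environmental covariance
#' matrix for the plot errors, trait means, design size, an optional
#' per-trait replicate (block) effect SD, and a seed. Both covariance
#' matrices must be symmetric positive definite.
#'
#' @param G_true m x m genetic covariance matrix (SPD).
#' @param E_true m x m environmental/error covariance matrix (SPD).
#' @param mu m-vector of trait means (default 0).
#' @param n_genotypes number of genotypes (>= 2).
#' @param n_reps number of replicates (>= 2).
#' @param rep_effect_sd replicate-effect SD, scalar or per-trait vector;
#'   default 0 (pure genotype + plot error, the usual setting since the
#'   index criteria never involve block effects).
#' @param seed integer RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(G_true, E_true, mu = NULL,
                            n_genotypes, n_reps,
                            rep_effect_sd = 0, seed = 1L) {
  m <- ncol(G_true)
  check_spd(G_true, "G_true")
  check_spd(E_true, "E_true")
  if (ncol(E_true) != m) stop("G_true and E_true must have the same dimension")
  if (is.null(mu)) mu <- numeric(m)
  if (length(mu) != m) stop("mu must have one entry per trait")
  if (n_genotypes < 2) stop("need at least 2 genotypes")
  if (n_reps < 2) stop("need at least 2 replicates")
  rep_effect_sd <- rep(rep_effect_sd, length.out = m)
  if (any(rep_effect_sd < 0)) stop("rep_effect_sd must be nonnegative")
  if (is.null(colnames(G_true)))
    colnames(G_true) <- rownames(G_true) <- paste0("trait", seq_len(m))
  dimnames(E_true) <- dimnames(G_true)
  structure(list(G_true = G_true, E_true = E_true, mu = mu,
                 n_genotypes = as.integer(n_genotypes),
                 n_reps = as.integer(n_reps),
                 rep_effect_sd = rep_effect_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

check_spd <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("%s must be a square matrix", name))
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(sprintf("%s is not symmetric", name))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                 name, min(ev)))
  invisible(M)
}

#' Simulate a balanced multi-trait RCBD trial with known ground truth
#'
#' Draws, in a fixed documented order under the spec's seed: (1) genotype
#' effects \eqn{g_i \sim MVN(0, G_{true})}; (2) per-trait replicate effects
#' \eqn{r_j \sim N(0, sd^2)}; (3) plot errors
#' \eqn{e_{ij} \sim MVN(0, E_{true})} in genotype-major order. Plot values
#' are \eqn{y_{ij} = \mu + g_i + r_j + e_{ij}}. Reruns with the same spec
#' are bit-identical.
#'
#' On a per-plot basis the true phenotypic covariance is
#' \eqn{P_{true} = G_{true} + E_{true}}; on a genotype-mean basis
#' \eqn{G_{true} + E_{true}/r}.
#'
#' @param spec a [simulation_spec()].
#' @return list with `trial` (an [rcbd_trial()]) and `truth` (list:
#'   `G_true`, `E_true`, `P_true_plot`, `P_true_mean`, `mu`,
#'   `genotype_effects` (n x m), `rep_effects` (r x m),
#'   `h2_true_plot`, `h2_true_mean`).
#' @export
simulate_rcbd_trial <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_genotypes
  r <- spec$n_reps
  m <- ncol(spec$G_true)

  set.seed(spec$seed)
  g <- MASS::mvrnorm(n, mu = numeric(m), Sigma = spec$G_true)
  g <- matrix(g, nrow = n, ncol = m)
  rep_eff <- matrix(stats::rnorm(r * m, sd = rep(spec$rep_effect_sd, each = r)),
                    nrow = r, ncol = m)
  e <- MASS::mvrnorm(n * r, mu = numeric(m), Sigma = spec$E_true)
  e <- matrix(e, nrow = n * r, ncol = m)

  geno_id <- rep(paste0("G", seq_len(n)), each = r)
  rep_id <- rep(paste0("R", seq_len(r)), times = n)
  Y <- matrix(spec$mu, nrow = n * r, ncol = m, byrow = TRUE) +
    g[rep(seq_len(n), each = r), , drop = FALSE] +
    rep_eff[rep(seq_len(r), times = n), , drop = FALSE] +
    e
  colnames(Y) <- colnames(spec$G_true)

  trial <- rcbd_trial(geno_id, rep_id, Y, trait_names = colnames(spec$G_true))
  P_plot <- spec$G_true + spec$E_true
  P_mean <- spec$G_true + spec$E_true / r
  truth <- list(G_true = spec$G_true, E_true = spec$E_true,
                P_true_plot = P_plot, P_true_mean = P_mean,
                mu = spec$mu,
                genotype_effects = g, rep_effects = rep_eff,
                h2_true_plot = diag(spec$G_true) / diag(P_plot),
                h2_true_mean = diag(spec$G_true) / diag(P_mean))
  list(trial = trial, truth = truth)
}

#' Two-trait worked fixture with hand-checkable index algebra
#'
#' A small reference problem used throughout the tests and documentation:
#' \deqn{P = \begin{pmatrix}4 & 1\\ 1 & 2\end{pmatrix}, \quad
#'       G = \begin{pmatrix}2 & 0.5\\ 0.5 & 1\end{pmatrix}, \quad
#'       a = (1, 1),}
#' together with a 6-genotype trait panel X constructed so that its sample
#' covariance equals P exactly. All downstream quantities (optimum
#' b = (0.5, 0.5), R_HI = sqrt(0.5), Pesek-Baker b, per-trait gains, RE)
#' follow by short hand matrix algebra.
#'
#' @return list with `panel` (a [trait_panel()]), `P`, `G`, `a`.
#' @export
worked_fixture <- function() {
  P <- matrix(c(4, 1, 1, 2), 2, dimnames = list(c("t1", "t2"), c("t1", "t2")))
  G <- matrix(c(2, 0.5, 0.5, 1), 2, dimnames = dimnames(P))
  a <- c(t1 = 1, t2 = 1)

  # deterministic 6 x 2 base matrix; whiten its sample covariance, then
  # color with chol(P) so that cov(X) == P exactly
  Z <- matrix(c(1.2, -0.7, 0.4, -1.5, 0.9, -0.3,
                0.2, 1.1, -0.8, 0.5, -1.3, 0.3), ncol = 2)
  Zc <- sweep(Z, 2, colMeans(Z))
  W <- Zc %*% solve(chol(stats::cov(Zc)))
  X <- W %*% chol(P)
  X <- sweep(X, 2, c(20, 10), "+")   # shift means off zero so CV is defined
  colnames(X) <- colnames(P)
  panel <- trait_panel(X, genotype_ids = paste0("g", 1:6),
                       trait_names = colnames(P))
  list(panel = panel, P = P, G = G, a = a)
}
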