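#' Smith-Hazel optimum index coefficients
#'
#' Solves the optimum-index equations \eqn{P b = G a} for the coefficient
#' vector b, where P and G are the phenotypic and genotypic covariance
#' matrices and a the economic-weight vector. The linear system is solved
#' directly (no explicit inverse); an ill-conditioned P (condition number
#' above `max_condition`) is an error, usually a sign of redundant or
#' collinear traits.
#'
#' @param P phenotypic covariance matrix (m x m, symmetric positive
#'   definite).
#' @param G genotypic covariance matrix (m x m, symmetric).
#' @param a economic weights: numeric m-vector or `economic_weights`.
#' @param max_condition condition-number guard for P (default 1e12).
#' @return a `selection_index` model with `method = "optimum"`, coefficient
#'   vector `b`, and the weights used.
#' @examples
#' P <- matrix(c(4, 1, 1, 2), 2)
#' G <- matrix(c(2, 0.5, 0.5, 1), 2)
#' optimum_coefficients(P, G, c(1, 1))$b  # 0.5 0.5
#' @export
optimum_coefficients <- function(P, G, a, max_condition = 1e12) {
  a <- as_weight_vector(a)
  check_cov_matrix(P, "P", length(a))
  check_cov_matrix(G, "G", length(a))
  kap <- kappa(P, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition)
    stop(sprintf(
      "P is singular or ill-conditioned (condition number %.3g > %.3g); consider removing redundant traits",
      kap, max_condition))
  b <- drop(solve(P, G %*% a))
  names(b) <- colnames(P)
  new_selection_index("optimum", b, a)
}

#' Brim base index coefficients
#'
#' The base index uses the economic weights directly as index
#' coefficients, \eqn{b = a}; it needs no estimates of genetic parameters.
#'
#' @param a economic weights: numeric vector or `economic_weights`.
#' @return a `selection_index` model with `method = "base"` and `b = a`.
#' @export
base_coefficients <- function(a) {
  b <- as_weight_vector(a)
  if (any(!is.finite(b))) stop("economic weights must be finite")
  new_selection_index("base", b, b)
}

#' Pesek-Baker desired-gains index coefficients
#'
#' Solves \eqn{G b = d} for the coefficient vector b, where d is the
#' desired-gains vector (by default the genetic standard deviations,
#' see [desired_gains()]). A singular G is an error; set
#' `pseudo_inverse = TRUE` to fall back to a Moore-Penrose least-squares
#' solution explicitly.
#'
#' @param G genotypic covariance matrix (m x m, symmetric, invertible).
#' @param d desired gains: numeric m-vector or `desired_gains`.
#' @param pseudo_inverse use a pseudo-inverse if G is singular
#'   (default FALSE).
#' @param max_condition condition-number guard for G (default 1e12).
#' @return a `selection_index` model with `method = "pesek_baker"`.
#' @export
pesek_baker_coefficients <- function(G, d, pseudo_inverse = FALSE,
                                     max_condition = 1e12) {
  d <- as_weight_vector(d)
  check_cov_matrix(G, "G", length(d))
  kap <- kappa(G, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    if (!pseudo_inverse)
      stop(sprintf(
        "G is singular or ill-conditioned (condition number %.3g); set pseudo_inverse = TRUE to force a least-squares solution",
        kap))
    b <- drop(MASS::ginv(G) %*% d)
  } else {
    b <- drop(solve(G, d))
  }
  names(b) <- colnames(G)
  new_selection_index("pesek_baker", b, d)
}

as_weight_vector <- function(w) {
  if (inherits(w, "economic_weights")) return(w$a)
  if (inherits(w, "desired_gains")) return(w$d)
  as.numeric(w)
}

check_cov_matrix <- function(M, name, m = NULL, tol = 1e-6) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("%s must be a square matrix", name))
  if (!is.null(m) && ncol(M) != m)
    stop(sprintf("%s is %dx%d but the weight vector has length %d",
                 name, nrow(M), ncol(M), m))
  rel <- max(abs(M - t(M))) / max(1, max(abs(M)))
  if (rel > tol)
    stop(sprintf("%s is asymmetric beyond tolerance (relative deviation %.3g)",
                 name, rel))
  invisible(M)
}

new_selection_index <- function(method, b, weights_used) {
  if (any(!is.finite(b))) stop("index coefficients are not finite")
  structure(list(method = method, b = b, weights_used = weights_used),
            class = "selection_index")
}

#' @export
print.selection_index <- function(x, digits = 4, ...) {
  label <- c(optimum = "Smith-Hazel optimum",
             base = "Brim base",
             pesek_baker = "Pesek-Baker desired-gains")[x$method]
  cat(sprintf("%s selection index\n", label))
  cat("Coefficients b:\n")
  print(round(x$b, digits))
  invisible(x)
}

#' Score and rank genotypes on a selection index
#'
#' Computes the index value \eqn{I = X b} for every genotype and ranks them
#' with rank 1 for the highest score (larger index is always better; traits
#' to be decreased should carry negative weights). Ties keep their order of
#' appearance.
#'
#' @param panel a [trait_panel()].
#' @param model a `selection_index` from one of the coefficient
#'   constructors.
#' @return an `index_scores` object: `I` (named n-vector), `ranks`
#'   (permutation of 1..n, 1 = best), `mean_score`, `sd_score` (sample SD),
#'   `method`.
#' @export
score_genotypes <- function(panel, model) {
  stopifnot(inherits(panel, "trait_panel"), inherits(model, "selection_index"))
  b <- model$b
  if (ncol(panel$X) != length(b))
    stop(sprintf("panel has %d traits but index has %d coefficients",
                 ncol(panel$X), length(b)))
  if (!is.null(names(b)) && !is.null(panel$trait_names) &&
      any(names(b) != panel$trait_names))
    stop("trait names of panel and index coefficients disagree")
  I <- drop(panel$X %*% b)
  names(I) <- panel$genotype_ids
  ord <- order(-I, seq_along(I))   # stable: ties by order of appearance
  ranks <- integer(length(I))
  ranks[ord] <- seq_along(I)
  names(ranks) <- panel$genotype_ids
  structure(list(I = I, ranks = ranks,
                 mean_score = mean(I), sd_score = stats::sd(I),
                 method = model$method),
            class = "index_scores")
}

#' @export
print.index_scores <- function(x, digits = 4, ...) {
  cat(sprintf("Index scores (%s): %d genotypes, mean %.4g, sd %.4g\n",
              x$method, length(x$I), x$mean_score, x$sd_score))
  top <- names(sort(x$ranks))[seq_len(min(5, length(x$I)))]
  cat("Top genotypes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Select the top genotypes at a given intensity
#'
#' Truncation selection on index rank: keeps the top
#' \eqn{\lceil n \cdot intensity \rceil} genotypes.
#'
#' @param scores an `index_scores` object.
#' @param intensity selected proportion, in (0, 1].
#' @return character vector of selected genotype ids, best first.
#' @export
rank_and_select <- function(scores, intensity) {
  stopifnot(inherits(scores, "index_scores"))
  if (!(intensity > 0 && intensity <= 1))
    stop("intensity must lie in (0, 1]")
  n_sel <- ceiling(length(scores$I) * intensity)
  names(sort(scores$ranks))[seq_len(n_sel)]
}

#' Correlation between index rankings
#'
#' Pearson correlation matrix of the per-genotype index values across a set
#' of indices scored on the same genotypes; a near-perfect correlation
#' means two indices rank the genotypes almost identically.
#'
#' @param score_sets named list of `index_scores` on identical genotype
#'   sets.
#' @return symmetric correlation matrix with unit diagonal; entries
#'   involving a constant score vector are `NA` with a warning.
#' @export
index_score_correlation <- function(score_sets) {
  stopifnot(length(score_sets) >= 2,
            all(vapply(score_sets, inherits, logical(1), "index_scores")))
  ids <- lapply(score_sets, function(s) names(s$I))
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("all score sets must cover the same genotypes in the same order")
  M <- vapply(score_sets, function(s) s$I, numeric(length(score_sets[[1]]$I)))
  if (is.null(colnames(M)))
    colnames(M) <- paste0("index", seq_along(score_sets))
  const <- apply(M, 2, stats::sd) == 0
  R <- suppressWarnings(stats::cor(M))
  if (any(const)) {
    warning(sprintf("constant score vector(s), correlation undefined: %s",
                    paste(colnames(M)[const], collapse = ", ")))
    R[const, ] <- NA_real_
    R[, const] <- NA_real_
  }
  diag(R)[!const] <- 1
  R
}
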