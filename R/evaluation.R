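#' Standardized selection differential for truncation selection
#'
#' For truncation selection of the best proportion p from a normal
#' distribution, the mean superiority of the selected group in phenotypic
#' standard-deviation units is \eqn{k = \phi(z)/p}, with z the upper-p
#' quantile of the standard normal (the mean of the truncated normal above
#' z). At 10\% intensity k is about 1.755, conventionally rounded to 1.76.
#'
#' @param p selected proportion, strictly between 0 and 1.
#' @return the selection differential k (scalar).
#' @examples
#' selection_differential(0.10)  # ~1.755
#' @export
selection_differential <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || !(p > 0 && p < 1))
    stop("selected proportion p must lie strictly in (0, 1)")
  z <- stats::qnorm(1 - p)
  stats::dnorm(z) / p
}

#' Index accuracy R_HI and breeding-value standard deviation
#'
#' The accuracy of index selection is the correlation between the index
#' I = b'x and the aggregate genotype H = w'g:
#' \deqn{R_{HI} = \frac{b'Gw}{\sqrt{(b'Pb)(w'Gw)}}, \qquad
#'       \sigma_H = \sqrt{w'Gw}.}
#' The general covariance form is always used; the optimum-index shortcut
#' \eqn{\sqrt{b'Ga/a'Ga}} holds only when b solves Pb = Ga and would be
#' wrong for the base and Pesek-Baker indices. For the Pesek-Baker index
#' the aggregate-genotype weights w are the desired gains d.
#'
#' @param model a `selection_index`.
#' @param P,G phenotypic and genotypic covariance matrices.
#' @param w aggregate-genotype weights (economic weights a, or d for the
#'   Pesek-Baker index); defaults to the weights stored in the model.
#' @return list with `R_HI` and `sigma_H`.
#' @export
response_correlation <- function(model, P, G, w = NULL) {
  stopifnot(inherits(model, "selection_index"))
  if (is.null(w)) w <- model$weights_used
  w <- as_weight_vector(w)
  b <- model$b
  check_cov_matrix(P, "P", length(b))
  check_cov_matrix(G, "G", length(b))
  var_I <- drop(crossprod(b, P %*% b))
  var_H <- drop(crossprod(w, G %*% w))
  if (var_I <= 0)
    stop("index variance b'Pb is not positive (indefinite P estimate?)")
  if (var_H <= 0)
    stop("breeding-value variance w'Gw is not positive (indefinite G estimate?)")
  cov_HI <- drop(crossprod(b, G %*% w))
  list(R_HI = cov_HI / sqrt(var_I * var_H), sigma_H = sqrt(var_H))
}

#' Aggregate genetic gain per selection cycle
#'
#' \eqn{\Delta H = k \, R_{HI} \, \sigma_H}: the expected gain in the
#' aggregate genotype from one cycle of truncation selection on the index.
#'
#' @param k selection differential (SD units).
#' @param R_HI index accuracy.
#' @param sigma_H breeding-value standard deviation \eqn{\sqrt{w'Gw}}.
#' @return scalar expected gain.
#' @export
aggregate_gain <- function(k, R_HI, sigma_H) {
  stopifnot(is.finite(k), is.finite(R_HI), is.finite(sigma_H))
  k * R_HI * sigma_H
}

#' Expected per-trait genetic gains from index selection
#'
#' \eqn{\Delta = k\,G b / \sqrt{b'Pb}}: the correlated response of each
#' trait (in its own units) to one cycle of selection on the index.
#'
#' @param k selection differential.
#' @param G genotypic covariance matrix.
#' @param model a `selection_index`.
#' @param P phenotypic covariance matrix.
#' @return named m-vector of expected gains.
#' @export
per_trait_gain <- function(k, G, model, P) {
  stopifnot(inherits(model, "selection_index"))
  b <- model$b
  check_cov_matrix(P, "P", length(b))
  check_cov_matrix(G, "G", length(b))
  var_I <- drop(crossprod(b, P %*% b))
  if (var_I <= 0)
    stop("index variance b'Pb is not positive; cannot scale gains (zero or degenerate index)")
  delta <- drop(k * (G %*% b) / sqrt(var_I))
  names(delta) <- colnames(G)
  delta
}

#' Relative efficiency of index selection versus direct selection
#'
#' Compares the correlated response of a target trait A under index
#' selection with the response to direct truncation selection on A alone:
#' \deqn{RE = r_{G(A)I} / h_A, \qquad
#'       r_{G(A)I} = \frac{b'g}{\sqrt{\sigma^2_{G(A)}\, b'Pb}},}
#' where g is the target trait's column of G, \eqn{\sigma^2_{G(A)}} its
#' genotypic variance, and \eqn{h_A = \sqrt{G_{AA}/P_{AA}}} the square root
#' of its broad-sense heritability. RE > 1 means the index improves the
#' target trait faster than selecting on the trait itself.
#'
#' @param model a `selection_index`.
#' @param P,G phenotypic and genotypic covariance matrices.
#' @param target target trait, 1-based index or name.
#' @return list with `RE`, `r_GAI`, `h_A`.
#' @export
relative_efficiency <- function(model, P, G, target) {
  stopifnot(inherits(model, "selection_index"))
  b <- model$b
  check_cov_matrix(P, "P", length(b))
  check_cov_matrix(G, "G", length(b))
  t_idx <- resolve_trait(target, colnames(G))
  var_GA <- G[t_idx, t_idx]
  var_PA <- P[t_idx, t_idx]
  if (var_GA <= 0) stop("target trait has non-positive genotypic variance")
  if (var_PA <= 0) stop("target trait has non-positive phenotypic variance")
  var_I <- drop(crossprod(b, P %*% b))
  if (var_I <= 0) stop("index variance b'Pb is not positive")
  g <- G[, t_idx]
  r_GAI <- drop(crossprod(b, g)) / sqrt(var_GA * var_I)
  h_A <- sqrt(var_GA / var_PA)
  list(RE = r_GAI / h_A, r_GAI = r_GAI, h_A = h_A)
}

#' Phenotypic coefficient of variation of the index
#'
#' \eqn{CV_I = 100\,\sigma_I/\bar X}, the sample standard deviation of the
#' per-genotype index values relative to their mean (in percent). With
#' `from = "model"` the standard deviation is taken as \eqn{\sqrt{b'Pb}}
#' instead of the realized sample SD (the mean still comes from the
#' realized scores).
#'
#' @param scores an `index_scores` object.
#' @param from `"scores"` (default; sample SD of realized scores) or
#'   `"model"` (requires `P` and `model`).
#' @param model,P only for `from = "model"`.
#' @param tol mean-score magnitude below which CV is undefined.
#' @return CV in percent, or `NA` with a warning when the mean score is
#'   within `tol` of zero.
#' @export
index_cv <- function(scores, from = c("scores", "model"),
                     model = NULL, P = NULL, tol = 1e-10) {
  from <- match.arg(from)
  stopifnot(inherits(scores, "index_scores"))
  if (abs(scores$mean_score) <= tol) {
    warning("mean index score is (near) zero; CV undefined")
    return(NA_real_)
  }
  sd_I <- if (from == "scores") scores$sd_score
          else {
            stopifnot(inherits(model, "selection_index"), is.matrix(P))
            sqrt(drop(crossprod(model$b, P %*% model$b)))
          }
  100 * sd_I / scores$mean_score
}

#' Evaluate a selection index by the five standard criteria
#'
#' One-stop report for a fitted index: selection differential k, accuracy
#' R_HI, aggregate gain \eqn{\Delta H}, per-trait expected gains
#' \eqn{\Delta}, relative efficiency RE against direct selection on the
#' target trait (with its components \eqn{r_{G(A)I}} and \eqn{h_A}), and
#' the index coefficient of variation CV_I (computed from realized scores,
#' so it requires a trait panel).
#'
#' @param model a `selection_index`.
#' @param P,G phenotypic and genotypic covariance matrices.
#' @param w aggregate-genotype weights (defaults to the model's own).
#' @param panel optional [trait_panel()]; needed for CV_I.
#' @param target target trait for relative efficiency (index or name).
#' @param p selected proportion for k (default 0.10); ignored when `k`
#'   is given.
#' @param k optional literal selection differential overriding `p`.
#' @return an object of class `sel_criteria`: list with `method`, `k`,
#'   `R_HI`, `sigma_H`, `delta_H`, `delta` (m-vector), `RE`, `r_GAI`,
#'   `h_A`, `CV_I` (`NA` without a panel).
#' @export
evaluate_index <- function(model, P, G, w = NULL, panel = NULL,
                           target, p = 0.10, k = NULL) {
  if (is.null(k)) k <- selection_differential(p)
  rc <- response_correlation(model, P, G, w)
  delta <- per_trait_gain(k, G, model, P)
  re <- relative_efficiency(model, P, G, target)
  cv <- NA_real_
  if (!is.null(panel)) {
    scores <- score_genotypes(panel, model)
    cv <- index_cv(scores)
  }
  structure(list(method = model$method, k = k,
                 R_HI = rc$R_HI, sigma_H = rc$sigma_H,
                 delta_H = aggregate_gain(k, rc$R_HI, rc$sigma_H),
                 delta = delta,
                 RE = re$RE, r_GAI = re$r_GAI, h_A = re$h_A,
                 CV_I = cv),
            class = "sel_criteria")
}

#' @export
print.sel_criteria <- function(x, digits = 4, ...) {
  cat(sprintf("Selection-index criteria (%s index, k = %.4f)\n",
              x$method, x$k))
  cat(sprintf("  R_HI = %.*f   delta_H = %.*f   RE = %.*f   CV_I = %s\n",
              digits, x$R_HI, digits, x$delta_H, digits, x$RE,
              if (is.na(x$CV_I)) "NA" else sprintf("%.*f", digits, x$CV_I)))
  cat("  Per-trait expected gains:\n")
  print(round(x$delta, digits))
  invisible(x)
}
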