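#' Unit economic weights
#'
#' The simplest weighting scheme: every trait gets relative economic value 1.
#'
#' @param m number of traits, or a character vector of trait names.
#' @return an `economic_weights` object with `a` = all-ones vector and
#'   `scheme = "unit"`.
#' @export
unit_weights <- function(m) {
  if (is.character(m)) {
    nm <- m
    m <- length(m)
  } else {
    nm <- NULL
  }
  if (m < 1) stop("need at least one trait")
  a <- rep(1, m)
  names(a) <- nm
  new_economic_weights(a, "unit")
}

new_economic_weights <- function(a, scheme) {
  structure(list(a = a, scheme = scheme), class = "economic_weights")
}

#' @export
print.economic_weights <- function(x, digits = 4, ...) {
  cat(sprintf("Economic weights (scheme: %s)\n", x$scheme))
  print(round(x$a, digits))
  invisible(x)
}

#' Correlation-based economic weights
#'
#' Weights each trait by its correlation with a target trait (typically
#' yield); the target itself gets weight 1. With `source = "total"` the
#' correlations are Pearson correlations computed across the rows of the
#' phenotypic trait panel X; with `"phenotypic"` or `"genotypic"` they are
#' taken from the corresponding correlation matrix of a
#' [correlation_matrices()] result.
#'
#' @param panel a [trait_panel()]; required for `source = "total"`.
#' @param target trait to correlate against: 1-based column index or name.
#' @param source `"total"` (default), `"phenotypic"`, or `"genotypic"`.
#' @param corr a `correlation_pair`; required for matrix-based sources.
#' @return an `economic_weights` object, `scheme = "correlation"`.
#' @export
correlation_weights <- function(panel = NULL, target,
                                source = c("total", "phenotypic", "genotypic"),
                                corr = NULL) {
  source <- match.arg(source)
  if (source == "total") {
    stopifnot(inherits(panel, "trait_panel"))
    X <- panel$X
    target <- resolve_trait(target, panel$trait_names)
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop(sprintf("zero-variance trait(s), correlation undefined: %s",
                   paste(panel$trait_names[sds == 0], collapse = ", ")))
    a <- drop(stats::cor(X, X[, target]))
    names(a) <- panel$trait_names
  } else {
    if (is.null(corr)) stop("matrix-based sources need a correlation_pair")
    R <- if (source == "phenotypic") corr$r_p else corr$r_g
    target <- resolve_trait(target, colnames(R))
    a <- R[, target]
    if (anyNA(a))
      stop(sprintf("undefined correlation(s) with target for trait(s): %s",
                   paste(names(a)[is.na(a)], collapse = ", ")))
  }
  a[target] <- 1
  new_economic_weights(a, "correlation")
}

resolve_trait <- function(target, trait_names) {
  if (is.character(target)) {
    i <- match(target, trait_names)
    if (is.na(i)) stop(sprintf("unknown trait '%s'", target))
    return(i)
  }
  target <- as.integer(target)
  if (target < 1 || (length(trait_names) && target > length(trait_names)))
    stop(sprintf("trait index %d out of range", target))
  target
}

#' Stepwise-regression economic weights (standardized betas)
#'
#' Regresses the target trait on the remaining traits by forward-stepwise
#' selection with F-test entry/removal thresholds (the classic SAS
#' `selection=stepwise` procedure): at each step the candidate with the
#' smallest partial-F p-value enters if below `sle`; after each entry,
#' in-model predictors whose p-value exceeds `sls` are removed (worst
#' first). Ties in entry p-value break toward the lowest column index.
#' The resulting weights are the standardized regression coefficients
#' (beta * sd(x)/sd(y)) of the entered traits, 0 for traits that never
#' entered, and 1 for the target itself.
#'
#' @param panel a [trait_panel()] (genotype-level records).
#' @param target target trait (dependent variable), index or name.
#' @param sle significance level to enter, in (0,1); default 0.15.
#' @param sls significance level to stay, in (0,1); default 0.15.
#' @return an `economic_weights` object, `scheme = "stepwise_beta"`, with
#'   attribute `"entered"` listing the selected predictors in entry order.
#' @export
stepwise_beta_weights <- function(panel, target, sle = 0.15, sls = 0.15) {
  stopifnot(inherits(panel, "trait_panel"))
  if (!(sle > 0 && sle < 1 && sls > 0 && sls < 1))
    stop("sle and sls must lie in (0, 1)")
  X <- panel$X
  n <- nrow(X)
  m <- ncol(X)
  if (n <= m) stop("need more genotypes than traits for stepwise regression")
  target <- resolve_trait(target, panel$trait_names)
  y <- X[, target]
  preds <- setdiff(seq_len(m), target)

  qrX <- qr(cbind(1, X[, preds, drop = FALSE]))
  if (qrX$rank < length(preds) + 1) {
    dropped <- preds[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop(sprintf("collinear predictors (singular normal equations): %s",
                 paste(panel$trait_names[dropped], collapse = ", ")))
  }

  in_model <- integer(0)
  repeat {
    moved <- FALSE
    candidates <- setdiff(preds, in_model)
    if (length(candidates)) {
      pvals <- vapply(candidates, function(j) {
        fit <- stats::lm(y ~ X[, c(in_model, j), drop = FALSE])
        cf <- summary(fit)$coefficients
        cf[nrow(cf), 4]
      }, numeric(1))
      best <- candidates[which.min(pvals)]   # which.min is first-min: lowest index on ties
      if (min(pvals) < sle) {
        in_model <- c(in_model, best)
        moved <- TRUE
      }
    }
    # removal phase: drop the worst-staying predictor while any exceeds sls
    while (length(in_model)) {
      fit <- stats::lm(y ~ X[, in_model, drop = FALSE])
      cf <- summary(fit)$coefficients
      pstay <- cf[-1, 4]
      if (max(pstay) <= sls) break
      worst <- in_model[which.max(pstay)]
      just_entered <- moved && worst == in_model[length(in_model)]
      in_model <- in_model[in_model != worst]
      if (just_entered) {
        # the variable just entered left again: terminate to avoid cycling
        moved <- FALSE
        break
      }
    }
    if (!moved) break
  }

  a <- numeric(m)
  names(a) <- panel$trait_names
  if (length(in_model)) {
    fit <- stats::lm(y ~ X[, in_model, drop = FALSE])
    beta <- stats::coef(fit)[-1]
    a[in_model] <- beta * apply(X[, in_model, drop = FALSE], 2, stats::sd) / stats::sd(y)
  }
  a[target] <- 1
  out <- new_economic_weights(a, "stepwise_beta")
  attr(out, "entered") <- panel$trait_names[in_model]
  out
}

#' Desired genetic gains vector for the Pesek-Baker index
#'
#' By default the desired gain per trait is the genetic standard deviation,
#' \eqn{d = \sqrt{diag(G)}}; a breeder-specified override vector may be
#' given instead (e.g. target increases in trait units).
#'
#' @param G genotypic covariance matrix (m x m).
#' @param override optional m-vector of desired gains, used verbatim.
#' @return a `desired_gains` object with element `d`.
#' @export
desired_gains <- function(G, override = NULL) {
  if (!is.null(override)) {
    d <- as.numeric(override)
    if (!is.null(G) && length(d) != ncol(G))
      stop("override length must match trait count")
    if (!is.null(colnames(G))) names(d) <- colnames(G)
    return(structure(list(d = d, source = "override"), class = "desired_gains"))
  }
  dg <- diag(G)
  if (any(dg < 0))
    stop(sprintf("negative genotypic variance for trait(s): %s; supply an override d",
                 paste(colnames(G)[dg < 0], collapse = ", ")))
  d <- sqrt(dg)
  names(d) <- colnames(G)
  structure(list(d = d, source = "sqrt_diag_G"), class = "desired_gains")
}

#' @export
print.desired_gains <- function(x, digits = 4, ...) {
  cat(sprintf("Desired genetic gains (source: %s)\n", x$source))
  print(round(x$d, digits))
  invisible(x)
}

#' Read an economic-weights CSV
#'
#' One row per trait (trait-name index column named `trait` or unnamed
#' first column), one column per weighting scheme.
#'
#' @param path CSV file path.
#' @return numeric matrix, traits x schemes, with trait rownames.
#' @export
read_weights_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  label_col <- if ("trait" %in% names(df)) "trait"
               else if (!is.numeric(df[[1]])) names(df)[1]
               else NULL
  if (!is.null(label_col)) {
    rn <- df[[label_col]]
    df <- df[setdiff(names(df), label_col)]
  } else rn <- NULL
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop(sprintf("%s: non-numeric weight column(s): %s", path,
                 paste(nonnum, collapse = ", ")))
  w <- as.matrix(df)
  rownames(w) <- rn
  w
}
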