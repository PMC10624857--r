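#' Variance and covariance components from a balanced RCBD trial
#'
#' Per-trait two-way ANOVA (genotype, replicate, residual) and the analogous
#' mean cross-products give the genotypic and error (co)variance components
#' under the balanced expected-mean-square solution:
#' \deqn{\sigma^2_g = (MS_g - MS_e)/r, \qquad \sigma^2_e = MS_e,}
#' and for each trait pair, \eqn{cov_g = (MCP_g - MCP_e)/r} from mean
#' cross-products of genotype means and residuals. Phenotypic components
#' depend on the reporting basis: on a per-plot basis
#' \eqn{\sigma^2_p = \sigma^2_g + \sigma^2_e}; on a genotype-mean basis
#' \eqn{\sigma^2_p = \sigma^2_g + \sigma^2_e/r} (covariances analogously).
#' Broad-sense heritability is \eqn{h^2_b = \sigma^2_g/\sigma^2_p}.
#'
#' Negative genotypic components (when \eqn{MS_g < MS_e}) are reported as
#' estimated, with a warning; `clamp = TRUE` truncates them at zero (this
#' breaks the sum-of-squares identity and is off by default).
#'
#' @param trial an [rcbd_trial()] object.
#' @param basis `"plot"` (default) or `"mean"`: scale on which phenotypic
#'   (co)variances are reported.
#' @param clamp logical; truncate negative genotypic components at zero.
#' @return an object of class `varcomp` with elements `sigma2_g`,
#'   `sigma2_e`, `sigma2_p` (m-vectors), `h2_broad` (m-vector, `NA` where
#'   `sigma2_p` is not positive), `P`, `G`, `E` (m x m matrices), `basis`,
#'   `r_reps`, `n_genotypes`, `anova` (per-trait data frame of SS/df/MS).
#' @examples
#' tr <- rcbd_trial(c("A", "B", "A", "B"), c(1, 1, 2, 2),
#'                  matrix(c(10, 14, 12, 16), ncol = 1,
#'                         dimnames = list(NULL, "yield")))
#' vc <- estimate_components(tr)
#' vc$sigma2_g  # 8
#' vc$h2_broad  # 1
#' @export
estimate_components <- function(trial, basis = c("plot", "mean"),
                                clamp = FALSE) {
  basis <- match.arg(basis)
  stopifnot(inherits(trial, "rcbd_trial"))
  Y <- trial$values
  n <- trial$n_genotypes
  r <- trial$n_reps
  m <- ncol(Y)

  grand <- colMeans(Y)
  Gm <- rowsum(Y, trial$genotype, reorder = FALSE) / r      # n x m genotype means
  Rm <- rowsum(Y, trial$replicate, reorder = FALSE) / n     # r x m replicate means

  # sums of squares and cross-products per stratum (m x m each)
  SCP_g   <- r * crossprod(sweep(Gm, 2, grand))
  SCP_rep <- n * crossprod(sweep(Rm, 2, grand))
  SCP_tot <- crossprod(sweep(Y, 2, grand))
  SCP_e   <- SCP_tot - SCP_g - SCP_rep

  MCP_g <- SCP_g / (n - 1)
  MCP_e <- SCP_e / ((n - 1) * (r - 1))

  G <- (MCP_g - MCP_e) / r
  E <- MCP_e
  # enforce exact symmetry against floating-point drift
  G <- (G + t(G)) / 2
  E <- (E + t(E)) / 2

  neg <- diag(G) < 0
  if (any(neg)) {
    msg <- sprintf("negative genotypic variance estimate for trait(s): %s",
                   paste(trial$trait_names[neg], collapse = ", "))
    if (clamp) {
      warning(paste(msg, "- clamped to zero"))
      diag(G)[neg] <- 0
    } else {
      warning(paste(msg, "- reported as estimated (use clamp = TRUE to truncate)"))
    }
  }

  P <- if (basis == "plot") G + E else G + E / r
  dimnames(P) <- dimnames(G) <- dimnames(E) <-
    list(trial$trait_names, trial$trait_names)

  sigma2_g <- diag(G)
  sigma2_e <- diag(E)
  sigma2_p <- diag(P)
  h2 <- ifelse(sigma2_p > 0, sigma2_g / sigma2_p, NA_real_)
  if (anyNA(h2))
    warning(sprintf("heritability undefined (zero phenotypic variance) for trait(s): %s",
                    paste(trial$trait_names[is.na(h2)], collapse = ", ")))
  names(sigma2_g) <- names(sigma2_e) <- names(sigma2_p) <- names(h2) <-
    trial$trait_names

  anova_tab <- data.frame(
    trait = trial$trait_names,
    SS_genotype = diag(SCP_g), SS_replicate = diag(SCP_rep),
    SS_error = diag(SCP_e), SS_total = diag(SCP_tot),
    df_genotype = n - 1, df_replicate = r - 1, df_error = (n - 1) * (r - 1),
    MS_genotype = diag(MCP_g), MS_error = diag(MCP_e),
    row.names = NULL)

  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_p, h2_broad = h2,
                 P = P, G = G, E = E, basis = basis,
                 r_reps = r, n_genotypes = n, anova = anova_tab),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components from balanced RCBD (%d genotypes, %d reps; %s basis)\n",
              x$n_genotypes, x$r_reps, x$basis))
  print(round(data.frame(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                         sigma2_p = x$sigma2_p, h2_broad = x$h2_broad),
              digits))
  invisible(x)
}

#' Genetic and phenotypic correlation matrices
#'
#' Standardizes the genotypic and phenotypic covariance matrices:
#' \eqn{r_g(j,k) = cov_g(j,k)/\sqrt{\sigma^2_g(j)\,\sigma^2_g(k)}} and
#' analogously for \eqn{r_p}. Entries involving a trait with non-positive
#' variance are flagged `NA` (undefined) rather than silently zeroed.
#'
#' @param vc a [estimate_components()] result, or a list with matrices
#'   `P` and `G`.
#' @return a list of class `correlation_pair` with `r_g` and `r_p`
#'   (unit-diagonal symmetric matrices, `NA` where undefined).
#' @export
correlation_matrices <- function(vc) {
  if (!all(c("P", "G") %in% names(vc)))
    stop("vc must contain P and G matrices")
  structure(list(r_g = .cov_to_cor(vc$G), r_p = .cov_to_cor(vc$P)),
            class = "correlation_pair")
}

.cov_to_cor <- function(S) {
  d <- diag(S)
  bad <- !(d > 0)
  sd <- sqrt(pmax(d, 0))
  R <- S / outer(sd, sd)
  R[bad, ] <- NA_real_
  R[, bad] <- NA_real_
  diag(R)[!bad] <- 1
  (R + t(R)) / 2
}
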