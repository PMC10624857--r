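#' Read a phenotypic trait-value matrix (X) from CSV
#'
#' Layout: optional `genotype` id column (or any non-numeric first column)
#' plus one numeric column per trait; header row required.
#'
#' @param path CSV file path.
#' @return a [trait_panel()].
#' @export
read_trait_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- if ("genotype" %in% names(df)) "genotype"
            else if (!is.numeric(df[[1]])) names(df)[1]
            else NULL
  if (!is.null(id_col)) {
    ids <- as.character(df[[id_col]])
    df <- df[setdiff(names(df), id_col)]
  } else ids <- NULL
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop(sprintf("%s: non-numeric trait column(s): %s", path,
                 paste(nonnum, collapse = ", ")))
  trait_panel(as.matrix(df), genotype_ids = ids, trait_names = names(df))
}

#' Read a square covariance matrix from CSV
#'
#' Layout: trait-name header row, optional trait-name first column. The
#' matrix must be square; asymmetry up to a relative tolerance of 1e-6 is
#' repaired by averaging with a warning, anything larger is an error.
#'
#' @param path CSV file path.
#' @param tol relative asymmetry tolerance (default 1e-6).
#' @return numeric m x m symmetric matrix with trait dimnames.
#' @export
read_covariance_csv <- function(path, tol = 1e-6) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) {
    rn <- df[[1]]
    df <- df[-1]
  } else rn <- names(df)
  nonnum <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(nonnum))
    stop(sprintf("%s: non-numeric cell(s) in column(s): %s", path,
                 paste(nonnum, collapse = ", ")))
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop(sprintf("%s: covariance matrix must be square, got %dx%d",
                 path, nrow(M), ncol(M)))
  rownames(M) <- if (length(rn) == nrow(M)) rn else colnames(M)
  rel <- max(abs(M - t(M))) / max(1, max(abs(M)))
  if (rel > tol)
    stop(sprintf("%s: matrix asymmetric beyond tolerance (relative deviation %.3g)",
                 path, rel))
  if (rel > 0) {
    warning(sprintf("%s: small asymmetry (%.3g) symmetrized by averaging", path, rel))
    M <- (M + t(M)) / 2
  }
  M
}

#' Write a matrix to CSV with a label column
#'
#' @param M matrix with dimnames.
#' @param path output path.
#' @param label name for the rowname column (default "trait").
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path, label = "trait") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full selection-index workflow
#'
#' From either a plot-level RCBD trial or precomputed (X, P, G) inputs:
#' builds the requested economic-weight schemes, fits the requested
#' indices, scores and ranks genotypes, selects at the given intensity,
#' evaluates every index/scheme pairing by the five criteria, and
#' cross-correlates the index scores. Results are returned as a list and,
#' when `outdir` is given, also written as a directory of CSV reports plus
#' a full-precision JSON sidecar and a plain-text log of the decisions
#' taken (variance basis, k, stepwise thresholds).
#'
#' @param trial optional [rcbd_trial()]; when given, X, P and G are
#'   estimated from it and `x`/`p_mat`/`g_mat` must be absent.
#' @param x,p_mat,g_mat precomputed inputs: a [trait_panel()] (or path to
#'   an X CSV) and covariance matrices (or paths to their CSVs).
#' @param weights optional traits x schemes matrix of user economic
#'   weights (or path to a weights CSV); used by scheme `"user"`.
#' @param target target trait for relative efficiency (1-based index or
#'   name); default: the last trait, matching the yield-last convention.
#' @param intensity selected proportion in (0, 1]; default 0.10.
#' @param k optional literal selection differential overriding
#'   `intensity` in the gain formulas (selection of genotypes still uses
#'   `intensity`).
#' @param methods subset of `c("optimum", "base", "pesek_baker")`.
#' @param schemes subset of `c("unit", "correlation", "stepwise_beta",
#'   "user")`; economic-weight schemes for the optimum and base indices
#'   (the Pesek-Baker index always uses the desired-gains vector d and is
#'   reported once).
#' @param basis phenotypic-variance basis for trial input,
#'   `"plot"` or `"mean"`.
#' @param sle,sls stepwise entry/stay thresholds (default 0.15).
#' @param outdir optional output directory for CSV reports.
#' @return (invisibly when writing) list with `P`, `G`, `d`, `weights`
#'   (list of scheme vectors), `models`, `scores`, `selected`, `criteria`
#'   (data frame shaped like the usual criteria table), `score_cor`,
#'   `k`, `target`.
#' @export
run_pipeline <- function(trial = NULL, x = NULL, p_mat = NULL, g_mat = NULL,
                         weights = NULL, target = NULL,
                         intensity = 0.10, k = NULL,
                         methods = c("optimum", "base", "pesek_baker"),
                         schemes = "unit",
                         basis = c("plot", "mean"),
                         sle = 0.15, sls = 0.15,
                         outdir = NULL) {
  basis <- match.arg(basis)
  methods <- match.arg(methods, c("optimum", "base", "pesek_baker"),
                       several.ok = TRUE)
  schemes <- match.arg(schemes, c("unit", "correlation", "stepwise_beta", "user"),
                       several.ok = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1]] <<- sprintf(fmt, ...)
  }

  if (!is.null(trial) && (!is.null(x) || !is.null(p_mat) || !is.null(g_mat)))
    stop("give either a trial or precomputed X/P/G, not both")
  if (!is.null(trial)) {
    vc <- estimate_components(trial, basis = basis)
    P <- vc$P; G <- vc$G
    panel <- genotype_means(trial)
    note("variance components estimated from trial on '%s' basis (r = %d)",
         basis, vc$r_reps)
  } else {
    if (is.null(x) || is.null(p_mat) || is.null(g_mat))
      stop("precomputed mode needs all of X, P and G")
    panel <- if (inherits(x, "trait_panel")) x else read_trait_panel(x)
    P <- if (is.matrix(p_mat)) p_mat else read_covariance_csv(p_mat)
    G <- if (is.matrix(g_mat)) g_mat else read_covariance_csv(g_mat)
  }
  m <- ncol(panel$X)
  if (ncol(P) != m || ncol(G) != m)
    stop(sprintf("dimension mismatch: X has %d traits, P is %dx%d, G is %dx%d",
                 m, nrow(P), ncol(P), nrow(G), ncol(G)))
  align_traits <- function(M, what) {
    if (!is.null(colnames(M)) && !is.null(panel$trait_names) &&
        !identical(colnames(M), panel$trait_names)) {
      if (all(panel$trait_names %in% colnames(M))) {
        note("%s columns reordered to match X trait order", what)
        return(M[panel$trait_names, panel$trait_names])
      }
      stop(sprintf("trait names of %s do not match X: %s vs %s", what,
                   paste(colnames(M), collapse = ","),
                   paste(panel$trait_names, collapse = ",")))
    }
    dimnames(M) <- list(panel$trait_names, panel$trait_names)
    M
  }
  P <- align_traits(P, "P")
  G <- align_traits(G, "G")

  if (is.null(target)) target <- m
  t_idx <- resolve_trait(target, panel$trait_names)
  note("target trait: %s (column %d)", panel$trait_names[t_idx], t_idx)

  if (!is.null(weights) && !is.matrix(weights))
    weights <- read_weights_csv(weights)

  k_use <- if (is.null(k)) selection_differential(intensity) else k
  note("selection: intensity p = %.4g, k = %.6f%s", intensity, k_use,
       if (is.null(k)) " (phi(z)/p)" else " (user-supplied)")

  weight_sets <- list()
  for (s in schemes) {
    weight_sets[[s]] <- switch(s,
      unit = unit_weights(panel$trait_names),
      correlation = correlation_weights(panel, t_idx, source = "total"),
      stepwise_beta = {
        note("stepwise thresholds: sle = %.3g, sls = %.3g", sle, sls)
        stepwise_beta_weights(panel, t_idx, sle = sle, sls = sls)
      },
      user = {
        if (is.null(weights)) stop("scheme 'user' requires a weights matrix/CSV")
        new_economic_weights(stats::setNames(weights[, 1], rownames(weights)),
                             "user")
      })
  }
  d <- desired_gains(G)

  models <- list()
  scores <- list()
  selected <- list()
  crit_rows <- list()
  for (method in methods) {
    combos <- if (method == "pesek_baker") "desired_gains" else schemes
    for (s in combos) {
      key <- paste(method, s, sep = ".")
      model <- switch(method,
        optimum = optimum_coefficients(P, G, weight_sets[[s]]),
        base = base_coefficients(weight_sets[[s]]),
        pesek_baker = pesek_baker_coefficients(G, d))
      sc <- score_genotypes(panel, model)
      models[[key]] <- model
      scores[[key]] <- sc
      selected[[key]] <- rank_and_select(sc, intensity)
      crit <- evaluate_index(model, P, G, panel = panel,
                             target = t_idx, k = k_use)
      row <- data.frame(index = method, scheme = s,
                        t(crit$delta),
                        R_HI = crit$R_HI, delta_H = crit$delta_H,
                        RE = crit$RE, CV_I = crit$CV_I,
                        check.names = FALSE)
      crit_rows[[key]] <- row
    }
  }
  criteria <- do.call(rbind, c(crit_rows, make.row.names = FALSE))
  score_cor <- if (length(scores) >= 2) index_score_correlation(scores) else NULL

  result <- list(P = P, G = G, d = d, weights = weight_sets,
                 models = models, scores = scores, selected = selected,
                 criteria = criteria, score_cor = score_cor,
                 k = k_use, intensity = intensity,
                 target = panel$trait_names[t_idx], panel = panel,
                 log = log_lines)

  if (!is.null(outdir)) {
    write_pipeline_reports(result, outdir)
    return(invisible(result))
  }
  result
}

#' Write pipeline reports to a directory of CSV files
#'
#' Emits `coefficients.csv` (trait x index/scheme), one
#' `scores_<index>.<scheme>.csv` per pairing (genotype, score, rank,
#' selected flag), `criteria.csv` (rows = index x scheme; per-trait gains
#' then R_HI, delta_H, RE, CV_I, rounded to 4 decimals),
#' `criteria_full.json` (full precision), `score_correlations.csv`, and
#' `log.txt`.
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_reports <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  B <- vapply(result$models, function(m) m$b,
              numeric(length(result$panel$trait_names)))
  B <- matrix(B, ncol = length(result$models),
              dimnames = list(result$panel$trait_names, names(result$models)))
  write_matrix_csv(round(B, 6), file.path(outdir, "coefficients.csv"))

  for (key in names(result$scores)) {
    sc <- result$scores[[key]]
    df <- data.frame(genotype = names(sc$I),
                     score = sc$I, rank = sc$ranks,
                     selected = names(sc$I) %in% result$selected[[key]],
                     row.names = NULL)
    utils::write.csv(df, file.path(outdir, sprintf("scores_%s.csv", key)),
                     row.names = FALSE)
  }

  crit <- result$criteria
  num <- vapply(crit, is.numeric, logical(1))
  crit[num] <- lapply(crit[num], round, 4)
  utils::write.csv(crit, file.path(outdir, "criteria.csv"), row.names = FALSE)
  jsonlite::write_json(result$criteria, file.path(outdir, "criteria_full.json"),
                       dataframe = "rows", digits = NA)

  if (!is.null(result$score_cor))
    write_matrix_csv(round(result$score_cor, 5),
                     file.path(outdir, "score_correlations.csv"),
                     label = "index")
  writeLines(result$log, file.path(outdir, "log.txt"))
  invisible(outdir)
}
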