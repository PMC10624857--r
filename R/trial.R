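#' Construct a balanced RCBD trial object
#'
#' Bundles plot-level records from a randomized complete block design:
#' one row per plot, identified by genotype and replicate (block), with one
#' numeric measurement per trait. The design must be balanced — every
#' genotype observed exactly once in every replicate — because downstream
#' variance components rely on the balanced expected-mean-square solution.
#' Missing trait values are an error, never imputed.
#'
#' @param genotype vector of genotype labels, one per plot.
#' @param replicate vector of replicate (block) labels, one per plot.
#' @param values numeric matrix or data frame of trait measurements,
#'   plots in rows, traits in columns.
#' @param trait_names optional character vector of trait names; defaults to
#'   the column names of `values`.
#' @return an object of class `rcbd_trial` with elements `genotype`
#'   (factor, levels in order of first appearance), `replicate` (factor),
#'   `values` (numeric matrix), `n_genotypes`, `n_reps`, `trait_names`.
#' @examples
#' tr <- rcbd_trial(genotype  = c("A", "B", "A", "B"),
#'                  replicate = c(1, 1, 2, 2),
#'                  values    = matrix(c(10, 14, 12, 16), ncol = 1,
#'                                     dimnames = list(NULL, "yield")))
#' genotype_means(tr)
#' @export
rcbd_trial <- function(genotype, replicate, values, trait_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(genotype) != nrow(values) || length(replicate) != nrow(values))
    stop("genotype, replicate and values must have one entry per plot")
  if (anyNA(values)) {
    bad <- which(apply(values, 1, anyNA))[1]
    stop(sprintf(
      "missing trait value in plot %d (genotype %s, replicate %s); missing data are not supported",
      bad, genotype[bad], replicate[bad]))
  }
  if (is.null(trait_names)) trait_names <- colnames(values)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  colnames(values) <- trait_names

  geno <- factor(genotype, levels = unique(as.character(genotype)))
  repl <- factor(replicate, levels = unique(as.character(replicate)))
  n <- nlevels(geno)
  r <- nlevels(repl)
  if (n < 2) stop("need at least 2 genotypes")
  if (r < 2) stop("need at least 2 replicates (error mean square undefined otherwise)")

  tab <- table(geno, repl)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unbalanced design: genotype %s appears %d times in replicate %s (expected exactly 1)",
      levels(geno)[bad[1]], tab[bad[1], bad[2]], levels(repl)[bad[2]]))
  }

  structure(list(genotype = geno, replicate = repl, values = values,
                 n_genotypes = n, n_reps = r, trait_names = trait_names),
            class = "rcbd_trial")
}

#' @export
print.rcbd_trial <- function(x, ...) {
  cat(sprintf("Balanced RCBD trial: %d genotypes x %d replicates, %d trait(s)\n",
              x$n_genotypes, x$n_reps, length(x$trait_names)))
  cat("Traits:", paste(x$trait_names, collapse = ", "), "\n")
  invisible(x)
}

#' Per-genotype trait means of an RCBD trial
#'
#' Averages each trait over replicates, producing the phenotypic matrix X
#' (genotypes in rows, traits in columns) that the selection indices score.
#' Genotype order follows first appearance in the trial.
#'
#' @param trial an [rcbd_trial()] object.
#' @return a [trait_panel()] with one row per genotype.
#' @export
genotype_means <- function(trial) {
  stopifnot(inherits(trial, "rcbd_trial"))
  X <- rowsum(trial$values, trial$genotype, reorder = FALSE) / trial$n_reps
  trait_panel(X, genotype_ids = levels(trial$genotype),
              trait_names = trial$trait_names)
}

#' Construct a phenotypic trait panel
#'
#' An n x m matrix of phenotypic values (genotypes in rows, traits in
#' columns) with genotype and trait labels — the X matrix of a selection
#' index I = sum(b_i * X_i).
#'
#' @param X numeric matrix or data frame, genotypes x traits.
#' @param genotype_ids optional genotype labels (default: rownames or 1..n).
#' @param trait_names optional trait labels (default: colnames).
#' @return an object of class `trait_panel`.
#' @export
trait_panel <- function(X, genotype_ids = NULL, trait_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("trait panel contains missing values")
  if (nrow(X) < 2) stop("need at least 2 genotypes")
  if (is.null(genotype_ids)) genotype_ids <- rownames(X)
  if (is.null(genotype_ids)) genotype_ids <- as.character(seq_len(nrow(X)))
  if (is.null(trait_names)) trait_names <- colnames(X)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(X)))
  if (length(genotype_ids) != nrow(X)) stop("genotype_ids length must match rows of X")
  if (length(trait_names) != ncol(X)) stop("trait_names length must match columns of X")
  dimnames(X) <- list(genotype_ids, trait_names)
  structure(list(X = X, genotype_ids = as.character(genotype_ids),
                 trait_names = trait_names),
            class = "trait_panel")
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf("Trait panel: %d genotypes x %d traits\n",
              nrow(x$X), ncol(x$X)))
  print(utils::head(x$X, 6))
  if (nrow(x$X) > 6) cat("...\n")
  invisible(x)
}

#' Read a plot-level RCBD trial from CSV
#'
#' Expects columns `genotype`, `replicate`, then one numeric column per
#' trait; a header row is required.
#'
#' @param path CSV file path.
#' @return an [rcbd_trial()].
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("genotype", "replicate")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: trial CSV must have 'genotype' and 'replicate' columns", path))
  traits <- setdiff(names(df), need)
  if (length(traits) == 0) stop(sprintf("%s: no trait columns found", path))
  vals <- df[traits]
  nonnum <- traits[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum))
    stop(sprintf("%s: non-numeric trait column(s): %s", path,
                 paste(nonnum, collapse = ", ")))
  rcbd_trial(df$genotype, df$replicate, as.matrix(vals), trait_names = traits)
}

#' Write a plot-level RCBD trial to CSV
#'
#' @param trial an [rcbd_trial()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(genotype = as.character(trial$genotype),
                   replicate = as.character(trial$replicate),
                   trial$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
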