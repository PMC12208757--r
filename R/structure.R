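#' Genotype trait means
#'
#' Arithmetic mean per genotype and trait over the blocks in which the
#' genotype was observed (missing plots excluded pairwise). Correlation,
#' ordination, clustering and the selection index all operate on these
#' means, the genotype-level summary of a replicated trial.
#'
#' @param trial a [trial_table()].
#' @return an object of class `genotype_means`: numeric matrix (genotype x
#'   trait) with the trait specifications attached as attribute `traits`.
#' @export
#' @examples
#' trial <- simulate_trial(demo_trial_config(seed = 1))
#' gm <- genotype_means(trial)
#' dim(gm)
genotype_means <- function(trial) {
  if (!inherits(trial, "trial_table")) stop("`trial` must be a trial_table", call. = FALSE)
  if (nrow(trial) == 0) stop("empty trial", call. = FALSE)
  specs <- attr(trial, "traits")
  nm <- trait_names(specs)
  g <- sort(unique(trial$genotype))
  M <- matrix(NA_real_, length(g), length(nm), dimnames = list(g, nm))
  for (t in nm) {
    mns <- tapply(trial[[t]], trial$genotype, mean, na.rm = TRUE)
    M[names(mns), t] <- as.numeric(mns)
  }
  M[is.nan(M)] <- NA_real_
  if (anyNA(M)) {
    warning("genotype(s) with no observations for some trait: mean reported as NA",
            call. = FALSE)
  }
  structure(M, traits = specs, class = c("genotype_means", "matrix"))
}

#' @export
print.genotype_means <- function(x, ...) {
  cat(sprintf("Genotype means: %d genotypes x %d traits\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Pairwise Pearson correlations with significance
#'
#' Pearson correlation between all trait pairs on genotype means, with
#' two-sided p-values from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom and the
#' conventional star codes. Zero-variance traits yield `NA` correlations for
#' their pairs.
#'
#' @param means a [genotype_means()] matrix (or plain numeric matrix).
#' @return object of class `trait_correlations`: list with symmetric
#'   matrices `r`, `p` and character matrix `stars`, plus `n` (genotypes).
#' @export
correlation_with_significance <- function(means) {
  M <- unclass(means)
  n <- nrow(M)
  if (n < 4) stop("need at least 4 genotypes for correlation tests", call. = FALSE)
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("zero-variance trait(s): correlations reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- NA_real_
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  stars <- matrix(sig_stars(p), nrow(p), ncol(p), dimnames = dimnames(p))
  stars[is.na(r)] <- NA_character_
  p[is.na(r)] <- NA_real_
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat(sprintf("Trait correlations over %d genotypes\n", x$n))
  disp <- matrix(paste0(format(round(x$r, digits)), " ",
                        ifelse(is.na(x$stars), "", x$stars)),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "1"
  print(disp, quote = FALSE, ...)
  invisible(x)
}

#' Percent variance explained by eigenvalues of a correlation matrix
#'
#' For a correlation-matrix PCA the eigenvalues sum to the number of traits
#' `K`, so each component explains `eigenvalue / K * 100` percent.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param k number of traits; defaults to `sum(eigenvalues)`.
#' @return percent of total variance per component.
#' @export
#' @examples
#' variance_explained(c(3.37, 1.70, 1.45, 1.28), k = 10)
variance_explained <- function(eigenvalues, k = sum(eigenvalues)) {
  if (any(eigenvalues < -1e-8)) stop("eigenvalues must be non-negative", call. = FALSE)
  100 * eigenvalues / k
}

#' Principal component analysis of trait structure
#'
#' Eigendecomposition of the trait correlation matrix computed from
#' standardized genotype means. Loadings are reported correlation-scaled
#' (eigenvector times the square root of its eigenvalue), so a loading is
#' the correlation of the trait with the component. Components are retained
#' when their eigenvalue strictly exceeds `retain_threshold` (Kaiser rule by
#' default). Loading signs are whatever the eigensolver returns; they are
#' arbitrary up to a component-wise flip.
#'
#' @param means a [genotype_means()] matrix.
#' @param retain_threshold eigenvalue cutoff for retention (default 1.0,
#'   strict inequality).
#' @return object of class `trait_pca`: list with `eigenvalues`, `loadings`
#'   (trait x component), `percent`, `cumulative`, `n_retained`.
#' @export
pca_traits <- function(means, retain_threshold = 1.0) {
  M <- unclass(means)
  if (ncol(M) < 2) stop("need at least 2 traits", call. = FALSE)
  if (nrow(M) <= ncol(M)) {
    warning("fewer genotypes than traits + 1: PCA may be unstable", call. = FALSE)
  }
  R <- stats::cor(M, use = "pairwise.complete.obs")
  if (any(!is.finite(R))) stop("non-finite correlation matrix", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(vals), length(vals))
  dimnames(L) <- list(colnames(M), paste0("PC", seq_along(vals)))
  pct <- variance_explained(vals, k = ncol(M))
  structure(
    list(eigenvalues = vals, loadings = L, percent = pct,
         cumulative = cumsum(pct), n_retained = sum(vals > retain_threshold),
         retain_threshold = retain_threshold),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("PCA of the trait correlation matrix (%d traits, %d retained with eigenvalue > %g)\n",
              k, x$n_retained, x$retain_threshold))
  show <- max(x$n_retained, 1)
  tab <- rbind(
    Eigenvalue = x$eigenvalues[seq_len(show)],
    `Variance %` = x$percent[seq_len(show)],
    `Cumulative %` = x$cumulative[seq_len(show)]
  )
  colnames(tab) <- paste0("PC", seq_len(show))
  print(round(tab, digits), ...)
  invisible(x)
}

#' Path coefficient analysis
#'
#' Decomposes each predictor's total correlation with a dependent trait into
#' a direct effect (standardized partial regression coefficient) and
#' indirect effects through the other predictors. Direct effects solve the
#' standardized normal equations \eqn{R_{xx} b = r_{xy}}; the indirect
#' effect of predictor i via j is \eqn{r_{ij} b_j}; the residual effect is
#' \eqn{\sqrt{1 - b^\top r_{xy}}}.
#'
#' @param corr a [correlation_with_significance()] result, or a correlation
#'   matrix.
#' @param dependent name of the dependent trait.
#' @param predictors predictor trait names; default all other traits.
#' @param cond_threshold condition-number threshold above which the
#'   predictor correlation matrix is declared collinear.
#' @return object of class `path_analysis`: list with `dependent`, `direct`
#'   (named vector), `indirect` (predictor x via-predictor matrix, `NA`
#'   diagonal), `total` (correlations with the dependent) and `residual`.
#' @export
path_analysis <- function(corr, dependent, predictors = NULL,
                          cond_threshold = 1e8) {
  R <- if (inherits(corr, "trait_correlations")) corr$r else as.matrix(corr)
  traits <- colnames(R)
  if (!dependent %in% traits) stop("dependent trait not in correlation matrix", call. = FALSE)
  predictors <- predictors %||% setdiff(traits, dependent)
  if (dependent %in% predictors) stop("predictors must exclude the dependent trait", call. = FALSE)
  if (!all(predictors %in% traits)) stop("unknown predictor trait(s)", call. = FALSE)
  Rxx <- R[predictors, predictors, drop = FALSE]
  rxy <- R[predictors, dependent]
  if (kappa(Rxx, exact = TRUE) > cond_threshold) {
    stop("predictor correlation matrix is (near-)singular: collinear predictors among ",
         paste(predictors, collapse = ", "), call. = FALSE)
  }
  b <- solve(Rxx, rxy)
  indirect <- Rxx * matrix(b, nrow(Rxx), length(b), byrow = TRUE)
  diag(indirect) <- NA_real_
  r2 <- sum(b * rxy)
  structure(
    list(dependent = dependent,
         direct = stats::setNames(as.numeric(b), predictors),
         indirect = indirect,
         total = stats::setNames(as.numeric(rxy), predictors),
         residual = sqrt(max(0, 1 - r2))),
    class = "path_analysis"
  )
}

#' @export
print.path_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Path analysis: dependent trait %s\n", x$dependent))
  tab <- data.frame(
    direct = round(x$direct, digits),
    indirect_total = round(x$total - x$direct, digits),
    total_r = round(x$total, digits)
  )
  print(tab, ...)
  cat(sprintf("Residual effect: %.3f\n", x$residual))
  invisible(x)
}
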