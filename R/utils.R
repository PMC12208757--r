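# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Significance codes for p-values
#'
#' Maps p-values to the conventional star codes used in trial reports:
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#' Missing p-values map to `ns`.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
#' @examples
#' sig_stars(c(0.0004, 0.004, 0.04, 0.4, NA))
sig_stars <- function(p) {
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

# symmetric matrix square root; errors if S is not positive semidefinite
# (small negative eigenvalues within tol are clipped to zero)
mat_sqrt <- function(S, name = "covariance matrix", tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-8)) {
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  }
  e <- eigen(S, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  if (min(e$values) < -tol * scale) {
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(e$values)), call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# force a symmetric matrix to be a valid correlation matrix by clipping
# eigenvalues at min_eig and renormalising to unit diagonal
as_correlation <- function(R, min_eig = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, min_eig)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  M
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

# draw n rows from MVN(0, S) using an eigen square root (handles PSD S)
rmvn0 <- function(n, S, name = "covariance matrix") {
  L <- mat_sqrt(S, name)
  matrix(stats::rnorm(n * ncol(S)), n, ncol(S)) %*% t(L)
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}
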