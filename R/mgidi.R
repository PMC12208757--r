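#' Rescale trait means to a directed 0-100 scale
#'
#' Linearly maps each trait from its observed range onto `[0, 100]` so that
#' 100 is always the desired extreme: for increase-sense traits the observed
#' maximum maps to 100 and the minimum to 0; for decrease-sense traits the
#' mapping is reversed. The map is monotone per trait, so genotype rankings
#' are preserved (reversed for decrease-sense traits) and the correlation
#' structure is preserved up to sign flips of decrease-sense columns.
#'
#' @param means a [genotype_means()] matrix.
#' @param specs list of [trait_spec()]; defaults to the specs attached to
#'   `means`.
#' @return object of class `rescaled_matrix`: genotype x trait matrix in
#'   `[0, 100]`, with original ranges and senses as attributes.
#' @export
rescale_traits <- function(means, specs = NULL) {
  M <- unclass(means)
  specs <- specs %||% attr(means, "traits")
  if (is.null(specs)) stop("trait specs required", call. = FALSE)
  nm <- trait_names(specs)
  if (!all(nm %in% colnames(M))) stop("specs do not match trait columns", call. = FALSE)
  M <- M[, nm, drop = FALSE]
  lo <- apply(M, 2, min, na.rm = TRUE)
  hi <- apply(M, 2, max, na.rm = TRUE)
  zero <- hi - lo == 0
  if (any(zero)) {
    stop("zero range for trait(s): ", paste(nm[zero], collapse = ", "), call. = FALSE)
  }
  senses <- trait_senses(specs)
  RX <- M
  for (j in seq_along(nm)) {
    p <- (M[, j] - lo[j]) / (hi[j] - lo[j])
    RX[, j] <- if (senses[j] == "increase") 100 * p else 100 * (1 - p)
  }
  structure(RX, orig_min = lo, orig_max = hi, senses = senses, traits = specs,
            class = c("rescaled_matrix", "matrix"))
}

#' Factor analysis of the rescaled trait matrix
#'
#' Extracts initial loadings as the correlation-scaled eigenvectors of the
#' correlation matrix of the rescaled traits, retaining factors with
#' eigenvalue above `retain_threshold` (at least one factor is always
#' retained), then applies a varimax rotation with Kaiser normalization.
#' Genotype factor scores use the regression method,
#' \eqn{S = Z R^{-1} \Lambda}, where `Z` is the column-standardized rescaled
#' matrix, `R` its correlation matrix and \eqn{\Lambda} the rotated
#' loadings. A singular `R` is ridge-stabilized (1e-8 on the diagonal) with
#' a warning.
#'
#' @param rx a [rescale_traits()] matrix.
#' @param retain_threshold eigenvalue retention cutoff (strict; default 1.0).
#' @return object of class `factor_model`: list with `m` (factor count),
#'   `loadings` (trait x factor, rotated), `communality`, `uniqueness`,
#'   `scores` (genotype x factor), `eigenvalues`, `assignment` (factor index
#'   of the dominant absolute loading per trait), plus the standardization
#'   and score-transform pieces needed to score new observations.
#' @export
fit_factor_model <- function(rx, retain_threshold = 1.0) {
  X <- unclass(rx)
  k <- ncol(X)
  if (k < 3) stop("need at least 3 traits for factor analysis", call. = FALSE)
  if (nrow(X) < 4) stop("need more genotypes than retained factors", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) stop("zero-variance column in rescaled matrix", call. = FALSE)
  Z <- scale(X, center = mu, scale = sdv)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  m <- max(1L, sum(vals > retain_threshold))
  A <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals[seq_len(m)]), m)
  if (m > 1) {
    rot <- stats::varimax(A, normalize = TRUE)
    L <- unclass(rot$loadings)
  } else {
    L <- A
  }
  dimnames(L) <- list(colnames(X), paste0("FA", seq_len(m)))
  Rinv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix: ridge-stabilized inverse used", call. = FALSE)
    solve(R + diag(1e-8, k))
  })
  W <- Rinv %*% L # k x m score-transform
  scores <- Z %*% W
  dimnames(scores) <- list(rownames(X), colnames(L))
  communality <- rowSums(L^2)
  structure(
    list(m = m, loadings = L, communality = communality,
         uniqueness = 1 - communality, scores = scores,
         eigenvalues = vals, retain_threshold = retain_threshold,
         assignment = apply(abs(L), 1, which.max),
         center = mu, scale = sdv, transform = W),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, digits = 2, ...) {
  cat(sprintf("Factor model: %d factors retained (eigenvalue > %g)\n",
              x$m, x$retain_threshold))
  tab <- cbind(round(x$loadings, digits),
               Communality = round(x$communality, digits),
               Uniqueness = round(x$uniqueness, digits))
  print(tab, ...)
  cat(sprintf("Average communality: %.2f\n", mean(x$communality)))
  invisible(x)
}

#' Factor scores of the ideotype
#'
#' The ideotype attains the rescaled value 100 in every trait (the desired
#' extreme under each trait's sense). Its factor scores use exactly the
#' standardization and regression transform of the fitted model.
#'
#' @param rx the [rescale_traits()] matrix the model was fitted on.
#' @param model the [fit_factor_model()] fit.
#' @return numeric vector of length `model$m`.
#' @export
build_ideotype <- function(rx, model) {
  ideal <- rep(100, ncol(rx))
  z <- (ideal - model$center) / model$scale
  as.numeric(z %*% model$transform)
}

#' Genotype-ideotype distance (MGIDI values)
#'
#' Euclidean distance between each genotype's rotated factor scores and the
#' ideotype scores; smaller means closer to the ideal.
#'
#' @param model a [fit_factor_model()] fit.
#' @param ideotype ideotype factor scores from [build_ideotype()].
#' @return named non-negative numeric vector, one value per genotype.
#' @export
mgidi_index <- function(model, ideotype) {
  if (length(ideotype) != model$m) {
    stop("ideotype and factor scores must share the factor dimension", call. = FALSE)
  }
  dev <- sweep(model$scores, 2, ideotype)
  stats::setNames(sqrt(rowSums(dev^2)), rownames(model$scores))
}

#' Select genotypes by index value
#'
#' Sorts ascending by index (smallest distance is best) and retains
#' `round(alpha/100 * n)` genotypes, at least 1. Ties break by genotype ID,
#' so selection is deterministic.
#'
#' @param index named per-genotype index values.
#' @param alpha selection intensity in percent, in `(0, 100]`.
#' @return character vector of selected genotype IDs (best first).
#' @export
#' @examples
#' select_genotypes(c(a = 3, b = 1, c = 2, d = 5), alpha = 50)
select_genotypes <- function(index, alpha) {
  if (alpha <= 0 || alpha > 100) stop("`alpha` must be in (0, 100]", call. = FALSE)
  n_sel <- max(1L, round(alpha / 100 * length(index)))
  ord <- order(index, names(index))
  names(index)[ord][seq_len(n_sel)]
}

#' Predicted selection gains
#'
#' Per-trait expected response to selection on original trait units:
#' \deqn{SG_t\% = \frac{\bar X_{s,t} - \bar X_{o,t}}{\bar X_{o,t}} h^2_t
#'   \times 100,} where \eqn{\bar X_s} is the mean of the selected genotypes
#' and \eqn{\bar X_o} the mean of all genotypes. Totals are reported split
#' by desired selection sense.
#'
#' @param means a [genotype_means()] matrix (original units).
#' @param selected character vector of selected genotype IDs.
#' @param h2 named per-trait heritability in `[0, 1]`.
#' @param specs trait specs (for senses); default taken from `means`.
#' @return object of class `selection_gains`: data frame with columns
#'   `trait`, `mean_all`, `mean_selected`, `h2`, `sg_pct`, `sense`; totals
#'   by sense as attributes `total_increase`, `total_decrease`.
#' @export
selection_gains <- function(means, selected, h2, specs = NULL) {
  M <- unclass(means)
  specs <- specs %||% attr(means, "traits")
  if (length(selected) == 0) stop("`selected` must be non-empty", call. = FALSE)
  if (!all(selected %in% rownames(M))) stop("unknown selected genotype(s)", call. = FALSE)
  if (any(h2 < 0 | h2 > 1, na.rm = TRUE)) stop("`h2` must lie in [0, 1]", call. = FALSE)
  nm <- colnames(M)
  h2 <- h2[nm]
  senses <- trait_senses(specs)[nm]
  mean_all <- colMeans(M, na.rm = TRUE)
  mean_sel <- colMeans(M[selected, , drop = FALSE], na.rm = TRUE)
  sg <- ifelse(mean_all == 0, NA_real_,
               (mean_sel - mean_all) / mean_all * h2 * 100)
  if (anyNA(sg) && any(mean_all == 0)) {
    warning("selection gain undefined for trait(s) with zero population mean",
            call. = FALSE)
  }
  out <- data.frame(
    trait = nm, mean_all = mean_all, mean_selected = mean_sel,
    h2 = as.numeric(h2), sg_pct = sg, sense = senses,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            total_increase = sum(sg[senses == "increase"], na.rm = TRUE),
            total_decrease = sum(sg[senses == "decrease"], na.rm = TRUE),
            class = c("selection_gains", "data.frame"))
}

#' @export
print.selection_gains <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE, ...)
  cat(sprintf("Total gain (increase-sense traits): %.2f%%\n",
              attr(x, "total_increase")))
  if (any(x$sense == "decrease")) {
    cat(sprintf("Total gain (decrease-sense traits): %.2f%%\n",
                attr(x, "total_decrease")))
  }
  invisible(x)
}

#' Per-factor strengths and weaknesses
#'
#' Splits each genotype's squared genotype-ideotype distance across factors:
#' \deqn{\theta_{if} = (\gamma_{if} - \gamma^I_f)^2 /
#'   \sum_k (\gamma_{ik} - \gamma^I_k)^2.} Proportions per genotype sum to
#' 1; a small proportion on a factor means the genotype is close to the
#' ideotype on that factor's traits (a strength). A genotype sitting exactly
#' at the ideotype has undefined proportions and is reported uniform, with
#' its ID recorded in attribute `undefined`.
#'
#' @param model a [fit_factor_model()] fit.
#' @param ideotype ideotype factor scores.
#' @param genotypes genotype IDs to report (default all).
#' @return genotype x factor matrix of proportions, class
#'   `factor_contributions`.
#' @export
strengths_weaknesses <- function(model, ideotype, genotypes = NULL) {
  genotypes <- genotypes %||% rownames(model$scores)
  if (!all(genotypes %in% rownames(model$scores))) {
    stop("unknown genotype(s)", call. = FALSE)
  }
  dev2 <- sweep(model$scores[genotypes, , drop = FALSE], 2, ideotype)^2
  tot <- rowSums(dev2)
  undef <- names(tot)[tot == 0]
  prop <- dev2 / ifelse(tot == 0, 1, tot)
  prop[tot == 0, ] <- 1 / model$m
  if (length(undef)) {
    warning("genotype(s) at the ideotype: uniform factor proportions reported for ",
            paste(undef, collapse = ", "), call. = FALSE)
  }
  structure(prop, undefined = undef, class = c("factor_contributions", "matrix"))
}

#' Multitrait genotype-ideotype distance index (MGIDI)
#'
#' Fits the full MGIDI selection analysis to a replicated trial: (i) trait
#' means per genotype are rescaled to a directed 0-100 scale, (ii) an
#' exploratory factor analysis with varimax rotation reduces the rescaled
#' traits to `m` factors, (iii) an ideotype is scored as the (rescaled)
#' best value in every trait, and (iv) genotypes are ranked by Euclidean
#' distance to the ideotype in factor-score space and the closest
#' `alpha` percent are selected. Predicted selection gains use per-trait
#' broad-sense heritability estimated from the trial's RCBD ANOVA (or
#' supplied directly when `x` is a plain matrix of genotype means).
#'
#' @param x a [trial_table()] (preferred: heritabilities are estimated from
#'   the replicated data), or a [genotype_means()] matrix with `h2` given.
#' @param alpha selection intensity in percent; default 15.
#' @param divisor heritability divisor passed to [variance_summary()];
#'   default the number of genotypes.
#' @param retain_threshold eigenvalue retention cutoff for the factor model.
#' @param specs trait specifications (senses); default those attached to `x`.
#' @param h2 named per-trait heritability, required when `x` is not a
#'   `trial_table`.
#' @return object of class `mgidi`: list with `index` (named MGIDI values),
#'   `ranking` (data frame genotype/index/rank/selected), `selected`,
#'   `model` (the [fit_factor_model()] fit), `ideotype` (factor scores),
#'   `gains` ([selection_gains()]), `contributions`
#'   ([strengths_weaknesses()] of the selected set), `means`, `rescaled`,
#'   `h2`, `alpha`, `divisor`.
#' @seealso [predict.mgidi()], [plot.mgidi()]
#' @export
#' @examples
#' trial <- simulate_trial(demo_trial_config(seed = 1))
#' fit <- mgidi(trial, alpha = 15)
#' fit
#' head(fit$ranking)
mgidi <- function(x, alpha = 15, divisor = NULL, retain_threshold = 1.0,
                  specs = NULL, h2 = NULL) {
  if (inherits(x, "trial_table")) {
    means <- genotype_means(x)
    vs <- variance_summary(x, divisor = divisor)
    h2 <- stats::setNames(vs$h2, vs$trait)
    divisor <- attr(vs, "divisor")
  } else {
    means <- x
    if (is.null(h2)) stop("`h2` must be supplied when `x` is not a trial_table",
                          call. = FALSE)
    if (is.null(names(h2))) stop("`h2` must be named by trait", call. = FALSE)
  }
  specs <- specs %||% attr(means, "traits")
  rx <- rescale_traits(means, specs)
  model <- fit_factor_model(rx, retain_threshold = retain_threshold)
  ideo <- build_ideotype(rx, model)
  index <- mgidi_index(model, ideo)
  selected <- select_genotypes(index, alpha)
  ord <- order(index, names(index))
  ranking <- data.frame(
    genotype = names(index)[ord],
    mgidi = as.numeric(index)[ord],
    rank = seq_along(index),
    selected = names(index)[ord] %in% selected,
    stringsAsFactors = FALSE
  )
  gains <- selection_gains(means, selected, h2, specs)
  contrib <- strengths_weaknesses(model, ideo, selected)
  structure(
    list(index = index, ranking = ranking, selected = selected,
         model = model, ideotype = ideo, gains = gains,
         contributions = contrib, means = means, rescaled = rx,
         h2 = h2, alpha = alpha, divisor = divisor,
         call = match.call()),
    class = "mgidi"
  )
}

#' @export
print.mgidi <- function(x, ...) {
  cat("Multitrait genotype-ideotype distance index (MGIDI)\n")
  cat(sprintf("  %d genotypes, %d traits, %d factors retained\n",
              nrow(x$means), ncol(x$means), x$model$m))
  cat(sprintf("  Selection intensity: %g%% -> %d genotypes selected\n",
              x$alpha, length(x$selected)))
  cat("  Selected (best first): ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat(sprintf("  Total predicted gain, increase-sense traits: %.2f%%\n",
              attr(x$gains, "total_increase")))
  invisible(x)
}

#' @export
summary.mgidi <- function(object, ...) {
  cat("Call: ")
  print(object$call)
  print(object)
  cat("\nRotated loadings, communality and uniqueness:\n")
  print(object$model, ...)
  cat("\nPredicted selection gains:\n")
  print(object$gains, ...)
  cat("\nFactor contributions of selected genotypes (share of squared distance):\n")
  print(round(unclass(object$contributions), 3))
  invisible(object)
}

#' @export
coef.mgidi <- function(object, ...) object$model$loadings

#' Score new genotype means against a fitted MGIDI model
#'
#' Rescales new genotype means with the training ranges and senses, applies
#' the fitted standardization and factor-score transform, and returns the
#' distance to the fitted ideotype. Values outside the training range
#' extrapolate linearly (and may rescale outside 0-100).
#'
#' @param object a fitted [mgidi()] object.
#' @param newdata genotype x trait numeric matrix with the training traits.
#' @param ... unused.
#' @return named numeric vector of MGIDI values for the new genotypes.
#' @export
predict.mgidi <- function(object, newdata, ...) {
  M <- as.matrix(newdata)
  nm <- colnames(object$means)
  if (!all(nm %in% colnames(M))) stop("`newdata` must contain the training traits", call. = FALSE)
  M <- M[, nm, drop = FALSE]
  lo <- attr(object$rescaled, "orig_min")
  hi <- attr(object$rescaled, "orig_max")
  senses <- attr(object$rescaled, "senses")
  RX <- M
  for (j in seq_along(nm)) {
    p <- (M[, j] - lo[j]) / (hi[j] - lo[j])
    RX[, j] <- if (senses[j] == "increase") 100 * p else 100 * (1 - p)
  }
  Z <- scale(RX, center = object$model$center, scale = object$model$scale)
  scores <- Z %*% object$model$transform
  dev <- sweep(scores, 2, object$ideotype)
  stats::setNames(sqrt(rowSums(dev^2)), rownames(M))
}

#' Plot MGIDI genotype ranking
#'
#' Dot plot of genotypes ordered by index value with the selection cut
#' point; selected genotypes are highlighted.
#'
#' @param x a fitted [mgidi()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mgidi <- function(x, ...) {
  rk <- x$ranking
  graphics::plot(rk$rank, rk$mgidi, pch = 19,
                 col = ifelse(rk$selected, "red", "black"),
                 xlab = "Rank", ylab = "MGIDI (distance to ideotype)", ...)
  cut <- max(rk$mgidi[rk$selected])
  graphics::abline(h = cut, lty = 2, col = "red")
  graphics::text(rk$rank[rk$selected], rk$mgidi[rk$selected],
                 labels = rk$genotype[rk$selected], pos = 4, cex = 0.7)
  invisible(x)
}
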