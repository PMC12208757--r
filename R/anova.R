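#' Per-trait randomized complete block ANOVA
#'
#' Fits, for each trait, the two-way fixed-effects decomposition
#' \deqn{Y_{ij} = \mu + G_i + B_j + \varepsilon_{ij}} by least squares with
#' sequential (block-then-genotype) sums of squares. For balanced data this
#' reduces to the classical RCBD decomposition with
#' `df_genotype = n_genotypes - 1`, `df_block = n_blocks - 1` and
#' `df_residual = (n_genotypes - 1)(n_blocks - 1)`, and
#' `F_genotype = MSg / MSe`. Genotypes observed in fewer than two blocks
#' trigger a warning; degrees of freedom adjust automatically through the
#' least-squares fit.
#'
#' @param trial a [trial_table()].
#' @param traits character vector of trait names to analyse (default: all).
#' @return an object of class `rcbd_anova`: a data frame with one row per
#'   trait and columns `trait`, `df_block`, `df_genotype`, `df_residual`,
#'   `ms_block`, `ms_genotype`, `ms_residual`, `f_block`, `p_block`,
#'   `f_genotype`, `p_genotype`, `sig_block`, `sig_genotype`, `mean`, `min`,
#'   `max`, `cv_pct`.
#' @export
#' @examples
#' trial <- simulate_trial(demo_trial_config(seed = 1))
#' aov_tab <- rcbd_anova(trial)
#' head(aov_tab)
rcbd_anova <- function(trial, traits = NULL) {
  if (!inherits(trial, "trial_table")) stop("`trial` must be a trial_table", call. = FALSE)
  specs <- attr(trial, "traits")
  all_traits <- trait_names(specs)
  traits <- traits %||% all_traits
  unknown <- setdiff(traits, all_traits)
  if (length(unknown)) {
    stop("trait(s) not present in trial: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(trial$block)) < 2 || length(unique(trial$genotype)) < 2) {
    stop("need at least 2 blocks and 2 genotypes", call. = FALSE)
  }
  rows <- lapply(traits, function(t) fit_one_rcbd(trial, t))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_blocks = length(unique(trial$block)),
            n_genotypes = length(unique(trial$genotype)),
            class = c("rcbd_anova", "data.frame"))
}

fit_one_rcbd <- function(trial, trait) {
  d <- data.frame(
    y = trial[[trait]],
    genotype = factor(trial$genotype),
    block = factor(trial$block)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  per_geno <- table(d$genotype)
  if (any(per_geno < 2)) {
    warning(sprintf("trait %s: genotype(s) observed in fewer than 2 blocks: %s",
                    trait, paste(names(per_geno)[per_geno < 2], collapse = ", ")),
            call. = FALSE)
  }
  fit <- stats::lm(y ~ block + genotype, data = d)
  # perfect fits are handled explicitly below; silence lm's own complaint
  at <- withCallingHandlers(
    stats::anova(fit), # sequential: block, genotype, Residuals
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  ms <- at$`Mean Sq`
  df <- at$Df
  f_b <- at$`F value`[1]
  p_b <- at$`Pr(>F)`[1]
  f_g <- at$`F value`[2]
  p_g <- at$`Pr(>F)`[2]
  # degenerate cases (detected at numerical tolerance): with zero residual MS
  # a zero effect MS carries no evidence (F undefined, reported ns, p = 1); a
  # positive effect MS fits perfectly (p = 0)
  eps <- 1e-12 * (abs(mean(d$y)) + 1)^2
  if (!is.finite(ms[3]) || ms[3] < eps) {
    if (ms[1] < eps || !is.finite(f_b)) { f_b <- NA_real_; p_b <- 1 }
    else { f_b <- Inf; p_b <- 0 }
    if (ms[2] < eps || !is.finite(f_g)) { f_g <- NA_real_; p_g <- 1 }
    else { f_g <- Inf; p_g <- 0 }
  }
  data.frame(
    trait = trait,
    df_block = df[1], df_genotype = df[2], df_residual = df[3],
    ms_block = ms[1], ms_genotype = ms[2], ms_residual = ms[3],
    f_block = f_b, p_block = p_b, f_genotype = f_g, p_genotype = p_g,
    sig_block = sig_stars(p_b), sig_genotype = sig_stars(p_g),
    mean = mean(d$y), min = min(d$y), max = max(d$y),
    cv_pct = if (mean(d$y) > 0) 100 * sqrt(ms[3]) / mean(d$y) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.rcbd_anova <- function(x, digits = 3, ...) {
  cat(sprintf("RCBD ANOVA: %d traits, %d genotypes, %d blocks\n",
              nrow(x), attr(x, "n_genotypes"), attr(x, "n_blocks")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Expected-mean-square variance components
#'
#' Equates the observed genotype and residual mean squares of a balanced
#' RCBD to their expectations: \eqn{\sigma^2_g = (MS_g - MS_e)/r} with
#' \eqn{r} the number of blocks, truncated at zero (with a warning) when
#' \eqn{MS_g < MS_e}, and \eqn{\sigma^2_p = \sigma^2_g + MS_e}.
#'
#' @param ms_genotype genotype mean square.
#' @param ms_residual residual mean square.
#' @param n_blocks number of complete blocks `r` (>= 2).
#' @return named numeric vector `c(sigma2_g, sigma2_p)`.
#' @export
#' @examples
#' variance_components(0.62, 0.07, 3) # sigma2_g ~ 0.18
variance_components <- function(ms_genotype, ms_residual, n_blocks) {
  stopifnot_scalar_count(n_blocks, "n_blocks", min = 2)
  if (ms_genotype < 0 || ms_residual < 0) {
    stop("mean squares must be non-negative", call. = FALSE)
  }
  s2g <- (ms_genotype - ms_residual) / n_blocks
  if (s2g < 0) {
    warning("negative genotypic variance estimate truncated at 0", call. = FALSE)
    s2g <- 0
  }
  c(sigma2_g = s2g, sigma2_p = s2g + ms_residual)
}

#' Broad-sense heritability
#'
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_p / d)} clamped to
#' `[0, 1]`. The divisor `d` is an explicit parameter: the shipped analyses
#' use the number of genotypes (the convention under which the published
#' worked examples reproduce), but the conventional number of replicates can
#' be passed instead.
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param sigma2_p phenotypic variance (>= `sigma2_g`).
#' @param divisor positive count `d`.
#' @return heritability in `[0, 1]`; `NA` with a warning when both variances
#'   are zero.
#' @export
#' @examples
#' heritability(1.18, 7.16, 42) # ~0.87
heritability <- function(sigma2_g, sigma2_p, divisor) {
  stopifnot_scalar_count(divisor, "divisor", min = 1)
  if (any(sigma2_g < 0) || any(sigma2_p < sigma2_g)) {
    stop("need sigma2_p >= sigma2_g >= 0", call. = FALSE)
  }
  h2 <- ifelse(sigma2_g == 0 & sigma2_p == 0, NA_real_,
               sigma2_g / (sigma2_g + sigma2_p / divisor))
  if (anyNA(h2)) {
    warning("heritability undefined where both variances are zero", call. = FALSE)
  }
  # zero genetic variance with positive phenotypic variance is exactly 0
  h2[!is.na(h2) & sigma2_g == 0] <- 0
  pmin(pmax(h2, 0), 1)
}

#' Coefficient of variation from a variance component
#'
#' \eqn{\sqrt{v} / \bar{x}}, returned as a proportion. Applied to the
#' genotypic variance it gives the GCV, to the phenotypic variance the PCV,
#' and to the residual mean square the experimental CV.
#'
#' @param variance non-negative variance (trait units squared).
#' @param grand_mean positive grand mean (trait units).
#' @param percent if `TRUE`, return the value multiplied by 100.
#' @return coefficient of variation (proportion, or percent).
#' @export
#' @examples
#' coefficient_of_variation(0.1, 1.37)           # GCV ~ 0.23
#' coefficient_of_variation(9.28, 19.46, TRUE)   # CV% ~ 15.65
coefficient_of_variation <- function(variance, grand_mean, percent = FALSE) {
  if (any(variance < 0)) stop("`variance` must be non-negative", call. = FALSE)
  if (any(grand_mean <= 0)) stop("`grand_mean` must be positive", call. = FALSE)
  cv <- sqrt(variance) / grand_mean
  if (percent) 100 * cv else cv
}

#' Variance components, heritability and coefficients of variation per trait
#'
#' Combines [rcbd_anova()], [variance_components()], [heritability()] and
#' [coefficient_of_variation()] into the per-trait genetic-parameter summary
#' of a trial, with the conventional low/intermediate/high classifications.
#'
#' @param trial a [trial_table()] (or an `rcbd_anova` object, in which case
#'   `n_blocks` is taken from it).
#' @param divisor heritability divisor; default the number of genotypes.
#' @return an object of class `variance_summary`: data frame with columns
#'   `trait`, `sigma2_g`, `sigma2_p`, `h2`, `gcv`, `pcv`, `cv_pct`, `mean`,
#'   `gcv_class`, `pcv_class`, `h2_class`.
#' @export
#' @examples
#' trial <- simulate_trial(demo_trial_config(seed = 1))
#' variance_summary(trial)
variance_summary <- function(trial, divisor = NULL) {
  if (inherits(trial, "rcbd_anova")) {
    av <- trial
  } else {
    av <- rcbd_anova(trial)
  }
  r <- attr(av, "n_blocks")
  n_g <- attr(av, "n_genotypes")
  divisor <- divisor %||% n_g
  comps <- t(mapply(function(msg, mse) variance_components(msg, mse, r),
                    av$ms_genotype, av$ms_residual))
  s2g <- comps[, "sigma2_g"]
  s2p <- comps[, "sigma2_p"]
  h2 <- suppressWarnings(heritability(s2g, s2p, divisor))
  gcv <- coefficient_of_variation(s2g, av$mean)
  pcv <- coefficient_of_variation(s2p, av$mean)
  out <- data.frame(
    trait = av$trait,
    sigma2_g = s2g, sigma2_p = s2p, h2 = h2,
    gcv = gcv, pcv = pcv,
    cv_pct = av$cv_pct, mean = av$mean,
    gcv_class = classify_variability(100 * gcv, "gcv_pcv"),
    pcv_class = classify_variability(100 * pcv, "gcv_pcv"),
    h2_class = ifelse(is.na(h2), NA_character_,
                      classify_variability(100 * ifelse(is.na(h2), 0, h2), "heritability")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, divisor = divisor, n_blocks = r,
            class = c("variance_summary", "data.frame"))
}

#' @export
print.variance_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Variance components and heritability (divisor = %d)\n",
              attr(x, "divisor")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
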