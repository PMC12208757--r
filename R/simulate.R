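#' Configure a synthetic randomized complete block trial
#'
#' Defines the generating model for a multitrait RCBD phenotype simulation:
#' \deqn{Y_{ijt} = \mu_t + g_{it} + b_{jt} + e_{ijt}}
#' with genotype effects \eqn{g_i \sim MVN(0, \Sigma_g)} drawn once per trial
#' (and thereafter treated as fixed, as genotypes are in the analysis model),
#' per-trait block effects \eqn{b_{jt} \sim N(0, \mathrm{block\_sd}_t^2)} and
#' plot residuals \eqn{e_{ij} \sim MVN(0, \Sigma_e)}.
#'
#' @param n_genotypes number of genotypes (>= 3).
#' @param n_blocks number of complete blocks (>= 2).
#' @param traits named list of [trait_spec()] objects, one per trait.
#' @param trait_means numeric vector of population means, one per trait.
#' @param genetic_cov positive semidefinite genotypic covariance matrix
#'   (trait units squared), dimension = number of traits.
#' @param block_sd per-trait standard deviation of block effects (scalar or
#'   vector of length = number of traits).
#' @param residual_cov positive definite residual (plot error) covariance.
#' @param seed integer seed; mandatory so a configuration pins its data.
#' @param missing_fraction fraction of plots masked (set to `NA` across all
#'   traits) at random, to exercise unbalanced-data handling. Default 0.
#' @param clip_range optional named list `trait -> c(lo, hi)`; generated
#'   values are clipped post hoc. Off by default because clipping biases
#'   variance-component recovery.
#' @return an object of class `trial_config`.
#' @seealso [simulate_trial()], [demo_trial_config()]
#' @export
trial_config <- function(n_genotypes, n_blocks, traits, trait_means,
                         genetic_cov, block_sd, residual_cov, seed,
                         missing_fraction = 0, clip_range = NULL) {
  stopifnot_scalar_count(n_genotypes, "n_genotypes", min = 3)
  stopifnot_scalar_count(n_blocks, "n_blocks", min = 2)
  stopifnot_scalar_count(seed, "seed", min = 0)
  if (!is.list(traits) || !all(vapply(traits, inherits, logical(1), "trait_spec"))) {
    stop("`traits` must be a list of trait_spec objects", call. = FALSE)
  }
  k <- length(traits)
  nm <- trait_names(traits)
  if (anyDuplicated(nm)) stop("trait names must be unique", call. = FALSE)
  names(traits) <- nm
  if (length(trait_means) != k) {
    stop("`trait_means` length must equal the number of traits", call. = FALSE)
  }
  genetic_cov <- as.matrix(genetic_cov)
  residual_cov <- as.matrix(residual_cov)
  for (mat in list(genetic = genetic_cov, residual = residual_cov)) NULL
  if (!all(dim(genetic_cov) == k)) {
    stop("`genetic_cov` dimension must match the number of traits", call. = FALSE)
  }
  if (!all(dim(residual_cov) == k)) {
    stop("`residual_cov` dimension must match the number of traits", call. = FALSE)
  }
  # validate factorizability up front so errors name the offending matrix
  mat_sqrt(genetic_cov, "genetic_cov")
  mat_sqrt(residual_cov, "residual_cov")
  block_sd <- rep_len(block_sd, k)
  if (any(block_sd < 0)) stop("`block_sd` must be non-negative", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_genotypes = as.integer(n_genotypes), n_blocks = as.integer(n_blocks),
      traits = traits,
      trait_means = stats::setNames(as.numeric(trait_means), nm),
      genetic_cov = `dimnames<-`(genetic_cov, list(nm, nm)),
      block_sd = stats::setNames(block_sd, nm),
      residual_cov = `dimnames<-`(residual_cov, list(nm, nm)),
      seed = as.integer(seed),
      missing_fraction = missing_fraction,
      clip_range = clip_range
    ),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("<trial_config: %d genotypes x %d blocks, %d traits, seed %d>\n",
              x$n_genotypes, x$n_blocks, length(x$traits), x$seed))
  invisible(x)
}

#' Construct a plot-level trial table
#'
#' A trial table is a long-format data frame with one row per plot
#' (genotype x block) and one column per trait, carrying the trait
#' specifications as an attribute. Invariants are checked: no duplicated
#' (genotype, block) pair, and trait values finite or `NA`.
#'
#' @param data data.frame with columns `genotype`, `block` and one numeric
#'   column per trait.
#' @param traits named list of [trait_spec()] matching the trait columns.
#' @return the data, classed `trial_table`.
#' @export
trial_table <- function(data, traits) {
  if (!all(c("genotype", "block") %in% names(data))) {
    stop("`data` must have `genotype` and `block` columns", call. = FALSE)
  }
  nm <- trait_names(traits)
  missing_cols <- setdiff(nm, names(data))
  if (length(missing_cols)) {
    stop("trait columns absent from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data[c("genotype", "block")])) {
    stop("duplicated (genotype, block) pair in trial data", call. = FALSE)
  }
  for (t in nm) {
    v <- data[[t]]
    if (!is.numeric(v) || any(is.infinite(v) | is.nan(v))) {
      stop(sprintf("trait `%s` must be numeric with finite or NA values", t),
           call. = FALSE)
    }
  }
  data$genotype <- as.character(data$genotype)
  data$block <- as.character(data$block)
  structure(data[, c("genotype", "block", nm)],
            traits = traits, class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Trial table: %d plots, %d genotypes, %d blocks, %d traits\n",
              nrow(x), length(unique(x$genotype)), length(unique(x$block)),
              length(attr(x, "traits"))))
  NextMethod()
}

#' Simulate a multitrait RCBD trial
#'
#' Draws a complete trial from the generating model in [trial_config()].
#' Identical configurations (including seed) produce identical tables. The
#' realized genotype effects, block effects and population means are attached
#' as attributes (`genotype_effects`, `block_effects`, `mu`) so that
#' parameter-recovery checks can condition on the drawn effects.
#'
#' @param config a [trial_config()].
#' @return a [trial_table()] with `n_genotypes * n_blocks` rows.
#' @export
#' @examples
#' cfg <- demo_trial_config(seed = 1)
#' trial <- simulate_trial(cfg)
#' dim(trial)
simulate_trial <- function(config) {
  if (!inherits(config, "trial_config")) stop("`config` must be a trial_config", call. = FALSE)
  n <- config$n_genotypes
  r <- config$n_blocks
  nm <- names(config$traits)
  k <- length(nm)
  set.seed(config$seed)
  g <- rmvn0(n, config$genetic_cov, "genetic_cov")            # n x k
  b <- sapply(seq_len(k), function(t) stats::rnorm(r, 0, config$block_sd[t])) # r x k
  b <- matrix(b, nrow = r, ncol = k)
  e <- rmvn0(n * r, config$residual_cov, "residual_cov")      # (n*r) x k
  gid <- sprintf("G%02d", seq_len(n))
  bid <- sprintf("B%d", seq_len(r))
  idx_g <- rep(seq_len(n), times = r)
  idx_b <- rep(seq_len(r), each = n)
  Y <- matrix(config$trait_means, n * r, k, byrow = TRUE) +
    g[idx_g, , drop = FALSE] + b[idx_b, , drop = FALSE] + e
  colnames(Y) <- nm
  if (!is.null(config$clip_range)) {
    for (t in intersect(names(config$clip_range), nm)) {
      rng <- config$clip_range[[t]]
      Y[, t] <- pmin(pmax(Y[, t], rng[1]), rng[2])
    }
  }
  dat <- data.frame(genotype = gid[idx_g], block = bid[idx_b], Y,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (config$missing_fraction > 0) {
    n_mask <- floor(config$missing_fraction * nrow(dat))
    if (n_mask > 0) {
      mask <- sample(nrow(dat), n_mask)
      dat[mask, nm] <- NA_real_
    }
  }
  out <- trial_table(dat, config$traits)
  attr(out, "genotype_effects") <- `dimnames<-`(g, list(gid, nm))
  attr(out, "block_effects") <- `dimnames<-`(b, list(bid, nm))
  attr(out, "mu") <- config$trait_means
  out
}

#' Heritability implied by a simulation configuration
#'
#' Closed-form broad-sense heritability of the generating model,
#' \eqn{H^2_t = \sigma^2_{g,t} / (\sigma^2_{g,t} + \sigma^2_{p,t}/d)} with
#' \eqn{\sigma^2_{p,t} = \sigma^2_{g,t} + \sigma^2_{e,t}}, used as the oracle
#' for recovery tests of the estimation pipeline.
#'
#' @param config a [trial_config()].
#' @param divisor positive count `d` (commonly the number of genotypes).
#' @return named numeric vector of per-trait heritabilities in `[0, 1]`.
#' @export
implied_heritability <- function(config, divisor) {
  if (!inherits(config, "trial_config")) stop("`config` must be a trial_config", call. = FALSE)
  stopifnot_scalar_count(divisor, "divisor", min = 1)
  s2g <- diag(config$genetic_cov)
  s2p <- s2g + diag(config$residual_cov)
  h2 <- ifelse(s2g == 0 & s2p == 0, 0, s2g / (s2g + s2p / divisor))
  stats::setNames(pmin(pmax(h2, 0), 1), names(config$traits))
}

#' Demonstration trial configuration (42 genotypes x 3 blocks x 10 traits)
#'
#' The shipped demonstration configuration emulates a published tiger nut
#' evaluation trial: 42 genotypes in 3 complete blocks, with the 10 agronomic
#' and tuber-yield traits PG (percentage germination), NT (tillers per
#' plant), DTP (distance of last tiller to the mother plant), PH (plant
#' height), NTS (tubers per stand), NRT (rings per tuber), LT (tuber length),
#' WT (tuber width), TS (tuber shape, length/width ratio) and HTW (hundred
#' tuber weight). Trait means and residual variances follow the trial's
#' published summary statistics, genotypic variances its reported variance
#' components (implied heritabilities span roughly 0.84-0.98), block
#' variances are backed out of the reported block mean squares, and the
#' genetic correlation matrix encodes the reported sign pattern among traits
#' at moderate magnitude.
#'
#' @param seed integer seed for [simulate_trial()].
#' @param missing_fraction passed to [trial_config()].
#' @return a [trial_config()].
#' @export
demo_trial_config <- function(seed = 42, missing_fraction = 0) {
  st <- published_trial_summary()
  nm <- st$trait
  s2g <- stats::setNames(st$sigma2_g, nm)
  s2e <- stats::setNames(st$ms_residual, nm)
  block_var <- pmax(0, (st$ms_block - st$ms_residual) / 42)
  Rg <- demo_genetic_correlation(nm)
  Sg <- (sqrt(s2g) %o% sqrt(s2g)) * Rg
  Se <- diag(s2e)
  dimnames(Se) <- list(nm, nm)
  trial_config(
    n_genotypes = 42, n_blocks = 3,
    traits = trait_spec_list(nm, units = st$units, sense = "increase"),
    trait_means = stats::setNames(st$mean, nm),
    genetic_cov = Sg,
    block_sd = sqrt(block_var),
    residual_cov = Se,
    seed = seed,
    missing_fraction = missing_fraction
  )
}

# published per-trait summary statistics of the demonstration trial:
# block/genotype/residual mean squares, grand mean, and genotypic variance
published_trial_summary <- function() {
  data.frame(
    trait = c("DTP", "HTW", "LT", "NRT", "NT", "NTS", "PG", "PH", "TS", "WT"),
    units = c("cm", "g", "mm", "count", "count", "count", "%", "cm", "", "mm"),
    ms_block = c(49.72, 1.64, 271.82, 0.10, 274.65, 3230.89, 1736.89, 1569.56, 0.21, 60.94),
    ms_genotype = c(9.528, 4554.42, 76.12, 0.62, 53.72, 504.74, 1323.49, 806.06, 0.36, 11.33),
    ms_residual = c(4.91, 0.06, 9.28, 0.07, 16.88, 306.83, 465.13, 303.21, 0.06, 1.45),
    mean = c(9.45, 133.46, 19.46, 5.75, 13.09, 39, 70.04, 91.77, 1.37, 14.22),
    sigma2_g = c(1.18, 1520, 20.19, 0.18, 10.23, 42.76, 276, 157.6, 0.1, 2.82),
    stringsAsFactors = FALSE
  )
}

# genetic correlation matrix for the demo: starred pairwise associations of
# the source trial at moderate magnitude, 0.1 elsewhere; eigenvalue-clipped
# to guarantee a valid correlation matrix
demo_genetic_correlation <- function(nm) {
  k <- length(nm)
  R <- matrix(0.1, k, k, dimnames = list(nm, nm))
  diag(R) <- 1
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("HTW", "TS", 0.55); set_r("HTW", "LT", 0.55); set_r("HTW", "WT", 0.50)
  set_r("HTW", "NT", 0.50); set_r("HTW", "DTP", 0.50); set_r("HTW", "PH", 0.50)
  set_r("PG", "DTP", 0.50); set_r("PG", "PH", 0.50)
  set_r("NTS", "PH", 0.45); set_r("NTS", "DTP", 0.45); set_r("NTS", "NT", 0.55)
  set_r("NT", "PH", 0.55); set_r("NT", "DTP", 0.55)
  set_r("PH", "DTP", 0.60)
  set_r("WT", "NRT", 0.45)
  set_r("TS", "LT", 0.50); set_r("TS", "WT", -0.20)
  as_correlation(R)
}

#' Write / read a trial table as CSV with a trait-metadata sidecar
#'
#' The CSV has columns `genotype,block,<trait1>,...,<traitK>`; trait
#' metadata (name, units, sense) goes to a JSON sidecar next to it.
#'
#' @param trial a [trial_table()].
#' @param path CSV file path; the sidecar is `<path>.traits.json`.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   a [trial_table()].
#' @export
write_trial <- function(trial, path) {
  if (!inherits(trial, "trial_table")) stop("`trial` must be a trial_table", call. = FALSE)
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  specs <- attr(trial, "traits")
  meta <- lapply(specs, function(s) list(name = s$name, units = s$units, sense = s$sense))
  jsonlite::write_json(unname(meta), paste0(path, ".traits.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trial
#' @param path CSV file written by [write_trial()].
#' @export
read_trial <- function(path) {
  dat <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed CSV `%s`: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  sidecar <- paste0(path, ".traits.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    specs <- lapply(meta, function(m) trait_spec(m$name, m$units %||% "", m$sense %||% "increase"))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  } else {
    nm <- setdiff(names(dat), c("genotype", "block"))
    specs <- trait_spec_list(nm)
  }
  trial_table(dat, specs)
}
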