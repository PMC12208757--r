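#' Configure a full analysis run
#'
#' Bundles every tunable of the pipeline: exactly one of `input` (a trial
#' CSV written by [write_trial()]) or `simulate` (a [trial_config()]) must
#' be given. Remaining options mirror the stage functions.
#'
#' @param input path to a trial CSV, or `NULL`.
#' @param simulate a [trial_config()], or `NULL`.
#' @param alpha selection intensity in percent (default 15).
#' @param divisor heritability divisor (default: number of genotypes).
#' @param linkage clustering linkage (default `"average"`).
#' @param k_range candidate cluster counts (default `2:min(10, n-1)`).
#' @param retain_threshold factor/component retention cutoff (default 1.0).
#' @param path_dependents traits used as dependents in path analysis
#'   (default: intersect of `c("HTW", "NTS")` with the traits, else none).
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param seed master seed; per-stage seeds derive from it.
#' @param log_level `"info"` (log defaulted decisions) or `"quiet"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, alpha = 15,
                       divisor = NULL, linkage = "average", k_range = NULL,
                       retain_threshold = 1.0, path_dependents = NULL,
                       out_dir, seed = 1, log_level = c("info", "quiet")) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of `input` or `simulate` must be given", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 100) stop("`alpha` must be in (0, 100]", call. = FALSE)
  if (retain_threshold < 0) stop("`retain_threshold` must be >= 0", call. = FALSE)
  structure(
    list(input = input, simulate = simulate, alpha = alpha, divisor = divisor,
         linkage = linkage, k_range = k_range,
         retain_threshold = retain_threshold,
         path_dependents = path_dependents, out_dir = out_dir,
         seed = as.integer(seed), log_level = match.arg(log_level)),
    class = "run_config"
  )
}

log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[INFO] ", fmt), ...))
  }
}

#' Run the full multitrait selection pipeline
#'
#' Executes the stages in dependency order — simulate/load, per-trait ANOVA
#' and variance summary, correlation/PCA/path analysis, Gower clustering,
#' MGIDI selection — writing each stage's tables as CSV under
#' `config$out_dir`. A JSON manifest (resolved options, file list, warnings)
#' is written on both success and handled failure; a stage failure aborts
#' downstream stages but completed outputs are kept. Identical config and
#' seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return object of class `run_manifest` (invisibly the list written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  warnings_seen <- character(0)
  stages_done <- character(0)
  error_msg <- NULL
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    files <<- c(files, name)
  }
  withCallingHandlers(
    tryCatch({
      # stage: data
      if (!is.null(config$simulate)) {
        log_info(config, "simulating trial (seed %d)", config$simulate$seed)
        trial <- simulate_trial(config$simulate)
        input_path <- out("trial.csv")
        write_trial(trial, input_path)
        files <- c(files, "trial.csv", "trial.csv.traits.json")
      } else {
        trial <- read_trial(config$input)
        input_path <- config$input
      }
      stages_done <- c(stages_done, "data")

      # stage: anova
      av <- rcbd_anova(trial)
      emit(as.data.frame(av), "anova.csv")
      divisor <- config$divisor %||% attr(av, "n_genotypes")
      log_info(config, "heritability divisor defaulted to %d (number of genotypes)", divisor)
      vs <- variance_summary(av, divisor = divisor)
      emit(as.data.frame(vs), "variance_summary.csv")
      stages_done <- c(stages_done, "anova")

      # stage: structure
      gm <- genotype_means(trial)
      cr <- correlation_with_significance(gm)
      emit(data.frame(trait = rownames(cr$r), cr$r, check.names = FALSE), "correlations.csv")
      emit(data.frame(trait = rownames(cr$p), cr$p, check.names = FALSE), "correlation_pvalues.csv")
      pca <- pca_traits(gm, retain_threshold = config$retain_threshold)
      emit(rbind(
        data.frame(quantity = rownames(pca$loadings), pca$loadings, check.names = FALSE),
        data.frame(quantity = "Eigenvalue", t(pca$eigenvalues), check.names = FALSE) |>
          stats::setNames(c("quantity", colnames(pca$loadings))),
        data.frame(quantity = "Variance %", t(pca$percent), check.names = FALSE) |>
          stats::setNames(c("quantity", colnames(pca$loadings))),
        data.frame(quantity = "Cumulative %", t(pca$cumulative), check.names = FALSE) |>
          stats::setNames(c("quantity", colnames(pca$loadings)))
      ), "pca.csv")
      deps <- config$path_dependents %||% intersect(c("HTW", "NTS"), colnames(gm))
      for (dep in deps) {
        pa <- path_analysis(cr, dep)
        emit(data.frame(predictor = names(pa$direct), direct = pa$direct,
                        total_r = pa$total, residual = pa$residual),
             sprintf("path_%s.csv", dep))
      }
      stages_done <- c(stages_done, "structure")

      # stage: cluster
      D <- gower_distance(gm)
      emit(data.frame(genotype = rownames(D), D, check.names = FALSE), "distance.csv")
      log_info(config, "clustering linkage: %s", config$linkage)
      k <- choose_k_silhouette(D, k_range = config$k_range, linkage = config$linkage)
      sol <- hierarchical_clusters(D, k = as.integer(k), linkage = config$linkage)
      emit(data.frame(genotype = names(sol$labels), cluster = sol$labels,
                      silhouette = sol$silhouette), "clusters.csv")
      write_dendrogram_newick(sol, out("dendrogram.nwk"))
      files <- c(files, "dendrogram.nwk")
      emit(as.data.frame(cluster_trait_summary(trial, sol)), "cluster_summary.csv")
      stages_done <- c(stages_done, "cluster")

      # stage: mgidi
      log_info(config, "selection intensity alpha = %g%%", config$alpha)
      fit <- mgidi(trial, alpha = config$alpha, divisor = divisor,
                   retain_threshold = config$retain_threshold)
      emit(fit$ranking, "mgidi_ranking.csv")
      emit(cbind(data.frame(trait = rownames(fit$model$loadings)),
                 as.data.frame(fit$model$loadings),
                 communality = fit$model$communality,
                 uniqueness = fit$model$uniqueness), "factor_loadings.csv")
      emit(as.data.frame(fit$gains), "selection_gains.csv")
      emit(data.frame(genotype = rownames(fit$contributions),
                      unclass(fit$contributions), check.names = FALSE),
           "factor_contributions.csv")
      stages_done <- c(stages_done, "mgidi")
      NULL
    }, error = function(e) {
      error_msg <<- conditionMessage(e)
      NULL
    }),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("mgidi")),
    seed = config$seed,
    alpha = config$alpha,
    divisor = config$divisor,
    linkage = config$linkage,
    retain_threshold = config$retain_threshold,
    input = if (is.null(config$input)) "simulated" else config$input,
    stages_completed = stages_done,
    files = files,
    warnings = warnings_seen,
    error = error_msg
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  manifest$out_dir <- config$out_dir
  class(manifest) <- "run_manifest"
  if (!is.null(error_msg)) {
    warning("pipeline stopped early: ", error_msg, call. = FALSE)
  }
  invisible(manifest)
}

#' Render a markdown summary of a pipeline run
#'
#' Produces a human-readable report with sections for the ANOVA table,
#' variance components, PCA, cluster summary and the MGIDI selection
#' (including the genotype x factor proportion matrix used for radar
#' plots). Sections whose stage did not run are marked "not run".
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return a single markdown string.
#' @export
render_summary <- function(manifest) {
  if (!inherits(manifest, "run_manifest")) stop("`manifest` must be a run_manifest", call. = FALSE)
  od <- manifest$out_dir
  section <- function(title, file) {
    if (file %in% manifest$files) {
      tab <- utils::read.csv(file.path(od, file), check.names = FALSE)
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], round, digits = 3)
      body <- paste(utils::capture.output(print(tab, row.names = FALSE)), collapse = "\n")
    } else {
      body <- "_not run_"
    }
    sprintf("## %s\n\n```\n%s\n```\n", title, body)
  }
  paste(
    sprintf("# Multitrait selection report\n\nSelection intensity: %g%%; linkage: %s.\n",
            manifest$alpha, manifest$linkage),
    section("ANOVA mean squares", "anova.csv"),
    section("Variance components and heritability", "variance_summary.csv"),
    section("Principal components", "pca.csv"),
    section("Cluster summary", "cluster_summary.csv"),
    section("Factor loadings", "factor_loadings.csv"),
    section("MGIDI ranking", "mgidi_ranking.csv"),
    section("Predicted selection gains", "selection_gains.csv"),
    section("Factor contributions (radar data)", "factor_contributions.csv"),
    sep = "\n"
  )
}
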