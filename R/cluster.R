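#' Gower dissimilarity between genotypes
#'
#' For all-quantitative traits the Gower coefficient reduces to the
#' range-normalized Manhattan distance
#' \deqn{d(i,j) = \frac{1}{K}\sum_t |x_{it} - x_{jt}| / \mathrm{range}_t,}
#' bounded in `[0, 1]`. Traits with zero range carry no information and are
#' dropped with a warning.
#'
#' @param means a [genotype_means()] matrix (or plain numeric matrix with
#'   genotype rownames).
#' @return symmetric genotype x genotype matrix of class `gower_dist` with
#'   zero diagonal and entries in `[0, 1]`.
#' @export
#' @examples
#' M <- rbind(a = c(0, 0), b = c(10, 2), c = c(5, 1))
#' gower_distance(M)
gower_distance <- function(means) {
  M <- unclass(means)
  if (nrow(M) < 2) stop("need at least 2 genotypes", call. = FALSE)
  rng <- apply(M, 2, function(v) diff(range(v, na.rm = TRUE)))
  keep <- is.finite(rng) & rng > 0
  if (!any(keep)) stop("all traits have zero range", call. = FALSE)
  if (!all(keep)) {
    warning("dropping zero-range trait(s): ",
            paste(colnames(M)[!keep], collapse = ", "), call. = FALSE)
  }
  X <- sweep(M[, keep, drop = FALSE], 2, rng[keep], "/")
  D <- as.matrix(stats::dist(X, method = "manhattan")) / sum(keep)
  dimnames(D) <- list(rownames(M), rownames(M))
  structure(D, class = c("gower_dist", "matrix"))
}

# map user-facing linkage names onto hclust methods; "ward" operates on
# squared dissimilarities (ward.D2)
linkage_method <- function(linkage) {
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward"))
  c(average = "average", single = "single",
    complete = "complete", ward = "ward.D2")[[linkage]]
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the hierarchical tree at each candidate `k` and returns the `k`
#' maximising the mean silhouette width over genotypes; ties break to the
#' smallest `k`.
#'
#' @param d a [gower_distance()] matrix (or any symmetric dissimilarity).
#' @param k_range candidate cluster counts; default `2:min(10, n - 1)`.
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"`.
#' @return the chosen `k`, with the silhouette profile attached as attribute
#'   `silhouette` (named numeric vector over the scanned `k`).
#' @export
choose_k_silhouette <- function(d, k_range = NULL, linkage = "average") {
  D <- as.matrix(d)
  n <- nrow(D)
  if (all(D == 0)) stop("degenerate dissimilarity matrix (all zeros)", call. = FALSE)
  k_range <- k_range %||% seq(2, min(10, n - 1))
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(D), method = linkage_method(linkage))
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  best <- k_range[which.max(sil)] # which.max takes the first maximum: smallest k on ties
  structure(best, silhouette = sil)
}

#' Hierarchical clustering of genotypes
#'
#' Agglomerative clustering on a dissimilarity matrix, cut to `k` groups.
#' Clusters are relabeled deterministically so that cluster 1 is the
#' largest (ties broken by first genotype appearance).
#'
#' @param d a [gower_distance()] matrix.
#' @param k number of clusters (1 <= k <= n).
#' @param linkage linkage method, see [choose_k_silhouette()].
#' @return object of class `cluster_solution`: list with `labels` (named
#'   integer vector in `1..k`), `k`, `silhouette` (per-genotype widths; `NA`
#'   when `k` is 1 or n), `mean_silhouette`, `tree` (the `hclust` object)
#'   and `linkage`.
#' @export
hierarchical_clusters <- function(d, k, linkage = "average") {
  D <- as.matrix(d)
  n <- nrow(D)
  stopifnot_scalar_count(k, "k", min = 1)
  if (k > n) stop("k cannot exceed the number of genotypes", call. = FALSE)
  tree <- stats::hclust(stats::as.dist(D), method = linkage_method(linkage))
  raw <- stats::cutree(tree, k = k)
  # relabel: 1 = largest cluster, ties by order of first appearance
  sizes <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.numeric(sizes), as.numeric(first))
  remap <- stats::setNames(seq_len(k), names(sizes)[ord])
  labels <- stats::setNames(as.integer(remap[as.character(raw)]), names(raw))
  if (k > 1 && k < n) {
    sw <- cluster::silhouette(labels, dmatrix = D)[, "sil_width"]
  } else {
    sw <- rep(NA_real_, n)
  }
  names(sw) <- names(labels)
  structure(
    list(labels = labels, k = as.integer(k), silhouette = sw,
         mean_silhouette = if (anyNA(sw)) NA_real_ else mean(sw),
         tree = tree, linkage = linkage),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage): k = %d\n", x$linkage, x$k))
  print(table(cluster = x$labels))
  if (!is.na(x$mean_silhouette)) {
    cat(sprintf("Mean silhouette width: %.3f\n", x$mean_silhouette))
  }
  invisible(x)
}

#' Export the clustering tree in newick format
#'
#' @param solution a [hierarchical_clusters()] result.
#' @param path output file; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to file.
#' @export
write_dendrogram_newick <- function(solution, path = NULL) {
  phy <- ape::as.phylo(solution$tree)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Per-cluster trait summary with LSD contrasts
#'
#' Average genotype means per cluster and trait, the least significant
#' difference at the 5% level, and a significance flag per trait. The LSD
#' uses the pooled residual mean square of the per-trait RCBD fits:
#' \eqn{LSD_t = t_{0.975, df_e} \sqrt{2 MS_{e,t} / \tilde n}} with
#' \eqn{\tilde n} the harmonic mean of cluster sizes times the number of
#' blocks. A trait is flagged `***` when a one-way ANOVA of genotype means
#' across clusters gives p <= 0.001, `ns` otherwise.
#'
#' @param trial a [trial_table()].
#' @param solution a [hierarchical_clusters()] result whose labels cover all
#'   genotypes in the trial.
#' @return object of class `cluster_summary`: data frame with one row per
#'   trait, per-cluster mean columns, `lsd_5pct`, `p_value`, `flag`; cluster
#'   sizes as attribute `sizes`.
#' @export
cluster_trait_summary <- function(trial, solution) {
  if (!inherits(trial, "trial_table")) stop("`trial` must be a trial_table", call. = FALSE)
  gm <- genotype_means(trial)
  g <- rownames(gm)
  if (!all(g %in% names(solution$labels))) {
    stop("cluster labels do not cover all genotypes in the trial", call. = FALSE)
  }
  lab <- solution$labels[g]
  sizes <- table(lab)
  if (length(sizes) != solution$k) stop("empty cluster", call. = FALSE)
  n_blocks <- length(unique(trial$block))
  av <- rcbd_anova(trial)
  n_tilde <- harmonic_mean(as.numeric(sizes)) * n_blocks
  rows <- lapply(seq_len(nrow(av)), function(i) {
    t <- av$trait[i]
    cl_means <- tapply(gm[, t], lab, mean)
    lsd <- if (av$ms_residual[i] > 0) {
      stats::qt(0.975, av$df_residual[i]) * sqrt(2 * av$ms_residual[i] / n_tilde)
    } else 0
    if (solution$k > 1 && stats::var(gm[, t]) > 0) {
      p <- stats::anova(stats::lm(gm[, t] ~ factor(lab)))$`Pr(>F)`[1]
    } else {
      p <- 1
    }
    out <- data.frame(trait = t, stringsAsFactors = FALSE)
    for (cl in seq_len(solution$k)) out[[paste0("cluster_", cl)]] <- unname(cl_means[as.character(cl)])
    out$lsd_5pct <- lsd
    out$p_value <- p
    out$flag <- if (p <= 0.001) "***" else "ns"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, sizes = as.integer(sizes), n_blocks = n_blocks,
            error_term = "pooled RCBD residual MS per trait",
            class = c("cluster_summary", "data.frame"))
}

#' @export
print.cluster_summary <- function(x, digits = 3, ...) {
  sizes <- attr(x, "sizes")
  cat(sprintf("Cluster trait summary (%s; sizes: %s)\n",
              attr(x, "error_term"), paste(sizes, collapse = ", ")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
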