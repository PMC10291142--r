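# Phenotype-convergence analyses: dimension reduction, SNN clustering,
# cluster composition, single-sample enrichment scoring and flux-stress
# correlation.

#' Top principal components of a samples x features matrix
#'
#' Column-centered (unscaled) PCA scores, ordered by decreasing explained
#' variance.  For determinism the sign of each component is fixed so that
#' the loading of largest magnitude is positive.
#'
#' @param x Samples x features numeric matrix.
#' @param n_components Number of leading components (must not exceed
#'   `min(dim(x))`).
#' @return Samples x `n_components` score matrix; the per-component explained
#'   variance fraction is attached as attribute `"explained_variance"`.
#' @export
top_principal_components <- function(x, n_components = 12L) {
  x <- as.matrix(x)
  if (n_components > min(dim(x)))
    stop("n_components (", n_components, ") exceeds min(samples, features) = ",
         min(dim(x)), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  flip <- vapply(seq_len(k), function(i) {
    v <- pc$rotation[, i]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}

#' Two-dimensional t-SNE embedding of a fluxome profile
#'
#' Thin deterministic wrapper around [Rtsne::Rtsne()].
#'
#' @param x Samples x features matrix.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; requires `nrow(x) - 1 >= 3 * perplexity`.
#' @param ... Passed on to [Rtsne::Rtsne()].
#' @return Data.frame with `sample_id`, `tsne1`, `tsne2`; seed and perplexity
#'   attached as attributes.
#' @export
tsne_embed <- function(x, seed = 42L, perplexity = 30, ...) {
  x <- as.matrix(x)
  if (nrow(x) - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " is too large for ", nrow(x),
         " samples (need samples > 3*perplexity)", call. = FALSE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity,
                      check_duplicates = FALSE, ...)
  out <- data.frame(sample_id = rownames(x) %||% seq_len(nrow(x)),
                    tsne1 = fit$Y[, 1L], tsne2 = fit$Y[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances (typically over
#' top principal-component scores), weights edges by the Jaccard overlap of
#' neighborhoods (shared nearest neighbors), prunes weak edges, and runs
#' modularity-maximizing Louvain community detection.
#'
#' @param pc_scores Samples x dims matrix.
#' @param k_neighbors Neighborhood size (must be < number of samples).
#' @param resolution Louvain resolution parameter; larger values give more
#'   clusters.
#' @param seed Integer seed (community detection tie-breaking).
#' @param prune Jaccard weight below which SNN edges are dropped.
#' @return Integer-coded factor of cluster labels, one per row.
#' @export
knn_cluster <- function(pc_scores, k_neighbors = 20L, resolution = 0.8,
                        seed = 42L, prune = 1 / 15) {
  x <- as.matrix(pc_scores)
  n <- nrow(x)
  if (k_neighbors >= n)
    stop("k_neighbors (", k_neighbors, ") must be smaller than the number of samples (",
         n, ")", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  if (max(D) == 0) {
    warning("all rows identical; returning a single cluster")
    return(factor(rep(1L, n)))
  }
  # k nearest neighbours of each point (self included, Seurat-style)
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_neighbors)]))
  memb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) memb[i, nn[i, ]] <- TRUE
  shared <- tcrossprod(memb * 1)              # shared neighbour counts
  jac <- shared / (2 * k_neighbors - shared)  # Jaccard of the two k-sets
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  factor(igraph::membership(comm))
}

#' Cluster composition and stage-distribution report
#'
#' Tallies per-cluster counts over (cancer type, tumor/normal status) and
#' over stage, and tests stage-by-cluster enrichment with a chi-square test
#' (samples with missing stage are tallied as NA and excluded from the test).
#'
#' @param labels Per-sample cluster labels.
#' @param metadata Data.frame with per-sample columns among `cancer_type`,
#'   `group` (tumor/normal status) and `stage`; missing columns are skipped.
#' @return List of class `cluster_report`: `n_clusters`, `sizes`,
#'   `composition` (cluster x type/status table or `NULL`), `stage_table`
#'   (cluster x stage counts incl. NA), `stage_proportions`, and
#'   `stage_test` (`htest` or `NULL`).
#' @export
cluster_stage_distribution <- function(labels, metadata) {
  labels <- as.factor(labels)
  if (nrow(metadata) != length(labels))
    stop("metadata must cover all labeled samples", call. = FALSE)
  sizes <- table(cluster = labels)
  comp <- NULL
  if (all(c("cancer_type", "group") %in% names(metadata))) {
    comp <- table(cluster = labels,
                  type_status = interaction(metadata$cancer_type, metadata$group,
                                            drop = TRUE, sep = "/"))
  } else if ("group" %in% names(metadata)) {
    comp <- table(cluster = labels, status = metadata$group)
  }
  stage_table <- stage_prop <- stage_test <- NULL
  if ("stage" %in% names(metadata)) {
    stage_table <- table(cluster = labels, stage = addNA(factor(metadata$stage)))
    known <- !is.na(metadata$stage)
    if (any(known) && nlevels(droplevels(factor(metadata$stage[known]))) >= 2 &&
        nlevels(droplevels(labels[known])) >= 2) {
      stage_test <- suppressWarnings(
        stats::chisq.test(table(droplevels(labels[known]),
                                droplevels(factor(metadata$stage[known])))))
    } else {
      warning("stage enrichment test skipped (needs >= 2 clusters and >= 2 ",
              "observed stage levels)")
    }
    stage_prop <- prop.table(stage_table, margin = 1L)
  }
  structure(list(n_clusters = nlevels(labels), sizes = sizes,
                 composition = comp, stage_table = stage_table,
                 stage_proportions = stage_prop, stage_test = stage_test),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster report:", x$n_clusters, "clusters\n")
  print(x$sizes)
  if (!is.null(x$stage_test))
    cat(sprintf("Stage x cluster chi-square: X2 = %.3g, p = %.3g\n",
                unname(x$stage_test$statistic), x$stage_test$p.value))
  invisible(x)
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ordered by decreasing expression and the
#' enrichment score of a set is the sum, over all rank positions, of the
#' difference between the weighted in-set cumulative fraction (weights
#' `rank^alpha`, ranks computed with midranks so scores are invariant under
#' strictly increasing transforms of a sample's values) and the unweighted
#' out-of-set cumulative fraction.
#'
#' @param expression Genes x samples matrix.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Non-negative rank-weighting exponent.
#' @return Samples x sets matrix of ES values; sets sharing no gene with the
#'   matrix get `NA` with a warning.
#' @export
ssgsea_scores <- function(expression, gene_sets, alpha = 0.75) {
  stopifnot(alpha >= 0)
  expression <- as.matrix(expression)
  genes <- rownames(expression)
  if (is.null(genes)) stop("expression must have gene rownames", call. = FALSE)
  overlap <- vapply(gene_sets, function(s) length(intersect(s, genes)), integer(1))
  if (any(overlap == 0L))
    warning("gene set(s) with no overlap scored as NA: ",
            paste(names(gene_sets)[overlap == 0L], collapse = ", "))
  n_genes <- length(genes)
  ES <- matrix(NA_real_, ncol(expression), length(gene_sets),
               dimnames = list(colnames(expression), names(gene_sets)))
  in_set <- lapply(gene_sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expression))) {
    v <- expression[, j]
    rk <- rank(v, ties.method = "average")   # monotone-invariant statistic
    ord <- order(v, decreasing = TRUE)
    w <- rk[ord]^alpha
    for (s in seq_along(gene_sets)) {
      if (overlap[s] == 0L) next
      ins <- in_set[[s]][ord]
      w_in <- w * ins
      p_in <- cumsum(w_in) / sum(w_in)
      n_out <- n_genes - overlap[s]
      p_out <- if (n_out > 0) cumsum(!ins) / n_out else rep(0, n_genes)
      ES[j, s] <- sum(p_in - p_out)
    }
  }
  attr(ES, "alpha") <- alpha
  ES
}

#' Spearman correlation between module fluxes and enrichment scores
#'
#' @param flux Samples x modules matrix.
#' @param scores Samples x gene-sets matrix (e.g. from [ssgsea_scores()]).
#' @return Modules x gene-sets matrix of Spearman correlations over the
#'   shared samples (at least 3 required).
#' @export
flux_stress_correlation <- function(flux, scores) {
  flux <- as.matrix(flux); scores <- as.matrix(scores)
  shared <- intersect(rownames(flux), rownames(scores))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples (found ", length(shared), ")",
         call. = FALSE)
  stats::cor(flux[shared, , drop = FALSE], scores[shared, , drop = FALSE],
             method = "spearman")
}

#' Read / write GMT gene-set files
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  writeLines(vapply(names(gene_sets), function(n)
    paste(c(n, n, gene_sets[[n]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
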