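# Synthetic data with known, approximately balanced ground-truth fluxes.
#
# Fluxes are non-negative combinations of balanced unit flux modes with
# log-normal per-sample loads.  Each mode starts from a source-to-sink
# simple path (unit flux on its modules); on graphs whose modules each
# consume and produce a single intermediate (chains, diamonds) the path is
# already balanced.  Modules with several substrate inputs (e.g. the
# citrate synthase module, which consumes both acetyl-CoA and oxaloacetate)
# leave deficits that are resolved by a completion step: integer units of
# producing/consuming modules are added until every intermediate balances
# exactly, which closes cycles (e.g. the TCA loop) where needed.

# Complete an integer module-multiplicity vector into a balanced flux mode:
# while some intermediate has a production deficit (surplus), add one unit of
# a producing (consuming) module, preferring the module with the lowest
# current multiplicity.  Returns NULL if no balance is reached within the
# iteration cap.
complete_mode <- function(graph, S, mult, max_steps = 500L) {
  r <- drop(S %*% mult)
  for (step in seq_len(max_steps)) {
    k <- which(r != 0)
    if (length(k) == 0L) return(mult)
    k <- k[1L]
    met <- rownames(S)[k]
    cand <- if (r[k] < 0) graph$fin[[met]] else graph$fout[[met]]
    if (length(cand) == 0L) return(NULL)
    m <- cand[which.min(mult[cand])]
    mult[m] <- mult[m] + 1L
    r <- r + S[, m]
  }
  NULL
}

#' Balanced flux-mode basis from source-to-sink paths
#'
#' Sources are end metabolites with at least one consuming module; sinks are
#' end metabolites with at least one producing module.  Each simple
#' source-to-sink walk on the bipartite graph (no metabolite revisited)
#' yields a unit flux on its modules and is then completed into an exactly
#' balanced mode (see the completion step above); modules lying only on
#' internal cycles (never crossed by any source-to-sink path) are covered by
#' additional cycle modes seeded at those modules.
#'
#' @param graph A validated `factor_graph`.
#' @param max_paths Enumeration cap; a warning is thrown if reached.
#' @return A non-negative integer matrix of dimension `n_modes x M`; every
#'   row satisfies the intermediate balance exactly.
#' @export
flux_path_basis <- function(graph, max_paths = 500L) {
  role <- stats::setNames(graph$metabolites$role, graph$metabolites$id)
  sources <- names(which(role == "end" & lengths(graph$fout[names(role)]) > 0))
  sinks <- names(which(role == "end" & lengths(graph$fin[names(role)]) > 0))
  paths <- list()
  capped <- FALSE

  walk <- function(met, mods_used, mets_seen) {
    if (length(paths) >= max_paths) { capped <<- TRUE; return() }
    for (m_id in graph$fout[[met]]) {
      m <- graph$modules[[m_id]]
      if (m_id %in% mods_used) next
      for (out in m$outputs) {
        if (out %in% mets_seen) next
        if (role[[out]] == "end") {
          if (out %in% sinks)
            paths[[length(paths) + 1L]] <<- c(mods_used, m_id)
        } else {
          walk(out, c(mods_used, m_id), c(mets_seen, out))
        }
      }
    }
  }
  for (s in sources) walk(s, character(0), s)
  if (capped) warning("path enumeration capped at ", max_paths, " paths")
  if (length(paths) == 0L)
    stop("no directed source-to-sink path in the graph; cannot generate fluxes",
         call. = FALSE)
  mods <- names(graph$modules)
  S <- incidence_matrix(graph)
  modes <- list()
  for (p in paths) {
    mult <- stats::setNames(integer(length(mods)), mods)
    mult[unique(p)] <- 1L
    mode <- complete_mode(graph, S, mult)
    if (!is.null(mode)) modes[[length(modes) + 1L]] <- mode
  }
  if (length(modes) == 0L)
    stop("no source-to-sink path could be completed into a balanced mode",
         call. = FALSE)
  B <- do.call(rbind, modes)
  # cover modules on internal cycles with dedicated cycle modes
  repeat {
    uncovered <- names(which(colSums(B) == 0))
    if (length(uncovered) == 0L) break
    mult <- stats::setNames(integer(length(mods)), mods)
    mult[uncovered[1L]] <- 1L
    mode <- complete_mode(graph, S, mult)
    if (is.null(mode) || mode[uncovered[1L]] == 0L) {
      warning("module(s) carry zero flux in every generated sample: ",
              paste(uncovered, collapse = ", "))
      break
    }
    B <- rbind(B, mode)
  }
  rownames(B) <- NULL
  stopifnot(max(abs(B %*% t(S))) == 0)
  B
}

#' Sample non-negative, balanced ground-truth flux matrices
#'
#' Draws per-sample positive loads (log-normal) on the balanced flux-mode
#' basis of the graph ([flux_path_basis()]) and sums them into module fluxes,
#' then adds optional per-module slack drawn from a Gaussian truncated at
#' zero (half-normal with scale `slack_sd`), keeping fluxes non-negative.
#' With `slack_sd = 0` the returned fluxes balance every intermediate
#' metabolite exactly, since every basis mode does.
#'
#' @param graph A validated `factor_graph` with at least one source-to-sink path.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed; generation is deterministic given `seed`.
#' @param slack_sd Scale of the truncated-Gaussian per-module slack.
#' @param meanlog,sdlog Log-normal parameters of the path loads.
#' @param max_paths Path-enumeration cap, see [flux_path_basis()].
#' @return A `n_samples x M` flux matrix (samples in rows); the path basis
#'   and loads are attached as attributes `"paths"` and `"loads"`.
#' @export
sample_balanced_fluxes <- function(graph, n_samples, seed = 1L, slack_sd = 0,
                                   meanlog = 0, sdlog = 0.5, max_paths = 500L) {
  stopifnot(n_samples >= 1, slack_sd >= 0)
  B <- flux_path_basis(graph, max_paths)
  set.seed(seed)
  loads <- matrix(stats::rlnorm(n_samples * nrow(B), meanlog, sdlog),
                  nrow = n_samples)
  F <- loads %*% B
  if (slack_sd > 0)
    F <- F + matrix(abs(stats::rnorm(length(F), 0, slack_sd)), nrow = nrow(F))
  dimnames(F) <- list(sprintf("S%04d", seq_len(n_samples)), names(graph$modules))
  attr(F, "paths") <- B
  attr(F, "loads") <- loads
  F
}

#' Simulate expression from ground-truth fluxes through a monotone link
#'
#' For each synthetic gene `i` of module `m`, expression in sample `j` is
#' `log(1 + w_im * Flux_mj) + eps`, with `w_im` drawn uniformly from
#' `weight_range` and `eps ~ Normal(0, noise_sd)`, clipped at zero so values
#' live on the log(FPKM+1) scale.  Gene names encode module membership
#' (`<module>_g<i>`).
#'
#' @param true_flux A samples x modules flux matrix (non-negative).
#' @param graph The `factor_graph` the flux columns align to.
#' @param genes_per_module Number of synthetic genes per module.
#' @param noise_sd Gaussian noise standard deviation on the log scale.
#' @param seed Integer seed.
#' @param weight_range Length-2 positive range for the gene weights; use
#'   `c(1, 1)` for unit weights.
#' @return A list with `expression` (genes x samples matrix), `link`
#'   (data.frame gene/module/weight plus the noise scale and link family),
#'   and `graph` (a copy of the input graph whose module gene rosters are
#'   the synthetic gene names, ready for [train_flux_model()]).
#' @export
expression_from_flux <- function(true_flux, graph, genes_per_module = 3L,
                                 noise_sd = 0.1, seed = 1L,
                                 weight_range = c(0.5, 2)) {
  stopifnot(genes_per_module >= 1, noise_sd >= 0, all(weight_range > 0))
  if (min(true_flux) < 0)
    stop("true_flux contains negative entries; generator contract violated",
         call. = FALSE)
  mods <- names(graph$modules)
  if (!identical(colnames(true_flux), mods))
    true_flux <- true_flux[, mods, drop = FALSE]
  set.seed(seed)
  n <- nrow(true_flux)
  link <- data.frame(
    gene = as.vector(t(outer(mods, seq_len(genes_per_module),
                             function(m, i) paste0(m, "_g", i)))),
    module = rep(mods, each = genes_per_module),
    weight = stats::runif(length(mods) * genes_per_module,
                          weight_range[1], weight_range[2]),
    stringsAsFactors = FALSE)
  expr <- matrix(0, nrow = nrow(link), ncol = n,
                 dimnames = list(link$gene, rownames(true_flux)))
  for (i in seq_len(nrow(link)))
    expr[i, ] <- log1p(link$weight[i] * true_flux[, link$module[i]])
  if (noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd), nrow = nrow(expr))
  expr[expr < 0] <- 0
  list(expression = expr,
       link = list(weights = link, noise_sd = noise_sd, family = "log1p_linear"),
       graph = synthetic_gene_graph(graph, genes_per_module))
}

# copy of a graph whose module gene rosters are replaced by the synthetic
# gene names emitted by expression_from_flux(), so that trained predictors
# read exactly the simulated genes of each module
synthetic_gene_graph <- function(graph, genes_per_module) {
  g2 <- graph
  for (m in names(g2$modules))
    g2$modules[[m]]$genes <- paste0(m, "_g", seq_len(genes_per_module))
  g2
}

#' Simulate a two-group (tumor vs normal) flux study
#'
#' Generates balanced ground-truth fluxes and matching expression for a
#' normal and a tumor group.  For each entry of `perturbed_modules` the
#' tumor-group loads of every path through that module are scaled by the
#' fold change, so the module's expected flux changes by exactly that fold
#' (modules sharing those paths co-scale, as flux balance requires).
#'
#' @param graph A validated `factor_graph`.
#' @param n_per_group Samples per group.
#' @param perturbed_modules Named numeric vector of fold changes (> 0),
#'   names are module ids; empty for a null study.
#' @param seed Integer seed.
#' @param slack_sd,meanlog,sdlog Passed to the flux sampler.
#' @param genes_per_module,noise_sd,weight_range Passed to the expression link.
#' @return An object of class `synthetic_dataset`: list with `expression`
#'   (genes x samples), `metadata` (sample_id, group, stage), `true_flux`
#'   (samples x modules), `link`, `group_labels`, `perturbed_modules`.
#' @export
make_two_group_study <- function(graph, n_per_group, perturbed_modules = numeric(0),
                                 seed = 1L, slack_sd = 0, meanlog = 0, sdlog = 0.5,
                                 genes_per_module = 3L, noise_sd = 0.1,
                                 weight_range = c(0.5, 2)) {
  stopifnot(n_per_group >= 1)
  if (length(perturbed_modules)) {
    if (is.null(names(perturbed_modules)) || any(!nzchar(names(perturbed_modules))))
      stop("perturbed_modules must be a named vector (module id -> fold change)",
           call. = FALSE)
    unknown <- setdiff(names(perturbed_modules), names(graph$modules))
    if (length(unknown))
      stop("perturbed module(s) not in graph: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(perturbed_modules <= 0))
      stop("fold changes must be > 0", call. = FALSE)
  }
  B <- flux_path_basis(graph)
  S <- incidence_matrix(graph)
  mods <- names(graph$modules)
  set.seed(seed)
  n <- n_per_group
  loads_n <- matrix(stats::rlnorm(n * nrow(B), meanlog, sdlog), nrow = n)
  loads_t <- matrix(stats::rlnorm(n * nrow(B), meanlog, sdlog), nrow = n)
  for (m in names(perturbed_modules)) {
    on_mode <- B[, m] > 0
    loads_t[, on_mode] <- loads_t[, on_mode] * perturbed_modules[[m]]
  }
  F <- rbind(loads_n %*% B, loads_t %*% B)
  if (slack_sd > 0)
    F <- F + matrix(abs(stats::rnorm(length(F), 0, slack_sd)), nrow = nrow(F))
  ids <- c(sprintf("N%04d", seq_len(n)), sprintf("T%04d", seq_len(n)))
  dimnames(F) <- list(ids, mods)
  group <- rep(c("normal", "tumor"), each = n)
  stage <- rep(NA_character_, 2L * n)
  stage[group == "tumor"] <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  ex <- expression_from_flux(F, graph, genes_per_module = genes_per_module,
                             noise_sd = noise_sd,
                             seed = seed + 1L, weight_range = weight_range)
  structure(list(
    expression = ex$expression,
    metadata = data.frame(sample_id = ids, group = group, stage = stage,
                          stringsAsFactors = FALSE),
    true_flux = F,
    link = ex$link,
    graph = ex$graph,
    group_labels = stats::setNames(group, ids),
    perturbed_modules = perturbed_modules
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic flux study: ", ncol(x$expression), " samples, ",
      nrow(x$expression), " genes, ", ncol(x$true_flux), " modules\n", sep = "")
  if (length(x$perturbed_modules))
    cat("Perturbed:", paste0(names(x$perturbed_modules), " x",
                             x$perturbed_modules, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression matrix, metadata, ground-truth flux and link
#' parameters in the plain-text formats consumed by the pipeline stages.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             true_flux = file.path(dir, "true_flux.tsv"),
             link = file.path(dir, "link_parameters.json"))
  write_tsv_matrix(dataset$expression, paths[["expression"]], "gene")
  utils::write.table(dataset$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(dataset$true_flux, paths[["true_flux"]], "sample_id")
  jsonlite::write_json(dataset$link, paths[["link"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# shared TSV writer: matrix with rownames in a named first column,
# numbers at 6 significant digits for byte-stable output
write_tsv_matrix <- function(x, path, id_col = "id") {
  d <- data.frame(rownames(x), signif(x, 6), check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
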