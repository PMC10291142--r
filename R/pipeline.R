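# End-to-end driver: simulate -> estimate -> diff -> phenotype.
#
# A single global seed fans out to per-stage seeds by fixed offsets
# (simulate +1, estimate +2, phenotype +3) so stages are independently
# reproducible.  All tabular outputs are TSV with a header row and 6
# significant digits, which makes re-runs byte-identical.

.config_schema <- list(
  seed = NULL, output_dir = NULL, graph = NULL,
  expression = NULL, metadata = NULL,
  stages = NULL,
  simulate = list(n_per_group = NULL, perturbed_modules = NULL,
                  slack_sd = NULL, noise_sd = NULL, genes_per_module = NULL,
                  meanlog = NULL, sdlog = NULL),
  training = list(lambda_scale = NULL, hidden_sizes = NULL, epochs = NULL,
                  learning_rate = NULL, ta_mode = NULL, ta_constant = NULL,
                  convergence_tol = NULL, patience = NULL),
  differential = list(alpha = NULL),
  phenotype = list(n_components = NULL, k_neighbors = NULL, resolution = NULL,
                   perplexity = NULL, run_tsne = NULL, gene_sets = NULL)
)

#' Default pipeline configuration
#'
#' @param output_dir Output directory for the run.
#' @param seed Global seed fanned out to the stages.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_config <- function(output_dir = "fluxcentral_run", seed = 42L) {
  list(
    seed = seed, output_dir = output_dir, graph = NULL,
    expression = NULL, metadata = NULL,
    stages = c("simulate", "estimate", "diff", "phenotype"),
    simulate = list(n_per_group = 50L, perturbed_modules = list(),
                    slack_sd = 0, noise_sd = 0.1, genes_per_module = 3L,
                    meanlog = 0, sdlog = 0.5),
    training = list(lambda_scale = 1, hidden_sizes = c(8L, 4L), epochs = 100L,
                    learning_rate = 0.008, ta_mode = "metabolic_total",
                    ta_constant = NULL, convergence_tol = 1e-4, patience = 10L),
    differential = list(alpha = 0.001),
    phenotype = list(n_components = 12L, k_neighbors = 20L, resolution = 0.8,
                     perplexity = 30, run_tsne = TRUE, gene_sets = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a config list or a path to a YAML/JSON file; checks it against the
#' known key schema and value constraints and returns either the completed
#' config (defaults filled in) or stops with the exhaustive list of errors.
#'
#' @param config A list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return The validated, default-completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  errors <- character(0)
  err <- function(...) errors <<- c(errors, paste0(...))

  unknown <- setdiff(names(config), names(.config_schema))
  for (k in unknown) err("unknown key: '", k, "'")
  for (sec in c("simulate", "training", "differential", "phenotype")) {
    if (!is.null(config[[sec]])) {
      if (!is.list(config[[sec]])) { err("'", sec, "' must be a list"); next }
      for (k in setdiff(names(config[[sec]]), names(.config_schema[[sec]])))
        err("unknown key: '", sec, ".", k, "'")
    }
  }

  defaults <- default_config()
  full <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  if (!is.null(config$output_dir)) full$output_dir <- config$output_dir

  if (!is.numeric(full$seed) || length(full$seed) != 1)
    err("'seed' must be a single integer")
  bad_stage <- setdiff(full$stages, c("simulate", "estimate", "diff", "phenotype"))
  for (s in bad_stage) err("unknown stage: '", s, "'")
  tr <- full$training
  if (tr$lambda_scale < 0) err("'training.lambda_scale' must be >= 0")
  if (tr$learning_rate <= 0) err("'training.learning_rate' must be > 0")
  if (tr$epochs < 0) err("'training.epochs' must be >= 0")
  if (!tr$ta_mode %in% c("metabolic_total", "constant"))
    err("'training.ta_mode' must be 'metabolic_total' or 'constant'")
  if (tr$ta_mode == "constant" && (is.null(tr$ta_constant) || tr$ta_constant < 0))
    err("'training.ta_constant' must be supplied and >= 0 for constant TA")
  sim <- full$simulate
  if (sim$n_per_group < 1) err("'simulate.n_per_group' must be >= 1")
  if (sim$slack_sd < 0) err("'simulate.slack_sd' must be >= 0")
  if (sim$noise_sd < 0) err("'simulate.noise_sd' must be >= 0")
  if (length(sim$perturbed_modules) && any(unlist(sim$perturbed_modules) <= 0))
    err("'simulate.perturbed_modules' fold changes must be > 0")
  if (full$differential$alpha <= 0 || full$differential$alpha > 1)
    err("'differential.alpha' must be in (0, 1]")
  ph <- full$phenotype
  if (ph$n_components < 1) err("'phenotype.n_components' must be >= 1")
  if (ph$k_neighbors < 1) err("'phenotype.k_neighbors' must be >= 1")
  if (ph$resolution <= 0) err("'phenotype.resolution' must be > 0")
  if (!"simulate" %in% full$stages && is.null(full$expression))
    err("'expression' path is required when the simulate stage is disabled")

  if (length(errors))
    stop("invalid configuration:\n", paste0("  - ", errors, collapse = "\n"),
         call. = FALSE)
  full
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in the fixed order simulate -> estimate ->
#' diff -> phenotype, writing each stage's outputs before the next starts,
#' and finishes with an atomically written run manifest (config hash, package
#' version, per-file md5 checksums, timestamps, collected warnings).  Given
#' the same config, stage outputs are byte-identical across runs.
#'
#' @param config A config list or file path accepted by [validate_config()].
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- if (is.null(config$graph)) central_metabolism_fixture()
           else load_network_json(config$graph)
  seed <- as.integer(config$seed)
  warnings_log <- character(0)
  note <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
                        invokeRestart("muffleWarning") }
  files <- character(0)
  stage_status <- list()
  t0 <- Sys.time()

  run_stage <- function(name, fn) {
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        stage_status[[name]] <<- paste("failed:", conditionMessage(e))
        write_manifest(config, files, stage_status, warnings_log, t0, out)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = note)
    stage_status[[name]] <<- "ok"
    res
  }

  expr <- meta <- flux <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      sim <- config$simulate
      ds <- make_two_group_study(
        graph, n_per_group = sim$n_per_group,
        perturbed_modules = unlist(sim$perturbed_modules),
        seed = seed + 1L, slack_sd = sim$slack_sd, meanlog = sim$meanlog,
        sdlog = sim$sdlog, genes_per_module = sim$genes_per_module,
        noise_sd = sim$noise_sd)
      p <- write_synthetic_dataset(ds, out)
      files <<- c(files, p)
      expr <<- ds$expression
      meta <<- ds$metadata
      graph <<- ds$graph  # same topology, synthetic gene rosters
      invisible(NULL)
    })
  } else {
    expr <- read_tsv_matrix(config$expression)
    meta <- if (!is.null(config$metadata))
      utils::read.delim(config$metadata, stringsAsFactors = FALSE) else NULL
  }

  if ("estimate" %in% config$stages) {
    run_stage("estimate", function() {
      tr <- config$training
      cfg <- flux_training_config(
        lambda_scale = tr$lambda_scale, hidden_sizes = tr$hidden_sizes,
        epochs = tr$epochs, learning_rate = tr$learning_rate,
        seed = seed + 2L, ta_mode = tr$ta_mode, ta_constant = tr$ta_constant,
        convergence_tol = tr$convergence_tol, patience = tr$patience)
      fit <- train_flux_model(graph, expr, cfg)
      flux <<- fit$flux
      p <- c(flux = file.path(out, "flux.tsv"),
             balance = file.path(out, "balance.tsv"),
             trace = file.path(out, "loss_trace.csv"))
      write_tsv_matrix(fit$flux, p[["flux"]], "sample_id")
      write_tsv_matrix(metabolite_change(fit$flux, graph), p[["balance"]], "sample_id")
      utils::write.csv(data.frame(lapply(fit$trace, signif, 6)), p[["trace"]],
                       row.names = FALSE, quote = FALSE)
      files <<- c(files, p)
      invisible(NULL)
    })
  }

  if ("diff" %in% config$stages) {
    run_stage("diff", function() {
      if (is.null(flux)) stop("no flux available (enable the estimate stage)")
      if (is.null(meta) || !"group" %in% names(meta))
        stop("metadata with a 'group' column is required for differential testing")
      dt <- differential_flux(flux, meta$group, alpha = config$differential$alpha)
      db <- differential_flux(metabolite_change(flux, graph), meta$group,
                              alpha = config$differential$alpha)
      p <- c(diff_flux = file.path(out, "differential_flux.tsv"),
             diff_abundance = file.path(out, "differential_abundance.tsv"))
      for (nm in names(p)) {
        d <- if (nm == "diff_flux") dt else db
        d[sapply(d, is.numeric)] <- lapply(d[sapply(d, is.numeric)], signif, 6)
        utils::write.table(d, p[[nm]], sep = "\t", quote = FALSE, row.names = FALSE)
      }
      files <<- c(files, p)
      invisible(NULL)
    })
  }

  if ("phenotype" %in% config$stages) {
    run_stage("phenotype", function() {
      if (is.null(flux)) stop("no flux available (enable the estimate stage)")
      ph <- config$phenotype
      k <- min(ph$n_components, dim(flux))
      pcs <- top_principal_components(flux, k)
      labels <- knn_cluster(pcs, k_neighbors = min(ph$k_neighbors, nrow(pcs) - 1L),
                            resolution = ph$resolution, seed = seed + 3L)
      rep <- cluster_stage_distribution(labels, meta)
      p <- c(clusters = file.path(out, "clusters.tsv"),
             report = file.path(out, "cluster_report.json"))
      utils::write.table(
        data.frame(sample_id = rownames(flux), cluster = as.integer(labels)),
        p[["clusters"]], sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(
        n_clusters = rep$n_clusters,
        sizes = as.list(stats::setNames(as.integer(rep$sizes), names(rep$sizes))),
        stage_table = if (!is.null(rep$stage_table)) as.data.frame(rep$stage_table),
        stage_test_p = if (!is.null(rep$stage_test)) rep$stage_test$p.value
      ), p[["report"]], auto_unbox = TRUE, pretty = TRUE, digits = 6)
      if (isTRUE(ph$run_tsne) && nrow(flux) - 1 >= 3 * ph$perplexity) {
        emb <- tsne_embed(flux, seed = seed + 3L, perplexity = ph$perplexity)
        emb[c("tsne1", "tsne2")] <- lapply(emb[c("tsne1", "tsne2")], signif, 6)
        p <- c(p, tsne = file.path(out, "tsne.tsv"))
        utils::write.table(emb, p[["tsne"]], sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
      if (!is.null(ph$gene_sets)) {
        sets <- read_gmt(ph$gene_sets)
        es <- ssgsea_scores(expr, sets)
        co <- flux_stress_correlation(flux, es)
        p <- c(p, enrichment = file.path(out, "enrichment_scores.tsv"),
               correlation = file.path(out, "flux_stress_correlation.tsv"))
        write_tsv_matrix(es, p[["enrichment"]], "sample_id")
        write_tsv_matrix(co, p[["correlation"]], "module")
        }
      files <<- c(files, p)
      invisible(NULL)
    })
  }

  manifest <- write_manifest(config, files, stage_status, warnings_log, t0, out)
  invisible(manifest)
}

write_manifest <- function(config, files, stage_status, warnings_log, t0, out) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  tmp_cfg <- tempfile(); writeLines(cfg_json, tmp_cfg)
  manifest <- list(
    package = "fluxcentral",
    version = as.character(utils::packageVersion("fluxcentral")),
    config = config,
    config_hash = unname(tools::md5sum(tmp_cfg)),
    stages = stage_status,
    files = as.list(stats::setNames(unname(tools::md5sum(files[file.exists(files)])),
                                    basename(files[file.exists(files)]))),
    warnings = warnings_log,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(tmp_cfg)
  tmp <- tempfile(tmpdir = out, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, file.path(out, "manifest.json"))  # atomic on one filesystem
  manifest
}
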