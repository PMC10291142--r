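#' Construct a metabolite record
#'
#' @param id Short unique identifier, e.g. `"PYR_c"`.
#' @param name Display name.
#' @param compartment One of `"cytosol"`, `"mitochondria"`, `"extracellular"`.
#' @param role `"intermediate"` (participates in the balance loss) or `"end"`
#'   (source/sink, excluded from balance constraints).
#' @return A named list of class `metabolite`.
#' @export
metabolite <- function(id, name = id,
                       compartment = c("cytosol", "mitochondria", "extracellular"),
                       role = c("intermediate", "end")) {
  compartment <- match.arg(compartment)
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment, role = role),
            class = "metabolite")
}

#' Construct a reaction module
#'
#' A reaction module is a lumped set of consecutive reactions treated as one
#' directed flux-carrying unit, with unit stoichiometry on every consumed and
#' produced metabolite and a non-empty set of associated genes.
#'
#' @param id Short unique identifier, e.g. `"M01"`.
#' @param name Display name.
#' @param inputs Character vector of consumed metabolite ids.
#' @param outputs Character vector of produced metabolite ids.
#' @param genes Non-empty character vector of gene symbols.
#' @return A named list of class `reaction_module`.
#' @export
reaction_module <- function(id, name = id, inputs, outputs, genes) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  inputs <- as.character(inputs); outputs <- as.character(outputs)
  genes <- as.character(genes)
  if (length(genes) == 0L)
    stop("reaction module '", id, "' has an empty gene list", call. = FALSE)
  if (length(inputs) + length(outputs) == 0L)
    stop("reaction module '", id, "' has neither inputs nor outputs", call. = FALSE)
  both <- intersect(inputs, outputs)
  if (length(both))
    stop("reaction module '", id, "' lists ", paste(both, collapse = ", "),
         " as both input and output", call. = FALSE)
  structure(list(id = id, name = name, inputs = unique(inputs),
                 outputs = unique(outputs), genes = unique(genes)),
            class = "reaction_module")
}

#' Assemble a factor graph from metabolites and reaction modules
#'
#' The factor graph is the bipartite representation linking metabolites
#' (variables) and reaction modules (factors) through consume/produce edges.
#' For every metabolite `C_k` the producing set `Fin(C_k)` and consuming set
#' `Fout(C_k)` are derived from the module edge lists.
#'
#' @param metabolites List of [metabolite()] records (or a data.frame with
#'   columns id, name, compartment, role).
#' @param modules List of [reaction_module()] records.
#' @param check If `TRUE` (default), fail on any validation issue reported by
#'   [validate_network()].
#' @return An object of class `factor_graph` with elements `metabolites`
#'   (data.frame), `modules` (named list), `fin`/`fout` (named lists of module
#'   ids per metabolite), and counts `K`, `K_int`, `M`.
#' @export
factor_graph <- function(metabolites, modules, check = TRUE) {
  if (is.data.frame(metabolites)) {
    met_df <- metabolites[, c("id", "name", "compartment", "role")]
  } else {
    met_df <- do.call(rbind, lapply(metabolites, function(m)
      data.frame(id = m$id, name = m$name, compartment = m$compartment,
                 role = m$role, stringsAsFactors = FALSE)))
  }
  rownames(met_df) <- NULL
  if (anyDuplicated(met_df$id))
    stop("duplicated metabolite id(s): ",
         paste(unique(met_df$id[duplicated(met_df$id)]), collapse = ", "),
         call. = FALSE)
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "reaction_module"))
      m <- reaction_module(m$id, m$name, m$inputs, m$outputs, m$genes)
    m
  })
  ids <- vapply(modules, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicated module id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(modules) <- ids

  fin <- fout <- stats::setNames(vector("list", nrow(met_df)), met_df$id)
  for (m in modules) {
    for (k in m$outputs) fin[[k]] <- c(fin[[k]], m$id)
    for (k in m$inputs) fout[[k]] <- c(fout[[k]], m$id)
  }
  g <- structure(list(
    metabolites = met_df,
    modules = modules,
    fin = fin, fout = fout,
    K = nrow(met_df),
    K_int = sum(met_df$role == "intermediate"),
    M = length(modules)
  ), class = "factor_graph")
  if (check) {
    rep <- validate_network(g)
    if (nrow(rep))
      stop("invalid factor graph:\n",
           paste(sprintf("  [%s] %s: %s", rep$type, rep$id, rep$message),
                 collapse = "\n"), call. = FALSE)
  }
  g
}

#' @export
print.factor_graph <- function(x, ...) {
  cat("Factor graph: ", x$M, " reaction modules, ",
      x$K_int, " intermediate and ", x$K - x$K_int, " end metabolites\n",
      sep = "")
  cat("Genes:", length(network_genes(x)), "unique symbols\n")
  invisible(x)
}

#' Metabolite ids of the graph's intermediates, in declared order
#' @param graph A `factor_graph`.
#' @return Character vector.
#' @export
intermediates <- function(graph) {
  graph$metabolites$id[graph$metabolites$role == "intermediate"]
}

#' Union of all gene symbols attached to the graph's modules
#' @param graph A `factor_graph`.
#' @return Character vector of unique gene symbols.
#' @export
network_genes <- function(graph) {
  unique(unlist(lapply(graph$modules, `[[`, "genes"), use.names = FALSE))
}

#' Validate a factor graph
#'
#' Report-only check used both by [factor_graph()] and directly: flags
#' intermediates with an empty producing set (`|Fin| = 0`) or consuming set
#' (`|Fout| = 0`), modules with empty gene lists, and edges pointing at
#' undeclared metabolite ids.  An empty report means the graph is usable by
#' the flux estimator.
#'
#' @param graph A `factor_graph` (possibly built with `check = FALSE`).
#' @return A data.frame with columns `type`, `id`, `message`; zero rows when
#'   the graph is valid.
#' @export
validate_network <- function(graph) {
  issues <- list()
  add <- function(type, id, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, id = id, message = message, stringsAsFactors = FALSE)

  declared <- graph$metabolites$id
  for (m in graph$modules) {
    bad <- setdiff(c(m$inputs, m$outputs), declared)
    for (b in bad) add("dangling_id", m$id, paste0("references undeclared metabolite '", b, "'"))
    if (length(m$genes) == 0L) add("empty_genes", m$id, "module has no genes")
  }
  for (k in intermediates(graph)) {
    if (length(graph$fin[[k]]) == 0L)
      add("orphan_intermediate", k, "intermediate has no producing module (|Fin| = 0)")
    if (length(graph$fout[[k]]) == 0L)
      add("orphan_intermediate", k, "intermediate has no consuming module (|Fout| = 0)")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(type = character(), id = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Signed incidence matrix of intermediates versus modules
#'
#' Entry `(k, m)` is `+1` if module `m` produces intermediate `C_k`
#' (`m` in `Fin(C_k)`), `-1` if it consumes it (`m` in `Fout(C_k)`), and 0
#' otherwise.  This is the stoichiometric matrix of the module-lumped map
#' restricted to balanced (intermediate) metabolites; row order follows the
#' declared intermediate order.
#'
#' @param graph A validated `factor_graph`.
#' @return A numeric `K_int x M` matrix with dimnames.
#' @export
incidence_matrix <- function(graph) {
  ints <- intermediates(graph)
  mods <- names(graph$modules)
  S <- matrix(0, nrow = length(ints), ncol = length(mods),
              dimnames = list(ints, mods))
  for (m in graph$modules) {
    S[intersect(m$outputs, ints), m$id] <- 1
    S[intersect(m$inputs, ints), m$id] <- -1
  }
  S
}

# ---- file I/O --------------------------------------------------------------

#' Load a factor graph from a module table and a gene map
#'
#' The module table is a TSV with columns `module_id`, `role` (`input` or
#' `output`), `metabolite_id`, `compartment`, `met_role` (`intermediate` or
#' `end`), one row per module/metabolite edge.  The gene map is either a GMT
#' file (set name = module id) or a two-column TSV `module_id<TAB>gene`.
#'
#' @param module_table Path to the module-edge TSV.
#' @param gene_map Path to the gene map (GMT or two-column TSV).
#' @return A validated `factor_graph`.
#' @export
load_network <- function(module_table, gene_map) {
  if (!file.exists(module_table)) stop("module table not found: ", module_table, call. = FALSE)
  if (!file.exists(gene_map)) stop("gene map not found: ", gene_map, call. = FALSE)
  tab <- utils::read.delim(module_table, stringsAsFactors = FALSE)
  req <- c("module_id", "role", "metabolite_id", "compartment", "met_role")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("module table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!tab$role %in% c("input", "output"))
  if (length(bad))
    stop("module table row ", bad[1], ": role must be 'input' or 'output', got '",
         tab$role[bad[1]], "'", call. = FALSE)
  bad <- which(!tab$met_role %in% c("intermediate", "end"))
  if (length(bad))
    stop("module table row ", bad[1], ": met_role must be 'intermediate' or 'end', got '",
         tab$met_role[bad[1]], "'", call. = FALSE)

  dup <- duplicated(tab[, c("module_id", "role", "metabolite_id")])
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate module/metabolite edge(s)")
    tab <- tab[!dup, , drop = FALSE]
  }
  # metabolite roles/compartments must be declared consistently across rows
  met <- unique(tab[, c("metabolite_id", "compartment", "met_role")])
  if (anyDuplicated(met$metabolite_id)) {
    d <- met$metabolite_id[duplicated(met$metabolite_id)][1]
    stop("metabolite '", d, "' declared with conflicting compartment/role", call. = FALSE)
  }

  gm <- read_gene_map(gene_map)
  mods <- lapply(split(tab, tab$module_id)[unique(tab$module_id)], function(d) {
    id <- d$module_id[1]
    genes <- gm[[id]]
    if (is.null(genes) || length(genes) == 0L)
      stop("gene map has no genes for module '", id, "'", call. = FALSE)
    reaction_module(id,
                    inputs = d$metabolite_id[d$role == "input"],
                    outputs = d$metabolite_id[d$role == "output"],
                    genes = genes)
  })
  mets <- mapply(metabolite, id = met$metabolite_id, compartment = met$compartment,
                 role = met$met_role, SIMPLIFY = FALSE)
  factor_graph(mets, mods)
}

read_gene_map <- function(path) {
  first <- readLines(path, n = 1L)
  ncol1 <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol1 >= 3L) {  # GMT: name, description, genes...
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[[`, character(1), 1L)
    sets
  } else {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("module_id", "gene"))
    split(d$gene, d$module_id)
  }
}

#' Serialize a factor graph to JSON (and read it back)
#'
#' `save_network()`/`load_network_json()` round-trip a graph losslessly at the
#' id level.
#'
#' @param graph A `factor_graph`.
#' @param path Output (input) file path.
#' @return `save_network()` returns `path` invisibly; `load_network_json()`
#'   returns a validated `factor_graph`.
#' @export
save_network <- function(graph, path) {
  obj <- list(
    metabolites = graph$metabolites,
    modules = lapply(unname(graph$modules), function(m)
      list(id = m$id, name = m$name, inputs = I(m$inputs),
           outputs = I(m$outputs), genes = I(m$genes)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  mets <- obj$metabolites
  mods <- if (is.data.frame(obj$modules)) {
    lapply(seq_len(nrow(obj$modules)), function(i)
      reaction_module(obj$modules$id[i], obj$modules$name[i],
                      unlist(obj$modules$inputs[i]), unlist(obj$modules$outputs[i]),
                      unlist(obj$modules$genes[i])))
  } else {
    lapply(obj$modules, function(m)
      reaction_module(m$id, m$name, unlist(m$inputs), unlist(m$outputs),
                      unlist(m$genes)))
  }
  factor_graph(mets, mods)
}

#' Export a factor graph as a module table + gene map pair
#'
#' Writes the TSV/GMT dialect read by [load_network()].
#'
#' @param graph A `factor_graph`.
#' @param module_table,gene_map Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
export_network_tables <- function(graph, module_table, gene_map) {
  met <- graph$metabolites
  rows <- lapply(graph$modules, function(m) {
    ids <- c(m$inputs, m$outputs)
    data.frame(module_id = m$id,
               role = rep(c("input", "output"), c(length(m$inputs), length(m$outputs))),
               metabolite_id = ids,
               compartment = met$compartment[match(ids, met$id)],
               met_role = met$role[match(ids, met$id)],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), module_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gmt <- vapply(graph$modules, function(m)
    paste(c(m$id, m$name, m$genes), collapse = "\t"), character(1))
  writeLines(gmt, gene_map)
  invisible(c(module_table, gene_map))
}
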