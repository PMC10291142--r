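test_that("a minimal chain assembles with derived Fin/Fout sets", {
  g <- chain_graph(3)
  expect_s3_class(g, "factor_graph")
  expect_equal(g$M, 3)
  expect_equal(g$K_int, 2)
  expect_equal(g$fin[["X1"]], "M1")
  expect_equal(g$fout[["X1"]], "M2")
  expect_equal(nrow(validate_network(g)), 0)
})

test_that("constructor enforces module invariants", {
  expect_error(reaction_module("Mx", inputs = "A", outputs = "B", genes = character(0)),
               "empty gene list")
  expect_error(reaction_module("Mx", inputs = "A", outputs = "A", genes = "g"),
               "both input and output")
  expect_error(factor_graph(list(metabolite("A"), metabolite("A")),
                            list(reaction_module("M", inputs = "A", outputs = "B",
                                                 genes = "g"))),
               "duplicated metabolite")
})

test_that("validation reports orphan intermediates and dangling ids", {
  g <- chain_graph(3)
  broken <- factor_graph(g$metabolites, g$modules[c("M1", "M2")], check = FALSE)
  rep <- validate_network(broken)
  expect_true(any(rep$type == "orphan_intermediate" & rep$id == "X2"))
  expect_match(rep$message[rep$id == "X2"], "Fout")

  dangling <- factor_graph(g$metabolites,
                           c(g$modules,
                             list(reaction_module("M4", inputs = "X3", outputs = "NOPE",
                                                  genes = "g4"))),
                           check = FALSE)
  expect_true(any(validate_network(dangling)$type == "dangling_id"))
})

test_that("incidence matrix follows the +1/-1 producer/consumer convention", {
  S <- incidence_matrix(chain_graph(3))
  expect_equal(unname(S), rbind(c(1, -1, 0), c(0, 1, -1)))
  expect_equal(rownames(S), c("X1", "X2"))

  # metabolite with two producers and one consumer
  g <- factor_graph(
    list(metabolite("S1", role = "end"), metabolite("S2", role = "end"),
         metabolite("K"), metabolite("T", role = "end")),
    list(reaction_module("a", inputs = "S1", outputs = "K", genes = "ga"),
         reaction_module("b", inputs = "S2", outputs = "K", genes = "gb"),
         reaction_module("c", inputs = "K", outputs = "T", genes = "gc")))
  expect_equal(unname(incidence_matrix(g)), matrix(c(1, 1, -1), 1))

  # no intermediates -> 0 x M matrix
  g0 <- factor_graph(list(metabolite("A", role = "end"), metabolite("B", role = "end")),
                     list(reaction_module("M", inputs = "A", outputs = "B", genes = "g")))
  expect_equal(dim(incidence_matrix(g0)), c(0L, 1L))

  # each column has one nonzero per module/intermediate edge
  S_fix <- incidence_matrix(central_metabolism_fixture())
  g_fix <- central_metabolism_fixture()
  for (m in names(g_fix$modules)) {
    mod <- g_fix$modules[[m]]
    n_edges <- length(intersect(c(mod$inputs, mod$outputs), intermediates(g_fix)))
    expect_equal(sum(S_fix[, m] != 0), n_edges)
  }
})

test_that("packaged central-metabolism fixture matches the curated counts", {
  g <- central_metabolism_fixture()
  expect_equal(g$M, 42)
  expect_equal(g$K_int, 27)
  expect_equal(sum(g$metabolites$role == "end"), 15)
  expect_true(all(lengths(lapply(g$modules, `[[`, "genes")) >= 1))
  expect_true(all(g$metabolites$compartment %in%
                    c("cytosol", "mitochondria", "extracellular")))
  expect_equal(nrow(validate_network(g)), 0)
  pw <- module_pathways(g)
  expect_setequal(unique(pw),
                  c("glycolysis", "tca_upper", "tca_lower", "glutaminolysis",
                    "glutamine_glutamate", "glutathione",
                    "nucleotide_synthesis", "serine_synthesis",
                    "aspartate_malate_shuttle", "fatty_acid_synthesis",
                    "2og_transport", "2hg_production"))
})

test_that("table/GMT and JSON round trips preserve the graph at id level", {
  g <- central_metabolism_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  export_network_tables(g, tsv, gmt)
  g2 <- load_network(tsv, gmt)
  expect_equal(sort(names(g2$modules)), sort(names(g$modules)))
  cols <- c("id", "compartment", "role")  # display names are not in the dialect
  expect_equal(g2$metabolites[order(g2$metabolites$id), cols],
               g$metabolites[order(g$metabolites$id), cols],
               ignore_attr = TRUE)
  for (m in names(g$modules)) {
    expect_setequal(g2$modules[[m]]$inputs, g$modules[[m]]$inputs)
    expect_setequal(g2$modules[[m]]$outputs, g$modules[[m]]$outputs)
    expect_setequal(g2$modules[[m]]$genes, g$modules[[m]]$genes)
  }

  js <- withr::local_tempfile(fileext = ".json")
  save_network(g, js)
  g3 <- load_network_json(js)
  expect_equal(names(g3$modules), names(g$modules))
  expect_equal(g3$metabolites, g$metabolites, ignore_attr = TRUE)
  expect_equal(lapply(g3$modules, `[[`, "genes"), lapply(g$modules, `[[`, "genes"))
})

test_that("load_network rejects malformed inputs with informative errors", {
  g <- chain_graph(2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  export_network_tables(g, tsv, gmt)

  # gene map missing a module
  gm_lines <- readLines(gmt)
  writeLines(gm_lines[!grepl("^M2\t", gm_lines)], gmt)
  expect_error(load_network(tsv, gmt), "M2")

  export_network_tables(g, tsv, gmt)
  # duplicate edges collapse with a warning
  tab <- read.delim(tsv)
  write.table(rbind(tab, tab[1, ]), tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(g2 <- load_network(tsv, gmt), "duplicate")
  expect_equal(g2$M, 2)

  expect_error(load_network("no/such/file.tsv", gmt), "not found")
})
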