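# Small graphs used across the suite.

# linear chain X0 -> M1 -> X1 -> ... -> Mk -> Xk (X0/Xk are ends)
chain_graph <- function(k = 3L, genes_per_module = 1L) {
  mets <- c(list(metabolite("X0", role = "end", compartment = "extracellular")),
            lapply(seq_len(k - 1L), function(i) metabolite(paste0("X", i))),
            list(metabolite(paste0("X", k), role = "end")))
  mods <- lapply(seq_len(k), function(i)
    reaction_module(paste0("M", i),
                    inputs = paste0("X", i - 1L), outputs = paste0("X", i),
                    genes = paste0("g", i, "_", seq_len(genes_per_module))))
  factor_graph(mets, mods)
}

# one source splitting into two parallel branches that rejoin
diamond_graph <- function() {
  factor_graph(
    list(metabolite("SRC", role = "end", compartment = "extracellular"),
         metabolite("X"), metabolite("Y"),
         metabolite("SNK", role = "end")),
    list(reaction_module("M1", inputs = "SRC", outputs = "X", genes = "gm1"),
         reaction_module("M2", inputs = "X", outputs = "Y", genes = "gm2"),
         reaction_module("M3", inputs = "X", outputs = "Y", genes = "gm3"),
         reaction_module("M4", inputs = "Y", outputs = "SNK", genes = "gm4")))
}
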