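# Packaged central-metabolism factor graph.
#
# The curation covers six major pathways -- glycolysis, upper and lower TCA
# cycle, glutaminolysis, glutamine and glutamate metabolism, glutathione
# metabolism -- and six minor branches: G3P to nucleotide synthesis, 3PD to
# serine synthesis, the aspartate-malate shuttle, mitochondrial citrate
# fueling fatty-acid synthesis, 2OG transport to the cytosol, and 2OG to 2HG.
# Reaction modules are directed, unit-stoichiometry lumps of consecutive
# reactions; gene rosters are best-effort HGNC symbols per module.

# id | name | compartment | role
.fc_metabolites <- c(
  "G6P_c|glucose-6-phosphate|cytosol|intermediate",
  "G3P_c|glyceraldehyde-3-phosphate|cytosol|intermediate",
  "3PD_c|3-phospho-D-glycerate|cytosol|intermediate",
  "PEP_c|phosphoenolpyruvate|cytosol|intermediate",
  "PYR_c|pyruvate|cytosol|intermediate",
  "LAC_c|lactate|cytosol|intermediate",
  "ACCOA_m|acetyl-CoA|mitochondria|intermediate",
  "CIT_m|citrate|mitochondria|intermediate",
  "ACO_m|cis-aconitate|mitochondria|intermediate",
  "2OG_m|2-oxoglutarate|mitochondria|intermediate",
  "SUCCOA_m|succinyl-CoA|mitochondria|intermediate",
  "SUC_m|succinate|mitochondria|intermediate",
  "MAL_m|malate|mitochondria|intermediate",
  "OAA_m|oxaloacetate|mitochondria|intermediate",
  "GLN_c|glutamine|cytosol|intermediate",
  "GLU_c|glutamate|cytosol|intermediate",
  "GLN_m|glutamine|mitochondria|intermediate",
  "GLU_m|glutamate|mitochondria|intermediate",
  "GABA_m|gamma-aminobutyric acid|mitochondria|intermediate",
  "GSH_c|glutathione (reduced)|cytosol|intermediate",
  "GSH_m|glutathione (reduced)|mitochondria|intermediate",
  "GSSG_m|glutathione disulfide|mitochondria|intermediate",
  "MAL_c|malate|cytosol|intermediate",
  "ASP_c|aspartate|cytosol|intermediate",
  "CIT_c|citrate|cytosol|intermediate",
  "2OG_c|2-oxoglutarate|cytosol|intermediate",
  "SER_c|serine|cytosol|intermediate",
  "GLC_e|glucose|extracellular|end",
  "GLN_e|glutamine|extracellular|end",
  "GLU_e|glutamate|extracellular|end",
  "CYS_c|cysteine|cytosol|end",
  "GLY_c|glycine|cytosol|end",
  "LAC_e|lactate|extracellular|end",
  "CO2_m|carbon dioxide|mitochondria|end",
  "NH4_m|ammonia|mitochondria|end",
  "AA_c|amino-acid pool|cytosol|end",
  "AA_m|amino-acid pool|mitochondria|end",
  "NUC_c|nucleotides|cytosol|end",
  "ASN_c|asparagine|cytosol|end",
  "FA_c|fatty acids|cytosol|end",
  "2HG_c|2-hydroxyglutarate|cytosol|end",
  "MTHF_c|one-carbon units (methylene-THF)|cytosol|end"
)

# id | name | inputs | outputs | genes | pathway
.fc_modules <- c(
  "M01|glucose uptake and phosphorylation|GLC_e|G6P_c|SLC2A1,SLC2A2,SLC2A3,SLC2A4,HK1,HK2,HK3,GCK|glycolysis",
  "M02|G6P to G3P (upper glycolysis)|G6P_c|G3P_c|GPI,PFKL,PFKM,PFKP,PFKFB1,PFKFB2,PFKFB3,PFKFB4,ALDOA,ALDOB,ALDOC,TPI1|glycolysis",
  "M03|G3P to 3PD|G3P_c|3PD_c|GAPDH,GAPDHS,PGK1,PGK2|glycolysis",
  "M04|3PD to PEP|3PD_c|PEP_c|PGAM1,PGAM2,PGAM4,ENO1,ENO2,ENO3|glycolysis",
  "M05|PEP to pyruvate|PEP_c|PYR_c|PKM,PKLR|glycolysis",
  "M06|lactate production|PYR_c|LAC_c|LDHA,LDHB,LDHC,LDHAL6A,LDHAL6B|glycolysis",
  "M07|lactate export|LAC_c|LAC_e|SLC16A1,SLC16A3,SLC16A7,SLC16A8|glycolysis",
  "M08|pyruvate to acetyl-CoA|PYR_c|ACCOA_m,CO2_m|MPC1,MPC2,PDHA1,PDHA2,PDHB,DLAT,DLD,PDHX,PDK1,PDK2,PDK3,PDK4|tca_upper",
  "M09|acetyl-CoA + oxaloacetate to citrate|ACCOA_m,OAA_m|CIT_m|CS|tca_upper",
  "M10|citrate to cis-aconitate|CIT_m|ACO_m|ACO2|tca_upper",
  "M11|cis-aconitate to 2OG|ACO_m|2OG_m,CO2_m|IDH2,IDH3A,IDH3B,IDH3G|tca_upper",
  "M12|2OG to succinyl-CoA|2OG_m|SUCCOA_m,CO2_m|OGDH,OGDHL,DLST,DLD|tca_lower",
  "M13|succinyl-CoA to succinate|SUCCOA_m|SUC_m|SUCLA2,SUCLG1,SUCLG2|tca_lower",
  "M14|succinate to malate|SUC_m|MAL_m|SDHA,SDHB,SDHC,SDHD,FH|tca_lower",
  "M15|malate to oxaloacetate|MAL_m|OAA_m|MDH2|tca_lower",
  "M16|glutamine import|GLN_e|GLN_c|SLC1A5,SLC38A1,SLC38A2,SLC38A3,SLC38A5,SLC7A5,SLC7A8|glutamine_glutamate",
  "M17|glutamate import|GLU_e|GLU_c|SLC1A1,SLC1A2,SLC1A3,SLC1A6,SLC1A7|glutamine_glutamate",
  "M18|glutamine transport into mitochondria|GLN_c|GLN_m|SLC1A5,SLC38A1|glutamine_glutamate",
  "M19|glutaminase (Gln to Glu, mito)|GLN_m|GLU_m,NH4_m|GLS,GLS2|glutaminolysis",
  "M20|glutamate dehydrogenase (Glu to 2OG)|GLU_m|2OG_m,NH4_m|GLUD1,GLUD2,GOT2|glutaminolysis",
  "M21|glutamate decarboxylase (Glu to GABA)|GLU_m|GABA_m,CO2_m|GAD1,GAD2|glutaminolysis",
  "M22|GABA shunt (GABA to succinate)|GABA_m|SUC_m|ABAT,ALDH5A1|glutaminolysis",
  "M23|glutamate transport mito to cytosol|GLU_m|GLU_c|SLC25A18,SLC25A22|glutamine_glutamate",
  "M24|glutamine synthetase (Glu to Gln, cyto)|GLU_c|GLN_c|GLUL|glutamine_glutamate",
  "M25|glutamine to other amino acids (cyto)|GLN_c|AA_c|ASNS,PPAT,GFPT1,GFPT2,CTPS1,CTPS2,NADSYN1|glutamine_glutamate",
  "M26|glutamate to other amino acids (cyto)|GLU_c|AA_c|GOT1,GPT,GPT2,TAT,OAT|glutamine_glutamate",
  "M27|glutathione biosynthesis (cyto)|GLU_c,CYS_c,GLY_c|GSH_c|GCLC,GCLM,GSS|glutathione",
  "M28|glutathione biosynthesis from Glu (mito)|GLU_m|GSH_m|GCLC,GCLM,GSS|glutathione",
  "M29|glutathione transport into mitochondria|GSH_c|GSH_m|SLC25A39,SLC25A40|glutathione",
  "M30|GSH oxidation to GSSG (enzyme-catalyzed)|GSH_m|GSSG_m|GPX1,GPX2,GPX3,GPX4,GPX7,GSTP1,GSTM1,GSTA1|glutathione",
  "M31|GSSG reduction to GSH|GSSG_m|GSH_m|GSR|glutathione",
  "M32|glutathione to other amino acids|GSH_m|AA_m|GGT1,GGT5,GGT6,GGT7,CHAC1,CHAC2,OPLAH,ANPEP|glutathione",
  "M33|G3P to nucleotide synthesis|G3P_c|NUC_c|TKT,TKTL1,TKTL2,TALDO1,PRPS1,PRPS2,PRPS1L1,RRM1,RRM2,RRM2B|nucleotide_synthesis",
  "M34|3PD to serine|3PD_c|SER_c|PHGDH,PSAT1,PSPH|serine_synthesis",
  "M35|serine to glycine + one-carbon units|SER_c|GLY_c,MTHF_c|SHMT1,SHMT2|serine_synthesis",
  "M36|malate transport mito to cytosol|MAL_m|MAL_c|SLC25A10,SLC25A11|aspartate_malate_shuttle",
  "M37|malate to aspartate (cyto)|MAL_c|ASP_c|MDH1,GOT1|aspartate_malate_shuttle",
  "M38|aspartate to asparagine/other amino acids|ASP_c|ASN_c|ASNS,ADSS,ADSL,ASS1,ASL|aspartate_malate_shuttle",
  "M39|citrate export to cytosol|CIT_m|CIT_c|SLC25A1|fatty_acid_synthesis",
  "M40|citrate to fatty-acid synthesis|CIT_c|FA_c|ACLY,ACACA,ACACB,FASN,ELOVL6,SCD|fatty_acid_synthesis",
  "M41|2OG transport mito to cytosol|2OG_m|2OG_c|SLC25A11|2og_transport",
  "M42|2OG to 2HG|2OG_c|2HG_c|IDH1,IDH2|2hg_production"
)

#' Packaged central-metabolism factor graph
#'
#' Returns the curated central-metabolism network shipped with the package:
#' 42 reaction modules, 27 intermediate and 15 end metabolites spanning
#' cytosol, mitochondria and the extracellular space.  The curation covers
#' the six major pathways (glycolysis, upper and lower TCA cycle,
#' glutaminolysis, glutamine and glutamate metabolism, glutathione
#' metabolism) and six minor branches (nucleotide synthesis from G3P, serine
#' synthesis from 3PD, the aspartate-malate shuttle, citrate-fueled
#' fatty-acid synthesis, 2OG transport to the cytosol, and 2OG to 2HG).
#' Each module carries a `pathway` tag, retrievable with
#' [module_pathways()].
#'
#' @return A validated `factor_graph`.
#' @examples
#' g <- central_metabolism_fixture()
#' g$M      # 42
#' g$K_int  # 27
#' @export
central_metabolism_fixture <- function() {
  mets <- lapply(strsplit(.fc_metabolites, "|", fixed = TRUE), function(x)
    metabolite(x[1], x[2], x[3], x[4]))
  parsed <- strsplit(.fc_modules, "|", fixed = TRUE)
  mods <- lapply(parsed, function(x)
    reaction_module(x[1], x[2],
                    inputs = strsplit(x[3], ",", fixed = TRUE)[[1]],
                    outputs = strsplit(x[4], ",", fixed = TRUE)[[1]],
                    genes = strsplit(x[5], ",", fixed = TRUE)[[1]]))
  g <- factor_graph(mets, mods)
  attr(g, "pathway") <- stats::setNames(
    vapply(parsed, `[[`, character(1), 6L),
    vapply(parsed, `[[`, character(1), 1L))
  g
}

#' Pathway tag of each module in the packaged fixture
#'
#' @param graph A graph produced by [central_metabolism_fixture()].
#' @return Named character vector (module id -> pathway tag), or `NULL` for
#'   graphs without pathway annotation.
#' @export
module_pathways <- function(graph) {
  attr(graph, "pathway", exact = TRUE)
}
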