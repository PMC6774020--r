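#' The default 168-gene capture panel
#'
#' Gene symbols emulating a targeted capture panel of 168 cancer genes, as
#' used for plasma circulating-DNA profiling. The set always contains
#' `ARID1A`, `BRCA2`, `TGFBR2` and `IDH1`, which downstream analyses
#' (resistance screen, acquired-mutation analysis, combined classifier)
#' refer to by name.
#'
#' @return Character vector of 168 gene symbols.
#' @export
panel_genes_168 <- function() {
  genes <- c(
    "ARID1A", "BRCA2", "TGFBR2", "IDH1", "EGFR", "ALK", "ROS1", "TP53",
    "KRAS", "BRAF", "MET", "ERBB2", "ERBB3", "ERBB4", "PIK3CA", "PTEN",
    "STK11", "KEAP1", "NF1", "NF2", "RB1", "CDKN2A", "CDKN2B", "CDK4",
    "CDK6", "CCND1", "CCND2", "CCND3", "CCNE1", "MYC", "MYCN", "MYCL",
    "MDM2", "MDM4", "ATM", "ATR", "BRCA1", "PALB2", "BARD1", "CHEK1",
    "CHEK2", "RAD51", "RAD51B", "RAD51C", "RAD51D", "RAD54L", "FANCA",
    "FANCC", "FANCD2", "FANCE", "FANCF", "FANCG", "FANCL", "MLH1", "MSH2",
    "MSH3", "MSH6", "PMS2", "POLE", "POLD1", "APC", "SMAD2", "SMAD3",
    "SMAD4", "TGFBR1", "ARID1B", "ARID2", "SMARCA4", "SMARCB1", "PBRM1",
    "BAP1", "SETD2", "KMT2A", "KMT2C", "KMT2D", "KDM5C", "KDM6A", "EZH2",
    "CREBBP", "EP300", "NSD1", "SETBP1", "DNMT3A", "TET2", "IDH2", "ASXL1",
    "BCOR", "BCORL1", "STAG2", "RAD21", "SMC1A", "SMC3", "CTCF", "AXIN1",
    "AXIN2", "CTNNB1", "FBXW7", "NOTCH1", "NOTCH2", "NOTCH3", "NOTCH4",
    "JAK1", "JAK2", "JAK3", "STAT3", "SOCS1", "IL7R", "FLT1", "FLT3",
    "FLT4", "KDR", "KIT", "PDGFRA", "PDGFRB", "FGFR1", "FGFR2", "FGFR3",
    "FGFR4", "IGF1R", "INSR", "NTRK1", "NTRK2",
    "NTRK3", "RET", "AKT1", "AKT2", "AKT3", "MTOR", "RICTOR", "RPTOR",
    "TSC1", "TSC2", "PIK3CB", "PIK3CD", "PIK3R1", "PIK3R2", "INPP4B",
    "NRAS", "HRAS", "RIT1", "MAP2K1", "MAP2K2", "MAP2K4", "MAPK1", "RAF1",
    "ARAF", "RASA1", "SOS1", "PTPN11", "CBL", "SRC", "ABL1",
    "GNAS", "GNAQ", "GNA11", "VHL", "HIF1A", "EPAS1", "ESR1", "AR",
    "CDH1", "VEGFA", "HGF", "GATA3", "RUNX1", "FOXA1", "SPOP", "NFE2L2"
  )
  stopifnot(!anyDuplicated(genes), length(genes) == 168L)
  genes
}
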