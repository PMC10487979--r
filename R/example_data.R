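#' Seed-plant intron complement worked example
#'
#' Builds the presence/absence matrix implied by the printed seed-plant
#' intron complements -- gymnosperms carry sites 1-22, with Gnetum and
#' Welwitschia additionally carrying the derived site 21'; ANA-grade
#' angiosperms carry sites 1-22; Mesangiospermae carry sites 1-20 and 22
#' (intron 21 lost on their stem) -- on a rooted seed-plant topology with
#' gymnosperms sister to angiosperms and the ANA grade subtending
#' Mesangiospermae. Dollo reconstruction on this input places 22 introns
#' at the seed-plant ancestor, 21 at the Mesangiospermae ancestor and 23
#' at the Gnetum + Welwitschia ancestor.
#'
#' @return list with `matrix` (taxa x sites, sites labeled `1..22` and
#'   `21'`), `tree` (labeled `phylo`; internal nodes include
#'   `seed_plants`, `gymnosperms`, `gnetales`, `angiosperms`,
#'   `mesangiospermae`).
#' @export
seed_plant_example <- function() {
  newick <- paste0(
    "((Cycas_panzhihuaensis,(Ginkgo_biloba,",
    "(Gnetum_montanum,Welwitschia_mirabilis)gnetales)gnetophyte_allies)",
    "gymnosperms,(Amborella_trichopoda,((Nymphaea_thermarum,Euryale_ferox)",
    "nymphaeales,((Oryza_sativa,Liriodendron_chinense)mesang_a,",
    "(Vitis_vinifera,Arabidopsis_thaliana)mesang_b)mesangiospermae)",
    "core_angiosperms)angiosperms)seed_plants;")
  tree <- parse_newick(newick)

  gymnosperms <- c("Cycas_panzhihuaensis", "Ginkgo_biloba")
  gnetales <- c("Gnetum_montanum", "Welwitschia_mirabilis")
  ana <- c("Amborella_trichopoda", "Nymphaea_thermarum", "Euryale_ferox")
  mesang <- c("Oryza_sativa", "Liriodendron_chinense", "Vitis_vinifera",
              "Arabidopsis_thaliana")

  sites <- c(as.character(1:21), "21'", "22")
  taxa <- c(gymnosperms, gnetales, ana, mesang)
  mat <- matrix(0L, nrow = length(taxa), ncol = length(sites),
                dimnames = list(taxa, sites))
  mat[c(gymnosperms, gnetales, ana), as.character(1:22)] <- 1L
  mat[gnetales, "21'"] <- 1L
  mat[mesang, c(as.character(1:20), "22")] <- 1L
  list(matrix = mat, tree = tree)
}
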