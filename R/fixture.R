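#' Synthetic softshell-turtle study fixture
#'
#' A fully synthetic, seeded bundle emulating a comparative qPCR
#' gene-dosage study of the softshell turtle family: 10 trionychid taxa
#' (7 Trionychinae, 3 Cyclanorbinae including both \emph{Lissemys
#' punctata} subspecies) assayed for 2 autosomal controls, 6 candidate
#' Z-linked genes, 2 single-copy reference genes and one 18S rRNA
#' copy-number assay, in triplicate for 3 animals per sex. The taxa,
#' copy-number structure, primer-failure pattern and rRNA multipliers are
#' constructed, not measured: primer dropout increases with distance from
#' \emph{Pelodiscus sinensis} (the primer-design genome), every species
#' keeps both autosomal controls and at least three usable Z genes, both
#' \emph{Lissemys} subspecies get female:male 18S multipliers at or below
#' 1 (the regime where rRNA sexing fails) while all other taxa draw
#' multipliers uniformly from [2.8, 18.4] (\emph{Apalone spinifera} is
#' pinned at 3.43). \emph{P. sinensis} and \emph{A. spinifera} are
#' flagged as having previously documented sex chromosomes.
#'
#' @param seed integer seed governing the rRNA multiplier draws and the
#'   Cq simulation.
#' @param n_per_sex animals per sex per species, default 3.
#' @param cq_sd,template_sd,rrna_jitter_sd noise settings (cycles / log
#'   scale), defaults 0.05, 0.15, 0.1. The default technical noise is the
#'   clean-plate regime of a well-optimized assay; the fixture's contract
#'   (every taxon resolvable end-to-end under default pipeline settings)
#'   presumes it. Harsher plates are simulated by raising \code{cq_sd}.
#' @param n_replicates technical replicates, default 3.
#' @return List: \code{panel}, \code{genomes}, \code{noise},
#'   \code{cq_table}, \code{meta}, \code{tree} (a
#'   \code{\link{parse_dated_newick}} chronogram with tip states),
#'   \code{prior_documented}, \code{seed}.
#' @examples
#' fx <- default_trionychid_fixture(seed = 7)
#' table(fx$meta$species_id, fx$meta$phenotypic_sex)
#' @export
default_trionychid_fixture <- function(seed = 1, n_per_sex = 3,
                                       cq_sd = 0.05, template_sd = 0.15,
                                       rrna_jitter_sd = 0.1,
                                       n_replicates = 3) {
  panel <- qpcr_panel(
    gene_id = c("adarb2", "mecom",
                "anapc7", "ccdc92", "cux2", "ppm1f", "sh2b3", "tmem132d",
                "rag1", "mos", "rRNA_18S"),
    role = c("target", "target",
             "target", "target", "target", "target", "target", "target",
             "reference", "reference", "rrna"))
  z_genes <- c("anapc7", "ccdc92", "cux2", "ppm1f", "sh2b3", "tmem132d")
  all_genes <- panel$gene_id

  taxa <- trionychid_fixture_taxa()
  set.seed(as.integer(seed))
  mult <- stats::setNames(stats::runif(length(taxa), 2.8, 18.4), taxa)
  mult["Apalone_spinifera"] <- 3.43
  mult["Lissemys_punctata_punctata"] <- 0.94
  mult["Lissemys_punctata_andersoni"] <- 0.62

  genomes <- lapply(taxa, function(sp) {
    cm <- stats::setNames(rep(2L, length(all_genes)), all_genes)
    cf <- cm
    cf[z_genes] <- 1L
    genome_model(cm, cf, rrna_w_multiplier = mult[[sp]],
                 rrna_jitter_sd = rrna_jitter_sd)
  })
  names(genomes) <- taxa

  # deterministic primer-failure pattern: assays designed on P. sinensis
  # fail in phylogenetically distant lineages
  dropout <- list(
    Trionyx_triunguis = list(tmem132d = 1),
    Chitra_chitra = list(sh2b3 = 1),
    Cyclanorbis_senegalensis = list(tmem132d = 1, sh2b3 = 1),
    Lissemys_punctata_punctata = list(tmem132d = 1, sh2b3 = 1),
    Lissemys_punctata_andersoni = list(tmem132d = 1, sh2b3 = 1))
  secondary <- list(
    Lissemys_punctata_andersoni = list(cux2 = 1))

  noise <- noise_model(cq_sd = cq_sd, template_sd = template_sd,
                       dropout = dropout, secondary_product = secondary)
  sim <- simulate_cq_table(
    genomes, panel, n_per_sex = n_per_sex, noise = noise, seed = seed,
    n_replicates = n_replicates,
    prior_documented = c("Pelodiscus_sinensis", "Apalone_spinifera"))

  tree <- trionychid_fixture_tree()
  list(panel = panel, genomes = genomes, noise = noise,
       cq_table = sim$cq_table, meta = sim$meta, tree = tree,
       prior_documented = c("Pelodiscus_sinensis", "Apalone_spinifera"),
       seed = seed)
}

trionychid_fixture_taxa <- function() {
  c("Pelodiscus_sinensis", "Palea_steindachneri", "Apalone_spinifera",
    "Amyda_cartilaginea", "Nilssonia_nigricans", "Chitra_chitra",
    "Trionyx_triunguis", "Cyclanorbis_senegalensis",
    "Lissemys_punctata_punctata", "Lissemys_punctata_andersoni")
}

#' Fixture chronogram for the softshell-turtle family
#'
#' An ultrametric synthetic chronogram of the 10 fixture taxa plus the
#' ESD outgroup \emph{Carettochelys insculpta}. Two node ages carry the
#' published calibration this package's origin bracketing is built
#' around: the Trionychidae-Carettochelyidae split at 200 Mya and the
#' trionychid crown at \code{crown_age} (default 120 Mya; 105 is the
#' lower edge of published crown estimates). All other internal ages are
#' invented fixture values (scaled with \code{crown_age}) — the tree is a
#' test harness, not an inference.
#'
#' @param crown_age trionychid crown age in Mya, default 120.
#' @param root_age family-split age in Mya, default 200.
#' @return A \code{\link{parse_dated_newick}} object with tip states
#'   (all trionychids \code{zw}, outgroup \code{esd}).
#' @export
trionychid_fixture_tree <- function(crown_age = 120, root_age = 200) {
  stopifnot(crown_age > 0, root_age > crown_age)
  s <- crown_age / 120
  a <- function(x) x * s   # interior fixture ages scale with the crown
  # node ages (Mya)
  cy <- a(60); li <- a(10)                 # Cyclanorbinae crown, Lissemys split
  tr <- a(95); n2 <- a(85); n3 <- a(75)    # Trionychinae ladder
  pp <- a(56); ap <- a(60); an <- a(45)
  nwk <- sprintf(paste0(
    "(((Cyclanorbis_senegalensis:%g,(Lissemys_punctata_punctata:%g,",
    "Lissemys_punctata_andersoni:%g):%g):%g,",
    "(Chitra_chitra:%g,(Trionyx_triunguis:%g,",
    "((Pelodiscus_sinensis:%g,Palea_steindachneri:%g):%g,",
    "(Apalone_spinifera:%g,(Amyda_cartilaginea:%g,",
    "Nilssonia_nigricans:%g):%g):%g):%g):%g):%g):%g,",
    "Carettochelys_insculpta:%g);"),
    cy, li, li, cy - li, crown_age - cy,
    tr, n2, pp, pp, n3 - pp, ap, an, an, ap - an, n3 - ap, n2 - n3,
    tr - n2, crown_age - tr, root_age - crown_age, root_age)
  states <- stats::setNames(
    c(rep("zw", 10L), "esd"),
    c(trionychid_fixture_taxa(), "Carettochelys_insculpta"))
  parse_dated_newick(nwk, tip_states = states)
}
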