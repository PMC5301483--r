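#' Genome copy-number model for one species
#'
#' Declares, per assayed gene, how many copies male and female genomes
#' carry. Under female heterogamety a Z-specific gene is present twice in
#' ZZ males and once in ZW females; autosomal and reference genes are 2/2.
#' The 18S rRNA assay is modelled multiplicatively: females carry
#' \code{rrna_w_multiplier} times the male copy number (W-linked rRNA
#' amplification), with optional lognormal individual jitter reflecting
#' the copy-number lability of rRNA clusters.
#'
#' @param copies_male,copies_female named integer vectors (gene ->
#'   copies). Genes default to 2/2 when present in only one vector.
#' @param rrna_w_multiplier female:male 18S copy factor, >= 0; 1 means no
#'   sex difference (the assay then cannot sex this species).
#' @param rrna_jitter_sd lognormal sd (log scale) of individual rRNA
#'   copy-number variation, default 0.
#' @return Object of class \code{"genome_model"}.
#' @export
genome_model <- function(copies_male, copies_female,
                         rrna_w_multiplier = 1, rrna_jitter_sd = 0) {
  genes <- union(names(copies_male), names(copies_female))
  cm <- stats::setNames(rep(2L, length(genes)), genes)
  cf <- cm
  cm[names(copies_male)] <- as.integer(copies_male)
  cf[names(copies_female)] <- as.integer(copies_female)
  if (any(cm < 1L))
    stop("copies_male must be >= 1 for every assayed gene")
  if (any(cf < 0L)) stop("negative female copy number")
  if (rrna_w_multiplier < 0) stop("rrna_w_multiplier must be >= 0")
  structure(list(copies_male = cm, copies_female = cf,
                 rrna_w_multiplier = rrna_w_multiplier,
                 rrna_jitter_sd = rrna_jitter_sd),
            class = "genome_model")
}

#' Technical noise model for simulated qPCR
#'
#' @param cq_sd technical replicate noise, cycles (sd of a well's Cq).
#' @param template_sd per-sample DNA-amount variation, sd on the natural
#'   log of the template quantity (shifts all of a sample's wells
#'   together; normalization cancels it).
#' @param dropout,secondary_product assay-failure probabilities: scalar,
#'   or nested named list \code{species -> gene -> probability}. A failure
#'   is drawn once per species x gene (primer-template mismatch affects
#'   the species, not the well): dropout turns all wells of the assay into
#'   \code{no_amplification}, a secondary product flags them all
#'   \code{secondary_product}.
#' @return Object of class \code{"noise_model"}.
#' @export
noise_model <- function(cq_sd = 0, template_sd = 0, dropout = 0,
                        secondary_product = 0) {
  stopifnot(cq_sd >= 0, template_sd >= 0)
  structure(list(cq_sd = cq_sd, template_sd = template_sd,
                 dropout = dropout, secondary_product = secondary_product),
            class = "noise_model")
}

prob_lookup <- function(map, species, gene) {
  if (is.numeric(map) && length(map) == 1L) return(map)
  p <- map[[species]][[gene]]
  if (is.null(p)) 0 else p
}

#' Simulate a Cq table from genome and noise models
#'
#' Generates triplicate quantification cycles for every sample x assay
#' under exponential amplification: a well's expected Cq is
#' \code{baseline_cq - log_E(copies x template)}, so doubling the copy
#' number advances amplification by one cycle at E = 2. Technical noise
#' is added per well; template-amount variation per sample; assay
#' failures (primer dropout, unspecific secondary products) are drawn per
#' species x gene. A single integer seed governs all draws through a
#' fixed stream order — species (list order), then per-species assay
#' failures (panel order), then samples (females first), each sample's
#' template draw, then genes in panel order, replicates innermost — so a
#' given seed always yields an identical table.
#'
#' @param genomes named list species_id -> \code{\link{genome_model}}.
#' @param panel \code{\link{qpcr_panel}}; panel genes must all appear in
#'   each genome model.
#' @param n_per_sex individuals per sex per species (scalar or named
#'   vector by species), default 3.
#' @param noise \code{\link{noise_model}}, default noiseless.
#' @param seed integer seed.
#' @param n_replicates technical replicates per well group, default 3.
#' @param baseline_cq Cq of a single-copy gene at unit template, default
#'   22 (cancels in every ratio).
#' @param rrna_baseline_offset additive Cq offset for the rRNA assay,
#'   default -8 (rDNA is high-copy; also cancels in ratios).
#' @param prior_documented character vector of species whose sex
#'   chromosomes were already published (sets the metadata flag).
#' @return List with \code{cq_table} and \code{meta} data frames in the
#'   package's standard formats.
#' @examples
#' gm <- genome_model(c(z1 = 2, a1 = 2, rag1 = 2, mos = 2),
#'                    c(z1 = 1, a1 = 2, rag1 = 2, mos = 2))
#' p <- qpcr_panel(c("z1", "a1", "rag1", "mos"),
#'                 c("target", "target", "reference", "reference"))
#' sim <- simulate_cq_table(list(sp = gm), p, n_per_sex = 1, seed = 1)
#' head(sim$cq_table)
#' @export
simulate_cq_table <- function(genomes, panel, n_per_sex = 3,
                              noise = noise_model(), seed = 1,
                              n_replicates = 3, baseline_cq = 22,
                              rrna_baseline_offset = -8,
                              prior_documented = character()) {
  stopifnot(is.list(genomes), length(genomes) >= 1L,
            !is.null(names(genomes)))
  rrna_gene <- panel_genes(panel, "rrna")
  for (sp in names(genomes)) {
    missing_genes <- setdiff(panel$gene_id, names(genomes[[sp]]$copies_male))
    if (length(missing_genes))
      stop("genome model for ", sp, " lacks panel gene(s): ",
           paste(missing_genes, collapse = ", "))
  }
  if (length(n_per_sex) == 1L && is.null(names(n_per_sex)))
    n_per_sex <- stats::setNames(rep(n_per_sex, length(genomes)),
                                 names(genomes))
  set.seed(as.integer(seed))

  n_wells <- sum(vapply(names(genomes), function(sp) n_per_sex[[sp]], 0)) *
    2L * nrow(panel) * n_replicates
  cq_sample <- character(n_wells); cq_gene <- character(n_wells)
  cq_rep <- integer(n_wells); cq_val <- numeric(n_wells)
  cq_qc <- character(n_wells); w <- 0L
  meta_rows <- list()
  for (sp in names(genomes)) {
    gm <- genomes[[sp]]
    # assay fate in this species, one draw per gene (panel order)
    fate <- stats::setNames(rep("ok", nrow(panel)), panel$gene_id)
    for (g in panel$gene_id) {
      u <- stats::runif(2L)
      if (u[1L] < prob_lookup(noise$dropout, sp, g)) fate[g] <- "no_amplification"
      else if (u[2L] < prob_lookup(noise$secondary_product, sp, g))
        fate[g] <- "secondary_product"
    }
    n <- n_per_sex[[sp]]
    for (sex in c("female", "male")) {
      for (i in seq_len(n)) {
        sid <- sprintf("%s_%s%d", sp, if (sex == "female") "F" else "M", i)
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          sample_id = sid, species_id = sp, phenotypic_sex = sex,
          prior_documented = sp %in% prior_documented,
          stringsAsFactors = FALSE)
        log_template <- stats::rnorm(1L, 0, noise$template_sd)
        rrna_jitter <- stats::rnorm(1L, 0, gm$rrna_jitter_sd)
        for (g in panel$gene_id) {
          copies <- if (sex == "female") gm$copies_female[[g]]
                    else gm$copies_male[[g]]
          base <- baseline_cq
          if (length(rrna_gene) && g == rrna_gene) {
            base <- base + rrna_baseline_offset
            if (sex == "female")
              copies <- copies * gm$rrna_w_multiplier * exp(rrna_jitter)
          }
          eps <- stats::rnorm(n_replicates, 0, noise$cq_sd)
          flag <- fate[[g]]
          if (flag == "ok" && copies <= 0) flag <- "no_amplification"
          cq <- rep(NA_real_, n_replicates)
          if (flag == "ok") {
            e <- panel_efficiency(panel, g)
            cq <- base - log(copies * exp(log_template)) / log(e) + eps
          }
          idx <- w + seq_len(n_replicates)
          cq_sample[idx] <- sid; cq_gene[idx] <- g
          cq_rep[idx] <- seq_len(n_replicates); cq_val[idx] <- cq
          cq_qc[idx] <- flag
          w <- w + n_replicates
        }
      }
    }
  }
  list(cq_table = data.frame(
         sample_id = cq_sample, gene_id = cq_gene, replicate = cq_rep,
         cq = cq_val, qc_flag = cq_qc, stringsAsFactors = FALSE),
       meta = do.call(rbind, meta_rows))
}
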