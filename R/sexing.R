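# Reference-normalized rRNA quantity of one sample: q(18S)/q(ref gene),
# from QC'd replicate sets; NULL when either assay is unusable.
rrna_quantity <- function(sample, reps, rrna_gene, reference_gene, panel) {
  q18_reps <- reps[[paste(sample, rrna_gene, sep = "\r")]]
  ref_reps <- reps[[paste(sample, reference_gene, sep = "\r")]]
  if (is.null(q18_reps) || is.null(ref_reps)) return(NULL)
  relative_quantity(mean(q18_reps), panel_efficiency(panel, rrna_gene)) /
    relative_quantity(mean(ref_reps), panel_efficiency(panel, reference_gene))
}

#' 18S rRNA copy-number ratio of a sample against male references
#'
#' In several trionychid turtles the W chromosome carries a large
#' amplification of the 18S-28S rRNA cluster, so ZW females carry far more
#' 18S copies than ZZ males. This assay expresses a sample's
#' reference-normalized 18S quantity as a percentage of the mean level in
#' known male reference individuals of the same species: 100 means
#' male-like; several hundred percent indicates a W-amplified female.
#' Normalization uses the single-copy gene \code{rag1} by default; there
#' is deliberately no fallback to another reference for this assay.
#'
#' @param sample sample_id to score.
#' @param male_reference_samples sample_ids of known males (same species).
#' @param cq_table validated Cq table.
#' @param panel \code{\link{qpcr_panel}} containing an \code{rrna} assay.
#' @param meta optional sample metadata (used to attach species_id).
#' @param reference_gene normalizing single-copy gene, default
#'   \code{"rag1"}.
#' @param min_replicates,max_spread replicate QC settings.
#' @return One-row data frame (an RrnaRatio): \code{sample_id},
#'   \code{species_id}, \code{pct_of_male}, \code{reference_gene}.
#' @export
rrna_copy_ratio <- function(sample, male_reference_samples, cq_table, panel,
                            meta = NULL, reference_gene = "rag1",
                            min_replicates = 2, max_spread = 0.5) {
  rrna_gene <- panel_genes(panel, "rrna")
  if (length(rrna_gene) != 1L)
    stop("panel must contain exactly one rrna assay")
  if (!reference_gene %in% panel$gene_id)
    stop("reference gene not in panel: ", reference_gene)
  reps <- if (is.list(cq_table) && !is.data.frame(cq_table)) cq_table
    else qc_replicate_sets(validate_cq_table(cq_table), min_replicates,
                           max_spread)
  q_s <- rrna_quantity(sample, reps, rrna_gene, reference_gene, panel)
  if (is.null(q_s))
    zdose_stop("RRNA_UNUSABLE", sprintf(
      "%s: 18S or %s assay unusable; no fallback reference for the rRNA assay",
      sample, reference_gene))
  q_m <- Filter(Negate(is.null), lapply(
    male_reference_samples, rrna_quantity, reps = reps,
    rrna_gene = rrna_gene, reference_gene = reference_gene, panel = panel))
  if (length(q_m) == 0L)
    zdose_stop("RRNA_UNUSABLE", "no usable male reference for the rRNA assay")
  species <- NA_character_
  if (!is.null(meta)) {
    i <- match(sample, meta$sample_id)
    if (!is.na(i)) species <- meta$species_id[i]
  }
  data.frame(
    sample_id = sample, species_id = species,
    pct_of_male = 100 * q_s / mean(unlist(q_m)),
    reference_gene = reference_gene, stringsAsFactors = FALSE)
}

#' Sex call from an 18S rRNA copy-number ratio
#'
#' Calls female when the sample's 18S level reaches
#' \code{female_threshold_pct} of the male reference level, male when it
#' falls in the male band [50, 150)%, and \code{unreliable} otherwise.
#' When the species is flagged unreliable for this assay (rRNA clusters
#' are evolutionarily labile and some species show no sex difference),
#' the call is \code{unreliable} regardless of the score.
#'
#' @param ratio one-row RrnaRatio (see \code{\link{rrna_copy_ratio}}).
#' @param female_threshold_pct minimum percentage called female, default
#'   200.
#' @param reliability_table named logical vector or data frame
#'   (\code{species_id}, \code{reliable}); species absent from the table
#'   are treated unreliable with a warning.
#' @return One-row data frame (a SexCall): \code{sample_id}, \code{assay},
#'   \code{call}, \code{score}, \code{species_reliability}.
#' @export
sex_call_rrna <- function(ratio, female_threshold_pct = 200,
                          reliability_table = NULL) {
  stopifnot(nrow(ratio) == 1L)
  pct <- ratio$pct_of_male
  if (!is.finite(pct) || pct <= 0) stop("invalid pct_of_male")
  reliable <- TRUE
  if (!is.null(reliability_table)) {
    tab <- if (is.data.frame(reliability_table)) {
      stats::setNames(as.logical(reliability_table$reliable),
                      reliability_table$species_id)
    } else reliability_table
    sp <- ratio$species_id
    if (is.na(sp) || !sp %in% names(tab)) {
      zdose_warn("SPECIES_NOT_IN_RELIABILITY_TABLE", sprintf(
        "species '%s' absent from rRNA reliability table; call unreliable",
        sp))
      reliable <- FALSE
    } else reliable <- isTRUE(tab[[sp]])
  }
  call <- if (!reliable) "unreliable"
    else if (pct >= female_threshold_pct) "female"
    else if (pct >= 50 && pct < 150) "male"
    else "unreliable"
  data.frame(sample_id = ratio$sample_id, assay = "rrna_cnv", call = call,
             score = pct, species_reliability = reliable,
             stringsAsFactors = FALSE)
}

#' Assess per-species reliability of the rRNA sexing assay
#'
#' A species is reliable for 18S copy-number sexing when every
#' known-sex individual is classified correctly by the thresholds: all
#' known females reach \code{female_threshold_pct} of the male level and
#' all known males fall in the male band. Species where females score
#' male-like (no W rRNA amplification) come out unreliable, reproducing
#' the empirical failure mode of this assay.
#'
#' @param cq_table validated Cq table.
#' @param meta sample metadata with phenotypic sexes.
#' @param panel \code{\link{qpcr_panel}} with an rrna assay.
#' @inheritParams rrna_copy_ratio
#' @inheritParams sex_call_rrna
#' @return Data frame: \code{species_id}, \code{reliable}.
#' @export
assess_rrna_reliability <- function(cq_table, meta, panel,
                                    reference_gene = "rag1",
                                    female_threshold_pct = 200,
                                    min_replicates = 2, max_spread = 0.5) {
  cq_table <- validate_cq_table(cq_table)
  meta <- validate_sample_meta(meta)
  rrna_gene <- panel_genes(panel, "rrna")
  if (length(rrna_gene) != 1L)
    stop("panel must contain exactly one rrna assay")
  reps <- qc_replicate_sets(cq_table, min_replicates, max_spread)
  out <- lapply(sort(unique(meta$species_id)), function(sp) {
    m <- meta[meta$species_id == sp, , drop = FALSE]
    males <- m$sample_id[m$phenotypic_sex == "male"]
    known <- m$sample_id[m$phenotypic_sex %in% c("male", "female")]
    ok <- length(males) >= 1L && length(known) >= 2L
    if (ok) {
      q_m <- Filter(Negate(is.null), lapply(
        males, rrna_quantity, reps = reps, rrna_gene = rrna_gene,
        reference_gene = reference_gene, panel = panel))
      if (length(q_m) == 0L) ok <- FALSE
      ref_level <- if (ok) mean(unlist(q_m)) else NA_real_
      for (s in if (ok) known else character()) {
        q_s <- rrna_quantity(s, reps, rrna_gene, reference_gene, panel)
        pct <- if (is.null(q_s)) NA_real_ else 100 * q_s / ref_level
        truth <- m$phenotypic_sex[m$sample_id == s]
        good <- !is.na(pct) &&
          ((truth == "female" && pct >= female_threshold_pct) ||
           (truth == "male" && pct >= 50 && pct < 150))
        if (!good) { ok <- FALSE; break }
      }
    }
    data.frame(species_id = sp, reliable = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  for (sp in out$species_id[!out$reliable])
    zdose_warn("RRNA_SPECIES_UNRELIABLE", sprintf(
      "rRNA copy-number sexing unreliable in %s", sp))
  out
}

#' Sex call from Z-gene dosage against male references
#'
#' Scores a sample's relative dose of validated Z-specific genes against
#' known male reference individuals: per gene, the sample's normalized
#' dose divided by the mean normalized dose of the male references. A ZW
#' female carries one Z copy where ZZ males carry two, so the median
#' per-gene relative dose is expected at 0.5 for females and 1.0 for
#' males; a median falling in neither band yields \code{unreliable}. The
#' bands are shared with \code{\link{classify_gene}}. Because Z-specific
#' dosage of protein-coding genes is evolutionarily stable across the
#' family, this is the recommended default sexing assay.
#'
#' @param sample sample_id to sex.
#' @param male_reference_samples sample_ids of known males (same species).
#' @param z_genes character vector of genes validated Z-specific in this
#'   species (from \code{\link{classify_linkage}}).
#' @param cq_table validated Cq table (internally, a precomputed list of
#'   QC'd replicate sets is also accepted).
#' @param panel \code{\link{qpcr_panel}}.
#' @param z_band,auto_band classification bands, as in
#'   \code{\link{classify_gene}}.
#' @param min_replicates,max_spread replicate QC settings.
#' @return One-row data frame (a SexCall): \code{sample_id}, \code{assay},
#'   \code{call}, \code{score} (median relative dose),
#'   \code{species_reliability} (TRUE: the assay is applicable wherever
#'   Z-specific genes validated), \code{n_genes}.
#' @export
sex_call_zdosage <- function(sample, male_reference_samples, z_genes,
                             cq_table, panel, z_band = c(0.35, 0.65),
                             auto_band = c(0.85, 1.15),
                             min_replicates = 2, max_spread = 0.5) {
  if (length(z_genes) == 0L)
    zdose_stop("NO_Z_GENES", paste(
      "no validated Z-specific genes for this species;",
      "run the linkage analysis (dose_ratio + classify_linkage) first"))
  reps <- if (is.list(cq_table) && !is.data.frame(cq_table)) cq_table
    else qc_replicate_sets(validate_cq_table(cq_table), min_replicates,
                           max_spread)
  ref_genes <- panel_genes(panel, "reference")
  rel_dose <- function(g) {
    d_s <- individual_dose(reps, sample, g, ref_genes, panel)
    if (is.null(d_s)) return(NA_real_)
    d_m <- Filter(Negate(is.null), lapply(
      male_reference_samples, function(s)
        individual_dose(reps, s, g, ref_genes, panel)))
    if (length(d_m) == 0L) return(NA_real_)
    d_s$dose / mean(vapply(d_m, `[[`, 0, "dose"))
  }
  doses <- vapply(sort(z_genes), rel_dose, 0)
  doses <- doses[!is.na(doses)]
  if (length(doses) == 0L)
    zdose_stop("NO_Z_GENES", sprintf(
      "%s: no Z-specific gene usable in this sample/reference set", sample))
  med <- stats::median(doses)
  call <- if (med >= z_band[1] && med <= z_band[2]) "female"
    else if (med >= auto_band[1] && med <= auto_band[2]) "male"
    else "unreliable"
  data.frame(sample_id = sample, assay = "z_dosage", call = call,
             score = med, species_reliability = TRUE,
             n_genes = length(doses), stringsAsFactors = FALSE)
}
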