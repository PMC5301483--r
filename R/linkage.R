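#' Classify one gene's sex linkage from its dose-ratio result
#'
#' A gene is called \code{z_specific} when its whole confidence interval
#' lies inside the Z band around the hemizygous expectation r = 0.5, and
#' \code{autosomal} when the interval lies inside the band around r = 1.0.
#' Anything else is \code{indeterminate}: the call is made on the interval,
#' not the point estimate, so a noisy ratio near 0.5 with a wide interval
#' stays honest. A result with status \code{not_tested} maps to
#' \code{not_tested}. Ratios whose interval sits inside the doubled band
#' around r = 2 (an X-specific pattern under male heterogamety) are
#' reported \code{indeterminate} with a note: female-heterogametic panels
#' cannot call an XX/XY system.
#'
#' @param result one-row DoseRatioResult (see \code{\link{gene_dose_ratio}}).
#' @param z_band numeric length-2, default \code{c(0.35, 0.65)}.
#' @param auto_band numeric length-2, default \code{c(0.85, 1.15)}.
#' @return One-row data frame (a LinkageCall): \code{gene_id},
#'   \code{species_id}, \code{call}, \code{r_used}, \code{ci_low},
#'   \code{ci_high}, \code{note}.
#' @examples
#' res <- data.frame(gene_id = "anapc7", species_id = "sp", r = 0.5,
#'                   ci_low = 0.45, ci_high = 0.55, n_female = 3,
#'                   n_male = 3, n_bootstrap = 1000, status = "ok")
#' classify_gene(res)$call  # "z_specific"
#' @export
classify_gene <- function(result, z_band = c(0.35, 0.65),
                          auto_band = c(0.85, 1.15)) {
  stopifnot(nrow(result) == 1L)
  out <- data.frame(
    gene_id = result$gene_id, species_id = result$species_id,
    call = "not_tested", r_used = result$r,
    ci_low = result$ci_low, ci_high = result$ci_high,
    note = NA_character_, stringsAsFactors = FALSE)
  if (result$status == "not_tested") return(out)
  lo <- result$ci_low; hi <- result$ci_high
  if (is.na(lo) || is.na(hi)) { lo <- result$r; hi <- result$r }
  if (lo > hi) stop("malformed confidence interval: low > high")
  within <- function(band) lo >= band[1] && hi <= band[2]
  out$call <-
    if (within(z_band)) "z_specific"
    else if (within(auto_band)) "autosomal"
    else "indeterminate"
  if (out$call == "indeterminate" && within(2 * auto_band))
    out$note <- "doubled dose (r ~ 2): X-specific pattern, outside ZZ/ZW scope"
  out
}

#' Classify every tested gene of a dose-ratio fit
#'
#' @param fit a \code{\link{dose_ratio}} fit or its results data frame.
#' @inheritParams classify_gene
#' @return Data frame of LinkageCall rows, one per gene x species.
#' @export
classify_linkage <- function(fit, z_band = c(0.35, 0.65),
                             auto_band = c(0.85, 1.15)) {
  r <- if (inherits(fit, "dose_ratio_fit")) fit$results else fit
  out <- do.call(rbind, lapply(seq_len(nrow(r)), function(i)
    classify_gene(r[i, , drop = FALSE], z_band, auto_band)))
  rownames(out) <- NULL
  out
}

#' Call the species-level sex-determination system
#'
#' A species is called ZZ/ZW when at least \code{min_z_genes} genes were
#' classified Z-specific and at least one autosomal control behaved
#' autosomally (confirming that halved doses are not a normalization
#' artefact); otherwise the system is left unresolved. \code{not_tested}
#' genes never count toward either tally.
#'
#' @param calls LinkageCall rows for one species
#'   (\code{\link{classify_linkage}} output subset).
#' @param min_z_genes minimum Z-specific genes required, default 3.
#' @param prior_documented logical: the species' sex chromosomes were
#'   already published before this analysis (then the call is not novel).
#' @return One-row data frame (a SpeciesSystemCall): \code{species_id},
#'   \code{system} (\code{zz_zw}/\code{unresolved}), \code{n_z_specific},
#'   \code{n_autosomal_controls}, \code{novel}.
#' @export
call_species_system <- function(calls, min_z_genes = 3,
                                prior_documented = FALSE) {
  if (NROW(calls) == 0L) stop("no linkage calls supplied")
  if (length(unique(calls$species_id)) != 1L)
    stop("calls mix species; call one species at a time")
  n_z <- sum(calls$call == "z_specific")
  n_auto <- sum(calls$call == "autosomal")
  system <- if (n_z >= min_z_genes && n_auto >= 1) "zz_zw" else "unresolved"
  data.frame(
    species_id = calls$species_id[1L], system = system,
    n_z_specific = n_z, n_autosomal_controls = n_auto,
    novel = system == "zz_zw" && !isTRUE(prior_documented),
    stringsAsFactors = FALSE)
}

#' Call systems for all species in a set of linkage calls
#'
#' @param calls \code{\link{classify_linkage}} output.
#' @param meta sample metadata carrying \code{prior_documented} per
#'   species (any sample's flag counts for its species), or \code{NULL}
#'   for all-FALSE.
#' @inheritParams call_species_system
#' @return Data frame of SpeciesSystemCall rows.
#' @export
call_all_species <- function(calls, meta = NULL, min_z_genes = 3) {
  prior <- function(sp) {
    if (is.null(meta)) return(FALSE)
    isTRUE(any(meta$prior_documented[meta$species_id == sp], na.rm = TRUE))
  }
  out <- do.call(rbind, lapply(split(calls, calls$species_id), function(cc)
    call_species_system(cc, min_z_genes = min_z_genes,
                        prior_documented = prior(cc$species_id[1L]))))
  rownames(out) <- NULL
  out[order(out$species_id), , drop = FALSE]
}

#' Count newly documented sex-chromosome systems
#'
#' The number of species called ZZ/ZW here whose sex chromosomes were not
#' previously documented.
#'
#' @param species_calls SpeciesSystemCall rows, one per species.
#' @param prior_flags optional named logical vector (species_id -> TRUE if
#'   previously documented), overriding the \code{novel} column.
#' @return Integer count.
#' @export
count_novel_systems <- function(species_calls, prior_flags = NULL) {
  if (anyDuplicated(species_calls$species_id))
    stop("duplicate species in system calls")
  novel <- if (is.null(prior_flags)) {
    species_calls$novel
  } else {
    !vapply(species_calls$species_id,
            function(sp) isTRUE(prior_flags[[sp]]), TRUE)
  }
  sum(species_calls$system == "zz_zw" & novel)
}
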