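# Replicate-level QC: returns a list keyed "sample\rgene" -> numeric vector
# of usable replicate Cqs (outliers beyond max_spread of the cell median
# removed); a cell is absent from the list when excluded (secondary product
# or too few usable wells).
qc_replicate_sets <- function(cq_table, min_replicates = 2, max_spread = 0.5) {
  parts <- split(cq_table, paste(cq_table$sample_id, cq_table$gene_id,
                                 sep = "\r"), drop = TRUE)
  out <- lapply(parts, function(m) {
    if (any(m$qc_flag == "secondary_product")) return(NULL)
    cq <- m$cq[m$qc_flag == "ok"]
    if (length(cq)) cq <- cq[abs(cq - stats::median(cq)) <= max_spread]
    if (length(cq) < min_replicates) return(NULL)
    cq
  })
  out[!vapply(out, is.null, TRUE)]
}

# Per-individual normalized dose from QC'd replicate sets.
# Returns list(dose = scalar or NA, reps = list(target=..., refs=named list))
individual_dose <- function(reps, sample, gene, ref_genes, panel) {
  tkey <- paste(sample, gene, sep = "\r")
  t_reps <- reps[[tkey]]
  if (is.null(t_reps)) return(NULL)          # target not usable in this animal
  ref_reps <- list()
  for (rg in sort(ref_genes)) {
    rr <- reps[[paste(sample, rg, sep = "\r")]]
    if (!is.null(rr)) ref_reps[[rg]] <- rr
  }
  if (length(ref_reps) == 0L) return(NULL)   # no usable reference
  if (length(ref_reps) < length(ref_genes))
    zdose_warn("REFERENCE_FALLBACK", sprintf(
      "%s: reference(s) %s unusable; falling back to %s", sample,
      paste(setdiff(sort(ref_genes), names(ref_reps)), collapse = ","),
      paste(names(ref_reps), collapse = ",")))
  e_t <- panel_efficiency(panel, gene)
  q_t <- relative_quantity(mean(t_reps), e_t)
  q_r <- vapply(names(ref_reps), function(rg)
    relative_quantity(mean(ref_reps[[rg]]), panel_efficiency(panel, rg)), 0)
  list(dose = q_t / geomean(q_r), target = t_reps, refs = ref_reps,
       e_target = e_t,
       e_refs = vapply(names(ref_reps), panel_efficiency, 0, panel = panel))
}

# One bootstrap stream draw for one individual: resampled mean Cq per
# iteration for each gene (target first, then references in sorted order).
# Consumes the RNG in the documented order.
resampled_doses <- function(ind, B) {
  resample_means <- function(v) {
    k <- length(v)
    idx <- matrix(sample.int(k, B * k, replace = TRUE), nrow = B)
    rowMeans(matrix(v[idx], nrow = B))
  }
  mcq_t <- resample_means(ind$target)
  log_q_ref <- matrix(0, nrow = B, ncol = length(ind$refs))
  for (j in seq_along(ind$refs)) {
    mcq_r <- resample_means(ind$refs[[j]])
    log_q_ref[, j] <- -mcq_r * log(ind$e_refs[j])
  }
  q_t <- ind$e_target^(-mcq_t)
  q_t / exp(rowMeans(log_q_ref))
}

#' Female:male gene-dose ratio for one gene in one species
#'
#' The central statistic of comparative qPCR sex-linkage testing. Each
#' individual's relative target-gene dose is its efficiency-corrected
#' target quantity E_t^(-Cq_t) divided by the geometric mean of its
#' reference-gene quantities; the ratio r is the mean dose over females
#' divided by the mean dose over males. A Z-specific gene (hemizygous in
#' ZW females) is expected at r = 0.5, an autosomal or pseudoautosomal
#' gene at r = 1.0, and an X-specific gene under male heterogamety at
#' r = 2.
#'
#' Uncertainty comes from a nonparametric bootstrap over the experiment's
#' two levels of replication; the confidence interval is the percentile
#' interval of the bootstrap ratios. \code{boot_scheme} selects what is
#' resampled per iteration: \code{"two_stage"} (default) resamples
#' technical replicates within every sample x gene cell and then animals
#' with replacement within each sex; \code{"replicates"} and
#' \code{"individuals"} resample only one of the two levels. With few
#' animals and few replicates each single-level bootstrap understates the
#' sampling variance by its (m-1)/m factor and undercovers badly; in the
#' two-stage scheme the two shrinkage factors offset the partial
#' double-counting of technical noise across levels, giving near-nominal
#' (slightly conservative) interval coverage at this package's typical
#' design sizes. Given \code{seed} the result is reproducible: the
#' generator is seeded once and streams are consumed in a fixed documented
#' order (replicate draws for each female in sample_id order then each
#' male, target gene first then references alphabetically; then female
#' individual draws; then male individual draws; schemes skip the streams
#' they do not use).
#'
#' @param gene gene_id of the target (or rRNA) assay.
#' @param cq_table validated Cq table (see \code{\link{read_cq_table}}).
#' @param meta sample metadata (see \code{\link{read_sample_meta}}).
#' @param panel \code{\link{qpcr_panel}} with at least one reference assay.
#' @param species species_id to analyse; required when the metadata
#'   contains more than one species.
#' @param n_bootstrap bootstrap iterations (default 1000); 0 disables the
#'   interval.
#' @param conf_level confidence level, default 0.95.
#' @param seed integer seed for the bootstrap; \code{NULL} uses the
#'   current RNG state.
#' @param boot_scheme resampling scheme, one of \code{"two_stage"},
#'   \code{"replicates"}, \code{"individuals"}; see Details.
#' @param min_replicates,max_spread replicate QC settings, see
#'   \code{\link{aggregate_replicates}}.
#' @return One-row data frame (a DoseRatioResult): \code{gene_id},
#'   \code{species_id}, \code{r}, \code{ci_low}, \code{ci_high},
#'   \code{n_female}, \code{n_male}, \code{n_bootstrap}, \code{status}
#'   (\code{"ok"} or \code{"not_tested"} when a sex has no usable
#'   individual — distinct from r = 0).
#' @export
gene_dose_ratio <- function(gene, cq_table, meta, panel, species = NULL,
                            n_bootstrap = 1000, conf_level = 0.95,
                            seed = NULL,
                            boot_scheme = c("two_stage", "replicates",
                                            "individuals"),
                            min_replicates = 2, max_spread = 0.5) {
  boot_scheme <- match.arg(boot_scheme)
  cq_table <- validate_cq_table(cq_table)
  meta <- validate_sample_meta(meta)
  if (is.null(species)) {
    sp <- unique(meta$species_id)
    if (length(sp) > 1L)
      stop("metadata covers several species; pass 'species'")
    species <- sp
  }
  meta <- meta[meta$species_id == species, , drop = FALSE]
  if (!gene %in% panel$gene_id) stop("gene not in panel: ", gene)
  ref_genes <- panel_genes(panel, "reference")
  if (gene %in% ref_genes)
    stop("'", gene, "' is a reference assay; dose ratios are computed for ",
         "target or rrna assays")

  no_result <- data.frame(
    gene_id = gene, species_id = species, r = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_,
    n_female = 0L, n_male = 0L, n_bootstrap = as.integer(n_bootstrap),
    status = "not_tested", stringsAsFactors = FALSE)

  cq_table <- cq_table[cq_table$sample_id %in% meta$sample_id, , drop = FALSE]
  if (nrow(cq_table) == 0L) return(no_result)
  reps <- qc_replicate_sets(cq_table, min_replicates, max_spread)

  females <- sort(meta$sample_id[meta$phenotypic_sex == "female"])
  males <- sort(meta$sample_id[meta$phenotypic_sex == "male"])
  ind_f <- Filter(Negate(is.null), lapply(
    females, individual_dose, reps = reps, gene = gene,
    ref_genes = ref_genes, panel = panel))
  ind_m <- Filter(Negate(is.null), lapply(
    males, individual_dose, reps = reps, gene = gene,
    ref_genes = ref_genes, panel = panel))
  if (length(ind_f) == 0L || length(ind_m) == 0L) return(no_result)

  dose_f <- vapply(ind_f, `[[`, 0, "dose")
  dose_m <- vapply(ind_m, `[[`, 0, "dose")
  r <- mean(dose_f) / mean(dose_m)

  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    B <- as.integer(n_bootstrap)
    if (boot_scheme %in% c("replicates", "two_stage")) {
      Fm <- vapply(ind_f, resampled_doses, numeric(B), B = B)
      Mm <- vapply(ind_m, resampled_doses, numeric(B), B = B)
      Fm <- matrix(Fm, nrow = B); Mm <- matrix(Mm, nrow = B)
    } else {
      Fm <- matrix(dose_f, nrow = B, ncol = length(dose_f), byrow = TRUE)
      Mm <- matrix(dose_m, nrow = B, ncol = length(dose_m), byrow = TRUE)
    }
    n_f <- ncol(Fm); n_m <- ncol(Mm)
    if (boot_scheme %in% c("individuals", "two_stage")) {
      idx_f <- matrix(sample.int(n_f, B * n_f, replace = TRUE), nrow = B)
      idx_m <- matrix(sample.int(n_m, B * n_m, replace = TRUE), nrow = B)
      mean_f <- rowMeans(matrix(Fm[cbind(rep(seq_len(B), times = n_f),
                                         c(idx_f))], nrow = B))
      mean_m <- rowMeans(matrix(Mm[cbind(rep(seq_len(B), times = n_m),
                                         c(idx_m))], nrow = B))
    } else {
      mean_f <- rowMeans(Fm)
      mean_m <- rowMeans(Mm)
    }
    boot_r <- mean_f / mean_m
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boot_r, c(a, 1 - a)))
  }

  data.frame(
    gene_id = gene, species_id = species, r = r,
    ci_low = ci[1L], ci_high = ci[2L],
    n_female = length(ind_f), n_male = length(ind_m),
    n_bootstrap = as.integer(n_bootstrap), status = "ok",
    stringsAsFactors = FALSE)
}

#' Fit female:male dose ratios across a gene panel and species set
#'
#' The package's main fitting function. For every target gene and every
#' species with at least one phenotypic female and male it computes the
#' reference-normalized female:male dose ratio r with a bootstrap
#' percentile confidence interval (see \code{\link{gene_dose_ratio}} for
#' the estimator). Genes unusable in a species (primer dropout, secondary
#' products, or a sex with no usable animal) are reported with status
#' \code{"not_tested"} rather than dropped, so downstream classification
#' can distinguish "not tested" from "tested and ambiguous".
#'
#' @param cq_table Cq table (data frame or CSV path).
#' @param meta sample metadata (data frame or CSV path).
#' @param panel \code{\link{qpcr_panel}} (or path to a panel YAML/JSON).
#' @param genes genes to test; default all \code{target} assays in the
#'   panel.
#' @param species species to test; default all in the metadata.
#' @param n_bootstrap,conf_level,boot_scheme,min_replicates,max_spread
#'   passed to \code{\link{gene_dose_ratio}}.
#' @param seed integer; combination i (species-major, gene-minor, both in
#'   sorted/panel order) uses seed + i - 1, making each gene x species
#'   result independent of which other combinations are run.
#' @return An object of class \code{"dose_ratio_fit"}: list with elements
#'   \code{results} (data frame of DoseRatioResult rows), \code{panel},
#'   \code{meta}, \code{n_bootstrap}, \code{conf_level}, \code{seed},
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{confint}, \code{plot}, \code{as.data.frame}.
#' @examples
#' fx <- default_trionychid_fixture(seed = 1)
#' fit <- dose_ratio(fx$cq_table, fx$meta, fx$panel,
#'                   species = "Pelodiscus_sinensis", n_bootstrap = 200)
#' fit
#' @export
dose_ratio <- function(cq_table, meta, panel, genes = NULL, species = NULL,
                       n_bootstrap = 1000, conf_level = 0.95, seed = 1L,
                       boot_scheme = c("two_stage", "replicates",
                                       "individuals"),
                       min_replicates = 2, max_spread = 0.5) {
  boot_scheme <- match.arg(boot_scheme)
  cl <- match.call()
  if (is.character(cq_table)) cq_table <- read_cq_table(cq_table)
  if (is.character(meta)) meta <- read_sample_meta(meta)
  if (is.character(panel)) panel <- read_panel(panel)
  cq_table <- validate_cq_table(cq_table)
  meta <- validate_sample_meta(meta)
  unknown <- setdiff(unique(cq_table$gene_id), panel$gene_id)
  if (length(unknown))
    stop("Cq table contains gene(s) absent from the panel: ",
         paste(unknown, collapse = ", "))
  if (is.null(genes)) genes <- panel_genes(panel, "target")
  if (is.null(species)) species <- sort(unique(meta$species_id))

  grid <- expand.grid(gene = genes, species = species,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows[[i]] <- gene_dose_ratio(
      grid$gene[i], cq_table, meta, panel, species = grid$species[i],
      n_bootstrap = n_bootstrap, conf_level = conf_level,
      seed = if (is.null(seed)) NULL else as.integer(seed) + i - 1L,
      boot_scheme = boot_scheme,
      min_replicates = min_replicates, max_spread = max_spread)
  }
  structure(
    list(results = do.call(rbind, rows), panel = panel, meta = meta,
         n_bootstrap = n_bootstrap, conf_level = conf_level, seed = seed,
         call = cl),
    class = "dose_ratio_fit")
}

#' @export
print.dose_ratio_fit <- function(x, digits = 3, ...) {
  r <- x$results
  cat("Female:male gene-dose ratio fit\n")
  cat(sprintf("  %d gene x species combinations (%d tested), %d bootstrap resamples, %g%% CI\n",
              nrow(r), sum(r$status == "ok"), x$n_bootstrap,
              100 * x$conf_level))
  show <- r
  for (cc in c("r", "ci_low", "ci_high"))
    show[[cc]] <- round(show[[cc]], digits)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dose_ratio_fit <- function(object, z_band = c(0.35, 0.65),
                                   auto_band = c(0.85, 1.15), ...) {
  calls <- classify_linkage(object, z_band = z_band, auto_band = auto_band)
  structure(list(fit = object, calls = calls, z_band = z_band,
                 auto_band = auto_band),
            class = "summary.dose_ratio_fit")
}

#' @export
print.summary.dose_ratio_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nLinkage calls (Z band [%.2f, %.2f], autosomal band [%.2f, %.2f]):\n",
              x$z_band[1], x$z_band[2], x$auto_band[1], x$auto_band[2]))
  print(table(x$calls$species_id, x$calls$call))
  invisible(x)
}

#' @export
coef.dose_ratio_fit <- function(object, ...) {
  r <- object$results
  stats::setNames(r$r, paste(r$species_id, r$gene_id, sep = ":"))
}

#' @export
confint.dose_ratio_fit <- function(object, parm, level, ...) {
  r <- object$results
  m <- cbind(ci_low = r$ci_low, ci_high = r$ci_high)
  rownames(m) <- paste(r$species_id, r$gene_id, sep = ":")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
as.data.frame.dose_ratio_fit <- function(x, ...) x$results

#' Plot a dose-ratio fit
#'
#' Point estimates with confidence bars for every tested gene x species
#' combination, grouped by species, with dashed guides at the Z-specific
#' (0.5) and autosomal (1.0) expectations.
#'
#' @param x a \code{dose_ratio_fit}.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.dose_ratio_fit <- function(x, ...) {
  r <- x$results[x$results$status == "ok", , drop = FALSE]
  if (nrow(r) == 0L) stop("nothing to plot: no tested combinations")
  r <- r[order(r$species_id, r$gene_id), , drop = FALSE]
  y <- rev(seq_len(nrow(r)))
  xlim <- range(0, 1.3, r$ci_low, r$ci_high, na.rm = TRUE)
  op <- graphics::par(mar = c(4.5, 11, 1.5, 1))
  on.exit(graphics::par(op))
  plot(r$r, y, xlim = xlim, pch = 19, yaxt = "n", ylab = "",
       xlab = "female : male relative gene dose (r)", ...)
  graphics::segments(r$ci_low, y, r$ci_high, y)
  graphics::abline(v = c(0.5, 1), lty = 2, col = "grey40")
  graphics::axis(2, at = y, las = 1, cex.axis = 0.7,
                 labels = paste(r$species_id, r$gene_id, sep = "  "))
  invisible(x)
}

#' Write dose-ratio results as TSV
#'
#' @param fit a \code{dose_ratio_fit} (or its results data frame).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dose_ratios <- function(fit, path) {
  r <- if (inherits(fit, "dose_ratio_fit")) fit$results else fit
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
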