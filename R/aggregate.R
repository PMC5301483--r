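#' Aggregate technical replicates of one sample x gene cell
#'
#' Summarises the wells of a single sample-by-gene combination into a mean
#' and standard deviation of Cq, applying plate-level quality control:
#' only \code{ok} wells are used; among those, a well whose Cq deviates
#' from the cell median by more than \code{max_spread} cycles is dropped
#' as an outlier; the cell is excluded outright when any well amplified a
#' secondary product (unspecific amplification invalidates the assay in
#' that animal) or when fewer than \code{min_replicates} usable wells
#' remain. Missing wells are never imputed.
#'
#' @param measurements data frame of wells for one sample x gene: columns
#'   \code{sample_id}, \code{gene_id}, \code{replicate}, \code{cq},
#'   \code{qc_flag}.
#' @param min_replicates minimum usable wells, default 2.
#' @param max_spread maximum |Cq - cell median| in cycles, default 0.5.
#' @return One-row data frame: \code{sample_id}, \code{gene_id},
#'   \code{mean_cq}, \code{sd_cq}, \code{n_used}, \code{excluded},
#'   \code{reason}.
#' @examples
#' w <- data.frame(sample_id = "s1", gene_id = "anapc7", replicate = 1:3,
#'                 cq = c(20.0, 20.1, 19.9), qc_flag = "ok")
#' aggregate_replicates(w)
#' @export
aggregate_replicates <- function(measurements, min_replicates = 2,
                                 max_spread = 0.5) {
  if (NROW(measurements) == 0L) stop("no measurements supplied")
  if (length(unique(measurements$sample_id)) != 1L ||
      length(unique(measurements$gene_id)) != 1L)
    stop("measurements mix sample or gene ids; aggregate one cell at a time")
  out <- data.frame(
    sample_id = measurements$sample_id[1L],
    gene_id = measurements$gene_id[1L],
    mean_cq = NA_real_, sd_cq = NA_real_, n_used = 0L,
    excluded = TRUE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(measurements$qc_flag == "secondary_product")) {
    out$reason <- "secondary_product"
    return(out)
  }
  cq <- measurements$cq[measurements$qc_flag == "ok"]
  if (length(cq)) {
    keep <- abs(cq - stats::median(cq)) <= max_spread
    if (!all(keep)) {
      zdose_warn("REPLICATE_DROPPED", sprintf(
        "%s/%s: dropped %d replicate(s) > %.2f cycles from cell median",
        out$sample_id, out$gene_id, sum(!keep), max_spread))
    }
    cq <- cq[keep]
  }
  if (length(cq) < min_replicates) {
    out$reason <- "insufficient_replicates"
    out$n_used <- length(cq)
    return(out)
  }
  out$mean_cq <- mean(cq)
  out$sd_cq <- stats::sd(cq)
  out$n_used <- length(cq)
  out$excluded <- FALSE
  out
}

#' Aggregate every sample x gene cell of a Cq table
#'
#' Applies \code{\link{aggregate_replicates}} across the whole table.
#'
#' @param cq_table validated Cq table.
#' @inheritParams aggregate_replicates
#' @return Data frame with one row per sample x gene cell.
#' @export
aggregate_cq <- function(cq_table, min_replicates = 2, max_spread = 0.5) {
  cq_table <- validate_cq_table(cq_table)
  parts <- split(cq_table,
                 list(cq_table$sample_id, cq_table$gene_id), drop = TRUE)
  out <- do.call(rbind, lapply(parts, aggregate_replicates,
                               min_replicates = min_replicates,
                               max_spread = max_spread))
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene_id), , drop = FALSE]
}

#' Relative quantity from a mean Cq
#'
#' Converts a quantification cycle into a relative template quantity under
#' exponential amplification with per-cycle factor \code{efficiency}:
#' quantity = E^(-Cq). One cycle earlier means E times more template; with
#' E = 2 the classic doubling rule. Quantities are relative (Cq 0 maps to
#' 1), which is all that dose ratios require.
#'
#' @param mean_cq Cq value(s), cycles.
#' @param efficiency amplification factor(s) E > 1.
#' @return Dimensionless relative quantity, same length as \code{mean_cq}.
#' @examples
#' relative_quantity(10, 2) / relative_quantity(11, 2)  # exactly 2
#' @export
relative_quantity <- function(mean_cq, efficiency) {
  if (any(efficiency <= 1)) stop("efficiency must exceed 1")
  efficiency^(-mean_cq)
}

#' Sample normalization factor from reference-gene quantities
#'
#' The geometric mean of the available (non-excluded) reference-gene
#' relative quantities of one sample; with a single usable reference it is
#' that reference's quantity. This factor absorbs template-amount
#' differences between samples.
#'
#' @param reference_quantities named numeric vector (gene -> relative
#'   quantity) of usable reference assays; NAs are dropped.
#' @return Dimensionless normalization factor.
#' @export
normalization_factor <- function(reference_quantities) {
  q <- reference_quantities[!is.na(reference_quantities)]
  if (length(q) == 0L)
    zdose_stop("NO_REFERENCE", "no usable reference gene; sample unusable")
  geomean(q)
}
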