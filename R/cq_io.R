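#' Read a long-format Cq table
#'
#' The Cq table is the pipeline's raw input: one row per well, columns
#' \code{sample_id}, \code{gene_id}, \code{replicate}, \code{cq},
#' \code{qc_flag}. \code{qc_flag} is one of \code{ok},
#' \code{no_amplification}, \code{secondary_product}; \code{cq} must be
#' present exactly when the flag is \code{ok} (a failed well has no
#' quantification cycle). The file is comma-separated UTF-8 with a header
#' row and "." as decimal mark; a missing Cq is an empty field.
#'
#' @param path CSV file path.
#' @return A validated data frame (see \code{\link{validate_cq_table}}).
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop("Cq table not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(cq = "numeric"))
  validate_cq_table(x)
}

#' Validate a Cq measurement table
#'
#' Checks column presence, flag vocabulary, Cq range, the missingness rule
#' (Cq present iff \code{qc_flag == "ok"}) and replicate uniqueness within
#' each sample-by-gene cell.
#'
#' @param x data frame with columns \code{sample_id}, \code{gene_id},
#'   \code{replicate}, \code{cq}, \code{qc_flag}.
#' @return \code{x}, invisibly validated (returned unchanged on success).
#' @export
validate_cq_table <- function(x) {
  need <- c("sample_id", "gene_id", "replicate", "cq", "qc_flag")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("Cq table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("Cq table is empty")
  bad <- setdiff(unique(x$qc_flag),
                 c("ok", "no_amplification", "secondary_product"))
  if (length(bad))
    stop("unknown qc_flag value(s): ", paste(bad, collapse = ", "))
  ok <- x$qc_flag == "ok"
  if (any(ok & is.na(x$cq)))
    stop("wells flagged 'ok' must carry a Cq value")
  if (any(!ok & !is.na(x$cq)))
    stop("failed wells must not carry a Cq value")
  if (any(x$cq[ok] < 0))
    stop("negative Cq value")
  key <- paste(x$sample_id, x$gene_id, x$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate replicate index within a sample x gene cell")
  x
}

#' Read sample metadata
#'
#' Columns \code{sample_id}, \code{species_id}, \code{phenotypic_sex}
#' (\code{male}/\code{female}/\code{unknown}) and optionally
#' \code{prior_documented} (logical: the species already had published sex
#' chromosomes before this study).
#'
#' @param path CSV file path.
#' @return A validated metadata data frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  validate_sample_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_meta
#' @param x a metadata data frame to validate.
#' @export
validate_sample_meta <- function(x) {
  need <- c("sample_id", "species_id", "phenotypic_sex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in metadata")
  if (any(!nzchar(x$species_id)) || anyNA(x$species_id))
    stop("species_id must be nonempty")
  bad <- setdiff(unique(x$phenotypic_sex), c("male", "female", "unknown"))
  if (length(bad))
    stop("unknown phenotypic_sex value(s): ", paste(bad, collapse = ", "))
  if (is.null(x$prior_documented)) x$prior_documented <- NA
  x$prior_documented <- as.logical(x$prior_documented)
  x
}
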