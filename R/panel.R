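#' Define a qPCR assay panel
#'
#' A panel lists the assays (one per gene) used in a comparative gene-dosage
#' experiment: target genes whose sex linkage is under test, single-copy
#' reference genes used for normalization, and optionally an rRNA
#' copy-number assay. Each assay carries its amplification efficiency, the
#' per-cycle amplification factor E in (1, 2.2] (E = 2 is perfect doubling).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param role character vector, one of \code{"target"}, \code{"reference"},
#'   \code{"rrna"} per gene.
#' @param efficiency numeric vector of amplification factors, each in
#'   (1, 2.2]. Recycled if length 1. Default 2.
#' @param amplicon_length optional integer vector of amplicon sizes in bp
#'   (informational only).
#' @return A data frame of class \code{"qpcr_panel"} with one row per assay.
#' @examples
#' qpcr_panel(
#'   gene_id = c("anapc7", "adarb2", "rag1", "mos"),
#'   role = c("target", "target", "reference", "reference")
#' )
#' @export
qpcr_panel <- function(gene_id, role, efficiency = 2, amplicon_length = NA_integer_) {
  gene_id <- as.character(gene_id)
  role <- as.character(role)
  if (length(role) != length(gene_id))
    stop("'role' must have one entry per gene")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in panel: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  bad <- setdiff(role, c("target", "reference", "rrna"))
  if (length(bad))
    stop("unknown assay role(s): ", paste(bad, collapse = ", "))
  efficiency <- rep_len(as.numeric(efficiency), length(gene_id))
  if (any(!is.finite(efficiency)) || any(efficiency <= 1) || any(efficiency > 2.2))
    stop("amplification efficiency must be in (1, 2.2]")
  if (!any(role == "reference"))
    stop("a panel needs at least one reference assay")
  amplicon_length <- rep_len(as.integer(amplicon_length), length(gene_id))
  structure(
    data.frame(
      gene_id = gene_id, role = role, efficiency = efficiency,
      amplicon_length = amplicon_length, stringsAsFactors = FALSE
    ),
    class = c("qpcr_panel", "data.frame")
  )
}

#' @export
print.qpcr_panel <- function(x, ...) {
  cat("qPCR assay panel:", nrow(x), "assays (",
      sum(x$role == "target"), "target,",
      sum(x$role == "reference"), "reference,",
      sum(x$role == "rrna"), "rRNA )\n", sep = " ")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

panel_genes <- function(panel, role) panel$gene_id[panel$role %in% role]

panel_efficiency <- function(panel, gene) {
  i <- match(gene, panel$gene_id)
  if (anyNA(i)) stop("gene(s) not in panel: ",
                     paste(gene[is.na(i)], collapse = ", "))
  panel$efficiency[i]
}

#' Read or write a panel configuration file
#'
#' Panels are stored as YAML or JSON: a list of assay records with fields
#' \code{gene_id}, \code{role}, \code{efficiency} and optionally
#' \code{amplicon_length}. The format is chosen from the file extension
#' (\code{.yaml}/\code{.yml} vs \code{.json}).
#'
#' @param path file path.
#' @return \code{read_panel} returns a \code{\link{qpcr_panel}};
#'   \code{write_panel} returns \code{path} invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(recs)) stop("panel file is empty: ", path)
  qpcr_panel(
    gene_id = vapply(recs, function(r) as.character(r$gene_id), ""),
    role = vapply(recs, function(r) as.character(r$role), ""),
    efficiency = vapply(recs, function(r) as.numeric(r$efficiency %||% 2), 0),
    amplicon_length = vapply(
      recs, function(r) as.integer(r$amplicon_length %||% NA_integer_), 1L)
  )
}

#' @rdname read_panel
#' @param panel a \code{\link{qpcr_panel}}.
#' @export
write_panel <- function(panel, path) {
  recs <- lapply(seq_len(nrow(panel)), function(i) {
    r <- list(gene_id = panel$gene_id[i], role = panel$role[i],
              efficiency = panel$efficiency[i])
    if (!is.na(panel$amplicon_length[i]))
      r$amplicon_length <- panel$amplicon_length[i]
    r
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}
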