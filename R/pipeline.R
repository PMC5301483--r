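#' Assemble a run configuration for the full analysis
#'
#' Inputs may be in-memory objects (data frames, a
#' \code{\link{qpcr_panel}}, a \code{\link{parse_dated_newick}} tree) or
#' file paths in the package's documented formats; paths are checked for
#' existence here, before any stage runs.
#'
#' @param cq_table Cq table (data frame or CSV path).
#' @param panel assay panel (\code{qpcr_panel} or YAML/JSON path).
#' @param meta sample metadata (data frame or CSV path).
#' @param tree optional dated tree (\code{dated_tree} or Newick path).
#' @param tip_states optional tip states (named vector or CSV path);
#'   defaults to the states attached to \code{tree}.
#' @param out_dir output directory (created if absent); \code{NULL}
#'   disables file output.
#' @param z_band,auto_band,min_z_genes,female_threshold_pct
#'   classification thresholds, see \code{\link{classify_gene}},
#'   \code{\link{call_species_system}}, \code{\link{sex_call_rrna}}.
#' @param n_bootstrap,conf_level,boot_scheme bootstrap settings for
#'   \code{\link{dose_ratio}}.
#' @param seed integer seed for all randomness in the run.
#' @param min_replicates,max_spread replicate QC settings.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(cq_table, panel, meta, tree = NULL,
                       tip_states = NULL, out_dir = NULL,
                       z_band = c(0.35, 0.65), auto_band = c(0.85, 1.15),
                       min_z_genes = 3, female_threshold_pct = 200,
                       n_bootstrap = 1000, conf_level = 0.95, seed = 1L,
                       boot_scheme = "two_stage",
                       min_replicates = 2, max_spread = 0.5) {
  chk_path <- function(x, what) {
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop(what, " path does not exist: ", x)
    x
  }
  stopifnot(z_band[1] < z_band[2], auto_band[1] < auto_band[2],
            min_z_genes >= 1, female_threshold_pct > 150,
            n_bootstrap >= 0, conf_level > 0, conf_level < 1)
  structure(list(
    cq_table = chk_path(cq_table, "Cq table"),
    panel = chk_path(panel, "panel"),
    meta = chk_path(meta, "metadata"),
    tree = chk_path(tree, "tree"),
    tip_states = chk_path(tip_states, "tip states"),
    out_dir = out_dir, z_band = z_band, auto_band = auto_band,
    min_z_genes = min_z_genes,
    female_threshold_pct = female_threshold_pct,
    n_bootstrap = n_bootstrap, conf_level = conf_level,
    boot_scheme = boot_scheme,
    seed = as.integer(seed), min_replicates = min_replicates,
    max_spread = max_spread), class = "run_config")
}

load_config_inputs <- function(config) {
  cq <- config$cq_table
  if (is.character(cq)) cq <- read_cq_table(cq)
  panel <- config$panel
  if (is.character(panel)) panel <- read_panel(panel)
  meta <- config$meta
  if (is.character(meta)) meta <- read_sample_meta(meta)
  tree <- config$tree
  if (is.character(tree)) tree <- parse_dated_newick(tree)
  ts <- config$tip_states
  if (is.character(ts)) ts <- read_tip_states(ts)
  if (!is.null(tree) && !is.null(ts))
    tree$tip_states[names(ts)] <- ts
  list(cq_table = cq, panel = panel, meta = meta, tree = tree)
}

#' Run the full gene-dosage analysis pipeline
#'
#' Executes, in order: replicate QC and dose-ratio estimation for every
#' target gene x species (\code{\link{dose_ratio}}); per-gene linkage
#' classification and species-level system calls
#' (\code{\link{classify_linkage}}, \code{\link{call_all_species}});
#' origin-age bracketing on the supplied chronogram
#' (\code{\link{origin_interval}}, skipped without a tree); and molecular
#' sexing of every sample by both the 18S rRNA copy-number assay and
#' Z-gene dosage, with a data-driven per-species rRNA reliability table
#' (\code{\link{assess_rrna_reliability}}). When \code{out_dir} is set,
#' results are written as TSV/JSON, a per-species dose-ratio plot (PDF,
#' best effort) and a structured warning log in which each distinct
#' warning code/message appears exactly once. Re-running with the same
#' configuration and seed reproduces identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list of class \code{"zdose_run"}: \code{fit},
#'   \code{linkage_calls}, \code{species_systems}, \code{n_novel},
#'   \code{origin}, \code{rrna_reliability}, \code{sex_calls},
#'   \code{warnings}, \code{config}.
#' @examples
#' \donttest{
#' fx <- default_trionychid_fixture(seed = 1)
#' cfg <- run_config(fx$cq_table, fx$panel, fx$meta, tree = fx$tree,
#'                   n_bootstrap = 200, seed = 1)
#' run <- run_full_analysis(cfg)
#' run$species_systems
#' }
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warn_log <- list()
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)),
      zdose_warning = function(w) {
        key <- conditionMessage(w)
        warn_log[[key]] <<- list(code = w$code, message = conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  inp <- collect({
    x <- load_config_inputs(config)
    validate_cq_table(x$cq_table)
    validate_sample_meta(x$meta)
    unknown <- setdiff(unique(x$cq_table$gene_id), x$panel$gene_id)
    if (length(unknown))
      stop("Cq table contains gene(s) absent from the panel: ",
           paste(unknown, collapse = ", "))
    x
  }, "validation")

  fit <- collect(dose_ratio(
    inp$cq_table, inp$meta, inp$panel,
    n_bootstrap = config$n_bootstrap, conf_level = config$conf_level,
    seed = config$seed, boot_scheme = config$boot_scheme,
    min_replicates = config$min_replicates,
    max_spread = config$max_spread), "dose_ratio")

  calls <- collect(classify_linkage(fit, z_band = config$z_band,
                                    auto_band = config$auto_band),
                   "classify")
  systems <- collect(call_all_species(calls, meta = inp$meta,
                                      min_z_genes = config$min_z_genes),
                     "classify")
  n_novel <- count_novel_systems(systems)

  origin <- NULL
  if (!is.null(inp$tree))
    origin <- collect(origin_interval(inp$tree, derived = "zw"), "phylo")

  sexing <- collect(
    sex_all_samples(inp$cq_table, inp$meta, inp$panel, calls,
                    female_threshold_pct = config$female_threshold_pct,
                    z_band = config$z_band, auto_band = config$auto_band,
                    min_replicates = config$min_replicates,
                    max_spread = config$max_spread), "sexing")

  run <- structure(
    list(fit = fit, linkage_calls = calls, species_systems = systems,
         n_novel = n_novel, origin = origin,
         rrna_reliability = sexing$reliability,
         sex_calls = sexing$calls, warnings = unname(warn_log),
         config = config), class = "zdose_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  invisible(run)
}

# Both sexing assays applied to every sample, using the species' known
# males as references; Z genes per species come from the linkage calls.
sex_all_samples <- function(cq_table, meta, panel, linkage_calls,
                            female_threshold_pct = 200,
                            z_band = c(0.35, 0.65),
                            auto_band = c(0.85, 1.15),
                            min_replicates = 2, max_spread = 0.5) {
  reliability <- assess_rrna_reliability(
    cq_table, meta, panel, female_threshold_pct = female_threshold_pct,
    min_replicates = min_replicates, max_spread = max_spread)
  reps <- qc_replicate_sets(validate_cq_table(cq_table), min_replicates,
                            max_spread)
  rows <- list()
  for (sp in sort(unique(meta$species_id))) {
    m <- meta[meta$species_id == sp, , drop = FALSE]
    males <- sort(m$sample_id[m$phenotypic_sex == "male"])
    if (length(males) == 0L) next
    z_genes <- linkage_calls$gene_id[
      linkage_calls$species_id == sp & linkage_calls$call == "z_specific"]
    for (s in sort(m$sample_id)) {
      rr <- tryCatch({
        rat <- rrna_copy_ratio(s, males, reps, panel, meta = m,
                               min_replicates = min_replicates,
                               max_spread = max_spread)
        sex_call_rrna(rat, female_threshold_pct = female_threshold_pct,
                      reliability_table = reliability)
      }, zdose_error = function(e) NULL)
      if (!is.null(rr)) rows[[length(rows) + 1L]] <- cbind(
        rr, species_id = sp, n_genes = NA_integer_)
      zd <- tryCatch(
        sex_call_zdosage(s, setdiff(males, s), z_genes, reps, panel,
                         z_band = z_band, auto_band = auto_band,
                         min_replicates = min_replicates,
                         max_spread = max_spread),
        zdose_error = function(e) NULL)
      if (!is.null(zd)) rows[[length(rows) + 1L]] <- cbind(
        zd[, c("sample_id", "assay", "call", "score",
               "species_reliability")],
        species_id = sp, n_genes = zd$n_genes)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), assay = character(),
               call = character(), score = numeric(),
               species_reliability = logical(), species_id = character(),
               n_genes = integer(), stringsAsFactors = FALSE)
  list(reliability = reliability, calls = calls)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_dose_ratios(run$fit, fp("dose_ratios.tsv"))
  utils::write.table(run$linkage_calls, fp("linkage_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(species_systems = run$species_systems, n_novel = run$n_novel),
    fp("species_systems.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (!is.null(run$origin))
    jsonlite::write_json(
      list(state = run$origin$state, min_age = run$origin$min_age,
           max_age = run$origin$max_age,
           crown_node = run$origin$crown_node,
           stem_node = run$origin$stem_node),
      fp("origin_interval.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(run$sex_calls, fp("sex_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$rrna_reliability, fp("rrna_reliability.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  logdf <- if (length(run$warnings)) data.frame(
    code = vapply(run$warnings, `[[`, "", "code"),
    message = vapply(run$warnings, `[[`, "", "message"),
    stringsAsFactors = FALSE) else
      data.frame(code = character(), message = character())
  utils::write.table(logdf, fp("run_log.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tryCatch({
    grDevices::pdf(fp("dose_ratios.pdf"), width = 7, height = 9)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(run$fit)
  }, error = function(e)
    zdose_warn("PLOT_FAILED",
               paste("dose-ratio plot not produced:",
                     conditionMessage(e))))
  invisible(out_dir)
}

#' @export
print.zdose_run <- function(x, ...) {
  cat("zdose pipeline run\n")
  cat(sprintf("  %d species, %d gene x species dose ratios (%d tested)\n",
              nrow(x$species_systems), nrow(x$fit$results),
              sum(x$fit$results$status == "ok")))
  cat(sprintf("  ZZ/ZW species: %d (novel: %d)\n",
              sum(x$species_systems$system == "zz_zw"), x$n_novel))
  if (!is.null(x$origin))
    cat(sprintf("  origin bracket: %.4g-%.4g Mya\n",
                x$origin$min_age, x$origin$max_age))
  cat(sprintf("  sex calls: %d (%d unreliable)\n", nrow(x$sex_calls),
              sum(x$sex_calls$call == "unreliable")))
  invisible(x)
}
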