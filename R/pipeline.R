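#' Validate a pipeline configuration
#'
#' Fills defaults, checks parameter ranges and, for stages consuming
#' external files, that every referenced file exists — before any stage
#' runs. Numeric defaults follow the values used throughout the
#' package: `min_reads` 2, QC thresholds 60/10, DE thresholds
#' `lfc` 1 / `p` 0.05, DMR `alpha` 0.05, concordance `window` 5000 bp.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized fields: `seed`, `outdir`, `stages` (subset of
#'   `simulate`, `junctions`, `dmr`, `concordance`), `anchor`,
#'   `min_reads`, `alpha`, `window`, `sim` (arguments for
#'   [sim_config()]), `junction_files`, `model_file`, `roles_file`,
#'   `events1`, `events2`, `dmrs1`, `dmrs2`.
#' @return The validated config list (class `pipeline_config`).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("validation: config must be a list or YAML path")
  defaults <- list(seed = 1L, outdir = "methsplice_out",
                   stages = c("simulate", "junctions", "dmr", "concordance"),
                   anchor = NULL, min_reads = 2, alpha = 0.05, window = 5000,
                   sim = list())
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  bad_stage <- setdiff(config$stages,
                       c("simulate", "junctions", "dmr", "concordance"))
  if (length(bad_stage) > 0)
    stop("validation: unknown stage(s): ", paste(bad_stage, collapse = ", "))
  if (config$min_reads < 1) stop("validation: min_reads must be >= 1")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("validation: alpha must be in (0, 1)")
  if (config$window < 0) stop("validation: window must be >= 0")
  config$sim$seed <- config$sim$seed %||% config$seed
  config$sim_config <- do.call(sim_config, config$sim)
  if (!"simulate" %in% config$stages) {
    for (f in c("junction_files", "model_file", "roles_file",
                "events1", "events2", "dmrs1", "dmrs2")) {
      for (p in config[[f]])
        if (!file.exists(p)) stop("validation: missing input file: ", p)
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order (simulate, then
#' junction quantification, DMR calling, and concordance
#' classification), writing TSV/JSON artifacts into `outdir` and a run
#' manifest recording the parameter hash and the MD5 checksum of every
#' artifact. Re-running with an identical config reproduces
#' byte-identical outputs. A stage failure halts the run with a
#' stage-tagged error.
#'
#' @param config list or YAML path, see [validate_pipeline_config()].
#' @return The manifest (list), invisibly written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  cfg <- config$sim_config
  sim_jx <- sim_meth <- NULL
  model <- NULL

  if ("simulate" %in% config$stages) stage("simulate", {
    model <- cd44_gene_model()
    sim_jx <- simulate_junction_counts(model, cfg)
    sim_meth <- simulate_methylation(model, cfg)
    note(write_gene_model_bed(model, file.path(outdir, "gene_model.bed")))
    for (s in names(sim_jx$group))
      note(write_sj_tab(sim_jx$junctions, s,
                        file.path(outdir, paste0("junctions_", s, ".sj.tab"))))
    cnt <- data.frame(bin = rownames(sim_meth$counts), sim_meth$counts,
                      check.names = FALSE)
    p <- file.path(outdir, "meth_counts.tsv")
    write.table(cnt, p, sep = "\t", quote = FALSE, row.names = FALSE)
    note(p)
    note(write_tsv_table(sim_meth$roi, file.path(outdir, "meth_roi.tsv")))
    note(write_tsv_table(sim_meth$true_dmrs,
                         file.path(outdir, "true_dmrs.tsv")))
    qc <- simulate_qc(2 * cfg$n_per_group, fraction_bad = 0, seed = cfg$seed)
    note(write_tsv_table(qc, file.path(outdir, "qc_metrics.tsv")))
  })

  if ("junctions" %in% config$stages) stage("junctions", {
    if (is.null(sim_jx)) {
      model <- load_gene_model(config$model_file, config$gene_id %||% "gene",
                                config$roles_file)
      tables <- lapply(config$junction_files, read_junction_table,
                       dialect = config$dialect %||% "sj_tab")
      jx <- merge_junction_tables(tables)
      group <- setNames(config$group, config$sample %||% junction_samples(jx))
    } else {
      jx <- sim_jx$junctions
      group <- sim_jx$group
    }
    anchor <- config$anchor %||% {
      vb <- variant_block(model)
      model$exon_id[model$ordinal == min(vb) - 1]
    }
    ajs <- enumerate_anchor_junctions(jx, model, anchor,
                                      min_reads = config$min_reads)
    incl <- inclusion_percentage(ajs)
    note(write_tsv_table(incl, file.path(outdir, "inclusion.tsv")))
    by_group <- split(incl$inclusion_pct, group[incl$sample])
    if (length(by_group) == 2) {
      gl <- names(by_group)
      cmp <- compare_inclusion(by_group[[1]], by_group[[2]],
                               design = "paired", test = "wilcoxon_signed_rank")
      p <- file.path(outdir, "inclusion_test.json")
      jsonlite::write_json(
        list(group_a = gl[1], group_b = gl[2],
             mean_a = mean(by_group[[1]], na.rm = TRUE),
             mean_b = mean(by_group[[2]], na.rm = TRUE),
             test = cmp$method, p_value = cmp$p.value),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note(p)
    }
  })

  dmrs <- NULL
  if ("dmr" %in% config$stages) stage("dmr", {
    if (is.null(sim_meth))
      stop("external methylation inputs require the simulate stage in ",
           "this release; supply dmrs1/dmrs2 directly for concordance")
    dmrs <- call_dmrs(sim_meth$counts, sim_meth$roi, sim_meth$group,
                       "A", "B", alpha = config$alpha)
    note(write_dmr_table(dmrs, file.path(outdir, "dmrs.tsv")))
  })

  if ("concordance" %in% config$stages) stage("concordance", {
    if (!is.null(config$events1)) {
      e1 <- read_event_table(config$events1)
      e2 <- read_event_table(config$events2)
      d1 <- as_tibble(read.table(config$dmrs1, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
      d2 <- as_tibble(read.table(config$dmrs2, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
    } else {
      sim_ev <- simulate_event_tables(seed = cfg$seed)
      e1 <- sim_ev$events1; e2 <- sim_ev$events2
      d1 <- sim_ev$dmrs1; d2 <- sim_ev$dmrs2
      note(write_tsv_table(sim_ev$truth,
                           file.path(outdir, "event_truth.tsv")))
    }
    records <- classify_concordance(e1, e2, d1, d2, window = config$window)
    note(write_concordance_records(records,
                                   file.path(outdir, "concordance.tsv")))
    note(write_category_summary(tally_categories(records),
                                file.path(outdir, "concordance_summary.json")))
  })

  param_json <- file.path(outdir, "params.json")
  cfg_plain <- unclass(config)
  cfg_plain$sim_config <- unclass(cfg_plain$sim_config)
  jsonlite::write_json(cfg_plain, param_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note(param_json)
  sums <- tools::md5sum(artifacts)
  manifest <- list(
    package = "methsplice",
    parameter_hash = unname(tools::md5sum(param_json)),
    stages = config$stages,
    outputs = lapply(seq_along(artifacts), function(i)
      list(path = basename(artifacts[i]), md5 = unname(sums[i])))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
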