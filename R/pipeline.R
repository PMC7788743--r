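#' Run the full ROH analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> ROH detection -> inbreeding ->
#' islands in fixed order, writing every stage output as a plain TSV under
#' `out_dir` plus a machine-readable JSON run manifest. Re-running with an
#' identical config reproduces identical outputs (the manifest timestamp
#' aside).
#'
#' @param config list with elements:
#'   * `sim`: a [sim_config()] (simulate stage), or
#'   * `ped`, `map`, `meta`: paths to existing inputs (load stage);
#'   * optional `qc`: list(min_rate, min_maf, max_missing);
#'   * optional `roh`: arguments for [roh_params()];
#'   * optional `islands`: list(min_samples, min_span_bp, min_snps,
#'     max_gap_bp);
#'   * optional `l_auto`: bp constant for F_ROH (default: from the post-QC
#'     map);
#'   * optional `stages`: subset of
#'     c("simulate", "qc", "detect", "inbreeding", "islands") to run
#'     (prefix of the full order).
#' @param out_dir output directory, created if needed.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "qc", "detect", "inbreeding", "islands")
  stages <- config$stages
  if (is.null(stages)) {
    stages <- if (!is.null(config$sim)) all_stages else all_stages[-1]
  }
  if (!all(stages %in% all_stages)) {
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  }
  stages <- all_stages[all_stages %in% stages]
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(tool = "rohscan",
                   version = as.character(utils::packageVersion("rohscan")),
                   seed = if (!is.null(config$sim)) config$sim$seed else NULL,
                   stages = stages, outputs = list(),
                   config = config_echo(config))
  add_out <- function(name, path, n_rows) {
    manifest$outputs[[name]] <<- list(path = basename(path), rows = n_rows)
  }

  panel <- NULL; meta <- NULL; truth <- NULL
  completed <- character()
  for (stage in stages) {
    if (stage == "simulate") {
      if (is.null(config$sim)) stop("simulate stage requires config$sim")
      sim <- simulate_panel(config$sim)
      panel <- sim$panel; meta <- sim$meta; truth <- sim$truth
      write_ped_map(panel, pth("genotypes.ped"), pth("genotypes.map"), meta)
      write_metadata(meta, pth("metadata.tsv"))
      write_truth(truth, meta, pth("truth.tsv"))
      add_out("ped", pth("genotypes.ped"), nrow(panel$calls))
      add_out("map", pth("genotypes.map"), ncol(panel$calls))
      add_out("metadata", pth("metadata.tsv"), nrow(meta))
      add_out("truth", pth("truth.tsv"), nrow(truth$intervals))
    } else if (stage == "qc") {
      if (is.null(panel)) {
        if (is.null(config$ped)) stop("qc stage requires config$ped/map/meta or a simulate stage")
        panel <- read_ped_map(config$ped, config$map)
        meta <- read_metadata(config$meta)
      }
      qa <- config$qc
      qc <- qc_apply(panel,
                     min_rate = qa$min_rate %||% 0.95,
                     min_maf = qa$min_maf %||% 0.01,
                     max_missing = qa$max_missing %||% 0.02)
      panel <- qc$panel
      meta <- meta[meta$animal_id %in% panel$animal_ids, , drop = FALSE]
      write_qc_report(qc$report, pth("qc_report.tsv"))
      add_out("qc_report", pth("qc_report.tsv"), 8L)
    } else if (stage == "detect") {
      if (is.null(panel)) stop("detect stage needs a panel (run qc first)")
      p <- do.call(roh_params, config$roh %||% list())
      runs <- detect_roh(panel, meta, p)
      validate_roh(runs, panel, p)
      write_roh_table(runs, pth("roh.tsv"))
      bs <- summarize_by_breed(runs, meta)
      utils::write.table(bs, pth("breed_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cc <- runs_per_chromosome(runs, meta, chroms = sort(unique(panel$map$chrom)))
      utils::write.table(cbind(population = rownames(cc), as.data.frame(cc)),
                         pth("chrom_counts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_out("roh", pth("roh.tsv"), nrow(runs))
      add_out("breed_summary", pth("breed_summary.tsv"), nrow(bs))
      add_out("chrom_counts", pth("chrom_counts.tsv"), nrow(cc))
    } else if (stage == "inbreeding") {
      runs <- read_roh_table(pth("roh.tsv"))
      inb <- inbreeding_table(runs, meta, panel, l_auto = config$l_auto)
      utils::write.table(inb, pth("inbreeding.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      si <- summarize_inbreeding(inb, meta)
      utils::write.table(si, pth("inbreeding_by_breed.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_out("inbreeding", pth("inbreeding.tsv"), nrow(inb))
      add_out("inbreeding_by_breed", pth("inbreeding_by_breed.tsv"), nrow(si))
    } else if (stage == "islands") {
      runs <- read_roh_table(pth("roh.tsv"))
      ia <- config$islands
      inc <- incidence_per_snp(runs, panel$map, meta)
      utils::write.table(inc, pth("incidence.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      isl <- call_islands(inc,
                          min_samples = ia$min_samples %||% 20,
                          min_span_bp = ia$min_span_bp %||% 1e6,
                          min_snps = ia$min_snps %||% 30,
                          max_gap_bp = ia$max_gap_bp %||% 0)
      isl <- classify_island_sharing(isl, runs, meta, panel$map)
      utils::write.table(as.data.frame(isl), pth("islands.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      props <- island_snp_proportions(isl, runs, meta, panel$map)
      utils::write.table(props, pth("island_proportions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      anova_tab <- fit_breed_models(props)
      utils::write.table(anova_tab, pth("island_anova.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_out("incidence", pth("incidence.tsv"), nrow(inc))
      add_out("islands", pth("islands.tsv"), nrow(isl))
      add_out("island_proportions", pth("island_proportions.tsv"), nrow(props))
      add_out("island_anova", pth("island_anova.tsv"), nrow(anova_tab))
    }
    completed <- c(completed, stage)
  }
  manifest$completed <- completed
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten a pipeline config for the manifest echo
config_echo <- function(config) {
  ech <- config
  if (!is.null(ech$sim)) ech$sim <- unclass(ech$sim)
  ech
}
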