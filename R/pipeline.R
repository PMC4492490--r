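# One-call orchestration: simulate (or load) a cohort, resample copy
# number onto the grid, run the two-level association cascade, call 13q
# gain, quantify the qPCR panel and run the group contrasts; all outputs
# are plain-text tables plus a JSON run manifest with file digests.

#' Run the full dosage-effect pipeline
#'
#' Stages: cohort (simulated from `scenario` or loaded from `input_dir`),
#' grid resampling, association cascade, gain calling, 2^(-ddCt)
#' quantification (calibrator = adenoma group) and the three group
#' contrasts per qPCR assay. Re-running with the same seed reproduces the
#' result tables byte-identically.
#'
#' @param output_dir Directory for the result tables; must be empty or
#'   absent unless `force`.
#' @param config An [analysis_config()].
#' @param scenario A [scenario_config()] used when `input_dir` is NULL.
#' @param input_dir Optional cohort directory laid out as by
#'   [write_cohort()]; NULL simulates.
#' @param region Region for gain calling (default the generator's 13q arm).
#' @param genome Genome description for the grid; default the generator's.
#' @param force Overwrite an existing non-empty output directory.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(output_dir, config = analysis_config(),
                         scenario = scenario_config(), input_dir = NULL,
                         region = region_13q(), genome = NULL, force = FALSE) {
  if (dir.exists(output_dir) && length(list.files(output_dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  cohort <- stage("cohort", {
    if (is.null(input_dir)) generate_cohort(scenario) else read_cohort(input_dir)
  })
  if (is.null(genome))
    genome <- if (!is.null(cohort$genome)) cohort$genome else default_genome()

  gridcn <- stage("grid", {
    grid <- build_grid(genome, config$grid_points)
    segments_to_grid(cohort$segments, grid)
  })
  aligned <- align_samples(cohort$mirna, gridcn, cohort$mrna)
  cascade <- stage("cascade", {
    suppressWarnings(run_cascade(aligned[[1]], aligned[[3]], aligned[[2]],
                                 cohort$catalogs, config))
  })
  gain <- stage("gain_calls", call_gain(gridcn, region, config$gain_threshold))

  relquant <- contrasts_df <- NULL
  if (!is.null(cohort$ct)) {
    relquant <- stage("relquant", {
      cal <- cohort$phenotype$sample[cohort$phenotype$histology == "adenoma"]
      relative_expression(cohort$ct, calibrator = cal)
    })
    contrasts_df <- stage("contrasts", {
      do.call(rbind, lapply(unique(relquant$assay), function(a) {
        v <- stats::setNames(relquant$rel_expr[relquant$assay == a],
                             relquant$sample[relquant$assay == a])
        do.call(rbind, lapply(c("histology", "gain13q",
                                "adenoma_nogain_vs_carcinoma_gain"), function(d) {
          ct <- contrast(v, cohort$phenotype, d)
          data.frame(assay = a, design = d, nA = ct$nA, nB = ct$nB, U = ct$U,
                     p = ct$p, medianA = ct$medianA, medianB = ct$medianB,
                     stringsAsFactors = FALSE)
        }))
      }))
    })
  }

  paths <- list(
    mirna_association = file.path(output_dir, "mirna_association.tsv"),
    target_priority = file.path(output_dir, "target_priority.tsv"),
    gain_calls = file.path(output_dir, "gain_calls.tsv"))
  write_tsv_plain(cascade$mirna_table, paths$mirna_association)
  write_tsv_plain(cascade$target_table, paths$target_priority)
  write_tsv_plain(data.frame(sample = names(gain), status = unname(gain)),
                  paths$gain_calls)
  if (!is.null(relquant)) {
    paths$relative_expression <- file.path(output_dir, "relative_expression.tsv")
    paths$contrasts <- file.path(output_dir, "contrasts.tsv")
    write_tsv_plain(as.data.frame(relquant), paths$relative_expression)
    write_tsv_plain(contrasts_df, paths$contrasts)
  }
  if (!is.null(cohort$truth)) {
    paths$truth_metrics <- file.path(output_dir, "truth_metrics.tsv")
    tm <- truth_metrics(cascade, cohort$truth)
    write_tsv_plain(data.frame(metric = names(tm),
                               value = unlist(lapply(tm, as.numeric))),
                    paths$truth_metrics)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirdosage")),
    seed = config$seed,
    config = unclass(config),
    scenario = if (is.null(input_dir)) unclass(scenario) else NULL,
    input_dir = input_dir,
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stage_timings_s = as.list(timings))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Reads the result tables listed in a run manifest and renders a short
#' markdown summary: counts of tested and selected miRNAs, the top
#' prioritized targets with their signs, and the contrast p-values. Every
#' number is taken from the written tables.
#'
#' @param manifest A manifest as returned by [run_pipeline()], or the path
#'   of a `manifest.json`.
#' @return A character scalar (markdown), invisibly printed with `cat()`.
#' @export
report <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  files <- vapply(manifest$outputs, function(o) o$path, character(1))
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("missing output file(s): ", paste(miss, collapse = ", "))
  mt <- utils::read.delim(files[["mirna_association"]], stringsAsFactors = FALSE)
  tt <- utils::read.delim(files[["target_priority"]], stringsAsFactors = FALSE)
  lines <- c("# Dosage-effect pipeline run",
             "",
             sprintf("- miRNAs tested: %d", nrow(mt)),
             sprintf("- candidate miRNAs selected (both FDR levels): %d%s",
                     sum(mt$selected),
                     if (any(mt$selected))
                       paste0(" (", paste(mt$mirna[mt$selected], collapse = ", "), ")")
                     else ""),
             sprintf("- prioritized targets: %d", nrow(tt)))
  if (nrow(tt)) {
    top <- utils::head(tt[order(tt$p), ], 10)
    lines <- c(lines, "", "Top targets:",
               sprintf("  - %s -> %s (p = %.3g, %s)", top$mirna, top$gene,
                       top$p, top$sign))
  }
  if (!is.null(manifest$outputs$contrasts)) {
    cf <- utils::read.delim(files[["contrasts"]], stringsAsFactors = FALSE)
    lines <- c(lines, "", "Group contrasts:",
               sprintf("  - %s / %s: p = %.3g (medians %.3g vs %.3g)",
                       cf$assay, cf$design, cf$p, cf$medianA, cf$medianB))
  }
  out <- paste(lines, collapse = "\n")
  cat(out, "\n")
  invisible(out)
}
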