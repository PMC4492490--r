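# Domain containers, validators and plain-text readers/writers shared by
# every stage of the dosage-effect pipeline. Coordinates are 0-based
# half-open (BED convention) throughout.

#' Analysis configuration
#'
#' Bundles every tunable threshold of the association cascade. Defaults
#' reflect the published analysis settings: a 2 Mb copy-number window
#' centred on each miRNA start, FDR significance at 0.05, a per-target
#' raw-p cut of 0.01, consensus support from at least 3 of 4 prediction
#' catalogs, a 30,000-point genome grid, and a log2 gain-call threshold
#' of 0.2.
#'
#' @param window_bp Total width (bp) of the copy-number window centred on
#'   each miRNA start position. Must be even.
#' @param fdr_alpha Benjamini-Hochberg FDR significance level.
#' @param target_p_cut Raw p-value cut for individual target prioritization.
#' @param consensus_min_tools Minimum number of catalogs that must predict a
#'   miRNA-gene pair for it to enter the consensus target set.
#' @param grid_points Number of equally spaced genomic grid positions.
#' @param gain_threshold Mean log2 ratio at or above which a region is
#'   called gained.
#' @param permutations Monte-Carlo permutation count B for the global test.
#' @param exact_cap Largest n! for which the permutation null is enumerated
#'   exhaustively instead of sampled (default 5040, i.e. n <= 7).
#' @param scale_covariates Scale covariate columns to unit variance before
#'   testing (default TRUE, so every window position contributes comparably).
#' @param seed Integer seed governing all randomness of a run.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window_bp = 2e6,
                            fdr_alpha = 0.05,
                            target_p_cut = 0.01,
                            consensus_min_tools = 3L,
                            grid_points = 30000L,
                            gain_threshold = 0.2,
                            permutations = 9999L,
                            exact_cap = 5040L,
                            scale_covariates = TRUE,
                            seed = 1L) {
  cfg <- list(window_bp = as.numeric(window_bp),
              fdr_alpha = as.numeric(fdr_alpha),
              target_p_cut = as.numeric(target_p_cut),
              consensus_min_tools = as.integer(consensus_min_tools),
              grid_points = as.integer(grid_points),
              gain_threshold = as.numeric(gain_threshold),
              permutations = as.integer(permutations),
              exact_cap = as.integer(exact_cap),
              scale_covariates = isTRUE(scale_covariates),
              seed = as.integer(seed))
  if (cfg$window_bp <= 0 || cfg$window_bp %% 2 != 0)
    stop("window_bp must be a positive even number of base pairs")
  if (cfg$fdr_alpha <= 0 || cfg$fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  if (cfg$target_p_cut <= 0 || cfg$target_p_cut >= 1) stop("target_p_cut must be in (0, 1)")
  if (cfg$consensus_min_tools < 1L) stop("consensus_min_tools must be >= 1")
  if (cfg$grid_points < 1L) stop("grid_points must be >= 1")
  if (cfg$permutations < 99L) stop("permutations must be >= 99")
  if (cfg$exact_cap < 1L) stop("exact_cap must be >= 1")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys map 1:1 onto the arguments of [analysis_config()]; absent
#' keys keep their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

# ---------------------------------------------------------------------------
# Segmented copy-number profiles

#' Segmented copy-number profiles
#'
#' Holds per-sample genomic segments carrying log2 copy-number ratios, the
#' usual output of a segmentation algorithm. Enforced invariants: start <
#' end for every segment, segments on one chromosome of one sample do not
#' overlap, all values are finite.
#'
#' @param x A data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `value` (0-based half-open intervals, log2 ratios).
#' @return `x`, sorted by sample/chrom/start, with class `seg_profiles`.
#' @export
seg_profiles <- function(x) {
  req <- c("sample", "chrom", "start", "end", "value")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("segment table lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[req]
  x$sample <- as.character(x$sample)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$value <- as.numeric(x$value)
  if (anyNA(x$start) || anyNA(x$end) || any(!is.finite(x$value)))
    stop("segment coordinates and values must be finite")
  bad <- x$start >= x$end
  if (any(bad))
    stop("segment with start >= end for sample ", x$sample[which(bad)[1]],
         " on ", x$chrom[which(bad)[1]])
  x <- x[order(x$sample, x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  for (grp in split(x, list(x$sample, x$chrom), drop = TRUE)) {
    n <- nrow(grp)
    if (n > 1L && any(grp$start[-1L] < grp$end[-n]))
      stop("overlapping segments for sample ", grp$sample[1],
           " on chromosome ", grp$chrom[1])
  }
  structure(x, class = c("seg_profiles", "data.frame"))
}

#' Read segmented copy-number profiles from a SEG-like TSV
#'
#' Expects a tab-separated file with header columns `sample`, `chrom`,
#' `start`, `end`, `value`. Non-numeric values are reported with their
#' (1-based) file line number; overlapping segments name the offending
#' sample and chromosome.
#'
#' @param path Path to the TSV file.
#' @return A [seg_profiles] object.
#' @export
read_segments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("start", "end", "value")) {
    if (is.null(tab[[col]])) stop("segment file lacks column '", col, "'")
    num <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(num) & !(trimws(tab[[col]]) %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric '", col, "' value '", tab[[col]][bad[1]],
           "' at line ", bad[1] + 1L, " of ", path)
    tab[[col]] <- num
  }
  seg_profiles(tab)
}

#' Write segmented profiles as a SEG-like TSV
#' @param x A [seg_profiles] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path) {
  write_tsv_plain(as.data.frame(x), path)
}

# ---------------------------------------------------------------------------
# Expression matrices

#' Expression matrix with optional feature annotation
#'
#' Features x samples continuous expression, assumed already normalised on
#' a log-like scale (no platform normalisation is performed). Feature
#' annotation is genomic loci for miRNAs (chrom, 0-based start) or absent
#' for mRNAs, whose feature ids are gene symbols.
#'
#' @param values Numeric matrix, features in rows (rownames) and samples in
#'   columns (colnames). Duplicate feature ids are rejected.
#' @param annotation Optional data.frame with columns `feature`, `chrom`,
#'   `start` (and optionally `end`). Annotation rows for features absent
#'   from the matrix are dropped with a warning.
#' @return A list of class `expr_matrix` with elements `values` and
#'   `annotation`.
#' @export
expr_matrix <- function(values, annotation = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ", colnames(values)[anyDuplicated(colnames(values))])
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) stop("expression values must be finite where present")
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!all(c("feature", "chrom", "start") %in% names(annotation)))
      stop("annotation needs columns feature, chrom, start")
    annotation$feature <- as.character(annotation$feature)
    extra <- setdiff(annotation$feature, rownames(values))
    if (length(extra)) {
      warning(length(extra), " annotated feature(s) absent from the matrix: ",
              paste(utils::head(extra, 5), collapse = ", "))
      annotation <- annotation[!annotation$feature %in% extra, , drop = FALSE]
    }
    rownames(annotation) <- NULL
  }
  structure(list(values = values, annotation = annotation), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "features x", ncol(x$values), "samples;",
      if (is.null(x$annotation)) "no annotation" else
        paste(nrow(x$annotation), "annotated loci"), "\n")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each. An
#' optional BED sidecar supplies genomic loci for the features (miRNAs).
#'
#' @param path Path to the matrix TSV.
#' @param loci Optional path to a BED file of feature loci.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, loci = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  feats <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- feats
  ann <- if (!is.null(loci)) read_loci(loci) else NULL
  expr_matrix(vals, annotation = ann)
}

#' Write an expression matrix as TSV
#' @param x An [expr_matrix].
#' @param path Output path.
#' @param loci Optional path for a BED sidecar holding the annotation.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, loci = NULL) {
  out <- data.frame(feature = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(out, path)
  if (!is.null(loci)) {
    if (is.null(x$annotation)) stop("no annotation to write")
    write_loci(x$annotation, loci)
  }
  invisible(path)
}

#' Read feature loci from BED
#'
#' @param path Path to a BED file (0-based half-open; the `name` field
#'   carries the feature id).
#' @return A data.frame with columns `feature`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(feature = as.character(gr$name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write feature loci as BED
#' @param ann Data.frame with columns `feature`, `chrom`, `start` and
#'   optionally `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(ann, path) {
  end <- if (!is.null(ann$end)) ann$end else ann$start + 1L
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(start = ann$start + 1L, end = end),
                               name = ann$feature)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Phenotypes

.histology_levels <- c("adenoma", "carcinoma", "cell_line", "unknown")
.gain_levels <- c("gain", "no_gain", "unknown")

#' Sample phenotype table
#'
#' One row per sample with the histology (adenoma / carcinoma / cell_line /
#' unknown) and the 13q copy-number status (gain / no_gain / unknown).
#'
#' @param x Data.frame with columns `sample`, `histology`, `gain13q`.
#' @return `x` with validated enums and class `phenotype_table`.
#' @export
phenotype_table <- function(x) {
  req <- c("sample", "histology", "gain13q")
  if (!all(req %in% names(x))) stop("phenotype table needs columns ",
                                    paste(req, collapse = ", "))
  x <- as.data.frame(x)[req]
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) stop("duplicate sample in phenotype table")
  x$histology <- as.character(x$histology)
  x$gain13q <- as.character(x$gain13q)
  if (!all(x$histology %in% .histology_levels))
    stop("histology must be one of: ", paste(.histology_levels, collapse = ", "))
  if (!all(x$gain13q %in% .gain_levels))
    stop("gain13q must be one of: ", paste(.gain_levels, collapse = ", "))
  rownames(x) <- NULL
  structure(x, class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype table from TSV
#' @param path Path to a TSV with columns sample, histology, gain13q.
#' @return A [phenotype_table].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a phenotype table as TSV
#' @param x A [phenotype_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) write_tsv_plain(as.data.frame(x), path)

# ---------------------------------------------------------------------------
# Target-prediction catalogs

#' Target-prediction catalogs
#'
#' A named list of per-tool data.frames of predicted (miRNA, gene) pairs,
#' as exported by target-prediction tools. Pairs are unique within a tool.
#'
#' @param x Named list of data.frames, each with columns `mirna`, `gene`;
#'   names are the tool names.
#' @return `x` with class `target_catalogs`.
#' @export
target_catalogs <- function(x) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("catalogs must be a named list (one name per tool)")
  if (anyDuplicated(names(x))) stop("duplicate tool name")
  x <- lapply(x, function(d) {
    if (!all(c("mirna", "gene") %in% names(d)))
      stop("each catalog needs columns mirna, gene")
    d <- data.frame(mirna = as.character(d$mirna), gene = as.character(d$gene),
                    stringsAsFactors = FALSE)
    d <- unique(d)
    d[order(d$mirna, d$gene), , drop = FALSE]
  })
  structure(x, class = "target_catalogs")
}

#' Read target-prediction catalogs
#' @param paths Named character vector of TSV paths (names are tool names);
#'   each file has columns `mirna`, `gene`.
#' @return A [target_catalogs] object.
#' @export
read_catalogs <- function(paths) {
  target_catalogs(lapply(paths, utils::read.delim, stringsAsFactors = FALSE))
}

#' Write target-prediction catalogs
#' @param x A [target_catalogs] object.
#' @param dir Output directory; one `<tool>.tsv` per catalog.
#' @return The written paths, invisibly.
#' @export
write_catalogs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(x), function(tool) {
    p <- file.path(dir, paste0(tool, ".tsv"))
    write_tsv_plain(x[[tool]], p)
    p
  }, character(1))
  invisible(paths)
}

# ---------------------------------------------------------------------------
# qPCR Ct tables

#' qPCR Ct table
#'
#' Raw cycle-threshold values, one row per (sample, assay) after averaging
#' technical replicates on the Ct scale. One assay is designated the
#' reference (housekeeping) assay used for delta-Ct normalisation.
#'
#' @param x Data.frame with columns `sample`, `assay`, `ct`; replicate rows
#'   for one (sample, assay) are averaged.
#' @param reference_assay Assay id of the reference gene.
#' @return Data.frame of class `ct_table` with attribute `reference_assay`.
#' @export
ct_table <- function(x, reference_assay) {
  req <- c("sample", "assay", "ct")
  if (!all(req %in% names(x))) stop("Ct table needs columns ", paste(req, collapse = ", "))
  x <- as.data.frame(x)[req]
  x$sample <- as.character(x$sample)
  x$assay <- as.character(x$assay)
  x$ct <- as.numeric(x$ct)
  if (any(!is.finite(x$ct)) || any(x$ct <= 0)) stop("Ct values must be finite and > 0")
  agg <- stats::aggregate(ct ~ sample + assay, data = x, FUN = mean)
  agg <- agg[order(agg$sample, agg$assay), , drop = FALSE]
  rownames(agg) <- NULL
  if (!reference_assay %in% agg$assay)
    stop("reference assay '", reference_assay, "' absent from table")
  structure(agg, class = c("ct_table", "data.frame"),
            reference_assay = as.character(reference_assay))
}

#' Read a Ct table from TSV
#' @param path TSV with columns sample, assay, ct.
#' @param reference_assay Assay id of the reference gene.
#' @return A [ct_table].
#' @export
read_ct <- function(path, reference_assay) {
  ct_table(utils::read.delim(path, stringsAsFactors = FALSE), reference_assay)
}

#' Write a Ct table as TSV
#' @param x A [ct_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(x, path) write_tsv_plain(as.data.frame(x), path)

# ---------------------------------------------------------------------------
# Sample alignment

#' Sample ids carried by a pipeline object
#' @param x An object holding per-sample data.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.expr_matrix <- function(x) colnames(x$values)
#' @export
sample_ids.seg_profiles <- function(x) unique(x$sample)
#' @export
sample_ids.phenotype_table <- function(x) x$sample
#' @export
sample_ids.ct_table <- function(x) unique(x$sample)
#' @export
sample_ids.grid_cn <- function(x) rownames(x$values)

#' Restrict an object to a given sample set and order
#' @param x A sample-indexed object.
#' @param samples Character vector of sample ids (the new order).
#' @return The restricted object.
#' @export
restrict_samples <- function(x, samples) UseMethod("restrict_samples")

#' @export
restrict_samples.expr_matrix <- function(x, samples) {
  expr_matrix(x$values[, samples, drop = FALSE], annotation = x$annotation)
}
#' @export
restrict_samples.seg_profiles <- function(x, samples) {
  y <- as.data.frame(x)[as.character(x$sample) %in% samples, , drop = FALSE]
  y$sample <- factor(y$sample, levels = samples)
  y <- y[order(y$sample, y$chrom, y$start), , drop = FALSE]
  y$sample <- as.character(y$sample)
  seg_profiles(y)
}
#' @export
restrict_samples.phenotype_table <- function(x, samples) {
  y <- as.data.frame(x)
  phenotype_table(y[match(samples, y$sample), , drop = FALSE])
}
#' @export
restrict_samples.ct_table <- function(x, samples) {
  y <- as.data.frame(x)[as.character(x$sample) %in% samples, , drop = FALSE]
  ct_table(y, attr(x, "reference_assay"))
}
#' @export
restrict_samples.grid_cn <- function(x, samples) {
  grid_cn(x$values[samples, , drop = FALSE], x$grid)
}

#' Restrict a set of objects to their common samples
#'
#' Intersects the sample ids of all supplied objects (order taken from the
#' first) and returns each object restricted to that common, identically
#' ordered sample set. Dropped samples are reported via a message and the
#' `"dropped"` attribute.
#'
#' @param ... Two or more sample-indexed objects ([expr_matrix],
#'   [seg_profiles], [phenotype_table], [ct_table], `grid_cn`), or a single
#'   list of them.
#' @return List of the restricted objects (same names/order), with
#'   attribute `dropped` naming the removed samples per object.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) && !inherits(objs[[1]], c(
    "expr_matrix", "seg_profiles", "phenotype_table", "ct_table", "grid_cn")))
    objs <- objs[[1]]
  if (length(objs) < 2L) stop("align_samples needs at least two objects")
  ids <- lapply(objs, sample_ids)
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no samples shared by all objects")
  dropped <- lapply(ids, setdiff, y = common)
  ndrop <- sum(lengths(dropped))
  if (ndrop) message("align_samples: dropped ", ndrop, " sample instance(s)")
  out <- lapply(objs, restrict_samples, samples = common)
  attr(out, "dropped") <- dropped
  out
}

# internal: deterministic TSV writer (fixed eol, no quoting, full precision)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                               scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
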