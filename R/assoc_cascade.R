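# The two-level inference cascade: association 1 (copy-number window ->
# miRNA expression), association 2 (consensus target-set expression ->
# miRNA expression), joint FDR filtering and per-target prioritization.
# The miRNA expression is always the response; copy number or target
# expression is the covariate set.

#' Consensus target set of a miRNA
#'
#' Genes predicted as targets of `mirna_id` by at least `min_tools` of the
#' supplied prediction catalogs.
#'
#' @param catalogs A [target_catalogs] object.
#' @param mirna_id miRNA identifier.
#' @param min_tools Minimum catalog support (default 3).
#' @return List of class `consensus_targets`: `mirna_id`, `genes` (sorted),
#'   `support` (named integer, gene -> number of predicting tools). A miRNA
#'   absent from every catalog yields an empty set with a warning.
#' @export
consensus_targets <- function(catalogs, mirna_id, min_tools = 3L) {
  if (length(catalogs) < min_tools)
    stop("need at least min_tools = ", min_tools, " catalogs")
  per_tool <- lapply(catalogs, function(d) unique(d$gene[d$mirna == mirna_id]))
  if (all(lengths(per_tool) == 0L))
    warning("miRNA '", mirna_id, "' absent from all catalogs; empty consensus set")
  support <- table(unlist(per_tool, use.names = FALSE))
  keep <- sort(names(support)[support >= min_tools])
  structure(list(mirna_id = mirna_id, genes = keep,
                 support = stats::setNames(as.integer(support[keep]), keep)),
            class = "consensus_targets")
}

# response/covariate completion policy: samples with any missing covariate
# in the window are excluded from that one test
complete_case_test <- function(y, X, config, method = "auto") {
  ok <- stats::complete.cases(X) & is.finite(y)
  if (sum(ok) < length(y))
    warning(length(y) - sum(ok), " sample(s) with missing covariates excluded")
  global_test(y[ok], X[ok, , drop = FALSE], B = config$permutations,
              seed = config$seed, method = method,
              scale = config$scale_covariates, exact_cap = config$exact_cap)
}

#' Association 1: copy-number window vs miRNA expression
#'
#' For every annotated miRNA, tests whether the copy-number values at the
#' grid positions inside a `window_bp` window centred on the miRNA start
#' are jointly associated with the miRNA's expression (one global-test
#' p-value per miRNA), then adjusts the p-values by Benjamini-Hochberg
#' across all tested miRNAs. miRNAs without locus annotation are skipped
#' with a warning.
#'
#' @param mirnas [expr_matrix] of miRNA expression with locus annotation.
#' @param gridcn [grid_cn] copy-number matrix, sample-aligned with `mirnas`.
#' @param config An [analysis_config()].
#' @return Data.frame: `mirna`, `chrom`, `start`, `statistic`, `p`, `fdr`,
#'   `method`, `n_permutations`.
#' @export
associate_cn <- function(mirnas, gridcn, config = analysis_config()) {
  stopifnot(inherits(mirnas, "expr_matrix"), inherits(gridcn, "grid_cn"))
  if (!identical(colnames(mirnas$values), rownames(gridcn$values)))
    stop("mirnas and gridcn are not sample-aligned; run align_samples() first")
  ann <- mirnas$annotation
  if (is.null(ann) || !nrow(ann)) stop("miRNA matrix carries no locus annotation")
  skipped <- setdiff(rownames(mirnas$values), ann$feature)
  if (length(skipped))
    warning(length(skipped), " miRNA(s) without locus skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    id <- ann$feature[i]
    wc <- window_covariates(gridcn, ann$chrom[i], ann$start[i],
                            window_bp = config$window_bp, mirna_id = id)
    res <- complete_case_test(mirnas$values[id, ], wc$values, config,
                              method = "permutation")
    data.frame(mirna = id, chrom = ann$chrom[i], start = ann$start[i],
               statistic = res$statistic, p = res$p_value, method = res$method,
               n_permutations = res$n_permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[c("mirna", "chrom", "start", "statistic", "p", "fdr", "method",
        "n_permutations")]
}

#' Association 2: consensus target expression vs miRNA expression
#'
#' For every miRNA with a non-empty consensus target set, tests whether the
#' expression of its consensus target genes (those present in the mRNA
#' matrix) is jointly associated with the miRNA's expression. miRNAs with
#' an empty or fully absent target set are reported as not determined
#' (`p = NA`) and excluded from the FDR denominator, mirroring the "n.d."
#' convention of published result tables.
#'
#' @param mirnas [expr_matrix] of miRNA expression.
#' @param mrnas [expr_matrix] of mRNA expression (features = gene symbols),
#'   sample-aligned with `mirnas`.
#' @param consensus Named list of [consensus_targets] (one per miRNA), or
#'   NULL to derive from `catalogs`.
#' @param catalogs Optional [target_catalogs] used when `consensus` is NULL.
#' @param config An [analysis_config()].
#' @return Data.frame: `mirna`, `n_targets`, `statistic`, `p`, `fdr`
#'   (NA where not determined), `method`, `n_permutations`.
#' @export
associate_targets <- function(mirnas, mrnas, consensus = NULL, catalogs = NULL,
                              config = analysis_config()) {
  stopifnot(inherits(mirnas, "expr_matrix"), inherits(mrnas, "expr_matrix"))
  if (!identical(colnames(mirnas$values), colnames(mrnas$values)))
    stop("mirnas and mrnas are not sample-aligned; run align_samples() first")
  ids <- rownames(mirnas$values)
  if (is.null(consensus)) {
    if (is.null(catalogs)) stop("supply consensus sets or catalogs")
    consensus <- lapply(stats::setNames(ids, ids), function(id)
      suppressWarnings(consensus_targets(catalogs, id,
                                         min_tools = config$consensus_min_tools)))
  }
  rows <- lapply(ids, function(id) {
    cs <- consensus[[id]]
    genes <- if (is.null(cs)) character(0) else cs$genes
    missing <- setdiff(genes, rownames(mrnas$values))
    if (length(missing))
      warning(length(missing), " consensus target(s) of ", id,
              " absent from mRNA matrix")
    genes <- setdiff(genes, missing)
    if (!length(genes))
      return(data.frame(mirna = id, n_targets = 0L, statistic = NA_real_,
                        p = NA_real_, method = "not_determined",
                        n_permutations = NA_integer_, stringsAsFactors = FALSE))
    X <- t(mrnas$values[genes, , drop = FALSE])
    res <- complete_case_test(mirnas$values[id, ], X, config,
                              method = "permutation")
    data.frame(mirna = id, n_targets = length(genes), statistic = res$statistic,
               p = res$p_value, method = res$method,
               n_permutations = res$n_permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  det <- !is.na(out$p)
  out$fdr[det] <- bh_fdr(out$p[det])
  out[c("mirna", "n_targets", "statistic", "p", "fdr", "method",
        "n_permutations")]
}

#' Select candidate miRNAs jointly significant at both levels
#'
#' A miRNA is selected when its copy-number FDR and its (determined)
#' target-set FDR are both below `fdr_alpha`; not-determined miRNAs are
#' never selected. Selection is monotone in `fdr_alpha`.
#'
#' @param cn_res Result of [associate_cn()] (needs columns `mirna`, `fdr`).
#' @param target_res Result of [associate_targets()] (needs `mirna`, `fdr`;
#'   NA marks not determined).
#' @param fdr_alpha Significance level (default 0.05).
#' @return Character vector of selected miRNA ids (in `cn_res` order).
#' @export
select_candidates <- function(cn_res, target_res, fdr_alpha = 0.05) {
  if (!nrow(cn_res)) return(character(0))
  tf <- target_res$fdr[match(cn_res$mirna, target_res$mirna)]
  sel <- cn_res$fdr < fdr_alpha & !is.na(tf) & tf < fdr_alpha
  cn_res$mirna[sel]
}

#' Prioritize individual targets of a selected miRNA
#'
#' Runs one single-covariate global test per consensus gene (miRNA
#' expression as response, that gene's expression as sole covariate),
#' keeps genes with raw p below `target_p_cut` (strict), and attaches the
#' sign of the miRNA-target Pearson correlation. Output is sorted by p
#' (ties by gene symbol) and invariant to the input gene order.
#'
#' @param mirna_id The selected miRNA.
#' @param mirnas,mrnas Sample-aligned [expr_matrix] objects.
#' @param consensus A [consensus_targets] set for `mirna_id`.
#' @param config An [analysis_config()]; `target_p_cut` supplies the cut.
#' @return Data.frame: `mirna`, `gene`, `p`, `sign`.
#' @export
prioritize_targets <- function(mirna_id, mirnas, mrnas, consensus,
                               config = analysis_config()) {
  genes <- sort(consensus$genes)
  missing <- setdiff(genes, rownames(mrnas$values))
  if (length(missing))
    warning(length(missing), " gene(s) absent from mRNA matrix skipped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  genes <- setdiff(genes, missing)
  y <- mirnas$values[mirna_id, ]
  rows <- lapply(genes, function(g) {
    t_expr <- mrnas$values[g, ]
    if (stats::sd(t_expr) == 0) return(NULL)
    res <- complete_case_test(y, matrix(t_expr, ncol = 1), config,
                              method = "permutation")
    if (res$p_value >= config$target_p_cut) return(NULL)
    data.frame(mirna = mirna_id, gene = g, p = res$p_value,
               sign = association_sign(y, t_expr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(0), gene = character(0),
                      p = numeric(0), sign = character(0))
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full association cascade
#'
#' Association 1 (copy number -> miRNA), association 2 (consensus targets
#' -> miRNA), joint selection at `fdr_alpha`, and per-target
#' prioritization for the selected miRNAs.
#'
#' @param mirnas,mrnas Sample-aligned [expr_matrix] objects.
#' @param gridcn Sample-aligned [grid_cn] matrix.
#' @param catalogs A [target_catalogs] object.
#' @param config An [analysis_config()].
#' @return List of class `cascade_result`: `mirna_table` (per-miRNA cn/
#'   target p and FDR plus `selected`), `target_table` (per-target rows for
#'   selected miRNAs), `selected`, `config`.
#' @export
run_cascade <- function(mirnas, mrnas, gridcn, catalogs,
                        config = analysis_config()) {
  ids <- rownames(mirnas$values)
  consensus <- lapply(stats::setNames(ids, ids), function(id)
    suppressWarnings(consensus_targets(catalogs, id,
                                       min_tools = config$consensus_min_tools)))
  cn_res <- associate_cn(mirnas, gridcn, config)
  tg_res <- associate_targets(mirnas, mrnas, consensus = consensus,
                              config = config)
  sel <- select_candidates(cn_res, tg_res, config$fdr_alpha)
  mt <- merge(cn_res[c("mirna", "chrom", "start", "p", "fdr")],
              tg_res[c("mirna", "n_targets", "p", "fdr")],
              by = "mirna", suffixes = c("_cn", "_target"))
  mt <- mt[order(mt$fdr_cn, mt$p_cn, mt$mirna), , drop = FALSE]
  mt$selected <- mt$mirna %in% sel
  rownames(mt) <- NULL
  tt <- do.call(rbind, lapply(sel, function(id)
    prioritize_targets(id, mirnas, mrnas, consensus[[id]], config)))
  if (is.null(tt))
    tt <- data.frame(mirna = character(0), gene = character(0),
                     p = numeric(0), sign = character(0))
  structure(list(mirna_table = mt, target_table = tt, selected = sel,
                 config = config),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("association cascade:", nrow(x$mirna_table), "miRNAs tested,",
      length(x$selected), "selected at FDR <", x$config$fdr_alpha, "\n")
  if (length(x$selected))
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  cat(nrow(x$target_table), "prioritized targets at p <",
      x$config$target_p_cut, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bundled published reference summaries (worked-example inputs)

#' Published reference miRNA association summary
#'
#' The bundled per-miRNA association summary for the 14 expressed 13q
#' miRNAs of a published 125-sample colorectal-cancer cohort: genomic
#' start, copy-number FDR and target-expression FDR (NA where the
#' consensus target set was not determined). Used as the worked-example
#' input for the selection filters.
#'
#' @return Data.frame: `mirna`, `chrom`, `start`, `cn_fdr`, `target_fdr`.
#' @export
reference_mirna_associations <- function() {
  path <- system.file("extdata", "reference_mirna_associations.tsv",
                      package = "mirdosage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "n.d.")
}

#' Published reference target summary for miR-15a
#'
#' The bundled prioritized-target summary for miR-15a from the same
#' published cohort: gene symbol, chromosome arm, individual global-test
#' p-value and association sign.
#'
#' @return Data.frame: `gene`, `chrom`, `p`, `sign`.
#' @export
reference_mir15a_targets <- function() {
  path <- system.file("extdata", "reference_mir15a_targets.tsv",
                      package = "mirdosage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Filter a printed target table at a raw-p cut
#'
#' Printed p-values are rounded to `digits` decimals, so a printed value
#' equal to the cut (e.g. 0.010 under a 0.01 cut) cannot be distinguished
#' from values just below it; the filter therefore keeps genes whose
#' printed p is below `p_cut + 0.5 * 10^-digits`. The pipeline itself
#' applies a strict `<` to exact computed p-values.
#'
#' @param targets Data.frame with columns `gene`, `p` (printed, rounded).
#' @param p_cut Raw p cut (default 0.01).
#' @param digits Decimals of the printed values (default 3).
#' @return The retained rows.
#' @export
filter_printed_targets <- function(targets, p_cut = 0.01, digits = 3) {
  targets[targets$p < p_cut + 0.5 * 10^-digits, , drop = FALSE]
}
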