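# 2^(-ddCt) relative quantification of qPCR Ct values and rank-based
# group contrasts (histology, 13q-gain status, and the progression
# contrast adenoma-without-gain vs carcinoma-with-gain).

#' Relative expression by the 2^(-ddCt) method
#'
#' Per sample and assay: dCt = Ct(assay) - Ct(reference assay); ddCt =
#' dCt - centre(dCt over the calibrator samples); relative expression =
#' 2^(-ddCt). Samples lacking a reference Ct are dropped with a warning.
#' The calibrator centre is the arithmetic mean of the calibrator dCt by
#' default; the median is offered for outlier robustness.
#'
#' @param ct A [ct_table] (technical replicates already averaged on the Ct
#'   scale).
#' @param calibrator Character vector of calibrator sample ids (e.g. the
#'   adenoma group, or non-targeting control transfectants).
#' @param centre `"mean"` (default) or `"median"` of the calibrator dCt.
#' @return Data.frame of class `rel_quant`: `sample`, `assay`, `delta_ct`,
#'   `ddct`, `rel_expr` (fold, > 0; 1 when ddCt = 0).
#' @export
relative_expression <- function(ct, calibrator, centre = c("mean", "median")) {
  centre <- match.arg(centre)
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference_assay")
  if (!length(calibrator)) stop("calibrator group is empty")
  d <- as.data.frame(ct)
  refct <- stats::setNames(d$ct[d$assay == ref], d$sample[d$assay == ref])
  targ <- d[d$assay != ref, , drop = FALSE]
  noref <- !(targ$sample %in% names(refct))
  if (any(noref)) {
    warning(length(unique(targ$sample[noref])),
            " sample(s) without reference Ct dropped")
    targ <- targ[!noref, , drop = FALSE]
  }
  if (!any(targ$sample %in% calibrator))
    stop("no calibrator sample present in the Ct table")
  targ$delta_ct <- targ$ct - refct[targ$sample]
  cfun <- if (centre == "mean") mean else stats::median
  out <- do.call(rbind, lapply(split(targ, targ$assay), function(a) {
    cal <- a$delta_ct[a$sample %in% calibrator]
    if (!length(cal)) stop("no calibrator sample measured for assay ", a$assay[1])
    a$ddct <- a$delta_ct - cfun(cal)
    a$rel_expr <- 2^(-a$ddct)
    a
  }))
  out <- out[order(out$sample, out$assay),
             c("sample", "assay", "delta_ct", "ddct", "rel_expr")]
  rownames(out) <- NULL
  structure(out, class = c("rel_quant", "data.frame"))
}

#' Group contrast of per-sample measurements
#'
#' Compares a per-sample measurement between two phenotype-defined groups
#' with the Mann-Whitney U test. Designs: `histology` (adenoma vs
#' carcinoma), `gain13q` (no_gain vs gain), and
#' `adenoma_nogain_vs_carcinoma_gain` (the progression contrast). Samples
#' with the relevant status unknown are excluded and counted.
#'
#' @param values Named numeric vector (sample -> measurement).
#' @param phenotypes A [phenotype_table].
#' @param design One of `"histology"`, `"gain13q"`,
#'   `"adenoma_nogain_vs_carcinoma_gain"`.
#' @return List of class `group_contrast`: `design`, `groupA`/`groupB`
#'   sample ids (A = adenoma / no_gain / adenoma-without-gain), `nA`, `nB`,
#'   `U`, `p`, `medianA`, `medianB`, `n_excluded`.
#' @export
contrast <- function(values, phenotypes,
                     design = c("histology", "gain13q",
                                "adenoma_nogain_vs_carcinoma_gain")) {
  design <- match.arg(design)
  stopifnot(inherits(phenotypes, "phenotype_table"))
  ph <- as.data.frame(phenotypes)
  ph <- ph[ph$sample %in% names(values), , drop = FALSE]
  grp <- switch(design,
    histology = list(A = ph$sample[ph$histology == "adenoma"],
                     B = ph$sample[ph$histology == "carcinoma"],
                     excl = ph$sample[!ph$histology %in% c("adenoma", "carcinoma")]),
    gain13q = list(A = ph$sample[ph$gain13q == "no_gain"],
                   B = ph$sample[ph$gain13q == "gain"],
                   excl = ph$sample[ph$gain13q == "unknown"]),
    adenoma_nogain_vs_carcinoma_gain = {
      known <- ph$histology %in% c("adenoma", "carcinoma") & ph$gain13q != "unknown"
      list(A = ph$sample[ph$histology == "adenoma" & ph$gain13q == "no_gain"],
           B = ph$sample[ph$histology == "carcinoma" & ph$gain13q == "gain"],
           excl = ph$sample[!known])
    })
  if (length(grp$A) < 2L || length(grp$B) < 2L)
    stop("design '", design, "': a group has fewer than 2 samples after filtering")
  a <- values[grp$A]; b <- values[grp$B]
  mw <- mann_whitney(a, b)
  structure(list(design = design, groupA = grp$A, groupB = grp$B,
                 nA = mw$nA, nB = mw$nB, U = mw$U, p = mw$p,
                 medianA = stats::median(a), medianB = stats::median(b),
                 n_excluded = length(grp$excl)),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("%s: nA = %d (median %.3g) vs nB = %d (median %.3g), U = %g, p = %.4g\n",
              x$design, x$nA, x$medianA, x$nB, x$medianB, x$U, x$p))
  invisible(x)
}
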