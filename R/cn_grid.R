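# Resampling of segmented copy-number profiles onto an equally spaced
# genomic grid, extraction of per-miRNA window covariate sets, and arm
# gain calling.

#' Build an equally spaced genomic grid
#'
#' Places `n_points` positions at a constant spacing of
#' `sum(genome)/n_points` along the concatenated genome (at the midpoints
#' of consecutive spacing intervals) and maps them back to chromosome
#' coordinates. Each chromosome thereby receives a number of points
#' proportional to its length, and spacing is uniform across the whole
#' genome to within 1 bp rounding.
#'
#' @param genome Named numeric vector, chromosome -> length in bp. The
#'   genome description is caller-supplied (no build is embedded).
#' @param n_points Number of grid positions (default 30000).
#' @return A data.frame of class `genomic_grid` with columns `chrom`,
#'   `pos` (0-based bp), and attributes `genome`, `spacing`, `n_points`.
#' @export
build_grid <- function(genome, n_points = 30000L) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L) stop("n_points must be >= 1")
  if (is.null(names(genome)) || any(names(genome) == ""))
    stop("genome must be a named chrom -> length vector")
  genome <- vapply(genome, as.numeric, numeric(1))
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  total <- sum(genome)
  if (total <= n_points) stop("genome shorter than requested point count")
  spacing <- total / n_points
  gpos <- (seq_len(n_points) - 0.5) * spacing
  offsets <- cumsum(c(0, unname(genome)))
  chrom_idx <- findInterval(gpos, offsets)
  out <- data.frame(chrom = names(genome)[chrom_idx],
                    pos = floor(gpos - offsets[chrom_idx]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("genomic_grid", "data.frame"),
            genome = genome, spacing = spacing, n_points = n_points)
}

#' Grid copy-number matrix
#'
#' Samples x grid-positions matrix of log2 copy-number ratios; the
#' container returned by [segments_to_grid()].
#'
#' @param values Numeric matrix, samples in rows (rownames), one column per
#'   grid position.
#' @param grid The [build_grid()] object the columns refer to.
#' @return A list of class `grid_cn` with elements `values`, `grid`.
#' @export
grid_cn <- function(values, grid) {
  values <- as.matrix(values)
  if (!inherits(grid, "genomic_grid")) stop("grid must be a genomic_grid")
  if (ncol(values) != nrow(grid)) stop("matrix columns must match grid size")
  if (is.null(rownames(values))) stop("values needs sample rownames")
  colnames(values) <- paste0(grid$chrom, ":", grid$pos)
  structure(list(values = values, grid = grid), class = "grid_cn")
}

#' @export
print.grid_cn <- function(x, ...) {
  cat("grid_cn:", nrow(x$values), "samples x", ncol(x$values), "grid positions",
      sprintf("(spacing ~%.0f bp)\n", attr(x$grid, "spacing")))
  invisible(x)
}

#' Resample segmented profiles onto a genomic grid
#'
#' Every grid cell takes the log2 value of the segment covering it. A grid
#' point falling in a gap between segments of a covered chromosome takes
#' the value of the nearest segment on that chromosome (segmented output
#' should tile a chromosome; gaps are platform artifacts). A chromosome
#' with no segments in a sample yields missing values for that sample.
#'
#' @param profiles A [seg_profiles] object.
#' @param grid A [build_grid()] grid.
#' @return A [grid_cn] matrix (samples x grid positions).
#' @export
segments_to_grid <- function(profiles, grid) {
  if (!inherits(profiles, "seg_profiles")) profiles <- seg_profiles(profiles)
  samples <- unique(profiles$sample)
  if (!length(samples)) stop("no profiles supplied")
  cols_by_chrom <- split(seq_len(nrow(grid)), grid$chrom)
  vals <- matrix(NA_real_, nrow = length(samples), ncol = nrow(grid),
                 dimnames = list(samples, NULL))
  segs_by_sample <- split(as.data.frame(profiles), profiles$sample)
  for (s in samples) {
    segs <- segs_by_sample[[s]]
    for (chrom in intersect(names(cols_by_chrom), unique(segs$chrom))) {
      cols <- cols_by_chrom[[chrom]]
      sc <- segs[segs$chrom == chrom, , drop = FALSE]    # sorted by start
      pos <- grid$pos[cols]
      nseg <- nrow(sc)
      i <- findInterval(pos, sc$start)
      v <- rep(NA_real_, length(pos))
      covered <- i >= 1L & pos < sc$end[pmax(i, 1L)]
      v[covered] <- sc$value[i[covered]]
      unc <- which(!covered)
      if (length(unc)) {
        ii <- i[unc]
        left_d <- ifelse(ii >= 1L, pos[unc] - sc$end[pmax(ii, 1L)] + 1, Inf)
        right_d <- ifelse(ii < nseg, sc$start[pmin(ii + 1L, nseg)] - pos[unc], Inf)
        pick_left <- left_d <= right_d
        v[unc] <- ifelse(pick_left, sc$value[pmax(ii, 1L)],
                         sc$value[pmin(ii + 1L, nseg)])
      }
      vals[s, cols] <- v
    }
  }
  grid_cn(vals, grid)
}

#' Extract the copy-number covariate set around a miRNA locus
#'
#' The window is `[start - window_bp/2, start + window_bp/2)` centred on
#' the miRNA's genomic start, clipped to the chromosome bounds; its
#' covariates are the grid copy-number columns falling inside. Two miRNAs
#' with identical (chrom, start) — e.g. members of one cluster — receive
#' identical covariate sets.
#'
#' @param gridcn A [grid_cn] matrix.
#' @param chrom,start Locus of the miRNA (0-based start bp).
#' @param window_bp Total window width in bp (default 2 Mb).
#' @param mirna_id Optional feature id carried through to the result.
#' @return List of class `window_covariates`: `mirna_id`, `window`
#'   (chrom/start/end), `columns` (grid column indices), `values`
#'   (samples x columns matrix).
#' @export
window_covariates <- function(gridcn, chrom, start, window_bp = 2e6,
                              mirna_id = NULL) {
  if (!inherits(gridcn, "grid_cn")) stop("gridcn must be a grid_cn")
  genome <- attr(gridcn$grid, "genome")
  half <- window_bp / 2
  lo <- max(0, start - half)
  hi <- start + half
  if (chrom %in% names(genome)) hi <- min(hi, genome[[chrom]])
  cols <- which(gridcn$grid$chrom == chrom &
                  gridcn$grid$pos >= lo & gridcn$grid$pos < hi)
  if (!length(cols))
    stop("window empty - grid too coarse for ", chrom, ":", start,
         "; enlarge window_bp or use a denser grid")
  structure(list(mirna_id = mirna_id,
                 window = list(chrom = chrom, start = lo, end = hi),
                 columns = cols,
                 values = gridcn$values[, cols, drop = FALSE]),
            class = "window_covariates")
}

#' Call copy-number gain over a region
#'
#' A sample is called `gain` when its mean log2 ratio over the region is at
#' or above `threshold` (the boundary is inclusive), `no_gain` otherwise,
#' and `unknown` when the region carries no data for that sample. An
#' in-silico stand-in for wet-lab arm-status assays whose output is a gain
#' call.
#'
#' @param x A [grid_cn] matrix or a [seg_profiles] object.
#' @param region List or vector with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param threshold Log2 gain threshold (default 0.2).
#' @return Named character vector (sample -> "gain"/"no_gain"/"unknown").
#' @export
call_gain <- function(x, region, threshold = 0.2) UseMethod("call_gain")

region_fields <- function(region) {
  list(chrom = as.character(region[["chrom"]]),
       start = as.numeric(region[["start"]]),
       end = as.numeric(region[["end"]]))
}

#' @export
call_gain.grid_cn <- function(x, region, threshold = 0.2) {
  r <- region_fields(region)
  cols <- which(x$grid$chrom == r$chrom &
                  x$grid$pos >= r$start & x$grid$pos < r$end)
  if (!length(cols)) stop("region overlaps no grid position")
  mval <- rowMeans(x$values[, cols, drop = FALSE], na.rm = TRUE)
  status <- ifelse(is.nan(mval), "unknown",
                   ifelse(mval >= threshold, "gain", "no_gain"))
  if (any(status == "unknown"))
    message(sum(status == "unknown"), " sample(s) without data in region: status unknown")
  stats::setNames(status, rownames(x$values))
}

#' @export
call_gain.seg_profiles <- function(x, region, threshold = 0.2) {
  r <- region_fields(region)
  samples <- unique(x$sample)
  status <- vapply(samples, function(s) {
    sc <- x[x$sample == s & x$chrom == r$chrom, , drop = FALSE]
    ov_lo <- pmax(sc$start, r$start)
    ov_hi <- pmin(sc$end, r$end)
    w <- pmax(0, ov_hi - ov_lo)
    if (sum(w) == 0) return("unknown")
    if (sum(w * sc$value) / sum(w) >= threshold) "gain" else "no_gain"
  }, character(1))
  if (any(status == "unknown"))
    message(sum(status == "unknown"), " sample(s) without data in region: status unknown")
  stats::setNames(status, samples)
}
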