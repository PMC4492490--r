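# Seeded generator of synthetic tumour cohorts carrying the statistical
# structure the cascade assumes: a recurrent 13q-arm gain, a subset of 13q
# miRNAs whose expression is affine in local copy number, and target genes
# whose expression is negatively (occasionally positively) coupled to a
# dosage miRNA. Every stage of the pipeline is testable on these cohorts
# with no external data.

# default genome description: autosome lengths rounded to the Mb, used by
# the generator only (grid construction always takes the genome as input)
default_genome <- function() {
  c(chr1 = 249e6, chr2 = 243e6, chr3 = 198e6, chr4 = 191e6, chr5 = 181e6,
    chr6 = 171e6, chr7 = 159e6, chr8 = 146e6, chr9 = 141e6, chr10 = 136e6,
    chr11 = 135e6, chr12 = 134e6, chr13 = 115e6, chr14 = 107e6,
    chr15 = 103e6, chr16 = 90e6, chr17 = 81e6, chr18 = 78e6, chr19 = 59e6,
    chr20 = 63e6, chr21 = 48e6, chr22 = 51e6)
}

#' The 13q arm region of the generator's genome
#' @return List with `chrom`, `start`, `end` (0-based half-open).
#' @export
region_13q <- function() list(chrom = "chr13", start = 17.9e6, end = 115e6)

#' Synthetic-cohort scenario configuration
#'
#' Defaults emulate the published study setting: a 125-sample colorectal
#' cohort, a whole-arm 13q gain in half the samples (the reported 40-60%
#' range), 14 expressed miRNAs on 13q of which 3 carry a copy-number
#' dosage effect, and ~2000 measured genes of which each dosage miRNA
#' represses a subset of its listed targets.
#'
#' @param n_samples Cohort size.
#' @param gain_fraction Fraction of samples carrying the 13q-arm gain.
#' @param gain_level_mean,gain_level_sd Log2 level of the gained arm.
#' @param n_mirnas_region Number of expressed miRNAs on the 13q arm.
#' @param planted_dosage_mirnas How many of them carry the dosage effect.
#' @param dosage_slope Expression units per log2 copy-number unit.
#' @param n_genes Number of measured genes.
#' @param targets_per_mirna Catalog-listed targets per miRNA.
#' @param true_repressed_fraction Fraction of a dosage miRNA's listed
#'   targets that are truly repressed.
#' @param repression_slope Magnitude of the (negative) coupling slope.
#' @param positive_target_fraction Fraction of listed targets positively
#'   coupled instead.
#' @param noise_sd Residual expression noise (log-scale units).
#' @param tool_sensitivity Probability a tool lists a true listed target.
#' @param tool_false_targets Random decoy genes added per tool per miRNA.
#' @param carcinoma_gain_odds Odds multiplier for carcinoma histology in
#'   gained samples (progression coupling; baseline odds 1:1).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 125L,
                            gain_fraction = 0.5,
                            gain_level_mean = 0.4,
                            gain_level_sd = 0.05,
                            n_mirnas_region = 14L,
                            planted_dosage_mirnas = 3L,
                            dosage_slope = 1.0,
                            n_genes = 2000L,
                            targets_per_mirna = 20L,
                            true_repressed_fraction = 0.25,
                            repression_slope = 0.7,
                            positive_target_fraction = 0.05,
                            noise_sd = 0.5,
                            tool_sensitivity = 0.8,
                            tool_false_targets = 30L,
                            carcinoma_gain_odds = 4,
                            seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              gain_fraction = as.numeric(gain_fraction),
              gain_level_mean = as.numeric(gain_level_mean),
              gain_level_sd = as.numeric(gain_level_sd),
              n_mirnas_region = as.integer(n_mirnas_region),
              planted_dosage_mirnas = as.integer(planted_dosage_mirnas),
              dosage_slope = as.numeric(dosage_slope),
              n_genes = as.integer(n_genes),
              targets_per_mirna = as.integer(targets_per_mirna),
              true_repressed_fraction = as.numeric(true_repressed_fraction),
              repression_slope = as.numeric(repression_slope),
              positive_target_fraction = as.numeric(positive_target_fraction),
              noise_sd = as.numeric(noise_sd),
              tool_sensitivity = as.numeric(tool_sensitivity),
              tool_false_targets = as.integer(tool_false_targets),
              carcinoma_gain_odds = as.numeric(carcinoma_gain_odds),
              seed = as.integer(seed))
  fr <- c("gain_fraction", "true_repressed_fraction",
          "positive_target_fraction", "tool_sensitivity")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must lie in [0, 1]")
  if (cfg$n_samples < 4L) stop("n_samples must be >= 4")
  if (cfg$gain_level_sd <= 0 || cfg$noise_sd <= 0) stop("sds must be > 0")
  if (cfg$planted_dosage_mirnas > cfg$n_mirnas_region)
    stop("planted_dosage_mirnas cannot exceed n_mirnas_region")
  if (cfg$n_genes < cfg$n_mirnas_region * cfg$targets_per_mirna)
    stop("n_genes too small for the requested target sets")
  structure(cfg, class = "scenario_config")
}

.catalog_tools <- c("targetscan", "pita", "microcosm", "mirtarbase")

#' Generate a synthetic tumour cohort
#'
#' Gain samples carry a 13q-arm segment at a log2 level around
#' `gain_level_mean`; dosage miRNA expression is affine in the local copy
#' number (`base + dosage_slope * CN + noise`), null miRNAs are
#' independent of copy number; truly repressed targets follow
#' `base - repression_slope * miRNA + noise` (positively coupled targets
#' with `+`); each of four prediction catalogs lists a true listed target
#' with probability `tool_sensitivity` and adds `tool_false_targets`
#' random decoys; Ct values are `30 - expression + N(0, 0.1)` against a
#' constant reference assay; carcinoma histology is enriched among gained
#' samples by `carcinoma_gain_odds`.
#'
#' @param config A [scenario_config()].
#' @return List of class `synthetic_cohort`: `segments` ([seg_profiles]),
#'   `mirna` / `mrna` ([expr_matrix]), `phenotype` ([phenotype_table]),
#'   `catalogs` ([target_catalogs]), `ct` ([ct_table]), `genome`, `region`,
#'   `truth` (planted miRNA ids, coupled target genes with signs, gain
#'   status), `config`.
#' @export
generate_cohort <- function(config = scenario_config()) {
  if (!inherits(config, "scenario_config")) config <- do.call(scenario_config, config)
  genome <- default_genome()
  region <- region_13q()
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    gain <- rep(FALSE, n)
    gain[sample.int(n, round(config$gain_fraction * n))] <- TRUE

    # one baseline segment per chromosome; chr13 split into p and q arms
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      base <- data.frame(sample = samples[i], chrom = names(genome),
                         start = 0, end = unname(genome),
                         value = stats::rnorm(length(genome), 0, 0.03),
                         stringsAsFactors = FALSE)
      q13 <- if (gain[i])
        stats::rnorm(1, config$gain_level_mean, config$gain_level_sd)
      else stats::rnorm(1, 0, 0.03)
      c13 <- base$chrom == "chr13"
      rbind(base[!c13, ],
            data.frame(sample = samples[i], chrom = "chr13",
                       start = c(0, region$start),
                       end = c(region$start, genome[["chr13"]]),
                       value = c(stats::rnorm(1, 0, 0.03), q13),
                       stringsAsFactors = FALSE))
    }))
    segments <- seg_profiles(segs)

    # 13q miRNA loci: fixed spread of starts incl. two clustered pairs
    k <- config$n_mirnas_region
    starts_mb <- seq(20, 108, length.out = k)
    starts <- round(starts_mb * 1e6)
    mirna_ids <- sprintf("mir-13q-%02d", seq_len(k))
    loci <- data.frame(feature = mirna_ids, chrom = "chr13",
                       start = starts, end = starts + 80L,
                       stringsAsFactors = FALSE)
    planted <- sort(sample(mirna_ids, config$planted_dosage_mirnas))

    # local copy number of each sample at each miRNA locus (all on 13q)
    q_values <- vapply(samples, function(s) {
      sc <- segs[segs$sample == s & segs$chrom == "chr13" &
                   segs$start == region$start, "value"]
      sc[1]
    }, numeric(1))
    mirna_base <- stats::rnorm(k, 5, 1)
    mirna_vals <- t(vapply(seq_len(k), function(j) {
      mu <- mirna_base[j] +
        if (mirna_ids[j] %in% planted) config$dosage_slope * q_values else 0
      mu + stats::rnorm(n, 0, config$noise_sd)
    }, numeric(n)))
    dimnames(mirna_vals) <- list(mirna_ids, samples)
    mirna <- expr_matrix(mirna_vals, annotation = loci)

    # genes: disjoint listed-target blocks per miRNA, rest background
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    listed <- split(sample(genes, k * config$targets_per_mirna),
                    rep(mirna_ids, each = config$targets_per_mirna))
    gene_base <- stats::setNames(stats::rnorm(config$n_genes, 7, 1), genes)
    mrna_vals <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                        nrow = config$n_genes,
                        dimnames = list(genes, samples)) + gene_base
    truth_targets <- NULL
    for (id in planted) {
      tg <- listed[[id]]
      n_rep <- round(config$true_repressed_fraction * length(tg))
      n_pos <- round(config$positive_target_fraction * length(tg))
      coupled <- sample(tg, n_rep + n_pos)
      rep_g <- coupled[seq_len(n_rep)]
      pos_g <- setdiff(coupled, rep_g)
      y <- mirna_vals[id, ]
      for (g in rep_g)
        mrna_vals[g, ] <- gene_base[g] - config$repression_slope * y +
          stats::rnorm(n, 0, config$noise_sd)
      for (g in pos_g)
        mrna_vals[g, ] <- gene_base[g] + config$repression_slope * y +
          stats::rnorm(n, 0, config$noise_sd)
      truth_targets <- rbind(truth_targets,
        data.frame(mirna = id, gene = c(rep_g, pos_g),
                   sign = c(rep("negative", length(rep_g)),
                            rep("positive", length(pos_g))),
                   stringsAsFactors = FALSE))
    }
    mrna <- expr_matrix(mrna_vals)

    # catalogs: each tool lists a listed target with prob tool_sensitivity
    # plus tool_false_targets decoys from the non-listed pool
    catalogs <- target_catalogs(lapply(
      stats::setNames(.catalog_tools, .catalog_tools), function(tool) {
        do.call(rbind, lapply(mirna_ids, function(id) {
          tg <- listed[[id]]
          hit <- tg[stats::runif(length(tg)) < config$tool_sensitivity]
          pool <- setdiff(genes, tg)
          decoys <- sample(pool, min(config$tool_false_targets, length(pool)))
          data.frame(mirna = id, gene = c(hit, decoys), stringsAsFactors = FALSE)
        }))
      }))

    # histology coupled to gain through an odds multiplier
    p_gain <- config$carcinoma_gain_odds / (1 + config$carcinoma_gain_odds)
    p_carc <- ifelse(gain, p_gain, 0.5)
    histology <- ifelse(stats::runif(n) < p_carc, "carcinoma", "adenoma")
    phenotype <- phenotype_table(data.frame(
      sample = samples, histology = histology,
      gain13q = ifelse(gain, "gain", "no_gain"), stringsAsFactors = FALSE))

    # qPCR panel: planted miRNA assays against a constant reference gene
    assays <- c(planted, "mir-ref")
    ct_rows <- do.call(rbind, lapply(assays, function(a) {
      expr <- if (a == "mir-ref") rep(5, n) else mirna_vals[a, ]
      data.frame(sample = samples, assay = a,
                 ct = 30 - expr + stats::rnorm(n, 0, 0.1),
                 stringsAsFactors = FALSE)
    }))
    ct <- ct_table(ct_rows, reference_assay = "mir-ref")

    structure(list(segments = segments, mirna = mirna, mrna = mrna,
                   phenotype = phenotype, catalogs = catalogs, ct = ct,
                   genome = genome, region = region,
                   truth = list(planted = planted, targets = truth_targets,
                                gain = stats::setNames(gain, samples),
                                seed = config$seed),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort as a plain-text directory
#'
#' Emits `segments.seg`, `mirna.tsv`, `loci.bed`, `mrna.tsv`,
#' `phenotype.tsv`, `ct.tsv`, `catalogs/<tool>.tsv` and `truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  write_expression(cohort$mirna, file.path(dir, "mirna.tsv"),
                   loci = file.path(dir, "loci.bed"))
  write_expression(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_phenotypes(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  write_ct(cohort$ct, file.path(dir, "ct.tsv"))
  write_catalogs(cohort$catalogs, file.path(dir, "catalogs"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir The cohort directory.
#' @param reference_assay Reference assay of the Ct table.
#' @return A list with the same data elements as [generate_cohort()].
#' @export
read_cohort <- function(dir, reference_assay = "mir-ref") {
  tools <- sub("[.]tsv$", "", list.files(file.path(dir, "catalogs")))
  paths <- stats::setNames(file.path(dir, "catalogs", paste0(tools, ".tsv")), tools)
  list(segments = read_segments(file.path(dir, "segments.seg")),
       mirna = read_expression(file.path(dir, "mirna.tsv"),
                               loci = file.path(dir, "loci.bed")),
       mrna = read_expression(file.path(dir, "mrna.tsv")),
       phenotype = read_phenotypes(file.path(dir, "phenotype.tsv")),
       ct = read_ct(file.path(dir, "ct.tsv"), reference_assay),
       catalogs = read_catalogs(paths))
}

#' Recovery metrics of a cascade run against the generative truth
#'
#' @param cascade A `cascade_result` from [run_cascade()] on the cohort
#'   that produced `truth`.
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @return List: `sensitivity` (planted miRNAs selected / planted),
#'   `false_selections` (non-planted selected), `target_recovery` (truly
#'   coupled targets of selected planted miRNAs retained at the p cut),
#'   `sign_accuracy` (retained true targets with the correct sign; NA when
#'   none retained).
#' @export
truth_metrics <- function(cascade, truth) {
  tested <- cascade$mirna_table$mirna
  if (!all(truth$planted %in% tested))
    stop("truth and cascade result refer to different miRNA universes")
  sel <- cascade$selected
  sens <- if (length(truth$planted))
    length(intersect(sel, truth$planted)) / length(truth$planted) else NA_real_
  false_sel <- length(setdiff(sel, truth$planted))
  tt <- cascade$target_table
  truly <- truth$targets[truth$targets$mirna %in% intersect(sel, truth$planted), ,
                         drop = FALSE]
  if (is.null(truly) || !nrow(truly)) {
    recovery <- NA_real_; sign_acc <- NA_real_
  } else {
    key <- paste(tt$mirna, tt$gene)
    hit <- paste(truly$mirna, truly$gene) %in% key
    recovery <- mean(hit)
    if (any(hit)) {
      got <- tt$sign[match(paste(truly$mirna, truly$gene)[hit], key)]
      sign_acc <- mean(got == truly$sign[hit])
    } else sign_acc <- NA_real_
  }
  list(sensitivity = sens, false_selections = false_sel,
       target_recovery = recovery, sign_accuracy = sign_acc)
}
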