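make_catalogs <- function(tab) {
  # tab: named list tool -> character vector of genes for one miRNA
  target_catalogs(lapply(tab, function(genes)
    data.frame(mirna = "mir-x", gene = genes, stringsAsFactors = FALSE)))
}

test_that("consensus sets require the configured tool support", {
  cat4 <- make_catalogs(list(t1 = c("A", "B", "C"), t2 = c("A", "B"),
                             t3 = c("A", "D"), t4 = c("A", "B", "E")))
  cs <- consensus_targets(cat4, "mir-x", min_tools = 3)
  expect_equal(cs$genes, c("A", "B"))          # A in 4 tools, B in 3
  expect_equal(unname(cs$support[c("A", "B")]), c(4L, 3L))

  # gene in only 2 of 4 excluded at min_tools = 3
  expect_false("C" %in% cs$genes)

  # engineered 4x5 overlap fixture: support counts match a hand tally
  cat5 <- make_catalogs(list(t1 = c("g1", "g2", "g3", "g4", "g5"),
                             t2 = c("g1", "g2", "g3", "g6", "g7"),
                             t3 = c("g1", "g2", "g8", "g9", "g10"),
                             t4 = c("g1", "g11", "g12", "g13", "g14")))
  cs5 <- consensus_targets(cat5, "mir-x", min_tools = 3)
  expect_equal(cs5$genes, c("g1", "g2"))
  expect_equal(unname(cs5$support), c(4L, 3L))

  expect_warning(empty <- consensus_targets(cat4, "mir-none", min_tools = 3),
                 "absent from all catalogs")
  expect_equal(length(empty$genes), 0L)
  expect_error(consensus_targets(cat4[1:2], "mir-x", min_tools = 3), "at least")
})

# small planted fixture shared by the level-1 tests
planted_level1 <- function(seed, n = 60) {
  set.seed(seed)
  genome <- toy_genome()
  grid <- build_grid(genome, 60)
  samples <- sprintf("s%02d", seq_len(n))
  gain <- rep(c(TRUE, FALSE), length.out = n)
  segs <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(sample = samples[i], chrom = c("chrA", "chrB"), start = 0,
               end = c(10e6, 5e6),
               value = c(if (gain[i]) rnorm(1, 0.4, 0.05) else rnorm(1, 0, 0.03),
                         rnorm(1, 0, 0.03)))))
  gcn <- segments_to_grid(seg_profiles(segs), grid)
  cn_local <- vapply(seq_len(n), function(i) segs$value[2 * i - 1], numeric(1))
  ids <- c("mir-dose", sprintf("mir-null-%02d", 1:10))
  vals <- rbind(5 + 2 * cn_local + rnorm(n, 0, 0.3),
                matrix(rnorm(10 * n, 5, 0.5), 10, n))
  dimnames(vals) <- list(ids, samples)
  ann <- data.frame(feature = ids, chrom = "chrA",
                    start = seq(1e6, 9e6, length.out = 11))
  list(mirnas = expr_matrix(vals, annotation = ann), gridcn = gcn, gain = gain)
}

test_that("copy-number association ranks a planted dosage miRNA first", {
  fx <- planted_level1(21)
  res <- associate_cn(fx$mirnas, fx$gridcn, fast_config(21))
  expect_equal(nrow(res), 11L)
  expect_equal(res$mirna[which.min(res$fdr)], "mir-dose")
  expect_lt(res$fdr[res$mirna == "mir-dose"], 0.05)
})

test_that("constant copy number gives statistic 0 and p = 1 everywhere", {
  fx <- planted_level1(22)
  flat <- fx$gridcn
  flat$values[] <- 0.1
  res <- suppressWarnings(associate_cn(fx$mirnas, flat, fast_config(22)))
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
})

test_that("a duplicated miRNA row receives an identical p under a fixed seed", {
  fx <- planted_level1(23)
  m <- fx$mirnas
  vals <- rbind(m$values, "mir-dup" = m$values["mir-dose", ])
  ann <- rbind(m$annotation,
               data.frame(feature = "mir-dup",
                          chrom = m$annotation$chrom[1],
                          start = m$annotation$start[1]))
  m2 <- expr_matrix(vals, annotation = ann)
  res <- associate_cn(m2, fx$gridcn, fast_config(23))
  expect_identical(res$p[res$mirna == "mir-dup"],
                   res$p[res$mirna == "mir-dose"])
})

test_that("target association detects planted repression and reports n.d. for empty sets", {
  set.seed(24)
  n <- 60
  samples <- sprintf("s%02d", seq_len(n))
  y <- rnorm(n, 5, 1)
  mir <- expr_matrix(matrix(y, 1, n, dimnames = list("mir-x", samples)))
  genes <- sprintf("G%02d", 1:40)
  mv <- matrix(rnorm(40 * n, 7, 0.5), 40, n, dimnames = list(genes, samples))
  hit <- genes[1:5]
  for (g in hit) mv[g, ] <- 7 - 0.7 * y + rnorm(n, 0, 0.5)
  mrna <- expr_matrix(mv)
  cs <- list("mir-x" = structure(list(mirna_id = "mir-x", genes = genes[1:20],
                                      support = NULL), class = "consensus_targets"))
  res <- associate_targets(mir, mrna, consensus = cs, config = fast_config(24))
  expect_lt(res$fdr[res$mirna == "mir-x"], 0.05)
  expect_equal(res$n_targets, 20L)

  # empty consensus -> not determined, excluded from FDR
  cs_empty <- list("mir-x" = structure(list(mirna_id = "mir-x",
                                            genes = character(0), support = NULL),
                                       class = "consensus_targets"))
  nd <- associate_targets(mir, mrna, consensus = cs_empty,
                          config = fast_config(24))
  expect_true(is.na(nd$p))
  expect_true(is.na(nd$fdr))
  expect_identical(nd$method, "not_determined")
})

test_that("target-association p-values are uniform under independence", {
  set.seed(25)
  n <- 40
  samples <- sprintf("s%02d", seq_len(n))
  cfg <- analysis_config(permutations = 199L, seed = 25)
  ps <- replicate(200, {
    y <- rnorm(n)
    mir <- expr_matrix(matrix(y, 1, n, dimnames = list("mir-x", samples)))
    mv <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(sprintf("G%d", 1:5), samples))
    cs <- list("mir-x" = structure(list(mirna_id = "mir-x",
                                        genes = sprintf("G%d", 1:5),
                                        support = NULL),
                                   class = "consensus_targets"))
    associate_targets(mir, expr_matrix(mv), consensus = cs,
                      config = analysis_config(permutations = 199L,
                                               seed = sample.int(1e6, 1)))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("candidate selection applies both FDR levels, skips n.d., and is monotone in alpha", {
  cn <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                   fdr = c(0.001, 0.01, 0.2, 0.04))
  tg <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                   fdr = c(0.02, NA, 0.01, 0.2))
  expect_equal(select_candidates(cn, tg, 0.05), "m1")
  expect_equal(select_candidates(cn[0, ], tg[0, ], 0.05), character(0))

  set.seed(26)
  for (rep in 1:20) {
    cnr <- data.frame(mirna = sprintf("m%d", 1:10), fdr = runif(10))
    tgr <- data.frame(mirna = sprintf("m%d", 1:10),
                      fdr = ifelse(runif(10) < 0.3, NA, runif(10)))
    a1 <- runif(1, 0.01, 0.5); a2 <- runif(1, a1, 0.9)
    s1 <- select_candidates(cnr, tgr, a1)
    s2 <- select_candidates(cnr, tgr, a2)
    expect_true(all(s1 %in% s2))
    expect_false(any(is.na(tgr$fdr[match(s2, tgr$mirna)])))
  }
})

test_that("target prioritization keeps sub-threshold genes with correct signs, deterministically", {
  set.seed(27)
  n <- 60
  samples <- sprintf("s%02d", seq_len(n))
  y <- rnorm(n, 5, 1)
  mir <- expr_matrix(matrix(y, 1, n, dimnames = list("mir-x", samples)))
  genes <- c("COPY", "REPR", sprintf("N%02d", 1:8))
  mv <- matrix(rnorm(10 * n, 7, 0.5), 10, n, dimnames = list(genes, samples))
  mv["COPY", ] <- y                      # identical expression
  mv["REPR", ] <- 7 - 0.8 * y + rnorm(n, 0, 0.4)
  mrna <- expr_matrix(mv)
  cs <- structure(list(mirna_id = "mir-x", genes = genes, support = NULL),
                  class = "consensus_targets")
  cfg <- fast_config(27)
  out <- prioritize_targets("mir-x", mir, mrna, cs, cfg)
  expect_equal(out$p[out$gene == "COPY"], min(out$p))
  expect_identical(out$sign[out$gene == "COPY"], "positive")
  expect_true("REPR" %in% out$gene)
  expect_identical(out$sign[out$gene == "REPR"], "negative")
  expect_true(all(out$p < cfg$target_p_cut))
  expect_true(!is.unsorted(out$p))

  # invariant to gene input order, reproducible under the same seed
  cs_rev <- structure(list(mirna_id = "mir-x", genes = rev(genes),
                           support = NULL), class = "consensus_targets")
  expect_identical(out, prioritize_targets("mir-x", mir, mrna, cs_rev, cfg))

  # planted repressed gene recovered with a negative sign in >= 95% of reps
  hits <- replicate(60, {
    y <- rnorm(n, 5, 1)
    mirr <- expr_matrix(matrix(y, 1, n, dimnames = list("mir-x", samples)))
    g <- matrix(7 - 0.8 * y + rnorm(n, 0, 0.4), 1, n,
                dimnames = list("REPR", samples))
    csr <- structure(list(mirna_id = "mir-x", genes = "REPR", support = NULL),
                     class = "consensus_targets")
    res <- prioritize_targets("mir-x", mirr, expr_matrix(g), csr,
                              analysis_config(permutations = 999L,
                                              seed = sample.int(1e6, 1)))
    nrow(res) == 1L && res$sign == "negative"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("published reference tables reproduce the reported selections", {
  ref <- reference_mirna_associations()
  expect_equal(nrow(ref), 14L)

  # copy-number level alone: 6 significant miRNAs
  cn_sig <- ref$mirna[ref$cn_fdr < 0.05]
  expect_equal(length(cn_sig), 6L)
  expect_setequal(cn_sig, c("hsa-mir-15a", "hsa-mir-17", "hsa-mir-19a",
                            "hsa-mir-20a", "hsa-mir-19b-1", "hsa-mir-92a-1"))

  # joint filter via select_candidates: the three reported candidates
  sel <- select_candidates(data.frame(mirna = ref$mirna, fdr = ref$cn_fdr),
                           data.frame(mirna = ref$mirna, fdr = ref$target_fdr),
                           0.05)
  expect_setequal(sel, c("hsa-mir-15a", "hsa-mir-17", "hsa-mir-20a"))

  # printed target table: 5 genes at the printed-precision cut, 4 - / 1 +
  tg <- filter_printed_targets(reference_mir15a_targets())
  expect_equal(nrow(tg), 5L)
  expect_equal(sum(tg$sign == "negative"), 4L)
  expect_equal(sum(tg$sign == "positive"), 1L)
})
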