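test_that("grid construction spaces points uniformly and allocates by length", {
  g <- build_grid(c(chr1 = 1000), 10)
  expect_equal(nrow(g), 10L)
  expect_equal(unique(diff(g$pos)), 100)
  expect_equal(attr(g, "spacing"), 100)

  # two chromosomes 600/400 bp -> 6 and 4 points
  g2 <- build_grid(c(c1 = 600, c2 = 400), 10)
  expect_equal(as.vector(table(g2$chrom)[c("c1", "c2")]), c(6L, 4L))

  # spacing uniform within 1 bp across a genome-scale description
  g3 <- build_grid(c(a = 249e6, b = 115e6, c = 51e6), 4000)
  d <- diff(ifelse(g3$chrom == "a", 0, ifelse(g3$chrom == "b", 249e6, 364e6)) + g3$pos)
  expect_lte(max(d) - min(d), 1)
  expect_equal(nrow(g3), 4000L)

  # default point count
  expect_equal(formals(build_grid)$n_points, 30000L)
  expect_error(build_grid(c(a = 100), 0), ">= 1")
  expect_error(build_grid(c(a = 5), 10), "shorter")
})

test_that("segment resampling takes covering segments, fills gaps from the nearest, and leaves absent chromosomes missing", {
  grid <- build_grid(toy_genome(), 30)  # spacing 0.5 Mb

  # one whole-genome segment -> every cell equals its value
  whole <- seg_profiles(data.frame(sample = "s1",
                                   chrom = c("chrA", "chrB"),
                                   start = 0, end = c(10e6, 5e6), value = 0.3))
  gcn <- segments_to_grid(whole, grid)
  expect_true(all(gcn$values == 0.3))

  # abutting segments 0.0/0.5 -> step function located by position
  step <- seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                  start = c(0, 4.6e6), end = c(4.6e6, 10e6),
                                  value = c(0, 0.5)))
  gcn2 <- segments_to_grid(step, grid)
  colsA <- which(grid$chrom == "chrA")
  expected <- ifelse(grid$pos[colsA] < 4.6e6, 0, 0.5)
  expect_equal(unname(gcn2$values[1, colsA]), expected)

  # sample lacking chrB: chrB columns missing, chrA intact
  onlyA <- seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                   start = 0, end = 10e6, value = 0.1))
  gcn3 <- segments_to_grid(onlyA, grid)
  expect_true(all(is.na(gcn3$values[1, grid$chrom == "chrB"])))
  expect_true(all(gcn3$values[1, grid$chrom == "chrA"] == 0.1))

  # gap between segments: nearest segment supplies the value
  gap <- seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                 start = c(0, 8e6), end = c(2e6, 10e6),
                                 value = c(-1, 1)))
  gcn4 <- segments_to_grid(gap, grid)
  vals <- gcn4$values[1, colsA]
  expect_equal(unname(vals[grid$pos[colsA] < 2e6]), rep(-1, 4))
  expect_equal(unname(vals[grid$pos[colsA] >= 8e6]), rep(1, 4))
  near_left <- grid$pos[colsA] >= 2e6 & grid$pos[colsA] < 5e6
  expect_true(all(vals[near_left] == -1))
  expect_true(all(vals[grid$pos[colsA] >= 5e6 & grid$pos[colsA] < 8e6] == 1))

  # conservation: every resampled value occurs in the source profile
  set.seed(10)
  rnd <- seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                 start = c(0, 3e6, 7e6),
                                 end = c(3e6, 7e6, 10e6),
                                 value = rnorm(3)))
  gcn5 <- segments_to_grid(rnd, grid)
  got <- gcn5$values[1, colsA]
  expect_true(all(got %in% rnd$value))
})

test_that("window covariate sets are centred, clipped and shared by co-located miRNAs", {
  grid <- build_grid(toy_genome(), 30)  # 0.5 Mb spacing
  whole <- seg_profiles(do.call(rbind, lapply(c("s1", "s2"), function(s)
    data.frame(sample = s, chrom = c("chrA", "chrB"), start = 0,
               end = c(10e6, 5e6), value = 0.1))))
  gcn <- segments_to_grid(whole, grid)

  # mid-chromosome 2 Mb window at 0.5 Mb spacing -> exactly 4 columns
  wc <- window_covariates(gcn, "chrA", 5e6, window_bp = 2e6)
  expect_equal(length(wc$columns), 4L)
  expect_equal(wc$window$start, 4e6)
  expect_equal(wc$window$end, 6e6)

  # miRNA at bp 0: clipped at 0, still valid
  wc0 <- window_covariates(gcn, "chrA", 0, window_bp = 2e6)
  expect_equal(wc0$window$start, 0)
  expect_gt(length(wc0$columns), 0L)

  # identical loci (clustered miRNAs) share the covariate set
  wca <- window_covariates(gcn, "chrA", 5e6, mirna_id = "mir-x")
  wcb <- window_covariates(gcn, "chrA", 5e6, mirna_id = "mir-y")
  expect_equal(wca$columns, wcb$columns)
  expect_equal(wca$values, wcb$values)

  # empty window errors with guidance
  tiny <- build_grid(toy_genome(), 3)
  gtin <- segments_to_grid(whole, tiny)
  expect_error(window_covariates(gtin, "chrB", 4.9e6, window_bp = 2e3),
               "window empty")
})

test_that("gain calling averages the region with an inclusive threshold", {
  grid <- build_grid(toy_genome(), 30)
  region <- list(chrom = "chrA", start = 0, end = 10e6)

  flat <- function(v) seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                              start = 0, end = 10e6, value = v))
  z <- segments_to_grid(flat(0), grid)
  expect_identical(unname(call_gain(z, region, 0.2)["s1"]), "no_gain")
  g <- segments_to_grid(flat(0.4), grid)
  expect_identical(unname(call_gain(g, region, 0.2)["s1"]), "gain")

  # 50/50 mosaic at 0.4/0.0 -> mean exactly 0.2 -> gain (inclusive boundary)
  mosaic <- seg_profiles(data.frame(sample = "s1", chrom = "chrA",
                                    start = c(0, 5e6), end = c(5e6, 10e6),
                                    value = c(0.4, 0)))
  gm <- segments_to_grid(mosaic, grid)
  expect_identical(unname(call_gain(gm, region, 0.2)["s1"]), "gain")
  expect_identical(unname(call_gain(mosaic, region, 0.2)["s1"]), "gain")

  # region without data -> unknown, reported
  expect_message(st <- call_gain(segments_to_grid(flat(0), grid),
                                 list(chrom = "chrB", start = 0, end = 5e6), 0.2),
                 "unknown")
  expect_identical(unname(st["s1"]), "unknown")
})
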