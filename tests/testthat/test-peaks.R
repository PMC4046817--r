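test_that("normalization averages duplicates, centres the median and preserves differences", {
  gr <- GRanges("chrT", IRanges(start = rep(c(1, 26, 51), 2), width = 10))
  gr$probe_id <- rep(c("a", "b", "c"), 2)
  gr$duplicate_index <- rep(1:2, each = 3)
  gr$log2_ratio <- c(1.0, 0.7, 2.7, 3.0, 0.7, 2.7)
  scan <- ChIPtiling:::newProbeScan("s", "chip-replicate", gr)
  norm <- normalizeScan(scan)
  v <- scanProbes(norm)$log2_ratio
  expect_equal(median(v), 0)
  # duplicates (1.0, 3.0) average to 2.0 before centring
  expect_equal(v[1] - v[2], 2.0 - 0.7)
  expect_equal(diff(sort(v)), diff(sort(c(2.0, 0.7, 2.7))))
})

test_that("an all-identical scan is centred to zeros with a warning", {
  scan <- mkScan(c(1, 26, 51, 76), rep(0.4, 4))
  expect_warning(norm <- normalizeScan(scan), "identical")
  expect_equal(scanProbes(norm)$log2_ratio, rep(0, 4))
})

test_that("running-median smoothing is exact against naive recomputation", {
  set.seed(31)
  for (circular in c(TRUE, FALSE)) {
    n <- 120
    pos <- sort(sample.int(3000, n))
    v <- rnorm(n)
    scan <- mkScan(pos, v)
    sm <- smoothScan(scan, halfWidthBp = 150, circular = circular,
                     genomeLength = 3000)
    expect_equal(scanProbes(sm)$log2_ratio,
                 bruteSmooth(pos, v, 150, 3000, circular))
  }
})

test_that("smoothing removes isolated spikes and fixes plateau interiors", {
  pos <- seq(1, 1000, by = 25)
  v <- rep(0, length(pos))
  v[20] <- 5
  sm <- smoothScan(mkScan(pos, v), halfWidthBp = 100, circular = FALSE)
  expect_equal(scanProbes(sm)$log2_ratio[20], 0)

  step <- c(rep(0, 15), rep(2, 15), rep(0, 10))
  sm1 <- smoothScan(mkScan(pos, step), halfWidthBp = 100,
                    circular = FALSE)
  sm2 <- smoothScan(sm1, halfWidthBp = 100, circular = FALSE)
  interior <- 20:26  # plateau interior, > window away from the edges
  expect_equal(scanProbes(sm1)$log2_ratio[interior],
               scanProbes(sm2)$log2_ratio[interior])
  expect_equal(scanProbes(sm1)$log2_ratio[interior], rep(2, 7))

  konst <- smoothScan(mkScan(pos, rep(1.3, length(pos))), 100,
                      circular = FALSE)
  expect_equal(scanProbes(konst)$log2_ratio, rep(1.3, length(pos)))
})

test_that("region calling matches exhaustive run enumeration exactly", {
  set.seed(77)
  for (rep_i in 1:8) {
    n <- 400
    pos <- cumsum(sample(10:40, n, replace = TRUE))
    ends <- pos + 9
    v <- rnorm(n, 0.6, 0.6)
    scan <- mkScan(pos, v)
    got <- callRegions(scan, y0 = 1, minProbes = 3, maxGapBp = 60,
                       circular = FALSE)
    want <- bruteCallRegions(pos, ends, v, 1, 3, 60)
    expect_equal(length(got), nrow(want))
    if (length(got)) {
      expect_equal(start(got), unname(want[, 1]))
      expect_equal(end(got), unname(want[, 2]))
    }
  }
})

test_that("region calling respects thresholds, minimum probes and the null case", {
  pos <- seq(1, 2000, by = 25)
  zeros <- callRegions(mkScan(pos, rep(0, length(pos))), y0 = 1,
                       circular = FALSE)
  expect_length(zeros, 0)

  v <- rep(0, length(pos)); v[30:39] <- 1.5
  one <- callRegions(mkScan(pos, v), y0 = 1, circular = FALSE)
  expect_length(one, 1)
  expect_equal(start(one), pos[30])
  expect_equal(end(one), pos[39] + 9)
  expect_equal(one$n_probes, 10L)

  v2 <- rep(0, length(pos)); v2[10:11] <- 2
  expect_length(callRegions(mkScan(pos, v2), y0 = 1, minProbes = 3,
                            circular = FALSE), 0)
})

test_that("raising the call threshold never enlarges regions nor adds regions", {
  set.seed(5)
  pos <- seq(1, 5000, by = 25)
  v <- rnorm(length(pos), 0.8, 0.5)
  prev_n <- Inf; prev_cov <- Inf
  for (y0 in c(0.8, 1.0, 1.2, 1.5)) {
    regs <- callRegions(mkScan(pos, v), y0 = y0, circular = FALSE)
    cov <- sum(width(regs))
    expect_lte(length(regs), prev_n)
    expect_lte(cov, prev_cov)
    prev_n <- length(regs); prev_cov <- cov
  }
})

test_that("a run crossing the origin of a circular genome is called once", {
  pos <- seq(1, 2000, by = 25)
  v <- rep(0, length(pos))
  v[c(1:4, 77:80)] <- 2  # qualifying probes hug both ends
  regs <- callRegions(mkScan(pos, v), y0 = 1, circular = TRUE,
                      genomeLength = 2009)
  expect_length(regs, 1)
  expect_equal(start(regs), pos[77])
  expect_equal(end(regs), pos[4] + 9 + 2009)
})

test_that("replicate combination enforces the all-replicate and mock rules", {
  pos <- seq(1, 3000, by = 25)
  peak <- function(idx, height) {
    v <- rep(0, length(pos)); v[idx] <- height
    mkScan(pos, v)
  }
  idx <- 40:50
  r1 <- peak(idx, 1.6); r2 <- peak(idx, 1.4)
  r3_hit <- peak(idx, 1.5); r3_miss <- peak(90:100, 1.5)
  mock_quiet <- peak(idx, 0.2)
  mock_loud <- peak(idx, 1.5)
  call <- function(s) callRegions(s, y0 = 1, circular = FALSE)

  got <- combineReplicates(lapply(list(r1, r2, r3_hit), call),
                           list(r1, r2, r3_hit), mock_quiet)
  expect_length(got, 1)
  expect_equal(got$fold_enrichment, 2^mean(c(1.6, 1.4, 1.5)))

  # called in only 2 of 3 replicates -> excluded
  got2 <- combineReplicates(lapply(list(r1, r2, r3_miss), call),
                            list(r1, r2, r3_miss), mock_quiet)
  expect_length(got2[start(got2) < 2000], 0)

  # also enriched in the mock -> excluded
  got3 <- combineReplicates(lapply(list(r1, r2, r3_hit), call),
                            list(r1, r2, r3_hit), mock_loud)
  expect_length(got3, 0)
  flagged <- combineReplicates(lapply(list(r1, r2, r3_hit), call),
                               list(r1, r2, r3_hit), mock_loud,
                               keepAll = TRUE)
  expect_false(any(flagged$passed_mock_filter))

  expect_error(combineReplicates(list(), list(), mock_quiet),
               "at least one")
})

test_that("a replicate below the fold threshold vetoes the region", {
  pos <- seq(1, 3000, by = 25)
  mk <- function(h) {
    v <- rep(0, length(pos)); v[40:50] <- h
    mkScan(pos, v)
  }
  scans <- list(mk(1.6), mk(1.4), mk(1.05))
  regs <- lapply(scans, callRegions, y0 = 1, circular = FALSE)
  mock <- mk(0)
  # all replicates called a region, but one maximum is ~2.07-fold: passes 2
  got2 <- combineReplicates(regs, scans, mock, foldThreshold = 2)
  expect_length(got2, 1)
  # at threshold 2.2 the weakest replicate (2^1.05 = 2.07) fails
  got22 <- combineReplicates(regs, scans, mock, foldThreshold = 2.2)
  expect_length(got22, 0)
})

test_that("qPCR enrichment is the reference-corrected ddCq power of two", {
  cq <- data.frame(
    target = rep(c("t1", "t2", "spike"), each = 2),
    fraction = rep(c("IP", "input"), 3),
    cq = c(20, 24, 21, 24, 25, 25))
  # t1: dCq 4 vs reference dCq 0 -> 16-fold; t2: 8-fold
  folds <- qpcrEnrichment(cq, refTarget = "spike")
  expect_equal(unname(folds["t1"]), 16)
  expect_equal(unname(folds["t2"]), 8)

  same <- data.frame(target = rep(c("t", "spike"), each = 2),
                     fraction = rep(c("IP", "input"), 2),
                     cq = c(22, 25, 19, 22))
  expect_equal(unname(qpcrEnrichment(same, "spike")["t"]), 1)

  expect_error(qpcrEnrichment(cq[-1, ], "spike"), "missing Cq cell")
})

test_that("a planted qPCR enrichment is recovered", {
  set.seed(12)
  true_fold <- 5
  cq <- data.frame(
    target = rep(c("t", "spike"), each = 6),
    fraction = rep(rep(c("IP", "input"), each = 3), 2),
    cq = c(20 - log2(true_fold) + rnorm(3, 0, 0.05), 20 + rnorm(3, 0, 0.05),
           24 + rnorm(3, 0, 0.05), 24 + rnorm(3, 0, 0.05)))
  expect_equal(unname(qpcrEnrichment(cq, "spike")["t"]), 5,
               tolerance = 0.1)
})

test_that("rank correlation validation behaves at its extremes and in simulation", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(validateCorrelation(x, x)$rho, 1)
  expect_equal(validateCorrelation(x, rev(x))$rho, -1)
  set.seed(8)
  chip <- runif(30, 2, 11)
  qpcr <- chip * exp(rnorm(30, 0, 0.3))
  v <- validateCorrelation(chip, qpcr)
  expect_gt(v$rho, 0)
  expect_lt(v$p, 0.05)
  expect_error(validateCorrelation(1:3, 3:1), "at least 5")
})
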