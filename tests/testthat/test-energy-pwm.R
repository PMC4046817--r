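test_that("word energies are additive and match per-position lookup", {
  pwm <- examplePWM()
  expect_equal(scoreWord(pwm, consensusWord(pwm)), 0)

  # one substitution adds exactly that cell's penalty
  E <- pwmEnergies(pwm)
  word <- strsplit(consensusWord(pwm), "")[[1]]
  word[3] <- "A"  # consensus base at 3 is G
  expect_equal(scoreWord(pwm, paste(word, collapse = "")),
               unname(E[3, "A"]))

  set.seed(19)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    idx <- sample(1:4, pwmWidth(pwm), replace = TRUE)
    w <- paste(bases[idx], collapse = "")
    manual <- sum(vapply(seq_along(idx),
                         function(p) E[p, bases[idx[p]]], numeric(1)))
    expect_equal(scoreWord(pwm, w), manual)
  }
  expect_error(scoreWord(pwm, paste(rep("N", 15), collapse = "")),
               "ambiguous")
  expect_error(scoreWord(pwm, "ACGT"), "length")
})

test_that("theoretical K_D follows the Boltzmann factor and is bounded below", {
  pwm <- examplePWM()
  expect_equal(kdOfWord(pwm, consensusWord(pwm)), kdConsensus(pwm))

  # a word with energy exactly 2 kT: K_D = 63 nM * e^2
  word <- strsplit(consensusWord(pwm), "")[[1]]
  word[3] <- "T"  # penalty 2.0 in the bundled matrix
  kd2 <- kdOfWord(pwm, paste(word, collapse = ""))
  expect_equal(kd2, 6.3e-8 * exp(2), tolerance = 1e-12)
  expect_equal(kd2, 4.655e-7, tolerance = 1e-3)

  set.seed(20)
  for (i in 1:50) {
    w <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
               collapse = "")
    expect_gte(kdOfWord(pwm, w), kdConsensus(pwm))
  }
})

test_that("hamming distance counts mismatching positions", {
  expect_equal(wordDistance("ACGT", "ACGT"), 0)
  expect_equal(wordDistance("ACGT", "ACTT"), 1)
  expect_equal(wordDistance("AAAA", "TTTT"), 4)
  expect_error(wordDistance("ACG", "ACGT"), "equal length")
})

test_that("a planted consensus in hostile sequence yields exactly one hit", {
  pwm <- tinyPWM(width = 5)
  # hostile background: the per-position maximal-penalty bases
  E <- pwmEnergies(pwm)
  hostile <- paste(rep(colnames(E)[apply(E, 1, which.max)], 30),
                   collapse = "")
  seqchar <- paste0(substr(hostile, 1, 9), consensusWord(pwm),
                    substr(hostile, 15, 100))
  hits <- scanSequence(pwm, seqchar, kdThreshold = kdConsensus(pwm) * 1.01)
  plus <- hits[as.character(strand(hits)) == "+"]
  expect_length(plus, 1)
  expect_equal(start(plus), 10)
  expect_identical(plus$word, consensusWord(pwm))
})

test_that("scanning equals the exhaustive per-window oracle", {
  pwm <- tinyPWM(width = 5)
  set.seed(23)
  seqchar <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                   collapse = "")
  thr <- kdConsensus(pwm) * exp(2.5)
  got <- scanSequence(pwm, seqchar, kdThreshold = thr)
  want <- bruteScanSequence(pwm, seqchar, thr)
  key <- function(s, st, w) paste(s, st, w)
  expect_setequal(key(start(got), as.character(strand(got)), got$word),
                  key(want$start, want$strand, want$word))
  expect_equal(sort(got$kd_theoretical), sort(want$kd))
})

test_that("reverse-complementing the sequence mirrors hits and keeps counts", {
  pwm <- tinyPWM(width = 5)
  set.seed(29)
  n <- 300
  seqchar <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
  rc <- as.character(reverseComplement(DNAString(seqchar)))
  thr <- kdConsensus(pwm) * exp(2)
  h1 <- scanSequence(pwm, seqchar, thr)
  h2 <- scanSequence(pwm, rc, thr)
  expect_equal(length(h1), length(h2))
  # a + hit at s maps to a - hit starting at n - (s + w - 1) + 1
  w <- pwmWidth(pwm)
  mirrored <- sort(n - (start(h1) + w - 1) + 1)
  expect_equal(sort(start(h2)), mirrored)
  expect_setequal(h1$word, h2$word)
})

test_that("circular scanning reports origin-spanning hits", {
  pwm <- tinyPWM(width = 5)
  E <- pwmEnergies(pwm)
  hostile <- paste(rep(colnames(E)[apply(E, 1, which.max)], 20),
                   collapse = "")
  cons <- consensusWord(pwm)
  # place the consensus across the origin: last 2 bases then first 3
  seqchar <- paste0(substr(cons, 3, 5), substr(hostile, 1, 92),
                    substr(cons, 1, 2))
  hits <- scanSequence(pwm, seqchar, kdThreshold = kdConsensus(pwm) * 1.01,
                       circular = TRUE)
  plus <- hits[as.character(strand(hits)) == "+"]
  expect_length(plus, 1)
  expect_equal(start(plus), 96)
  lin <- scanSequence(pwm, seqchar, kdThreshold = kdConsensus(pwm) * 1.01,
                      circular = FALSE)
  expect_length(lin[as.character(strand(lin)) == "+"], 0)
})

test_that("hit count is non-increasing in the K_D threshold", {
  pwm <- tinyPWM(width = 5)
  set.seed(37)
  seqchar <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  counts <- vapply(kdConsensus(pwm) * exp(c(4, 3, 2, 1, 0.5)),
                   function(t) length(scanSequence(pwm, seqchar, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("upstream windows respect gene strand and find planted sites", {
  pwm <- examplePWM()
  cfg <- simConfig(genomeLength = 30000, nGenes = 4, seed = 13)
  g <- generateGenome(cfg)
  genes <- geneRanges(g)
  plus_i <- which(as.character(strand(genes)) == "+")[1]
  minus_i <- which(as.character(strand(genes)) == "-")[1]
  w <- pwmWidth(pwm)
  # plant the consensus 50 bp upstream of a + gene (centre at start - 50)
  pos_plus <- start(genes)[plus_i] - 50
  pos_minus <- end(genes)[minus_i] + 50
  pl <- plantMotifs(g, pwm, data.frame(
    position = c(pos_plus, pos_minus), target_kd = kdConsensus(pwm),
    permissive = TRUE))
  res <- scanUpstream(pwm, pl$genome, windowBp = 200,
                      kdThreshold = kdConsensus(pwm) * 10)
  pg <- res$perGene
  expect_true(genes$gene_id[plus_i] %in% pg$gene_id)
  expect_true(genes$gene_id[minus_i] %in% pg$gene_id)
  expect_equal(pg$best_start[pg$gene_id == genes$gene_id[plus_i]],
               pos_plus - (w - 1) %/% 2)
  expect_equal(pg$best_start[pg$gene_id == genes$gene_id[minus_i]],
               pos_minus - (w - 1) %/% 2)
  # hand-computed window bounds for the - strand gene
  hit_start <- pg$best_start[pg$gene_id == genes$gene_id[minus_i]]
  expect_gte(hit_start, end(genes)[minus_i] + 1)
  expect_lte(hit_start + w - 1, end(genes)[minus_i] + 200)
})

test_that("a motif-free genome yields an empty upstream report", {
  pwm <- examplePWM()
  cfg <- simConfig(genomeLength = 15000, nGenes = 3, seed = 17)
  g <- generateGenome(cfg)
  res <- scanUpstream(pwm, g, windowBp = 200,
                      kdThreshold = kdConsensus(pwm) * 1.001)
  expect_equal(res$nHits, 0)
  expect_equal(nrow(res$perGene), 0)
})

test_that("best hit in a region equals exhaustive enumeration and breaks ties fairly", {
  pwm <- tinyPWM(width = 5)
  cfg <- simConfig(genomeLength = 12000, nGenes = 2, seed = 21)
  g <- generateGenome(cfg)
  set.seed(55)
  for (i in 1:25) {
    s <- sample.int(11000, 1)
    wdt <- sample(20:150, 1)
    region <- GRanges("synthChr", IRanges(s, width = wdt))
    got <- bestHitInRegion(pwm, g, region)
    sub <- substr(as.character(genomeSeq(g)), s, s + wdt - 1)
    want <- bruteScanSequence(pwm, sub, Inf)
    want <- want[order(want$kd, want$start, want$strand != "+"), ][1, ]
    expect_equal(start(got), s + want$start - 1)
    expect_identical(got$word, want$word)
    expect_equal(got$kd_theoretical, want$kd)
  }
  narrow <- GRanges("synthChr", IRanges(100, width = 3))
  expect_null(bestHitInRegion(pwm, g, narrow))
})

test_that("motif presence uses an inclusive threshold", {
  pwm <- examplePWM()
  cfg <- simConfig(genomeLength = 12000, nGenes = 2, seed = 25)
  g <- generateGenome(cfg)
  pl <- plantMotifs(g, pwm, data.frame(position = 6000,
                                       target_kd = kdConsensus(pwm),
                                       permissive = TRUE))
  region <- GRanges("synthChr", IRanges(5900, 6100))
  best <- bestHitInRegion(pwm, pl$genome, region)
  expect_true(motifPresenceFlag(pwm, pl$genome, region,
                                kdThreshold = best$kd_theoretical))
  expect_false(motifPresenceFlag(pwm, pl$genome, region,
                                 kdThreshold = best$kd_theoretical * 0.99))
})
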