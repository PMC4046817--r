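# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-window loops, O(n^2) enumeration) so they check
# the vectorized implementations from outside their code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# small energy matrix with distinctive, irregular penalties
tinyPWM <- function(width = 5, kd = 1e-7) {
  set.seed(42)
  E <- matrix(round(runif(width * 4, 0.2, 2.5), 2), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  E[cbind(seq_len(width), sample(1:4, width, replace = TRUE))] <- 0
  energyPWM(E, kdConsensus = kd)
}

examplePWM <- function() {
  readEnergyMatrix(system.file("extdata",
                               "lrpB_energy_matrix_synthetic.tsv",
                               package = "ChIPtiling"))
}

# ProbeScan from explicit positions/values (one duplicate)
mkScan <- function(positions, values, probeLen = 10L,
                   sampleId = "s", role = "chip-replicate",
                   chrom = "chrT") {
  gr <- GRanges(chrom, IRanges(start = positions, width = probeLen))
  gr$probe_id <- sprintf("p%05d", seq_along(positions))
  gr$duplicate_index <- 1L
  gr$log2_ratio <- values
  ChIPtiling:::newProbeScan(sampleId, role, gr)
}

# exhaustive run enumeration: every maximal run of qualifying probes
bruteCallRegions <- function(positions, ends, values, y0, minProbes,
                             maxGapBp) {
  q <- which(values >= y0)
  n <- length(q)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j == 0) next
      idx <- q[i:j]
      gaps_ok <- j == i || all(diff(positions[idx]) <= maxGapBp)
      left_max <- i == 1 ||
        positions[q[i]] - positions[q[i - 1]] > maxGapBp
      right_max <- j == n ||
        positions[q[j + 1]] - positions[q[j]] > maxGapBp
      if (gaps_ok && left_max && right_max && length(idx) >= minProbes)
        out[[length(out) + 1L]] <- c(positions[idx[1]],
                                     ends[idx[length(idx)]])
    }
  }
  if (!length(out)) return(matrix(numeric(), ncol = 2))
  do.call(rbind, out)
}

# per-window scoring loop over both strands
bruteScanSequence <- function(pwm, seqchar, kdThreshold) {
  w <- pwmWidth(pwm)
  n <- nchar(seqchar) - w + 1L
  hits <- list()
  for (i in seq_len(n)) {
    word <- substr(seqchar, i, i + w - 1L)
    rc <- as.character(reverseComplement(DNAString(word)))
    for (s in c("+", "-")) {
      ww <- if (s == "+") word else rc
      kd <- kdConsensus(pwm) * exp(scoreWord(pwm, ww))
      if (kd <= kdThreshold)
        hits[[length(hits) + 1L]] <- data.frame(
          start = i, strand = s, word = ww, kd = kd)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), strand = character(),
                      word = character(), kd = numeric()))
  do.call(rbind, hits)
}

# per-probe window median recomputed naively
bruteSmooth <- function(positions, values, halfWidth, L,
                        circular = TRUE) {
  vapply(seq_along(positions), function(i) {
    d <- abs(positions - positions[i])
    if (circular) d <- pmin(d, L - d)
    median(values[d <= halfWidth])
  }, numeric(1))
}

sharedRegionsPath <- function() {
  system.file("extdata", "lrpB_lysM_shared_regions.tsv",
              package = "ChIPtiling")
}
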