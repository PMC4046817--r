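#' Generate a synthetic annotated genome
#'
#' Draws a circular genome of i.i.d. bases at the requested GC content and
#' places non-overlapping ORFs, each with a transcription start site a short
#' distance upstream of its start (respecting strand). Deterministic under
#' the configuration seed.
#'
#' ORFs are placed one per equal-sized genome bin at a random in-bin offset,
#' which guarantees non-overlap without rejection sampling. Generation is
#' refused when the ORFs cannot fit (total ORF length above 80% of the
#' genome, or a bin too small for its ORF).
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @param genomeName chromosome name used in all emitted files.
#' @return A [TiledGenome-class].
#' @examples
#' g <- generateGenome(simConfig(genomeLength = 20000, nGenes = 5, seed = 1))
#' genomeLength(g)
#' @export
generateGenome <- function(config, genomeName = "synthChr") {
  stopifnot(is(config, "SimConfig"))
  L <- config@genomeLength
  if (L < 10000L) stop("genomeLength must be at least 10 kb")
  if (config@nGenes < 1L) stop("at least one gene is required")
  set.seed(config@seed)

  gc <- config@gcContent
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  n <- config@nGenes
  orf_len <- 3L * sample(100:500, n, replace = TRUE)  # 300-1500 bp ORFs
  if (sum(orf_len) > 0.8 * L)
    stop("infeasible gene packing: total ORF length ", sum(orf_len),
         " bp exceeds 80% of the genome (", L, " bp)")
  bin <- L %/% n
  margin <- 120L  # room for an upstream TSS inside the bin
  if (any(orf_len + 2L * margin > bin))
    stop("infeasible gene packing: an ORF does not fit in its ", bin,
         " bp placement bin")
  offset <- vapply(seq_len(n), function(i)
    sample.int(bin - orf_len[i] - 2L * margin, 1L) + margin, integer(1))
  start <- (seq_len(n) - 1L) * bin + offset
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%03d", seq_len(n))

  genes <- GenomicRanges::GRanges(
    seqnames = genomeName,
    ranges = IRanges::IRanges(start = start, width = orf_len),
    strand = strand, gene_id = gene_id)

  tss_off <- sample(20:80, n, replace = TRUE)
  tss_pos <- ifelse(strand == "+", start - tss_off,
                    start + orf_len - 1L + tss_off)
  tss_pos <- wrapPos(tss_pos, L)
  tss <- GenomicRanges::GRanges(
    seqnames = genomeName,
    ranges = IRanges::IRanges(start = tss_pos, width = 1L),
    strand = strand, gene_id = gene_id)

  new("TiledGenome", genomeName = genomeName,
      sequence = Biostrings::DNAString(paste(bases, collapse = "")),
      circular = TRUE, genes = genes, tss = tss)
}

#' Design a word of prescribed theoretical affinity
#'
#' Greedy local search over single-base substitutions of the consensus,
#' minimizing the gap between the word's predicted dissociation constant and
#' `targetKd`. Used by [plantMotifs()] to embed sites of graded affinity.
#'
#' @param pwm an [EnergyPWM-class].
#' @param targetKd requested dissociation constant (molar); must be at least
#'   the consensus K_D.
#' @param tolFactor acceptance factor: the realized K_D must be within this
#'   multiplicative factor of `targetKd` (default 1.5).
#' @return A list with `word`, `energy` (kT) and `kd` (molar).
#' @export
designSiteWord <- function(pwm, targetKd, tolFactor = 1.5) {
  E <- pwm@energies
  w <- nrow(E)
  kdc <- pwm@kdConsensus
  if (targetKd < kdc * (1 - 1e-9))
    stop("targetKd is below the consensus K_D (", format(kdc), " M)")
  epsTarget <- log(targetKd / kdc)
  epsMax <- sum(apply(E, 1L, max))
  if (epsTarget > epsMax + log(tolFactor))
    stop("targetKd unreachable under this matrix; maximal attainable K_D is ",
         format(kdc * exp(epsMax), digits = 4), " M")
  # hill-climb: state = base index per position, move = set one position to
  # any base; deterministic tie-break by (position, base)
  idx <- apply(E, 1L, which.min)
  eps <- 0
  repeat {
    best_gain <- 0; best_move <- NULL
    for (i in seq_len(w)) {
      cur <- E[i, idx[i]]
      for (b in 1:4) {
        if (b == idx[i]) next
        cand <- eps - cur + E[i, b]
        gain <- abs(eps - epsTarget) - abs(cand - epsTarget)
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_move <- c(i, b, cand)
        }
      }
    }
    if (is.null(best_move)) break
    idx[best_move[1L]] <- best_move[2L]
    eps <- best_move[3L]
  }
  eps <- unname(eps)
  if (abs(eps - epsTarget) > log(tolFactor))
    stop("could not realize targetKd within a factor ", tolFactor,
         " (closest attainable: ", format(kdc * exp(eps), digits = 4), " M)")
  list(word = paste(colnames(E)[idx], collapse = ""), energy = eps,
       kd = kdc * exp(eps))
}

#' Plant binding motifs of graded affinity into a genome
#'
#' For each requested site, designs a word whose predicted K_D is within a
#' factor 1.5 of the target (see [designSiteWord()]) and writes it into the
#' sequence centred at the given position. Occupancy is computed from the
#' configured free protein concentration P as P / (K_D + P). Non-permissive
#' sites model loci where chromatin blocks in vivo binding: they remain
#' present in the sequence (and therefore in motif scans) but contribute no
#' ChIP signal in [simulateChip()].
#'
#' @param genome a [TiledGenome-class].
#' @param pwm an [EnergyPWM-class].
#' @param sites data.frame with columns `position` (1-based site centre),
#'   `target_kd` (molar) and `permissive` (logical); optional `strand`
#'   (default "+").
#' @param proteinConc free protein concentration (molar) used for occupancy.
#' @return A list with `genome` (sequence modified in place) and `sites`, a
#'   data.frame of planted-truth records (position, strand, word, energy,
#'   realized kd, permissive flag, occupancy).
#' @export
plantMotifs <- function(genome, pwm, sites, proteinConc = 1e-6) {
  stopifnot(is(genome, "TiledGenome"), is(pwm, "EnergyPWM"))
  sites <- as.data.frame(sites)
  if (is.null(sites$strand)) sites$strand <- "+"
  L <- genomeLength(genome)
  if (any(sites$position < 1L | sites$position > L))
    stop("planted positions must lie in [1, genome length]")
  w <- pwmWidth(pwm)
  seqchar <- as.character(genomeSeq(genome))

  out <- lapply(seq_len(nrow(sites)), function(i) {
    d <- designSiteWord(pwm, sites$target_kd[i])
    word_fwd <- if (sites$strand[i] == "+") d$word else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(d$word)))
    start <- sites$position[i] - (w - 1L) %/% 2L
    seqchar <<- replaceCircular(seqchar, start, word_fwd, L,
                                isCircularGenome(genome))
    data.frame(position = as.integer(sites$position[i]),
               strand = sites$strand[i], word = d$word,
               energy = d$energy, kd = d$kd,
               target_kd = sites$target_kd[i],
               permissive = as.logical(sites$permissive[i]),
               occupancy = proteinConc / (d$kd + proteinConc))
  })
  truth <- do.call(rbind, out)
  genome@sequence <- Biostrings::DNAString(seqchar)
  validObject(genome)
  list(genome = genome, sites = truth)
}

# noise-free per-probe enrichment signal (log2 units)
probeTrueSignal <- function(probeCenters, sites, config, L,
                            circular = TRUE) {
  sig <- numeric(length(probeCenters))
  if (is.null(sites) || nrow(sites) == 0L) return(sig)
  fl <- config@fragmentLength
  for (i in seq_len(nrow(sites))) {
    if (!sites$permissive[i]) next
    d <- circDist(probeCenters, sites$position[i], L, circular)
    sig <- sig + sites$occupancy[i] * pmax(0, 1 - d / fl)
  }
  config@amplitude * sig
}

#' Simulate replicate ChIP scans and a mock scan
#'
#' Probes tile the genome at `probeStep`. The noise-free signal at a probe is
#' the sum over permissive planted sites of occupancy times a triangular
#' kernel of half-width `fragmentLength` centred at the site (wrapping on
#' circular genomes), scaled so a fully occupied site peaks at `amplitude`
#' log2 units. Each replicate adds independent N(0, noiseSd) noise per probe
#' measurement; every probe is measured twice (technical duplicates with
#' independent noise). The mock scan is noise only.
#'
#' @param genome a [TiledGenome-class].
#' @param sites planted-truth data.frame from [plantMotifs()] (or NULL for a
#'   site-free null experiment).
#' @param config a [SimConfig-class]; its seed governs all noise draws.
#' @return A list of [ProbeScan-class] objects: `nReplicates` scans with role
#'   "chip-replicate" followed by one "mock".
#' @export
simulateChip <- function(genome, sites, config) {
  stopifnot(is(genome, "TiledGenome"), is(config, "SimConfig"))
  L <- genomeLength(genome)
  starts <- seq.int(1L, L, by = config@probeStep)
  centers <- starts + config@probeLength %/% 2L
  n <- length(starts)
  true_sig <- probeTrueSignal(centers, sites, config, L,
                              isCircularGenome(genome))
  probe_id <- sprintf("P%06d", seq_len(n))
  gr0 <- GenomicRanges::GRanges(
    seqnames = genome@genomeName,
    ranges = IRanges::IRanges(start = starts, width = config@probeLength))

  set.seed(config@seed)
  mk_scan <- function(sampleId, role, signal) {
    probes <- rep(gr0, 2L)
    probes$probe_id <- rep(probe_id, 2L)
    probes$duplicate_index <- rep(1:2, each = n)
    probes$log2_ratio <- rep(signal, 2L) +
      rnorm(2L * n, sd = config@noiseSd)
    newProbeScan(sampleId, role, probes)
  }
  scans <- lapply(seq_len(config@nReplicates), function(r)
    mk_scan(sprintf("chip_rep%d", r), "chip-replicate", true_sig))
  c(scans, list(mk_scan("mock", "mock", numeric(n))))
}

#' Simulate an equilibrium binding titration
#'
#' Fraction bound follows the single-site isotherm f = P / (K_D + P) with
#' additive Gaussian noise, clipped to [0, 1] — the structure of EMSA
#' densitometry data.
#'
#' @param kd true dissociation constant (molar).
#' @param concentrations protein concentrations (molar), strictly positive,
#'   sorted increasing.
#' @param noiseSd standard deviation of the additive noise on fraction
#'   bound (default 0.03).
#' @param seed integer seed.
#' @return A [BindingIsotherm-class].
#' @examples
#' iso <- simulateIsotherm(63e-9, c(1, 2, 4, 8, 16, 32, 64) * 1e-8)
#' @export
simulateIsotherm <- function(kd, concentrations, noiseSd = 0.03, seed = 1L) {
  stopifnot(kd > 0, all(concentrations > 0),
            !is.unsorted(concentrations))
  set.seed(seed)
  f <- concentrations / (kd + concentrations) +
    rnorm(length(concentrations), sd = noiseSd)
  bindingIsotherm(concentrations, pmin(1, pmax(0, f)))
}

#' Simulate a qRT-PCR quantification-cycle table
#'
#' Draws Cq values for wild-type and mutant strains across biological
#' replicates. A planted fold change F for a target gene shifts its mutant
#' Cq by -log2(F) relative to wild type after reference alignment; the
#' reference gene's fold change is fixed at 1. Each biological replicate
#' receives a shared Cq offset (input-amount variation) that the ddCt
#' normalization must cancel.
#'
#' @param genes character vector of target gene ids (reference excluded).
#' @param foldChanges numeric vector, mutant/WT expression ratio per gene.
#' @param refGene reference gene id (default "tbp").
#' @param nBioreps biological replicates per strain (default 4).
#' @param noiseSd per-measurement Cq noise in cycles (default 0.15).
#' @param seed integer seed.
#' @return A data.frame with columns gene_id, strain ("WT"/"mutant"),
#'   biorep, cq.
#' @export
simulateCqTable <- function(genes, foldChanges, refGene = "tbp",
                            nBioreps = 4L, noiseSd = 0.15, seed = 1L) {
  stopifnot(length(genes) == length(foldChanges), nBioreps >= 2L,
            !refGene %in% genes)
  set.seed(seed)
  all_genes <- c(refGene, genes)
  fold <- c(1, foldChanges)
  base_cq <- runif(length(all_genes), 18, 26)
  rows <- list()
  for (strain in c("WT", "mutant")) {
    for (b in seq_len(nBioreps)) {
      rep_offset <- rnorm(1L, sd = 0.3)
      cq <- base_cq + rep_offset + rnorm(length(all_genes), sd = noiseSd)
      if (strain == "mutant") cq <- cq - log2(fold)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = all_genes, strain = strain, biorep = b, cq = cq)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default planted-site scenario
#'
#' The study conditions used throughout the package's own validation: six
#' permissive sites with dissociation constants between 63 and 200 nM
#' (high-occupancy at 1 uM protein) and two non-permissive high-affinity
#' sites that motif scans must find but the region caller must not.
#'
#' @param config a [SimConfig-class]; positions are spread evenly over the
#'   genome.
#' @return data.frame with columns position, target_kd, permissive.
#' @export
studySites <- function(config) {
  L <- config@genomeLength
  pos <- as.integer(round(L * (1:8) / 9))
  data.frame(
    position = pos,
    target_kd = c(63e-9, 100e-9, 150e-9, 200e-9, 63e-9, 100e-9,
                  63e-9, 100e-9),
    permissive = c(rep(TRUE, 6L), FALSE, FALSE))
}
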