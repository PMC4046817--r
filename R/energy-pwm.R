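#' Score a word under a binding-energy matrix
#'
#' The energy penalty of a word is the sum over positions of the matrix
#' entries for its bases, in kT units relative to the consensus (which
#' scores exactly 0 under min-zero rows).
#'
#' @param pwm an [EnergyPWM-class].
#' @param word character word of length `pwmWidth(pwm)` over {A,C,G,T};
#'   IUPAC ambiguity codes are rejected.
#' @return Energy in kT (>= 0).
#' @examples
#' # a single substitution adds exactly that cell's penalty
#' @export
scoreWord <- function(pwm, word) {
  stopifnot(is(pwm, "EnergyPWM"))
  word <- toupper(word)
  w <- pwmWidth(pwm)
  if (nchar(word) != w)
    stop("word length ", nchar(word), " differs from matrix width ", w)
  idx <- match(strsplit(word, "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(idx))
    stop("word contains a base outside {A,C,G,T}; ambiguous bases are not scored")
  sum(pwm@energies[cbind(seq_len(w), idx)])
}

#' Theoretical dissociation constant of a word
#'
#' Boltzmann model on additive energies: K_D(w) = kdConsensus * exp(energy),
#' strictly increasing in the energy penalty. Any constant shift of the
#' matrix (removed by min-zero normalization) rescales all K_Ds by a common
#' factor and leaves their ratios unchanged.
#'
#' @inheritParams scoreWord
#' @return K_D in molar (>= kdConsensus).
#' @export
kdOfWord <- function(pwm, word) {
  pwm@kdConsensus * exp(scoreWord(pwm, word))
}

#' Hamming distance between two equal-length words
#'
#' @param a,b character words of equal length.
#' @return Integer count of mismatching positions.
#' @export
wordDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("words must have equal length")
  sum(strsplit(toupper(a), "")[[1L]] != strsplit(toupper(b), "")[[1L]])
}

# reverse-complemented matrix: scoring a window with it equals scoring the
# window's reverse complement with the original matrix
rcMatrix <- function(E) {
  w <- nrow(E)
  Erc <- E[w:1, c("T", "G", "C", "A"), drop = FALSE]
  colnames(Erc) <- c("A", "C", "G", "T")
  Erc
}

# vectorized window energies of a coded sequence under matrix E
windowEnergies <- function(code, E, nWindows) {
  w <- nrow(E)
  e <- numeric(nWindows)
  for (i in seq_len(w)) {
    row <- E[i, ]
    e <- e + row[code[seq_len(nWindows) + i - 1L]]
  }
  unname(e)
}

#' Scan a sequence for binding motifs below a K_D threshold
#'
#' Scores every window on both strands and reports those with theoretical
#' K_D at or below `kdThreshold` (inclusive). On circular genomes,
#' origin-spanning windows are included; their reported end exceeds the
#' genome length (coordinates modulo the length). When both orientations of
#' one locus pass, each is reported separately.
#'
#' @param pwm an [EnergyPWM-class].
#' @param genome a [TiledGenome-class], `DNAString` or character sequence.
#' @param kdThreshold K_D cutoff in molar (default 14e-6); use `Inf` to
#'   score all windows.
#' @param circular whether the sequence wraps; taken from the genome when a
#'   [TiledGenome-class] is given.
#' @return A `GRanges` of motif hits with strand and mcols `word` (the bound
#'   word, reverse-complemented for minus-strand hits), `energy` (kT) and
#'   `kd_theoretical` (molar), sorted by position.
#' @export
scanSequence <- function(pwm, genome, kdThreshold = 14e-6,
                         circular = NULL) {
  stopifnot(is(pwm, "EnergyPWM"))
  if (is(genome, "TiledGenome")) {
    seqchar <- as.character(genomeSeq(genome))
    if (is.null(circular)) circular <- isCircularGenome(genome)
    seqn <- genome@genomeName
  } else {
    seqchar <- toupper(as.character(genome))
    if (is.null(circular)) circular <- FALSE
    seqn <- "seq"
  }
  w <- pwmWidth(pwm)
  L <- nchar(seqchar)
  if (L < w) stop("sequence shorter than the matrix width")
  scanchar <- if (circular) paste0(seqchar, substr(seqchar, 1L, w - 1L))
              else seqchar
  code <- match(strsplit(scanchar, "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(code)) stop("sequence contains a base outside {A,C,G,T}")
  nW <- if (circular) L else L - w + 1L

  hits_one <- function(E, strand) {
    e <- windowEnergies(code, E, nW)
    kd <- pwm@kdConsensus * exp(e)
    sel <- which(kd <= kdThreshold)
    list(start = sel, energy = e[sel], kd = kd[sel],
         strand = rep(strand, length(sel)))
  }
  fwd <- hits_one(pwm@energies, "+")
  rev <- hits_one(rcMatrix(pwm@energies), "-")
  start <- c(fwd$start, rev$start)
  if (!length(start)) {
    gr <- GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges())
    gr$word <- character(); gr$energy <- numeric()
    gr$kd_theoretical <- numeric()
    return(gr)
  }
  strand <- c(fwd$strand, rev$strand)
  words <- substring(scanchar, start, start + w - 1L)
  minus <- strand == "-"
  if (any(minus))
    words[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words[minus])))
  gr <- GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = start, width = w),
    strand = strand)
  gr$word <- words
  gr$energy <- c(fwd$energy, rev$energy)
  gr$kd_theoretical <- c(fwd$kd, rev$kd)
  sort(gr, ignore.strand = TRUE)
}

#' Scan the upstream window of every gene
#'
#' For each annotated gene, scans the `windowBp` bases 5' of the ORF start
#' (downstream end for minus-strand genes), both strands, and reports all
#' hits plus the per-gene minimum-K_D hit. On circular genomes windows wrap.
#'
#' @param pwm an [EnergyPWM-class].
#' @param genome a [TiledGenome-class] with gene annotation.
#' @param windowBp upstream window size in bp (default 200).
#' @param kdThreshold K_D cutoff in molar (default 14e-6).
#' @return list with `hits` (GRanges of all upstream hits, mcols include
#'   `gene_id`), `perGene` (data.frame of each gene's best hit; NA rows for
#'   genes without hits) and `nHits`.
#' @export
scanUpstream <- function(pwm, genome, windowBp = 200L,
                         kdThreshold = 14e-6) {
  stopifnot(is(genome, "TiledGenome"))
  genes <- geneRanges(genome)
  if (!length(genes)) stop("genome carries no gene annotation")
  L <- genomeLength(genome)
  seqchar <- as.character(genomeSeq(genome))
  circ <- isCircularGenome(genome)
  w <- pwmWidth(pwm)

  all_hits <- list()
  best <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    st <- as.character(GenomicRanges::strand(genes)[i])
    win_start <- if (st == "+")
      GenomicRanges::start(genes)[i] - windowBp
    else GenomicRanges::end(genes)[i] + 1L
    if (!circ) win_start <- max(1L, win_start)
    win_width <- min(windowBp, if (circ) windowBp else
      if (st == "+") GenomicRanges::start(genes)[i] - win_start
      else nchar(seqchar) - win_start + 1L)
    if (win_width < w) next
    sub <- subseqCircular(seqchar, win_start, win_width, L, circ)
    h <- scanSequence(pwm, sub, kdThreshold = kdThreshold,
                      circular = FALSE)
    if (!length(h)) next
    gstart <- wrapPos(win_start + GenomicRanges::start(h) - 1L, L)
    gr <- GenomicRanges::GRanges(
      seqnames = genome@genomeName,
      ranges = IRanges::IRanges(start = gstart, width = w),
      strand = GenomicRanges::strand(h))
    gr$word <- h$word
    gr$energy <- h$energy
    gr$kd_theoretical <- h$kd_theoretical
    gr$gene_id <- genes$gene_id[i]
    all_hits[[length(all_hits) + 1L]] <- gr
    b <- which.min(h$kd_theoretical)
    best[[i]] <- data.frame(
      gene_id = genes$gene_id[i], best_start = gstart[b],
      best_strand = as.character(GenomicRanges::strand(h))[b],
      best_word = h$word[b], best_kd = h$kd_theoretical[b])
  }
  hits <- if (length(all_hits)) do.call(c, all_hits) else
    GenomicRanges::GRanges()
  best <- best[!vapply(best, is.null, logical(1))]
  per_gene <- if (length(best))
    do.call(rbind, c(best, list(make.row.names = FALSE)))
  else
    data.frame(gene_id = character(), best_start = integer(),
               best_strand = character(),
               best_word = character(), best_kd = numeric())
  list(hits = hits, perGene = per_gene, nHits = length(hits))
}

#' Best (minimum-K_D) motif hit fully inside a region
#'
#' Ties are broken by smaller start, then plus strand.
#'
#' @param pwm an [EnergyPWM-class].
#' @param genome a [TiledGenome-class].
#' @param region a length-1 `GRanges` inside the genome.
#' @return A length-1 `GRanges` motif hit, or NULL when the region is
#'   shorter than the matrix width.
#' @export
bestHitInRegion <- function(pwm, genome, region) {
  stopifnot(is(genome, "TiledGenome"), length(region) == 1L)
  w <- pwmWidth(pwm)
  if (GenomicRanges::width(region) < w) return(NULL)
  L <- genomeLength(genome)
  sub <- subseqCircular(as.character(genomeSeq(genome)),
                        GenomicRanges::start(region),
                        GenomicRanges::width(region), L,
                        isCircularGenome(genome))
  h <- scanSequence(pwm, sub, kdThreshold = Inf, circular = FALSE)
  if (!length(h)) return(NULL)
  o <- order(h$kd_theoretical, GenomicRanges::start(h),
             as.character(GenomicRanges::strand(h)) != "+")
  h <- h[o[1L]]
  gstart <- wrapPos(GenomicRanges::start(region) +
                      GenomicRanges::start(h) - 1L, L)
  gr <- GenomicRanges::GRanges(
    seqnames = genome@genomeName,
    ranges = IRanges::IRanges(start = gstart, width = w),
    strand = GenomicRanges::strand(h))
  gr$word <- h$word
  gr$energy <- h$energy
  gr$kd_theoretical <- h$kd_theoretical
  gr
}

#' Does a region contain a motif below the K_D threshold?
#'
#' @inheritParams bestHitInRegion
#' @param kdThreshold inclusive K_D cutoff in molar (default 14e-6).
#' @return TRUE iff the region's best hit has K_D <= `kdThreshold`.
#' @export
motifPresenceFlag <- function(pwm, genome, region, kdThreshold = 14e-6) {
  h <- bestHitInRegion(pwm, genome, region)
  !is.null(h) && h$kd_theoretical <= kdThreshold
}
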