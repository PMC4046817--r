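#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats median rnorm runif setNames coef cor.test t.test sd var
#' @importFrom utils read.table write.table write.csv read.csv
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic ChIP-chip study design: a circular genome
#' tiled by overlapping probes, sonication-smeared enrichment signal over
#' planted binding sites, replicate ChIP scans plus one mock.
#'
#' @slot genomeLength genome size in bp.
#' @slot gcContent GC fraction in [0, 1].
#' @slot nGenes number of non-overlapping ORFs to place.
#' @slot probeStep bp between consecutive probe starts.
#' @slot probeLength probe length in bp.
#' @slot fragmentLength sonication smear half-width in bp; the enrichment
#'   kernel is triangular with this half-width.
#' @slot nReplicates number of ChIP replicates (a single mock is always added).
#' @slot noiseSd per-probe log2-ratio noise standard deviation.
#' @slot amplitude log2 peak height of a fully occupied site.
#' @slot proteinConc effective in vivo free protein concentration (molar),
#'   used to convert a site's dissociation constant into occupancy
#'   P / (K_D + P).
#' @slot seed integer seed governing all randomness of the generators.
#'
#' @export
setClass("SimConfig", representation(
  genomeLength = "integer", gcContent = "numeric", nGenes = "integer",
  probeStep = "integer", probeLength = "integer", fragmentLength = "integer",
  nReplicates = "integer", noiseSd = "numeric", amplitude = "numeric",
  proteinConc = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genomeLength <= 10L * object@fragmentLength)
    msg <- c(msg, "genomeLength must exceed 10 x fragmentLength")
  if (object@probeStep > object@fragmentLength / 2)
    msg <- c(msg, "probeStep must be <= fragmentLength / 2")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must lie in [0, 1]")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@proteinConc <= 0) msg <- c(msg, "proteinConc must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale version of a high-density tiling-array
#' study: a 200 kb circular genome tiled every 25 bp with 50-mer probes,
#' 500 bp sonication fragments, three ChIP replicates plus one mock, and
#' per-probe log2 noise of 0.25.
#'
#' @param genomeLength,gcContent,nGenes,probeStep,probeLength,fragmentLength
#'   see the slot documentation of [SimConfig-class].
#' @param nReplicates,noiseSd,amplitude,proteinConc,seed see
#'   [SimConfig-class].
#' @return A `SimConfig` object.
#' @examples
#' cfg <- simConfig(genomeLength = 50000, nGenes = 10, seed = 7)
#' @export
simConfig <- function(genomeLength = 200000L, gcContent = 0.5, nGenes = 60L,
                      probeStep = 25L, probeLength = 50L,
                      fragmentLength = 500L, nReplicates = 3L,
                      noiseSd = 0.25, amplitude = 2.5, proteinConc = 1e-6,
                      seed = 1L) {
  new("SimConfig",
      genomeLength = as.integer(genomeLength), gcContent = gcContent,
      nGenes = as.integer(nGenes), probeStep = as.integer(probeStep),
      probeLength = as.integer(probeLength),
      fragmentLength = as.integer(fragmentLength),
      nReplicates = as.integer(nReplicates), noiseSd = noiseSd,
      amplitude = amplitude, proteinConc = proteinConc,
      seed = as.integer(seed))
}

#' Annotated genome for tiling-array analysis
#'
#' A (usually circular) genome sequence together with its ORF annotation and
#' experimentally determined transcription start sites. Coordinates follow
#' GenomicRanges conventions (1-based, closed intervals).
#'
#' @slot genomeName single chromosome/replicon name.
#' @slot sequence a [Biostrings::DNAString] over {A,C,G,T}.
#' @slot circular logical; if TRUE, positions wrap modulo the length.
#' @slot genes a [GenomicRanges::GRanges] of ORFs with mcols `gene_id`.
#' @slot tss a [GenomicRanges::GRanges] of width-1 TSS positions with mcols
#'   `gene_id`.
#' @export
setClass("TiledGenome", representation(
  genomeName = "character", sequence = "DNAString", circular = "logical",
  genes = "GRanges", tss = "GRanges"
))

setValidity("TiledGenome", function(object) {
  msg <- character()
  if (length(object@genomeName) != 1L) msg <- c(msg, "genomeName must be length 1")
  if (length(object@genes)) {
    if (anyDuplicated(object@genes$gene_id)) msg <- c(msg, "gene ids must be unique")
    if (any(GenomicRanges::end(object@genes) > length(object@sequence)) ||
        any(GenomicRanges::start(object@genes) < 1L))
      msg <- c(msg, "gene coordinates outside the sequence")
  }
  bad <- Biostrings::letterFrequency(object@sequence, "ACGT")
  if (bad != length(object@sequence))
    msg <- c(msg, "sequence must contain only A, C, G, T")
  if (length(msg)) msg else TRUE
})

#' @describeIn TiledGenome-class genome sequence as a `DNAString`.
#' @param genome a `TiledGenome`.
#' @export
genomeSeq <- function(genome) genome@sequence

#' @describeIn TiledGenome-class genome length in bp.
#' @export
genomeLength <- function(genome) length(genome@sequence)

#' @describeIn TiledGenome-class ORF annotation as a `GRanges`.
#' @export
geneRanges <- function(genome) genome@genes

#' @describeIn TiledGenome-class TSS positions as a `GRanges`.
#' @export
tssRanges <- function(genome) genome@tss

#' @describeIn TiledGenome-class whether coordinates wrap.
#' @export
isCircularGenome <- function(genome) genome@circular

setMethod("show", "TiledGenome", function(object) {
  cat("TiledGenome '", object@genomeName, "': ",
      length(object@sequence), " bp",
      if (object@circular) " (circular)" else " (linear)",
      ", ", length(object@genes), " genes, ",
      length(object@tss), " TSSs\n", sep = "")
})

#' One tiling-array scan
#'
#' Per-probe log2 ratios of one two-channel hybridization (ChIP versus input
#' DNA), for one ChIP replicate, the mock ChIP, or an input-only scan.
#' Probes are a `GRanges`; mcols carry `probe_id`, `duplicate_index` and
#' `log2_ratio`. Technical duplicates (`duplicate_index` 1 and 2) are present
#' until [normalizeScan()] averages them.
#'
#' @slot sampleId sample label.
#' @slot role one of "chip-replicate", "mock", "input".
#' @slot probes `GRanges` of probe positions with the mcols above.
#' @slot processing character vector recording applied steps
#'   ("normalized", "smoothed").
#' @export
setClass("ProbeScan", representation(
  sampleId = "character", role = "character", probes = "GRanges",
  processing = "character"
))

setValidity("ProbeScan", function(object) {
  msg <- character()
  if (!object@role %in% c("chip-replicate", "mock", "input"))
    msg <- c(msg, "role must be chip-replicate, mock or input")
  need <- c("probe_id", "duplicate_index", "log2_ratio")
  if (!all(need %in% names(S4Vectors::mcols(object@probes))))
    msg <- c(msg, paste("probe mcols must include",
                        paste(need, collapse = ", ")))
  else {
    key <- paste(object@probes$probe_id, object@probes$duplicate_index)
    if (anyDuplicated(key))
      msg <- c(msg, "one value per (probe_id, duplicate_index) required")
    if (any(!is.finite(object@probes$log2_ratio)))
      msg <- c(msg, "log2 ratios must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProbeScan-class probe `GRanges` (sorted by start).
#' @param scan a `ProbeScan`.
#' @export
scanProbes <- function(scan) scan@probes

#' @describeIn ProbeScan-class sample label.
#' @export
scanSample <- function(scan) scan@sampleId

#' @describeIn ProbeScan-class scan role.
#' @export
scanRole <- function(scan) scan@role

setMethod("show", "ProbeScan", function(object) {
  cat("ProbeScan '", object@sampleId, "' [", object@role, "]: ",
      length(object@probes), " probe measurements",
      if (length(object@processing))
        paste0(" (", paste(object@processing, collapse = ", "), ")") else "",
      "\n", sep = "")
})

newProbeScan <- function(sampleId, role, probes, processing = character()) {
  o <- order(GenomicRanges::start(probes), probes$duplicate_index)
  new("ProbeScan", sampleId = sampleId, role = role, probes = probes[o],
      processing = processing)
}

#' Binding-energy position weight matrix
#'
#' A position-specific matrix of binding free-energy penalties in kT units,
#' relative to the consensus word: each row's minimum is zero and the
#' per-row minimizing bases spell the consensus. A word's theoretical
#' dissociation constant is `kdConsensus * exp(energy)` (Boltzmann factor on
#' additive per-position energies).
#'
#' @slot energies numeric matrix, width x 4, columns A, C, G, T, entries in
#'   kT, row minima 0.
#' @slot consensus the minimal-energy word.
#' @slot kdConsensus dissociation constant (molar) anchoring the consensus.
#' @export
setClass("EnergyPWM", representation(
  energies = "matrix", consensus = "character", kdConsensus = "numeric"
))

setValidity("EnergyPWM", function(object) {
  msg <- character()
  E <- object@energies
  if (ncol(E) != 4L || !identical(colnames(E), c("A", "C", "G", "T")))
    msg <- c(msg, "energies must have columns A, C, G, T")
  if (any(E < 0)) msg <- c(msg, "energies must be non-negative (min-zero rows)")
  if (any(abs(apply(E, 1L, min)) > 1e-9))
    msg <- c(msg, "each row's minimum must be 0")
  cons <- paste(colnames(E)[apply(E, 1L, which.min)], collapse = "")
  if (!identical(cons, object@consensus))
    msg <- c(msg, "consensus must spell the per-row argmin bases")
  if (object@kdConsensus <= 0) msg <- c(msg, "kdConsensus must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an energy PWM
#'
#' Rows are min-zero normalized (the per-row minimum is subtracted), which
#' shifts all word energies by a constant and leaves all K_D ratios intact.
#'
#' @param energies width x 4 numeric matrix of energy penalties (kT);
#'   columns A, C, G, T (set as such if unnamed).
#' @param kdConsensus consensus dissociation constant in molar.
#' @return An `EnergyPWM`.
#' @examples
#' E <- matrix(c(0, 1, 1, 1), nrow = 4, ncol = 4, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "C", "G", "T")))
#' energyPWM(E, kdConsensus = 63e-9)
#' @export
energyPWM <- function(energies, kdConsensus) {
  energies <- as.matrix(energies)
  if (is.null(colnames(energies))) colnames(energies) <- c("A", "C", "G", "T")
  energies <- energies[, c("A", "C", "G", "T"), drop = FALSE]
  energies <- sweep(energies, 1L, apply(energies, 1L, min))
  cons <- paste(colnames(energies)[apply(energies, 1L, which.min)],
                collapse = "")
  new("EnergyPWM", energies = energies, consensus = cons,
      kdConsensus = kdConsensus)
}

#' @describeIn EnergyPWM-class motif width in bp.
#' @param pwm an `EnergyPWM`.
#' @export
pwmWidth <- function(pwm) nrow(pwm@energies)

#' @describeIn EnergyPWM-class consensus word.
#' @export
consensusWord <- function(pwm) pwm@consensus

#' @describeIn EnergyPWM-class consensus dissociation constant (molar).
#' @export
kdConsensus <- function(pwm) pwm@kdConsensus

#' @describeIn EnergyPWM-class energy matrix (kT penalties).
#' @export
pwmEnergies <- function(pwm) pwm@energies

setMethod("show", "EnergyPWM", function(object) {
  cat("EnergyPWM: width ", nrow(object@energies),
      ", consensus ", object@consensus,
      ", consensus K_D ", format(object@kdConsensus, digits = 3),
      " M\n", sep = "")
})

#' Equilibrium binding isotherm
#'
#' A protein titration read out as fraction of probe DNA bound, e.g. from
#' EMSA band densitometry. Fit with [fitKd()].
#'
#' @slot concentrations protein concentrations (molar), strictly positive
#'   and sorted.
#' @slot fractionBound fraction bound per point, in [0, 1].
#' @slot fittedKd fitted dissociation constant (molar); length 0 before
#'   fitting.
#' @slot stderr standard error of the fitted K_D (molar).
#' @export
setClass("BindingIsotherm", representation(
  concentrations = "numeric", fractionBound = "numeric",
  fittedKd = "numeric", stderr = "numeric"
))

setValidity("BindingIsotherm", function(object) {
  msg <- character()
  if (length(object@concentrations) != length(object@fractionBound))
    msg <- c(msg, "concentrations and fractionBound lengths differ")
  if (any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be strictly positive")
  if (is.unsorted(object@concentrations))
    msg <- c(msg, "concentrations must be sorted increasing")
  if (any(object@fractionBound < 0 | object@fractionBound > 1))
    msg <- c(msg, "fractionBound must lie in [0, 1]")
  if (length(object@fittedKd) && object@fittedKd <= 0)
    msg <- c(msg, "fittedKd must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a binding isotherm
#'
#' @param concentrations protein concentrations (molar), sorted increasing.
#' @param fractionBound fraction bound per point.
#' @return A `BindingIsotherm`.
#' @export
bindingIsotherm <- function(concentrations, fractionBound) {
  new("BindingIsotherm", concentrations = as.numeric(concentrations),
      fractionBound = as.numeric(fractionBound),
      fittedKd = numeric(0), stderr = numeric(0))
}

setMethod("show", "BindingIsotherm", function(object) {
  cat("BindingIsotherm: ", length(object@concentrations), " points, [P] ",
      format(min(object@concentrations), digits = 3), "-",
      format(max(object@concentrations), digits = 3), " M", sep = "")
  if (length(object@fittedKd))
    cat("; fitted K_D ", format(object@fittedKd, digits = 3), " M (se ",
        format(object@stderr, digits = 2), ")", sep = "")
  cat("\n")
})
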