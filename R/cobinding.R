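#' Overlap two region sets for co-occupancy analysis
#'
#' Each TF-A region is first extended by `extendBp` on both ends (the span a
#' sonication fragment can report binding over), then every pair with at
#' least 1 bp intersection against the TF-B set is recorded. The relation is
#' `inside` when the extended A region lies within B (including identical
#' regions), `including` when B lies within A, otherwise `overlap`; the
#' overlap percentage is the fraction of the extended A region covered by B,
#' rounded to an integer.
#'
#' @param setA `GRanges` of TF-A (ChIP-enriched) regions.
#' @param setB `GRanges` of TF-B regions.
#' @param extendBp extension of each A region on both ends (default 500).
#' @return data.frame with one row per overlapping pair: indices and
#'   coordinates of both regions (A as extended), `relation` and
#'   `overlap_pct`.
#' @export
overlapRegions <- function(setA, setB, extendBp = 500L) {
  a_ext <- setA
  GenomicRanges::start(a_ext) <-
    pmax(1L, GenomicRanges::start(setA) - as.integer(extendBp))
  GenomicRanges::end(a_ext) <-
    GenomicRanges::end(setA) + as.integer(extendBp)
  hits <- GenomicRanges::findOverlaps(a_ext, setB, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(
      a_index = integer(), b_index = integer(), a_start = integer(),
      a_end = integer(), b_start = integer(), b_end = integer(),
      relation = character(), overlap_pct = integer()))
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  as_ <- GenomicRanges::start(a_ext)[qa]
  ae <- GenomicRanges::end(a_ext)[qa]
  bs <- GenomicRanges::start(setB)[qb]
  be <- GenomicRanges::end(setB)[qb]
  inter <- pmin(ae, be) - pmax(as_, bs) + 1L
  relation <- ifelse(as_ >= bs & ae <= be, "inside",
                     ifelse(bs >= as_ & be <= ae, "including", "overlap"))
  pct <- as.integer(round(100 * inter / (ae - as_ + 1L)))
  data.frame(a_index = qa, b_index = qb, a_start = as_, a_end = ae,
             b_start = bs, b_end = be, relation = relation,
             overlap_pct = pct)
}

#' Co-occupancy class of a shared binding region
#'
#' Class I: the region carries a TF-A motif and binds TF-A but not TF-B in
#' vitro. Class II: the symmetric case for TF-B. Class III: neither motif
#' nor in vitro binding for either factor. Any other flag combination (e.g.
#' both motifs present) is returned as `unclassified` so violations of the
#' expected inverse pattern surface rather than being forced into a class.
#'
#' @param motifA,invitroA,motifB,invitroB logical vectors (recycled to a
#'   common length): motif presence and in vitro binding for each factor.
#' @return factor with levels I, II, III, unclassified.
#' @export
assignCoClass <- function(motifA, invitroA, motifB, invitroB) {
  n <- max(length(motifA), length(invitroA), length(motifB),
           length(invitroB))
  motifA <- rep_len(motifA, n); invitroA <- rep_len(invitroA, n)
  motifB <- rep_len(motifB, n); invitroB <- rep_len(invitroB, n)
  if (anyNA(c(motifA, invitroA, motifB, invitroB)))
    stop("all four flags must be set before classification")
  cls <- rep("unclassified", n)
  cls[motifA & invitroA & !invitroB] <- "I"
  cls[motifB & invitroB & !invitroA] <- "II"
  cls[!motifA & !motifB & !invitroA & !invitroB] <- "III"
  factor(cls, levels = c("I", "II", "III", "unclassified"))
}

#' Gene-level occupancy class (I-V)
#'
#' Extends [assignCoClass()] with two classes for genes outside the shared
#' set: class IV, gene associated with a region bound by TF-A in vivo but
#' not co-bound by TF-B; class V, gene whose region binds TF-A in vitro but
#' shows no in vivo enrichment (the signature of a non-permissive locus).
#'
#' @param boundInVivoA logical: region called in the TF-A ChIP experiment.
#' @param coboundB logical: region also bound by TF-B in vivo.
#' @param motifA,invitroA,motifB,invitroB flags as in [assignCoClass()];
#'   only consulted for co-bound regions.
#' @return factor with levels I, II, III, IV, V, unclassified.
#' @export
geneClass <- function(boundInVivoA, coboundB, motifA = NA, invitroA = NA,
                      motifB = NA, invitroB = NA) {
  n <- max(length(boundInVivoA), length(coboundB), length(motifA),
           length(invitroA), length(motifB), length(invitroB))
  boundInVivoA <- rep_len(boundInVivoA, n)
  coboundB <- rep_len(coboundB, n)
  motifA <- rep_len(motifA, n); invitroA <- rep_len(invitroA, n)
  motifB <- rep_len(motifB, n); invitroB <- rep_len(invitroB, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (!boundInVivoA[i]) {
      if (isTRUE(invitroA[i])) "V" else "unclassified"
    } else if (!coboundB[i]) {
      "IV"
    } else {
      as.character(assignCoClass(motifA[i], invitroA[i], motifB[i],
                                 invitroB[i]))
    }
  }
  factor(out, levels = c("I", "II", "III", "IV", "V", "unclassified"))
}
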