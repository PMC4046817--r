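#' Normalize an array scan
#'
#' Averages technical duplicates per probe, then median-centres the log2
#' ratios so the array median is exactly zero. Median-centring is scale-free
#' and robust to the sparse enrichment signal; it preserves all differences
#' between probes.
#'
#' @param scan a [ProbeScan-class].
#' @return A [ProbeScan-class] with one value per probe and median 0.
#' @export
normalizeScan <- function(scan) {
  stopifnot(is(scan, "ProbeScan"))
  p <- scan@probes
  df <- data.frame(probe_id = p$probe_id, v = p$log2_ratio)
  first <- !duplicated(p$probe_id)
  means <- tapply(df$v, df$probe_id, mean)
  gr <- p[first]
  gr$log2_ratio <- as.numeric(means[gr$probe_id])
  gr$duplicate_index <- 1L
  med <- median(gr$log2_ratio)
  if (all(abs(gr$log2_ratio - gr$log2_ratio[1L]) < 1e-12))
    warning("all probe ratios identical; scan centred to zeros")
  gr$log2_ratio <- gr$log2_ratio - med
  newProbeScan(scan@sampleId, scan@role, gr,
               processing = unique(c(scan@processing, "normalized")))
}

#' Running-median smoothing of an array scan
#'
#' Replaces each probe's value by the median of all probe values whose
#' positions lie within +/- `halfWidthBp` of it. On circular genomes the
#' window wraps around the origin.
#'
#' @param scan a [ProbeScan-class] (typically normalized).
#' @param halfWidthBp window half-width in bp (default 400).
#' @param circular whether the genome wraps.
#' @param genomeLength genome length in bp; required when `circular` and
#'   defaulting to the largest probe end.
#' @return A smoothed [ProbeScan-class].
#' @export
smoothScan <- function(scan, halfWidthBp = 400, circular = TRUE,
                       genomeLength = NULL) {
  stopifnot(is(scan, "ProbeScan"))
  p <- scan@probes
  if (any(p$duplicate_index != 1L)) {
    first <- !duplicated(p$probe_id)
    means <- tapply(p$log2_ratio, p$probe_id, mean)
    p <- p[first]
    p$log2_ratio <- as.numeric(means[p$probe_id])
    p$duplicate_index <- 1L
  }
  pos <- GenomicRanges::start(p)
  o <- order(pos)
  pos <- pos[o]
  v <- p$log2_ratio[o]
  n <- length(pos)
  if (is.null(genomeLength)) genomeLength <- max(GenomicRanges::end(p))
  if (circular) {
    ext_pos <- c(pos - genomeLength, pos, pos + genomeLength)
    ext_v <- rep(v, 3L)
    off <- n
  } else {
    ext_pos <- pos
    ext_v <- v
    off <- 0L
  }
  lo <- findInterval(pos - halfWidthBp - 0.5, ext_pos) + 1L
  hi <- findInterval(pos + halfWidthBp + 0.5, ext_pos)
  sm <- vapply(seq_len(n), function(i)
    median(ext_v[lo[i]:hi[i]]), numeric(1))
  gr <- p[o]
  gr$log2_ratio <- sm
  newProbeScan(scan@sampleId, scan@role, gr,
               processing = unique(c(scan@processing, "smoothed")))
}

#' Call candidate enriched regions on one smoothed scan
#'
#' Finds maximal runs of probes with smoothed log2 ratio at or above `y0`,
#' allowing gaps of at most `maxGapBp` between consecutive qualifying probe
#' starts, and keeps runs of at least `minProbes` probes. A region spans the
#' first probe's start to the last probe's end. On circular genomes a run
#' crossing the origin is reported as a single region whose end exceeds the
#' genome length (coordinates modulo the length).
#'
#' @param scan a smoothed, normalized [ProbeScan-class].
#' @param y0 log2-ratio call threshold (default 1).
#' @param minProbes minimum qualifying probes per region (default 3).
#' @param maxGapBp maximum gap between consecutive qualifying probe starts;
#'   defaults to twice the median probe spacing.
#' @param circular whether the genome wraps.
#' @param genomeLength genome length in bp (needed for circular calls);
#'   defaults to the largest probe end.
#' @return A `GRanges` of regions with mcols `max_value` (maximum smoothed
#'   log2 within the region) and `n_probes`.
#' @export
callRegions <- function(scan, y0 = 1, minProbes = 3L, maxGapBp = NULL,
                        circular = TRUE, genomeLength = NULL) {
  stopifnot(is(scan, "ProbeScan"))
  p <- scan@probes
  o <- order(GenomicRanges::start(p))
  p <- p[o]
  pos <- GenomicRanges::start(p)
  ends <- GenomicRanges::end(p)
  v <- p$log2_ratio
  if (is.null(maxGapBp)) {
    step <- if (length(pos) > 1L) median(diff(pos)) else 1
    maxGapBp <- 2 * step
  }
  if (is.null(genomeLength)) genomeLength <- max(ends)

  q <- which(v >= y0)
  empty <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    max_value = numeric(), n_probes = integer())
  if (!length(q)) return(empty)

  gap <- diff(pos[q])
  grp <- cumsum(c(1L, as.integer(gap > maxGapBp)))
  runs <- split(q, grp)

  # merge a run touching the end with one touching the start (wrap)
  if (circular && length(runs) > 1L) {
    first_run <- runs[[1L]]
    last_run <- runs[[length(runs)]]
    wrap_gap <- pos[first_run[1L]] + genomeLength -
      pos[last_run[length(last_run)]]
    if (wrap_gap <= maxGapBp) {
      runs[[length(runs)]] <- c(last_run, first_run)
      runs <- runs[-1L]
    }
  }

  keep <- vapply(runs, length, integer(1)) >= minProbes
  runs <- runs[keep]
  if (!length(runs)) return(empty)

  seqn <- as.character(GenomicRanges::seqnames(p))[1L]
  recs <- lapply(runs, function(idx) {
    s <- pos[idx[1L]]
    e <- ends[idx[length(idx)]]
    if (e < s) e <- e + genomeLength  # wrapped run
    list(start = s, end = e, max_value = max(v[idx]),
         n_probes = length(idx))
  })
  gr <- GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(
      start = vapply(recs, `[[`, numeric(1), "start"),
      end = vapply(recs, `[[`, numeric(1), "end")))
  gr$max_value <- unname(vapply(recs, `[[`, numeric(1), "max_value"))
  gr$n_probes <- unname(vapply(recs, `[[`, integer(1), "n_probes"))
  sort(gr)
}

# max smoothed value of a scan over a region (NA if no probe overlaps)
regionMax <- function(scan, region) {
  p <- scan@probes
  hits <- GenomicRanges::findOverlaps(region, p)
  vapply(seq_along(region), function(i) {
    idx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (!length(idx)) return(NA_real_)
    max(p$log2_ratio[idx])
  }, numeric(1))
}

#' Combine replicate region calls with a mock-ChIP filter
#'
#' A candidate region is the intersection of overlapping calls across all
#' replicates (the strictest reading of a replicate-consistency rule). A
#' candidate is retained only if every replicate's maximum smoothed log2
#' ratio over it exceeds `log2(foldThreshold)` and the mock scan's maximum
#' over it stays below `y0`. Fold enrichment is recorded as 2 to the mean of
#' the per-replicate maxima.
#'
#' @param replicateRegions list of `GRanges` from [callRegions()], one per
#'   ChIP replicate.
#' @param replicateScans list of the corresponding smoothed, normalized
#'   [ProbeScan-class] objects.
#' @param mockScan smoothed, normalized mock [ProbeScan-class].
#' @param foldThreshold per-replicate fold-enrichment requirement
#'   (default 2).
#' @param y0 mock rejection threshold on the smoothed log2 scale
#'   (default 1).
#' @param keepAll if TRUE, return all candidates with pass/fail flags
#'   instead of only the retained regions.
#' @return A `GRanges` of enriched regions with mcols `fold_enrichment`,
#'   `n_probes`, per-replicate maxima (`rep_max.*`), `mock_max` and
#'   `passed_mock_filter`.
#' @export
combineReplicates <- function(replicateRegions, replicateScans, mockScan,
                              foldThreshold = 2, y0 = 1, keepAll = FALSE) {
  if (length(replicateRegions) == 0L)
    stop("at least one replicate region set is required")
  if (length(replicateRegions) != length(replicateScans))
    stop("replicateRegions and replicateScans lengths differ")
  if (length(replicateRegions) < 2L)
    warning("replicate-consistency filtering with a single replicate")

  cand <- Reduce(GenomicRanges::intersect, replicateRegions)
  if (!length(cand)) {
    cand$fold_enrichment <- numeric()
    cand$n_probes <- integer()
    cand$mock_max <- numeric()
    cand$passed_mock_filter <- logical()
    return(cand)
  }
  repmax <- vapply(replicateScans, regionMax, numeric(length(cand)),
                   region = cand)
  repmax <- matrix(repmax, nrow = length(cand))
  mockmax <- regionMax(mockScan, cand)
  fold_ok <- apply(repmax > log2(foldThreshold), 1L, all)
  mock_ok <- is.na(mockmax) | mockmax < y0
  n_probes <- GenomicRanges::countOverlaps(
    cand, replicateScans[[1L]]@probes)

  cand$fold_enrichment <- 2^rowMeans(repmax)
  for (r in seq_len(ncol(repmax)))
    S4Vectors::mcols(cand)[[sprintf("rep_max.%d", r)]] <- repmax[, r]
  cand$n_probes <- n_probes
  cand$mock_max <- mockmax
  cand$passed_mock_filter <- mock_ok
  cand$passed_fold_filter <- fold_ok
  if (keepAll) cand else cand[fold_ok & mock_ok]
}

#' ChIP-qPCR enrichment folds normalized to a spiked reference
#'
#' For each target t, fold = 2^[(Cq_input,t - Cq_IP,t) -
#' (Cq_input,ref - Cq_IP,ref)]: the IP/input abundance ratio of the target
#' corrected by the same ratio for a non-enriched spiked reference fragment.
#'
#' @param cq data.frame with columns `target`, `fraction` ("IP" or
#'   "input") and `cq`; technical replicates are averaged.
#' @param refTarget name of the spiked reference target (default "spike").
#' @return Named numeric vector of enrichment folds per non-reference
#'   target.
#' @export
qpcrEnrichment <- function(cq, refTarget = "spike") {
  stopifnot(all(c("target", "fraction", "cq") %in% names(cq)))
  cell <- function(target, fraction) {
    x <- cq$cq[cq$target == target & cq$fraction == fraction]
    if (!length(x))
      stop("missing Cq cell: target '", target, "', fraction '",
           fraction, "'")
    mean(x)
  }
  ref_d <- cell(refTarget, "input") - cell(refTarget, "IP")
  targets <- setdiff(unique(cq$target), refTarget)
  vapply(setNames(targets, targets), function(t)
    2^((cell(t, "input") - cell(t, "IP")) - ref_d), numeric(1))
}

#' Rank correlation between array and qPCR enrichment folds
#'
#' @param chipFolds,qpcrFolds paired fold-enrichment vectors (n >= 5).
#' @return list with `rho` (Spearman) and `p` (two-sided).
#' @export
validateCorrelation <- function(chipFolds, qpcrFolds) {
  stopifnot(length(chipFolds) == length(qpcrFolds))
  if (length(chipFolds) < 5L)
    stop("at least 5 paired folds are required")
  ct <- suppressWarnings(
    cor.test(chipFolds, qpcrFolds, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
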