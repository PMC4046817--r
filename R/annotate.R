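locationCategories <- c("intergenic_only", "intergenic_plus_one_orf",
                        "intergenic_plus_multiple_orfs",
                        "intragenic_single", "intragenic_spanning")

# split a region whose end runs past the genome length into in-range pieces
unwrapRegion <- function(region, genomeLength) {
  s <- GenomicRanges::start(region)
  e <- GenomicRanges::end(region)
  seqn <- as.character(GenomicRanges::seqnames(region))
  if (e <= genomeLength) return(region)
  GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = c(s, 1L),
                              end = c(genomeLength, e - genomeLength)))
}

#' Classify enriched regions by genomic context
#'
#' A region overlapping at least one intergenic base falls in one of the
#' `intergenic_*` categories according to how many ORFs it also overlaps
#' (0, 1, or 2 and more); a region lying entirely within coding sequence is
#' `intragenic_single` (one ORF) or `intragenic_spanning` (two or more).
#' The five categories are mutually exclusive and exhaustive.
#'
#' @param regions a `GRanges` of enriched regions.
#' @param genes a `GRanges` ORF annotation (mcols `gene_id`).
#' @param genomeLength genome length in bp, used to resolve regions that
#'   wrap past the origin; defaults to the largest annotated end.
#' @return factor of categories, one per region, levels as above.
#' @export
classifyLocation <- function(regions, genes, genomeLength = NULL) {
  if (!length(genes)) stop("empty gene annotation")
  if (is.null(genomeLength))
    genomeLength <- max(GenomicRanges::end(genes),
                        GenomicRanges::end(regions))
  red <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  cats <- vapply(seq_along(regions), function(i) {
    pieces <- unwrapRegion(regions[i], genomeLength)
    genic <- sum(GenomicRanges::width(
      GenomicRanges::intersect(pieces, red, ignore.strand = TRUE)))
    total <- sum(GenomicRanges::width(pieces))
    n_orf <- length(unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(pieces, genes, ignore.strand = TRUE))))
    if (genic < total) {
      if (n_orf == 0L) "intergenic_only"
      else if (n_orf == 1L) "intergenic_plus_one_orf"
      else "intergenic_plus_multiple_orfs"
    } else {
      if (n_orf <= 1L) "intragenic_single" else "intragenic_spanning"
    }
  }, character(1))
  factor(cats, levels = locationCategories)
}

#' Two-way summary of location categories
#'
#' Collapses the five-way classification into the coarse split between
#' regions touching intergenic sequence and purely intragenic regions.
#'
#' @param categories factor from [classifyLocation()].
#' @return Named integer vector with counts `intergenic` and `intragenic`.
#' @export
locationSummary <- function(categories) {
  inter <- grepl("^intergenic", as.character(categories))
  c(intergenic = sum(inter), intragenic = sum(!inter))
}

# integer region centre: floor midpoint, ties to the lower coordinate
regionCenter <- function(regions) {
  (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L
}

#' Signed distance from region centres to the closest TSS
#'
#' Distance is the minimal circular distance from the region's integer
#' centre (floor midpoint) to any TSS; the sign is orientation-corrected so
#' that a negative value means the centre lies 5' (upstream) of the gene.
#'
#' @param regions a `GRanges` of regions.
#' @param tss a `GRanges` of width-1 TSS positions with strand and mcols
#'   `gene_id`.
#' @param genomeLength genome length in bp for circular distances.
#' @param circular whether distances wrap (default TRUE).
#' @return data.frame with columns `gene_id` and `tss_distance` (signed
#'   bp), one row per region.
#' @export
distanceToTss <- function(regions, tss, genomeLength = NULL,
                          circular = TRUE) {
  if (!length(tss)) stop("at least one TSS is required")
  if (is.null(genomeLength))
    genomeLength <- max(GenomicRanges::end(tss),
                        GenomicRanges::end(regions))
  centers <- wrapPos(regionCenter(regions), genomeLength)
  tpos <- GenomicRanges::start(tss)
  tstrand <- as.character(GenomicRanges::strand(tss))
  out <- lapply(centers, function(cc) {
    d <- circSignedDiff(cc, tpos, genomeLength, circular)
    j <- which.min(abs(d))
    signed <- if (tstrand[j] == "-") -d[j] else d[j]
    data.frame(gene_id = tss$gene_id[j], tss_distance = signed)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Annotate enriched regions with context and TSS distance
#'
#' @param regions a `GRanges` of enriched regions.
#' @param genome a [TiledGenome-class] carrying gene and TSS annotation.
#' @return data.frame with region coordinates, location category, closest
#'   gene and signed TSS distance.
#' @export
annotatePeaks <- function(regions, genome) {
  stopifnot(is(genome, "TiledGenome"))
  L <- genomeLength(genome)
  cat <- classifyLocation(regions, geneRanges(genome), L)
  td <- distanceToTss(regions, tssRanges(genome), L,
                      isCircularGenome(genome))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    center = regionCenter(regions),
    location_category = cat,
    closest_gene_id = td$gene_id,
    tss_distance = td$tss_distance)
}
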