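#' Read and write pipeline file formats
#'
#' All on-disk conventions are fixed here and nowhere else: BED and the
#' probe-table `start` column are 0-based half-open, GFF3 is 1-based
#' inclusive. In memory everything is a `GRanges` (1-based, closed), so
#' conversions are lossless and confined to this layer.
#'
#' @name io-formats
NULL

#' @describeIn io-formats write the genome sequence as FASTA.
#' @param genome a [TiledGenome-class].
#' @param path file path.
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome@sequence)
  names(ss) <- genome@genomeName
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @describeIn io-formats write ORFs (`gene`) and TSSs
#'   (`transcription_start_site`) as GFF3.
#' @export
writeAnnotationGFF3 <- function(genome, path) {
  g <- genome@genes
  g$type <- "gene"
  g$ID <- g$gene_id
  t <- genome@tss
  t$type <- "transcription_start_site"
  t$ID <- paste0("tss_", t$gene_id)
  all <- c(g, t)
  all$source <- "ChIPtiling"
  rtracklayer::export.gff3(all, path)
  invisible(path)
}

#' @describeIn io-formats read a FASTA genome, optionally with a GFF3
#'   annotation, into a [TiledGenome-class].
#' @param gff3Path optional GFF3 annotation path.
#' @param circular whether coordinates wrap (default TRUE).
#' @export
readGenomeFasta <- function(path, gff3Path = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-replicon FASTA, found ", length(ss), " records")
  name <- sub("\\s.*$", "", names(ss)[1])
  genes <- GenomicRanges::GRanges()
  tss <- GenomicRanges::GRanges()
  if (!is.null(gff3Path)) {
    ann <- readAnnotationGFF3(gff3Path)
    genes <- ann$genes
    tss <- ann$tss
    chroms <- unique(c(as.character(GenomicRanges::seqnames(genes)),
                       as.character(GenomicRanges::seqnames(tss))))
    if (length(chroms) && !all(chroms == name))
      stop("mixed chromosome names: FASTA has '", name, "', GFF3 has '",
           paste(setdiff(chroms, name), collapse = "', '"), "'")
  }
  new("TiledGenome", genomeName = name, sequence = ss[[1L]],
      circular = circular, genes = genes, tss = tss)
}

#' @describeIn io-formats read a GFF3 annotation; returns a list with
#'   `genes` and `tss` GRanges (mcols `gene_id`).
#' @export
readAnnotationGFF3 <- function(path) {
  ann <- rtracklayer::import(path, format = "gff3")
  genes <- ann[ann$type == "gene"]
  tss <- ann[ann$type == "transcription_start_site"]
  genes$gene_id <- genes$ID
  tss$gene_id <- sub("^tss_", "", tss$ID)
  keep <- c("gene_id")
  S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[, keep, drop = FALSE]
  S4Vectors::mcols(tss) <- S4Vectors::mcols(tss)[, keep, drop = FALSE]
  list(genes = genes, tss = tss)
}

#' @describeIn io-formats write a region set (or probe map) as 6-column BED.
#' @param regions a `GRanges`; names column taken from mcols `name`,
#'   `probe_id` or `region_id` if present.
#' @export
writeRegionsBed <- function(regions, path) {
  gr <- regions
  mc <- S4Vectors::mcols(gr)
  nm <- intersect(c("name", "probe_id", "region_id"), names(mc))
  gr$name <- if (length(nm)) as.character(mc[[nm[1L]]]) else
    sprintf("region_%04d", seq_along(gr))
  gr$score <- if ("fold_enrichment" %in% names(mc))
    mc$fold_enrichment else 0
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("name", "score")]
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @describeIn io-formats read a BED region set into a `GRanges`.
#' @export
readRegionsBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @describeIn io-formats write one array scan as a probe TSV with 0-based
#'   half-open coordinates (columns probe_id, chrom, start, end,
#'   duplicate_index, log2_ratio).
#' @param scan a [ProbeScan-class].
#' @export
writeProbeTable <- function(scan, path) {
  p <- scan@probes
  df <- data.frame(
    probe_id = p$probe_id,
    chrom = as.character(GenomicRanges::seqnames(p)),
    start = GenomicRanges::start(p) - 1L,
    end = GenomicRanges::end(p),
    duplicate_index = p$duplicate_index,
    log2_ratio = p$log2_ratio)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn io-formats read a probe TSV into a [ProbeScan-class];
#'   malformed numeric fields are reported with their row number.
#' @param sampleId sample label for the scan.
#' @param role scan role: "chip-replicate", "mock" or "input".
#' @export
readProbeTable <- function(path, sampleId = basename(path),
                           role = "chip-replicate") {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "character", "character", "character"))
  need <- c("probe_id", "chrom", "start", "log2_ratio")
  if (!all(need %in% names(df)))
    stop("probe table must have columns ", paste(need, collapse = ", "))
  num <- suppressWarnings(as.numeric(df$log2_ratio))
  if (anyNA(num))
    stop("non-numeric log2_ratio in probe table row ",
         which(is.na(num))[1L], " of ", path)
  start0 <- suppressWarnings(as.integer(df$start))
  if (anyNA(start0))
    stop("non-numeric start in probe table row ",
         which(is.na(start0))[1L], " of ", path)
  if (length(unique(df$chrom)) > 1L)
    stop("mixed chromosome names in ", path, ": ",
         paste(unique(df$chrom), collapse = ", "))
  end <- if ("end" %in% names(df)) as.integer(df$end) else start0 + 1L
  dup <- if ("duplicate_index" %in% names(df))
    as.integer(df$duplicate_index) else 1L
  probes <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end))
  probes$probe_id <- df$probe_id
  probes$duplicate_index <- dup
  probes$log2_ratio <- num
  newProbeScan(sampleId, role, probes)
}

#' @describeIn io-formats read a binding-energy matrix TSV. The file starts
#'   with a header line `# kd_consensus=<molar>`, then a column header
#'   `A C G T` and one row of kT penalties per motif position. Rows are
#'   min-zero normalized on read (a per-row constant shift, leaving all K_D
#'   ratios unchanged). A width other than 15 is accepted with a warning.
#' @export
readEnergyMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kd_line <- grep("kd_consensus", hdr, value = TRUE)
  if (!length(kd_line))
    stop("energy matrix file lacks a '# kd_consensus=<value>' header line")
  kd <- as.numeric(sub(".*kd_consensus\\s*=\\s*", "", kd_line[1L]))
  if (!is.finite(kd) || kd <= 0)
    stop("invalid kd_consensus in energy matrix header")
  body <- lines[!grepl("^#", lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t")
  if (!all(c("A", "C", "G", "T") %in% names(tab)))
    stop("energy matrix must have columns A, C, G, T")
  E <- as.matrix(tab[, c("A", "C", "G", "T")])
  if (nrow(E) != 15L)
    warning("energy matrix width is ", nrow(E), " (15 is typical)")
  energyPWM(E, kdConsensus = kd)
}

#' @describeIn io-formats write an [EnergyPWM-class] in the format read by
#'   [readEnergyMatrix()].
#' @param pwm an `EnergyPWM`.
#' @export
writeEnergyMatrix <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kd_consensus=%.6g", pwm@kdConsensus), con)
  df <- as.data.frame(pwm@energies)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @describeIn io-formats read a two-factor co-binding table (TSV with
#'   columns target, start, end, relation, motif_a, motif_b and optionally
#'   class). Motif flags use "+" for present; "-" and annotated variants such
#'   as "-*" count as absent, with the raw string kept in `motif_a_raw` /
#'   `motif_b_raw`.
#' @export
readCoBindingTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  need <- c("target", "start", "end", "relation", "motif_a", "motif_b")
  if (!all(need %in% names(df)))
    stop("co-binding table must have columns ",
         paste(need, collapse = ", "))
  out <- data.frame(
    target = df$target,
    start = as.integer(df$start),
    end = as.integer(df$end),
    relation = df$relation,
    motif_a = df$motif_a == "+",
    motif_b = df$motif_b == "+",
    motif_a_raw = df$motif_a,
    motif_b_raw = df$motif_b)
  if ("class" %in% names(df)) out$class <- df$class
  out
}
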